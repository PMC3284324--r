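test_that("ibs_kinship computes allele-sharing similarity", {
  G <- make_geno(rbind(c(0, 1, 2, 1),
                       c(0, 1, 2, 1),     # identical to sample 1
                       c(2, 1, 0, 1)))    # opposite homozygotes where possible
  K <- ibs_kinship(G)
  expect_equal(K[1, 2], 1)
  expect_true(isSymmetric(K))
  expect_equal(unname(diag(K)), rep(1, 3))
  # AA vs AB at every SNP -> half the alleles shared
  G2 <- make_geno(rbind(rep(0, 10), rep(1, 10)))
  expect_equal(ibs_kinship(G2)[1, 2], 0.5)
  # fully opposite homozygotes -> 0
  G3 <- make_geno(rbind(rep(0, 10), rep(2, 10)))
  expect_equal(ibs_kinship(G3)[1, 2], 0)
})

test_that("ibs_kinship is equivariant under sample permutation", {
  fx <- tiny_fixture()
  G <- fx$G[1:20, ]
  K <- ibs_kinship(G)
  perm <- with_seed_local(2, sample(20))
  Kp <- ibs_kinship(G[perm, ])
  expect_equal(unname(Kp), unname(K[perm, perm]))
})

test_that("pairwise_identity flags duplicates and matches a brute-force loop", {
  fx <- tiny_fixture()
  G <- fx$G[1:12, ]
  g <- rbind(G$geno, G$geno[3, ])   # plant an exact duplicate of sample 3
  Gd <- make_geno(g, pos = G$map$pos, chrom = G$map$chrom,
                  ids = c(G$sample_ids, "dup"))
  pid <- pairwise_identity(Gd)
  expect_true(any(pid$flagged$identity == 1 &
                  pid$flagged$sample_b == "dup"))
  # independent oracle: nested loop over pairs
  n <- n_samples(Gd)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, mean(Gd$geno[i, ] == Gd$geno[j, ]))
  expect_equal(pid$mean, mean(vals))
  expect_equal(pid$min, min(vals))
  expect_equal(pid$max, max(vals))
  # two samples differing everywhere
  Gopp <- make_geno(rbind(rep(0, 5), rep(2, 5)))
  expect_equal(pairwise_identity(Gopp, threshold = 2)$mean, 0)
})

test_that("ld_pairs emits windowed within-chromosome r2", {
  v <- c(0, 1, 2, 0, 1, 2, 1, 0)
  G <- geno_matrix(cbind(v, v, rev(v), v),
                   data.frame(snp_id = c("a", "b", "c", "d"),
                              chrom = c("1", "1", "1", "1"),
                              pos = c(1e6, 2e6, 30e6, 70e6)))
  pairs <- ld_pairs(G, window = 5e7)
  ab <- pairs[pairs$snp_a == "a" & pairs$snp_b == "b", ]
  expect_equal(ab$r2, 1)                    # duplicated column
  expect_false(any(pairs$snp_a == "a" & pairs$snp_b == "d"))  # 69 Mb apart
  expect_true(all(pairs$distance < 5e7))
  # monomorphic SNPs are skipped
  Gm <- make_geno(cbind(v, rep(2, 8)))
  expect_equal(nrow(ld_pairs(Gm)), 0)
})

test_that("r2 of independent SNPs has null mean ~ 1/n", {
  n <- 5000
  G <- with_seed_local(31,
    make_geno(matrix(stats::rbinom(n * 60, 2, 0.4), n, 60),
              pos = seq_len(60) * 1e4))
  pairs <- ld_pairs(G)
  expect_lt(abs(mean(pairs$r2) - 1 / n), 0.5 / n)
})

test_that("ld_decay finds the crossing of a step curve and reports sentinels", {
  set.seed(77)
  d <- runif(4000, 0, 5e6)
  step <- data.frame(snp_a = "x", snp_b = "y", chrom = "1", distance = d,
                     r2 = ifelse(d < 1e6, 1, 0))
  dec <- ld_decay(step, bin_width = 1e4)
  expect_true(dec$reached)
  expect_equal(dec$decay_radius, 1e6, tolerance = 0.15e6)
  flat <- transform(step, r2 = 0.9)
  dec2 <- ld_decay(flat, bin_width = 1e4)
  expect_false(dec2$reached)
  expect_true(is.na(dec2$decay_radius))
  expect_error(ld_decay(step[1:50, ]), ">= 100")
})

test_that("snp_entropy is the standard symmetric Shannon form", {
  expect_equal(snp_entropy(0.5), log(2))
  expect_equal(snp_entropy(0), 0)
  expect_equal(snp_entropy(0.2), 0.5004, tolerance = 1e-4)
  p <- seq(0, 0.5, by = 0.01)
  expect_equal(snp_entropy(p), snp_entropy(1 - p))   # symmetry
  expect_true(all(diff(snp_entropy(p)) > 0))          # increasing on [0, .5]
  expect_error(snp_entropy(1.2), "0, 1")
})

test_that("entropy_windows tiles chromosomes and matches a recount", {
  fx <- tiny_fixture()
  ew <- entropy_windows(fx$G, window = 4e6)
  maf <- compute_maf(fx$G)
  for (i in with_seed_local(5, sample(nrow(ew), 10))) {
    j <- fx$G$map$chrom == ew$chrom[i] & fx$G$map$pos >= ew$start[i] &
      fx$G$map$pos <= ew$end[i]
    if (!any(j)) expect_true(is.na(ew$mean_entropy[i]))
    else expect_equal(ew$mean_entropy[i], mean(snp_entropy(maf[j])))
  }
  # all SNPs at MAF 0.5 -> every occupied window at log 2
  G5 <- make_geno(matrix(rep(c(0, 2), 10), 2, 10, byrow = FALSE),
                  pos = seq_len(10) * 1e6)
  ew5 <- entropy_windows(G5)
  expect_true(all(ew5$mean_entropy[ew5$n_snps > 0] == log(2)))
  # monomorphic chromosome -> zero entropy
  G0 <- make_geno(matrix(2, 4, 6), pos = seq_len(6) * 1e5)
  expect_true(all(entropy_windows(G0)$mean_entropy == 0))
})

test_that("cluster_samples separates constructed families", {
  K <- family_kinship(n_per = 5, within = 0.9)
  cl <- cluster_samples(K)
  grp <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(grp[1:5])), 1)
  expect_equal(length(unique(grp[6:10])), 1)
  expect_false(grp[1] == grp[6])
  # identical samples merge at height 0
  K2 <- matrix(1, 2, 2)
  expect_equal(cluster_samples(K2)$hclust$height, 0)
  # single leaf degenerate case
  expect_equal(cluster_samples(matrix(1, 1, 1))$order, 1L)
})

test_that("LD decay radius grows as the founder pool shrinks", {
  radius <- function(nf, seed) {
    G <- simulate_population(sim_preset("nmri-like", seed = seed,
                                        n_founders = nf,
                                        n_snps_per_chrom = 250,
                                        n_chroms = 3))
    G <- impute_missing(filter_snps(G)$G, seed = 1)
    d <- ld_decay(ld_pairs(G))
    if (d$reached) d$decay_radius else Inf
  }
  for (seed in c(1, 2)) {
    r <- vapply(c(10, 25, 80), radius, numeric(1), seed = seed)
    expect_true(all(diff(r) <= 0))   # more drift (smaller pool) -> longer LD
  }
})
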