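test_that("simulate_population is deterministic and validates its config", {
  cfg <- sim_preset("tiny", seed = 11, n_snps_per_chrom = 60, n_samples = 20)
  G1 <- simulate_population(cfg)
  G2 <- simulate_population(cfg)
  expect_identical(G1$geno, G2$geno)
  expect_identical(G1$map, G2$map)
  expect_true(all(G1$geno %in% c(0, 1, 2)))
  # positions strictly increasing within chromosome
  for (ch in unique(G1$map$chrom))
    expect_true(all(diff(G1$map$pos[G1$map$chrom == ch]) > 0))
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(maf_floor = 0.7), "maf_floor")
})

test_that("opposite-homozygous founders with no pool generations give all-het offspring", {
  m <- 30
  haps <- rbind(matrix(0L, 2, m), matrix(1L, 2, m))   # founder1 0|0, founder2 1|1
  cfg <- sim_config(n_founders = 2, n_samples = 12, n_snps_per_chrom = m,
                    n_chroms = 1, n_generations = 0, recomb_rate = 1,
                    seed = 5)
  G <- simulate_population(cfg, founder_haps = list(haps))
  expect_true(all(G$geno == 1))
})

test_that("simulated founder pool leaves the documented statistical footprint", {
  fx <- tiny_fixture()
  maf <- compute_maf(fx$G)
  # broad spectrum: post-filter mean MAF in a plausible outbred band
  expect_gt(mean(maf), 0.10)
  expect_lt(mean(maf), 0.40)
  # mild family structure: known sib families more similar than non-sibs
  for (seed in c(1, 2, 3)) {
    G <- simulate_population(sim_preset("tiny", seed = seed,
                                        n_snps_per_chrom = 120))
    fam <- attr(G, "families")
    K <- ibs_kinship(impute_missing(G, seed = 1))
    same <- outer(fam, fam, "==") & upper.tri(K)
    diff_fam <- (!outer(fam, fam, "==")) & upper.tri(K)
    expect_gt(mean(K[same]), mean(K[diff_fam]))
  }
})

test_that("nmri-like preset LD decays through r2 = 0.5 on the ~1 Mb scale", {
  # scaled-down copy of the preset's demographic history (fewer SNPs/chroms)
  G <- simulate_population(sim_preset("nmri-like", seed = 7,
                                      n_snps_per_chrom = 300, n_chroms = 4))
  G <- impute_missing(filter_snps(G)$G, seed = 1)
  dec <- ld_decay(ld_pairs(G))
  expect_true(dec$reached)
  expect_gt(dec$decay_radius, 0.5e6)
  expect_lt(dec$decay_radius, 2e6)
})

test_that("simulate_trait degenerate and calibrated cases behave", {
  # pure noise: iid normal with variance sigma_e2
  Gbig <- make_geno(matrix(rep(c(0, 1, 2), length.out = 5000), ncol = 1))
  tr <- simulate_trait(Gbig, K = NULL,
                       truth_record(sigma_g2 = 0, sigma_e2 = 2.5), seed = 9)
  expect_equal(stats::var(tr$y), 2.5, tolerance = 0.1)
  expect_gt(stats::ks.test(tr$y / sqrt(2.5), "pnorm")$p.value, 0.01)

  # noise-free single causal SNP: y collinear with its scores
  fx <- tiny_fixture()
  snp <- fx$G$map$snp_id[10]
  tr0 <- simulate_trait(fx$G, NULL,
                        truth_record(snp, beta = 2, sigma_g2 = 0,
                                     sigma_e2 = 0))
  s <- fx$G$geno[, snp] - 1
  expect_equal(unname(tr0$y), unname(2 * s))
  expect_error(simulate_trait(fx$G, NULL,
                              truth_record("nosuch", beta = 1,
                                           sigma_g2 = 0, sigma_e2 = 1)),
               "unknown snp_id")

  # 20%-of-variance SNP at n = 288: average OLS R^2 across replicates ~ 0.20
  g288 <- with_seed_local(3, matrix(stats::rbinom(288, 2, 0.3), ncol = 1))
  G288 <- make_geno(g288)
  truth <- truth_record("s1", var_explained = 0.2, sigma_g2 = 0,
                        sigma_e2 = 0.8)
  r2 <- vapply(1:100, function(i) {
    y <- simulate_trait(G288, NULL, truth, seed = 1000 + i)$y
    summary(stats::lm(y ~ I(g288 - 1)))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.20, tolerance = 0.06)
})

test_that("generator variance scaling gives the nominal heritability at large n", {
  G <- make_geno(matrix(rep_len(0:2, 2000), ncol = 1))
  K <- diag(2000)
  u <- simulate_trait(G, K, truth_record(sigma_g2 = 0.5, sigma_e2 = 0),
                      seed = 21)$y
  e <- simulate_trait(G, K, truth_record(sigma_g2 = 0, sigma_e2 = 0.5),
                      seed = 22)$y
  h2 <- stats::var(u) / (stats::var(u) + stats::var(e))
  expect_equal(h2, 0.5, tolerance = 0.05)
})

test_that("simulate_acr_like is zero-inflated and reduces correctly", {
  G <- make_geno(matrix(rep(0:2, length.out = 2000), ncol = 1))
  truth <- truth_record(sigma_g2 = 0, sigma_e2 = 1)
  acr <- simulate_acr_like(G, NULL, truth, zero_fraction = 0.3, seed = 4)
  expect_true(all(acr$y >= 0))
  expect_lt(abs(mean(acr$y == 0) - 0.30), 0.03)
  # zero_fraction = 0: exponentiated base trait, all positive
  acr0 <- simulate_acr_like(G, NULL, truth, zero_fraction = 0, seed = 4)
  expect_true(all(acr0$y > 0))
  base <- with_seed_local(4, {
    b <- simulate_trait(G, NULL, truth)
    stats::runif(2000)   # consume the zero-mask draws as simulate_acr_like does
    b
  })
  expect_equal(unname(acr0$y), unname(exp(base$y)))
  # near-1 zero fraction: almost everything zero
  acr1 <- simulate_acr_like(G, NULL, truth, zero_fraction = 1 - 1e-6,
                            seed = 4)
  expect_gt(mean(acr1$y == 0), 0.99)
  expect_error(simulate_acr_like(G, NULL, truth, zero_fraction = 1),
               "zero_fraction")
})

test_that("inject_missing masks at the requested rate, deterministically", {
  G <- make_geno(matrix(0L, 1000, 1000))
  expect_identical(inject_missing(G, 0, seed = 1)$geno, G$geno)
  M1 <- inject_missing(G, 0.013, seed = 8)
  M2 <- inject_missing(G, 0.013, seed = 8)
  expect_identical(M1$geno, M2$geno)
  expect_lt(abs(mean(is.na(M1$geno)) - 0.013), 3e-4)
  expect_identical(unname(is.na(M1$geno)), attr(M1, "missing_mask"))
})
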