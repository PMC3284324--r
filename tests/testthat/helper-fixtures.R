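# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# quick geno_matrix from a plain matrix; one chromosome unless chrom given
make_geno <- function(g, pos = NULL, chrom = NULL, ids = NULL) {
  g <- as.matrix(g)
  m <- ncol(g)
  geno_matrix(g,
              data.frame(snp_id = paste0("s", seq_len(m)),
                         chrom = chrom %||% rep("chr1", m),
                         pos = pos %||% (seq_len(m) * 1000)),
              sample_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny preset population after QC + imputation, with kinship; cached
tiny_fixture <- function(seed = 42) {
  key <- paste0("tiny_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  G0 <- simulate_population(sim_preset("tiny", seed = seed))
  fl <- filter_snps(G0)
  cl <- collapse_identical(fl$G)
  G <- impute_missing(cl$G, seed = seed)
  fx <- list(G0 = G0, G = G, K = ibs_kinship(G), mapping = cl$mapping,
             report = fl$report)
  .fixture_env[[key]] <- fx
  fx
}

# random 0/1/2 genotype matrix with iid Binomial(2, p) columns (HWE)
random_geno <- function(n, m, p = 0.3, seed = 1) {
  with_seed_local(seed, {
    g <- matrix(stats::rbinom(n * m, 2, p), n, m)
    # keep every column polymorphic for scan-oriented tests
    for (j in which(apply(g, 2, function(x) length(unique(x)) < 2)))
      g[1:2, j] <- c(0, 2)
    make_geno(g, pos = sort(sample.int(2e8, m)))
  })
}

# evaluate expr under a seed without disturbing the suite's RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# block-diagonal two-family kinship for structure-retention tests
family_kinship <- function(n_per = 4, within = 0.9) {
  n <- 2 * n_per
  K <- diag(n)
  K[1:n_per, 1:n_per] <- within
  K[(n_per + 1):n, (n_per + 1):n] <- within
  diag(K) <- 1
  K
}

# 288-sample population at reduced SNP density (cohort-scale REML/stepwise
# tests); cached
pop288_fixture <- function(seed = 42) {
  key <- paste0("pop288_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  G0 <- simulate_population(sim_preset("nmri-like", seed = seed,
                                       n_snps_per_chrom = 150, n_chroms = 4))
  G <- impute_missing(filter_snps(G0)$G, seed = seed)
  fx <- list(G = G, K = ibs_kinship(G))
  .fixture_env[[key]] <- fx
  fx
}

# 288-sample cohort at mapping density (~10 SNPs/Mb over 8 chromosomes):
# the nmri-like demographic history scaled down in genome size, used for
# RMIP and mapping-precision acceptance runs; cached
cohort_fixture <- function(seed = 42) {
  key <- paste0("cohort_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  G0 <- simulate_population(sim_preset("nmri-like", seed = seed,
                                       n_snps_per_chrom = 1000,
                                       n_chroms = 8))
  fl <- filter_snps(G0)
  cl <- collapse_identical(fl$G)
  G <- impute_missing(cl$G, seed = seed)
  fx <- list(G = G, K = ibs_kinship(G), mapping = cl$mapping)
  .fixture_env[[key]] <- fx
  fx
}
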