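test_that("trend test matches the brute-force least-squares oracle", {
  set.seed(101)
  n <- 30
  g <- rbinom(n, 2, 0.4)
  g[1:2] <- c(0, 2)
  y <- 0.3 * (g - 1) + rnorm(n)
  cov <- cbind(rnorm(n))
  for (cv in list(NULL, cov)) {
    res <- trend_test(y, g, covariates = cv)
    fit <- if (is.null(cv)) stats::lm(y ~ I(g - 1))
           else stats::lm(y ~ I(g - 1) + cv)
    sm <- summary(fit)$coefficients["I(g - 1)", ]
    expect_equal(res$statistic, unname(sm["t value"]^2), tolerance = 1e-10)
    expect_equal(res$p_value, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(res$beta, unname(sm["Estimate"]), tolerance = 1e-10)
  }
  # perfect fit: p underflows to zero, score saturates
  yp <- as.numeric(g - 1)
  res_p <- trend_test(yp, g)
  expect_equal(res_p$p_value, 0)
  expect_gt(res_p$neg_log10_p, 15)
  expect_error(trend_test(y, rep(1, n)), "constant")
})

test_that("null trend-test p-values are uniform", {
  # fixed genotype vector, gaussian traits: p is exactly Uniform(0, 1)
  set.seed(202)
  g <- rbinom(30, 2, 0.4); g[1:2] <- c(0, 2)
  G1 <- make_geno(matrix(g, ncol = 1))
  p <- replicate(2000, genome_scan(rnorm(30), G1, "trend")$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("anova test matches the group-sums oracle and collapses to 1 df", {
  set.seed(303)
  n <- 30
  g <- rbinom(n, 2, 0.5); g[1:3] <- 0:2
  y <- rnorm(n) + 0.5 * (g == 1)
  res <- anova_test(y, g)
  fit <- stats::anova(stats::lm(y ~ factor(g)))
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df, c(2, n - 3))
  # covariate version against lm
  cv <- rnorm(n)
  res_c <- anova_test(y, g, covariates = cbind(cv))
  fit_c <- stats::anova(stats::lm(y ~ cv + factor(g)))
  expect_equal(res_c$statistic, fit_c$`F value`[2], tolerance = 1e-10)
  # two genotype classes -> 1-df two-group comparison
  g2 <- rep(c(0, 2), 15)
  y2 <- rnorm(30)
  res2 <- anova_test(y2, g2)
  expect_equal(res2$df[1], 1)
  expect_equal(res2$p_value, trend_test(y2, g2)$p_value, tolerance = 1e-12)
  # classes exactly determine y -> p of 0
  y3 <- as.numeric(g == 1)
  expect_equal(anova_test(y3, g)$p_value, 0)
  expect_error(anova_test(y2, rep(2, 30)), "single genotype class")
})

test_that("model nesting: anova never fits worse than the trend line", {
  set.seed(404)
  for (i in 1:20) {
    g <- rbinom(40, 2, 0.5)
    if (length(unique(g)) < 3) next
    y <- rnorm(40)
    rss_trend <- sum(stats::resid(stats::lm(y ~ I(g - 1)))^2)
    rss_anova <- sum(stats::resid(stats::lm(y ~ factor(g)))^2)
    expect_lte(rss_anova, rss_trend + 1e-12)
  }
})

test_that("p-values are invariant to affine rescaling of the trait", {
  fx <- tiny_fixture()
  y <- with_seed_local(6, rnorm(n_samples(fx$G)))
  y2 <- 7 - 3 * y
  for (tst in c("trend", "anova")) {
    s1 <- genome_scan(y, fx$G, tst)
    s2 <- genome_scan(y2, fx$G, tst)
    expect_equal(s1$p, s2$p, tolerance = 1e-9)
  }
  sm1 <- genome_scan(y, fx$G, "mixed", K = fx$K)
  sm2 <- genome_scan(y2, fx$G, "mixed", K = fx$K)
  expect_equal(sm1$p, sm2$p, tolerance = 1e-6)
})

test_that("reml_fit recovers variance components and flags degeneracy", {
  fx <- tiny_fixture()
  K <- fx$K
  n <- nrow(K)
  # null heritability: estimates collapse toward zero
  h0 <- vapply(1:25, function(i) {
    y <- simulate_trait(fx$G, K, truth_record(sigma_g2 = 0, sigma_e2 = 1),
                        seed = 500 + i)$y
    suppressWarnings(reml_fit(y, K))$heritability
  }, numeric(1))
  expect_gt(mean(h0 < 0.25), 0.7)
  # K = I: only the total variance is identifiable
  yI <- with_seed_local(8, rnorm(40))
  vcI <- reml_fit(yI, diag(40))
  expect_true(vcI$unidentifiable)
  expect_equal(vcI$sigma_g2 + vcI$sigma_e2, stats::var(yI) * 39 / 39,
               tolerance = 0.05)
})

test_that("mixed scan with K = I reduces to the trend test", {
  fx <- tiny_fixture()
  y <- with_seed_local(9, rnorm(n_samples(fx$G)))
  sm <- genome_scan(y, fx$G, "mixed", K = diag(n_samples(fx$G)))
  st <- genome_scan(y, fx$G, "trend")
  expect_equal(sm$p, st$p, tolerance = 1e-8)
})

test_that("mixed model controls polygenic inflation better than the trend test", {
  fx <- tiny_fixture()
  ratios <- vapply(1:5, function(i) {
    y <- simulate_trait(fx$G, fx$K,
                        truth_record(sigma_g2 = 0.9, sigma_e2 = 0.1),
                        seed = 700 + i)$y
    lam <- function(p) stats::median(stats::qchisq(p, 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, 1)
    c(trend = lam(genome_scan(y, fx$G, "trend")$p),
      mixed = lam(genome_scan(y, fx$G, "mixed", K = fx$K)$p))
  }, numeric(2))
  expect_lt(mean(abs(ratios["mixed", ] - 1)), mean(abs(ratios["trend", ] - 1)))
})

test_that("mixed scan localizes a strong planted QTL at cohort scale", {
  fx <- cohort_fixture()
  prep_scan <- function(y) genome_scan(y, fx$G, "mixed", K = fx$K)
  hits <- 0L
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    snp <- with_seed_local(900 + i,
      sample(fx$G$map$snp_id[compute_maf(fx$G) > 0.2], 1))
    y <- simulate_trait(fx$G, fx$K,
                        truth_record(snp, var_explained = 0.2,
                                     sigma_g2 = 0.24, sigma_e2 = 0.56),
                        seed = 1900 + i)$y
    sc <- prep_scan(y)
    top <- sc$snp_id[which.max(sc$neg_log10_p)]
    # the peak lands on the causal SNP, a collapsed duplicate, or a tight
    # LD proxy (r2 >= 0.8) -- exact-top recovery is not expected when
    # near-duplicate neighbors survive collapsing
    ok <- snp %in% expand_collapsed(top, fx$mapping) ||
      suppressWarnings(stats::cor(fx$G$geno[, snp],
                                  fx$G$geno[, top]))^2 >= 0.8
    if (isTRUE(ok)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("per-SNP refit agrees closely with the one-shot approximation", {
  fx <- tiny_fixture()
  G <- fx$G[, 1:40]
  y <- simulate_trait(G, fx$K, truth_record(sigma_g2 = 0.3, sigma_e2 = 0.7),
                      seed = 31)$y
  once <- mixed_scan(y, G, fx$K, refit = "once")
  per <- mixed_scan(y, G, fx$K, refit = "per_snp")
  expect_equal(per$neg_log10_p, once$neg_log10_p, tolerance = 0.2)
  expect_gt(stats::cor(per$neg_log10_p, once$neg_log10_p), 0.97)
})

test_that("conditional scan removes signal at linked SNPs and excludes itself", {
  fx <- tiny_fixture()
  causal <- fx$G$map$snp_id[25]
  y <- simulate_trait(fx$G, fx$K,
                      truth_record(causal, var_explained = 0.3,
                                   sigma_g2 = 0.2, sigma_e2 = 0.5),
                      seed = 41)$y
  un <- genome_scan(y, fx$G, "mixed", K = fx$K)
  cond <- conditional_scan(y, fx$G, fx$K, causal)
  expect_false(causal %in% cond$snp_id)
  # linked neighborhood (within 2 Mb) drops
  near <- un$snp_id[un$chrom == fx$G$map$chrom[25] &
                    abs(un$pos - fx$G$map$pos[25]) < 2e6 &
                    un$snp_id != causal]
  near <- intersect(near, cond$snp_id)
  drop <- un$neg_log10_p[match(near, un$snp_id)] -
    cond$neg_log10_p[match(near, cond$snp_id)]
  expect_gt(mean(drop), 0)
  # conditioning on a null SNP leaves the scan essentially unchanged
  null_snp <- fx$G$map$snp_id[which.max(fx$G$map$chrom != fx$G$map$chrom[25])]
  cond0 <- conditional_scan(y, fx$G, fx$K, null_snp)
  shared <- intersect(un$snp_id, cond0$snp_id)
  expect_lt(stats::median(abs(un$neg_log10_p[match(shared, un$snp_id)] -
                              cond0$neg_log10_p[match(shared, cond0$snp_id)])),
            0.3)
})

test_that("variance_explained decomposes nested models", {
  fx <- tiny_fixture()
  s <- fx$G$geno[, 5] - 1
  y <- 2 * s + 1
  ve <- variance_explained(y, fx$G, fx$G$map$snp_id[5])
  expect_equal(ve$r2_marginal, 1)
  ve0 <- variance_explained(y, fx$G, list(character(0)))
  expect_equal(ve0$r2_cumulative, 0)
  # correlated causal pair: marginal exceeds incremental for the second SNP
  r <- abs(suppressWarnings(stats::cor(fx$G$geno)))
  diag(r) <- 0
  idx <- which(r > 0.25 & r < 0.6, arr.ind = TRUE)[1, ]
  a <- fx$G$map$snp_id[idx[1]]; b <- fx$G$map$snp_id[idx[2]]
  yy <- simulate_trait(fx$G, NULL,
                       truth_record(c(a, b), beta = c(1, 1), sigma_g2 = 0,
                                    sigma_e2 = 0.5), seed = 55)$y
  ve2 <- variance_explained(yy, fx$G, list(c(a, b)))
  expect_gt(ve2$r2_marginal[2], ve2$r2_incremental[2])
})
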