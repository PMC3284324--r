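# Single-locus genome scans: additive trend test, 2-df ANOVA, and a
# kinship mixed-model trend test with REML variance components.

# ---- shared least-squares machinery -------------------------------------

# Orthonormal basis of the column space of X (drops collinear columns).
ortho_basis <- function(X) {
  qx <- qr(X)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

# Vectorized 1-df score test: F statistic of each column of S added to the
# fixed-effect design X, by residual correlation.  Returns NA (with reason)
# for columns collinear with X.
score_scan <- function(y, S, X, tol = 1e-10) {
  n <- length(y)
  Q <- ortho_basis(X)
  p <- ncol(Q)
  df2 <- n - p - 1
  if (df2 < 1) stopf("not enough residual degrees of freedom")
  yr <- y - Q %*% crossprod(Q, y)
  Sr <- S - Q %*% crossprod(Q, S)
  sy2 <- sum(yr^2)
  ss2 <- colSums(Sr^2)
  num <- as.vector(crossprod(Sr, yr))
  scale_s <- colSums(S^2)
  ok <- ss2 > tol * pmax(scale_s, 1)
  r2 <- rep(NA_real_, ncol(S))
  r2[ok] <- pmin(1, num[ok]^2 / (sy2 * ss2[ok]))
  Fstat <- r2 / (1 - r2) * df2
  logp <- stats::pf(Fstat, 1, df2, lower.tail = FALSE, log.p = TRUE)
  list(stat = Fstat, df1 = 1L, df2 = df2,
       p = exp(logp), neg_log10_p = -logp / log(10),
       beta = num / ss2, skipped = !ok)
}

# residual sum of squares of y on the column space of X
rss_on <- function(y, X) {
  Q <- ortho_basis(X)
  r <- y - Q %*% crossprod(Q, y)
  sum(r^2)
}

scan_result <- function(map, test, stat, df, p, neg_log10_p, extra = NULL) {
  out <- data.frame(map[, c("snp_id", "chrom", "pos")], test = test,
                    stat = stat, df = df, p = p,
                    neg_log10_p = neg_log10_p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gwas_scan", "data.frame")
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d SNPs, test = %s; top hit %s (-log10 p = %.2f)\n",
              nrow(x), x$test[1], x$snp_id[which.max(x$neg_log10_p)],
              max(x$neg_log10_p, na.rm = TRUE)))
  invisible(as.data.frame(x))
}

# ---- single-SNP tests ----------------------------------------------------

#' Additive (linear trend) association test
#'
#' Least-squares regression of the trait on -1/0/1 genotype scores (plus an
#' intercept and optional covariates); 1-df F test (equivalently t-squared)
#' for the score coefficient.  P-values use the F reference distribution
#' with the residual degrees of freedom.
#'
#' @param y numeric trait vector.
#' @param g genotype vector coded 0/1/2 (no missing).
#' @param covariates optional numeric matrix of fixed-effect covariates.
#' @return list with `statistic`, `df` (c(1, df2)), `p_value`,
#'   `neg_log10_p`, `beta`.
#' @export
trend_test <- function(y, g, covariates = NULL) {
  if (anyNA(y) || anyNA(g)) stopf("missing values in y or g")
  if (length(unique(g)) < 2) stopf("'g' is constant; trend test undefined")
  X <- design_matrix(length(y), covariates)
  sc <- score_scan(y, matrix(g - 1, ncol = 1), X)
  if (sc$skipped[1]) stopf("'g' is collinear with the covariates")
  list(statistic = sc$stat[1], df = c(1, sc$df2), p_value = sc$p[1],
       neg_log10_p = sc$neg_log10_p[1], beta = sc$beta[1])
}

#' Genotype-class ANOVA association test (up to 2 df)
#'
#' F-test of the genotype treated as a factor (additive + dominance) against
#' the covariates-only model; df1 = number of observed genotype classes - 1
#' (so 1 when only two classes are present).
#'
#' @inheritParams trend_test
#' @return list with `statistic`, `df`, `p_value`, `neg_log10_p`.
#' @export
anova_test <- function(y, g, covariates = NULL) {
  if (anyNA(y) || anyNA(g)) stopf("missing values in y or g")
  classes <- sort(unique(g))
  if (length(classes) < 2) stopf("'g' has a single genotype class")
  X0 <- design_matrix(length(y), covariates)
  Gf <- sapply(classes[-1], function(k) as.numeric(g == k))
  n <- length(y)
  q0 <- ortho_basis(X0)
  q1 <- ortho_basis(cbind(X0, Gf))
  df1 <- ncol(q1) - ncol(q0)
  if (df1 < 1) stopf("genotype classes collinear with covariates")
  df2 <- n - ncol(q1)
  rss0 <- rss_on(y, X0)
  rss1 <- rss_on(y, cbind(X0, Gf))
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  logp <- stats::pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE)
  list(statistic = Fstat, df = c(df1, df2), p_value = exp(logp),
       neg_log10_p = -logp / log(10))
}

# ---- REML variance components (kinship mixed model) ----------------------

# Restricted log-likelihood profile over delta = sigma_e2 / sigma_g2 given
# the spectral decomposition of the kinship projected off the fixed effects.
reml_profile <- function(eta2, lambda, q) {
  function(log_delta) {
    d <- exp(log_delta)
    s <- sum(eta2 / (lambda + d))
    0.5 * (q * (log(q / (2 * pi)) - 1 - log(s)) - sum(log(lambda + d)))
  }
}

# Decomposition pieces reused across repeated REML fits with the same K, X.
reml_decompose <- function(K, X) {
  n <- nrow(K)
  K <- (K + t(K)) / 2
  Q <- ortho_basis(X)
  p <- ncol(Q)
  q <- n - p
  if (q < 2) stopf("not enough residual degrees of freedom for REML")
  # eigen of S (K + I) S with S the projector off X; adding I keeps the
  # matrix PD so the null-space eigenvalues separate cleanly at 1
  M <- K + diag(n)
  SM <- M - Q %*% crossprod(Q, M)
  SMS <- SM - tcrossprod(SM %*% Q, Q)
  e <- eigen(SMS, symmetric = TRUE)
  lambda <- e$values[seq_len(q)] - 1
  if (min(lambda) < -0.05 * max(abs(lambda)))
    stopf("kinship matrix is not positive semi-definite")
  lambda <- pmax(lambda, 0)
  list(U = e$vectors[, seq_len(q), drop = FALSE], lambda = lambda,
       q = q, p = p, n = n)
}

reml_fit_decomposed <- function(y, dec, n_grid = 100,
                                delta_range = c(1e-5, 1e5)) {
  eta <- as.vector(crossprod(dec$U, y))
  eta2 <- eta^2
  ll <- reml_profile(eta2, dec$lambda, dec$q)
  unident <- diff(range(dec$lambda)) < 1e-8 * max(dec$lambda, 1e-12)
  grid <- seq(log(delta_range[1]), log(delta_range[2]), length.out = n_grid)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  boundary <- i == 1L || i == n_grid
  if (unident) {
    delta <- 1
    loglik <- ll(0)
    boundary <- FALSE
  } else {
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
    opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE)
    delta <- exp(opt$maximum)
    loglik <- opt$objective
  }
  sigma_g2 <- sum(eta2 / (dec$lambda + delta)) / dec$q
  sigma_e2 <- delta * sigma_g2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
                 reml_loglik = loglik,
                 heritability = sigma_g2 / (sigma_g2 + sigma_e2),
                 unidentifiable = unident, boundary = boundary,
                 n = dec$n, p = dec$p),
            class = "variance_components")
}

#' REML variance components under a kinship mixed model
#'
#' Fits `y ~ N(X beta, sigma_g2 K + sigma_e2 I)` by restricted maximum
#' likelihood: the kinship is spectrally decomposed in the space orthogonal
#' to the fixed effects, and the restricted likelihood is maximized over the
#' variance ratio `delta = sigma_e2 / sigma_g2` on a 100-point log grid over
#' `[1e-5, 1e5]` with local refinement.  With `K` proportional to the
#' identity only the total variance is identifiable; the fit is then flagged
#' `unidentifiable` (delta set to 1) and the restricted likelihood is flat.
#'
#' @param y numeric trait vector.
#' @param K kinship matrix (symmetric PSD).
#' @param X fixed-effect design matrix (default: intercept only).
#' @return object of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `reml_loglik`, `heritability`, flags `unidentifiable` and
#'   `boundary` (optimum at the delta-grid edge).
#' @export
reml_fit <- function(y, K, X = NULL) {
  K <- as.matrix(K)
  n <- length(y)
  if (any(dim(K) != n)) stopf("'K' must be %d x %d", n, n)
  X <- if (is.null(X)) matrix(1, n, 1) else as.matrix(X)
  dec <- reml_decompose(K, X)
  fit <- reml_fit_decomposed(y, dec)
  if (fit$boundary)
    warnf("REML optimum at the delta grid boundary (delta = %.3g)", fit$delta)
  fit
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)%s\n",
    x$sigma_g2, x$sigma_e2, x$heritability,
    if (x$unidentifiable) " [unidentifiable: K ~ I]" else ""))
  invisible(x)
}

# ---- genome scans --------------------------------------------------------

# Precompute everything reused across repeated mixed-model scans on the same
# genotypes/kinship/covariates: REML decomposition and kinship eigen pieces.
mixed_prep <- function(G, K, covariates = NULL) {
  S <- geno_scores(G)
  n <- n_samples(G)
  X <- design_matrix(n, covariates)
  K <- (as.matrix(K) + t(as.matrix(K))) / 2
  eK <- eigen(K, symmetric = TRUE)
  Ut <- t(eK$vectors)
  # genotypes and design rotated into the kinship eigenbasis once; each
  # scan then only needs a per-trait row scaling (whitening is diagonal here)
  list(S = S, X = X, K = K, map = G$map, dec = reml_decompose(K, X),
       eigvals = eK$values, Ut = Ut, UtS = Ut %*% S, UtX = Ut %*% X, n = n)
}

# Whitening transform for V = sigma_g2 K + sigma_e2 I from prep eigen pieces
whitener <- function(prep, vc) {
  w <- 1 / sqrt(pmax(prep$eigvals, 0) * vc$sigma_g2 + vc$sigma_e2)
  prep$Ut * w   # rows scaled: diag(w) %*% t(U)
}

mixed_scan_prepped <- function(y, prep, vc = NULL) {
  vc <- vc %||% reml_fit_decomposed(y, prep$dec)
  w <- 1 / sqrt(pmax(prep$eigvals, 0) * vc$sigma_g2 + vc$sigma_e2)
  sc <- score_scan(as.vector(prep$Ut %*% y) * w, prep$UtS * w,
                   prep$UtX * w)
  list(sc = sc, vc = vc)
}

#' Kinship mixed-model genome scan
#'
#' Generalized-least-squares trend test of each SNP under
#' `y ~ N(X beta + s b, sigma_g2 K + sigma_e2 I)`.  With `refit = "once"`
#' (the default) the variance components are estimated once under the null
#' model and reused genome-wide (the standard approximation); with
#' `refit = "per_snp"` they are re-estimated with each SNP in the fixed
#' effects.  SNPs whose scores are constant or collinear with the covariates
#' are skipped with a reason recorded in `attr(, "skipped")`.
#'
#' @param y numeric trait vector.
#' @param G a complete `geno_matrix`.
#' @param K kinship matrix.
#' @param covariates optional fixed-effect covariate matrix.
#' @param refit `"once"` or `"per_snp"`.
#' @return a `gwas_scan` data.frame (snp_id, chrom, pos, test, stat, df, p,
#'   neg_log10_p) with the null `variance_components` in `attr(, "vc")`.
#' @export
mixed_scan <- function(y, G, K, covariates = NULL,
                       refit = c("once", "per_snp")) {
  refit <- match.arg(refit)
  prep <- mixed_prep(G, K, covariates)
  if (refit == "once") {
    ms <- mixed_scan_prepped(y, prep)
    sc <- ms$sc; vc <- ms$vc
  } else {
    vc <- reml_fit_decomposed(y, prep$dec)
    m <- ncol(prep$S)
    stat <- p <- nl <- rep(NA_real_, m)
    skip <- logical(m)
    for (j in seq_len(m)) {
      Xj <- cbind(prep$X, prep$S[, j])
      if (qr(Xj)$rank <= ncol(prep$X)) { skip[j] <- TRUE; next }
      dj <- reml_decompose(prep$K, Xj)
      vj <- reml_fit_decomposed(y, dj)
      Tm <- whitener(prep, vj)
      s1 <- score_scan(as.vector(Tm %*% y),
                       Tm %*% prep$S[, j, drop = FALSE], Tm %*% prep$X)
      stat[j] <- s1$stat[1]; p[j] <- s1$p[1]; nl[j] <- s1$neg_log10_p[1]
      skip[j] <- s1$skipped[1]
    }
    sc <- list(stat = stat, df2 = prep$n - ncol(prep$X) - 1, p = p,
               neg_log10_p = nl, skipped = skip)
  }
  scan_result(prep$map, "mixed", sc$stat, 1L, sc$p, sc$neg_log10_p,
              extra = list(vc = vc,
                           skipped = prep$map$snp_id[sc$skipped]))
}

#' Single-locus genome scan with a chosen statistic
#'
#' Runs the additive trend test, the genotype-class ANOVA, or the kinship
#' mixed-model trend test at every SNP.
#'
#' @inheritParams mixed_scan
#' @param test `"trend"`, `"anova"` or `"mixed"`.
#' @param ... passed on to [mixed_scan()] (e.g. `refit`).
#' @return a `gwas_scan` data.frame.
#' @export
genome_scan <- function(y, G, test = c("trend", "anova", "mixed"), K = NULL,
                        covariates = NULL, ...) {
  test <- match.arg(test)
  stopifnot(inherits(G, "geno_matrix"))
  if (length(y) != n_samples(G)) stopf("length(y) != number of samples")
  if (test == "mixed") {
    if (is.null(K)) stopf("'K' is required for the mixed-model scan")
    return(mixed_scan(y, G, K, covariates, ...))
  }
  S <- geno_scores(G)
  X <- design_matrix(length(y), covariates)
  if (test == "trend") {
    sc <- score_scan(y, S, X)
    return(scan_result(G$map, "trend", sc$stat, 1L, sc$p, sc$neg_log10_p,
                       extra = list(skipped = G$map$snp_id[sc$skipped])))
  }
  m <- ncol(S)
  stat <- p <- nl <- rep(NA_real_, m)
  df1 <- rep(NA_integer_, m)
  skip <- logical(m)
  for (j in seq_len(m)) {
    g <- G$geno[, j]
    res <- tryCatch(anova_test(y, g, covariates), error = function(e) NULL)
    if (is.null(res)) { skip[j] <- TRUE; next }
    stat[j] <- res$statistic; df1[j] <- res$df[1]
    p[j] <- res$p_value; nl[j] <- res$neg_log10_p
  }
  scan_result(G$map, "anova", stat, df1, p, nl,
              extra = list(skipped = G$map$snp_id[skip]))
}

#' Conditional genome scan
#'
#' Mixed-model scan with the -1/0/1 scores of the conditioning SNPs appended
#' to the fixed effects; a collinear conditioning set is reduced by QR-based
#' pruning (pruned ids in `attr(, "pruned")`) and the conditioning SNPs are
#' excluded from the scanned set.
#'
#' @inheritParams mixed_scan
#' @param conditioning_snp_ids character vector of SNP ids to condition on.
#' @return a `gwas_scan` data.frame.
#' @export
conditional_scan <- function(y, G, K, conditioning_snp_ids,
                             covariates = NULL, ...) {
  C <- geno_scores(G, conditioning_snp_ids)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  X <- cbind(covariates, C)
  qx <- qr(cbind(1, X))
  pruned <- character(0)
  if (qx$rank < ncol(X) + 1L) {
    piv <- qx$pivot[seq_len(qx$rank)]
    keep_cols <- sort(piv[piv > 1L] - 1L)       # columns of X to keep
    dropped <- setdiff(seq_len(ncol(X)), keep_cols)
    pruned <- conditioning_snp_ids[dropped[dropped > ncov] - ncov]
    X <- X[, keep_cols, drop = FALSE]
  }
  keep_snps <- setdiff(G$map$snp_id, conditioning_snp_ids)
  out <- mixed_scan(y, G[, keep_snps], K, covariates = X, ...)
  attr(out, "conditioned_on") <- conditioning_snp_ids
  attr(out, "pruned") <- pruned
  out
}

#' Variance explained by SNP combinations
#'
#' Ordinary-least-squares R-squared of the trait on each requested SNP set,
#' with each SNP's marginal R-squared (alone) and its incremental
#' R-squared in the order given.
#'
#' @param y numeric trait vector.
#' @param G a complete `geno_matrix`.
#' @param snp_sets list of character vectors of snp_ids (a single vector is
#'   treated as one set).
#' @return data.frame with set, snp_id, order, r2_marginal, r2_cumulative,
#'   r2_incremental.
#' @export
variance_explained <- function(y, G, snp_sets) {
  if (!is.list(snp_sets)) snp_sets <- list(snp_sets)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (si in seq_along(snp_sets)) {
    ids <- snp_sets[[si]]
    if (length(ids) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        set = si, snp_id = NA_character_, order = 0L, r2_marginal = 0,
        r2_cumulative = 0, r2_incremental = 0, stringsAsFactors = FALSE)
      next
    }
    S <- geno_scores(G, ids)
    prev <- 0
    for (k in seq_along(ids)) {
      r2m <- 1 - rss_on(y, cbind(1, S[, k])) / tss
      r2c <- 1 - rss_on(y, cbind(1, S[, seq_len(k), drop = FALSE])) / tss
      rows[[length(rows) + 1]] <- data.frame(
        set = si, snp_id = ids[k], order = k, r2_marginal = r2m,
        r2_cumulative = r2c, r2_incremental = r2c - prev,
        stringsAsFactors = FALSE)
      prev <- r2c
    }
  }
  do.call(rbind, rows)
}
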