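# Genome-wide significance thresholds: kinship-preserving structured
# permutation (rank-matching against a multivariate-normal draw) and plain
# free permutation, with generalized extreme value tail fitting.

#' Van der Waerden normal scores
#'
#' Maps the value with rank `i` (mid-ranks for ties) to the standard-normal
#' quantile at `i / (n + 1)`.
#'
#' @param y numeric vector (length >= 3).
#' @return numeric vector of normal scores.
#' @export
vdw_scores <- function(y) {
  n <- length(y)
  if (n < 3) stopf("need n >= 3 for normal scores")
  stats::qnorm(rank(y, ties.method = "average") / (n + 1))
}

#' Kinship-preserving structured permutation of a trait
#'
#' Draws `z ~ MVN(0, sigma_g2 K + sigma_e2 I)` and reassigns the observed
#' trait value of rank `k` to the individual holding rank `k` in `z`.  The
#' output is an exact permutation of the input (the empirical distribution
#' is preserved) that retains the familial correlation implied by the
#' kinship matrix.  With `sigma_g2 = 0` the permutation is uniform over
#' orderings.  Rank ties in the observed trait are broken by original
#' sample order; ties in `z` (probability zero) by stable order.
#'
#' @param y observed trait vector.
#' @param K kinship matrix.
#' @param vc `variance_components` from [reml_fit()], conventionally fitted
#'   to the van der Waerden-transformed trait.
#' @param seed RNG seed or NULL.
#' @return permuted trait vector.
#' @export
structured_permute <- function(y, K, vc, seed = NULL) {
  n <- length(y)
  if (vc$sigma_g2 + vc$sigma_e2 <= 0)
    stopf("variance components are both zero; nothing to simulate")
  V <- vc$sigma_g2 * as.matrix(K) + vc$sigma_e2 * diag(n)
  with_seed(seed, {
    z <- mvn_draw_factor(mvn_factor(V))
    out <- numeric(n)
    out[order(z)] <- sort(y)
    names(out) <- names(y)
    out
  })
}

# internal: one scan maximum for a given test, reusing precomputed pieces
max_stat_engine <- function(G, K, test, covariates = NULL) {
  X <- design_matrix(n_samples(G), covariates)
  if (test == "mixed") {
    prep <- mixed_prep(G, K, covariates)
    function(yp) {
      ms <- mixed_scan_prepped(yp, prep)
      max(ms$sc$neg_log10_p[!ms$sc$skipped], na.rm = TRUE)
    }
  } else if (test == "trend") {
    S <- geno_scores(G)
    function(yp) {
      sc <- score_scan(yp, S, X)
      max(sc$neg_log10_p[!sc$skipped], na.rm = TRUE)
    }
  } else {
    function(yp) {
      sc <- genome_scan(yp, G, test = "anova", covariates = covariates)
      max(sc$neg_log10_p, na.rm = TRUE)
    }
  }
}

#' Null distribution of the genome-wide maximum score
#'
#' Repeats `R` structured permutations of the trait (see
#' [structured_permute()]) and records the genome-wide maximum
#' `-log10 p` of each permuted scan.  Variance components for the
#' permutation are estimated by REML on the van der Waerden-transformed
#' trait (transform first, then estimate).  A failed replicate is retried
#' on the next RNG substream.
#'
#' @param y observed trait vector.
#' @param G a complete `geno_matrix`.
#' @param K kinship matrix.
#' @param test `"trend"`, `"anova"` or `"mixed"`.
#' @param R number of permutation replicates (default 100).
#' @param seed root RNG seed; per-replicate substreams are derived from it.
#' @param covariates optional fixed-effect covariates.
#' @param method `"structured"` (kinship-preserving) or `"free"` (uniform
#'   permutation).
#' @return numeric vector of R maxima, with the fitted null
#'   `variance_components` in `attr(, "vc")` (structured method).
#' @export
null_maxima <- function(y, G, K = NULL, test = c("mixed", "trend", "anova"),
                        R = 100, seed = NULL, covariates = NULL,
                        method = c("structured", "free")) {
  test <- match.arg(test)
  method <- match.arg(method)
  check_number(R, "R", lower = 1, integer = TRUE)
  if (test == "mixed" && is.null(K)) stopf("'K' required for mixed test")
  vc <- NULL
  fac <- NULL
  n <- length(y)
  if (method == "structured") {
    if (is.null(K)) stopf("'K' required for structured permutation")
    yv <- vdw_scores(y)
    vc <- reml_fit(yv, K, design_matrix(length(y), covariates))
    V <- vc$sigma_g2 * as.matrix(K) + vc$sigma_e2 * diag(n)
    fac <- mvn_factor(V)
  }
  engine <- max_stat_engine(G, K, test, covariates)
  seeds <- substream_seeds(seed, R + 20L)   # spares for retried replicates
  maxima <- numeric(R)
  ys <- sort(y)
  k <- 0L
  for (r in seq_len(R)) {
    repeat {
      k <- k + 1L
      if (k > length(seeds)) stopf("too many failed scan replicates")
      mx <- tryCatch(with_seed(seeds[[k]], {
        yp <- if (method == "structured") {
          z <- mvn_draw_factor(fac)
          out <- numeric(n); out[order(z)] <- ys; out
        } else sample(y)
        engine(yp)
      }), error = function(e) NULL)
      if (!is.null(mx) && is.finite(mx)) { maxima[r] <- mx; break }
      message(sprintf("replicate %d failed or degenerate; retrying", r))
    }
  }
  attr(maxima, "vc") <- vc
  attr(maxima, "method") <- method
  maxima
}

# ---- generalized extreme value fitting ----------------------------------

gev_nll <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
  z <- (x - mu) / sigma
  if (abs(xi) < 1e-8) {
    sum(par[2] + z + exp(-z))
  } else {
    t <- 1 + xi * z
    if (any(t <= 0)) return(Inf)
    sum(par[2] + (1 + 1 / xi) * log(t) + t^(-1 / xi))
  }
}

gev_quantile <- function(p, loc, scale, shape) {
  if (abs(shape) < 1e-8) loc - scale * log(-log(p))
  else loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' Genome-wide significance thresholds from a GEV fit to scan maxima
#'
#' Fits a generalized extreme value distribution to per-replicate maxima by
#' maximum likelihood (shape free, Gumbel-moment initialization) and returns
#' the `1 - alpha` quantiles as thresholds.  When the fit is not wanted or
#' fails, `method = "empirical"` uses order-statistic quantiles instead.
#'
#' @param maxima numeric vector of per-replicate genome-wide maxima
#'   (>= 30 for the MLE fit, not all equal).
#' @param alphas significance levels (default 0.05).
#' @param method `"mle"` or `"empirical"`.
#' @param trait,test,perm_method labels stored in the result.
#' @return object of class `gwas_thresholds`: thresholds (named by alpha),
#'   fitted `gev` parameters (loc, scale, shape), the maxima, and labels.
#' @export
gev_threshold <- function(maxima, alphas = 0.05, method = c("mle", "empirical"),
                          trait = "trait", test = "mixed",
                          perm_method = "structured") {
  method <- match.arg(method)
  maxima <- as.numeric(maxima)
  if (any(!is.finite(maxima))) stopf("non-finite maxima")
  if (diff(range(maxima)) == 0)
    stopf("degenerate maxima (all equal); use method = 'empirical' on more replicates")
  if (any(alphas <= 0 | alphas >= 1)) stopf("alphas must be in (0, 1)")
  gev <- c(loc = NA_real_, scale = NA_real_, shape = NA_real_)
  if (method == "mle") {
    if (length(maxima) < 30)
      stopf("need >= 30 maxima for the GEV fit; use method = 'empirical'")
    s0 <- sqrt(6) * stats::sd(maxima) / pi
    init <- c(mean(maxima) - 0.5772 * s0, log(s0), 0.1)
    opt <- stats::optim(init, gev_nll, x = maxima, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (opt$convergence != 0)
      warnf("GEV fit did not fully converge (code %d)", opt$convergence)
    gev <- c(loc = opt$par[1], scale = exp(opt$par[2]), shape = opt$par[3])
    thr <- vapply(alphas, function(a)
      gev_quantile(1 - a, gev["loc"], gev["scale"], gev["shape"]), numeric(1))
  } else {
    thr <- as.numeric(stats::quantile(maxima, 1 - alphas, type = 7))
  }
  names(thr) <- as.character(alphas)
  structure(list(trait = trait, test = test, method = perm_method,
                 fit = method, R = length(maxima), maxima = maxima,
                 gev = gev, alphas = alphas, thresholds = thr),
            class = "gwas_thresholds")
}

#' @export
print.gwas_thresholds <- function(x, ...) {
  cat(sprintf("gwas_thresholds (%s permutation, %s test, R = %d, %s fit)\n",
              x$method, x$test, x$R, x$fit))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  alpha = %s: %.3f\n", names(x$thresholds)[i],
                x$thresholds[i]))
  invisible(x)
}

#' Permutation-based genome-wide significance threshold
#'
#' End-to-end: generates null maxima by [null_maxima()] (structured or free
#' permutation) and derives thresholds via [gev_threshold()].
#'
#' @inheritParams null_maxima
#' @param alphas significance levels (default 0.05).
#' @param trait label stored in the result.
#' @param fit `"mle"` (GEV) or `"empirical"`.
#' @return a `gwas_thresholds` object.
#' @export
permutation_threshold <- function(y, G, K = NULL,
                                  method = c("structured", "free"),
                                  test = c("mixed", "trend", "anova"),
                                  R = 100, alphas = 0.05, seed = NULL,
                                  covariates = NULL, trait = "trait",
                                  fit = "mle") {
  method <- match.arg(method)
  test <- match.arg(test)
  if (R < 2) stopf("R must be >= 2 for threshold estimation")
  mx <- null_maxima(y, G, K, test = test, R = R, seed = seed,
                    covariates = covariates, method = method)
  out <- gev_threshold(mx, alphas = alphas, method = fit, trait = trait,
                       test = test, perm_method = method)
  out$vc <- attr(mx, "vc")
  out
}

#' @rdname permutation_threshold
#' @export
free_permutation_threshold <- function(y, G, K = NULL, test = "mixed",
                                       R = 100, alphas = 0.05, seed = NULL,
                                       covariates = NULL, trait = "trait",
                                       fit = "mle") {
  permutation_threshold(y, G, K, method = "free", test = test, R = R,
                        alphas = alphas, seed = seed, covariates = covariates,
                        trait = trait, fit = fit)
}
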