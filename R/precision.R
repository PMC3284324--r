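# Mapping-precision simulation: plant a causal SNP, rescan without it, and
# summarize peak-to-target distances genome-wide.

#' Simulation-based mapping precision
#'
#' Repeats `n_sim` times: draw a target SNP uniformly at random (monomorphic
#' targets redrawn), simulate a trait in which the target explains
#' `var_explained` of the total variance on top of a polygenic component
#' (`sigma_g2 * K`) and residual noise (`sigma_e2`), remove the target from
#' the data, scan, and record the distance from the association peak to the
#' target.  The target effect is `beta = sqrt(f T / Var(s))` with
#' `T = (sigma_g2 + sigma_e2) / (1 - f)` the implied total variance, so the
#' planted fraction is held at `f` regardless of the target's allele
#' frequency.  Tied peaks contribute the median of their distances to the
#' target; peaks landing on another chromosome are flagged and excluded
#' from the distance distribution.
#'
#' @param G a complete `geno_matrix`.
#' @param K kinship matrix.
#' @param var_explained fraction of total variance explained by the target,
#'   in (0, 1); ignored (effect arbitrary) when both variances are zero.
#' @param sigma_g2,sigma_e2 polygenic and residual variances (>= 0).
#' @param n_sim number of simulations (default 1000).
#' @param test scan statistic (default `"mixed"`).
#' @param seed root RNG seed.
#' @param tie_tol two scores within this of the maximum -log10 p count as
#'   tied (default 1e-9).
#' @return object of class `precision_runs`: data.frame with sim,
#'   target_snp, peak_snp, n_ties, same_chromosome, distance_bp (NA when the
#'   peak is on another chromosome).
#' @export
precision_simulation <- function(G, K, var_explained, sigma_g2, sigma_e2,
                                 n_sim = 1000, test = c("mixed", "trend"),
                                 seed = NULL, tie_tol = 1e-9) {
  test <- match.arg(test)
  stopifnot(inherits(G, "geno_matrix"))
  check_fraction(var_explained, "var_explained", open_upper = TRUE)
  if (var_explained <= 0 && sigma_g2 + sigma_e2 > 0)
    stopf("'var_explained' must be in (0, 1)")
  check_number(sigma_g2, "sigma_g2", lower = 0)
  check_number(sigma_e2, "sigma_e2", lower = 0)
  check_number(n_sim, "n_sim", lower = 1, integer = TRUE)
  n <- n_samples(G)
  m <- n_snps(G)
  map <- G$map
  S <- geno_scores(G)
  vs <- apply(S, 2, stats::var)
  poly_fac <- if (sigma_g2 > 0) mvn_factor(sigma_g2 * as.matrix(K)) else NULL
  prep <- if (test == "mixed") mixed_prep(G, K) else NULL
  X <- matrix(1, n, 1)
  seeds <- substream_seeds(seed, n_sim)
  rows <- vector("list", n_sim)
  redraws <- 0L
  for (i in seq_len(n_sim)) {
    rows[[i]] <- with_seed(seeds[[i]], {
      repeat {
        tgt <- sample.int(m, 1L)
        if (vs[tgt] > 0) break
        redraws <- redraws + 1L
      }
      tot <- sigma_g2 + sigma_e2
      beta <- if (tot == 0) 1 else
        sqrt(var_explained * tot / ((1 - var_explained) * vs[tgt]))
      y <- beta * S[, tgt]
      if (!is.null(poly_fac)) y <- y + mvn_draw_factor(poly_fac)
      if (sigma_e2 > 0) y <- y + stats::rnorm(n, 0, sqrt(sigma_e2))
      nl <- if (test == "mixed") {
        ms <- mixed_scan_prepped(y, prep)
        out <- ms$sc$neg_log10_p
        out[ms$sc$skipped] <- NA
        out
      } else {
        sc <- score_scan(y, S, X)
        out <- sc$neg_log10_p
        out[sc$skipped] <- NA
        out
      }
      nl[tgt] <- NA   # the target SNP is removed before scanning
      mx <- max(nl, na.rm = TRUE)
      peaks <- if (is.infinite(mx)) which(is.infinite(nl)) else
        which(nl >= mx - tie_tol)
      same <- all(map$chrom[peaks] == map$chrom[tgt])
      dist <- if (same)
        stats::median(abs(map$pos[peaks] - map$pos[tgt])) else NA_real_
      data.frame(sim = i, target_snp = map$snp_id[tgt],
                 peak_snp = map$snp_id[peaks[1]], n_ties = length(peaks),
                 same_chromosome = same, distance_bp = dist,
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("precision_runs", "data.frame")
  attr(out, "redrawn_targets") <- redraws
  attr(out, "params") <- list(var_explained = var_explained,
                              sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                              test = test)
  out
}

#' Summarize peak-to-target distances
#'
#' Empirical quantiles of the distance distribution over simulations whose
#' peak landed on the target's chromosome, plus the same-chromosome rate.
#'
#' @param runs a `precision_runs` data.frame.
#' @param quantiles quantile levels (default 0.5, 0.8, 0.95).
#' @return list with `quantiles_bp` (named vector), `same_chromosome_rate`,
#'   `n_used`, `n_total`.
#' @export
distance_summary <- function(runs, quantiles = c(0.5, 0.8, 0.95)) {
  d <- runs$distance_bp[runs$same_chromosome]
  if (length(d) == 0) stopf("no run with a defined distance")
  q <- stats::quantile(d, probs = quantiles, names = FALSE)
  names(q) <- as.character(quantiles)
  list(quantiles_bp = q,
       same_chromosome_rate = mean(runs$same_chromosome),
       n_used = length(d), n_total = nrow(runs))
}

#' @export
print.precision_runs <- function(x, ...) {
  s <- distance_summary(x, quantiles = 0.5)
  cat(sprintf("precision_runs: %d simulations, %.1f%% same-chromosome peaks; median distance %.2f Mb\n",
              s$n_total, 100 * s$same_chromosome_rate,
              s$quantiles_bp[[1]] / 1e6))
  invisible(as.data.frame(x))
}
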