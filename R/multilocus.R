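# Multilocus mapping: forward stepwise selection under bootstrap resampling,
# summarized as resample model inclusion probabilities (RMIP).

#' Forward stepwise SNP selection
#'
#' Greedy ordinary-least-squares selection on additive (-1/0/1) genotype
#' scores: at each step the SNP with the smallest conditional p-value given
#' the current model (equivalently the largest partial F) enters; ties are
#' broken by (chromosome, position) order.  Selection stops at `max_terms`,
#' or early when no candidate adds estimable signal (all remaining scores
#' collinear with the model) or residual degrees of freedom run out.
#'
#' @param y numeric trait vector.
#' @param G a complete `geno_matrix`.
#' @param covariates optional fixed-effect covariate matrix.
#' @param max_terms maximum SNPs to select (default 20); must satisfy
#'   `max_terms < n - ncol(covariates) - 1`.
#' @return data.frame with step, snp_id, chrom, pos, f_stat, p_enter.
#' @export
forward_stepwise <- function(y, G, covariates = NULL, max_terms = 20) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- length(y)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  check_number(max_terms, "max_terms", lower = 1, integer = TRUE)
  if (max_terms >= n - ncov - 1)
    stopf("max_terms must be < n - #covariates - 1 (= %d)", n - ncov - 1)
  S <- geno_scores(G)
  m <- ncol(S)
  Q <- ortho_basis(design_matrix(n, covariates))
  yr <- as.vector(y - Q %*% crossprod(Q, y))
  Sr <- S - Q %*% crossprod(Q, S)
  scale_s <- pmax(colSums(S^2), 1)
  eligible <- rep(TRUE, m)
  steps <- list()
  p_model <- ncol(Q)
  for (t in seq_len(max_terms)) {
    df2 <- n - p_model - t   # model: basis (p_model) + t-1 selected + candidate
    if (df2 < 1) break
    ss2 <- colSums(Sr^2)
    ok <- eligible & ss2 > 1e-10 * scale_s
    if (!any(ok)) break
    sy2 <- sum(yr^2)
    if (sy2 <= 1e-12 * sum(y^2) || sy2 == 0) break   # perfect fit reached
    num <- as.vector(crossprod(Sr, yr))
    r2 <- rep(-Inf, m)
    r2[ok] <- pmin(1, num[ok]^2 / (sy2 * ss2[ok]))
    j <- which.max(r2)   # ties: first in (chrom, pos) order
    Fj <- r2[j] / max(1 - r2[j], .Machine$double.eps) * df2
    pj <- stats::pf(Fj, 1, df2, lower.tail = FALSE)
    qn <- Sr[, j] / sqrt(ss2[j])
    yr <- yr - qn * sum(qn * yr)
    Sr <- Sr - qn %*% crossprod(qn, Sr)
    eligible[j] <- FALSE
    steps[[t]] <- data.frame(step = t, snp_id = G$map$snp_id[j],
                             chrom = G$map$chrom[j], pos = G$map$pos[j],
                             f_stat = Fj, p_enter = pj,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), snp_id = character(), chrom = character(),
               pos = numeric(), f_stat = numeric(), p_enter = numeric())
  rownames(out) <- NULL
  out
}

#' Resample model inclusion probabilities (RMIP)
#'
#' Draws `R` bootstrap resamples of the samples (trait and genotype rows
#' together, with replacement), runs [forward_stepwise()] on each, and for
#' every SNP `m` computes `RMIP_m = (1/R) sum_r i_rm`, where `i_rm = 1` if
#' at least one selected SNP of resample `r` lies within `w` bp of SNP `m`
#' on the same chromosome.
#'
#' @inheritParams forward_stepwise
#' @param R number of bootstrap resamples (default 100).
#' @param w window half-width in bp (>= 0); `i_rm` uses `|pos_m - pos_sel| <= w`.
#' @param seed root RNG seed (per-resample substreams derived from it).
#' @return object of class `gwas_rmip`: data.frame (snp_id, chrom, pos,
#'   rmip) with per-resample selections in `attr(, "selections")`.
#' @export
rmip <- function(y, G, R = 100, w = 1e6, max_terms = 20, seed = NULL,
                 covariates = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  check_number(R, "R", lower = 1, integer = TRUE)
  check_number(w, "w", lower = 0)
  n <- length(y)
  seeds <- substream_seeds(seed, R)
  counts <- numeric(n_snps(G))
  selections <- vector("list", R)
  map <- G$map
  chroms <- unique(map$chrom)
  idx_by_chrom <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(idx_by_chrom) <- chroms
  for (r in seq_len(R)) {
    idx <- with_seed(seeds[[r]], sample.int(n, n, replace = TRUE))
    Gb <- G[idx, ]
    sel <- forward_stepwise(y[idx], Gb, covariates =
                              if (is.null(covariates)) NULL
                              else as.matrix(covariates)[idx, , drop = FALSE],
                            max_terms = max_terms)
    selections[[r]] <- sel$snp_id
    hit <- logical(n_snps(G))
    for (k in seq_len(nrow(sel))) {
      j <- idx_by_chrom[[sel$chrom[k]]]
      hit[j] <- hit[j] | abs(map$pos[j] - sel$pos[k]) <= w
    }
    counts <- counts + hit
  }
  out <- data.frame(map[, c("snp_id", "chrom", "pos")], rmip = counts / R,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gwas_rmip", "data.frame")
  attr(out, "selections") <- selections
  attr(out, "R") <- R
  attr(out, "w") <- w
  attr(out, "max_terms") <- max_terms
  out
}

#' @export
print.gwas_rmip <- function(x, ...) {
  cat(sprintf("gwas_rmip: %d SNPs, R = %d resamples, window +/- %.2g Mb; top RMIP = %.2f (%s)\n",
              nrow(x), attr(x, "R"), attr(x, "w") / 1e6,
              max(x$rmip), x$snp_id[which.max(x$rmip)]))
  invisible(as.data.frame(x))
}
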