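#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls; the minor allele is chosen so that the
#' result is in `[0, 0.5]`.  SNPs with no non-missing call get `NA` and are
#' excluded downstream.
#'
#' @param G a `geno_matrix`.
#' @return named numeric vector of MAFs (NA where undefined).
#' @export
compute_maf <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- colMeans(G$geno, na.rm = TRUE) / 2      # alt-allele frequency
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  names(maf) <- G$map$snp_id
  maf
}

#' Per-SNP Hardy-Weinberg chi-square (1 df)
#'
#' Pearson chi-square of observed genotype counts (AA, AB, BB) against
#' expectations `n p^2, 2 n p q, n q^2` from the sample allele frequency.
#' Monomorphic SNPs are defined to have chi-square 0.
#'
#' @param G a `geno_matrix`.
#' @return named numeric vector of chi-square statistics (NA where no calls).
#' @export
hwe_chisq <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- G$geno
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  chi[p == 0 | p == 1] <- 0      # monomorphic
  chi[n == 0] <- NA_real_
  names(chi) <- G$map$snp_id
  chi
}

# per-SNP missing fraction
missing_rate <- function(G) {
  mr <- colMeans(is.na(G$geno))
  names(mr) <- G$map$snp_id
  mr
}

#' Per-SNP QC statistics table
#'
#' @param G a `geno_matrix`.
#' @return data.frame with snp_id, chrom, pos, maf, hwe_chi2, missing_rate.
#' @export
snp_stats <- function(G) {
  data.frame(G$map, maf = unname(compute_maf(G)),
             hwe_chi2 = unname(hwe_chisq(G)),
             missing_rate = unname(missing_rate(G)),
             stringsAsFactors = FALSE)
}

#' Filter SNPs on MAF, Hardy-Weinberg and missingness
#'
#' Keeps SNPs with `maf > maf_min`, `hwe_chi2 < hwe_max` and
#' `missing_rate < miss_max` (strict comparisons).  A SNP failing several
#' rules is counted once, under the first failing rule in the order
#' MAF, HWE, missingness.  SNPs with every call missing are always dropped
#' (reason `all_missing`).
#'
#' @param G a `geno_matrix`.
#' @param maf_min MAF threshold (default 0.02).
#' @param hwe_max HWE chi-square ceiling (default 20).
#' @param miss_max missing-fraction ceiling (default 0.40).
#' @return list with `G` (filtered `geno_matrix`) and `report` (a
#'   `qc_report`: input/output counts and per-rule removal counts and ids).
#' @export
filter_snps <- function(G, maf_min = 0.02, hwe_max = 20, miss_max = 0.40) {
  stopifnot(inherits(G, "geno_matrix"))
  st <- snp_stats(G)
  all_missing <- is.na(st$maf)
  fail_maf <- !all_missing & !(st$maf > maf_min)
  fail_hwe <- !all_missing & !fail_maf & !(st$hwe_chi2 < hwe_max)
  fail_miss <- !all_missing & !fail_maf & !fail_hwe &
    !(st$missing_rate < miss_max)
  keep <- !(all_missing | fail_maf | fail_hwe | fail_miss)
  if (!any(keep)) warnf("no SNP passed the filters")
  report <- structure(list(
    n_input_snps = n_snps(G),
    n_polymorphic = sum(st$maf > 0, na.rm = TRUE),
    n_pass_filters = sum(keep),
    removed = list(all_missing = st$snp_id[all_missing],
                   maf = st$snp_id[fail_maf],
                   hwe = st$snp_id[fail_hwe],
                   missingness = st$snp_id[fail_miss]),
    params = list(maf_min = maf_min, hwe_max = hwe_max, miss_max = miss_max),
    notes = paste("missing calls, if any, are later filled by the",
                  "frequency-sampling imputer (no haplotype model)")),
    class = "qc_report")
  list(G = G[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d SNPs in, %d polymorphic, %d pass filters\n",
              x$n_input_snps, x$n_polymorphic, x$n_pass_filters))
  for (r in names(x$removed))
    cat(sprintf("  removed by %-12s %d\n", paste0(r, ":"),
                length(x$removed[[r]])))
  if (!is.null(x$n_after_collapse))
    cat(sprintf("  after collapsing identical SNPs: %d\n", x$n_after_collapse))
  invisible(x)
}

#' Collapse identical SNPs within a physical window
#'
#' Scanning left to right within each chromosome, a SNP whose genotype vector
#' is identical (over jointly non-missing entries) to an already retained SNP
#' within `window` bp is collapsed onto that left-most representative.
#'
#' @param G a `geno_matrix` (SNPs sorted by chrom, pos -- guaranteed by the
#'   container).
#' @param window physical window in bp (default 2 Mb).
#' @return list with `G` (collapsed matrix) and `mapping` (data.frame
#'   `collapsed_id`, `representative_id` for removed SNPs, zero rows when
#'   nothing collapsed).
#' @export
collapse_identical <- function(G, window = 2e6) {
  stopifnot(inherits(G, "geno_matrix"))
  check_number(window, "window", lower = 0)
  g <- G$geno
  map <- G$map
  m <- ncol(g)
  has_na <- colSums(is.na(g)) > 0
  hash <- rep(NA_character_, m)
  hash[!has_na] <- apply(g[, !has_na, drop = FALSE], 2, paste, collapse = "")
  keep <- logical(m)
  rep_of <- character(m)
  identical_cols <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    all(a[ok] == b[ok])
  }
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      cand <- retained[map$pos[j] - map$pos[retained] <= window]
      hit <- 0L
      for (k in cand) {
        same <- if (!has_na[j] && !has_na[k]) hash[j] == hash[k]
                else identical_cols(g[, j], g[, k])
        if (same) { hit <- k; break }
      }
      if (hit > 0L) {
        rep_of[j] <- map$snp_id[hit]
      } else {
        keep[j] <- TRUE
        retained <- c(retained, j)
      }
    }
  }
  mapping <- data.frame(collapsed_id = map$snp_id[!keep],
                        representative_id = rep_of[!keep],
                        stringsAsFactors = FALSE)
  list(G = G[, keep], mapping = mapping)
}

#' Expand SNP ids through a collapse mapping
#'
#' Returns the given ids plus all SNPs that were collapsed onto them, so that
#' scan hits can be reported on the pre-collapse SNP set.
#'
#' @param ids character vector of representative snp_ids.
#' @param mapping the `mapping` data.frame from [collapse_identical()].
#' @return character vector of ids.
#' @export
expand_collapsed <- function(ids, mapping) {
  unique(c(ids, mapping$collapsed_id[mapping$representative_id %in% ids]))
}

#' Impute missing genotype calls by frequency sampling
#'
#' Each missing call is filled by sampling from the SNP's observed genotype
#' frequencies.  This deliberately replaces haplotype-model imputation: at
#' the ~1% missingness this pipeline expects after filtering, the imputation
#' model is immaterial to every downstream statistic.
#'
#' @param G a `geno_matrix`.
#' @param seed RNG seed or NULL.
#' @return a complete `geno_matrix`.
#' @export
impute_missing <- function(G, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- G$geno
  if (!anyNA(g)) return(G)
  with_seed(seed, {
    for (j in which(colSums(is.na(g)) > 0)) {
      obs <- g[!is.na(g[, j]), j]
      if (length(obs) == 0)
        stopf("SNP %s has no observed call; filter it before imputing",
              G$map$snp_id[j])
      miss <- which(is.na(g[, j]))
      g[miss, j] <- sample(obs, length(miss), replace = TRUE)
    }
    geno_matrix(g, G$map, G$sample_ids)
  })
}

#' log(x + 1) transform for zero-inflated nonnegative traits
#'
#' @param acr nonnegative numeric vector.
#' @return `log(acr + 1)` (natural log).
#' @export
log_acr <- function(acr) {
  if (!is.numeric(acr)) stopf("'acr' must be numeric")
  if (any(acr < 0, na.rm = TRUE)) stopf("'acr' must be nonnegative")
  log(acr + 1)
}

#' Trim outlying repeated readings and summarize
#'
#' One pass: readings more than `k` standard deviations from the mean are
#' discarded, then the mean and SD are recomputed.  The record passes QC when
#' at least `min_retained` readings remain (e.g. blood-pressure cycles).
#'
#' @param readings numeric vector (>= 2 values).
#' @param k SD multiple for the outlier rule (default 2).
#' @param min_retained minimum retained readings for a pass (default 40).
#' @return list with `mean`, `sd`, `n_retained`, `pass`, `removed` (indices).
#' @export
trim_readings <- function(readings, k = 2, min_retained = 40) {
  if (!is.numeric(readings) || length(readings) < 2)
    stopf("'readings' must be a numeric vector of length >= 2")
  m0 <- mean(readings); s0 <- stats::sd(readings)
  out <- if (s0 > 0) which(abs(readings - m0) > k * s0) else integer(0)
  kept <- if (length(out)) readings[-out] else readings
  list(mean = mean(kept), sd = stats::sd(kept), n_retained = length(kept),
       pass = length(kept) >= min_retained, removed = out)
}
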