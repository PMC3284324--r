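#' Genotype matrix container
#'
#' Bundles a samples x SNPs diploid dosage matrix (codes 0/1/2, `NA` for
#' missing) with per-SNP metadata (chromosome, 1-based physical position).
#' SNPs are stored sorted by (chromosome, position); all downstream window
#' arithmetic relies on that ordering.
#'
#' @param geno integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (one row per
#'   SNP column, 1-based positions).
#' @param sample_ids character vector of sample identifiers (defaults to
#'   rownames of `geno` or `s1..sn`).
#' @return an object of class `geno_matrix` with elements `geno`, `map`,
#'   `sample_ids`.
#' @export
geno_matrix <- function(geno, map, sample_ids = NULL) {
  geno <- as.matrix(geno)
  if (!is.numeric(geno)) stopf("'geno' must be a numeric matrix")
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad)) stopf("genotype codes must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stopf("'map' needs columns %s", paste(need, collapse = ", "))
  if (nrow(map) != ncol(geno))
    stopf("map has %d rows but geno has %d SNP columns", nrow(map), ncol(geno))
  if (anyDuplicated(map$snp_id)) stopf("duplicated snp_id in map")
  if (any(map$pos < 1)) stopf("positions must be >= 1 (1-based bp)")
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  sample_ids <- sample_ids %||% rownames(geno) %||%
    paste0("s", seq_len(nrow(geno)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(geno))
    stopf("length(sample_ids) != number of sample rows")
  ord <- order(map$chrom, map$pos)
  geno <- geno[, ord, drop = FALSE]
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dimnames(geno) <- list(sample_ids, map$snp_id)
  structure(list(geno = geno, map = map, sample_ids = sample_ids),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of samples / SNPs in a genotype matrix
#' @param x a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$geno)

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("geno_matrix: %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              n_samples(x), n_snps(x), length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`
#' @param i sample index (integer/logical/character)
#' @param j SNP index (integer/logical/character snp_ids)
#' @param ... unused
#' @return a `geno_matrix`
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_snps(x))
  if (is.character(j)) {
    j2 <- match(j, x$map$snp_id)
    if (anyNA(j2)) stopf("unknown snp_id: %s", paste(j[is.na(j2)], collapse = ", "))
    j <- j2
  }
  g <- x$geno[i, j, drop = FALSE]
  geno_matrix(g, x$map[j, , drop = FALSE], sample_ids = rownames(g))
}

# internal: additive scores -1/0/1 for requested SNPs (columns), refusing NA
geno_scores <- function(G, snp_ids = NULL, allow_missing = FALSE) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(snp_ids)) S <- G$geno - 1
  else {
    j <- match(snp_ids, G$map$snp_id)
    if (anyNA(j))
      stopf("unknown snp_id: %s", paste(snp_ids[is.na(j)], collapse = ", "))
    S <- G$geno[, j, drop = FALSE] - 1
  }
  if (!allow_missing && anyNA(S))
    stopf("genotype matrix contains missing calls; run impute_missing() first")
  S
}

#' Ground-truth record for simulated traits
#'
#' Describes the generative model of a simulated quantitative trait:
#' additive causal SNP effects plus a polygenic component with covariance
#' proportional to kinship plus independent residual noise.  Either per-SNP
#' effects (`beta`) or per-SNP target variance fractions (`var_explained`)
#' may be given; in the latter case effect sizes are solved at simulation
#' time from the realized genotype score variances.
#'
#' @param causal_snp_ids character vector of causal SNP ids (may be empty).
#' @param beta numeric vector of additive effects per allele copy, or NULL.
#' @param var_explained numeric vector of target fractions of total trait
#'   variance per causal SNP, or NULL.  Fractions must sum to < 1.
#' @param sigma_g2 polygenic variance (>= 0).
#' @param sigma_e2 residual variance (>= 0).
#' @return an object of class `truth_record`.
#' @export
truth_record <- function(causal_snp_ids = character(), beta = NULL,
                         var_explained = NULL, sigma_g2 = 0, sigma_e2 = 1) {
  check_number(sigma_g2, "sigma_g2", lower = 0)
  check_number(sigma_e2, "sigma_e2", lower = 0)
  m <- length(causal_snp_ids)
  if (is.null(beta) && is.null(var_explained) && m > 0)
    stopf("give either 'beta' or 'var_explained' for causal SNPs")
  if (!is.null(beta) && length(beta) != m)
    stopf("length(beta) must match causal_snp_ids")
  if (!is.null(var_explained)) {
    if (length(var_explained) != m)
      stopf("length(var_explained) must match causal_snp_ids")
    if (any(var_explained < 0) || sum(var_explained) >= 1)
      stopf("var_explained fractions must be >= 0 and sum to < 1")
  }
  structure(list(causal_snp_ids = as.character(causal_snp_ids),
                 beta_per_snp = beta, var_explained_per_snp = var_explained,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth_record: %d causal SNP(s), sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              length(x$causal_snp_ids), x$sigma_g2, x$sigma_e2))
  invisible(x)
}
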