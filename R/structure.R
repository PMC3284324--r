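#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the average over SNPs of `(2 - |g_i - g_j|) / 2` with
#' genotypes coded 0/1/2, i.e. the mean fraction of alleles shared state-wise
#' between two individuals.  Missing calls are handled pairwise-complete;
#' the diagonal is 1 by definition.
#'
#' @param G a `geno_matrix`.
#' @return symmetric n x n matrix in `[0, 1]`, dimnames = sample ids.
#' @export
ibs_kinship <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- G$geno
  M <- !is.na(g)
  A0 <- (g == 0) & M; A1 <- (g == 1) & M; A2 <- (g == 2) & M
  storage.mode(A0) <- "numeric"; storage.mode(A1) <- "numeric"
  storage.mode(A2) <- "numeric"; storage.mode(M) <- "numeric"
  # sum over SNPs of |g_i - g_j| restricted to jointly observed calls
  D <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
       tcrossprod(A1, A2) + tcrossprod(A2, A1) +
       2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  Nij <- tcrossprod(M)
  if (any(Nij[upper.tri(Nij)] == 0))
    stopf("some sample pair has no jointly observed SNP")
  K <- 1 - D / (2 * Nij)
  diag(K) <- 1
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  K
}

#' Pairwise genotype identity and duplicate detection
#'
#' Fraction of identical genotype calls between every sample pair (over
#' jointly non-missing SNPs), with summary statistics and pairs at or above
#' a duplicate threshold flagged.
#'
#' @param G a `geno_matrix` with >= 2 samples.
#' @param threshold duplicate flagging threshold (default 0.99).
#' @return list with `mean`, `min`, `max`, `flagged` (data.frame sample_a,
#'   sample_b, identity) and the full `identity` matrix.
#' @export
pairwise_identity <- function(G, threshold = 0.99) {
  stopifnot(inherits(G, "geno_matrix"))
  if (n_samples(G) < 2) stopf("need >= 2 samples")
  g <- G$geno
  M <- !is.na(g)
  same <- matrix(0, nrow(g), nrow(g))
  for (k in 0:2) {
    Ak <- (g == k) & M
    storage.mode(Ak) <- "numeric"
    same <- same + tcrossprod(Ak)
  }
  storage.mode(M) <- "numeric"
  Nij <- tcrossprod(M)
  id <- same / Nij
  dimnames(id) <- list(G$sample_ids, G$sample_ids)
  ut <- upper.tri(id)
  hits <- which(ut & id >= threshold, arr.ind = TRUE)
  flagged <- data.frame(sample_a = G$sample_ids[hits[, 1]],
                        sample_b = G$sample_ids[hits[, 2]],
                        identity = id[hits], stringsAsFactors = FALSE)
  list(mean = mean(id[ut]), min = min(id[ut]), max = max(id[ut]),
       flagged = flagged, identity = id)
}

#' Within-chromosome LD pairs (r-squared)
#'
#' For every pair of SNPs on the same chromosome closer than `window` bp,
#' the squared Pearson correlation of genotype dosages (0/1/2), computed
#' pairwise-complete.  Monomorphic SNPs are skipped.
#'
#' @param G a `geno_matrix`.
#' @param window maximum pair distance in bp (default 50 Mb).
#' @param sample_frac optional fraction in (0, 1] to thin the emitted pairs
#'   at random (for memory on dense chromosomes); default 1 = keep all.
#' @param seed RNG seed used only when `sample_frac < 1`.
#' @return data.frame with snp_a, snp_b, chrom, distance, r2.
#' @export
ld_pairs <- function(G, window = 5e7, sample_frac = 1, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  check_number(window, "window", lower = 0)
  check_fraction(sample_frac, "sample_frac")
  maf <- compute_maf(G)
  out <- vector("list", 0L)
  for (ch in unique(G$map$chrom)) {
    j <- which(G$map$chrom == ch & !is.na(maf) & maf > 0)
    if (length(j) < 2) next
    g <- G$geno[, j, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
    pos <- G$map$pos[j]
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    keep <- ut & d < window & !is.na(r2)
    idx <- which(keep, arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      snp_a = G$map$snp_id[j][idx[, 1]],
      snp_b = G$map$snp_id[j][idx[, 2]],
      chrom = ch, distance = d[keep], r2 = r2[keep],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_a = character(), snp_b = character(), chrom = character(),
               distance = numeric(), r2 = numeric())
  if (sample_frac < 1 && nrow(pairs) > 0)
    pairs <- with_seed(seed, pairs[stats::runif(nrow(pairs)) < sample_frac, ])
  rownames(pairs) <- NULL
  pairs
}

#' LD decay curve and decay radius
#'
#' Pairs are binned by distance, the median r2 per bin is LOWESS-smoothed,
#' and the decay radius is the smallest distance at which the smoothed curve
#' first drops below `threshold` (linear interpolation between bin centers;
#' the first bin center if the curve starts below the threshold).  When the
#' curve never crosses, the radius is `NA` with `reached = FALSE`.
#'
#' @param pairs data.frame from [ld_pairs()] (>= 100 pairs).
#' @param span LOWESS smoother span `f` (default 0.02; with the usual ~500
#'   distance bins this is a ~10-bin local window, narrow enough to resolve
#'   a decay radius that is a small fraction of the pair window).
#' @param bin_width distance bin width in bp; default `max(distance) / 500`.
#' @param threshold r2 level defining the radius (default 0.5).
#' @return object of class `ld_decay`: list with `curve` (data.frame
#'   distance, median_r2, smooth, n_pairs), `decay_radius`, `reached`.
#' @export
ld_decay <- function(pairs, span = 0.02, bin_width = NULL, threshold = 0.5) {
  if (nrow(pairs) < 100) stopf("need >= 100 LD pairs, got %d", nrow(pairs))
  bin_width <- bin_width %||% (max(pairs$distance) / 500)
  bin <- pmax(1L, ceiling(pairs$distance / bin_width))
  lev <- sort(unique(bin))
  f <- factor(bin, levels = lev)
  med <- as.numeric(tapply(pairs$r2, f, stats::median))
  centers <- (lev - 0.5) * bin_width
  np <- as.vector(table(f))
  sm <- stats::lowess(centers, med, f = span)
  curve <- data.frame(distance = centers, median_r2 = med,
                      smooth = sm$y, n_pairs = np)
  below <- which(curve$smooth < threshold)
  if (length(below) == 0) {
    radius <- NA_real_; reached <- FALSE
  } else {
    i <- below[1]
    reached <- TRUE
    radius <- if (i == 1) curve$distance[1] else {
      x0 <- curve$distance[i - 1]; x1 <- curve$distance[i]
      y0 <- curve$smooth[i - 1]; y1 <- curve$smooth[i]
      x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  structure(list(curve = curve, decay_radius = radius, reached = reached,
                 threshold = threshold),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  if (x$reached)
    cat(sprintf("ld_decay: median r2 crosses %.2f at %.3f Mb (%d bins)\n",
                x$threshold, x$decay_radius / 1e6, nrow(x$curve)))
  else
    cat(sprintf("ld_decay: smoothed median r2 never drops below %.2f\n",
                x$threshold))
  invisible(x)
}

#' Symmetric Shannon entropy of a diallelic SNP
#'
#' `-(p log p + (1 - p) log(1 - p))` in nats, with `0 log 0 = 0`; the
#' standard (nonnegative) form, maximal `log 2` at p = 0.5 and symmetric in
#' `p` and `1 - p`.
#'
#' @param maf allele frequency (vectorized), in `[0, 1]`.
#' @return entropy in nats.
#' @export
snp_entropy <- function(maf) {
  if (any(maf < 0 | maf > 1, na.rm = TRUE))
    stopf("'maf' must be in [0, 1]")
  p <- maf; q <- 1 - maf
  h <- -(ifelse(p > 0, p * log(p), 0) + ifelse(q > 0, q * log(q), 0))
  h
}

#' Mean SNP information content in genomic windows
#'
#' Mean [snp_entropy()] of SNP MAFs in non-overlapping tiles per chromosome
#' (1-based; window `w` covers `[(k-1) w + 1, k w]`).  Empty windows are
#' reported with `NA`.
#'
#' @param G a `geno_matrix`.
#' @param window tile width in bp (default 4 Mb).
#' @return data.frame chrom, start, end, n_snps, mean_entropy.
#' @export
entropy_windows <- function(G, window = 4e6) {
  stopifnot(inherits(G, "geno_matrix"))
  check_number(window, "window", lower = 1)
  ent <- snp_entropy(compute_maf(G))
  out <- list()
  for (ch in unique(G$map$chrom)) {
    j <- which(G$map$chrom == ch)
    pos <- G$map$pos[j]
    nwin <- ceiling(max(pos) / window)
    win <- pmin(nwin, ceiling(pos / window))
    me <- tapply(ent[j], factor(win, levels = seq_len(nwin)), mean,
                 na.rm = TRUE)
    ns <- tabulate(win, nbins = nwin)
    out[[ch]] <- data.frame(chrom = ch,
                            start = (seq_len(nwin) - 1) * window + 1,
                            end = seq_len(nwin) * window,
                            n_snps = ns, mean_entropy = as.numeric(me),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of samples on kinship
#'
#' Average-linkage clustering on the distance `1 - K`; used to visualize
#' family structure.
#'
#' @param K kinship matrix.
#' @return list of class `sample_clustering` with `hclust` (NULL when n = 1)
#'   and `order` (leaf order).
#' @export
cluster_samples <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stopf("'K' must be square")
  if (nrow(K) == 1)
    return(structure(list(hclust = NULL, order = 1L),
                     class = "sample_clustering"))
  hc <- stats::hclust(stats::as.dist(1 - K), method = "average")
  structure(list(hclust = hc, order = hc$order), class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample_clustering: %d leaves (average linkage on 1 - kinship)\n",
              length(x$order)))
  invisible(x)
}
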