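# File I/O: PLINK-style .ped/.map, genotype/phenotype/kinship TSV, optional
# VCF import, JSON for reports and truth records.

#' Write genotypes as PLINK-style .ped/.map text files
#'
#' Alleles are written as A (reference) and B (alternate); missing calls as
#' `0 0`.  The .map file carries chrom, snp_id, a zero genetic position and
#' the bp position.
#'
#' @param G a `geno_matrix`.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param phenotype optional numeric vector written in the .ped phenotype
#'   column (defaults to -9).
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(G, prefix, phenotype = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- G$geno
  n <- nrow(g)
  m <- ncol(g)
  # two allele columns per SNP, interleaved (A = reference, B = alternate)
  alleles <- matrix("0", n, 2 * m)
  a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "B", "A"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 2, "B", "A"))
  alleles[, seq(1, 2 * m, by = 2)] <- a1
  alleles[, seq(2, 2 * m, by = 2)] <- a2
  ped <- data.table::data.table(
    fid = G$sample_ids, iid = G$sample_ids, pat = 0L, mat = 0L, sex = 0L,
    pheno = phenotype %||% rep(-9, n))
  ped <- cbind(ped, data.table::as.data.table(alleles))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ",
                     col.names = FALSE, quote = FALSE)
  map <- data.table::data.table(chrom = G$map$chrom, snp_id = G$map$snp_id,
                                cm = 0, pos = as.integer(G$map$pos))
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK-style .ped/.map text files
#'
#' Dosages count the alternate allele, taken as the alphabetically last
#' allele symbol at each SNP (so `B` in files written by [write_ped_map()],
#' making the round trip exact); `0` denotes missing.
#'
#' @param prefix path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @return a `geno_matrix`.
#' @export
read_ped_map <- function(prefix) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  if (!file.exists(mapf) || !file.exists(pedf))
    stopf("missing %s or %s", mapf, pedf)
  map <- data.table::fread(mapf, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- data.table::fread(pedf, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stopf(".ped has %d columns; expected %d for %d SNPs", ncol(ped),
          6 + 2 * m, m)
  ids <- ped[[2]]
  geno <- matrix(NA_real_, nrow(ped), m)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    obs <- c(a1, a2)
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) == 0) next
    # a monomorphic SNP offers no ref/alt evidence: count "B" (the writer's
    # alternate symbol) if that is what is observed, else dosage 0
    alt <- if (length(alleles) == 1 && alleles != "B") "__none__"
           else alleles[length(alleles)]
    miss <- a1 == "0" | a2 == "0"
    geno[, j] <- (a1 == alt) + (a2 == alt)
    geno[miss, j] <- NA
  }
  geno_matrix(geno, data.frame(snp_id = map$snp_id, chrom = map$chrom,
                               pos = map$pos), sample_ids = ids)
}

#' Write / read a genotype matrix as TSV
#'
#' Layout: columns snp_id, chrom, pos, then one column per sample with
#' dosages 0/1/2 (NA for missing).
#'
#' @param G a `geno_matrix`.
#' @param path file path.
#' @return `read_geno_tsv` returns a `geno_matrix`.
#' @export
write_geno_tsv <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  dt <- data.table::data.table(snp_id = G$map$snp_id, chrom = G$map$chrom,
                               pos = G$map$pos)
  dt <- cbind(dt, data.table::as.data.table(t(G$geno)))
  data.table::setnames(dt, c("snp_id", "chrom", "pos", G$sample_ids))
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(dt))) stopf("genotype TSV needs columns %s",
                                       paste(need, collapse = ", "))
  ids <- setdiff(names(dt), need)
  geno <- t(as.matrix(dt[, ids, with = FALSE]))
  geno_matrix(geno, data.frame(snp_id = dt$snp_id, chrom = dt$chrom,
                               pos = dt$pos), sample_ids = ids)
}

#' Write / read a phenotype table (TSV keyed by sample_id)
#'
#' @param pheno data.frame with a `sample_id` column and numeric trait
#'   columns.
#' @param path file path.
#' @return `read_pheno_tsv` returns a data.frame.
#' @export
write_pheno_tsv <- function(pheno, path) {
  if (!"sample_id" %in% names(pheno)) stopf("'pheno' needs a sample_id column")
  data.table::fwrite(data.table::as.data.table(pheno), path, sep = "\t",
                     na = "NA")
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"sample_id" %in% names(df)) stopf("phenotype TSV needs sample_id")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write / read a kinship matrix as square TSV with header ids
#'
#' @param K kinship matrix with sample-id dimnames.
#' @param path file path.
#' @return `read_kinship_tsv` returns a matrix.
#' @export
write_kinship_tsv <- function(K, path) {
  dt <- data.table::as.data.table(K, keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt$sample_id
  K <- as.matrix(dt[, -1, with = FALSE])
  dimnames(K) <- list(ids, colnames(K))
  K
}

#' Import genotype dosages from a VCF file
#'
#' Uses the VariantAnnotation package (suggested dependency) to read GT
#' calls; dosages count the first ALT allele, any call containing a missing
#' allele becomes NA.
#'
#' @param path VCF file path.
#' @return a `geno_matrix`.
#' @export
read_vcf_geno <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("VCF import needs the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- function(x) {
    if (x %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  geno <- t(apply(gt, c(1, 2), dose))
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(snp_id = rownames(gt),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr), stringsAsFactors = FALSE)
  geno_matrix(geno, map, sample_ids = rownames(geno))
}

#' Write a truth record or QC report as JSON
#'
#' @param x a `truth_record`, `qc_report` or plain list.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
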