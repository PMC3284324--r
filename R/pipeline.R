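# End-to-end orchestration: simulate or load data, QC, structure, scans,
# thresholds, multilocus and precision stages, with a rerunnable manifest.

#' Assemble and validate a pipeline configuration
#'
#' Either a simulation preset (`preset`, with optional `preset_overrides`)
#' or input files (`geno_tsv` or `ped_prefix`, plus `pheno_tsv`) must be
#' given.  All window/position arithmetic is 1-based bp.
#'
#' @param out_dir output directory (created if absent).
#' @param seed root RNG seed (integer, required: every stage derives its
#'   substreams from it).
#' @param preset `"nmri-like"`, `"tiny"`, or NULL when loading files.
#' @param preset_overrides named list of [sim_config()] overrides.
#' @param geno_tsv,ped_prefix,pheno_tsv input file paths (alternative to
#'   `preset`).
#' @param traits character vector of trait columns to analyze (NULL = all).
#' @param tests scan statistics to run (subset of trend/anova/mixed).
#' @param qc list: maf_min, hwe_max, miss_max, collapse_window.
#' @param thresholds list: method ("structured" and/or "free"), reps, alphas,
#'   test (single test used for thresholds), or NULL to skip.
#' @param rmip list: reps, window_mb, max_terms, or NULL to skip.
#' @param precision list: var_explained, sims, test, or NULL to skip.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, preset = NULL,
                            preset_overrides = list(), geno_tsv = NULL,
                            ped_prefix = NULL, pheno_tsv = NULL,
                            traits = NULL,
                            tests = c("trend", "anova", "mixed"),
                            qc = list(), thresholds = list(),
                            rmip = NULL, precision = NULL) {
  check_number(seed, "seed", integer = TRUE)
  if (length(tests) == 0) stopf("no tests selected")
  tests <- match.arg(tests, c("trend", "anova", "mixed"), several.ok = TRUE)
  if (is.null(preset) && is.null(geno_tsv) && is.null(ped_prefix))
    stopf("give a simulation preset or genotype input files")
  for (f in c(geno_tsv, pheno_tsv))
    if (!is.null(f) && !file.exists(f)) stopf("input file not found: %s", f)
  qc <- utils::modifyList(list(maf_min = 0.02, hwe_max = 20, miss_max = 0.40,
                               collapse_window = 2e6), qc)
  if (length(thresholds))
    thresholds <- utils::modifyList(
      list(method = "structured", reps = 100, alphas = 0.05, test = "mixed"),
      thresholds)
  if (!is.null(rmip))
    rmip <- utils::modifyList(list(reps = 100, window_mb = 1, max_terms = 20),
                              rmip)
  if (!is.null(precision))
    precision <- utils::modifyList(list(var_explained = 0.2, sims = 200,
                                        test = "mixed"), precision)
  structure(list(out_dir = out_dir, seed = seed, preset = preset,
                 preset_overrides = preset_overrides, geno_tsv = geno_tsv,
                 ped_prefix = ped_prefix, pheno_tsv = pheno_tsv,
                 traits = traits, tests = tests, qc = qc,
                 thresholds = thresholds, rmip = rmip,
                 precision = precision),
            class = "pipeline_config")
}

#' Run the full association-mapping pipeline
#'
#' Stages, in order: data (simulate or load), QC (filter, collapse, impute),
#' structure (kinship, pairwise identity, LD decay, entropy track), genome
#' scans (per trait x test), significance thresholds, optional multilocus
#' RMIP and optional precision simulation.  Every stage writes its outputs
#' under `out_dir` and the manifest (`manifest.json`) records inputs, seeds,
#' counts and package version so a run can be reproduced exactly.
#'
#' @param config a `pipeline_config` (or a path to a JSON file of its
#'   fields).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- do.call(pipeline_config, jsonlite::read_json(config,
                                                           simplifyVector = TRUE))
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config or a JSON path")
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  manifest <- list(package = "outbredgwas",
                   version = as.character(utils::packageVersion("outbredgwas")),
                   seed = cf$seed, stages = list())
  seeds <- substream_seeds(cf$seed, 8L)

  # -- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cf$preset)) {
    sim_cf <- do.call(sim_preset, c(list(name = cf$preset,
                                         seed = seeds[[1]]),
                                    cf$preset_overrides))
    G <- simulate_population(sim_cf)
    K0 <- NULL
    pheno <- data.frame(sample_id = G$sample_ids)
    log_line("data", "simulated preset '%s': %d samples x %d SNPs",
             cf$preset, n_samples(G), n_snps(G))
    manifest$stages$data <- list(source = "simulated", preset = cf$preset,
                                 n_samples = n_samples(G), n_snps = n_snps(G))
  } else {
    G <- if (!is.null(cf$geno_tsv)) read_geno_tsv(cf$geno_tsv)
         else read_ped_map(cf$ped_prefix)
    pheno <- read_pheno_tsv(cf$pheno_tsv)
    pheno <- pheno[match(G$sample_ids, pheno$sample_id), , drop = FALSE]
    if (anyNA(pheno$sample_id)) stopf("phenotype table misses some samples")
    log_line("data", "loaded %d samples x %d SNPs", n_samples(G), n_snps(G))
    manifest$stages$data <- list(source = "files", n_samples = n_samples(G),
                                 n_snps = n_snps(G))
  }

  # -- qc ------------------------------------------------------------------
  fl <- filter_snps(G, cf$qc$maf_min, cf$qc$hwe_max, cf$qc$miss_max)
  cl <- collapse_identical(fl$G, cf$qc$collapse_window)
  report <- fl$report
  report$n_after_collapse <- n_snps(cl$G)
  G <- impute_missing(cl$G, seed = seeds[[2]])
  write_json_report(report, file.path(cf$out_dir, "qc_report.json"))
  data.table::fwrite(cl$mapping, file.path(cf$out_dir, "collapse_mapping.tsv"),
                     sep = "\t")
  log_line("qc", "%d SNPs pass filters, %d after collapsing",
           report$n_pass_filters, report$n_after_collapse)
  manifest$stages$qc <- report[c("n_input_snps", "n_polymorphic",
                                 "n_pass_filters", "n_after_collapse")]

  # -- traits (simulated presets get one planted-QTL trait) ----------------
  if (!is.null(cf$preset)) {
    causal <- with_seed(seeds[[3]],
                        sample(G$map$snp_id[compute_maf(G) > 0.2], 1L))
    K0 <- ibs_kinship(G)
    tr <- simulate_trait(G, K0, truth_record(causal, var_explained = 0.2,
                                             sigma_g2 = 0.3, sigma_e2 = 0.7),
                         seed = seeds[[4]])
    truth <- tr$truth
    pheno$trait1 <- tr$y
    write_json_report(truth, file.path(cf$out_dir, "truth.json"))
  }
  trait_cols <- cf$traits %||% setdiff(names(pheno), "sample_id")
  if (length(trait_cols) == 0) stopf("no trait columns to analyze")

  # -- structure -----------------------------------------------------------
  K <- ibs_kinship(G)
  write_kinship_tsv(K, file.path(cf$out_dir, "kinship.tsv"))
  pid <- pairwise_identity(G)
  ld <- ld_decay(ld_pairs(G))
  data.table::fwrite(ld$curve, file.path(cf$out_dir, "ld_curve.tsv"),
                     sep = "\t")
  ent <- entropy_windows(G)
  data.table::fwrite(ent, file.path(cf$out_dir, "entropy_windows.tsv"),
                     sep = "\t")
  log_line("structure", "mean pairwise identity %.3f; LD radius %s",
           pid$mean, if (ld$reached) sprintf("%.2f Mb", ld$decay_radius / 1e6)
                     else "not reached")
  manifest$stages$structure <- list(
    mean_identity = pid$mean, n_duplicate_pairs = nrow(pid$flagged),
    ld_decay_radius_bp = if (ld$reached) ld$decay_radius else NA,
    mean_entropy = mean(ent$mean_entropy, na.rm = TRUE))

  # -- scans ---------------------------------------------------------------
  scan_summary <- list()
  for (trait in trait_cols) {
    y <- pheno[[trait]]
    for (test in cf$tests) {
      sc <- genome_scan(y, G, test = test, K = K)
      fn <- file.path(cf$out_dir, sprintf("scan_%s_%s.tsv", trait, test))
      data.table::fwrite(as.data.frame(sc), fn, sep = "\t")
      top <- sc[which.max(sc$neg_log10_p), ]
      log_line("scan", "%s/%s: top %s (-log10 p = %.2f)", trait, test,
               top$snp_id, top$neg_log10_p)
      scan_summary[[paste(trait, test, sep = ".")]] <-
        list(top_snp = top$snp_id, top_score = top$neg_log10_p)
    }
  }
  manifest$stages$scans <- scan_summary

  # -- thresholds ----------------------------------------------------------
  if (length(cf$thresholds)) {
    th_grid <- list()
    th_seeds <- substream_seeds(seeds[[5]],
                                length(trait_cols) * length(cf$thresholds$method))
    i <- 0L
    for (trait in trait_cols) for (meth in cf$thresholds$method) {
      i <- i + 1L
      th <- permutation_threshold(pheno[[trait]], G, K, method = meth,
                                  test = cf$thresholds$test,
                                  R = cf$thresholds$reps,
                                  alphas = cf$thresholds$alphas,
                                  seed = th_seeds[[i]], trait = trait)
      write_json_report(th[c("trait", "test", "method", "R", "gev",
                             "alphas", "thresholds", "maxima")],
                        file.path(cf$out_dir,
                                  sprintf("thresholds_%s_%s.json", trait, meth)))
      log_line("thresholds", "%s/%s: alpha 0.05 threshold %.2f", trait, meth,
               th$thresholds[1])
      th_grid[[paste(trait, meth, sep = ".")]] <- as.list(th$thresholds)
      key <- paste(trait, cf$thresholds$test, sep = ".")
      if (!is.null(scan_summary[[key]]))
        scan_summary[[key]]$above_threshold_0.05 <-
          scan_summary[[key]]$top_score > th$thresholds[1]
    }
    manifest$stages$thresholds <- th_grid
    manifest$stages$scans <- scan_summary
  }

  # -- multilocus ----------------------------------------------------------
  if (!is.null(cf$rmip)) {
    rm_res <- rmip(pheno[[trait_cols[1]]], G, R = cf$rmip$reps,
                   w = cf$rmip$window_mb * 1e6,
                   max_terms = cf$rmip$max_terms, seed = seeds[[6]])
    data.table::fwrite(as.data.frame(rm_res),
                       file.path(cf$out_dir, "rmip.tsv"), sep = "\t")
    write_json_report(list(selections = attr(rm_res, "selections")),
                      file.path(cf$out_dir, "rmip_selections.json"))
    log_line("rmip", "top RMIP %.2f at %s", max(rm_res$rmip),
             rm_res$snp_id[which.max(rm_res$rmip)])
    manifest$stages$rmip <- list(top_rmip = max(rm_res$rmip),
                                 top_snp = rm_res$snp_id[which.max(rm_res$rmip)])
  }

  # -- precision -----------------------------------------------------------
  if (!is.null(cf$precision)) {
    vc <- reml_fit(pheno[[trait_cols[1]]], K)
    pr <- precision_simulation(G, K, cf$precision$var_explained,
                               vc$sigma_g2, vc$sigma_e2,
                               n_sim = cf$precision$sims,
                               test = cf$precision$test, seed = seeds[[7]])
    data.table::fwrite(as.data.frame(pr),
                       file.path(cf$out_dir, "precision_runs.tsv"), sep = "\t")
    ds <- distance_summary(pr)
    write_json_report(ds, file.path(cf$out_dir, "precision_summary.json"))
    log_line("precision", "median distance %.2f Mb, %.1f%% same-chromosome",
             ds$quantiles_bp[[1]] / 1e6, 100 * ds$same_chromosome_rate)
    manifest$stages$precision <- ds
  }

  write_json_report(manifest, file.path(cf$out_dir, "manifest.json"))
  write_pheno_tsv(pheno, file.path(cf$out_dir, "phenotypes.tsv"))
  write_geno_tsv(G, file.path(cf$out_dir, "genotypes_postqc.tsv"))
  invisible(manifest)
}
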