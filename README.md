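# outbredgwas

Genome-wide association mapping of quantitative traits in outbred
populations — commercial outbred mouse stocks in particular — as a single,
tested R pipeline.

Outbred stocks (cohorts of a few hundred animals genotyped at tens of
thousands of SNPs) promise finer mapping resolution than inbred-line
crosses, but analyzing them raises the same issues as a small human GWAS:
marker quality control, cryptic relatedness, genome-wide multiple testing
with correlated markers, and linked or "ghost" association signals. This
package implements the full analysis stack:

- **QC** — minor-allele-frequency, Hardy–Weinberg (χ², 1 df) and
  missingness filters with strict, auditable first-fail accounting;
  collapsing of identical SNPs within a 2 Mb window; frequency-sampling
  imputation; phenotype rules (reading trimming at ±2 SD with a minimum
  retained count, `log(x + 1)` for zero-inflated ratios).
- **Structure** — identity-by-state kinship
  `K[i,j] = mean (2 − |g_i − g_j|)/2`, pairwise-identity duplicate
  screening, LD decay (median r² of dosages in distance bins, LOWESS
  smoothed, radius = first crossing of r² = 0.5), symmetric Shannon
  entropy `−(p ln p + q ln q)` as per-SNP information content, and
  average-linkage clustering on `1 − K`.
- **Scans** — three single-locus statistics: the additive trend test
  (regression on −1/0/1 scores, 1 df), genotype-class ANOVA (2 df), and a
  kinship mixed model `y ~ N(Xβ + s b, σ²_g K + σ²_e I)` with REML variance
  components estimated by spectral decomposition and a 1-D search over
  δ = σ²_e/σ²_g (variance components reused genome-wide by default,
  re-estimated per SNP on request). Conditional scans take previously
  selected SNPs as covariates.
- **Significance** — a kinship-preserving *structured permutation*: fit
  variance components to the van der Waerden scores of the trait, draw
  `z ~ MVN(0, σ²_g K + σ²_e I)`, and give the observed value of rank *k* to
  the individual holding rank *k* in `z`; scan each permuted trait, collect
  genome-wide maxima, fit a generalized extreme value distribution, and
  read thresholds off its quantiles. Plain (free) permutation is provided
  for comparison.
- **Multilocus** — forward-stepwise regression (up to 20 SNPs) on bootstrap
  resamples, summarized as resample model inclusion probabilities,
  `RMIP_m = (1/R) Σ_r i_rm`, where `i_rm = 1` if a SNP within ±w of SNP *m*
  entered the model of resample *r*.
- **Precision** — plant a causal SNP explaining a chosen fraction of trait
  variance, remove it, rescan, and record peak-to-target distances (median
  over tied peaks; cross-chromosome peaks flagged and excluded).
- **Synthetic cohorts** — a generator that emulates an outbred colony (a
  small founder pool bred closed for many generations, then expanded into
  sib families), giving realistic LD decay, a broad MAF spectrum and mild
  kinship structure, plus ground-truth records so every stage is testable
  without external data.

## Worked example

```r
library(outbredgwas)

# 1. simulate an outbred cohort (288 animals, 4 chromosomes for the demo)
cfg <- sim_preset("nmri-like", seed = 1, n_chroms = 4, n_snps_per_chrom = 600)
pop <- simulate_population(cfg)
pop
#> geno_matrix: 288 samples x 2400 SNPs on 4 chromosome(s); 1.28% missing

# 2. SNP QC: MAF/HWE/missingness filters, collapse identical SNPs, impute
qc <- filter_snps(pop)
qc$report
#> qc_report: 2400 SNPs in, 952 polymorphic, 930 pass filters
#>   removed by all_missing: 0
#>   removed by maf:         1470
#>   removed by hwe:         0
#>   removed by missingness: 0
geno <- impute_missing(collapse_identical(qc$G)$G, seed = 1)

# 3. population structure: IBS kinship and LD decay (LD on the filtered,
#    pre-collapse panel: identical neighbors are part of short-range LD)
K <- ibs_kinship(geno)
round(mean(K[upper.tri(K)]), 3)
#> [1] 0.709
ld_decay(ld_pairs(impute_missing(qc$G, seed = 1)))
#> ld_decay: median r2 crosses 0.50 at 0.232 Mb (500 bins)

# 4. a trait with one 20%-variance QTL plus polygenic background
qtl <- geno$map$snp_id[match(TRUE, compute_maf(geno) > 0.3)]
trait <- simulate_trait(geno, K, truth_record(qtl, var_explained = 0.2,
                                              sigma_g2 = 0.3, sigma_e2 = 0.7),
                        seed = 2)

# 5. kinship mixed-model genome scan and a structured-permutation threshold
scan <- genome_scan(trait$y, geno, test = "mixed", K = K)
scan
#> gwas_scan: 726 SNPs, test = mixed; top hit snp_c01_000002 (-log10 p = 8.83)
thr <- permutation_threshold(trait$y, geno, K, method = "structured",
                             test = "mixed", R = 100, seed = 3)
thr
#> gwas_thresholds (structured permutation, mixed test, R = 100, mle fit)
#>   alpha = 0.05: 3.857
sum(scan$neg_log10_p > thr$thresholds[["0.05"]], na.rm = TRUE)
#> [1] 2
qtl
#> [1] "snp_c01_000002"
```

The scan's top hit (−log10 p = 8.83) is exactly the planted QTL, it clears
the genome-wide 5% threshold of 3.86 derived from 100 kinship-preserving
permutations, and only one other (linked) SNP joins it above the line. The
mean pairwise kinship of 0.709 reflects the colony's shared ancestry —
which is why the mixed model and the structured permutation are used
instead of their naive counterparts.

Downstream, `rmip()` ranks loci by how reproducibly they enter bootstrap
multilocus models, and `precision_simulation()` estimates how far a peak
typically sits from its causal SNP on this marker map.

## Command line

Every stage is also a subcommand of the installed script
(`inst/cli/outbredgwas`):

```sh
outbredgwas simulate --preset nmri-like --seed 1 --out sim
outbredgwas qc --ped sim --out qc
outbredgwas scan --geno qc_geno.tsv --pheno sim_pheno.tsv \
    --trait trait1 --test mixed --out scan.tsv
outbredgwas thresholds --geno qc_geno.tsv --pheno sim_pheno.tsv \
    --trait trait1 --method structured --reps 100 --out thresholds.json
outbredgwas run-all --preset tiny --seed 7 --out pipeline_out
```

Genotypes are accepted as PLINK-style `.ped`/`.map`, a genotype TSV, or
(with VariantAnnotation installed) a VCF.

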