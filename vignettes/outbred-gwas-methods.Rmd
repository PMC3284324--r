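---
title: "Methods: association mapping in outbred cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association mapping in outbred cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generator and the numerical choices behind
`outbredgwas`. It states no empirical result that the test suite does not
itself compute.

## The setting

The package targets cohorts of a few hundred outbred animals genotyped at
tens of thousands of diallelic SNPs — for instance a commercial outbred
mouse stock phenotyped for metabolic and cardiovascular traits. Such
populations sit between an inbred cross and a human GWAS: minor allele
frequencies are high and linkage disequilibrium decays within a few
megabases, but all animals descend from a small founder pool, so cryptic
relatedness is pervasive and a scan statistic that assumes exchangeable
individuals is miscalibrated.

## Single-locus scans

Three statistics are offered, all reported as −log10 p:

* **Trend test (1 df).** Least squares of the trait on additive scores
  −1/0/1 for genotypes AA/AB/BB, plus an intercept and optional
  covariates; the F statistic for the score coefficient (equivalently the
  squared t). Assumes additivity at the locus.
* **ANOVA (up to 2 df).** Genotype as a factor, so dominance is free;
  df equals the number of observed genotype classes minus one. With two
  classes it coincides with the trend test on that contrast.
* **Kinship mixed model.** `y ~ N(Xβ + s b, σ²_g K + σ²_e I)` with `K` the
  identity-by-state kinship. Variance components are estimated by
  restricted maximum likelihood and each SNP is tested by a generalized
  least squares trend test after whitening by the fitted covariance.

P-values use the F reference distribution with the model's residual
degrees of freedom rather than the asymptotic χ²: at n ≈ 288 the
difference is visible in the extreme tail that genome-wide thresholds
live in. (Whether the original analyses used F or χ² is not documented;
F is the conservative small-sample choice.)

### REML details

With `S` the projector orthogonal to the fixed effects, the spectrum of
`S K S` reduces the restricted likelihood to a one-dimensional profile in
δ = σ²_e/σ²_g. The profile is evaluated on 100 log-spaced points over
[1e−5, 1e5] and refined by golden-section search in the winning bracket;
an optimum on the grid edge is flagged (`boundary`), which is the normal
outcome when the true σ²_g is ~0. Eigenvalues are computed from
`S(K + I)S` and shifted by −1 so the null-space eigenvalues separate
cleanly; small negative remainders are clamped to zero, and a kinship
whose projected spectrum is substantially negative is rejected. If the
projected spectrum is flat (e.g. `K = I`), only σ²_g + σ²_e is
identifiable: the fit sets δ = 1, flags `unidentifiable`, and the
whitening becomes a harmless rescaling — the mixed scan then reproduces
the trend scan exactly, which the test suite asserts to 1e−8.

By default the null-model components are reused for every SNP
(`refit = "once"`); `refit = "per_snp"` re-estimates them with the SNP in
the fixed effects. The two agree closely on traits with moderate signal
(tested), and the one-shot version is orders of magnitude faster, which
matters because the permutation thresholds re-scan the genome hundreds of
times.

## Genome-wide significance: structured permutation + GEV

Free permutation of the trait destroys the familial correlation that the
mixed model exists to respect, so the package's primary thresholding
procedure is a rank-matching scheme that permutes the data *without*
breaking the kinship structure:

1. transform the trait to van der Waerden scores (rank *i* of *n* maps to
   Φ⁻¹(i/(n+1)), mid-ranks for ties) — this happens first, and the
   variance components are estimated on the transformed trait;
2. draw `z ~ MVN(0, σ̂²_g K + σ̂²_e I)`;
3. reassign the observed value of rank *k* to the individual with rank
   *k* in `z`.

The output is an exact permutation of the observed values (the empirical
distribution is preserved; asserted for every seed in the tests), it is
uniform over orderings when σ̂²_g = 0 (χ² test over all 120 orderings of
n = 5 in the tests), and related individuals keep co-ranked values.
Each permuted trait is scanned, the genome-wide maximum −log10 p is
recorded, and after `R` replicates (default 100, the conventional choice;
the acceptance tests use more for Monte-Carlo stability) a generalized
extreme value distribution is fitted to the maxima by maximum likelihood
— location/scale initialized from Gumbel moment matching, shape free,
Nelder–Mead on (μ, log σ, ξ) — and threshold(α) is its 1−α quantile.
The GEV smooths the far tail that `R = 100` raw maxima estimate poorly; on
draws from a known Gumbel the fitted 95% quantile lands within ±0.15 of
the closed form (tested), and the family-wise error of the resulting
threshold on a fully null polygenic trait is inside the 99% binomial band
around 5% (tested, 200 independent scans). `fit = "empirical"` substitutes
order-statistic quantiles when the fit is unwanted or the maxima are
degenerate. Rank ties in the observed trait are broken by original sample
order; ties in `z` have probability zero and fall back to stable order.

## Multilocus mapping: bootstrap stepwise and RMIP

Complex traits carry several loci, and strongly linked pairs can forge a
spurious intermediate "ghost" peak. Forward stepwise selection — greedily
adding the SNP with the smallest conditional p-value, ties broken by map
order — is run on `R` bootstrap resamples of the samples (rows drawn with
replacement, duplicates kept as-is), up to `max_terms` SNPs (default 20;
the number only needs to exceed the plausible QTL count). Each SNP is then
scored by its resample model inclusion probability: the fraction of
resamples in which some SNP within ±w of it was selected. Windows from
±0.5 to ±4 Mb are the useful range on a mouse-stock LD landscape; RMIP is
non-decreasing in w by construction (tested). The stepwise models use
ordinary least squares with trend coding: selection frequency under
resampling, not mixed-model calibration, is what RMIP measures, and a
ghost SNP that never survives conditioning on its two parents gets high
marginal significance but near-zero RMIP (tested on a constructed ghost).

## Mapping precision

To estimate how far an association peak typically sits from its causal
variant, the precision module repeatedly samples a target SNP, simulates
a trait in which that SNP explains a fixed fraction *f* of the total
variance — the effect is solved from
β² Var(s) / (β² Var(s) + σ²_g + σ²_e) = f, the only reading that keeps
the total variance fixed as targets of different frequency are drawn —
removes the target from the panel, rescans, and records the distance from
the peak to the target. Exactly tied peaks contribute the median of their
distances; a peak on another chromosome is counted in the
cross-chromosome rate and excluded from the distance distribution.
Collapsed duplicates of the target are *not* removed (only the selected
SNP is), so a perfect surrogate can legitimately carry the peak. The
distance quantiles shrink as *f* grows and keep a long right tail
(q95/q50 > 3 at cohort scale — both tested).

## The synthetic cohort generator

`simulate_population()` emulates the demographic history of a commercial
outbred colony: `n_founders` diploid founders (default 25) whose
haplotypes carry independent per-SNP allele frequencies drawn uniformly
from [`maf_floor`, 1 − `maf_floor`]; `n_generations` (default 50) of
random mating at constant pool size, with Poisson(`recomb_rate`)
crossovers per chromosome per meiosis placed uniformly (no interference —
irrelevant to any tested property); and a final expansion in which the
output samples are produced by breeding pairs, giving known sib families.
Drift in the small closed pool is what creates linkage disequilibrium;
the preset parameters were calibrated once, before the test suite was
written, so that the genome-wide median r² crosses 0.5 at roughly 1 Mb
and the post-filter mean MAF lands near 0.25 — the regime reported for
real outbred mouse stocks. Two presets are named: `nmri-like`
(288 samples, 19 × 100 Mb chromosomes, ~2,400 SNPs each, 1.3% missing
calls) and `tiny` (64 samples, 500 SNPs on 2 chromosomes) for tests.

Traits are `y = Σ β_m s_m + u + e` with `u ~ MVN(0, σ²_g K)` and
`e ~ N(0, σ²_e I)`; effects can be given directly or solved from target
variance fractions, and realized fractions are recorded in the returned
truth record. `simulate_acr_like()` adds a zero-inflated, right-skewed
trait (a point mass at zero plus an exponentiated normal) to exercise the
`log(x + 1)` phenotype path.

What the generator does **not** emulate — and hence what a green test
does not establish:

* **Mutational ancestry.** Real tight SNP pairs share a coalescent
  history, so short-range r² is almost continuous up to 1. Drift from a
  founder pool instead makes short-range r² bimodal: pairs are either
  essentially duplicated or weakly correlated. Consequently, collapsing
  identical SNPs removes most of the r² ≈ 1 mass, and the post-collapse
  decay curve starts lower than a real array's would. LD-decay checks are
  therefore run on the pre-collapse panel.
* **Array ascertainment.** SNP positions are uniform and frequencies are
  not biased toward common variants the way array content is.
* **Real linkage maps.** The genetic↔physical map is linear and uniform
  per chromosome.
* The long-range LD it *does* produce (drift among few lineages) is a
  genuine feature of bottlenecked laboratory stocks, and it means the
  strongest proxy of a planted QTL can sit more than a megabase away —
  tests of localization accept tight LD proxies (r² ≥ 0.8) for this
  reason.

## QC rules and their edge cases

Filter comparisons are strict, exactly as conventionally printed:
MAF > 0.02, HWE χ² < 20, missingness < 0.40. A SNP failing several rules
is counted once, under the first failing rule in the order
MAF → HWE → missingness; SNPs with no observed call are always dropped.
The HWE χ² of a monomorphic SNP is defined as 0 (it passes HWE, fails
MAF). Identical-SNP collapsing compares genotype vectors over jointly
non-missing entries, scans left-to-right within each chromosome, and
keeps the left-most representative — orientation is a free choice and
left-most is deterministic; the emitted mapping lets scan hits be
expanded back to the full panel. Missing calls are imputed by sampling
each SNP's observed genotype frequencies: at the ~1% missingness that
survives filtering, the imputation model is immaterial to every
downstream statistic, so no haplotype model is re-implemented (the
report's metadata records this). Reading-trim performs a single
discard-and-recalculate pass (not iterated to convergence), with the
pass/fail flag at a minimum retained count of 40.

Two conventions the literature leaves ambiguous are resolved as follows.
The per-SNP information content is reported as the *standard* symmetric
Shannon entropy −(p ln p + q ln q): the sign-less printed form is
non-positive while reported averages are positive, so the negated form is
the only consistent reading. The IBS kinship is the raw allele-sharing
fraction (diagonal 1), with missing calls handled pairwise-complete.
Duplicate samples are flagged at ≥ 99% genotype identity; whether one or
both members of a pair are dropped is left to the caller (the screening
function only reports the pairs).

## Numerical and interface choices

* −log10 p is computed from `pf(..., log.p = TRUE)`, so it stays accurate
  far beyond double-precision p-values; a numerically perfect fit yields
  p = 0 with a saturated score.
* LD decay bins pairs into ~500 distance bins (bin width = window/500 by
  default, configurable), takes the median r² per bin, and LOWESS-smooths
  with span f = 0.02 — about a 10-bin window, narrow enough to resolve a
  decay radius that is a small fraction of the 50 Mb pair window. The
  radius interpolates linearly between bin centers; a curve that starts
  below the threshold reports the first bin center, and one that never
  crosses reports `NA` with `reached = FALSE`.
* Entropy windows are non-overlapping 4 Mb tiles (overlap is not
  specified anywhere; tiles are the simplest auditable choice), empty
  tiles reported as `NA`.
* All coordinates are 1-based base pairs; every window rule is a closed
  inequality on |Δpos|.
* Every stochastic routine takes a `seed`; replicated procedures derive
  per-replicate substreams from the root seed, so results are reproducible
  and a failed replicate can be retried on the next substream without
  disturbing the rest.
* The pipeline driver writes a manifest (inputs, seeds, stage counts,
  package version) sufficient to re-run any stage; the pipeline config
  file is JSON rather than YAML/TOML to avoid a parser dependency.

## Known limitations

* The mixed model uses a single kinship for all chromosomes
  (no leave-one-chromosome-out correction), matching standard EMMA-style
  practice; proximal contamination slightly depresses signal at causal
  SNPs that contribute to `K`, visibly so in small panels.
* ANOVA scans loop per SNP and are the slowest of the three statistics;
  trend and mixed scans are fully vectorized (the mixed scan rotates the
  genotype matrix into the kinship eigenbasis once, after which each
  permutation or simulated trait costs one diagonal whitening).
* `forward_stepwise` is greedy with no backward elimination and no
  information-criterion averaging, by design.
* The precision simulation redraws monomorphic targets rather than
  erroring, and its tie rule treats scores within 1e−9 as tied, which is
  only reachable by exact arithmetic ties in practice.
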