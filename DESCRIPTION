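Package: outbredgwas
Title: Genome-Wide Association Mapping in Outbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide association mapping of
    quantitative traits in outbred (e.g. commercial mouse stock) populations:
    SNP and phenotype quality control, identity-by-state kinship and linkage
    disequilibrium characterization, single-locus genome scans (additive trend
    test, 2-df ANOVA, and a kinship mixed-model trend test with REML variance
    components), genome-wide significance thresholds via kinship-preserving
    structured permutation with generalized extreme value tail fitting,
    bootstrap forward-stepwise multilocus mapping summarized as resample model
    inclusion probabilities, and a simulation-based estimate of mapping
    precision.  Includes a synthetic outbred-population generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
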