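Package: ppgvbanner
Title: Germline-Banner Classification of Potential Pathogenic Germline
    Variants from Tumor Profiling and ClinVar Snapshot Evolution
Version: 0.2.0
Authors@R:
    person("Maintainer", "ppgvbanner", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify potential pathogenic germline variants
    (PPGVs) detected by tumor-only comprehensive genomic profiling using
    dated ClinVar snapshots as the evidence source. Implements the
    three-way germline-banner classification of ClinVar records
    (pathogenic/likely pathogenic, benign/likely benign, or uncertain) by
    aggregate significance and review-status evidence tier, the
    gene-panel / variant-allele-fraction / ClinVar-evidence PPGV filter
    for tissue and liquid biopsies, diffing of two ClinVar snapshots
    (per-class and per-gene growth, novel-variant evidence breakdown),
    cohort prevalence analysis stratified by gene, cancer type and
    genomic ancestry with exact Fisher tests and Benjamini-Hochberg
    correction, and a synthetic-data generator producing paired
    ClinVar-like VCF snapshots and tumor-call cohorts with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
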