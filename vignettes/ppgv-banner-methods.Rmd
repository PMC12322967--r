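---
title: "Methods: germline-banner PPGV classification and ClinVar snapshot evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-banner PPGV classification and ClinVar snapshot evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumor-only comprehensive genomic profiling (CGP) routinely detects variants
in cancer susceptibility genes that may be of germline origin. Flagging such
*potential pathogenic germline variants* (PPGVs) on tumor reports — the
"germline banner" — prompts confirmatory germline testing, but the flag is
only as good as the public evidence behind it. ppgvbanner implements the
banner classification procedure end to end and the machinery to ask two
questions about it: how does the evolution of the ClinVar database between
two dated snapshots change what gets flagged, and how unevenly does the
ClinVar evidence filter treat patients of different genomic ancestries.

## The classification model

A tumor short-variant call is a PPGV when it passes three filters, applied
in a fixed order, with the first failure recorded as the decision reason:

1. **Gene**: the call lies in one of 24 cancer susceptibility genes
   (`banner_gene_panel()`): ATM, BAP1, BRCA1, BRCA2, BRIP1, CHEK2, FH,
   FLCN, MLH1, MSH2, MSH6, MUTYH, PALB2, PMS2, POLE, RAD51C, RAD51D, RET,
   SDHA, SDHB, SDHC, SDHD, TSC2, VHL.
2. **VAF**: the variant allele fraction meets the specimen threshold —
   ≥ 0.10 for tissue, ≥ 0.30 for liquid biopsies. Thresholds are
   *inclusive*: the printed criteria are "(≥10%)" and "(≥30%)". A
   heterozygous germline variant is expected near VAF 0.5; the liquid
   threshold is higher because circulating tumor DNA is a minority of
   plasma cell-free DNA, so somatic variants rarely reach 0.30 there.
3. **ClinVar evidence**: the exact variant (chrom, pos, ref, alt; GRCh37;
   no re-normalization) is present in the snapshot and classified
   pathogenic/likely pathogenic *with sufficient evidence*: review status
   "criteria provided, multiple submitters, no conflicts", "reviewed by
   expert panel", or "practice guideline". The benign side is symmetric
   for B/LB; everything else — including P/LP asserted by a single
   submitter — is treated as VUS for banner purposes.

The decision reasons at the ClinVar stage distinguish
`FAIL_NOT_IN_CLINVAR`, `FAIL_PLP_INSUFFICIENT` (pathogenic family, review
tier too weak), `FAIL_BLB` and `FAIL_VUS`; this decomposition is what makes
the ancestry analysis interpretable, because the two middle categories are
the direct fingerprints of database underrepresentation.

Some deliberate choices where the design was open:

- **"≥2 submitters" is read from the aggregate review status** ("multiple
  submitters, no conflicts"). The VCF aggregate does not expose
  per-significance submitter counts, and the parallel benign-side rule
  says "without conflicts"; records with two submitters *and* conflicts
  are VUS here. Submission-level modeling is out of scope.
- **"Practice guideline" counts as expert panel.** It is ClinVar's
  strictly higher (4-star) tier; excluding it would demote the
  best-reviewed variants.
- **Filter order is fixed** (gene → VAF → ClinVar) so that "calls with
  sufficient VAF" — the denominator of the filtering decomposition — is
  exactly the set that reached the ClinVar stage.
- **Matching is exact by variant key.** Both sides are expected
  pre-normalized (ClinVar VCF and pipeline calls); a representation
  mismatch surfaces as an auditable `FAIL_NOT_IN_CLINVAR` rather than
  being silently rescued by fuzzy matching.

## Snapshot handling

`read_clinvar_vcf()` is a deliberately thin, line-oriented reader: the
CLNSIG/CLNREVSTAT strings are kept byte-for-byte (significance strings
legitimately contain commas, which general INFO tokenizers split), ALT must
be a single concrete allele (multi-allelic lines abort — the ClinVar
aggregate emits one variation per line, so such a line signals a wrong
input file), and records are panel-restricted via GENEINFO symbols.
A record listing several genes is retained if any is on the panel and is
attributed to *each* panel gene it lists; per-gene tables may therefore
double-count a physical variant, while all overall counts de-duplicate by
variant key. Both the 2022-era ("conflicting interpretations") and
2024-era ("conflicting classifications") string dialects classify
identically.

`diff_snapshots()` reports per-class and per-gene counts, absolute deltas,
relative percent changes (percent *of baseline*) and class proportions;
zero-baseline relative changes are `NA` ("new"), not infinities. "Novel"
variants are a pure key set difference — a reclassified pre-existing record
is not novel. The evidence breakdown of novel entries is computed over
*significance families* (pathogenic-family / benign-family / rest-as-VUS),
not banner classes: the interesting fact about newly shared P/LP records is
precisely that most arrive with single-submitter support, which the banner
class would collapse into VUS.

## Statistics

Prevalence comparisons between ancestries use the two-sided conditional
Fisher exact test, implemented directly: conditional on both margins, the
p-value sums hypergeometric point probabilities not exceeding the observed
table's probability, with a relative tie tolerance of 1e-12. The
implementation is verified against a full enumeration oracle (binomial
coefficients on the log scale) for *every* 2×2 table with N ≤ 30. The odds
ratio reported is the sample cross-product ratio with Inf/NaN sentinels
for zero cells, not the conditional MLE.

Multiplicity is handled by the Benjamini–Hochberg step-up over the fixed
family of four comparisons (each non-European ancestry vs EUR), applied
separately to the sample-level prevalence family and the call-level
filtering family. Non-computable comparisons (empty stratum) are reported
as such and excluded from the BH family without affecting the others.
Sample-level counts are used for prevalence tests and call-level counts
for the filtering decomposition, mirroring the two units of analysis.
Because "% change" is ambiguous, every report carries both
`pp_change` (percentage points) and `rel_change_pct` (percent of
baseline) under those explicit names.

## The synthetic-data generator

Real inputs are a proprietary tumor-profiling cohort and ~100 MB dated
ClinVar archives, so the package carries a generator that emulates both
with known ground truth.

**Snapshots** (`snapshot_sim_config()`, `gen_snapshot_pair()`): records
are allocated to (significance family × review tier) cells. The default
baseline composition yields banner classes PLP 11.2% / BLB 11.4% /
VUS 77.4%, and the later snapshot grows each class by the default rates
+42.7% / +65.0% / +51.6% (≈ +52% overall) — the observed composition and
growth of the panel-restricted database between the 2022-03-13 and
2024-03-01 pulls. The default `scale` is 2,000 baseline records, about
40× smaller than reality: proportions, not absolute size, are the
modeled quantities, and the scale keeps the test suite in seconds.
BRCA1/BRCA2 carry 4× per-gene weight. Coordinates are synthetic reserved
blocks per gene (first half of each block for snapshot records, second
half for never-in-ClinVar variants); genomic plausibility is a non-goal.
Evidence *upgrades* (single submitter → multiple submitters, no
conflicts) are configurable per cell and default to zero, so the
documented identity "zero growth ⇒ zero diff" holds for the default
mechanism.

**Cohorts** (`cohort_sim_config()`, `gen_cohort()`): each sample's
carrier status is Bernoulli(π\[ancestry\]); a carrier gets exactly one
pathogenic-family germline variant which is, with probability
ρ\[ancestry\], a banner-sufficient snapshot record, else — split evenly —
a variant absent from the snapshot or a snapshot P/LP record with
insufficient evidence. Germline VAF is Normal(0.5, 0.1) truncated to
\[0, 1\]; background somatic calls arrive as Poisson(0.5) per sample with
Uniform(0.01, 0.45) VAF, half in off-panel genes. Defaults: π = 0.13 in
every ancestry and ρ = (EUR 0.92, AMR 0.80, EAS 0.76, SAS 0.72,
AFR 0.72), chosen once so that π·ρ reproduces the observed ancestry
prevalence gradient (≈11.9% EUR down to ≈9.4% AFR) *under equal carrier
rates* — i.e. the disparity is modeled entirely as database
representation, which is the hypothesis the decomposition is designed to
expose. Cohort size defaults to 13,000 samples (10k tissue / 3k liquid)
across six cancer types.

Two deliberate idealizations, and what they mean for a green test:

- Background somatic calls never land on banner-sufficient P/LP records,
  so observed tissue prevalence closes on π·ρ exactly (up to the ~3×10⁻⁵
  chance of a germline VAF below 0.10). Real tumors can present somatic
  hits at germline-like VAF in founder hotspots; a green closure test
  establishes pipeline correctness, not that real PPGV calls are free of
  somatic contamination.
- One planted variant per carrier; no tumor purity, copy number,
  mosaicism or read-level noise. Liquid-biopsy prevalence runs ≈2.3%
  below π·ρ by construction (mass of the truncated normal below 0.30).

## Numerical and degenerate-input conventions

- Empty snapshots, empty novel sets and zero-count strata return defined
  results (`NA` fraction sentinels), never crash.
- Relative change from a zero baseline is `NA`; printed as "new".
- Proportions are exact fractions; rounding happens only at rendering.
- Duplicate variant keys within one snapshot file are dropped with a
  warning (first kept); duplicate sample IDs are fatal.
- All randomness flows through a single integer seed per config;
  identical configs yield byte-identical output files.

## Verification strategy

The test suite checks, per module: hand-parsed toy VCFs; the exhaustive
significance × review-status decision table against independently
hand-labelled families; a brute-force re-implementation of the PPGV
conjunction on random instances; diff recounts and set-difference
properties; the Fisher enumeration oracle for all N ≤ 30 and BH against
the reference implementation; and generator-to-pipeline closure — planted
π·ρ recovered within a 99% binomial interval at n = 20,000, planted
representation disparity recovered as a significant AFR-vs-EUR result in
≥95% of 200 replicates, with ≤7.5% significant comparisons under a null
cohort over 400 replicates. Monte-Carlo scenario sizes (10,000 samples in
each contrasted stratum) were fixed from an analytic power calculation
before the simulations were run, and are still 2–13× smaller than the
ancestry strata of the cohorts the generator emulates.

## Known limitations

- The ≥2-submitter rule is approximated by the aggregate review status;
  production systems with submission-level access may classify a small
  set of conflicted multi-submitter records differently.
- Per-gene counts double-count multi-gene records (overlapping loci);
  overall counts do not.
- No GRCh38, no structural/copy-number records, no origin-based
  filtering, no covariate-adjusted disparity modeling.
- The generator's ancestry mechanism is intentionally single-cause
  (representation only); it cannot, and is not meant to, distinguish
  representation effects from true carrier-rate differences.
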