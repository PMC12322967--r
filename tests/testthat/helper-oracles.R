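# Independent oracles and fixture builders. These deliberately re-derive
# expected results by routes different from the package implementation
# (closed-form enumeration, brute-force conjunctions, hand-built tables).

# --- Fisher oracle: full hypergeometric enumeration with choose() --------
# p(two-sided) = sum of point probabilities <= observed, over all tables
# admissible under the fixed margins. Uses plain binomial coefficients,
# not dhyper (the implementation's route).
fisher_enum_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(support, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# --- Brute-force PPGV oracle --------------------------------------------
# Evaluates the three banner criteria as one conjunction per call, with
# the reason derived from the first violated criterion in the fixed order
# gene -> VAF -> ClinVar. Written against the spec prose, row by row.
ppgv_oracle <- function(calls, samples, snapshot, config) {
  classified <- classify_snapshot(snapshot)
  spec_map <- setNames(samples$specimen, samples$sample_id)
  out <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (!(row$gene %in% config$gene_panel)) { out[i] <- "FAIL_GENE"; next }
    thr <- if (toupper(spec_map[[row$sample_id]]) == "LIQUID")
      config$vaf_threshold_liquid else config$vaf_threshold_tissue
    if (row$vaf < thr) { out[i] <- "FAIL_VAF"; next }
    hit <- classified[chrom == as.character(row$chrom) & pos == row$pos &
                        ref == row$ref & alt == row$alt]
    if (nrow(hit) == 0) { out[i] <- "FAIL_NOT_IN_CLINVAR"; next }
    out[i] <- if (hit$banner_class == "PLP") "PASS"
    else if (hit$significance_family == "PATHOGENIC_FAMILY") "FAIL_PLP_INSUFFICIENT"
    else if (hit$banner_class == "BLB") "FAIL_BLB"
    else "FAIL_VUS"
  }
  out
}

# --- Toy VCF builder -----------------------------------------------------
clinvar_header <- c(
  "##fileformat=VCFv4.1",
  "##INFO=<ID=GENEINFO,Number=1,Type=String,Description=\"Gene(s)\">",
  "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
  "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"Review status\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

write_toy_vcf <- function(data_lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(clinvar_header, data_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gene, clnsig, revstat, id = ".") {
  sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tGENEINFO=%s;CLNSIG=%s;CLNREVSTAT=%s",
          chrom, pos, id, ref, alt, gene, clnsig, revstat)
}

# --- Snapshot builder from a compact record spec -------------------------
toy_snapshot <- function(..., label = "toy",
                         gene_panel = banner_gene_panel()) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(snapshot_table(
      data.table::data.table(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             genes = character(), clnsig_raw = character(),
                             revstat_raw = character()),
      gene_panel, label))
  }
  rec <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(chrom = r[[1]], pos = as.integer(r[[2]]),
                           ref = r[[3]], alt = r[[4]], genes = r[[5]],
                           clnsig_raw = r[[6]], revstat_raw = r[[7]])
  }))
  snapshot_table(rec, gene_panel, label)
}

# Canonical evidence-string pairs used across tests.
SIG_PLP <- "Pathogenic"
SIG_BLB <- "Benign/Likely_benign"
SIG_VUS <- "Uncertain_significance"
REV_EXPERT <- "reviewed_by_expert_panel"
REV_MULTI <- "criteria_provided,_multiple_submitters,_no_conflicts"
REV_SINGLE <- "criteria_provided,_single_submitter"

# Cohort tables for the caller tests.
toy_samples <- function(n = 3, specimen = "TISSUE", ancestry = "EUR",
                        cancer_type = "Breast") {
  data.table::data.table(sample_id = sprintf("S%02d", seq_len(n)),
                         specimen = specimen, cancer_type = cancer_type,
                         ancestry = ancestry)
}
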