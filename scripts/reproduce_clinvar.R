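#!/usr/bin/env Rscript
# OPTIONAL, NETWORK-GATED reproduction against the real dated ClinVar
# archives (GRCh37 VCF aggregate files, ~100 MB each):
#
#   clinvar_20220313.vcf.gz   (2022-03-13 pull)
#   clinvar_20240301.vcf.gz   (2024-03-01 pull)
#
# Usage:
#   Rscript scripts/reproduce_clinvar.R [--dir <download-dir>] [--out <dir>]
#
# Files already present under --dir are reused; otherwise they are fetched
# from the ClinVar FTP archive. This script is NOT part of the test suite:
# it needs network access and ~1 GB of scratch space. Exact agreement with
# the expected values may be limited by the multi-gene attribution
# ambiguity documented in the package vignette; residual discrepancies are
# reported per stage below.

suppressPackageStartupMessages(library(ppgvbanner))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(dir = "scratch/clinvar", out = "scratch/clinvar/results")
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  stopifnot(key %in% names(opt), i + 1 <= length(args))
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
dir.create(opt$dir, showWarnings = FALSE, recursive = TRUE)
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

base <- "https://ftp.ncbi.nlm.nih.gov/pub/clinvar/vcf_GRCh37/archive_2.0"
files <- c(a = "clinvar_20220313.vcf.gz", b = "clinvar_20240301.vcf.gz")
urls <- c(a = file.path(base, "2022", files["a"]),
          b = file.path(base, "2024", files["b"]))
paths <- file.path(opt$dir, files)
names(paths) <- names(files)
for (k in names(paths)) {
  if (!file.exists(paths[k])) {
    message("downloading ", urls[k])
    utils::download.file(urls[k], paths[k], mode = "wb", quiet = FALSE)
  }
}

message("reading 2022-03-13 snapshot (panel-restricted) ...")
a <- read_clinvar_vcf(paths["a"], label = "2022-03-13")
message("reading 2024-03-01 snapshot (panel-restricted) ...")
b <- read_clinvar_vcf(paths["b"], label = "2024-03-01")

d <- diff_snapshots(a, b)
write_snapshot_tsv(a, file.path(opt$out, "snapshot_2022.tsv"))
write_snapshot_tsv(b, file.path(opt$out, "snapshot_2024.tsv"))
data.table::fwrite(d$overall, file.path(opt$out, "diff_overall.tsv"), sep = "\t")
data.table::fwrite(d$by_gene, file.path(opt$out, "diff_by_gene.tsv"), sep = "\t")

nov <- novel_variants(a, b, c("BRCA1", "BRCA2"))
brk <- novel_evidence_breakdown(nov, b)

# Expected values for this dated comparison (percent scale).
expected <- list(
  total_rel_change_pct = 52.2, total_delta = 45174,
  plp_rel = 42.7, blb_rel = 65.0, vus_rel = 51.6,
  prop_a = c(PLP = 11.2, BLB = 11.4, VUS = 77.4),
  prop_b = c(PLP = 10.5, BLB = 12.4, VUS = 77.1),
  brca_n_novel = 6683,
  brca_class = c(PLP_family = 42.8, BLB_family = 25.6, VUS = 31.6),
  brca_plp_detail = c(SINGLE_SUBMITTER = 89.2,
                      MULTIPLE_SUBMITTERS_NO_CONFLICTS = 6.7,
                      NO_ASSERTION_CRITERIA = 4.1))

fmt <- function(x) formatC(x, format = "f", digits = 1)
report <- c(
  sprintf("stage 1 (panel restriction): %d / %d records retained", d$total_a, d$total_b),
  sprintf("stage 2 (overall growth): observed %+.1f%% (%+d) | expected %+.1f%% (%+d)",
          d$total_rel_change_pct, d$total_delta,
          expected$total_rel_change_pct, expected$total_delta),
  sprintf("stage 3 (per-class growth PLP/BLB/VUS): observed %s | expected %s",
          paste(fmt(d$overall$rel_change_pct), collapse = "/"),
          paste(fmt(c(expected$plp_rel, expected$blb_rel, expected$vus_rel)),
                collapse = "/")),
  sprintf("stage 4 (class proportions A): observed %s | expected %s",
          paste(fmt(100 * d$overall$prop_a), collapse = "/"),
          paste(fmt(expected$prop_a), collapse = "/")),
  sprintf("stage 4 (class proportions B): observed %s | expected %s",
          paste(fmt(100 * d$overall$prop_b), collapse = "/"),
          paste(fmt(expected$prop_b), collapse = "/")),
  sprintf("stage 5 (novel BRCA1/2): observed n=%d | expected n=%d",
          brk$n_novel, expected$brca_n_novel),
  sprintf("stage 6 (novel class fractions P/B/VUS): observed %s | expected %s",
          paste(fmt(100 * brk$class_fractions), collapse = "/"),
          paste(fmt(expected$brca_class[c("PLP_family", "BLB_family", "VUS")]),
                collapse = "/")),
  sprintf("stage 7 (novel P/LP detail single/multi/no-assert): observed %s | expected %s",
          paste(fmt(100 * brk$plp_detail_fractions[names(expected$brca_plp_detail)]),
                collapse = "/"),
          paste(fmt(expected$brca_plp_detail), collapse = "/")))
writeLines(report)
writeLines(report, file.path(opt$out, "reproduction_report.txt"))
jsonlite::write_json(
  list(observed = list(
    total_rel_change_pct = d$total_rel_change_pct, total_delta = d$total_delta,
    class_rel_change_pct = as.list(setNames(d$overall$rel_change_pct,
                                            d$overall$banner_class)),
    prop_a = as.list(setNames(100 * d$overall$prop_a, d$overall$banner_class)),
    prop_b = as.list(setNames(100 * d$overall$prop_b, d$overall$banner_class)),
    brca_n_novel = brk$n_novel,
    brca_class_fractions_pct = as.list(100 * brk$class_fractions),
    brca_plp_detail_pct = as.list(100 * brk$plp_detail_fractions)),
    expected = expected),
  file.path(opt$out, "reproduction_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
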