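# Internal helpers shared across modules.

# Canonical chromosome ordering for deterministic output.
.CHROM_LEVELS <- c(as.character(1:22), "X", "Y", "MT")

.ANCESTRIES <- c("AFR", "AMR", "EAS", "EUR", "SAS")
.SPECIMENS <- c("TISSUE", "LIQUID")
.FAMILIES <- c("PATHOGENIC_FAMILY", "BENIGN_FAMILY", "UNCERTAIN_FAMILY",
               "CONFLICTING_FAMILY", "OTHER_FAMILY")
.DETAILS <- c("EXPERT_PANEL", "MULTIPLE_SUBMITTERS_NO_CONFLICTS",
              "SINGLE_SUBMITTER", "CONFLICTING", "NO_ASSERTION_CRITERIA",
              "OTHER", "ABSENT")
.CLASSES <- c("PLP", "BLB", "VUS")
.REASONS <- c("PASS", "FAIL_GENE", "FAIL_VAF", "FAIL_NOT_IN_CLINVAR",
              "FAIL_VUS", "FAIL_PLP_INSUFFICIENT", "FAIL_BLB")

#' The 24 germline-banner cancer susceptibility genes
#'
#' Gene panel used for PPGV reporting: variants outside these genes are
#' never flagged, regardless of ClinVar evidence.
#'
#' @return Character vector of 24 HGNC gene symbols, sorted.
#' @export
#' @examples
#' banner_gene_panel()
banner_gene_panel <- function() {
  c("ATM", "BAP1", "BRCA1", "BRCA2", "BRIP1", "CHEK2", "FH", "FLCN",
    "MLH1", "MSH2", "MSH6", "MUTYH", "PALB2", "PMS2", "POLE", "RAD51C",
    "RAD51D", "RET", "SDHA", "SDHB", "SDHC", "SDHD", "TSC2", "VHL")
}

# Exact-match variant identity: chrom:pos:ref:alt. No re-normalization.
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Order index for (chrom, pos, ref, alt) using canonical chromosome levels.
variant_order <- function(chrom, pos, ref, alt) {
  order(factor(chrom, levels = .CHROM_LEVELS), pos, ref, alt)
}

# Split comma-joined gene strings into a list of character vectors.
split_genes <- function(genes) {
  strsplit(genes, ",", fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
  invisible(NULL)
}
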