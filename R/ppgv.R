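# The PPGV caller: apply the three germline-banner criteria (panel gene,
# specimen-specific VAF threshold, banner-sufficient P/LP in ClinVar) to
# tumor variant calls, in that fixed order, recording the first failing
# filter as the decision reason.

#' Banner configuration
#'
#' @param gene_panel Panel gene symbols (default: the 24 banner genes).
#' @param vaf_threshold_tissue Minimum variant allele fraction for tissue
#'   biopsies (inclusive); default 0.10.
#' @param vaf_threshold_liquid Minimum VAF for liquid biopsies (inclusive);
#'   default 0.30, higher because circulating tumor DNA dilutes germline
#'   signal less than tumor content dilutes it in tissue.
#' @return An object of class `banner_config`.
#' @export
banner_config <- function(gene_panel = banner_gene_panel(),
                          vaf_threshold_tissue = 0.10,
                          vaf_threshold_liquid = 0.30) {
  abort_if(!(vaf_threshold_tissue > 0 && vaf_threshold_tissue <= vaf_threshold_liquid &&
               vaf_threshold_liquid < 1),
           "need 0 < vaf_threshold_tissue <= vaf_threshold_liquid < 1")
  structure(list(gene_panel = sort(unique(as.character(gene_panel))),
                 vaf_threshold_tissue = vaf_threshold_tissue,
                 vaf_threshold_liquid = vaf_threshold_liquid),
            class = "banner_config")
}

validate_samples <- function(samples) {
  samples <- data.table::as.data.table(samples)
  needed <- c("sample_id", "specimen", "cancer_type", "ancestry")
  missing_cols <- setdiff(needed, names(samples))
  abort_if(length(missing_cols) > 0,
           "sample table missing columns: ", paste(missing_cols, collapse = ", "))
  abort_if(anyDuplicated(samples$sample_id) > 0, "duplicate sample_id in cohort")
  samples[, specimen := toupper(specimen)]
  bad <- setdiff(unique(samples$specimen), .SPECIMENS)
  abort_if(length(bad) > 0, "unknown specimen value(s): ", paste(bad, collapse = ", "))
  samples[, ancestry := toupper(ancestry)]
  samples[!ancestry %in% .ANCESTRIES, ancestry := "UNKNOWN"]
  samples[]
}

validate_calls <- function(calls) {
  calls <- data.table::as.data.table(calls)
  needed <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "vaf")
  missing_cols <- setdiff(needed, names(calls))
  abort_if(length(missing_cols) > 0,
           "call table missing columns: ", paste(missing_cols, collapse = ", "))
  calls[, chrom := sub("^chr", "", as.character(chrom))]
  calls[, pos := as.integer(pos)]
  abort_if(any(is.na(calls$vaf)) || any(calls$vaf < 0) || any(calls$vaf > 1),
           "vaf must lie in [0, 1]")
  calls[]
}

#' Call PPGV decisions for tumor variant calls
#'
#' Filters are applied in the fixed order gene -> VAF -> ClinVar; the first
#' failing filter determines the single decision reason. Thresholds are
#' inclusive. Variant-to-snapshot matching is exact on
#' (chrom, pos, ref, alt); both sides are expected pre-normalized, and a
#' representation mismatch surfaces (auditable) as `FAIL_NOT_IN_CLINVAR`.
#'
#' @param calls `data.frame` with columns `sample_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `vaf`.
#' @param samples `data.frame` with columns `sample_id`, `specimen`
#'   (TISSUE/LIQUID), `cancer_type`, `ancestry` (AFR/AMR/EAS/EUR/SAS or
#'   UNKNOWN).
#' @param snapshot A [snapshot_table()] restricted to the config's panel.
#' @param config A [banner_config()].
#' @return `data.table`, one row per call, with `is_ppgv`, `reason` (one of
#'   PASS, FAIL_GENE, FAIL_VAF, FAIL_NOT_IN_CLINVAR, FAIL_VUS,
#'   FAIL_PLP_INSUFFICIENT, FAIL_BLB) and the matched snapshot evidence
#'   columns (`NA` where the variant is absent or the ClinVar stage was not
#'   reached).
#' @export
call_ppgv <- function(calls, samples, snapshot, config = banner_config()) {
  stopifnot(inherits(snapshot, "snapshot_table"), inherits(config, "banner_config"))
  samples <- validate_samples(samples)
  calls <- validate_calls(calls)
  unknown <- setdiff(calls$sample_id, samples$sample_id)
  abort_if(length(unknown) > 0, "calls reference unknown sample(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))

  dec <- data.table::copy(calls)
  dec[samples, specimen := i.specimen, on = "sample_id"]
  dec[, vid := variant_id(chrom, pos, ref, alt)]

  classified <- classify_snapshot(snapshot)
  dec[classified, `:=`(significance_family = i.significance_family,
                       detail = i.detail, banner_class = i.banner_class),
      on = "vid"]

  thr <- ifelse(dec$specimen == "LIQUID", config$vaf_threshold_liquid,
                config$vaf_threshold_tissue)
  reason <- rep("FAIL_VUS", nrow(dec))
  reason[dec$banner_class == "BLB"] <- "FAIL_BLB"
  reason[dec$significance_family == "PATHOGENIC_FAMILY" &
           dec$banner_class == "VUS"] <- "FAIL_PLP_INSUFFICIENT"
  reason[dec$banner_class == "PLP"] <- "PASS"
  reason[is.na(dec$banner_class)] <- "FAIL_NOT_IN_CLINVAR"
  reason[dec$vaf < thr] <- "FAIL_VAF"
  reason[!dec$gene %in% config$gene_panel] <- "FAIL_GENE"
  dec[, reason := reason]
  dec[, is_ppgv := reason == "PASS"]
  # evidence is reported only when the ClinVar stage was reached and matched
  dec[reason %in% c("FAIL_GENE", "FAIL_VAF"),
      `:=`(significance_family = NA_character_, detail = NA_character_,
           banner_class = NA_character_)]
  dec[]
}

#' Summarize per-sample PPGV status
#'
#' A sample is PPGV-positive iff at least one of its decisions passed all
#' three banner filters; samples with no calls are PPGV-negative.
#'
#' @param decisions Output of [call_ppgv()].
#' @param samples Cohort sample table (one row per sample).
#' @return `data.table` with exactly one row per cohort sample: the sample
#'   metadata plus `n_calls`, `n_ppgv` and logical `ppgv_positive`.
#' @export
sample_ppgv_status <- function(decisions, samples) {
  samples <- validate_samples(samples)
  decisions <- data.table::as.data.table(decisions)
  unknown <- setdiff(decisions$sample_id, samples$sample_id)
  abort_if(length(unknown) > 0, "decisions reference unknown sample(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
  agg <- decisions[, .(n_calls = .N, n_ppgv = sum(reason == "PASS")),
                   by = sample_id]
  out <- data.table::copy(samples)
  out[agg, `:=`(n_calls = i.n_calls, n_ppgv = i.n_ppgv), on = "sample_id"]
  out[is.na(n_calls), `:=`(n_calls = 0L, n_ppgv = 0L)]
  out[, ppgv_positive := n_ppgv > 0L]
  out[]
}
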