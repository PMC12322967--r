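# Banner evidence classification: map ClinVar aggregate significance and
# review status to the three-way banner class (PLP / BLB / VUS) plus an
# evidence-detail tier.
#
# The banner rule: a variant is reportable P/LP only when ClinVar classifies
# it as pathogenic/likely pathogenic with review status "multiple
# submitters, no conflicts" or better (expert panel / practice guideline);
# the benign side is symmetric; everything else is treated as VUS for
# banner purposes, including P/LP assertions from a single submitter.

normalize_clnstr <- function(x) {
  x[is.na(x)] <- ""
  tolower(gsub("_", " ", x, fixed = TRUE))
}

#' Parse an aggregate clinical-significance string into a family
#'
#' Total function over verbatim `CLNSIG` strings. Matching is on the
#' normalized string (underscores to spaces, lowercased), with precedence
#' conflicting > pathogenic > benign > uncertain > other. Both the
#' "Conflicting_interpretations_of_pathogenicity" (pre-2024) and
#' "Conflicting_classifications_of_pathogenicity" spellings are recognized.
#'
#' @param clnsig_raw Character vector of verbatim `CLNSIG` strings.
#' @return Character vector over `{PATHOGENIC_FAMILY, BENIGN_FAMILY,
#'   UNCERTAIN_FAMILY, CONFLICTING_FAMILY, OTHER_FAMILY}`.
#' @export
#' @examples
#' parse_significance(c("Pathogenic/Likely_pathogenic", "Benign", ""))
parse_significance <- function(clnsig_raw) {
  s <- normalize_clnstr(clnsig_raw)
  has_path <- grepl("pathogenic", s, fixed = TRUE)
  has_ben <- grepl("benign", s, fixed = TRUE)
  out <- rep("OTHER_FAMILY", length(s))
  out[grepl("uncertain significance", s, fixed = TRUE)] <- "UNCERTAIN_FAMILY"
  out[has_ben & !has_path] <- "BENIGN_FAMILY"
  out[has_path & !has_ben] <- "PATHOGENIC_FAMILY"
  out[grepl("conflicting", s, fixed = TRUE)] <- "CONFLICTING_FAMILY"
  out
}

#' Parse a ClinVar review-status string into an evidence-detail tier
#'
#' Total function over verbatim `CLNREVSTAT` strings. "practice guideline"
#' (four-star) is folded into `EXPERT_PANEL`: it is a strictly higher
#' review tier and always suffices where expert-panel review does.
#' Unrecognized strings (including the 2024-era "no classification
#' provided") map to `OTHER`; `ABSENT` is reserved for variants not
#' present in a snapshot and is never returned here.
#'
#' @param revstat_raw Character vector of verbatim `CLNREVSTAT` strings.
#' @return Character vector over `{EXPERT_PANEL,
#'   MULTIPLE_SUBMITTERS_NO_CONFLICTS, SINGLE_SUBMITTER, CONFLICTING,
#'   NO_ASSERTION_CRITERIA, OTHER}`.
#' @export
#' @examples
#' parse_review_status("criteria_provided,_multiple_submitters,_no_conflicts")
parse_review_status <- function(revstat_raw) {
  s <- normalize_clnstr(revstat_raw)
  out <- rep("OTHER", length(s))
  out[grepl("no assertion criteria provided", s, fixed = TRUE)] <- "NO_ASSERTION_CRITERIA"
  out[grepl("conflicting", s, fixed = TRUE)] <- "CONFLICTING"
  out[grepl("single submitter", s, fixed = TRUE)] <- "SINGLE_SUBMITTER"
  out[grepl("multiple submitters", s, fixed = TRUE) &
        grepl("no conflicts", s, fixed = TRUE)] <- "MULTIPLE_SUBMITTERS_NO_CONFLICTS"
  out[grepl("expert panel", s, fixed = TRUE) |
        grepl("practice guideline", s, fixed = TRUE)] <- "EXPERT_PANEL"
  out
}

#' Classify ClinVar evidence into the banner three-way class
#'
#' Applies the banner evidence rule to verbatim significance and
#' review-status strings: `PLP` requires a pathogenic-family significance
#' with multiple-submitters-no-conflicts or expert-panel review; `BLB` is
#' the benign-side mirror; all other combinations are `VUS`.
#'
#' @param clnsig_raw,revstat_raw Character vectors (recycled to common
#'   length) of verbatim `CLNSIG` / `CLNREVSTAT` strings.
#' @return A `data.table` with columns `significance_family`, `detail`,
#'   `banner_class`.
#' @export
#' @examples
#' classify_evidence("Pathogenic", "reviewed_by_expert_panel")
#' classify_evidence("Pathogenic", "criteria_provided,_single_submitter")
classify_evidence <- function(clnsig_raw, revstat_raw) {
  n <- max(length(clnsig_raw), length(revstat_raw))
  fam <- parse_significance(rep_len(clnsig_raw, n))
  det <- parse_review_status(rep_len(revstat_raw, n))
  sufficient <- det %in% c("EXPERT_PANEL", "MULTIPLE_SUBMITTERS_NO_CONFLICTS")
  cls <- rep("VUS", n)
  cls[fam == "PATHOGENIC_FAMILY" & sufficient] <- "PLP"
  cls[fam == "BENIGN_FAMILY" & sufficient] <- "BLB"
  data.table::data.table(significance_family = fam, detail = det,
                         banner_class = cls)
}

#' Classify every record of a snapshot
#'
#' @param snapshot A [snapshot_table()].
#' @return The snapshot's records with `significance_family`, `detail` and
#'   `banner_class` columns appended (a copy; the snapshot is unchanged).
#' @export
classify_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "snapshot_table"))
  rec <- data.table::copy(snapshot$records)
  if (nrow(rec) == 0) {
    rec[, `:=`(significance_family = character(), detail = character(),
               banner_class = character())]
    return(rec[])
  }
  ev <- classify_evidence(rec$clnsig_raw, rec$revstat_raw)
  rec[, `:=`(significance_family = ev$significance_family,
             detail = ev$detail, banner_class = ev$banner_class)]
  rec[]
}
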