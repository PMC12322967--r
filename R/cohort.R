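# Cohort analysis: PPGV prevalence by stratum, the ClinVar-filter
# decomposition of eligible calls, and the ancestry disparity tests
# (conditional exact Fisher tests with Benjamini-Hochberg correction).

#' PPGV prevalence by stratum
#'
#' @param status Per-sample status table from [sample_ppgv_status()].
#' @param stratum Grouping key: one of `"overall"`, `"cancer_type"`,
#'   `"ancestry"`, `"specimen"`.
#' @param min_positive Optional rendering filter: drop strata with fewer
#'   PPGV-positive samples (default 0 = report all).
#' @return `data.table` with one row per observed stratum level plus an
#'   `"overall"` row: `n_samples`, `n_positive`, `prevalence`.
#' @export
prevalence_by <- function(status, stratum = c("overall", "cancer_type",
                                              "ancestry", "specimen"),
                          min_positive = 0L) {
  stratum <- match.arg(stratum)
  status <- data.table::as.data.table(status)
  overall <- status[, .(stratum = stratum, level = "overall",
                        n_samples = .N, n_positive = sum(ppgv_positive))]
  out <- if (stratum == "overall") overall else {
    per <- status[, .(n_samples = .N, n_positive = sum(ppgv_positive)),
                  by = .(level = get(stratum))]
    per[, stratum := stratum]
    data.table::setorder(per, level)
    rbind(per[n_positive >= min_positive,
              .(stratum, level, n_samples, n_positive)],
          overall)
  }
  out[, prevalence := n_positive / n_samples]
  out[]
}

#' Compare PPGV prevalence under two snapshots
#'
#' Joins two per-sample status tables (same cohort, decisions taken under
#' an earlier and a later ClinVar snapshot) and reports both the
#' percentage-point change and the percent change relative to baseline —
#' two different senses of "% change" that are easy to conflate.
#'
#' @param status_a,status_b Status tables from [sample_ppgv_status()] over
#'   the same cohort.
#' @inheritParams prevalence_by
#' @return `data.table` with `prevalence_a`, `prevalence_b`, `pp_change`
#'   (percentage points, `100 * (b - a)`) and `rel_change_pct`
#'   (`100 * (b - a) / a`).
#' @export
prevalence_compare <- function(status_a, status_b, stratum = "overall") {
  pa <- prevalence_by(status_a, stratum)
  pb <- prevalence_by(status_b, stratum)
  abort_if(!identical(pa$level, pb$level) || !identical(pa$n_samples, pb$n_samples),
           "status tables cover different cohorts or strata")
  out <- pa[, .(stratum, level, n_samples, n_positive_a = n_positive,
                prevalence_a = prevalence)]
  out[, `:=`(n_positive_b = pb$n_positive, prevalence_b = pb$prevalence)]
  out[, pp_change := 100 * (prevalence_b - prevalence_a)]
  out[, rel_change_pct := ifelse(prevalence_a > 0,
                                 100 * (prevalence_b - prevalence_a) / prevalence_a,
                                 NA_real_)]
  out[]
}

#' Per-gene PPGV counts and sample prevalence
#'
#' A sample counts as PPGV-positive for a gene if at least one of its
#' passing decisions is in that gene.
#'
#' @param decisions Output of [call_ppgv()].
#' @param samples Cohort sample table.
#' @return `data.table` with one row per panel gene carrying a PPGV:
#'   `n_ppgv` (passing calls) and `n_positive_samples` / `prevalence`.
#' @export
prevalence_by_gene <- function(decisions, samples) {
  samples <- validate_samples(samples)
  decisions <- data.table::as.data.table(decisions)
  n <- nrow(samples)
  pass <- decisions[reason == "PASS"]
  out <- pass[, .(n_ppgv = .N,
                  n_positive_samples = data.table::uniqueN(sample_id)),
              by = gene]
  out[, prevalence := n_positive_samples / n]
  data.table::setorder(out, gene)
  out[]
}

#' Decompose eligible calls by ClinVar filter outcome and ancestry
#'
#' Eligible calls are those passing the gene and VAF filters; the
#' decomposition mirrors the "variants with sufficient VAF excluded as
#' PPGVs" view. Samples of unknown ancestry are excluded and counted.
#'
#' @param decisions Output of [call_ppgv()].
#' @param samples Cohort sample table.
#' @return `data.table`, one row per ancestry: `n_eligible`, per-reason
#'   fractions (`frac_PASS`, `frac_FAIL_NOT_IN_CLINVAR`, `frac_FAIL_VUS`,
#'   `frac_FAIL_PLP_INSUFFICIENT`, `frac_FAIL_BLB`) and `frac_excluded`
#'   (their complement to `frac_PASS`). Attribute `n_unknown_ancestry`
#'   carries the number of excluded eligible calls.
#' @export
filter_decomposition <- function(decisions, samples) {
  samples <- validate_samples(samples)
  decisions <- data.table::as.data.table(decisions)
  dec <- data.table::copy(decisions)
  dec[samples, ancestry := i.ancestry, on = "sample_id"]
  elig <- dec[!reason %in% c("FAIL_GENE", "FAIL_VAF")]
  n_unknown <- elig[ancestry == "UNKNOWN", .N]
  elig <- elig[ancestry != "UNKNOWN"]
  reasons <- c("PASS", "FAIL_NOT_IN_CLINVAR", "FAIL_VUS",
               "FAIL_PLP_INSUFFICIENT", "FAIL_BLB")
  out <- elig[, {
    fr <- vapply(reasons, function(r) mean(reason == r), numeric(1))
    c(list(n_eligible = .N), as.list(fr))
  }, by = ancestry]
  data.table::setnames(out, reasons, paste0("frac_", reasons))
  out[, frac_excluded := 1 - frac_PASS]
  data.table::setorder(out, ancestry)
  data.table::setattr(out, "n_unknown_ancestry", n_unknown)
  out[]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test: the two-sided p-value sums the hypergeometric
#' point probabilities (conditional on both margins) that do not exceed the
#' observed table's probability, with a relative tolerance of 1e-12 for
#' ties. The odds ratio is the sample cross-product ratio `(a*d)/(b*c)`
#' (not the conditional MLE), with `Inf` / `NaN` sentinels for zero cells.
#'
#' @param x 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return List with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(1, 3, 3, 1), 2, byrow = TRUE))
fisher_exact_2x2 <- function(x) {
  from_matrix <- is.matrix(x)
  x <- as.integer(round(as.numeric(x)))
  abort_if(length(x) != 4, "expected a 2x2 table")
  abort_if(any(is.na(x)) || any(x < 0), "cells must be non-negative integers")
  if (from_matrix) {  # column-major storage
    a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]
  } else {            # length-4 vector, row-major
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  }
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  abort_if(n == 0, "table is all zero")
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure: with the p-values sorted ascending,
#' `adj_i = min(p_j * m / j : j >= i)`, capped at 1, returned in the
#' original input order.
#'
#' @param p Non-empty numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  abort_if(length(p) == 0, "empty p-value vector")
  abort_if(any(is.na(p)) || any(p < 0) || any(p > 1), "p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(scaled))))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Shared worker: each non-reference level vs the reference, Fisher + BH.
disparity_tests <- function(counts, alpha, reference) {
  abort_if(!reference %in% counts$level || counts[level == reference, n] == 0,
           "reference stratum '", reference, "' is empty")
  ref <- counts[level == reference]
  others <- setdiff(.ANCESTRIES, reference)
  res <- data.table::rbindlist(lapply(others, function(g) {
    row <- counts[level == g]
    if (nrow(row) == 0 || row$n == 0) {
      return(data.table::data.table(
        comparison = paste(g, "vs", reference), computable = FALSE,
        x = NA_integer_, n = NA_integer_, x_ref = ref$x, n_ref = ref$n,
        odds_ratio = NA_real_, p_raw = NA_real_))
    }
    ft <- fisher_exact_2x2(matrix(c(row$x, row$n - row$x,
                                    ref$x, ref$n - ref$x), 2, byrow = TRUE))
    data.table::data.table(
      comparison = paste(g, "vs", reference), computable = TRUE,
      x = row$x, n = row$n, x_ref = ref$x, n_ref = ref$n,
      odds_ratio = ft$odds_ratio, p_raw = ft$p_value)
  }))
  res[, p_adj := NA_real_]
  res[computable == TRUE, p_adj := bh_adjust(p_raw)]
  res[, significant := !is.na(p_adj) & p_adj < alpha]
  res[]
}

#' Ancestry disparity tests
#'
#' Compares each non-reference ancestry against the reference (default
#' EUR) with a two-sided Fisher exact test, adjusting the family of
#' comparisons with Benjamini-Hochberg. Two units are supported, mirroring
#' the two figure-level analyses: `measure = "prevalence"` tests
#' sample-level PPGV-positive counts from a status table;
#' `measure = "filtering"` tests call-level excluded-vs-retained counts
#' among eligible calls from a [filter_decomposition()] table.
#'
#' @param x A [sample_ppgv_status()] table (`measure = "prevalence"`) or a
#'   [filter_decomposition()] table (`measure = "filtering"`).
#' @param measure Which 2x2 unit to test.
#' @param alpha Significance level for the adjusted p-values (default
#'   0.05).
#' @param reference Reference ancestry (default `"EUR"`; must be
#'   non-empty).
#' @return `data.table`, one row per comparison: the 2x2 counts,
#'   `odds_ratio`, `p_raw`, `p_adj`, `significant`; non-computable
#'   comparisons (empty stratum) carry `NA`s and do not enter the BH
#'   family.
#' @export
ancestry_disparity_tests <- function(x, measure = c("prevalence", "filtering"),
                                     alpha = 0.05, reference = "EUR") {
  measure <- match.arg(measure)
  x <- data.table::as.data.table(x)
  counts <- if (measure == "prevalence") {
    x[ancestry != "UNKNOWN",
      .(x = sum(ppgv_positive), n = .N), by = .(level = ancestry)]
  } else {
    x[, .(x = as.integer(round(frac_excluded * n_eligible)), n = n_eligible),
      by = .(level = ancestry)]
  }
  disparity_tests(counts, alpha = alpha, reference = reference)
}
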