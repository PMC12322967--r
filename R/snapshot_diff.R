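# Snapshot evolution: per-class / per-gene counts and deltas between two
# dated ClinVar snapshots, novel-variant identification, and the evidence
# breakdown of novel entries.

# Per-gene class counts: multi-gene records are attributed to every panel
# gene they list (documented double-counting); the overall counts
# de-duplicate by variant key (records are unique per key by construction).
gene_class_counts <- function(classified, gene_panel) {
  if (nrow(classified) == 0) {
    return(data.table::data.table(gene = character(), banner_class = character(),
                                  n = integer()))
  }
  long <- classified[, .(gene = unlist(split_genes(genes))),
                     by = .(vid, banner_class)]
  long <- long[gene %in% gene_panel]
  long[, .(n = .N), by = .(gene, banner_class)]
}

#' Diff two ClinVar snapshots of the same gene panel
#'
#' Classifies every record of each snapshot with the banner evidence rule
#' and reports per-class and per-gene-by-class counts, absolute deltas,
#' relative percent changes and class proportions. A relative change from a
#' zero baseline is reported as `NA` (rendered "new"), not infinity.
#'
#' @param a,b [snapshot_table()] objects restricted to the same gene panel.
#' @return An object of class `snapshot_diff`: list with `label_a`,
#'   `label_b`, `overall` (per-class `data.table` with `count_a`,
#'   `count_b`, `delta`, `rel_change_pct`, `prop_a`, `prop_b`), `by_gene`
#'   (gene x class counts and deltas), and totals
#'   `total_a`/`total_b`/`total_delta`/`total_rel_change_pct`.
#' @export
diff_snapshots <- function(a, b) {
  stopifnot(inherits(a, "snapshot_table"), inherits(b, "snapshot_table"))
  abort_if(!setequal(a$gene_panel, b$gene_panel),
           "snapshots are restricted to different gene panels")
  ca <- classify_snapshot(a)
  cb <- classify_snapshot(b)
  count_classes <- function(x) {
    n <- vapply(.CLASSES, function(k) sum(x$banner_class == k), integer(1))
    names(n) <- .CLASSES
    n
  }
  na <- count_classes(ca); nb <- count_classes(cb)
  tot_a <- sum(na); tot_b <- sum(nb)
  rel <- function(d, base) ifelse(base > 0, 100 * d / base, NA_real_)
  overall <- data.table::data.table(
    banner_class = .CLASSES,
    count_a = as.integer(na), count_b = as.integer(nb),
    delta = as.integer(nb - na),
    rel_change_pct = rel(nb - na, na),
    prop_a = if (tot_a > 0) na / tot_a else rep(NA_real_, 3),
    prop_b = if (tot_b > 0) nb / tot_b else rep(NA_real_, 3))

  ga <- gene_class_counts(ca, a$gene_panel)
  gb <- gene_class_counts(cb, b$gene_panel)
  grid <- data.table::CJ(gene = sort(a$gene_panel), banner_class = .CLASSES)
  grid[ga, count_a := i.n, on = c("gene", "banner_class")]
  grid[gb, count_b := i.n, on = c("gene", "banner_class")]
  grid[is.na(count_a), count_a := 0L]
  grid[is.na(count_b), count_b := 0L]
  grid[, delta := count_b - count_a]
  grid[, rel_change_pct := rel(delta, count_a)]

  structure(list(label_a = a$label, label_b = b$label,
                 overall = overall, by_gene = grid[],
                 total_a = tot_a, total_b = tot_b,
                 total_delta = tot_b - tot_a,
                 total_rel_change_pct = if (tot_a > 0) 100 * (tot_b - tot_a) / tot_a else NA_real_),
            class = "snapshot_diff")
}

#' @export
print.snapshot_diff <- function(x, ...) {
  cat(sprintf("<snapshot_diff %s -> %s: %d -> %d records (%+d, %s)>\n",
              x$label_a, x$label_b, x$total_a, x$total_b, x$total_delta,
              if (is.na(x$total_rel_change_pct)) "new"
              else sprintf("%+.1f%%", x$total_rel_change_pct)))
  print(x$overall)
  invisible(x)
}

#' Variants novel to the second snapshot
#'
#' Novelty is defined purely by exact variant-key set difference:
#' reclassified but pre-existing variants are not novel.
#'
#' @param a,b [snapshot_table()] objects (same panel).
#' @param genes Optional gene subset (default: the whole shared panel);
#'   records of `b` are attributed to a gene if they list it.
#' @return `data.table` of novel variant keys (`chrom`, `pos`, `ref`,
#'   `alt`, `vid`), in key order.
#' @export
novel_variants <- function(a, b, genes = NULL) {
  stopifnot(inherits(a, "snapshot_table"), inherits(b, "snapshot_table"))
  genes <- genes %||% b$gene_panel
  abort_if(!all(genes %in% b$gene_panel),
           "genes must be a subset of the snapshot gene panel")
  rec <- b$records
  in_sub <- vapply(split_genes(rec$genes), function(g) any(g %in% genes), logical(1))
  rec[in_sub & !vid %in% a$records$vid,
      .(chrom, pos, ref, alt, vid)]
}

#' Evidence breakdown of novel snapshot entries
#'
#' Class fractions are computed over significance families
#' (pathogenic-family / benign-family / everything-else-as-VUS) — the
#' breakdown of what a database gained, before the banner sufficiency rule
#' — and, among the pathogenic-family novel entries, the fractions by
#' evidence-detail tier.
#'
#' @param novel Variant keys as returned by [novel_variants()] (must all be
#'   present in `b`).
#' @param b The later [snapshot_table()].
#' @return List with `n_novel`, `class_fractions` (named: `PLP_family`,
#'   `BLB_family`, `VUS`) and `plp_detail_fractions` (named by detail
#'   tier). Fractions are `NA` when their denominator is zero.
#' @export
novel_evidence_breakdown <- function(novel, b) {
  stopifnot(inherits(b, "snapshot_table"))
  vids <- if (is.character(novel)) novel else novel$vid
  abort_if(!all(vids %in% b$records$vid),
           "novel keys must all be present in the later snapshot")
  n_novel <- length(vids)
  details <- setdiff(.DETAILS, "ABSENT")
  if (n_novel == 0) {
    return(list(n_novel = 0L,
                class_fractions = stats::setNames(rep(NA_real_, 3),
                                                  c("PLP_family", "BLB_family", "VUS")),
                plp_detail_fractions = stats::setNames(rep(NA_real_, length(details)),
                                                       details)))
  }
  cb <- classify_snapshot(b)[vid %in% vids]
  fam <- cb$significance_family
  cls <- data.table::fcase(fam == "PATHOGENIC_FAMILY", "PLP_family",
                           fam == "BENIGN_FAMILY", "BLB_family",
                           default = "VUS")
  class_fractions <- vapply(c("PLP_family", "BLB_family", "VUS"),
                            function(k) mean(cls == k), numeric(1))
  plp <- cb[fam == "PATHOGENIC_FAMILY"]
  plp_detail_fractions <- if (nrow(plp) > 0) {
    vapply(details, function(d) mean(plp$detail == d), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(details)), details)
  }
  list(n_novel = n_novel, class_fractions = class_fractions,
       plp_detail_fractions = plp_detail_fractions)
}
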