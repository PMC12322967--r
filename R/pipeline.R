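# End-to-end orchestration: classify both snapshots, diff them, call PPGVs
# under each, and emit the cohort-level reports with a run manifest.
# Outputs are plain TSV + JSON only; every percentage column name states
# whether it is a percent-of-baseline or a percentage-point quantity.

as_snapshot <- function(x, gene_panel, label) {
  if (inherits(x, "snapshot_table")) return(x)
  abort_if(!is.character(x) || length(x) != 1, "expected a snapshot_table or file path")
  if (grepl("\\.vcf(\\.gz)?$", x)) read_clinvar_vcf(x, gene_panel, label = label)
  else read_snapshot_tsv(x, gene_panel, label = label)
}

as_table <- function(x, what) {
  if (is.data.frame(x)) return(data.table::as.data.table(x))
  abort_if(!is.character(x) || !file.exists(x), what, " file not found: ", x)
  out <- data.table::fread(x, sep = "\t")
  if ("chrom" %in% names(out)) out[, chrom := as.character(chrom)]
  out[]
}

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  path
}

#' Run the full snapshot-evolution and cohort analysis
#'
#' Executes classify -> diff -> PPGV calling under each snapshot ->
#' cohort report, writing TSV/JSON outputs and a run manifest to
#' `out_dir`. Result files are deterministic for identical inputs; the
#' manifest additionally records a wall-clock timestamp.
#'
#' @param snapshot_a,snapshot_b [snapshot_table()] objects or paths to
#'   ClinVar VCF / snapshot TSV files (earlier and later snapshot).
#' @param calls Tumor call table or TSV path (`sample_id`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `vaf`).
#' @param samples Sample metadata table or TSV path (`sample_id`,
#'   `specimen`, `cancer_type`, `ancestry`).
#' @param config A [banner_config()].
#' @param out_dir Output directory (created if needed).
#' @param breakdown_genes Gene subset for the novel-variant evidence
#'   breakdown (default `c("BRCA1", "BRCA2")`).
#' @param alpha Significance level for the disparity tests.
#' @param seed Optional integer recorded in the manifest (the analysis
#'   itself is deterministic; the seed matters only when the inputs were
#'   simulated).
#' @return Invisibly, a list of all in-memory results plus `paths`.
#' @export
run_full_analysis <- function(snapshot_a, snapshot_b, calls, samples,
                              config = banner_config(), out_dir,
                              breakdown_genes = c("BRCA1", "BRCA2"),
                              alpha = 0.05, seed = NULL) {
  stopifnot(inherits(config, "banner_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_paths <- Filter(is.character, list(snapshot_a = snapshot_a,
                                           snapshot_b = snapshot_b,
                                           calls = calls, samples = samples))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  a <- stage("read_snapshot_a", as_snapshot(snapshot_a, config$gene_panel, "snapshot_a"))
  b <- stage("read_snapshot_b", as_snapshot(snapshot_b, config$gene_panel, "snapshot_b"))
  calls <- stage("read_calls", as_table(calls, "calls"))
  samples <- stage("read_samples", as_table(samples, "samples"))

  paths <- character()
  # -- snapshot evolution -------------------------------------------------
  dif <- stage("diff_snapshots", diff_snapshots(a, b))
  paths["diff_overall"] <- write_tsv(dif$overall, out_dir, "diff_overall.tsv")
  paths["diff_by_gene"] <- write_tsv(dif$by_gene, out_dir, "diff_by_gene.tsv")
  breakdown_genes <- intersect(breakdown_genes, a$gene_panel)
  nov <- stage("novel_variants", novel_variants(a, b, breakdown_genes))
  brk <- stage("novel_evidence_breakdown", novel_evidence_breakdown(nov, b))
  # -- PPGV calling under each snapshot -----------------------------------
  dec_a <- stage("call_ppgv_a", call_ppgv(calls, samples, a, config))
  dec_b <- stage("call_ppgv_b", call_ppgv(calls, samples, b, config))
  paths["decisions_a"] <- write_tsv(dec_a, out_dir, "decisions_a.tsv")
  paths["decisions_b"] <- write_tsv(dec_b, out_dir, "decisions_b.tsv")
  st_a <- sample_ppgv_status(dec_a, samples)
  st_b <- sample_ppgv_status(dec_b, samples)
  paths["sample_status_a"] <- write_tsv(st_a, out_dir, "sample_status_a.tsv")
  paths["sample_status_b"] <- write_tsv(st_b, out_dir, "sample_status_b.tsv")
  # -- cohort report ------------------------------------------------------
  prev <- list()
  for (s in c("overall", "cancer_type", "ancestry", "specimen")) {
    prev[[s]] <- prevalence_compare(st_a, st_b, s)
    paths[paste0("prevalence_", s)] <-
      write_tsv(prev[[s]], out_dir, paste0("prevalence_", s, ".tsv"))
  }
  gene_prev <- list(a = prevalence_by_gene(dec_a, samples),
                    b = prevalence_by_gene(dec_b, samples))
  paths["ppgv_by_gene_a"] <- write_tsv(gene_prev$a, out_dir, "ppgv_by_gene_a.tsv")
  paths["ppgv_by_gene_b"] <- write_tsv(gene_prev$b, out_dir, "ppgv_by_gene_b.tsv")
  deco <- list(a = filter_decomposition(dec_a, samples),
               b = filter_decomposition(dec_b, samples))
  paths["decomposition_a"] <- write_tsv(deco$a, out_dir, "decomposition_a.tsv")
  paths["decomposition_b"] <- write_tsv(deco$b, out_dir, "decomposition_b.tsv")
  # ClinVar-filtered reduction: eligible calls excluded at the ClinVar
  # stage under each snapshot (the "conversion" view of database growth).
  n_excl <- vapply(list(dec_a, dec_b), function(d) {
    nrow(d[!reason %in% c("FAIL_GENE", "FAIL_VAF", "PASS")])
  }, integer(1))
  filtered_reduction <- list(
    n_filtered_a = n_excl[1], n_filtered_b = n_excl[2],
    delta = n_excl[2] - n_excl[1],
    rel_change_percent = if (n_excl[1] > 0) 100 * (n_excl[2] - n_excl[1]) / n_excl[1] else NA)
  tests <- list()
  has_anc <- any(st_b$ancestry != "UNKNOWN")
  if (has_anc && "EUR" %in% st_b$ancestry) {
    tests$prevalence <- stage("disparity_prevalence",
                              ancestry_disparity_tests(st_b, "prevalence", alpha))
    tests$filtering <- stage("disparity_filtering",
                             ancestry_disparity_tests(deco$b, "filtering", alpha))
    paths["tests_prevalence"] <- write_tsv(tests$prevalence, out_dir, "tests_prevalence.tsv")
    paths["tests_filtering"] <- write_tsv(tests$filtering, out_dir, "tests_filtering.tsv")
  }
  summary_json <- list(
    snapshot_totals = list(a = dif$total_a, b = dif$total_b,
                           delta = dif$total_delta,
                           rel_change_percent = dif$total_rel_change_pct),
    novel_breakdown = list(genes = breakdown_genes, n_novel = brk$n_novel,
                           class_fractions = as.list(brk$class_fractions),
                           plp_detail_fractions = as.list(brk$plp_detail_fractions)),
    ppgv_totals = list(a = sum(dec_a$is_ppgv), b = sum(dec_b$is_ppgv),
                       delta = sum(dec_b$is_ppgv) - sum(dec_a$is_ppgv)),
    prevalence_overall = list(
      a = prev$overall$prevalence_a[1], b = prev$overall$prevalence_b[1],
      pp_change_percentage_points = prev$overall$pp_change[1],
      rel_change_percent = prev$overall$rel_change_pct[1]),
    filtered_reduction = filtered_reduction)
  paths["summary"] <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, paths["summary"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  manifest <- list(
    tool = "ppgvbanner", version = as.character(utils::packageVersion("ppgvbanner")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = list(gene_panel = config$gene_panel,
                  vaf_threshold_tissue = config$vaf_threshold_tissue,
                  vaf_threshold_liquid = config$vaf_threshold_liquid,
                  breakdown_genes = breakdown_genes, alpha = alpha),
    inputs = lapply(input_paths, function(p) list(path = p,
                                                  md5 = unname(tools::md5sum(p)))),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(list(diff = dif, novel = nov, breakdown = brk,
                 decisions = list(a = dec_a, b = dec_b),
                 status = list(a = st_a, b = st_b),
                 prevalence = prev, gene_prevalence = gene_prev,
                 decomposition = deco, tests = tests,
                 filtered_reduction = filtered_reduction, paths = paths))
}
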