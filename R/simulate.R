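# Synthetic-data generators: paired ClinVar-like VCF snapshots with
# configurable per-class growth and evidence upgrades, and tumor-call
# cohorts whose true carrier rate (pi) and ClinVar-representation
# probability (rho) vary by ancestry. Every downstream stage is testable
# against the planted ground truth without any download.

# Reserved coordinate blocks: panel gene i owns positions
# (i*2e6, i*2e6 + 2e6]; the first half holds snapshot records, the second
# half holds variants guaranteed absent from generated snapshots.
.BLOCK <- 2e6L
gene_block_start <- function(gene, gene_panel) {
  idx <- match(gene, sort(gene_panel))
  abort_if(anyNA(idx), "gene(s) outside the panel: ",
           paste(unique(gene[is.na(idx)]), collapse = ", "))
  idx * .BLOCK
}
gene_chrom <- function(gene, gene_panel) {
  as.character((match(gene, sort(gene_panel)) - 1L) %% 22L + 1L)
}

.SIG_STRINGS <- c(
  PATHOGENIC_FAMILY = "Pathogenic",
  BENIGN_FAMILY = "Benign/Likely_benign",
  UNCERTAIN_FAMILY = "Uncertain_significance",
  CONFLICTING_FAMILY = "Conflicting_interpretations_of_pathogenicity",
  OTHER_FAMILY = "not_provided")
.REV_STRINGS <- c(
  EXPERT_PANEL = "reviewed_by_expert_panel",
  MULTIPLE_SUBMITTERS_NO_CONFLICTS = "criteria_provided,_multiple_submitters,_no_conflicts",
  SINGLE_SUBMITTER = "criteria_provided,_single_submitter",
  CONFLICTING = "criteria_provided,_conflicting_interpretations",
  NO_ASSERTION_CRITERIA = "no_assertion_criteria_provided",
  OTHER = "no_classification_provided")

# Default evidence-cell mix of the baseline snapshot: fractions chosen so
# the banner-class composition is PLP 11.2% / BLB 11.4% / VUS 77.4%, the
# class mix observed in panel-restricted ClinVar pulls.
default_cell_mix <- function() {
  data.table::data.table(
    family = c("PATHOGENIC_FAMILY", "PATHOGENIC_FAMILY", "BENIGN_FAMILY",
               "BENIGN_FAMILY", "PATHOGENIC_FAMILY", "PATHOGENIC_FAMILY",
               "BENIGN_FAMILY", "UNCERTAIN_FAMILY", "UNCERTAIN_FAMILY",
               "UNCERTAIN_FAMILY", "CONFLICTING_FAMILY"),
    detail = c("EXPERT_PANEL", "MULTIPLE_SUBMITTERS_NO_CONFLICTS",
               "EXPERT_PANEL", "MULTIPLE_SUBMITTERS_NO_CONFLICTS",
               "SINGLE_SUBMITTER", "NO_ASSERTION_CRITERIA",
               "SINGLE_SUBMITTER", "SINGLE_SUBMITTER",
               "MULTIPLE_SUBMITTERS_NO_CONFLICTS", "NO_ASSERTION_CRITERIA",
               "CONFLICTING"),
    weight = c(0.010, 0.102, 0.004, 0.110, 0.100, 0.020,
               0.060, 0.400, 0.120, 0.014, 0.060))
}

#' Configuration for a synthetic snapshot pair
#'
#' Either supply `cells` directly (per-gene baseline counts, novel counts
#' and upgrade counts by evidence cell) or let the constructor derive them
#' from `scale`: the baseline class composition is PLP 11.2% / BLB 11.4% /
#' VUS 77.4% and the later snapshot grows each banner class by the
#' relative rates in `growth` (defaults +42.7% PLP, +65.0% BLB, +51.6%
#' VUS, i.e. about +52% overall). BRCA1/BRCA2 carry 4x the per-gene weight
#' of the other panel genes.
#'
#' @param genes Gene panel (default the 24 banner genes).
#' @param scale Approximate total baseline record count (default 2000; the
#'   real panel-restricted database is ~40x larger, scaled down so tests
#'   run in seconds).
#' @param growth Named numeric: relative novel-record growth per banner
#'   class (`PLP`, `BLB`, `VUS`).
#' @param cells Optional explicit `data.table` with columns `gene`,
#'   `family`, `detail`, `n_a`, `n_novel`, `n_upgrade`. `n_upgrade`
#'   single-submitter records are re-issued in the later snapshot with
#'   multiple-submitters-no-conflicts review status.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return Object of class `snapshot_sim_config`.
#' @export
snapshot_sim_config <- function(genes = banner_gene_panel(), scale = 2000,
                                growth = c(PLP = 0.427, BLB = 0.650, VUS = 0.516),
                                cells = NULL, seed = 1L) {
  genes <- sort(unique(genes))
  if (is.null(cells)) {
    mix <- default_cell_mix()
    gene_w <- ifelse(genes %in% c("BRCA1", "BRCA2"), 4, 1)
    gene_w <- gene_w / sum(gene_w)
    cells <- data.table::CJ(gene = genes, cell = seq_len(nrow(mix)))
    cells <- cbind(cells[, .(gene)], mix[cells$cell])
    cells[, n_a := as.integer(round(scale * weight * gene_w[match(gene, genes)]))]
    cls <- classify_evidence(.SIG_STRINGS[cells$family],
                             .REV_STRINGS[cells$detail])$banner_class
    cells[, n_novel := as.integer(round(n_a * growth[cls]))]
    cells[, n_upgrade := 0L]
    cells[, weight := NULL]
  } else {
    cells <- data.table::as.data.table(cells)
    needed <- c("gene", "family", "detail", "n_a", "n_novel", "n_upgrade")
    abort_if(!all(needed %in% names(cells)),
             "cells needs columns: ", paste(needed, collapse = ", "))
    abort_if(!all(cells$family %in% .FAMILIES) || !all(cells$detail %in% names(.REV_STRINGS)),
             "unknown family/detail values in cells")
  }
  abort_if(any(cells$n_a < 0) || any(cells$n_novel < 0) || any(cells$n_upgrade < 0),
           "cell counts must be non-negative")
  abort_if(any(cells$n_upgrade > 0 & cells$detail != "SINGLE_SUBMITTER"),
           "upgrades are defined only for SINGLE_SUBMITTER cells")
  abort_if(any(cells$n_upgrade > cells$n_a),
           "upgrade count exceeds the cell's baseline population")
  structure(list(genes = genes, cells = cells[], seed = as.integer(seed)),
            class = "snapshot_sim_config")
}

#' Generate a synthetic ClinVar snapshot pair
#'
#' Emits two snapshot tables (and optionally two ClinVar-dialect VCF
#' files): B equals A plus the configured novel records per evidence cell,
#' with the configured number of single-submitter records upgraded to
#' multiple-submitters-no-conflicts review status. Byte-identical output
#' for identical configs.
#'
#' @param config A [snapshot_sim_config()].
#' @param out_dir Optional directory; if given, writes
#'   `snapshot_a.vcf` / `snapshot_b.vcf`.
#' @return List with `a`, `b` ([snapshot_table()]s), `truth` (novel-record
#'   table, upgraded keys, the config) and `paths`.
#' @export
gen_snapshot_pair <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "snapshot_sim_config"))
  set.seed(config$seed)
  cells <- config$cells
  per_gene <- split(cells, cells$gene)
  recs <- data.table::rbindlist(lapply(per_gene, function(cc) {
    g <- cc$gene[1]
    n_tot <- sum(cc$n_a) + sum(cc$n_novel)
    if (n_tot == 0) return(NULL)
    base <- gene_block_start(g, config$genes)
    pos <- base + sample.int(.BLOCK %/% 2L, n_tot)
    ref <- sample(c("A", "C", "G", "T"), n_tot, replace = TRUE)
    alt <- rand_alt(ref)
    idx <- rep(seq_len(nrow(cc)), cc$n_a + cc$n_novel)
    within_cell <- sequence(cc$n_a + cc$n_novel)
    data.table::data.table(
      gene = g, chrom = gene_chrom(g, config$genes), pos = pos,
      ref = ref, alt = alt,
      family = cc$family[idx], detail = cc$detail[idx],
      is_novel = within_cell > cc$n_a[idx],
      is_upgraded = within_cell <= cc$n_upgrade[idx])
  }))
  recs[, vid := variant_id(chrom, pos, ref, alt)]

  make_records <- function(x, detail_col) {
    data.table::data.table(
      chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt, genes = x$gene,
      clnsig_raw = unname(.SIG_STRINGS[x$family]),
      revstat_raw = unname(.REV_STRINGS[x[[detail_col]]]))
  }
  recs[, detail_b := ifelse(is_upgraded, "MULTIPLE_SUBMITTERS_NO_CONFLICTS", detail)]
  a <- snapshot_table(make_records(recs[is_novel == FALSE], "detail"),
                      config$genes, label = "snapshot_a")
  b <- snapshot_table(make_records(recs, "detail_b"),
                      config$genes, label = "snapshot_b")
  truth <- list(
    novel = recs[is_novel == TRUE, .(vid, gene, family, detail)],
    upgraded = recs[is_upgraded == TRUE, vid],
    config = config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("snapshot_a.vcf", "snapshot_b.vcf"))
    write_clinvar_vcf(a, paths[1])
    write_clinvar_vcf(b, paths[2])
  }
  list(a = a, b = b, truth = truth, paths = paths)
}

#' Configuration for a synthetic tumor-call cohort
#'
#' The generative model: each sample's ancestry-specific carrier status is
#' Bernoulli(`pi[ancestry]`); a carrier receives exactly one
#' pathogenic-family germline variant which is, with probability
#' `rho[ancestry]`, an existing snapshot record with banner-sufficient
#' evidence, and otherwise (split evenly) either a variant absent from the
#' snapshot or a snapshot P/LP record with insufficient evidence. Germline
#' VAFs are Normal(0.5, 0.1) truncated to \[0, 1\] (the heterozygous
#' expectation); background somatic calls arrive per sample as
#' Poisson(`background_rate`) with Uniform(0.01, 0.45) VAF and never hit
#' banner-sufficient snapshot records, so observed tissue prevalence
#' closes on `pi * rho`.
#'
#' @param cells `data.table` with columns `specimen`, `cancer_type`,
#'   `ancestry`, `n`; default: 13,000 samples (10,000 tissue, 3,000
#'   liquid) across six cancer types with ancestry mix EUR 60% / AMR 14% /
#'   AFR 12% / EAS 9% / SAS 5%.
#' @param pi Named per-ancestry carrier rate; default 0.13 everywhere.
#' @param rho Named per-ancestry probability that a carried variant is
#'   banner-representable; defaults (EUR 0.92, AMR 0.80, EAS 0.76, SAS
#'   0.72, AFR 0.72) reproduce the observed prevalence gradient
#'   (11.9% EUR down to 9.4% AFR) under equal carrier rates.
#' @param vaf_germline `c(mean, sd)` of the truncated-normal germline VAF.
#' @param vaf_somatic `c(min, max)` of the uniform somatic VAF.
#' @param background_rate Mean somatic calls per sample (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(cells = NULL,
                              pi = c(AFR = 0.13, AMR = 0.13, EAS = 0.13,
                                     EUR = 0.13, SAS = 0.13),
                              rho = c(AFR = 0.72, AMR = 0.80, EAS = 0.76,
                                      EUR = 0.92, SAS = 0.72),
                              vaf_germline = c(mean = 0.5, sd = 0.1),
                              vaf_somatic = c(min = 0.01, max = 0.45),
                              background_rate = 0.5, seed = 1L) {
  if (is.null(cells)) {
    ct <- c(Lung = 0.25, Breast = 0.20, Colorectal = 0.20, Prostate = 0.15,
            Pancreatic = 0.10, Kidney = 0.10)
    anc <- c(EUR = 0.60, AMR = 0.14, AFR = 0.12, EAS = 0.09, SAS = 0.05)
    sp <- c(TISSUE = 10000, LIQUID = 3000)
    cells <- data.table::CJ(specimen = names(sp), cancer_type = names(ct),
                            ancestry = names(anc))
    cells[, n := as.integer(round(sp[specimen] * ct[cancer_type] * anc[ancestry]))]
  } else {
    cells <- data.table::as.data.table(cells)
    abort_if(!all(c("specimen", "cancer_type", "ancestry", "n") %in% names(cells)),
             "cells needs columns specimen, cancer_type, ancestry, n")
    abort_if(any(cells$n < 0), "cell counts must be non-negative")
  }
  abort_if(!all(.ANCESTRIES %in% names(pi)) || !all(.ANCESTRIES %in% names(rho)),
           "pi and rho must be named for all five ancestries")
  abort_if(any(pi < 0 | pi > 1) || any(rho < 0 | rho > 1),
           "pi and rho must lie in [0, 1]")
  abort_if(vaf_somatic[1] <= 0 || vaf_somatic[2] >= 1 || vaf_somatic[1] >= vaf_somatic[2],
           "need 0 < vaf_somatic min < max < 1")
  structure(list(cells = cells[], pi = pi, rho = rho,
                 vaf_germline = vaf_germline, vaf_somatic = vaf_somatic,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Vectorized draw of a random alternate base differing from ref.
rand_alt <- function(ref) {
  bases <- c("A", "C", "G", "T")
  others <- vapply(bases, function(b) setdiff(bases, b), character(3))
  others[cbind(sample.int(3L, length(ref), replace = TRUE),
               match(ref, bases))]
}

rtruncnorm01 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

# First panel gene listed by each record (multi-gene records contribute
# their first panel symbol as the call's gene label).
first_panel_gene <- function(genes, panel) {
  vapply(split_genes(genes), function(g) g[g %in% panel][1], character(1))
}

#' Generate a synthetic tumor-call cohort against a snapshot
#'
#' See [cohort_sim_config()] for the generative model. Deterministic given
#' the config seed.
#'
#' @param config A [cohort_sim_config()].
#' @param snapshot The [snapshot_table()] the cohort is generated against
#'   (normally snapshot A of [gen_snapshot_pair()]; absent variants are
#'   drawn from the generator's reserved coordinate blocks and re-drawn on
#'   the rare collision with a snapshot key).
#' @param out_dir Optional directory; writes `calls.tsv`, `samples.tsv`
#'   and `truth.json`.
#' @return List with `calls`, `samples`, `truth` (per-sample carrier flag,
#'   mechanism among BANNER / INSUFFICIENT / ABSENT / NONE, planted key,
#'   and the pi/rho used) and `paths`.
#' @export
gen_cohort <- function(config, snapshot, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"),
            inherits(snapshot, "snapshot_table"))
  set.seed(config$seed)
  cells <- config$cells[n > 0]
  samples <- cells[rep(seq_len(nrow(cells)), n),
                   .(specimen, cancer_type, ancestry)]
  n_samp <- nrow(samples)
  samples[, sample_id := sprintf("S%07d", seq_len(n_samp))]
  data.table::setcolorder(samples, c("sample_id", "specimen", "cancer_type", "ancestry"))

  classified <- classify_snapshot(snapshot)
  pool_banner <- classified[banner_class == "PLP"]
  pool_insuff <- classified[significance_family == "PATHOGENIC_FAMILY" &
                              banner_class == "VUS"]
  panel <- snapshot$gene_panel

  carrier <- stats::rbinom(n_samp, 1, config$pi[samples$ancestry]) == 1
  mech <- rep("NONE", n_samp)
  u <- stats::runif(n_samp)
  v <- stats::runif(n_samp)
  mech[carrier] <- ifelse(u[carrier] < config$rho[samples$ancestry[carrier]],
                          "BANNER",
                          ifelse(v[carrier] < 0.5 & nrow(pool_insuff) > 0,
                                 "INSUFFICIENT", "ABSENT"))
  abort_if(any(mech == "BANNER") && nrow(pool_banner) == 0,
           "snapshot has no banner-sufficient P/LP records to plant")

  draw_pool <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE)]
  planted <- data.table::data.table(sample_idx = integer(), gene = character(),
                                    chrom = character(), pos = integer(),
                                    ref = character(), alt = character())
  add_planted <- function(idx, rec) {
    data.table::data.table(sample_idx = idx,
                           gene = first_panel_gene(rec$genes, panel),
                           chrom = rec$chrom, pos = rec$pos,
                           ref = rec$ref, alt = rec$alt)
  }
  ib <- which(mech == "BANNER")
  if (length(ib) > 0) planted <- rbind(planted, add_planted(ib, draw_pool(pool_banner, length(ib))))
  ii <- which(mech == "INSUFFICIENT")
  if (length(ii) > 0) planted <- rbind(planted, add_planted(ii, draw_pool(pool_insuff, length(ii))))
  ia <- which(mech == "ABSENT")
  if (length(ia) > 0) {
    g <- sample(panel, length(ia), replace = TRUE)
    pos <- gene_block_start(g, panel) + .BLOCK %/% 2L + sample.int(.BLOCK %/% 2L, length(ia), replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), length(ia), replace = TRUE)
    alt <- rand_alt(ref)
    abs_dt <- data.table::data.table(sample_idx = ia, gene = g,
                                     chrom = gene_chrom(g, panel),
                                     pos = as.integer(pos), ref = ref, alt = alt)
    # re-draw the rare collision with an actual snapshot key
    coll <- variant_id(abs_dt$chrom, abs_dt$pos, abs_dt$ref, abs_dt$alt) %in%
      snapshot$records$vid
    while (any(coll)) {
      k <- sum(coll)
      abs_dt[coll, pos := as.integer(gene_block_start(gene, panel) + .BLOCK %/% 2L +
                                       sample.int(.BLOCK %/% 2L, k, replace = TRUE))]
      coll <- variant_id(abs_dt$chrom, abs_dt$pos, abs_dt$ref, abs_dt$alt) %in%
        snapshot$records$vid
    }
    planted <- rbind(planted, abs_dt)
  }
  planted[, vaf := rtruncnorm01(.N, config$vaf_germline[["mean"]],
                                config$vaf_germline[["sd"]])]

  # Background somatic calls: half outside the panel, half in panel genes;
  # in-panel keys are either non-banner snapshot records (30%) or absent
  # keys, never banner-sufficient P/LP (so they cannot create a PPGV).
  n_bg <- stats::rpois(n_samp, config$background_rate)
  bg_idx <- rep(seq_len(n_samp), n_bg)
  n_b <- length(bg_idx)
  bg <- NULL
  if (n_b > 0) {
    off_panel_genes <- c("TP53", "KRAS", "EGFR", "PIK3CA", "APC", "STK11")
    in_panel <- stats::runif(n_b) < 0.5
    gene <- character(n_b)
    chrom <- character(n_b)
    pos <- integer(n_b)
    ref <- sample(c("A", "C", "G", "T"), n_b, replace = TRUE)
    alt <- rand_alt(ref)
    # off-panel calls live far outside any reserved block
    gene[!in_panel] <- sample(off_panel_genes, sum(!in_panel), replace = TRUE)
    chrom[!in_panel] <- "20"
    pos[!in_panel] <- 1e8L + sample.int(1e6L, sum(!in_panel), replace = TRUE)
    k_in <- sum(in_panel)
    if (k_in > 0) {
      pool_nonbanner <- classified[banner_class != "PLP"]
      use_snap <- stats::runif(k_in) < 0.3 & nrow(pool_nonbanner) > 0
      wi <- which(in_panel)
      if (any(use_snap)) {
        rec <- draw_pool(pool_nonbanner, sum(use_snap))
        j <- wi[use_snap]
        gene[j] <- first_panel_gene(rec$genes, panel)
        chrom[j] <- rec$chrom; pos[j] <- rec$pos
        ref[j] <- rec$ref; alt[j] <- rec$alt
      }
      if (any(!use_snap)) {
        j <- wi[!use_snap]
        g <- sample(panel, length(j), replace = TRUE)
        gene[j] <- g
        chrom[j] <- gene_chrom(g, panel)
        pos[j] <- as.integer(gene_block_start(g, panel) + .BLOCK %/% 2L +
                               sample.int(.BLOCK %/% 2L, length(j), replace = TRUE))
        coll <- variant_id(chrom[j], pos[j], ref[j], alt[j]) %in% snapshot$records$vid
        while (any(coll)) {
          jj <- j[coll]
          pos[jj] <- as.integer(gene_block_start(gene[jj], panel) + .BLOCK %/% 2L +
                                  sample.int(.BLOCK %/% 2L, length(jj), replace = TRUE))
          coll <- variant_id(chrom[j], pos[j], ref[j], alt[j]) %in% snapshot$records$vid
        }
      }
    }
    bg <- data.table::data.table(
      sample_idx = bg_idx, gene = gene, chrom = chrom, pos = pos,
      ref = ref, alt = alt,
      vaf = stats::runif(n_b, config$vaf_somatic[["min"]], config$vaf_somatic[["max"]]))
  }

  calls <- rbind(planted, bg)
  calls[, sample_id := samples$sample_id[sample_idx]]
  calls <- calls[, .(sample_id, gene, chrom, pos, ref, alt,
                     vaf = round(vaf, 4))]
  data.table::setorder(calls, sample_id, chrom, pos)

  truth_samples <- data.table::copy(samples)
  truth_samples[, `:=`(carrier = carrier, mechanism = mech,
                       planted_vid = NA_character_)]
  truth_samples[planted$sample_idx,
                planted_vid := variant_id(planted$chrom, planted$pos,
                                          planted$ref, planted$alt)]
  truth <- list(samples = truth_samples, pi = as.list(config$pi),
                rho = as.list(config$rho))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("calls.tsv", "samples.tsv", "truth.json"))
    data.table::fwrite(calls, paths[1], sep = "\t", quote = FALSE)
    data.table::fwrite(samples, paths[2], sep = "\t", quote = FALSE)
    jsonlite::write_json(list(pi = truth$pi, rho = truth$rho,
                              n_carriers = sum(carrier),
                              mechanism_counts = as.list(table(mech))),
                         paths[3], auto_unbox = TRUE, digits = NA)
  }
  list(calls = calls, samples = samples, truth = truth, paths = paths)
}
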