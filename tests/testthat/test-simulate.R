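# synthetic_data: determinism, planted ground truth, round-trips, closure.

test_that("identical configs yield byte-identical output files", {
  cfg <- snapshot_sim_config(scale = 300, seed = 21)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- gen_snapshot_pair(cfg, d1)
  p2 <- gen_snapshot_pair(cfg, d2)
  for (i in 1:2) {
    expect_identical(readLines(p1$paths[i]), readLines(p2$paths[i]))
  }
  co1 <- gen_cohort(cohort_sim_config(seed = 22), p1$a, d1)
  co2 <- gen_cohort(cohort_sim_config(seed = 22), p2$a, d2)
  expect_identical(readLines(co1$paths[1]), readLines(co2$paths[1]))
  expect_identical(readLines(co1$paths[2]), readLines(co2$paths[2]))
})

test_that("zero growth spec produces an all-zero diff", {
  cfg <- snapshot_sim_config(scale = 300, seed = 4,
                             growth = c(PLP = 0, BLB = 0, VUS = 0))
  pair <- gen_snapshot_pair(cfg)
  d <- diff_snapshots(pair$a, pair$b)
  expect_true(all(d$overall$delta == 0L))
  expect_equal(d$total_delta, 0L)
  expect_equal(nrow(novel_variants(pair$a, pair$b)), 0L)
})

test_that("planted novel cells are recovered exactly by the diff stage", {
  # 100 novel VUS and 10 novel banner-sufficient P/LP in BRCA1
  cells <- data.table::data.table(
    gene = "BRCA1",
    family = c("UNCERTAIN_FAMILY", "PATHOGENIC_FAMILY"),
    detail = c("SINGLE_SUBMITTER", "MULTIPLE_SUBMITTERS_NO_CONFLICTS"),
    n_a = c(50L, 5L), n_novel = c(100L, 10L), n_upgrade = 0L)
  pair <- gen_snapshot_pair(snapshot_sim_config(cells = cells, seed = 17))
  nov <- novel_variants(pair$a, pair$b, "BRCA1")
  expect_equal(nrow(nov), 110L)
  brk <- novel_evidence_breakdown(nov, pair$b)
  expect_equal(unname(brk$class_fractions[["PLP_family"]]), 10 / 110)
  expect_equal(brk$plp_detail_fractions[["MULTIPLE_SUBMITTERS_NO_CONFLICTS"]], 1)
})

test_that("written VCFs re-read to the exact generated snapshots", {
  pair <- gen_snapshot_pair(snapshot_sim_config(scale = 250, seed = 8),
                            out_dir = tempfile())
  a2 <- read_clinvar_vcf(pair$paths[1], label = "snapshot_a")
  b2 <- read_clinvar_vcf(pair$paths[2], label = "snapshot_b")
  expect_identical(a2$records, pair$a$records)
  expect_identical(b2$records, pair$b$records)
})

test_that("upgrade requests beyond the cell population are fatal", {
  cells <- data.table::data.table(
    gene = "ATM", family = "PATHOGENIC_FAMILY", detail = "SINGLE_SUBMITTER",
    n_a = 5L, n_novel = 0L, n_upgrade = 6L)
  expect_error(snapshot_sim_config(cells = cells), "exceeds")
})

test_that("zero carrier rate gives exactly zero PPGV prevalence", {
  pair <- gen_snapshot_pair(snapshot_sim_config(scale = 300, seed = 31))
  pi0 <- setNames(rep(0, 5), c("AFR", "AMR", "EAS", "EUR", "SAS"))
  co <- gen_cohort(cohort_sim_config(pi = pi0, seed = 32), pair$a)
  st <- sample_ppgv_status(call_ppgv(co$calls, co$samples, pair$a), co$samples)
  expect_equal(sum(st$ppgv_positive), 0L)
  expect_false(any(co$truth$samples$carrier))
})

test_that("planted evidence upgrades flip exactly their decisions to PASS", {
  cells <- data.table::data.table(
    gene = rep("BRCA1", 2),
    family = "PATHOGENIC_FAMILY",
    detail = c("MULTIPLE_SUBMITTERS_NO_CONFLICTS", "SINGLE_SUBMITTER"),
    n_a = c(30L, 40L), n_novel = 0L, n_upgrade = c(0L, 15L))
  pair <- gen_snapshot_pair(snapshot_sim_config(cells = cells, seed = 41))
  anc <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  co <- gen_cohort(cohort_sim_config(
    cells = data.table::data.table(specimen = "TISSUE", cancer_type = "Lung",
                                   ancestry = anc, n = 400L),
    pi = setNames(rep(0.3, 5), anc), rho = setNames(rep(0.5, 5), anc),
    background_rate = 0.3, seed = 42), pair$a)
  dec_a <- call_ppgv(co$calls, co$samples, pair$a)
  dec_b <- call_ppgv(co$calls, co$samples, pair$b)
  changed <- which(dec_a$reason != dec_b$reason)
  expect_gt(length(changed), 0)
  expect_true(all(dec_a$reason[changed] == "FAIL_PLP_INSUFFICIENT"))
  expect_true(all(dec_b$reason[changed] == "PASS"))
  expect_true(all(dec_a$vid[changed] %in% pair$truth$upgraded))
})

test_that("generator-to-caller closure: observed prevalence tracks pi * rho", {
  pair <- gen_snapshot_pair(snapshot_sim_config(scale = 400, seed = 51))
  anc <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  co <- gen_cohort(cohort_sim_config(
    cells = data.table::data.table(specimen = "TISSUE", cancer_type = "Lung",
                                   ancestry = "EUR", n = 6000L),
    pi = setNames(rep(0.2, 5), anc), rho = setNames(rep(1, 5), anc),
    seed = 52), pair$a)
  st <- sample_ppgv_status(call_ppgv(co$calls, co$samples, pair$a), co$samples)
  prev <- prevalence_by(st)$prevalence
  ci <- qbinom(c(0.005, 0.995), 6000, 0.2) / 6000
  expect_gte(prev, ci[1])
  expect_lte(prev, ci[2])
  # positives are exactly carriers, minus the rare carrier whose germline
  # VAF fell below the tissue threshold (background calls never PASS)
  expect_true(all(st[ppgv_positive == TRUE, sample_id] %in%
                    co$truth$samples[carrier == TRUE, sample_id]))
  expect_lte(sum(co$truth$samples$carrier) - sum(st$ppgv_positive), 2L)
})
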