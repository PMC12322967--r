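# ppgv_caller: filter order, thresholds, snapshot matching, per-sample
# status, and equivalence with a brute-force oracle.

snap_fixture <- function() {
  toy_snapshot(
    list("17", 1000, "G", "A", "BRCA1", SIG_PLP, REV_MULTI),     # banner PLP
    list("17", 2000, "C", "T", "BRCA1", SIG_PLP, REV_SINGLE),    # insufficient
    list("17", 3000, "A", "G", "BRCA1", SIG_BLB, REV_MULTI),     # BLB
    list("17", 4000, "T", "C", "BRCA1", SIG_VUS, REV_MULTI))     # VUS
}

call_row <- function(id, gene, pos, vaf, ref = "G", alt = "A") {
  data.table::data.table(sample_id = id, gene = gene, chrom = "17",
                         pos = pos, ref = ref, alt = alt, vaf = vaf)
}

test_that("the three banner criteria apply in gene -> VAF -> ClinVar order", {
  snap <- snap_fixture()
  samples <- data.table::data.table(
    sample_id = c("T1", "L1"), specimen = c("TISSUE", "LIQUID"),
    cancer_type = "Breast", ancestry = "EUR")
  calls <- rbind(
    call_row("T1", "BRCA1", 1000, 0.12),                  # PASS
    call_row("L1", "BRCA1", 1000, 0.25),                  # liquid below 0.30
    call_row("T1", "BRCA1", 9999, 0.50),                  # absent from snapshot
    call_row("T1", "BRCA1", 2000, 0.50, "C", "T"),        # P/LP single submitter
    call_row("T1", "BRCA1", 3000, 0.50, "A", "G"),        # B/LB
    call_row("T1", "BRCA1", 4000, 0.50, "T", "C"),        # VUS
    call_row("T1", "TP53", 1000, 0.50))                   # off panel
  dec <- call_ppgv(calls, samples, snap)
  expect_identical(dec$reason,
                   c("PASS", "FAIL_VAF", "FAIL_NOT_IN_CLINVAR",
                     "FAIL_PLP_INSUFFICIENT", "FAIL_BLB", "FAIL_VUS",
                     "FAIL_GENE"))
  expect_identical(dec$is_ppgv, dec$reason == "PASS")
  # evidence present exactly for the ClinVar-stage failures that matched
  expect_false(anyNA(dec$banner_class[4:6]))
  expect_true(all(is.na(dec$banner_class[c(2, 7)])))
})

test_that("thresholds are inclusive and unknown specimens are fatal", {
  snap <- snap_fixture()
  samples <- toy_samples(1)
  dec <- call_ppgv(call_row("S01", "BRCA1", 1000, 0.10), samples, snap)
  expect_identical(dec$reason, "PASS")
  bad <- data.table::data.table(sample_id = "S01", specimen = "SALIVA",
                                cancer_type = "Breast", ancestry = "EUR")
  expect_error(call_ppgv(call_row("S01", "BRCA1", 1000, 0.5), bad, snap),
               "specimen")
})

test_that("decisions match the brute-force oracle on random instances", {
  snap <- snap_fixture()
  cfg <- banner_config()
  set.seed(42)
  for (rep in 1:3) {
    n <- 400
    samples <- data.table::data.table(
      sample_id = sprintf("S%03d", 1:40),
      specimen = sample(c("TISSUE", "LIQUID"), 40, replace = TRUE),
      cancer_type = "Lung", ancestry = "EUR")
    calls <- data.table::data.table(
      sample_id = sample(samples$sample_id, n, replace = TRUE),
      gene = sample(c("BRCA1", "TP53", "ATM"), n, replace = TRUE),
      chrom = "17",
      pos = sample(c(1000L, 2000L, 3000L, 4000L, 7777L), n, replace = TRUE),
      vaf = round(runif(n), 3))
    keyed <- snap$records[match(calls$pos, pos)]
    calls[, ref := data.table::fifelse(is.na(keyed$ref), "G", keyed$ref)]
    calls[, alt := data.table::fifelse(is.na(keyed$alt), "A", keyed$alt)]
    dec <- call_ppgv(calls, samples, snap, cfg)
    expect_identical(dec$reason, ppgv_oracle(calls, samples, snap, cfg))
    expect_equal(nrow(dec), nrow(calls))  # count conservation
  }
})

test_that("raising a VAF threshold never increases the PPGV count", {
  pair <- gen_snapshot_pair(snapshot_sim_config(scale = 400, seed = 5))
  co <- gen_cohort(cohort_sim_config(seed = 6), pair$a)
  base <- sum(call_ppgv(co$calls, co$samples, pair$a)$is_ppgv)
  for (thr in list(c(0.2, 0.3), c(0.1, 0.5), c(0.3, 0.6))) {
    cfg <- banner_config(vaf_threshold_tissue = thr[1],
                         vaf_threshold_liquid = thr[2])
    expect_lte(sum(call_ppgv(co$calls, co$samples, pair$a, cfg)$is_ppgv), base)
  }
})

test_that("a snapshot superset never converts PASS to FAIL_NOT_IN_CLINVAR", {
  pair <- gen_snapshot_pair(snapshot_sim_config(scale = 400, seed = 5))
  co <- gen_cohort(cohort_sim_config(seed = 6), pair$a)
  dec_a <- call_ppgv(co$calls, co$samples, pair$a)  # B is a superset of A
  dec_b <- call_ppgv(co$calls, co$samples, pair$b)
  was_pass <- dec_a$reason == "PASS"
  expect_false(any(dec_b$reason[was_pass] == "FAIL_NOT_IN_CLINVAR"))
})

test_that("per-sample status counts any PASS as positive and covers the cohort", {
  snap <- snap_fixture()
  samples <- toy_samples(3)
  calls <- rbind(call_row("S01", "BRCA1", 1000, 0.5),      # PASS
                 call_row("S01", "BRCA1", 4000, 0.5, "T", "C"),  # FAIL_VUS
                 call_row("S02", "BRCA1", 1000, 0.5))      # PASS
  st <- sample_ppgv_status(call_ppgv(calls, samples, snap), samples)
  expect_equal(nrow(st), 3L)
  expect_identical(st$ppgv_positive, c(TRUE, TRUE, FALSE))  # S03: no calls
  expect_equal(st[sample_id == "S03", n_calls], 0L)

  rogue <- call_ppgv(call_row("S01", "BRCA1", 1000, 0.5), samples, snap)
  rogue[, sample_id := "GHOST"]
  expect_error(sample_ppgv_status(rogue, samples), "unknown sample")
})
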