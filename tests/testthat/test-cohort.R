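# cohort_analysis: prevalence strata, the filter decomposition, the exact
# Fisher test against an enumeration oracle, BH adjustment, disparity tests.

status_from_flags <- function(flags, ancestry = "EUR", cancer_type = "Breast") {
  data.table::data.table(
    sample_id = sprintf("S%03d", seq_along(flags)),
    specimen = "TISSUE", cancer_type = cancer_type, ancestry = ancestry,
    n_calls = 1L, n_ppgv = as.integer(flags), ppgv_positive = flags)
}

test_that("prevalence tables: ratios, strata and overall row", {
  st <- status_from_flags(rep(FALSE, 8))
  expect_true(all(prevalence_by(st, "overall")$prevalence == 0))

  st <- status_from_flags(c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(prevalence_by(st, "overall")$prevalence, 0.3)

  st <- status_from_flags(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                          cancer_type = rep(c("Lung", "Breast"), each = 3))
  out <- prevalence_by(st, "cancer_type")
  expect_equal(out[level == "Lung", prevalence], 2 / 3)
  expect_equal(out[level == "Breast", prevalence], 1 / 3)
  expect_equal(out[level == "overall", n_samples], 6L)
  # stratum sample counts partition the cohort
  expect_equal(sum(out[level != "overall", n_samples]), 6L)
})

test_that("prevalence_compare reports both percentage points and percent change", {
  st_a <- status_from_flags(c(rep(TRUE, 10), rep(FALSE, 90)))
  st_b <- status_from_flags(c(rep(TRUE, 15), rep(FALSE, 85)))
  cmp <- prevalence_compare(st_a, st_b)
  expect_equal(cmp$pp_change, 5)          # 10% -> 15% is +5 points
  expect_equal(cmp$rel_change_pct, 50)    # and +50% of baseline
})

test_that("filter decomposition: eligibility, fractions, unknown ancestry", {
  dec <- data.table::data.table(
    sample_id = sprintf("S%03d", 1:7),
    reason = c("PASS", "PASS", "FAIL_VUS", "FAIL_NOT_IN_CLINVAR",
               "FAIL_GENE", "FAIL_VAF", "PASS"))
  samples <- data.table::data.table(
    sample_id = sprintf("S%03d", 1:7), specimen = "TISSUE",
    cancer_type = "Lung",
    ancestry = c(rep("AFR", 6), "UNKNOWN"))
  out <- filter_decomposition(dec, samples)
  # ancestry AFR: 4 eligible (2 PASS, 1 FAIL_VUS, 1 FAIL_NOT_IN_CLINVAR)
  expect_equal(out[ancestry == "AFR", n_eligible], 4L)
  expect_equal(out[ancestry == "AFR", frac_excluded], 0.5)
  expect_equal(out[ancestry == "AFR", frac_FAIL_VUS], 0.25)
  expect_equal(out[ancestry == "AFR", frac_FAIL_NOT_IN_CLINVAR], 0.25)
  fr <- out[ancestry == "AFR",
            frac_PASS + frac_FAIL_NOT_IN_CLINVAR + frac_FAIL_VUS +
              frac_FAIL_PLP_INSUFFICIENT + frac_FAIL_BLB]
  expect_equal(fr, 1)
  expect_equal(attr(out, "n_unknown_ancestry"), 1L)
  expect_false("UNKNOWN" %in% out$ancestry)
})

test_that("fisher_exact_2x2 matches hand enumeration on the worked examples", {
  # [[1,3],[3,1]]: 5 admissible tables conditional on margins; the two
  # extreme-or-equal tables contribute 16/70 + 1/70 each side + observed
  res <- fisher_exact_2x2(matrix(c(1, 3, 3, 1), 2, byrow = TRUE))
  expect_equal(res$p_value, 34 / 70)
  expect_equal(res$odds_ratio, 1 / 9)

  res <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  res <- fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 / choose(20, 10))  # the two extreme tables

  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("fisher_exact_2x2 equals the enumeration oracle on random tables", {
  set.seed(99)
  for (i in 1:200) {
    x <- as.integer(rmultinom(1, sample(1:30, 1), prob = runif(4, 0.05, 1)))
    got <- fisher_exact_2x2(matrix(x, 2))$p_value
    want <- fisher_enum_oracle(x[1], x[3], x[2], x[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces the step-up rule and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)                       # m = 1
  expect_equal(bh_adjust(rep(0.5, 4)), rep(0.5, 4))         # ties
  set.seed(7)
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))                                # never smaller
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), adj[perm])               # order invariance
  expect_equal(adj, stats::p.adjust(p, method = "BH"))      # reference route
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("disparity tests: toy counts, BH family, empty strata, null case", {
  flags <- c(rep(TRUE, 600), rep(FALSE, 4400), rep(TRUE, 450), rep(FALSE, 4550))
  st <- status_from_flags(flags, ancestry = rep(c("EUR", "AFR"), each = 5000))
  res <- ancestry_disparity_tests(st, "prevalence")
  afr <- res[comparison == "AFR vs EUR"]
  expect_true(afr$computable)
  # oracle: enumeration p for [[450,4550],[600,4400]], BH within the
  # computable family (here a single comparison, so unchanged)
  expect_equal(afr$p_raw, fisher_enum_oracle(450, 4550, 600, 4400))
  expect_equal(afr$p_adj, afr$p_raw)
  # the three absent ancestries are reported, not dropped
  expect_equal(nrow(res), 4L)
  expect_false(any(res[comparison != "AFR vs EUR", computable]))
  expect_true(all(is.na(res[computable == FALSE, p_adj])))

  # identical prevalence in every ancestry: nothing significant
  flags <- rep(c(rep(TRUE, 10), rep(FALSE, 90)), 5)
  st <- status_from_flags(flags,
                          ancestry = rep(c("AFR", "AMR", "EAS", "EUR", "SAS"),
                                         each = 100))
  res <- ancestry_disparity_tests(st, "prevalence")
  expect_false(any(res$significant))

  # empty reference is fatal
  st_no_eur <- status_from_flags(c(TRUE, FALSE), ancestry = "AFR")
  expect_error(ancestry_disparity_tests(st_no_eur, "prevalence"), "EUR")
})

test_that("call-level filtering tests mirror the decomposition counts", {
  deco <- data.table::data.table(
    ancestry = c("EUR", "AFR"), n_eligible = c(1000L, 500L),
    frac_PASS = c(0.7, 0.6), frac_FAIL_NOT_IN_CLINVAR = c(0.2, 0.3),
    frac_FAIL_VUS = c(0.05, 0.05), frac_FAIL_PLP_INSUFFICIENT = c(0.04, 0.04),
    frac_FAIL_BLB = c(0.01, 0.01), frac_excluded = c(0.3, 0.4))
  res <- ancestry_disparity_tests(deco, "filtering")
  afr <- res[comparison == "AFR vs EUR"]
  expect_equal(afr$x, 200L)   # 0.4 * 500 excluded calls
  expect_equal(afr$x_ref, 300L)
  expect_equal(afr$p_raw, fisher_enum_oracle(200, 300, 300, 700))
})
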