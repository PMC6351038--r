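# Synergy factor and the exact conditional no-three-way-interaction test.

test_that("inclusion-exclusion reconstruction recovers the stratum cells", {
  t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  expect_equal(unname(t$case), c(21L, 24L, 89L, 149L))
  expect_equal(unname(t$control), c(4L, 21L, 101L, 164L))

  t2 <- reconstruct_from_marginals(45, 169, 35, 283, 25, 170, 14, 290)
  expect_equal(unname(t2$case), c(35L, 10L, 134L, 104L))
  expect_equal(unname(t2$control), c(14L, 11L, 156L, 109L))

  # joint carriers cannot exceed either marginal
  expect_error(
    reconstruct_from_marginals(10, 20, 15, 100, 5, 5, 2, 100),
    class = "mitosyn_data_error"
  )
})

test_that("cohort cross-classification equals marginal reconstruction on fixtures", {
  for (pair in c("CCL5", "PVT1")) {
    cohort <- study_fixture(pair)
    fs <- study_features(pair)
    t <- build_2x2x2(cohort, fs$a, fs$b)
    expected <- if (pair == "CCL5") {
      list(case = c(21L, 24L, 89L, 149L), control = c(4L, 21L, 101L, 164L))
    } else {
      list(case = c(35L, 10L, 134L, 104L), control = c(14L, 11L, 156L, 109L))
    }
    expect_equal(unname(t$case), expected$case, label = pair)
    expect_equal(unname(t$control), expected$control, label = pair)
  }

  # nobody carries B: the B-positive columns are all zero
  df <- tiny_cohort_df()
  df$rs2107538 <- "G/G"
  t0 <- build_2x2x2(as_cohort(df), "hg:J", "rs2107538:A")
  expect_equal(unname(t0$case[c("n11", "n01")]), c(0L, 0L))
  expect_equal(unname(t0$control[c("n11", "n01")]), c(0L, 0L))
})

test_that("synergy factor reproduces the published point estimates", {
  t_ccl5 <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  r <- synergy_factor(t_ccl5)
  expect_true(r$correction_applied)  # smallest cell is 4
  expect_equal(round(r$sf, 2), 4.32)
  expect_equal(r$sf, r$or11 / (r$or10 * r$or01))

  t_pvt <- reconstruct_from_marginals(45, 169, 35, 283, 25, 170, 14, 290)
  r2 <- synergy_factor(t_pvt)
  expect_false(r2$correction_applied)  # smallest cell is 10
  expect_equal(round(r2$sf, 2), 3.05)
  expect_equal(round(r2$ci_low, 2), 1.00)
  expect_equal(round(r2$ci_high, 2), 9.31)

  # multiplicative null: or11 = or10 * or01 exactly, no correction
  t_null <- two_by_two_by_two(c(20, 10, 10, 5), c(10, 10, 10, 10))
  expect_equal(synergy_factor(t_null)$sf, 1)
})

test_that("SF is factor-symmetric and inverts under status swap", {
  t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  swapped_factors <- two_by_two_by_two(
    t$case[c("n11", "n01", "n10", "n00")],
    t$control[c("n11", "n01", "n10", "n00")]
  )
  a <- synergy_factor(t)
  b <- synergy_factor(swapped_factors)
  expect_equal(a$sf, b$sf)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$ci_high, b$ci_high)

  swapped_status <- two_by_two_by_two(t$control, t$case)
  c_ <- synergy_factor(swapped_status)
  expect_equal(c_$sf, 1 / a$sf)
  expect_equal(c_$ci_low, 1 / a$ci_high)
  expect_equal(flint_exact(swapped_status)$p_flint, flint_exact(t)$p_flint)
})

test_that("the small-cell threshold is a real parameter", {
  t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  uncorrected <- synergy_factor(t, small_cell_threshold = 0)
  expect_false(uncorrected$correction_applied)
  expect_gt(uncorrected$sf, synergy_factor(t)$sf)  # 4.74 raw vs 4.32
})

test_that("FLINT handles degenerate and symmetric tables", {
  # only one table satisfies the margins
  single <- two_by_two_by_two(c(1, 0, 0, 0), c(0, 0, 0, 1))
  r <- flint_exact(single)
  expect_equal(r$n_tables, 1L)
  expect_equal(r$p_flint, 1)

  # all eight cells equal: observed table is modal, P = 1
  flat <- two_by_two_by_two(rep(5, 4), rep(5, 4))
  expect_equal(flint_exact(flat)$p_flint, 1)
})

test_that("FLINT's null distribution is normalized and oracle-consistent", {
  t_ccl5 <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  expect_equal(sum(flint_exact(t_ccl5)$probs), 1, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:20) {
    t <- random_2x2x2(60)
    r <- flint_exact(t)
    expect_equal(sum(r$probs), 1, tolerance = 1e-9)
    expect_equal(r$p_flint, oracle_flint_p(t), tolerance = 1e-9)
  }
  # larger tables stay normalized even where the oracle is infeasible
  set.seed(12)
  for (i in 1:5) {
    t <- random_2x2x2(200)
    expect_equal(sum(flint_exact(t)$probs), 1, tolerance = 1e-9)
  }
})

test_that("the one-sided synergy tail is coherent with the pivot ordering", {
  t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
  r <- flint_exact(t)
  expect_equal(r$observed, 21L)
  expect_true(r$p_synergy <= 1 && r$p_synergy > 0)
  probs <- r$probs
  expect_equal(
    r$p_synergy,
    sum(probs[as.integer(names(probs)) >= r$observed])
  )
})

test_that("interaction classification combines both criteria", {
  sf_hit <- list(ci_low = 1.20, ci_high = 15.60)
  sf_border <- list(ci_low = 1.0017, ci_high = 9.31)
  sf_miss <- list(ci_low = 0.63, ci_high = 7.97)
  expect_equal(
    classify_interaction(sf_hit, list(p_flint = 0.025)), "EPISTATIC"
  )
  expect_equal(
    classify_interaction(sf_border, list(p_flint = 0.084)), "SUGGESTIVE"
  )
  expect_equal(
    classify_interaction(sf_miss, list(p_flint = 0.34)), "NOT_SUPPORTED"
  )
})
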