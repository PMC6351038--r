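# Carriership 2x2 tables, Fisher exact test, Woolf OR/CI, sex strata.

test_that("carrier status follows dominant allele and exact genotype coding", {
  cohort <- as_cohort(tiny_cohort_df())
  # S1 C/A carries A; S2 G/G does not; S3 A/A carries; S4 missing
  expect_equal(
    carrier_status(cohort, feature_allele("rs2107538", "A")),
    c("CARRIER", "NONCARRIER", "CARRIER", NA)
  )
  # exact-genotype coding: heterozygote is NOT an A/A carrier
  expect_equal(
    carrier_status(cohort, feature_genotype("rs2107538", "A/A")),
    c("NONCARRIER", "NONCARRIER", "CARRIER", NA)
  )
  # haplogroup feature: UNKNOWN call maps to missing
  df <- tiny_cohort_df()
  df$mt_10398[1] <- "."
  expect_equal(
    carrier_status(as_cohort(df), feature_haplogroup("J"))[1],
    NA_character_
  )
  expect_error(
    carrier_status(cohort, feature_allele("rs9999", "A")),
    class = "mitosyn_feature_error"
  )
})

test_that("2x2 tables reproduce the reconstructed study counts", {
  t_j <- build_2x2(study_fixture("CCL5"), "hg:J")
  expect_equal(c(t_j$a, t_j$b, t_j$c, t_j$d), c(45L, 238L, 25L, 265L))

  t_pvt <- build_2x2(study_fixture("PVT1"), "rs2114358:G")
  expect_equal(c(t_pvt$a, t_pvt$b, t_pvt$c, t_pvt$d),
               c(169L, 114L, 170L, 120L))

  df <- tiny_cohort_df()
  df$rs2107538 <- "."
  expect_error(
    build_2x2(as_cohort(df), "rs2107538:A"),
    class = "mitosyn_degenerate_error"
  )
})

test_that("Fisher two-sided P matches enumeration on worked examples", {
  expect_equal(fisher_two_sided(c(2, 1, 1, 2)), 1)
  # both extreme tables have point probability 1/252; their sum is the P
  expect_equal(fisher_two_sided(c(5, 0, 0, 5)), 2 / 252)
  expect_equal(oracle_fisher_p(5, 0, 0, 5), 2 / 252)
  # observed table modal under equal proportions and symmetric margins
  expect_equal(fisher_two_sided(c(10, 10, 10, 10)), 1)
  expect_error(fisher_two_sided(c(0, 0, 3, 4)),
               class = "mitosyn_degenerate_error")
})

test_that("Fisher P agrees with the enumeration oracle and fisher.test on random tables", {
  set.seed(42)
  for (i in 1:60) {
    t <- random_2x2(60)
    p <- fisher_two_sided(t)
    expect_equal(p, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    p_ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(p, p_ref, tolerance = 1e-6)
  }
})

test_that("row/column swaps invert the OR and leave P unchanged", {
  set.seed(7)
  for (i in 1:25) {
    t <- random_2x2(50) + 1L  # keep cells positive so OR is finite
    or0 <- odds_ratio_woolf(t)
    swapped_cols <- odds_ratio_woolf(t[c(2, 1, 4, 3)])
    swapped_rows <- odds_ratio_woolf(t[c(3, 4, 1, 2)])
    expect_equal(swapped_cols$or_value, 1 / or0$or_value)
    expect_equal(swapped_rows$or_value, 1 / or0$or_value)
    expect_equal(swapped_cols$ci_low, 1 / or0$ci_high)
    expect_equal(fisher_two_sided(t[c(2, 1, 4, 3)]), fisher_two_sided(t))
    expect_equal(fisher_two_sided(t[c(3, 4, 1, 2)]), fisher_two_sided(t))
  }
})

test_that("Woolf OR and CI reproduce the published haplogroup-J rows", {
  r <- odds_ratio_woolf(c(45, 238, 25, 265))
  expect_equal(round(r$or_value, 2), 2.00)
  expect_equal(round(r$ci_low, 2), 1.19)
  expect_equal(round(r$ci_high, 2), 3.37)
  expect_false(r$correction_applied)

  r2 <- odds_ratio_woolf(c(35, 248, 14, 276))
  expect_equal(round(r2$or_value, 2), 2.78)
  expect_equal(round(r2$ci_low, 2), 1.46)
  expect_equal(round(r2$ci_high, 2), 5.29)

  expect_equal(odds_ratio_woolf(c(10, 10, 10, 10))$or_value, 1)
})

test_that("zero cells trigger the +0.5 correction and the CI stays ordered", {
  r <- odds_ratio_woolf(c(5, 0, 3, 7))
  expect_true(r$correction_applied)
  expect_true(r$ci_low <= r$or_value && r$or_value <= r$ci_high)
})

test_that("the CI widens as cells shrink proportionally at fixed OR", {
  widths <- sapply(c(8, 4, 2, 1), function(k) {
    r <- odds_ratio_woolf(k * c(20, 10, 10, 20))
    log(r$ci_high) - log(r$ci_low)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("sex stratification reproduces the study's group sizes", {
  strata <- stratify_by_sex(study_fixture("CCL5"))
  expect_equal(sum(strata$female$status == "case"), 198L)
  expect_equal(sum(strata$female$status == "control"), 197L)
  expect_equal(sum(strata$male$status == "case"), 85L)
  expect_equal(sum(strata$male$status == "control"), 93L)

  df <- tiny_cohort_df()
  df$sex <- "."
  empty <- stratify_by_sex(as_cohort(df))
  expect_equal(nrow(empty$female), 0L)
  expect_equal(nrow(empty$male), 0L)
})

test_that("carrier frequencies reproduce every printed fixture percentage within 0.1", {
  printed <- list(
    CCL5 = c(feat_case = 38.8, feat_ctrl = 36.2, joint_case = 7.4,
             joint_ctrl = 1.4),
    PVT1 = c(59.7, 58.6, 12.4, 4.8),
    TNFSF14 = c(93.9, 90.0, 15.5, 7.2),
    IL4 = c(94.3, 91.0, 15.5, 7.2),
    CLEC16A = c(78.0, 70.0, 13.7, 5.9)
  )
  for (pair in names(printed)) {
    cohort <- study_fixture(pair)
    fs <- study_features(pair)
    single <- associate(cohort, list(fs$b))
    joint <- build_2x2(cohort, list(fs$a, fs$b))
    got <- c(
      single$freq_case_pct, single$freq_control_pct,
      100 * joint$a / (joint$a + joint$b),
      100 * joint$c / (joint$c + joint$d)
    )
    expect_true(all(abs(got - unname(printed[[pair]])) <= 0.1),
                label = paste("percentages for", pair))
  }
})
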