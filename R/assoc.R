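# Case-control carriership association: 2x2 tables, Fisher's exact test
# (two-sided, probability ordering), odds ratio with Woolf-type 95% CI.

#' 2x2 case-control carriership table
#'
#' @param a case carriers
#' @param b case non-carriers
#' @param c control carriers
#' @param d control non-carriers
#' @return A `mitosyn_2x2` object.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    abort_config("2x2 cells must be non-negative integers")
  }
  structure(
    as.list(stats::setNames(as.integer(cells), names(cells))),
    class = "mitosyn_2x2"
  )
}

#' @export
print.mitosyn_2x2 <- function(x, ...) {
  m <- matrix(
    c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(c("case", "control"), c("carrier", "noncarrier"))
  )
  print(m)
  invisible(x)
}

#' Build the carriership 2x2 table for a feature (or joint combination)
#'
#' Counts carriers and non-carriers among informative subjects (complete-case
#' per feature: subjects whose carrier status is missing for any component
#' are excluded from both margins).
#'
#' @param cohort a `mitosyn_cohort`.
#' @param features one feature or a list of features; a list is scored as
#'   joint carriership (carrier of every component).
#' @param calls optional precomputed haplogroup calls.
#' @return A `mitosyn_2x2` with cells `a` (case carriers), `b` (case
#'   non-carriers), `c` (control carriers), `d` (control non-carriers).
#' @export
build_2x2 <- function(cohort, features, calls = NULL) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  st <- joint_carrier_status(cohort, features, calls)
  keep <- !is.na(st)
  status <- cohort$status[keep]
  carrier <- st[keep] == "CARRIER"
  t <- two_by_two(
    sum(status == "case" & carrier),
    sum(status == "case" & !carrier),
    sum(status == "control" & carrier),
    sum(status == "control" & !carrier)
  )
  if (t$a + t$b == 0L || t$c + t$d == 0L) {
    abort_degenerate(paste0(
      "no informative subjects in ",
      if (t$a + t$b == 0L) "cases" else "controls",
      " for feature ", feature_label(features)
    ))
  }
  t
}

as_2x2 <- function(t) {
  if (inherits(t, "mitosyn_2x2")) t
  else if (is.numeric(t) && length(t) == 4L) two_by_two(t[1], t[2], t[3], t[4])
  else abort_config("expected a mitosyn_2x2 or a numeric vector (a, b, c, d)")
}

#' Two-sided Fisher exact P for a 2x2 table
#'
#' Probability-ordering convention: with all margins fixed, the P value is
#' the sum of hypergeometric probabilities of every table whose point
#' probability does not exceed the observed one (relative tie tolerance
#' 1e-12).
#'
#' @param t a `mitosyn_2x2` or numeric `(a, b, c, d)`.
#' @return P in (0, 1].
#' @examples
#' fisher_two_sided(c(2, 1, 1, 2))  # 1
#' @export
fisher_two_sided <- function(t) {
  t <- as_2x2(t)
  r1 <- t$a + t$b
  r2 <- t$c + t$d
  k <- t$a + t$c     # carrier margin
  n <- r1 + r2
  if (r1 == 0L || r2 == 0L) {
    abort_degenerate("degenerate margins: a status row is empty")
  }
  support <- max(0L, r1 - (n - k)):min(r1, k)
  probs <- stats::dhyper(support, k, n - k, r1)
  p_obs <- stats::dhyper(t$a, k, n - k, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

#' Odds ratio with Woolf-type confidence interval
#'
#' OR = (a d)/(b c); the CI is `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))`. If any cell is zero, the Haldane-Anscombe correction (+0.5 to all
#' four cells) is applied first and flagged.
#'
#' @param t a `mitosyn_2x2` or numeric `(a, b, c, d)`.
#' @param z normal quantile for the interval (default 1.96 for 95%).
#' @return List with `or_value`, `ci_low`, `ci_high`, `correction_applied`.
#' @examples
#' odds_ratio_woolf(c(45, 238, 25, 265))  # OR 2.00, CI 1.19-3.37
#' @export
odds_ratio_woolf <- function(t, z = 1.96) {
  t <- as_2x2(t)
  if (t$a + t$b == 0L || t$c + t$d == 0L) {
    abort_degenerate("degenerate margins: a status row is empty")
  }
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0L)
  w <- if (corrected) cells + 0.5 else cells
  or <- (w[1] * w[4]) / (w[2] * w[3])
  se <- sqrt(sum(1 / w))
  list(
    or_value = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    correction_applied = corrected
  )
}

#' Split a cohort into female and male strata
#'
#' Subjects with missing sex belong to neither stratum.
#'
#' @param cohort a `mitosyn_cohort`.
#' @return List with elements `female` and `male`, each a `mitosyn_cohort`.
#' @export
stratify_by_sex <- function(cohort) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  list(
    female = cohort[!is.na(cohort$sex) & cohort$sex == "F", ],
    male = cohort[!is.na(cohort$sex) & cohort$sex == "M", ]
  )
}

# One association row (the Results TSV schema).
association_row <- function(cohort, features, calls = NULL, z = 1.96) {
  t <- build_2x2(cohort, features, calls)
  orci <- odds_ratio_woolf(t, z = z)
  data.frame(
    feature = feature_label(features),
    n_case_carrier = t$a,
    n_case_total = t$a + t$b,
    n_control_carrier = t$c,
    n_control_total = t$c + t$d,
    freq_case_pct = 100 * t$a / (t$a + t$b),
    freq_control_pct = 100 * t$c / (t$c + t$d),
    p_fisher = fisher_two_sided(t),
    odds_ratio = orci$or_value,
    ci_low = orci$ci_low,
    ci_high = orci$ci_high,
    correction_applied = orci$correction_applied,
    stringsAsFactors = FALSE
  )
}

#' Carriership association results for a set of features
#'
#' For each feature: carrier counts and frequencies by status, two-sided
#' Fisher exact P, odds ratio and Woolf 95% CI.
#'
#' @param cohort a `mitosyn_cohort`.
#' @param features features (objects or `"locus:value"` strings).
#' @param z normal quantile for the CI.
#' @return Data frame, one row per feature, columns `feature`,
#'   `n_case_carrier`, `n_case_total`, `n_control_carrier`,
#'   `n_control_total`, `freq_case_pct`, `freq_control_pct`, `p_fisher`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `correction_applied`.
#' @examples
#' cohort <- study_fixture("CCL5")
#' associate(cohort, c("hg:J", "rs2107538:A"))
#' @export
associate <- function(cohort, features, z = 1.96) {
  features <- as_feature_list(features)
  calls <- call_haplogroups(cohort)
  do.call(rbind, lapply(features, function(f) {
    association_row(cohort, list(f), calls, z = z)
  }))
}
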