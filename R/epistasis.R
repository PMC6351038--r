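# Epistasis between two carriership factors in a case-control cohort.
#
# The 2x2x2 table cross-classifies disease status by carriage of factor A
# and factor B. Two criteria quantify interaction:
#   * synergy factor SF = OR11 / (OR10 * OR01), all stratum odds ratios
#     referenced to double-non-carriers, with a Woolf-type CI on ln SF
#     (variance = sum of reciprocal cells);
#   * FLINT, a conditional exact test of no three-way interaction: with all
#     three two-way margins fixed the table family has one degree of
#     freedom, and the null distribution over it is proportional to
#     1 / prod(cell!).

#' 2x2x2 disease-by-carriage table
#'
#' @param case,control numeric vectors `(n11, n10, n01, n00)` of counts for
#'   that status: joint carriers, A-only, B-only, double non-carriers.
#' @return A `mitosyn_2x2x2` object with integer fields `case` and
#'   `control`, each named `n11, n10, n01, n00`.
#' @export
two_by_two_by_two <- function(case, control) {
  chk <- function(x, what) {
    if (length(x) != 4L || anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort_config(paste0(what, " cells must be 4 non-negative integers"))
    }
    stats::setNames(as.integer(x), c("n11", "n10", "n01", "n00"))
  }
  structure(
    list(case = chk(case, "case"), control = chk(control, "control")),
    class = "mitosyn_2x2x2"
  )
}

#' @export
print.mitosyn_2x2x2 <- function(x, ...) {
  m <- rbind(case = x$case, control = x$control)
  colnames(m) <- c("A+B+", "A+B-", "A-B+", "A-B-")
  print(m)
  invisible(x)
}

#' Cross-classify a cohort by two carriership factors
#'
#' Complete-case over both features: subjects missing either carrier status
#' are excluded.
#'
#' @param cohort a `mitosyn_cohort`.
#' @param feat_a,feat_b the two features; they must sit on distinct loci.
#' @param calls optional precomputed haplogroup calls.
#' @return A `mitosyn_2x2x2`.
#' @export
build_2x2x2 <- function(cohort, feat_a, feat_b, calls = NULL) {
  feat_a <- as_feature_list(feat_a)[[1]]
  feat_b <- as_feature_list(feat_b)[[1]]
  if (feat_a$locus == feat_b$locus) {
    abort_config("the two factors must be at distinct loci")
  }
  sa <- carrier_status(cohort, feat_a, calls)
  sb <- carrier_status(cohort, feat_b, calls)
  keep <- !is.na(sa) & !is.na(sb)
  if (!any(keep)) abort_degenerate("no informative subjects for the pair")
  status <- cohort$status[keep]
  ia <- sa[keep] == "CARRIER"
  ib <- sb[keep] == "CARRIER"
  cells <- function(s) {
    sel <- status == s
    c(
      sum(sel & ia & ib), sum(sel & ia & !ib),
      sum(sel & !ia & ib), sum(sel & !ia & !ib)
    )
  }
  t <- two_by_two_by_two(cells("case"), cells("control"))
  if (sum(t$case) == 0L || sum(t$control) == 0L) {
    abort_degenerate("a status group has no informative subjects")
  }
  t
}

#' Reconstruct a 2x2x2 table from aggregate carrier counts
#'
#' Inclusion-exclusion from marginal counts per status: given the number of
#' A-carriers, B-carriers and joint carriers among N subjects, the four
#' exposure-stratum counts are `n11 = nAB`, `n10 = nA - nAB`,
#' `n01 = nB - nAB`, `n00 = N - nA - nB + nAB`. This recovers
#' individual-level tables from published aggregate rows.
#'
#' @param n_a_case,n_b_case,n_ab_case,n_case counts among cases: A-carriers,
#'   B-carriers, joint carriers, total.
#' @param n_a_control,n_b_control,n_ab_control,n_control same among
#'   controls.
#' @return A `mitosyn_2x2x2`.
#' @examples
#' reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
#' @export
reconstruct_from_marginals <- function(n_a_case, n_b_case, n_ab_case, n_case,
                                       n_a_control, n_b_control,
                                       n_ab_control, n_control) {
  one <- function(na, nb, nab, n) {
    if (nab > min(na, nb) || na + nb - nab > n || min(na, nb, nab, n) < 0) {
      abort_data(paste0(
        "inconsistent marginals: nA=", na, " nB=", nb, " nAB=", nab,
        " N=", n
      ))
    }
    c(nab, na - nab, nb - nab, n - na - nb + nab)
  }
  two_by_two_by_two(
    one(n_a_case, n_b_case, n_ab_case, n_case),
    one(n_a_control, n_b_control, n_ab_control, n_control)
  )
}

as_2x2x2 <- function(t) {
  if (inherits(t, "mitosyn_2x2x2")) return(t)
  abort_config("expected a mitosyn_2x2x2 (see two_by_two_by_two())")
}

#' Synergy factor with 95% confidence interval
#'
#' Stratum odds ratios take double non-carriers as reference:
#' `OR11 = (case n11 / case n00) / (control n11 / control n00)` and
#' analogously `OR10`, `OR01`. Then `SF = OR11 / (OR10 * OR01)`; `SF > 1`
#' indicates synergistic (positive) epistasis. The CI is
#' `exp(ln SF +/- z * se)` with `se^2` the sum of reciprocals of all eight
#' working cells. When the smallest cell is below `small_cell_threshold`,
#' 0.5 is added to all eight cells first (Haldane-Anscombe) and flagged.
#'
#' @param t a `mitosyn_2x2x2`.
#' @param z normal quantile for the CI (default 1.96).
#' @param small_cell_threshold apply the +0.5 correction when the minimum
#'   cell is strictly below this (default 5; set 0 to disable).
#' @return List with `sf`, `ci_low`, `ci_high`, `ln_sf_se`,
#'   `correction_applied`, and the stratum odds ratios `or11`, `or10`,
#'   `or01`.
#' @examples
#' t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
#' synergy_factor(t)$sf  # 4.32
#' @export
synergy_factor <- function(t, z = 1.96, small_cell_threshold = 5) {
  t <- as_2x2x2(t)
  cells <- unname(c(t$case, t$control))
  corrected <- min(cells) < small_cell_threshold
  w <- if (corrected) cells + 0.5 else as.numeric(cells)
  if (any(w == 0)) {
    abort_degenerate("zero working cell; SF undefined under the current correction policy")
  }
  ca <- w[1:4]
  ct <- w[5:8]
  or_stratum <- function(i) (ca[i] / ca[4]) / (ct[i] / ct[4])
  or11 <- or_stratum(1)
  or10 <- or_stratum(2)
  or01 <- or_stratum(3)
  sf <- or11 / (or10 * or01)
  se <- sqrt(sum(1 / w))
  list(
    sf = sf,
    ci_low = exp(log(sf) - z * se),
    ci_high = exp(log(sf) + z * se),
    ln_sf_se = se,
    correction_applied = corrected,
    or11 = or11, or10 = or10, or01 = or01
  )
}

#' Exact conditional test of no three-way interaction (FLINT)
#'
#' Holds all three two-way margins of the 2x2x2 table fixed (status x A,
#' status x B, A x B). The family of non-negative integer tables with those
#' margins has a single degree of freedom, indexed by the case joint-carrier
#' cell; under the null of no three-way interaction each table's probability
#' is proportional to `1 / prod(cell!)` over its eight cells. `p_flint` sums
#' the normalized probabilities of all tables whose null probability does
#' not exceed the observed one (relative tie tolerance 1e-12); `p_synergy`
#' is the one-sided tail toward larger joint-carrier counts (the synergistic
#' direction). Enumeration is done in log-factorial space.
#'
#' @param t a `mitosyn_2x2x2`.
#' @return List with `p_flint`, `p_synergy`, `n_tables`, `free_range`
#'   (feasible range of the pivot cell), `observed` (its observed value) and
#'   `probs` (the normalized null distribution over the range).
#' @examples
#' t <- reconstruct_from_marginals(45, 110, 21, 283, 25, 105, 4, 290)
#' flint_exact(t)$p_flint
#' @export
flint_exact <- function(t) {
  t <- as_2x2x2(t)
  ca <- t$case
  ct <- t$control
  n_case <- sum(ca)
  n_ctrl <- sum(ct)
  ra_case <- ca["n11"] + ca["n10"]   # case x A margin
  rb_case <- ca["n11"] + ca["n01"]   # case x B margin
  ra_ctrl <- ct["n11"] + ct["n10"]
  rb_ctrl <- ct["n11"] + ct["n01"]
  m11 <- ca["n11"] + ct["n11"]       # A x B joint margin
  cells_at <- function(tt) {
    ca_t <- c(tt, ra_case - tt, rb_case - tt,
              n_case - ra_case - rb_case + tt)
    ct_t <- c(m11 - tt, ra_ctrl - m11 + tt, rb_ctrl - m11 + tt,
              n_ctrl - ra_ctrl - rb_ctrl + m11 - tt)
    c(ca_t, ct_t)
  }
  range_all <- 0:min(ra_case, rb_case, m11)
  feasible <- range_all[vapply(
    range_all, function(tt) all(cells_at(tt) >= 0L), NA
  )]
  if (length(feasible) == 0L) abort_data("infeasible two-way margins")
  logw <- vapply(
    feasible, function(tt) -sum(lfactorial(cells_at(tt))), 0
  )
  logz <- max(logw) + log(sum(exp(logw - max(logw))))
  probs <- exp(logw - logz)
  obs <- unname(ca["n11"])
  p_obs <- probs[match(obs, feasible)]
  list(
    p_flint = min(1, sum(probs[probs <= p_obs * (1 + 1e-12)])),
    p_synergy = min(1, sum(probs[feasible >= obs])),
    n_tables = length(feasible),
    free_range = c(min(feasible), max(feasible)),
    observed = obs,
    probs = stats::setNames(probs, feasible)
  )
}

#' Classify the interaction between two factors
#'
#' Epistasis calls combine both criteria: `EPISTATIC` when `p_flint` is
#' below `alpha` AND the SF confidence interval excludes 1; `SUGGESTIVE`
#' when exactly one criterion holds; `NOT_SUPPORTED` otherwise.
#'
#' @param sf_res result of [synergy_factor()].
#' @param flint_res result of [flint_exact()].
#' @param alpha significance threshold (default 0.05).
#' @return `"EPISTATIC"`, `"SUGGESTIVE"` or `"NOT_SUPPORTED"`.
#' @export
classify_interaction <- function(sf_res, flint_res, alpha = 0.05) {
  flint_ok <- flint_res$p_flint < alpha
  ci_ok <- sf_res$ci_low > 1 || sf_res$ci_high < 1
  if (flint_ok && ci_ok) "EPISTATIC"
  else if (flint_ok || ci_ok) "SUGGESTIVE"
  else "NOT_SUPPORTED"
}
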