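# Exhaustive mining of carriership combinations (haplogroup x nuclear
# variants). Replaces a stochastic multilocus search with exact enumeration:
# at a few haplogroups x a few dozen nuclear features and order <= 2 the
# whole search space is a few thousand tables.

#' Enumerate and score feature combinations
#'
#' Evaluates every subset of 1..`max_order` features whose loci are pairwise
#' distinct, scoring joint carriership (carrier of every component) with the
#' 2x2 association statistics. Rows are ordered by descending `|ln OR|`, ties
#' broken lexicographically by combination label.
#'
#' @param cohort a `mitosyn_cohort`.
#' @param features candidate features (objects or `"locus:value"` strings).
#' @param max_order largest combination size (default 2).
#' @param alpha significance threshold for the `significant` flag.
#' @param adjust `"none"` (nominal P, default) or `"bh"`
#'   (Benjamini-Hochberg across all enumerated combinations; the
#'   `significant` flag then uses the adjusted P).
#' @return Data frame: `combination`, `order`, the association columns of
#'   [associate()], `p_adj`, `significant` (P below `alpha` and CI excluding
#'   1), and `stronger_than_components` (P strictly below every component
#'   feature's P; `NA` for order-1 rows). Combinations whose joint table is
#'   degenerate (no informative subjects in a status group) are skipped.
#' @export
enumerate_combinations <- function(cohort, features, max_order = 2,
                                   alpha = 0.05,
                                   adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  features <- as_feature_list(features)
  if (length(features) == 0L) abort_config("no features given")
  if (max_order < 1L) abort_config("max_order must be >= 1")
  n_loci <- length(unique(vapply(features, function(f) f$locus, "")))
  if (max_order > n_loci) {
    abort_config(paste0(
      "max_order (", max_order, ") exceeds the number of distinct loci (",
      n_loci, ")"
    ))
  }
  calls <- call_haplogroups(cohort)

  rows <- list()
  component_p <- rep(NA_real_, length(features))
  for (ord in seq_len(max_order)) {
    for (idx in combn_list(length(features), ord)) {
      fs <- features[idx]
      loci <- vapply(fs, function(f) f$locus, "")
      if (anyDuplicated(loci)) next  # two features at one locus: different hypothesis
      row <- tryCatch(
        association_row(cohort, fs, calls),
        mitosyn_degenerate_error = function(e) NULL
      )
      if (is.null(row)) next
      row$combination <- row$feature
      row$feature <- NULL
      row$order <- ord
      if (ord == 1L) {
        component_p[idx] <- row$p_fisher
        row$stronger_than_components <- NA
      } else {
        row$stronger_than_components <-
          !anyNA(component_p[idx]) && all(row$p_fisher < component_p[idx])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    abort_degenerate("every candidate combination produced a degenerate table")
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bh") {
    stats::p.adjust(out$p_fisher, method = "BH")
  } else {
    out$p_fisher
  }
  out$significant <- out$p_adj < alpha & (out$ci_low > 1 | out$ci_high < 1)
  ord <- order(-abs(log(out$odds_ratio)), out$combination)
  out <- out[ord, c(
    "combination", "order", "n_case_carrier", "n_case_total",
    "n_control_carrier", "n_control_total", "freq_case_pct",
    "freq_control_pct", "p_fisher", "p_adj", "odds_ratio", "ci_low",
    "ci_high", "correction_applied", "significant",
    "stronger_than_components"
  )]
  rownames(out) <- NULL
  out
}

combn_list <- function(n, k) {
  if (k > n) return(list())
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Permutation validation of a combination's association
#'
#' Empirical P for a (joint) carriership feature: the case/control labels of
#' the informative subjects are shuffled `n_perm` times and the fraction of
#' permuted cohorts whose Fisher P is at or below the observed one is
#' reported with +1 smoothing, `(1 + hits) / (n_perm + 1)`.
#'
#' @param cohort a `mitosyn_cohort`.
#' @param features the combination to validate (one feature or a list).
#' @param n_perm number of permutations, at least 100.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return List with `p_empirical`, `p_observed`, `n_perm`.
#' @export
permutation_validate <- function(cohort, features, n_perm = 999, seed = 1) {
  if (n_perm < 100L) abort_config("n_perm must be at least 100")
  st <- joint_carrier_status(cohort, features)
  keep <- !is.na(st)
  carrier <- st[keep] == "CARRIER"
  status <- cohort$status[keep]
  n_case <- sum(status == "case")
  n_ctrl <- sum(status == "control")
  if (n_case == 0L || n_ctrl == 0L) {
    abort_degenerate("degenerate observed table: a status group is empty")
  }
  k <- sum(carrier)
  obs_a <- sum(carrier & status == "case")
  p_obs <- fisher_two_sided(c(obs_a, n_case - obs_a, k - obs_a,
                              n_ctrl - (k - obs_a)))
  # P depends on the permuted table only through the case-carrier count, so
  # precompute P over its support and look permutations up.
  support <- max(0L, k - n_ctrl):min(k, n_case)
  p_by_a <- vapply(support, function(a) {
    fisher_two_sided(c(a, n_case - a, k - a, n_ctrl - (k - a)))
  }, 0)
  hits <- with_seed(seed, {
    n <- length(status)
    sum(vapply(seq_len(n_perm), function(i) {
      perm_case <- sample.int(n, n_case)
      a <- sum(carrier[perm_case])
      p_by_a[match(a, support)] <= p_obs * (1 + 1e-12)
    }, NA))
  })
  list(
    p_empirical = (1 + hits) / (n_perm + 1),
    p_observed = p_obs,
    n_perm = as.integer(n_perm)
  )
}
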