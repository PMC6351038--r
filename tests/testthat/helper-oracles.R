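# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately take different computational routes
# from the package (choose()/factorial() arithmetic, full nested-loop
# enumeration) so that agreement is informative.

# Two-sided Fisher P by explicit hypergeometric enumeration with binomial
# coefficients (probability ordering, same tie tolerance as the package).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  k <- a + c
  n <- a + b + c + d
  xs <- max(0, k - (c + d)):min(r1, k)
  probs <- choose(k, xs) * choose(n - k, r1 - xs) / choose(n, r1)
  sum(probs[probs <= probs[match(a, xs)] * (1 + 1e-12)])
}

# Exact no-three-way-interaction P by exhaustive nested-loop enumeration of
# every 2x2x2 table sharing all three two-way margins with the observed one,
# weighting each by 1 / prod(cell!) via direct factorial products. Feasible
# only for small totals.
oracle_flint_p <- function(t) {
  ca <- unname(t$case)
  ct <- unname(t$control)
  n_case <- sum(ca)
  ra_case <- ca[1] + ca[2]
  rb_case <- ca[1] + ca[3]
  ra_ctrl <- ct[1] + ct[2]
  rb_ctrl <- ct[1] + ct[3]
  m_ab <- ca + ct
  tabs <- list()
  for (x11 in 0:n_case) for (x10 in 0:(n_case - x11)) {
    if (x11 + x10 != ra_case) next
    for (x01 in 0:(n_case - x11 - x10)) {
      if (x11 + x01 != rb_case) next
      x00 <- n_case - x11 - x10 - x01
      y <- m_ab - c(x11, x10, x01, x00)
      if (min(y) < 0) next
      if (y[1] + y[2] != ra_ctrl || y[1] + y[3] != rb_ctrl) next
      tabs[[length(tabs) + 1L]] <- c(x11, x10, x01, x00, y)
    }
  }
  w <- vapply(tabs, function(cl) 1 / prod(factorial(cl)), 0)
  probs <- w / sum(w)
  obs <- c(ca, ct)
  i_obs <- which(vapply(tabs, function(cl) all(cl == obs), NA))
  sum(probs[probs <= probs[i_obs] * (1 + 1e-12)])
}

# Random 2x2 table with positive status margins and total at most n_max.
random_2x2 <- function(n_max = 60) {
  repeat {
    n <- sample(8:n_max, 1)
    r1 <- sample(1:(n - 1), 1)
    k <- sample(0:n, 1)
    a <- max(0, k - (n - r1)):min(r1, k)
    a <- sample(rep(a, 2), 1)  # rep() guards length-1 sample()
    t <- c(a, r1 - a, k - a, (n - r1) - (k - a))
    if (all(t >= 0)) return(t)
  }
}

# Random 2x2x2 table with both status groups non-empty, total at most n_max.
random_2x2x2 <- function(n_max = 60) {
  repeat {
    n <- sample(12:n_max, 1)
    n_case <- sample(4:(n - 4), 1)
    ca <- as.vector(stats::rmultinom(1, n_case, rep(0.25, 4)))
    ct <- as.vector(stats::rmultinom(1, n - n_case, rep(0.25, 4)))
    if (sum(ca) > 0 && sum(ct) > 0) {
      return(two_by_two_by_two(ca, ct))
    }
  }
}

# Minimal hand-built cohort: the J-defining haplotype row plus controllable
# extra subjects.
tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("S1", "S2", "S3", "S4"),
    status = c("case", "case", "control", "control"),
    sex = c("F", "M", "F", "."),
    mt_1719 = c("G", "G", "G", "G"),
    mt_7028 = c("T", "C", "T", "T"),
    mt_9055 = c("G", "G", "A", "G"),
    mt_10398 = c("G", "A", "G", "A"),
    mt_12308 = c("A", "A", "G", "G"),
    rs2107538 = c("C/A", "G/G", "A/A", "."),
    stringsAsFactors = FALSE
  )
}
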