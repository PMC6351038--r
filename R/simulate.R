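# Synthetic cohorts.
#
# Two generators:
#  * generate_cohort(): retrospective (case-control) sampling from a
#    two-factor odds model. Exposure strata (i, j) = (A carriage, B
#    carriage) have independent population frequencies; disease odds in
#    stratum (i, j) are baseline_odds * or10^i * or01^j * sf^(i*j). Stratum
#    distributions conditional on status follow by Bayes' rule, and case /
#    control subjects are drawn multinomially from them -- exact and fast,
#    and odds ratios (the estimand under retrospective sampling) are
#    recovered regardless of baseline_odds.
#  * study_fixture(): deterministic reconstruction of a published aggregate
#    table into 283 case + 290 control individual records whose factor-A
#    (haplogroup J), factor-B and joint carriage reproduce the printed
#    counts exactly.

#' Simulation configuration
#'
#' @param n_case,n_control numbers of cases and controls sampled.
#' @param p_a population frequency of factor-A carriage (haplogroup J).
#' @param p_b population frequency of factor-B carriage (nuclear allele).
#' @param or10,or01 stratum odds ratios for A-only and B-only carriage
#'   versus double non-carriers.
#' @param sf target synergy factor: the joint-carriage odds ratio is
#'   `or10 * or01 * sf`.
#' @param baseline_odds disease odds among double non-carriers. Inert for
#'   the odds-ratio / SF estimands under case-control sampling.
#' @param het_fraction probability that a nuclear factor-B carrier is
#'   heterozygous (else minor-allele homozygous).
#' @param background_hg named probabilities of haplogroups `H`, `K`, `U`,
#'   `OTHER` among factor-A non-carriers; must sum to 1.
#' @param p_female probability a subject is female.
#' @param locus rsID used for the nuclear factor-B column.
#' @param allele_b carrier allele at `locus`.
#' @param allele_other the other allele at `locus`.
#' @param seed integer seed for [generate_cohort()].
#' @return A `mitosyn_sim_config` list.
#' @export
simulation_config <- function(n_case = 283, n_control = 290,
                              p_a = 0.10, p_b = 0.37,
                              or10 = 1.25, or01 = 0.97, sf = 4.3,
                              baseline_odds = 0.1,
                              het_fraction = 0.85,
                              background_hg = c(H = 0.45, K = 0.05,
                                                U = 0.22, OTHER = 0.28),
                              p_female = 0.69,
                              locus = "rs2107538",
                              allele_b = "A", allele_other = "G",
                              seed = 1L) {
  probs <- c(p_a, p_b, het_fraction, p_female)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    abort_config("p_a, p_b, het_fraction, p_female must lie in [0, 1]")
  }
  odds <- c(or10, or01, sf, baseline_odds)
  if (anyNA(odds) || any(!is.finite(odds)) || any(odds <= 0)) {
    abort_config("or10, or01, sf and baseline_odds must be finite and > 0")
  }
  if (n_case < 1 || n_control < 1) {
    abort_config("n_case and n_control must be positive")
  }
  if (!setequal(names(background_hg), c("H", "K", "U", "OTHER")) ||
      abs(sum(background_hg) - 1) > 1e-8 || any(background_hg < 0)) {
    abort_config("background_hg must be probabilities for H, K, U, OTHER summing to 1")
  }
  structure(
    list(
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      p_a = p_a, p_b = p_b, or10 = or10, or01 = or01, sf = sf,
      baseline_odds = baseline_odds, het_fraction = het_fraction,
      background_hg = background_hg[c("H", "K", "U", "OTHER")],
      p_female = p_female, locus = locus,
      allele_b = allele_b, allele_other = allele_other,
      seed = as.integer(seed)
    ),
    class = "mitosyn_sim_config"
  )
}

# Stratum order used throughout: (A,B) = 11, 10, 01, 00.
stratum_distributions <- function(cfg) {
  p_strata <- c(
    cfg$p_a * cfg$p_b, cfg$p_a * (1 - cfg$p_b),
    (1 - cfg$p_a) * cfg$p_b, (1 - cfg$p_a) * (1 - cfg$p_b)
  )
  odds <- cfg$baseline_odds *
    c(cfg$or10 * cfg$or01 * cfg$sf, cfg$or10, cfg$or01, 1)
  q <- odds / (1 + odds)   # P(case | stratum)
  w_case <- p_strata * q
  w_ctrl <- p_strata * (1 - q)
  if (sum(w_case) <= 0 || sum(w_ctrl) <= 0) {
    abort_config("degenerate disease model: a status has zero mass")
  }
  list(case = w_case / sum(w_case), control = w_ctrl / sum(w_ctrl))
}

#' Generate a synthetic case-control cohort
#'
#' Draws `n_case` cases and `n_control` controls from the exposure-stratum
#' distributions implied by the two-factor odds model (see
#' [simulation_config()]). Factor A is realized as mitochondrial haplogroup
#' J (carriers get the J-defining haplotype `G,T,G,G,A`; non-carriers draw a
#' background haplogroup pattern), factor B as a nuclear locus under
#' dominant coding. Byte-identical output for identical config and seed; the
#' caller's RNG state is untouched.
#'
#' @param cfg a `mitosyn_sim_config`.
#' @return A `mitosyn_cohort`.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_case = 100, n_control = 100))
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "mitosyn_sim_config")) {
    abort_config("cfg must come from simulation_config()")
  }
  dists <- stratum_distributions(cfg)
  with_seed(cfg$seed, {
    counts_case <- stats::rmultinom(1, cfg$n_case, dists$case)[, 1]
    counts_ctrl <- stats::rmultinom(1, cfg$n_control, dists$control)[, 1]
    build_half <- function(counts, status, prefix) {
      ia <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
      ib <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
      n <- sum(counts)
      # haplogroup patterns per subject
      pat <- matrix("", n, 5)
      pat[ia, ] <- matrix(HAPLOGROUP_PATTERNS$J, sum(ia), 5, byrow = TRUE)
      n_bg <- sum(!ia)
      if (n_bg > 0) {
        bg <- sample(
          c("H", "K", "U", "OTHER"), n_bg,
          replace = TRUE, prob = cfg$background_hg
        )
        bg_pat <- rbind(
          H = HAPLOGROUP_PATTERNS$H, K = HAPLOGROUP_PATTERNS$K,
          U = HAPLOGROUP_PATTERNS$U,
          OTHER = c("A", "C", "G", "A", "A")  # 1719A lineage, outside H/J/K/U
        )
        pat[!ia, ] <- bg_pat[bg, ]
      }
      gt <- rep(NA_character_, n)
      het <- stats::runif(n) < cfg$het_fraction
      hom <- normalize_genotype(paste(cfg$allele_b, cfg$allele_b, sep = "/"))
      hetg <- normalize_genotype(
        paste(cfg$allele_b, cfg$allele_other, sep = "/")
      )
      nong <- normalize_genotype(
        paste(cfg$allele_other, cfg$allele_other, sep = "/")
      )
      gt[ib] <- ifelse(het[ib], hetg, hom)
      gt[!ib] <- nong
      df <- data.frame(
        subject_id = sprintf("%s_%05d", prefix, seq_len(n)),
        status = status,
        sex = ifelse(stats::runif(n) < cfg$p_female, "F", "M"),
        mt_1719 = pat[, 1], mt_7028 = pat[, 2], mt_9055 = pat[, 3],
        mt_10398 = pat[, 4], mt_12308 = pat[, 5],
        stringsAsFactors = FALSE
      )
      df[[cfg$locus]] <- gt
      df
    }
    as_cohort(rbind(
      build_half(counts_case, "case", "case"),
      build_half(counts_ctrl, "control", "ctrl")
    ))
  })
}

# Aggregate carrier counts per pair, as published for this cohort:
# (nA = haplogroup-J carriers, nB = nuclear-feature carriers, nAB = joint),
# among 283 cases / 290 controls.
STUDY_PAIRS <- list(
  CCL5 = list(
    locus = "rs2107538", value = "A", kind = "allele", other = "G",
    case = c(45, 110, 21, 283), control = c(25, 105, 4, 290)
  ),
  PVT1 = list(
    locus = "rs2114358", value = "G", kind = "allele", other = "A",
    case = c(45, 169, 35, 283), control = c(25, 170, 14, 290)
  ),
  TNFSF14 = list(
    locus = "rs1077667", value = "C", kind = "allele", other = "T",
    case = c(45, 266, 44, 283), control = c(25, 261, 21, 290)
  ),
  IL4 = list(
    locus = "rs2243250", value = "C", kind = "allele", other = "T",
    case = c(45, 267, 44, 283), control = c(25, 264, 21, 290)
  ),
  CLEC16A = list(
    locus = "rs1640923", value = "A/A", kind = "genotype", other = "G",
    case = c(45, 221, 39, 283), control = c(25, 203, 17, 290)
  )
)

#' Deterministic study fixture for one haplogroup-J / nuclear pair
#'
#' Rebuilds an individual-level cohort of 283 cases and 290 controls whose
#' haplogroup-J carriage, nuclear-feature carriage and joint carriage
#' exactly reproduce the published aggregate counts for the chosen pair
#' (via [reconstruct_from_marginals()]). Sex is assigned to match the
#' 198/85 (case) and 197/93 (control) female/male splits, independently of
#' genotype, and every allocation is deterministic -- no randomness.
#'
#' @param pair one of `"CCL5"`, `"PVT1"`, `"TNFSF14"`, `"IL4"`,
#'   `"CLEC16A"` (case-insensitive).
#' @return A `mitosyn_cohort` with one nuclear locus.
#' @examples
#' cohort <- study_fixture("CCL5")
#' table(cohort$status)
#' @export
study_fixture <- function(pair) {
  key <- toupper(as.character(pair)[1])
  if (!(key %in% names(STUDY_PAIRS))) {
    abort_config(paste0(
      "unknown pair '", pair, "'; expected one of ",
      paste(names(STUDY_PAIRS), collapse = ", ")
    ))
  }
  sp <- STUDY_PAIRS[[key]]
  t <- reconstruct_from_marginals(
    sp$case[1], sp$case[2], sp$case[3], sp$case[4],
    sp$control[1], sp$control[2], sp$control[3], sp$control[4]
  )
  carrier_gt <- if (sp$kind == "genotype") {
    normalize_genotype(sp$value)
  } else {
    normalize_genotype(paste(sp$value, sp$other, sep = "/"))
  }
  noncarrier_gt <- if (sp$kind == "genotype") {
    normalize_genotype(paste(strsplit(sp$value, "/")[[1]][1], sp$other,
                             sep = "/"))
  } else {
    normalize_genotype(paste(sp$other, sp$other, sep = "/"))
  }
  bg_patterns <- list(
    HAPLOGROUP_PATTERNS$H, HAPLOGROUP_PATTERNS$H, HAPLOGROUP_PATTERNS$U,
    HAPLOGROUP_PATTERNS$H, HAPLOGROUP_PATTERNS$K, HAPLOGROUP_PATTERNS$U,
    c("A", "C", "G", "A", "A")
  )
  build_half <- function(cells, status, prefix, n_female) {
    ia <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    ib <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    n <- sum(cells)
    pat <- matrix("", n, 5)
    pat[ia, ] <- matrix(HAPLOGROUP_PATTERNS$J, sum(ia), 5, byrow = TRUE)
    if (any(!ia)) {
      idx <- rep_len(seq_along(bg_patterns), sum(!ia))
      pat[!ia, ] <- do.call(rbind, bg_patterns[idx])
    }
    df <- data.frame(
      subject_id = sprintf("%s_%03d", prefix, seq_len(n)),
      status = status,
      sex = c(rep("F", n_female), rep("M", n - n_female)),
      mt_1719 = pat[, 1], mt_7028 = pat[, 2], mt_9055 = pat[, 3],
      mt_10398 = pat[, 4], mt_12308 = pat[, 5],
      stringsAsFactors = FALSE
    )
    df[[sp$locus]] <- ifelse(ib, carrier_gt, noncarrier_gt)
    df
  }
  as_cohort(rbind(
    build_half(t$case, "case", "case", 198L),
    build_half(t$control, "control", "ctrl", 197L)
  ))
}

#' The feature pair behind a study fixture
#'
#' Convenience accessor: the haplogroup-J feature and the nuclear feature
#' that [study_fixture()] encodes for `pair`.
#'
#' @inheritParams study_fixture
#' @return List with elements `a` (haplogroup J feature) and `b` (nuclear
#'   feature).
#' @export
study_features <- function(pair) {
  key <- toupper(as.character(pair)[1])
  if (!(key %in% names(STUDY_PAIRS))) {
    abort_config(paste0("unknown pair '", pair, "'"))
  }
  sp <- STUDY_PAIRS[[key]]
  b <- if (sp$kind == "genotype") {
    feature_genotype(sp$locus, sp$value)
  } else {
    feature_allele(sp$locus, sp$value)
  }
  list(a = feature_haplogroup("J"), b = b)
}
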