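# Haplogroup assignment from the five marker SNPs.
#
# The decision table maps the complete five-allele haplotype at rCRS
# positions 1719, 7028, 9055, 10398, 12308 onto haplogroups:
#   H: G C G A A    J: G T G G A    K: G T A G G    U: G T G A G
# Any other complete haplotype is OTHER; any missing marker gives UNKNOWN.

HAPLOGROUP_PATTERNS <- list(
  H = c("G", "C", "G", "A", "A"),
  J = c("G", "T", "G", "G", "A"),
  K = c("G", "T", "A", "G", "G"),
  U = c("G", "T", "G", "A", "G")
)
HAPLOGROUP_LABELS <- c("H", "J", "K", "U", "OTHER")

#' Assign a mitochondrial haplogroup from the five marker alleles
#'
#' @param mt character vector of length 5: alleles at positions 1719, 7028,
#'   9055, 10398, 12308 (in that order); `NA` or `"."` marks a missing call.
#' @return A list with `label` (one of `"H"`, `"J"`, `"K"`, `"U"`, `"OTHER"`,
#'   `"UNKNOWN"`) and `matched_pattern` (the five-allele haplotype matched,
#'   or `""` when the call is `UNKNOWN`).
#' @examples
#' call_haplogroup(c("G", "T", "G", "G", "A"))$label  # "J"
#' @export
call_haplogroup <- function(mt) {
  mt <- toupper(as.character(mt))
  if (length(mt) != 5L) {
    abort_config("expected 5 marker alleles (1719, 7028, 9055, 10398, 12308)")
  }
  mt[!is.na(mt) & mt == MISSING_TOKEN] <- NA_character_
  bad <- !is.na(mt) & !(mt %in% NUCLEOTIDES)
  if (any(bad)) {
    abort_parse(paste0("non-nucleotide marker allele: '", mt[bad][1], "'"))
  }
  if (anyNA(mt)) {
    return(list(label = "UNKNOWN", matched_pattern = ""))
  }
  key <- paste(mt, collapse = "")
  hit <- names(which(vapply(
    HAPLOGROUP_PATTERNS, function(p) paste(p, collapse = "") == key, NA
  )))
  list(
    label = if (length(hit) == 1L) hit else "OTHER",
    matched_pattern = key
  )
}

#' Assign haplogroups for every subject of a cohort
#'
#' @param cohort a `mitosyn_cohort`.
#' @return Data frame with columns `subject_id`, `haplogroup`,
#'   `matched_pattern`, one row per subject in cohort order.
#' @export
call_haplogroups <- function(cohort) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  m <- as.matrix(as.data.frame(cohort)[, MT_COLUMNS, drop = FALSE])
  key <- apply(m, 1L, function(r) {
    if (anyNA(r)) NA_character_ else paste(r, collapse = "")
  })
  lut <- vapply(HAPLOGROUP_PATTERNS, paste, "", collapse = "")
  label <- names(lut)[match(key, lut)]
  label[is.na(label) & !is.na(key)] <- "OTHER"
  label[is.na(key)] <- "UNKNOWN"
  data.frame(
    subject_id = cohort$subject_id,
    haplogroup = label,
    matched_pattern = ifelse(is.na(key), "", key),
    stringsAsFactors = FALSE
  )
}

#' Haplogroup frequency table by case-control status
#'
#' Counts and percentages of H, J, K, U and OTHER calls per status column.
#' Subjects whose call is `UNKNOWN` (any missing marker) are excluded from
#' the denominators, so each status column's percentages sum to 100.
#'
#' @param cohort a `mitosyn_cohort`.
#' @param sex optional `"F"` or `"M"` to restrict to one sex stratum
#'   (subjects with missing sex belong to neither).
#' @return Data frame with columns `haplogroup`, `n_case`, `pct_case`,
#'   `n_control`, `pct_control`.
#' @export
haplogroup_frequencies <- function(cohort, sex = NULL) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("F", "M"))
    cohort <- cohort[!is.na(cohort$sex) & cohort$sex == sex, ]
  }
  if (nrow(cohort) == 0L) {
    abort_data("empty stratum: no subjects after sex filtering")
  }
  calls <- call_haplogroups(cohort)
  keep <- calls$haplogroup != "UNKNOWN"
  status <- cohort$status[keep]
  hg <- factor(calls$haplogroup[keep], levels = HAPLOGROUP_LABELS)
  n_case <- as.integer(table(hg[status == "case"]))
  n_ctrl <- as.integer(table(hg[status == "control"]))
  pct <- function(n) if (sum(n) == 0L) rep(NA_real_, length(n)) else 100 * n / sum(n)
  data.frame(
    haplogroup = HAPLOGROUP_LABELS,
    n_case = n_case,
    pct_case = pct(n_case),
    n_control = n_ctrl,
    pct_control = pct(n_ctrl),
    stringsAsFactors = FALSE
  )
}
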