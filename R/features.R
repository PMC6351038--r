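# Carriership features: the exposures whose case-control distribution is
# tested. Three kinds, all dominant-style codings of a genetic factor:
#   HAPLOGROUP       subject's mtDNA call equals a haplogroup label
#   ALLELE_CARRIER   subject has >= 1 copy of an allele at a nuclear locus
#   GENOTYPE_CARRIER subject has exactly a given unordered genotype

new_feature <- function(kind, locus, value) {
  structure(
    list(kind = kind, locus = locus, value = value),
    class = "mitosyn_feature"
  )
}

#' Feature constructors
#'
#' Define a carriership feature for association testing. `feature_haplogroup`
#' marks carriers of a mitochondrial haplogroup; `feature_allele` uses
#' dominant coding (carrier = at least one copy of `allele`);
#' `feature_genotype` requires an exact unordered genotype match.
#'
#' @param label haplogroup label: `"H"`, `"J"`, `"K"` or `"U"` (or
#'   `"OTHER"`).
#' @param locus nuclear locus rsID, e.g. `"rs2107538"`.
#' @param allele allele symbol, e.g. `"A"`.
#' @param genotype unordered genotype string, e.g. `"A/A"`.
#' @return A `mitosyn_feature` object.
#' @examples
#' feature_haplogroup("J")
#' feature_allele("rs2107538", "A")
#' feature_genotype("rs1640923", "A/A")
#' @name features
NULL

#' @rdname features
#' @export
feature_haplogroup <- function(label) {
  label <- toupper(label)
  if (!(label %in% HAPLOGROUP_LABELS)) {
    abort_config(paste0("unknown haplogroup label '", label, "'"))
  }
  new_feature("HAPLOGROUP", "mtDNA", label)
}

#' @rdname features
#' @export
feature_allele <- function(locus, allele) {
  if (!nzchar(locus) || !nzchar(allele) || grepl("/", allele, fixed = TRUE)) {
    abort_config("feature_allele() needs a locus and a single allele symbol")
  }
  new_feature("ALLELE_CARRIER", locus, allele)
}

#' @rdname features
#' @export
feature_genotype <- function(locus, genotype) {
  new_feature("GENOTYPE_CARRIER", locus, normalize_genotype(genotype))
}

#' Parse a feature from compact text syntax
#'
#' Accepts `"hg:J"` (haplogroup), `"rs2107538:A"` (allele carriage) and
#' `"rs1640923:A/A"` (exact genotype).
#'
#' @param text one feature specification string.
#' @return A `mitosyn_feature`.
#' @export
parse_feature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    abort_config(paste0(
      "cannot parse feature '", text,
      "' (expected 'hg:J', 'rsID:allele' or 'rsID:X/Y')"
    ))
  }
  if (tolower(parts[1]) == "hg") {
    feature_haplogroup(parts[2])
  } else if (grepl("/", parts[2], fixed = TRUE)) {
    feature_genotype(parts[1], parts[2])
  } else {
    feature_allele(parts[1], parts[2])
  }
}

#' @export
format.mitosyn_feature <- function(x, ...) {
  switch(x$kind,
    HAPLOGROUP = paste0("hg:", x$value),
    paste0(x$locus, "*", x$value)
  )
}

#' @export
print.mitosyn_feature <- function(x, ...) {
  cat("<feature>", format(x), paste0("(", x$kind, ")"), "\n")
  invisible(x)
}

as_feature_list <- function(features) {
  if (inherits(features, "mitosyn_feature")) return(list(features))
  if (is.character(features)) return(lapply(features, parse_feature))
  if (is.list(features)) {
    features <- lapply(features, function(f) {
      if (inherits(f, "mitosyn_feature")) f else parse_feature(f)
    })
    return(features)
  }
  abort_config("features must be mitosyn_feature objects or 'locus:value' strings")
}

#' Carrier status of each subject for a feature
#'
#' @param cohort a `mitosyn_cohort`.
#' @param feature a `mitosyn_feature` (or its text syntax, see
#'   [parse_feature()]).
#' @param calls optional precomputed [call_haplogroups()] table (recomputed
#'   when omitted and needed).
#' @return Character vector over subjects: `"CARRIER"`, `"NONCARRIER"`, or
#'   `NA` where the underlying genotype or haplogroup call is missing.
#' @export
carrier_status <- function(cohort, feature, calls = NULL) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  feature <- as_feature_list(feature)[[1]]
  if (feature$kind == "HAPLOGROUP") {
    if (is.null(calls)) calls <- call_haplogroups(cohort)
    out <- ifelse(calls$haplogroup == feature$value, "CARRIER", "NONCARRIER")
    out[calls$haplogroup == "UNKNOWN"] <- NA_character_
    return(out)
  }
  if (!(feature$locus %in% cohort_loci(cohort))) {
    abort_feature(paste0(
      "locus ", feature$locus, " is not in the cohort's registry"
    ))
  }
  gt <- cohort[[feature$locus]]
  if (feature$kind == "ALLELE_CARRIER") {
    carrier <- vapply(
      strsplit(gt, "/", fixed = TRUE),
      function(p) feature$value %in% p, NA
    )
  } else {
    carrier <- gt == feature$value
  }
  out <- ifelse(carrier, "CARRIER", "NONCARRIER")
  out[is.na(gt)] <- NA_character_
  out
}

# Joint carriership across several features: CARRIER iff carrier of ALL
# components, NA if any component is missing (complete-case).
joint_carrier_status <- function(cohort, features, calls = NULL) {
  features <- as_feature_list(features)
  mats <- lapply(features, carrier_status, cohort = cohort, calls = calls)
  out <- rep("CARRIER", nrow(cohort))
  for (s in mats) {
    out[!is.na(out) & !is.na(s) & s == "NONCARRIER"] <- "NONCARRIER"
    out[is.na(s)] <- NA_character_
  }
  out
}

feature_label <- function(features) {
  features <- as_feature_list(features)
  paste(vapply(features, format, ""), collapse = " + ")
}
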