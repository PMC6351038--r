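# Cohort data model and genotype TSV I/O.
#
# A cohort is a data.frame (class "mitosyn_cohort") with one row per subject:
#   subject_id  character, unique
#   status      "case" | "control"
#   sex         "F" | "M" | NA
#   mt_1719 ... mt_12308   single bases (A/C/G/T) or NA, haploid mtDNA markers
#   <rsID> ...  nuclear genotypes as normalized unordered "X/Y" strings or NA
# The attribute "loci" records the nuclear locus registry in column order.

MT_COLUMNS <- c("mt_1719", "mt_7028", "mt_9055", "mt_10398", "mt_12308")
MANDATORY_COLUMNS <- c("subject_id", "status", "sex", MT_COLUMNS)
MISSING_TOKEN <- "."
NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a cohort from a data frame
#'
#' Validates and normalizes a data frame of subject records into a cohort.
#' Every column that is not one of the mandatory columns (`subject_id`,
#' `status`, `sex`, `mt_1719`, `mt_7028`, `mt_9055`, `mt_10398`, `mt_12308`)
#' is treated as a nuclear locus named by its rsID and holding unordered
#' `"X/Y"` genotypes.
#'
#' @param df data frame with the mandatory columns and zero or more nuclear
#'   genotype columns. Missing values may be given as `NA` or `"."`.
#' @param strict if `TRUE`, malformed allele or genotype tokens raise a parse
#'   error naming the row and column; if `FALSE` (default) they become `NA`.
#' @return A `mitosyn_cohort` data frame.
#' @export
as_cohort <- function(df, strict = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  loci <- setdiff(names(df), MANDATORY_COLUMNS)
  df <- df[, c(MANDATORY_COLUMNS, loci), drop = FALSE]

  df$subject_id <- as.character(df$subject_id)
  if (anyNA(df$subject_id) || any(df$subject_id == "")) {
    abort_integrity("subject_id may not be missing")
  }
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    abort_integrity(paste0(
      "duplicate subject_id: ", paste(dup, collapse = ", ")
    ))
  }

  status <- tolower(as.character(df$status))
  bad <- is.na(status) | !(status %in% c("case", "control"))
  if (any(bad)) {
    abort_integrity(paste0(
      "status must be 'case' or 'control' (row ", which(bad)[1], ")"
    ))
  }
  df$status <- status

  df$sex <- parse_tokens(
    toupper(as.character(df$sex)), c("F", "M"), "sex", strict
  )
  for (col in MT_COLUMNS) {
    df[[col]] <- parse_tokens(
      toupper(as.character(df[[col]])), NUCLEOTIDES, col, strict
    )
  }
  for (col in loci) {
    df[[col]] <- parse_genotypes(as.character(df[[col]]), col, strict)
  }

  rownames(df) <- NULL
  structure(df, loci = loci, class = c("mitosyn_cohort", "data.frame"))
}

# Map a character vector onto a fixed token set; "." and NA become NA,
# anything else is NA (lenient) or a parse error (strict).
parse_tokens <- function(x, valid, col, strict) {
  x[!is.na(x) & x == MISSING_TOKEN] <- NA_character_
  bad <- !is.na(x) & !(x %in% valid)
  if (any(bad)) {
    if (strict) {
      abort_parse(paste0(
        "unparseable token '", x[which(bad)[1]], "' in column ", col,
        ", row ", which(bad)[1]
      ))
    }
    x[bad] <- NA_character_
  }
  x
}

# Normalize "X/Y" genotype strings so that A/B and B/A compare equal.
parse_genotypes <- function(x, col, strict) {
  x[!is.na(x) & (x == MISSING_TOKEN | x == "")] <- NA_character_
  parts <- strsplit(x, "/", fixed = TRUE)
  bad <- !is.na(x) & vapply(parts, length, 0L) != 2L
  if (any(bad)) {
    if (strict) {
      abort_parse(paste0(
        "unparseable genotype '", x[which(bad)[1]], "' in column ", col,
        ", row ", which(bad)[1]
      ))
    }
    x[bad] <- NA_character_
    parts[bad] <- list(NULL)
  }
  norm <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == "")) NA_character_
    else paste(sort(p), collapse = "/")
  }, "")
  norm[is.na(x)] <- NA_character_
  norm
}

normalize_genotype <- function(g) {
  p <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(p) != 2L || any(p == "")) {
    abort_config(paste0("genotype must be 'X/Y': '", g, "'"))
  }
  paste(sort(p), collapse = "/")
}

#' Read a genotype TSV into a cohort
#'
#' The format is UTF-8, tab-separated, with a header row. Mandatory columns:
#' `subject_id`, `status` (`case`|`control`), `sex` (`F`|`M`|`.`), and the
#' five mtDNA marker columns `mt_1719`, `mt_7028`, `mt_9055`, `mt_10398`,
#' `mt_12308` holding a single base or `.`. Any further column is a nuclear
#' locus named by rsID with `X/Y` unordered genotypes or `.`. Column order is
#' irrelevant.
#'
#' @param file path or connection to the TSV.
#' @inheritParams as_cohort
#' @return A `mitosyn_cohort` data frame; see [as_cohort()].
#' @examples
#' tsv <- paste(
#'   "subject_id\tstatus\tsex\tmt_1719\tmt_7028\tmt_9055\tmt_10398\tmt_12308\trs2107538",
#'   "S1\tcase\tF\tG\tT\tG\tG\tA\tC/A",
#'   sep = "\n"
#' )
#' cohort <- read_cohort(textConnection(tsv))
#' @export
read_cohort <- function(file, strict = FALSE) {
  df <- utils::read.delim(
    file,
    sep = "\t", header = TRUE, colClasses = "character",
    check.names = FALSE, na.strings = NULL, quote = "",
    comment.char = "", stringsAsFactors = FALSE
  )
  as_cohort(df, strict = strict)
}

#' Write a cohort back to genotype TSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x` exactly (allele tokens, statuses, missingness as `.`).
#'
#' @param cohort a `mitosyn_cohort`.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  stopifnot(inherits(cohort, "mitosyn_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    v <- out[[col]]
    v[is.na(v)] <- MISSING_TOKEN
    out[[col]] <- v
  }
  utils::write.table(
    out, file,
    sep = "\t", quote = FALSE, row.names = FALSE, na = MISSING_TOKEN
  )
  invisible(file)
}

#' Nuclear locus registry of a cohort
#' @param cohort a `mitosyn_cohort`.
#' @return Character vector of rsIDs in column order.
#' @export
cohort_loci <- function(cohort) attr(cohort, "loci")

#' @export
print.mitosyn_cohort <- function(x, ...) {
  cat(sprintf(
    "<mitosyn_cohort> %d subjects (%d case, %d control), %d nuclear loci\n",
    nrow(x), sum(x$status == "case"), sum(x$status == "control"),
    length(attr(x, "loci"))
  ))
  NextMethod()
}

# Subsetting keeps the class and the locus registry.
#' @export
`[.mitosyn_cohort` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(MANDATORY_COLUMNS %in% names(out))) {
    structure(
      out,
      loci = intersect(attr(x, "loci"), names(out)),
      class = c("mitosyn_cohort", "data.frame")
    )
  } else {
    out
  }
}

#' Write a table of results as TSV
#'
#' Writes any result data frame (association, mining or epistasis output)
#' with a stable column order and floats rendered at a configurable number of
#' significant digits.
#'
#' @param rows data frame of results sharing one schema.
#' @param file path or connection.
#' @param digits significant digits for numeric columns (default 4).
#' @return `file`, invisibly.
#' @export
write_results <- function(rows, file, digits = 4) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- signif(out[[col]], digits)
    }
  }
  utils::write.table(
    out, file,
    sep = "\t", quote = FALSE, row.names = FALSE, na = MISSING_TOKEN
  )
  invisible(file)
}
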