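# End-to-end orchestration: read -> call haplogroups -> associate -> mine
# combinations -> epistasis on every order-2 combination, with a plain-text
# run log. Deterministic: identical config and input give byte-identical
# result TSVs (timestamps only enter the log).

#' Run the full mito-nuclear analysis pipeline
#'
#' Stages: read the cohort, call haplogroups, per-feature association,
#' exhaustive combination mining up to `max_order`, then synergy-factor and
#' FLINT epistasis assessment of every order-2 pair. Each stage's output is
#' written as TSV under `out_dir` when given, and returned.
#'
#' @param input a `mitosyn_cohort` or a path to a genotype TSV.
#' @param features candidate features (objects or `"locus:value"` strings,
#'   e.g. `c("hg:J", "rs2107538:A")`).
#' @param max_order largest combination order mined (default 2).
#' @param alpha significance threshold for flags and classification.
#' @param small_cell_threshold +0.5 correction threshold for the synergy
#'   factor (default 5).
#' @param adjust multiple-testing adjustment for mining: `"none"` or
#'   `"bh"`.
#' @param by_sex also emit sex-stratified association tables.
#' @param n_perm permutations for empirical validation of mined order-2
#'   combinations; 0 (default) disables.
#' @param seed seed for the permutation stage.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `cohort`, `calls`, `frequencies`,
#'   `associations` (plus `associations_female` / `associations_male` when
#'   `by_sex`), `combinations`, `epistasis`, `log` (character vector).
#' @examples
#' res <- run_pipeline(study_fixture("CCL5"), c("hg:J", "rs2107538:A"))
#' res$epistasis$classification
#' @export
run_pipeline <- function(input, features, max_order = 2, alpha = 0.05,
                         small_cell_threshold = 5,
                         adjust = c("none", "bh"), by_sex = FALSE,
                         n_perm = 0, seed = 1, out_dir = NULL) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must be in (0, 1)")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, mitosyn_error = function(e) {
      e$message <- paste0("[stage ", name, "] ", conditionMessage(e))
      stop(e)
    })
  }

  note("mitosyn run, package version ",
       as.character(utils::packageVersion("mitosyn")))
  note("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  note("config: max_order=", max_order, " alpha=", alpha,
       " small_cell_threshold=", small_cell_threshold,
       " adjust=", adjust, " by_sex=", by_sex,
       " n_perm=", n_perm, " seed=", seed)

  cohort <- stage("read", {
    x <- if (inherits(input, "mitosyn_cohort")) input else read_cohort(input)
    if (nrow(x) == 0L) abort_data("empty cohort")
    x
  })
  note("cohort: ", nrow(cohort), " subjects (",
       sum(cohort$status == "case"), " case, ",
       sum(cohort$status == "control"), " control), ",
       length(cohort_loci(cohort)), " nuclear loci")

  features <- stage("features", as_feature_list(features))
  calls <- stage("call", call_haplogroups(cohort))
  note("haplogroup calls: ",
       paste(names(table(calls$haplogroup)), table(calls$haplogroup),
             sep = "=", collapse = " "))
  freqs <- stage("call", haplogroup_frequencies(cohort))

  assoc <- stage("assoc", associate(cohort, features))
  for (i in seq_along(features)) {
    n_missing <- nrow(cohort) -
      (assoc$n_case_total[i] + assoc$n_control_total[i])
    note("feature ", assoc$feature[i], ": ", n_missing,
         " subject(s) excluded as non-informative")
  }
  res <- list(
    cohort = cohort, calls = calls, frequencies = freqs,
    associations = assoc
  )

  if (by_sex) {
    strata <- stage("assoc", stratify_by_sex(cohort))
    note("sex strata: female ", nrow(strata$female),
         ", male ", nrow(strata$male), ", excluded ",
         nrow(cohort) - nrow(strata$female) - nrow(strata$male))
    res$associations_female <- stage(
      "assoc", associate(strata$female, features)
    )
    res$associations_male <- stage(
      "assoc", associate(strata$male, features)
    )
  }

  mined <- stage("mine", enumerate_combinations(
    cohort, features,
    max_order = max_order, alpha = alpha, adjust = adjust
  ))
  note("mining: ", nrow(mined), " combination(s) scored, ",
       sum(mined$significant), " significant at alpha=", alpha)
  res$combinations <- mined

  # Assess epistasis for every distinct-locus pair that mining scored.
  pair_idx <- Filter(
    function(ij) {
      feature_label(features[ij]) %in%
        mined$combination[mined$order == 2L]
    },
    if (length(features) >= 2L) combn_list(length(features), 2L) else list()
  )
  epi <- NULL
  if (length(pair_idx) > 0) {
    epi <- do.call(rbind, lapply(pair_idx, function(ij) {
      fs <- features[ij]
      lab <- feature_label(fs)
      t <- stage("epistasis", build_2x2x2(cohort, fs[[1]], fs[[2]], calls))
      sf_res <- stage("epistasis", synergy_factor(
        t, small_cell_threshold = small_cell_threshold
      ))
      fl <- stage("epistasis", flint_exact(t))
      row <- data.frame(
        pair = lab,
        n11_case = t$case[["n11"]], n10_case = t$case[["n10"]],
        n01_case = t$case[["n01"]], n00_case = t$case[["n00"]],
        n11_control = t$control[["n11"]], n10_control = t$control[["n10"]],
        n01_control = t$control[["n01"]], n00_control = t$control[["n00"]],
        sf = sf_res$sf, sf_ci_low = sf_res$ci_low,
        sf_ci_high = sf_res$ci_high,
        correction_applied = sf_res$correction_applied,
        p_flint = fl$p_flint, p_synergy = fl$p_synergy,
        classification = classify_interaction(sf_res, fl, alpha = alpha),
        stringsAsFactors = FALSE
      )
      if (n_perm > 0) {
        row$p_permutation <- stage("mine", permutation_validate(
          cohort, fs, n_perm = n_perm, seed = seed
        ))$p_empirical
      }
      row
    }))
    note("epistasis: ", nrow(epi), " pair(s); ",
         sum(epi$classification == "EPISTATIC"), " EPISTATIC, ",
         sum(epi$classification == "SUGGESTIVE"), " SUGGESTIVE")
  } else {
    note("epistasis: no order-2 combinations to assess")
  }
  res$epistasis <- epi

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_results(calls, p("haplogroup_calls.tsv"))
    write_results(freqs, p("haplogroup_frequencies.tsv"))
    write_results(assoc, p("associations.tsv"))
    if (by_sex) {
      write_results(res$associations_female, p("associations_female.tsv"))
      write_results(res$associations_male, p("associations_male.tsv"))
    }
    write_results(mined, p("combinations.tsv"))
    if (!is.null(epi)) write_results(epi, p("epistasis.tsv"))
    writeLines(log_lines, p("run_log.txt"))
    note("outputs written to ", out_dir)
  }
  res$log <- log_lines
  invisible(res)
}
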