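# Study orchestration: dataset -> one simulation run per cumulative
# examination combination -> cutoff calibration -> pattern differentiation
# -> outcome classification -> similarity/outcome cross-tables and gamma
# analysis.

outcome_levels <- function() c("correct diagnosis", "misdiagnosis", "undiagnosis")

#' Classify a differentiation outcome against the truth label
#'
#' For a case of pattern `K`: identifying `K` is a correct diagnosis,
#' identifying any other pattern is a misdiagnosis, identifying none is an
#' undiagnosis. For a control simulated against `K` (the profile actually
#' came from a donor pattern): identifying any pattern other than `K` is
#' correct, identifying `K` is a misdiagnosis, identifying none is an
#' undiagnosis. Missing profiles are classified `"missing"`.
#'
#' @param truth_class Character vector, `"case"` or `"control"`.
#' @param source_pattern Character vector of truth-label pattern names.
#' @param identified Character vector of identified pattern names (`NA` when
#'   none).
#' @param status Character vector: `"identified"`, `"undiagnosed"` or
#'   `"missing"`.
#' @return Factor with levels correct diagnosis < misdiagnosis <
#'   undiagnosis (< missing, excluded from ordinal analyses).
#' @export
classify_outcome <- function(truth_class, source_pattern, identified, status) {
  n <- length(truth_class)
  stopifnot(length(source_pattern) == n, length(identified) == n,
            length(status) == n)
  out <- character(n)
  is_missing <- status == "missing"
  none <- status == "undiagnosed"
  hit <- !is_missing & !none & identified == source_pattern
  case <- truth_class == "case"
  out[is_missing] <- "missing"
  out[!is_missing & none] <- "undiagnosis"
  out[!is_missing & !none & case & hit] <- "correct diagnosis"
  out[!is_missing & !none & case & !hit] <- "misdiagnosis"
  out[!is_missing & !none & !case & !hit] <- "correct diagnosis"
  out[!is_missing & !none & !case & hit] <- "misdiagnosis"
  factor(out, levels = c(outcome_levels(), "missing"), ordered = TRUE)
}

#' Study configuration
#'
#' Bundles every parameter of a full simulation study. The defaults are the
#' published design: the four cumulative combinations, 100 cases and 100
#' controls per pattern per combination (58,400 profiles for 73 patterns),
#' cutoffs estimated by calibration simulation, literal PDA ranking.
#'
#' @param dataset A `pattern_dataset`, or `NULL` to generate one from
#'   `generator`.
#' @param generator A [generator_config()] used when `dataset` is `NULL`
#'   (its seed is re-derived from `seed`).
#' @param combos Named list of examination combinations in ordinal order
#'   (default [canonical_combos()]).
#' @param n_cases,n_controls Profiles per pattern per combination.
#' @param cutoffs Named numeric vector of cutoffs (percent) per combination
#'   label, or `NULL` to estimate each by calibration.
#' @param calib_n_cases,calib_n_controls Calibration run sizes per pattern.
#' @param cutoff_grid Candidate cutoffs for calibration.
#' @param mode PDA ranking mode, `"literal"` or `"absdev"`.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(dataset = NULL, generator = generator_config(),
                         combos = canonical_combos(), n_cases = 100L,
                         n_controls = 100L, cutoffs = NULL,
                         calib_n_cases = 100L, calib_n_controls = 100L,
                         cutoff_grid = seq(0, 100, by = 0.5),
                         mode = c("literal", "absdev"), seed = 1L) {
  mode <- match.arg(mode)
  combos <- lapply(combos, exam_combo)
  names(combos) <- vapply(combos, combo_label, character(1L))
  if (!is.null(cutoffs) && !all(names(combos) %in% names(cutoffs))) {
    stop("cutoffs must be named after every combination label", call. = FALSE)
  }
  structure(list(dataset = dataset, generator = generator, combos = combos,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), cutoffs = cutoffs,
                 calib_n_cases = as.integer(calib_n_cases),
                 calib_n_controls = as.integer(calib_n_controls),
                 cutoff_grid = cutoff_grid, mode = mode,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full simulation study
#'
#' Executes the complete design: for every configured examination
#' combination, simulate cases and controls, calibrate (or take) the
#' available-information cutoff, differentiate every non-missing profile,
#' and classify outcomes. The report collects, per combination, the outcome
#' frequency tables for cases and controls (with the Missing column), the
#' dual-pattern similarity category histogram (a dataset-level property),
#' the outcome-by-S*-category cross-table for cases only, and the gamma
#' statistics: similarity category vs combination, outcome vs combination
#' (cases and controls separately), and outcome vs S* category per
#' combination.
#'
#' @param config A [study_config()].
#' @return List of class `study_report`; see Details. All seeds, cutoffs and
#'   resolved parameters are included.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  seed <- config$seed
  d <- config$dataset
  if (is.null(d)) {
    d <- generate_dataset(config$generator, seed = derive_seed(seed, "dataset"))
  }
  combos <- config$combos
  labs <- names(combos)
  sim_cats <- similarity_categories()
  # Table 1 analogue: dual-pattern similarity category per combination
  table1 <- matrix(0L, nrow = length(labs), ncol = length(sim_cats),
                   dimnames = list(labs, sim_cats))
  for (lab in labs) {
    sm <- dual_similarity_matrix(d, combos[[lab]])
    cat_tab <- table(similarity_category(sm$s[!is.na(sm$s)]))
    table1[lab, ] <- as.integer(cat_tab[sim_cats])
  }
  cutoffs <- numeric(0)
  outcome_tabs <- list(case = NULL, control = NULL)
  table3 <- list()
  s_star_gammas <- list()
  case_records <- list()
  control_records <- list()
  per_combo <- list()
  for (lab in labs) {
    combo <- combos[[lab]]
    cutoff <- if (!is.null(config$cutoffs)) {
      config$cutoffs[[lab]]
    } else {
      estimate_cutoff(d, combo, config$calib_n_cases, config$calib_n_controls,
                      seed = derive_seed(seed, lab, "calib"),
                      grid = config$cutoff_grid, mode = config$mode)$cutoff
    }
    cutoffs[[lab]] <- cutoff
    profiles <- simulate_run(d, combo, config$n_cases, config$n_controls,
                             seed = derive_seed(seed, lab, "run"))
    profiles <- differentiate_profiles(profiles, d, combo, cutoff, config$mode)
    profiles$outcome <- classify_outcome(profiles$truth_class,
                                         profiles$pattern,
                                         profiles$identified,
                                         profiles$status)
    ss <- pattern_dataset_similarity(d, combo)
    ss$category <- similarity_category(ss$s_star)
    profiles$s_star_category <- ss$category[match(profiles$pattern, ss$pattern)]
    for (cls in c("case", "control")) {
      sub <- profiles[profiles$truth_class == cls, , drop = FALSE]
      counts <- table(factor(as.character(sub$outcome),
                             levels = c(outcome_levels(), "missing")))
      row <- matrix(as.integer(counts), nrow = 1L,
                    dimnames = list(lab, names(counts)))
      outcome_tabs[[cls]] <- rbind(outcome_tabs[[cls]], row)
    }
    cases <- profiles[profiles$truth_class == "case" & !profiles$missing, ,
                      drop = FALSE]
    t3 <- build_crosstable(
      data.frame(outcome = as.character(cases$outcome),
                 s_star = as.character(cases$s_star_category),
                 stringsAsFactors = FALSE),
      "outcome", "s_star", outcome_levels(), sim_cats)
    table3[[lab]] <- t3
    s_star_gammas[[lab]] <- tryCatch(goodman_kruskal_gamma(t3),
                                     error = function(e) NULL)
    case_records[[lab]] <- data.frame(
      combo = lab,
      outcome = as.character(cases$outcome), stringsAsFactors = FALSE)
    controls <- profiles[profiles$truth_class == "control" & !profiles$missing, ,
                         drop = FALSE]
    control_records[[lab]] <- data.frame(
      combo = lab,
      outcome = as.character(controls$outcome), stringsAsFactors = FALSE)
    per_combo[[lab]] <- profiles
  }
  case_tab <- build_crosstable(do.call(rbind, case_records), "combo",
                               "outcome", labs, outcome_levels())
  control_tab <- build_crosstable(do.call(rbind, control_records), "combo",
                                  "outcome", labs, outcome_levels())
  gammas <- list(
    similarity_vs_combo = tryCatch(goodman_kruskal_gamma(table1),
                                   error = function(e) NULL),
    outcome_vs_combo_cases = tryCatch(goodman_kruskal_gamma(case_tab),
                                      error = function(e) NULL),
    outcome_vs_combo_controls = tryCatch(goodman_kruskal_gamma(control_tab),
                                         error = function(e) NULL),
    outcome_vs_s_star = s_star_gammas)
  structure(list(dataset = d, table1 = table1,
                 outcomes_cases = outcome_tabs$case,
                 outcomes_controls = outcome_tabs$control,
                 table3 = table3, gammas = gammas, cutoffs = cutoffs,
                 profiles = per_combo, config = config, seed = seed,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(pattern_names(x$dataset)), " patterns, ",
      sum(x$outcomes_cases) + sum(x$outcomes_controls), " profiles, seed ",
      x$seed, "\n", sep = "")
  cat("cutoffs:", paste(names(x$cutoffs), round(x$cutoffs, 1), sep = "=",
                        collapse = ", "), "\n")
  cat("\nCase outcomes by combination:\n")
  print(x$outcomes_cases)
  cat("\nControl outcomes by combination:\n")
  print(x$outcomes_controls)
  g <- x$gammas$outcome_vs_combo_cases
  if (!is.null(g)) {
    cat("\nOutcome vs combination (cases): gamma =", round(g$gamma, 3), "\n")
  }
  invisible(x)
}

#' Write study report artifacts to a directory
#'
#' Persists the report as plain-text files: the dataset (TSV), every
#' cross-table (TSV), and a JSON file with cutoffs, gamma statistics, seeds
#' and configuration, so a run is fully documented by its outputs. Existing
#' files are not silently overwritten.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param overwrite Allow overwriting existing files (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, overwrite = FALSE) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tab <- function(m, path) {
    if (file.exists(path) && !overwrite) {
      stop("refusing to overwrite ", path, call. = FALSE)
    }
    utils::write.table(data.frame(category = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_pattern_dataset(report$dataset, file.path(dir, "dataset.tsv"))
  write_tab(report$table1, file.path(dir, "similarity_by_combo.tsv"))
  write_tab(report$outcomes_cases, file.path(dir, "outcomes_cases.tsv"))
  write_tab(report$outcomes_controls, file.path(dir, "outcomes_controls.tsv"))
  for (lab in names(report$table3)) {
    write_tab(report$table3[[lab]],
              file.path(dir, paste0("outcome_by_s_star_",
                                    gsub("\\+", "_", lab), ".tsv")))
  }
  gamma_json <- lapply(report$gammas, function(g) {
    if (is.null(g)) return(NULL)
    if (inherits(g, "gamma_result")) {
      unclass(g)
    } else {
      lapply(g, function(gg) if (is.null(gg)) NULL else unclass(gg))
    }
  })
  jsonlite::write_json(list(seed = report$seed, cutoffs = as.list(report$cutoffs),
                            elapsed_seconds = report$elapsed,
                            gammas = gamma_json),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
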