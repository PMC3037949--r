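# Manifestation profile simulation: true-positive cases drawn from a
# pattern's own restricted term set, true-negative controls drawn from a
# pseudo-randomly chosen donor pattern, plus the dataset-reconstruction
# quality check.

empty_profile_frame <- function() {
  data.frame(pattern = character(0), truth_class = character(0),
             combo = character(0), donor = character(0),
             n_r = integer(0), missing = logical(0),
             terms = I(list()), stringsAsFactors = FALSE)
}

profile_row <- function(pattern, truth_class, combo, donor, terms) {
  data.frame(pattern = pattern, truth_class = truth_class,
             combo = combo_label(combo), donor = donor,
             n_r = length(terms), missing = length(terms) == 0L,
             terms = I(list(terms)), stringsAsFactors = FALSE)
}

draw_profile_terms <- function(terms) {
  n_t <- length(terms)
  n_r <- sample.int(n_t, 1L)
  terms[sample.int(n_t, n_r)]
}

#' Simulate one true-positive case profile
#'
#' A case for pattern `K` is built by drawing a pseudo-random quantity
#' `N_R` uniformly on the integers `[1, N_T]` (with `N_T` the pattern's
#' manifestation count under the examination combination) and then sampling
#' `N_R` distinct manifestations without replacement from the pattern's
#' restricted term set. A pattern with no manifestations under the
#' combination yields a missing (empty) profile, excluded from downstream
#' analysis. Uses the current RNG stream; see [simulate_run()] for the
#' seeded batch interface.
#'
#' @param d A `pattern_dataset`.
#' @param pattern Source pattern name.
#' @param combo Examination combination.
#' @return One-row data frame with columns `pattern`, `truth_class`,
#'   `combo`, `donor` (`NA` for cases), `n_r`, `missing`, and list-column
#'   `terms`.
#' @export
simulate_case <- function(d, pattern, combo = exam_methods()) {
  combo <- exam_combo(combo)
  terms <- pattern_terms(d, pattern, combo)
  drawn <- if (length(terms) == 0L) character(0) else draw_profile_terms(terms)
  profile_row(pattern, "case", combo, NA_character_, drawn)
}

#' Simulate one true-negative control profile
#'
#' A control for pattern `K` is a profile drawn from another pattern: a donor
#' is chosen uniformly among the patterns other than `K` that have at least
#' one manifestation under the combination, a count is drawn uniformly on
#' `[1, N_T(donor)]`, and that many distinct manifestations are sampled
#' without replacement from the donor. Although `K` itself is excluded, its
#' manifestations that co-occur in other patterns can still appear. The
#' profile keeps `K` as its source pattern for outcome scoring.
#'
#' @inheritParams simulate_case
#' @return One-row data frame as in [simulate_case()], with `donor` set.
#' @export
simulate_control <- function(d, pattern, combo = exam_methods()) {
  combo <- exam_combo(combo)
  if (!pattern %in% pattern_names(d)) stop("unknown pattern: ", pattern, call. = FALSE)
  nt <- n_manifestations(d, combo)
  eligible <- setdiff(names(nt)[nt >= 1L], pattern)
  if (length(eligible) == 0L) {
    return(profile_row(pattern, "control", combo, NA_character_, character(0)))
  }
  donor <- sample_one(eligible)
  drawn <- draw_profile_terms(pattern_terms(d, donor, combo))
  profile_row(pattern, "control", combo, donor, drawn)
}

#' Simulate a full run of case and control profiles
#'
#' Generates `n_cases` true-positive and `n_controls` true-negative profiles
#' for every pattern in the dataset under one examination combination (the
#' study design uses 100 + 100 per pattern, i.e. 14,600 profiles per run for
#' 73 patterns). Missing profiles are included and flagged. Each pattern
#' draws from its own RNG stream seeded from `(seed, combo, pattern index)`,
#' so results do not depend on pattern iteration order and the whole run is
#' reproducible from the seed.
#'
#' @param d A `pattern_dataset`.
#' @param combo Examination combination.
#' @param n_cases,n_controls Profiles per pattern (non-negative).
#' @param seed Integer seed for the run.
#' @return Data frame of profiles (one row each) with columns as in
#'   [simulate_case()]; attributes `combo` and `seed` carry the run
#'   metadata.
#' @export
simulate_run <- function(d, combo = exam_methods(), n_cases = 100L,
                         n_controls = 100L, seed = 1L) {
  stopifnot(inherits(d, "pattern_dataset"), n_cases >= 0L, n_controls >= 0L)
  combo <- exam_combo(combo)
  pats <- pattern_names(d)
  nt <- n_manifestations(d, combo)
  term_sets <- lapply(pats, function(p) pattern_terms(d, p, combo))
  names(term_sets) <- pats
  lab <- combo_label(combo)
  rows <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    p <- pats[[k]]
    rows[[k]] <- with_seed(derive_seed(seed, lab, k), {
      terms <- term_sets[[p]]
      cases <- if (n_cases == 0L) NULL else {
        drawn <- if (length(terms) == 0L) {
          replicate(n_cases, character(0), simplify = FALSE)
        } else {
          replicate(n_cases, draw_profile_terms(terms), simplify = FALSE)
        }
        data.frame(pattern = p, truth_class = "case", combo = lab,
                   donor = NA_character_, n_r = lengths(drawn),
                   missing = lengths(drawn) == 0L, terms = I(drawn),
                   stringsAsFactors = FALSE)
      }
      controls <- if (n_controls == 0L) NULL else {
        eligible <- setdiff(names(nt)[nt >= 1L], p)
        if (length(eligible) == 0L) {
          drawn <- replicate(n_controls, character(0), simplify = FALSE)
          donors <- rep(NA_character_, n_controls)
        } else {
          donors <- eligible[sample.int(length(eligible), n_controls,
                                        replace = TRUE)]
          drawn <- lapply(donors, function(dn) draw_profile_terms(term_sets[[dn]]))
        }
        data.frame(pattern = p, truth_class = "control", combo = lab,
                   donor = donors, n_r = lengths(drawn),
                   missing = lengths(drawn) == 0L, terms = I(drawn),
                   stringsAsFactors = FALSE)
      }
      rbind(cases, controls)
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_profile_frame()
  rownames(out) <- NULL
  attr(out, "combo") <- lab
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Reverse-engineering consistency check
#'
#' Recreates the dataset from simulated true-positive cases: for each
#' pattern, the union of its case-profile terms is compared with its term
#' set restricted to the run's combination. A pattern is "completely
#' simulated" when every restricted manifestation appeared in at least one
#' case, "partially simulated" when only some did, and "not used" when no
#' case profile drew from it.
#'
#' @param profiles Profile data frame from [simulate_run()] (controls are
#'   ignored).
#' @param d The `pattern_dataset` the profiles were simulated from.
#' @param combo Examination combination of the run.
#' @return List with `per_pattern` (data frame: `pattern`, `status`,
#'   `n_terms`, `n_recovered`), `unused_terms` (per-pattern list of
#'   never-sampled terms), and logical `complete` (`TRUE` when every
#'   non-empty pattern is completely simulated).
#' @export
reverse_engineer_check <- function(profiles, d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  cases <- profiles[profiles$truth_class == "case", , drop = FALSE]
  unknown <- setdiff(unique(cases$pattern), pattern_names(d))
  if (length(unknown) > 0L) {
    stop("profile(s) reference unknown pattern(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  recovered <- lapply(split(cases$terms, factor(cases$pattern,
                                                levels = pattern_names(d))),
                      function(ts) unique(unlist(ts, use.names = FALSE)))
  per <- lapply(pattern_names(d), function(p) {
    full <- unique(pattern_terms(d, p, combo))
    rec <- recovered[[p]] %||% character(0)
    status <- if (length(rec) == 0L) "not used"
      else if (setequal(rec, full)) "completely simulated"
      else "partially simulated"
    list(row = data.frame(pattern = p, status = status,
                          n_terms = length(full), n_recovered = length(rec),
                          stringsAsFactors = FALSE),
         unused = setdiff(full, rec))
  })
  per_pattern <- do.call(rbind, lapply(per, `[[`, "row"))
  unused <- lapply(per, `[[`, "unused")
  names(unused) <- per_pattern$pattern
  nonempty <- per_pattern$n_terms > 0L
  list(per_pattern = per_pattern, unused_terms = unused,
       complete = all(per_pattern$status[nonempty] == "completely simulated"))
}
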