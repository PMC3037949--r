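# Pattern differentiation algorithm: candidate generation by exact term
# matching, dual-criterion scoring (explained information F% and available
# information N% minus cutoff), ranking, and identification or undiagnosis.

#' Explained-information score (F%)
#'
#' The percentage of a profile's manifestations explained by a candidate
#' pattern: `F% = 100 * N_E / N_P`, where `N_E` is the number of the
#' profile's terms the pattern contains and `N_P` the number of terms in
#' the profile.
#'
#' @param n_e Explained-manifestation count(s).
#' @param n_p Profile manifestation count (must be >= 1).
#' @return Numeric percentage(s).
#' @export
score_F <- function(n_e, n_p) {
  if (any(n_p < 1L)) stop("F% undefined for an empty profile (N_P = 0)", call. = FALSE)
  if (any(n_e < 0L | n_e > n_p)) stop("require 0 <= N_E <= N_P", call. = FALSE)
  100 * n_e / n_p
}

#' Available-information score (N% - cutoff)
#'
#' The percentage of a candidate pattern's manifestations present in the
#' profile, shifted by the calibration cutoff:
#' `N% - cutoff = 100 * N_E / N_T - cutoff`, where `N_T` is the pattern's
#' manifestation count under the examination combination.
#'
#' @param n_e Explained-manifestation count(s).
#' @param n_t Pattern manifestation count (must be >= 1).
#' @param cutoff Calibration cutoff, in percent.
#' @return Numeric score(s).
#' @export
score_N <- function(n_e, n_t, cutoff) {
  if (any(n_t < 1L)) stop("N% undefined for a pattern empty under the combination",
                          call. = FALSE)
  if (any(n_e < 0L | n_e > n_t)) stop("require 0 <= N_E <= N_T", call. = FALSE)
  100 * n_e / n_t - cutoff
}

# Exact-matching index: term -> integer vector of pattern indices, plus the
# per-pattern restricted sizes. Built once per (dataset, combo).
pda_index <- function(d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  pats <- pattern_names(d)
  term_sets <- lapply(pats, function(p) unique(pattern_terms(d, p, combo)))
  long_term <- unlist(term_sets, use.names = FALSE)
  long_pat <- rep(seq_along(pats), lengths(term_sets))
  index <- split(long_pat, long_term)
  list(patterns = pats, index = index, n_t = lengths(term_sets),
       combo = combo_label(combo))
}

#' Candidate patterns for a profile
#'
#' First PDA stage: by exact matching of normalized terms, every pattern
#' explaining at least one of the profile's manifestations becomes a
#' candidate with its explained count `N_E`; patterns recognizing no
#' manifestation are excluded. Profile terms absent from the whole dataset
#' count toward `N_P` but are explained by no pattern.
#'
#' @param terms Character vector of the profile's terms (non-empty; missing
#'   profiles must be filtered out by the caller).
#' @param d A `pattern_dataset`.
#' @param combo Examination combination.
#' @return Data frame with columns `pattern`, `n_e`, `n_t` (one row per
#'   candidate; zero rows when nothing matches).
#' @export
find_candidates <- function(terms, d, combo = exam_methods()) {
  if (length(terms) == 0L) {
    stop("cannot differentiate a missing (empty) profile", call. = FALSE)
  }
  idx <- pda_index(d, combo)
  hits <- tabulate(unlist(idx$index[unique(terms)], use.names = FALSE),
                   nbins = length(idx$patterns))
  keep <- which(hits > 0L)
  data.frame(pattern = idx$patterns[keep], n_e = hits[keep],
             n_t = idx$n_t[keep], stringsAsFactors = FALSE)
}

#' Rank candidates and identify a pattern
#'
#' Final PDA stages. Candidates are scored with [score_F()] and [score_N()]
#' and ranked in descending order of `F%` then ascending order of
#' `N% - cutoff`. In `mode = "literal"` (default) candidates whose available
#' information falls below the cutoff (`N% - cutoff < 0`) are removed from
#' the hypothesis list before ranking; in `mode = "absdev"` no candidate is
#' removed and the secondary key is `|N% - cutoff|` ascending. The process
#' identifies a pattern only if a single candidate holds the top-ranked
#' `(F%, N% - cutoff)` pair; a tie on that pair — or an empty hypothesis
#' list — is an undiagnosis.
#'
#' @param candidates Data frame from [find_candidates()] (columns `pattern`,
#'   `n_e`, `n_t`).
#' @param n_p Profile manifestation count.
#' @param cutoff Calibration cutoff, in percent.
#' @param mode `"literal"` or `"absdev"`; see Details.
#' @return List of class `differentiation_result`: `status` (`"identified"`
#'   or `"undiagnosed"`), `identified` (pattern name or `NA`), and `ranked`
#'   (data frame of surviving candidates with `f_pct` and `n_pct_cutoff`,
#'   in rank order).
#' @export
rank_and_identify <- function(candidates, n_p, cutoff,
                              mode = c("literal", "absdev")) {
  mode <- match.arg(mode)
  if (nrow(candidates) == 0L) {
    return(structure(list(status = "undiagnosed", identified = NA_character_,
                          ranked = data.frame(pattern = character(0),
                                              n_e = integer(0), n_t = integer(0),
                                              f_pct = numeric(0),
                                              n_pct_cutoff = numeric(0),
                                              stringsAsFactors = FALSE)),
                     class = "differentiation_result"))
  }
  f_pct <- score_F(candidates$n_e, n_p)
  n_pct_cutoff <- score_N(candidates$n_e, candidates$n_t, cutoff)
  ranked <- cbind(candidates, f_pct = f_pct, n_pct_cutoff = n_pct_cutoff)
  if (mode == "literal") {
    ranked <- ranked[ranked$n_pct_cutoff >= 0, , drop = FALSE]
    key2 <- ranked$n_pct_cutoff
  } else {
    key2 <- abs(ranked$n_pct_cutoff)
  }
  ord <- order(-ranked$f_pct, key2)
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  if (nrow(ranked) == 0L) {
    status <- "undiagnosed"
    identified <- NA_character_
  } else {
    key2 <- key2[ord]
    top_tied <- ranked$f_pct == ranked$f_pct[1L] & key2 == key2[1L]
    if (sum(top_tied) == 1L) {
      status <- "identified"
      identified <- ranked$pattern[1L]
    } else {
      status <- "undiagnosed"
      identified <- NA_character_
    }
  }
  structure(list(status = status, identified = identified, ranked = ranked),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat("<differentiation_result> status:", x$status,
      if (x$status == "identified") paste0("(", x$identified, ")") else "", "\n")
  if (nrow(x$ranked) > 0L) print(utils::head(x$ranked, 5L))
  invisible(x)
}

#' Differentiate one profile
#'
#' Convenience wrapper running all three PDA stages on a single profile.
#'
#' @inheritParams find_candidates
#' @inheritParams rank_and_identify
#' @return A `differentiation_result`; see [rank_and_identify()].
#' @export
differentiate <- function(terms, d, combo = exam_methods(), cutoff = 0,
                          mode = c("literal", "absdev")) {
  candidates <- find_candidates(terms, d, combo)
  rank_and_identify(candidates, length(unique(terms)), cutoff, mode)
}

# Fast path over a precomputed index; returns minimal per-profile fields.
differentiate_with_index <- function(terms, idx, cutoff, mode = "literal") {
  terms <- unique(terms)
  hits <- tabulate(unlist(idx$index[terms], use.names = FALSE),
                   nbins = length(idx$patterns))
  keep <- which(hits > 0L)
  if (length(keep) == 0L) {
    return(list(status = "undiagnosed", identified = NA_character_,
                top_f = NA_real_, top_n = NA_real_, n_candidates = 0L))
  }
  f_pct <- 100 * hits[keep] / length(terms)
  n_pct <- 100 * hits[keep] / idx$n_t[keep]
  npc <- n_pct - cutoff
  if (mode == "literal") {
    surv <- npc >= 0
    keep <- keep[surv]; f_pct <- f_pct[surv]; npc <- npc[surv]
    key2 <- npc
  } else {
    key2 <- abs(npc)
  }
  n_cand <- length(keep)
  if (n_cand == 0L) {
    return(list(status = "undiagnosed", identified = NA_character_,
                top_f = NA_real_, top_n = NA_real_, n_candidates = 0L))
  }
  best <- which(f_pct == max(f_pct))
  best <- best[key2[best] == min(key2[best])]
  if (length(best) == 1L) {
    list(status = "identified", identified = idx$patterns[keep[best]],
         top_f = f_pct[best], top_n = npc[best], n_candidates = n_cand)
  } else {
    list(status = "undiagnosed", identified = NA_character_,
         top_f = f_pct[best[1L]], top_n = npc[best[1L]], n_candidates = n_cand)
  }
}

#' Differentiate a batch of simulated profiles
#'
#' Applies PDA to every non-missing profile of a simulation run. Missing
#' profiles are carried through with `status = "missing"` and are never fed
#' to the algorithm.
#'
#' @param profiles Profile data frame from [simulate_run()].
#' @param d A `pattern_dataset`.
#' @param combo Examination combination (must match the run's).
#' @param cutoff Calibration cutoff, in percent.
#' @param mode PDA ranking mode; see [rank_and_identify()].
#' @return `profiles` with added columns `status`, `identified`, `top_f`,
#'   `top_n`, `n_candidates`.
#' @export
differentiate_profiles <- function(profiles, d, combo = exam_methods(),
                                   cutoff = 0, mode = c("literal", "absdev")) {
  mode <- match.arg(mode)
  combo <- exam_combo(combo)
  idx <- pda_index(d, combo)
  n <- nrow(profiles)
  status <- character(n); identified <- rep(NA_character_, n)
  top_f <- rep(NA_real_, n); top_n <- rep(NA_real_, n)
  n_cand <- integer(n)
  for (i in seq_len(n)) {
    if (profiles$missing[[i]]) {
      status[[i]] <- "missing"
      next
    }
    r <- differentiate_with_index(profiles$terms[[i]], idx, cutoff, mode)
    status[[i]] <- r$status; identified[[i]] <- r$identified
    top_f[[i]] <- r$top_f; top_n[[i]] <- r$top_n; n_cand[[i]] <- r$n_candidates
  }
  profiles$status <- status
  profiles$identified <- identified
  profiles$top_f <- top_f
  profiles$top_n <- top_n
  profiles$n_candidates <- n_cand
  profiles
}

#' Estimate the optimal cutoff for the available-information criterion
#'
#' Runs a dedicated calibration simulation (cases and controls, with its own
#' seed so evaluation runs see no leakage), evaluates the overall
#' correct-diagnosis rate — correct diagnoses over non-missing profiles,
#' cases and controls jointly — at every grid value, and returns the
#' accuracy-maximizing cutoff. Ties are broken toward the smallest cutoff.
#'
#' @param d A `pattern_dataset`.
#' @param combo Examination combination.
#' @param n_cases,n_controls Calibration profiles per pattern (default
#'   100 each, the study's run size).
#' @param seed Seed of the calibration simulation.
#' @param grid Candidate cutoffs in percent (default 0 to 100 by 0.5).
#' @param mode PDA ranking mode.
#' @return List of class `cutoff_estimate`: `cutoff`, `accuracy` (at the
#'   chosen cutoff), and `curve` (data frame `cutoff`, `accuracy` over the
#'   grid).
#' @export
estimate_cutoff <- function(d, combo = exam_methods(), n_cases = 100L,
                            n_controls = 100L, seed = 1L,
                            grid = seq(0, 100, by = 0.5),
                            mode = c("literal", "absdev")) {
  mode <- match.arg(mode)
  combo <- exam_combo(combo)
  if (length(grid) == 0L) stop("cutoff grid is empty", call. = FALSE)
  if (length(empty_patterns(d, combo)) == length(pattern_names(d))) {
    stop("degenerate dataset: every pattern is empty under the combination",
         call. = FALSE)
  }
  grid <- sort(grid)
  profiles <- simulate_run(d, combo, n_cases, n_controls, seed = seed)
  profiles <- profiles[!profiles$missing, , drop = FALSE]
  idx <- pda_index(d, combo)
  correct <- numeric(length(grid))
  for (i in seq_len(nrow(profiles))) {
    terms <- unique(profiles$terms[[i]])
    hits <- tabulate(unlist(idx$index[terms], use.names = FALSE),
                     nbins = length(idx$patterns))
    keep <- which(hits > 0L)
    if (length(keep) == 0L) next
    f_pct <- 100 * hits[keep] / length(terms)
    n_pct <- 100 * hits[keep] / idx$n_t[keep]
    if (mode == "literal") {
      # Winner at cutoff c = best-ranked candidate among those with
      # N% >= c. Scanning candidates in rank order, the winner as c grows
      # is the next "record" of N%, so one pass gives every grid value.
      ord <- order(-f_pct, n_pct)
      keep <- keep[ord]; f_pct <- f_pct[ord]; n_pct <- n_pct[ord]
      grp <- paste(f_pct, n_pct)
      tie <- duplicated(grp) | duplicated(grp, fromLast = TRUE)
      rec <- which(n_pct == cummax(n_pct) & !duplicated(cummax(n_pct)))
      # rec: first index attaining each strictly increasing N% record
      rec_val <- n_pct[rec]
      win_ok <- !tie[rec] &
        idx$patterns[keep[rec]] == profiles$pattern[[i]]
      if (profiles$truth_class[[i]] == "control") {
        win_ok <- !tie[rec] &
          idx$patterns[keep[rec]] != profiles$pattern[[i]]
      }
      k <- colSums(outer(rec_val, grid, `<`)) + 1L
      ok <- k <= length(rec)
      add <- numeric(length(grid))
      add[ok] <- as.numeric(win_ok[k[ok]])
      correct <- correct + add
    } else {
      for (g in seq_along(grid)) {
        npc <- n_pct - grid[[g]]
        best <- which(f_pct == max(f_pct))
        best <- best[abs(npc[best]) == min(abs(npc[best]))]
        id <- if (length(best) == 1L) idx$patterns[keep[best]] else NA_character_
        ok <- if (profiles$truth_class[[i]] == "case") {
          !is.na(id) && id == profiles$pattern[[i]]
        } else {
          !is.na(id) && id != profiles$pattern[[i]]
        }
        correct[[g]] <- correct[[g]] + as.numeric(ok)
      }
    }
  }
  accuracy <- correct / nrow(profiles)
  best <- which.max(accuracy)  # which.max takes the first maximum: smallest cutoff
  structure(list(cutoff = grid[[best]], accuracy = accuracy[[best]],
                 curve = data.frame(cutoff = grid, accuracy = accuracy)),
            class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat("<cutoff_estimate> cutoff:", x$cutoff,
      " accuracy:", round(100 * x$accuracy, 1), "%\n")
  invisible(x)
}
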