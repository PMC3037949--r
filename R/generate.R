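# Synthetic pattern dataset generator. The study's real 73-pattern dataset is
# unpublished, so downstream stages are exercised on generated datasets that
# reproduce its printed structure: 539 distinct manifestations split across
# the Four Examinations (Ip 112, AO 42, Iq 359, P 26), per-pattern counts in
# the printed ranges, controllable inter-pattern term sharing, and optionally
# one pattern with no inspection/auscultation manifestations (the source of
# the study's missing cases).

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the printed structure of the study's dataset. `sharing`
#' controls inter-pattern manifestation overlap: it is the probability that a
#' term slot is filled by reusing a vocabulary term already assigned to some
#' pattern rather than by introducing a not-yet-used term. At 0 patterns are
#' as disjoint as the vocabulary allows; at 1 overlap is maximal.
#'
#' @param n_patterns Number of patterns (default 73).
#' @param vocab_sizes Named integer vector of distinct-term counts per method
#'   (default `c(Ip = 112, AO = 42, Iq = 359, P = 26)`).
#' @param count_ranges Named list of `c(min, max)` per-pattern per-method
#'   count ranges (defaults Ip 0-16, AO 0-6, Iq 2-29, P 0-5); counts are
#'   drawn uniformly on these integer ranges.
#' @param sharing Probability in `[0, 1]` of reusing an already-assigned term
#'   (default 0.3).
#' @param force_one_empty_Ip_AO If `TRUE` (default) exactly one pattern has
#'   empty inspection and auscultation-olfaction sets and every other pattern
#'   has at least one inspection term, so that a run under the `Ip`
#'   combination yields missing cases for exactly one pattern.
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   configuration and the seed.
#' @return A list of class `generator_config`.
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_patterns = 73L,
                             vocab_sizes = c(Ip = 112L, AO = 42L, Iq = 359L, P = 26L),
                             count_ranges = list(Ip = c(0L, 16L), AO = c(0L, 6L),
                                                 Iq = c(2L, 29L), P = c(0L, 5L)),
                             sharing = 0.3,
                             force_one_empty_Ip_AO = TRUE,
                             seed = 1L) {
  stopifnot(n_patterns >= 1L, sharing >= 0, sharing <= 1)
  vocab_sizes <- vocab_sizes[exam_methods()]
  if (any(is.na(vocab_sizes)) || any(vocab_sizes < 0L)) {
    stop("vocab_sizes must be named non-negative integers for all four methods",
         call. = FALSE)
  }
  count_ranges <- count_ranges[exam_methods()]
  ok <- vapply(count_ranges, function(r) {
    length(r) == 2L && !anyNA(r) && r[1L] >= 0L && r[1L] <= r[2L]
  }, logical(1L))
  if (!all(ok)) stop("count_ranges must be valid (min <= max) for all four methods",
                     call. = FALSE)
  structure(list(n_patterns = as.integer(n_patterns),
                 vocab_sizes = vapply(vocab_sizes, as.integer, integer(1L)),
                 count_ranges = lapply(count_ranges, as.integer),
                 sharing = sharing,
                 force_one_empty_Ip_AO = isTRUE(force_one_empty_Ip_AO),
                 seed = as.integer(seed)),
            class = "generator_config")
}

sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

draw_count <- function(range) {
  if (range[1L] == range[2L]) range[1L] else
    range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
}

#' Generate a synthetic pattern dataset
#'
#' Generation proceeds per design: (1) per-pattern per-method counts are
#' drawn uniformly on the configured ranges (redrawn until each pattern has
#' at least one manifestation overall, and — when one pattern is forced empty
#' under Ip and AO — until every other pattern has at least one inspection
#' term); (2) term slots are filled by a `sharing` coin flip between reusing
#' an already-assigned vocabulary term and introducing a fresh one; (3) a
#' final sweep assigns any still-unused vocabulary terms to random patterns
#' with spare capacity, so the per-method distinct-term counts equal the
#' configured vocabulary sizes exactly; (4) duplicate full profiles, should
#' they arise, are resolved by resampling one extra term for one of the
#' duplicates. Each method has its own vocabulary namespace, so intra-pattern
#' consistency holds by construction.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A valid `pattern_dataset` (both consistency validators pass); the
#'   seed and configuration are recorded in the dataset metadata.
#' @examples
#' d <- generate_dataset(generator_config(n_patterns = 8,
#'   vocab_sizes = c(Ip = 10, AO = 4, Iq = 20, P = 4), seed = 42))
#' summarize_dataset(d)
#' @export
generate_dataset <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patterns
  for (m in exam_methods()) {
    v <- config$vocab_sizes[[m]]
    if (v > 0L && n * config$count_ranges[[m]][2L] < v) {
      stop("infeasible configuration: vocabulary of method ", m, " (", v,
           " terms) cannot be placed within the per-pattern count ranges",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    empty_idx <- if (config$force_one_empty_Ip_AO) sample.int(n, 1L) else 0L
    # per-pattern per-method counts
    counts <- matrix(0L, nrow = n, ncol = 4L,
                     dimnames = list(NULL, exam_methods()))
    for (k in seq_len(n)) {
      for (tries in seq_len(1000L)) {
        row <- vapply(exam_methods(), function(m) draw_count(config$count_ranges[[m]]),
                      integer(1L))
        if (k == empty_idx) row[c("Ip", "AO")] <- 0L
        ok <- sum(row) >= 1L &&
          (k == empty_idx || !config$force_one_empty_Ip_AO || row[["Ip"]] >= 1L)
        if (ok) break
      }
      if (!ok) stop("could not draw a feasible manifestation count for pattern ", k,
                    call. = FALSE)
      counts[k, ] <- row
    }
    vocab <- lapply(exam_methods(), function(m) {
      v <- config$vocab_sizes[[m]]
      if (v == 0L) character(0) else
        sprintf("%s sign %03d", tolower(m), seq_len(v))
    })
    names(vocab) <- exam_methods()
    # fill term slots (indices into each method's vocabulary)
    sets <- replicate(n, stats::setNames(vector("list", 4L), exam_methods()),
                      simplify = FALSE)
    for (m in exam_methods()) {
      v <- config$vocab_sizes[[m]]
      used <- logical(v)
      for (k in seq_len(n)) {
        nk <- min(counts[k, m], v)
        cur <- integer(0)
        for (s in seq_len(nk)) {
          pool_used <- setdiff(which(used), cur)
          pool_fresh <- which(!used)
          reuse <- stats::runif(1L) < config$sharing
          pick <- if (reuse && length(pool_used) > 0L) {
            sample_one(pool_used)
          } else if (length(pool_fresh) > 0L) {
            sample_one(pool_fresh)
          } else if (length(pool_used) > 0L) {
            sample_one(pool_used)
          } else {
            NA_integer_
          }
          if (is.na(pick)) break
          cur <- c(cur, pick)
          used[pick] <- TRUE
        }
        sets[[k]][[m]] <- cur
        counts[k, m] <- length(cur)
      }
      # sweep: place never-used vocabulary terms in patterns with capacity
      for (t in which(!used)) {
        eligible <- which(counts[, m] < config$count_ranges[[m]][2L])
        if (m %in% c("Ip", "AO")) eligible <- setdiff(eligible, empty_idx)
        if (length(eligible) == 0L) {
          eligible <- setdiff(seq_len(n), if (m %in% c("Ip", "AO")) empty_idx else 0L)
        }
        if (length(eligible) == 0L) {
          stop("cannot place unused vocabulary term of method ", m, call. = FALSE)
        }
        k <- sample_one(eligible)
        sets[[k]][[m]] <- c(sets[[k]][[m]], t)
        counts[k, m] <- counts[k, m] + 1L
      }
    }
    patterns <- lapply(seq_len(n), function(k) {
      out <- lapply(exam_methods(), function(m) vocab[[m]][sets[[k]][[m]]])
      names(out) <- exam_methods()
      out
    })
    names(patterns) <- sprintf("pattern %02d", seq_len(n))
    # resolve duplicate full profiles by adding one extra term to a duplicate
    for (tries in seq_len(100L)) {
      keys <- vapply(patterns, profile_key, character(1L))
      dup <- which(duplicated(keys))
      if (length(dup) == 0L) break
      k <- dup[[1L]]
      fixed <- FALSE
      for (m in sample(exam_methods())) {
        if (k == empty_idx && m %in% c("Ip", "AO")) next
        avail <- setdiff(vocab[[m]], patterns[[k]][[m]])
        if (length(avail) > 0L) {
          patterns[[k]][[m]] <- c(patterns[[k]][[m]], sample_one(avail))
          fixed <- TRUE
          break
        }
      }
      if (!fixed) stop("could not resolve duplicate full profiles", call. = FALSE)
    }
    if (anyDuplicated(vapply(patterns, profile_key, character(1L)))) {
      stop("could not resolve duplicate full profiles", call. = FALSE)
    }
    new_pattern_dataset(patterns, meta = list(seed = as.integer(seed),
                                              config = config))
  })
}

#' Tune the sharing parameter toward a target similarity histogram
#'
#' Grid-searches `sharing` so that the generated dataset's dual-pattern
#' similarity category histogram (under the full four-method combination)
#' approximates a target. Distance is the total variation distance between
#' the category proportions. Note that a target putting all mass on
#' "Perfect" is unreachable: two perfectly similar patterns would share a
#' complete profile, which inter-pattern consistency forbids.
#'
#' @param config Base [generator_config()].
#' @param target Named numeric vector of target counts or proportions over
#'   the six similarity categories (names as in [similarity_categories()]).
#' @param sharing_grid Candidate sharing values (default `seq(0, 1, 0.1)`).
#' @param seed Seed used for every candidate generation.
#' @param tolerance Maximum acceptable total variation distance (default
#'   0.1).
#' @return List with the best `config`, its `sharing`, the achieved
#'   histogram, the `distance`, logical `ok`, and the full `grid` results.
#'   When the target is unreachable (`ok = FALSE`) the best-effort
#'   configuration is still returned, with the diagnostic in `grid`.
#' @export
tune_similarity <- function(config = generator_config(), target,
                            sharing_grid = seq(0, 1, by = 0.1),
                            seed = config$seed, tolerance = 0.1) {
  cats <- similarity_categories()
  target <- target[cats]
  target[is.na(target)] <- 0
  if (sum(target) <= 0) stop("target histogram must have positive mass", call. = FALSE)
  target <- target / sum(target)
  rows <- lapply(sharing_grid, function(s) {
    cfg <- config
    cfg$sharing <- s
    d <- generate_dataset(cfg, seed = seed)
    sim <- dual_similarity_matrix(d, exam_methods())
    hist <- table(factor(as.character(similarity_category(sim$s)), levels = cats))
    prop <- as.numeric(hist) / sum(hist)
    data.frame(sharing = s, distance = sum(abs(prop - target)) / 2,
               t(stats::setNames(as.numeric(hist), cats)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  best <- which.min(grid$distance)
  cfg <- config
  cfg$sharing <- grid$sharing[[best]]
  list(config = cfg, sharing = grid$sharing[[best]],
       histogram = stats::setNames(as.numeric(grid[best, cats]), cats),
       distance = grid$distance[[best]],
       ok = grid$distance[[best]] <= tolerance,
       grid = grid)
}
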