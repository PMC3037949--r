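# Pattern dataset data model: construction, normalization, validation,
# examination-restricted views and summary statistics.

#' Normalize a manifestation term
#'
#' Manifestation matching is by exact string comparison on a canonical form:
#' terms are case-folded, trimmed, and internal whitespace runs are collapsed
#' to a single space. Normalization is idempotent. The comma is the record
#' delimiter of the serialized formats and is therefore forbidden inside a
#' term.
#'
#' @param raw Character vector of raw terms.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("Dry  Tongue ")
#' @export
normalize_term <- function(raw) {
  if (!is.character(raw)) stop("terms must be character", call. = FALSE)
  out <- tolower(trimws(raw))
  out <- gsub("[[:space:]]+", " ", out)
  if (any(is.na(out) | out == "")) {
    stop("invalid manifestation term: empty after trimming", call. = FALSE)
  }
  if (any(grepl(",", out, fixed = TRUE))) {
    stop("invalid manifestation term: comma is the record delimiter and ",
         "cannot appear inside a term", call. = FALSE)
  }
  out
}

new_pattern_dataset <- function(patterns, meta = list()) {
  structure(list(patterns = patterns, meta = meta), class = "pattern_dataset")
}

#' Construct a pattern dataset
#'
#' A pattern dataset names a set of diagnostic patterns (e.g. the 73 Zangfu
#' single patterns) and assigns each a set of manifestation terms partitioned
#' across the Four Examinations. Terms are normalized with [normalize_term()]
#' and duplicated `(pattern, method, term)` records are dropped with a
#' warning. Pattern order and within-method term order follow first
#' appearance, so construction is deterministic.
#'
#' @param x A data frame with columns `pattern`, `method` and `manifestation`
#'   (one term per row, `method` one of `exam_methods()`), or a named list
#'   mapping pattern names to named lists of per-method character vectors.
#' @param meta Optional list of metadata (e.g. generator seed) stored with
#'   the dataset.
#' @return An object of class `pattern_dataset`.
#' @seealso [read_pattern_dataset()], [validate_dataset()],
#'   [restrict_dataset()]
#' @examples
#' d <- pattern_dataset(data.frame(
#'   pattern = c("A", "A", "B"),
#'   method = c("Ip", "Iq", "Iq"),
#'   manifestation = c("pale face", "fatigue", "thirst")
#' ))
#' pattern_names(d)
#' @export
pattern_dataset <- function(x, meta = list()) {
  if (is.data.frame(x)) {
    cols <- c("pattern", "method", "manifestation")
    if (!all(cols %in% names(x))) {
      stop("data frame must have columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
    pat <- as.character(x$pattern)
    method <- as.character(x$method)
    term <- normalize_term(as.character(x$manifestation))
    bad <- !method %in% exam_methods()
    if (any(bad)) {
      stop("unknown method code(s) at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), ": ",
           paste(unique(method[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(is.na(pat) | pat == "")) stop("empty pattern name", call. = FALSE)
    dup <- duplicated(paste(pat, method, term, sep = "\r"))
    if (any(dup)) {
      warning(sum(dup), " duplicated (pattern, method, term) record(s) dropped")
      pat <- pat[!dup]; method <- method[!dup]; term <- term[!dup]
    }
    pnames <- unique(pat)
    patterns <- lapply(pnames, function(p) {
      sets <- lapply(exam_methods(), function(m) term[pat == p & method == m])
      names(sets) <- exam_methods()
      sets
    })
    names(patterns) <- pnames
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("pattern list must be named", call. = FALSE)
    }
    if (anyDuplicated(names(x))) stop("duplicate pattern names", call. = FALSE)
    patterns <- lapply(x, function(sets) {
      out <- lapply(exam_methods(), function(m) {
        v <- sets[[m]]
        if (is.null(v) || length(v) == 0L) character(0) else normalize_term(v)
      })
      names(out) <- exam_methods()
      out
    })
    extra <- setdiff(unique(unlist(lapply(x, names))), exam_methods())
    if (length(extra) > 0L) {
      stop("unknown method code(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  } else {
    stop("x must be a data frame or a named list", call. = FALSE)
  }
  empty <- vapply(patterns, function(p) sum(lengths(p)) == 0L, logical(1L))
  if (any(empty)) {
    stop("pattern(s) without manifestations: ",
         paste(names(patterns)[empty], collapse = ", "), call. = FALSE)
  }
  new_pattern_dataset(patterns, meta)
}

#' @export
print.pattern_dataset <- function(x, ...) {
  nt <- n_manifestations(x)
  cat("<pattern_dataset> ", length(x$patterns), " patterns, ",
      length(dataset_vocabulary(x)), " distinct manifestations\n", sep = "")
  cat("  N_T per pattern: median ", stats::median(nt), " [", min(nt), "-",
      max(nt), "]\n", sep = "")
  invisible(x)
}

#' Pattern names of a dataset
#'
#' @param d A `pattern_dataset`.
#' @return Character vector of pattern names in dataset order.
#' @export
pattern_names <- function(d) {
  stopifnot(inherits(d, "pattern_dataset"))
  names(d$patterns)
}

#' Manifestation terms of one pattern
#'
#' @param d A `pattern_dataset`.
#' @param pattern Pattern name.
#' @param combo Examination combination; defaults to all four methods.
#' @return Character vector of the pattern's terms under `combo`.
#' @export
pattern_terms <- function(d, pattern, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  p <- d$patterns[[pattern]]
  if (is.null(p)) stop("unknown pattern: ", pattern, call. = FALSE)
  unlist(p[combo], use.names = FALSE)
}

#' Per-pattern manifestation counts (N_T)
#'
#' The total quantity of manifestations describing each pattern under an
#' examination combination.
#'
#' @inheritParams pattern_terms
#' @return Named integer vector, one count per pattern.
#' @export
n_manifestations <- function(d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  vapply(d$patterns, function(p) sum(lengths(p[combo])), integer(1L))
}

#' Dataset vocabulary
#'
#' @inheritParams pattern_terms
#' @return Character vector of distinct terms used by at least one pattern
#'   under `combo`, in first-appearance order.
#' @export
dataset_vocabulary <- function(d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  unique(unlist(lapply(d$patterns, function(p) unlist(p[combo], use.names = FALSE)),
                use.names = FALSE))
}

#' Restrict a dataset to an examination combination
#'
#' Returns a view of the dataset in which every method outside `combo` is
#' emptied. Patterns left with zero manifestations are retained (they yield
#' missing cases downstream rather than silently disappearing); use
#' [empty_patterns()] to list them.
#'
#' @inheritParams pattern_terms
#' @return A `pattern_dataset` whose metadata records the restriction.
#' @export
restrict_dataset <- function(d, combo) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  patterns <- lapply(d$patterns, function(p) {
    out <- lapply(exam_methods(), function(m) if (m %in% combo) p[[m]] else character(0))
    names(out) <- exam_methods()
    out
  })
  meta <- d$meta
  meta$combo <- combo_label(combo)
  new_pattern_dataset(patterns, meta)
}

#' Patterns with no manifestations under a combination
#'
#' @inheritParams pattern_terms
#' @return Character vector of pattern names whose restricted term set is
#'   empty (their simulated cases are flagged missing).
#' @export
empty_patterns <- function(d, combo = exam_methods()) {
  nt <- n_manifestations(d, combo)
  names(nt)[nt == 0L]
}

#' Intra-pattern consistency check
#'
#' A manifestation must be assigned to exactly one examination method within
#' a pattern. Reports every term that occurs in two methods of the same
#' pattern, naming the offending method pair.
#'
#' @param d A `pattern_dataset`.
#' @param pattern Optional pattern name; default checks every pattern.
#' @return Data frame with columns `pattern`, `term`, `method1`, `method2`;
#'   zero rows when consistent.
#' @export
validate_intra_pattern <- function(d, pattern = NULL) {
  stopifnot(inherits(d, "pattern_dataset"))
  pats <- if (is.null(pattern)) pattern_names(d) else pattern
  out <- list()
  for (p in pats) {
    sets <- d$patterns[[p]]
    if (is.null(sets)) stop("unknown pattern: ", p, call. = FALSE)
    ms <- exam_methods()
    for (i in seq_len(length(ms) - 1L)) {
      for (j in seq(i + 1L, length(ms))) {
        shared <- intersect(sets[[ms[i]]], sets[[ms[j]]])
        if (length(shared) > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            pattern = p, term = shared, method1 = ms[i], method2 = ms[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(pattern = character(0), term = character(0),
               method1 = character(0), method2 = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

profile_key <- function(sets) {
  paste(vapply(exam_methods(), function(m) paste(sort(sets[[m]]), collapse = ","),
               character(1L)), collapse = ";")
}

#' Inter-pattern consistency check
#'
#' Two patterns may not share an identical complete four-method manifestation
#' profile (they would describe the same pattern). Reports every offending
#' pattern pair.
#'
#' @param d A `pattern_dataset`.
#' @return Data frame with columns `pattern_i`, `pattern_j`; zero rows when
#'   all full profiles are distinct.
#' @export
validate_inter_pattern <- function(d) {
  stopifnot(inherits(d, "pattern_dataset"))
  keys <- vapply(d$patterns, profile_key, character(1L))
  out <- list()
  groups <- split(names(keys), keys)
  for (g in groups) {
    if (length(g) >= 2L) {
      pairs <- utils::combn(g, 2L)
      out[[length(out) + 1L]] <- data.frame(
        pattern_i = pairs[1L, ], pattern_j = pairs[2L, ],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    data.frame(pattern_i = character(0), pattern_j = character(0),
               stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res[order(match(res$pattern_i, pattern_names(d)),
              match(res$pattern_j, pattern_names(d))), , drop = FALSE]
  }
}

#' Run all dataset consistency checks
#'
#' @param d A `pattern_dataset`.
#' @return List with elements `intra` and `inter` (the two violation
#'   frames) and logical `valid`.
#' @export
validate_dataset <- function(d) {
  intra <- validate_intra_pattern(d)
  inter <- validate_inter_pattern(d)
  list(intra = intra, inter = inter,
       valid = nrow(intra) == 0L && nrow(inter) == 0L)
}

#' Summarize the distribution of manifestations across methods
#'
#' Reports, for each examination method, the number of distinct terms in the
#' dataset, its percentage of the vocabulary, and the per-pattern count as
#' median [min-max] — the same summary the study reports for its dataset
#' (e.g. inquiry holding two-thirds of the vocabulary).
#'
#' @param d A `pattern_dataset`.
#' @return Data frame with one row per method plus a `Total` row; columns
#'   `method`, `n_terms`, `pct`, `median`, `min`, `max`.
#' @export
summarize_dataset <- function(d) {
  stopifnot(inherits(d, "pattern_dataset"))
  rows <- lapply(exam_methods(), function(m) {
    vocab <- unique(unlist(lapply(d$patterns, `[[`, m), use.names = FALSE))
    counts <- vapply(d$patterns, function(p) length(p[[m]]), integer(1L))
    data.frame(method = m, n_terms = length(vocab), pct = NA_real_,
               median = stats::median(counts), min = min(counts),
               max = max(counts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- length(dataset_vocabulary(d))
  out$pct <- round(100 * out$n_terms / total, 1L)
  nt <- n_manifestations(d)
  rbind(out, data.frame(method = "Total", n_terms = total, pct = 100,
                        median = stats::median(nt), min = min(nt),
                        max = max(nt), stringsAsFactors = FALSE))
}

#' @describeIn pattern_dataset Long-format view: one row per
#'   `(pattern, method, manifestation)` record.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @export
as.data.frame.pattern_dataset <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  rows <- lapply(pattern_names(x), function(p) {
    sets <- x$patterns[[p]]
    do.call(rbind, lapply(exam_methods(), function(m) {
      if (length(sets[[m]]) == 0L) return(NULL)
      data.frame(pattern = p, method = m, manifestation = sets[[m]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pattern = character(0), method = character(0),
                      manifestation = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
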