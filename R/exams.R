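# The Four Examinations and their cumulative combinations.

#' The Four Examination methods
#'
#' Chinese medicine collects clinical manifestations through four examination
#' methods, applied in a canonical order: inspection (`Ip`), auscultation and
#' olfaction (`AO`), inquiry (`Iq`) and palpation (`P`). Every manifestation
#' in a pattern dataset is assigned to exactly one of them.
#'
#' @return Character vector `c("Ip", "AO", "Iq", "P")` in canonical order.
#' @examples
#' exam_methods()
#' @export
exam_methods <- function() c("Ip", "AO", "Iq", "P")

#' Parse and validate an examination combination
#'
#' An examination combination is a non-empty subset of the Four Examinations,
#' written either as a character vector of method codes or as a single
#' `"+"`-joined label such as `"Ip+AO"`. The result is always ordered
#' canonically (Ip < AO < Iq < P) and carries no duplicates.
#'
#' @param x Character vector of method codes, or a single string like
#'   `"Ip+AO+Iq"`.
#' @return Character vector of method codes in canonical order.
#' @examples
#' exam_combo("Ip+AO")
#' exam_combo(c("Iq", "Ip"))
#' @export
exam_combo <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && grepl("+", x, fixed = TRUE)) {
    x <- strsplit(x, "+", fixed = TRUE)[[1L]]
  }
  x <- trimws(x)
  bad <- setdiff(x, exam_methods())
  if (length(bad) > 0L) {
    stop("unknown examination method(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x)) {
    stop("duplicate examination methods in combination", call. = FALSE)
  }
  exam_methods()[exam_methods() %in% x]
}

#' Label for an examination combination
#'
#' @param combo Combination as accepted by [exam_combo()].
#' @return Single string, e.g. `"Ip+AO+Iq"`.
#' @examples
#' combo_label(c("Ip", "AO"))
#' @export
combo_label <- function(combo) paste(exam_combo(combo), collapse = "+")

#' The four cumulative study combinations
#'
#' The study applies the Four Examinations incrementally: `Ip`, `Ip+AO`,
#' `Ip+AO+Iq`, `Ip+AO+Iq+P`. These prefixes define the ordinal "combination"
#' variable used throughout the analysis.
#'
#' @return Named list of four combinations (character vectors), named by
#'   their labels in increasing order of information.
#' @examples
#' names(canonical_combos())
#' @export
canonical_combos <- function() {
  combos <- lapply(seq_along(exam_methods()), function(i) exam_methods()[seq_len(i)])
  names(combos) <- vapply(combos, combo_label, character(1L))
  combos
}
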