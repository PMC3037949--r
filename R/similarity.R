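# Pattern similarity: dual-pattern Jaccard coefficient, the pattern-vs-
# dataset variant, the upper-triangular similarity matrix, and ordinal
# categorization.

#' Jaccard similarity between two term sets
#'
#' For two patterns with `F_i` and `F_j` manifestations of which `F_ij` are
#' shared, similarity is `S = F_ij / (F_i + F_j - F_ij)`, i.e. intersection
#' over union. `S = 0` for disjoint sets (perfectly dissimilar patterns) and
#' `S = 1` for equal sets.
#'
#' @param terms_i,terms_j Character vectors of (normalized) terms; duplicates
#'   are ignored. Both empty is an error (similarity undefined).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' jaccard_similarity(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard_similarity <- function(terms_i, terms_j) {
  terms_i <- unique(terms_i)
  terms_j <- unique(terms_j)
  if (length(terms_i) == 0L && length(terms_j) == 0L) {
    stop("similarity undefined: both term sets are empty", call. = FALSE)
  }
  f_ij <- length(intersect(terms_i, terms_j))
  f_ij / (length(terms_i) + length(terms_j) - f_ij)
}

#' Dual-pattern similarity matrix
#'
#' Computes the Jaccard similarity of every unordered pattern pair on the
#' term sets restricted to an examination combination — the upper triangle
#' of the symmetric similarity matrix (`n(n-1)/2` entries; 2,628 for 73
#' patterns). Pairs in which either pattern is empty under the combination
#' have undefined similarity and are recorded with `s = NA` (they are
#' excluded from category counts, mirroring the missing-case exclusion).
#'
#' @param d A `pattern_dataset`.
#' @param combo Examination combination (default all four methods).
#' @return Data frame with one row per unordered pair: `pattern_i`,
#'   `pattern_j`, `f_i`, `f_j`, `f_ij`, `s`. The combination label is stored
#'   in the `"combo"` attribute.
#' @export
dual_similarity_matrix <- function(d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  pats <- pattern_names(d)
  n <- length(pats)
  term_sets <- lapply(pats, function(p) unique(pattern_terms(d, p, combo)))
  vocab <- unique(unlist(term_sets, use.names = FALSE))
  inc <- matrix(0L, nrow = n, ncol = length(vocab))
  for (k in seq_len(n)) inc[k, match(term_sets[[k]], vocab)] <- 1L
  shared <- tcrossprod(inc)       # shared[i, j] = F_ij
  f <- lengths(term_sets)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) seq(a + 1L, n)), use.names = FALSE)
  f_ij <- shared[cbind(i, j)]
  denom <- f[i] + f[j] - f_ij
  s <- ifelse(f[i] == 0L | f[j] == 0L, NA_real_, f_ij / denom)
  out <- data.frame(pattern_i = pats[i], pattern_j = pats[j],
                    f_i = f[i], f_j = f[j], f_ij = f_ij, s = s,
                    stringsAsFactors = FALSE)
  attr(out, "combo") <- combo_label(combo)
  out
}

#' Pattern-dataset similarity (S*)
#'
#' Measures how much of a pattern's manifestations recur anywhere else in
#' the dataset. With `F_i` the pattern's manifestation count under the
#' combination and `F_id` the number of those manifestations also present in
#' the union of all other patterns' restricted sets,
#' `S* = F_id / (2 F_i - F_id)`. `S* = 1` when every manifestation is shared
#' (`F_id = F_i`); `S* = 0` for a pathognomonic pattern (`F_id = 0`). A
#' pattern empty under the combination has undefined `S*` (`NA`).
#'
#' @inheritParams dual_similarity_matrix
#' @return Data frame with one row per pattern: `pattern`, `f_i`, `f_id`,
#'   `s_star`.
#' @export
pattern_dataset_similarity <- function(d, combo = exam_methods()) {
  stopifnot(inherits(d, "pattern_dataset"))
  combo <- exam_combo(combo)
  pats <- pattern_names(d)
  term_sets <- lapply(pats, function(p) unique(pattern_terms(d, p, combo)))
  freq <- table(unlist(term_sets, use.names = FALSE))
  f_i <- lengths(term_sets)
  f_id <- vapply(term_sets, function(ts) sum(freq[ts] >= 2L), numeric(1L))
  s_star <- ifelse(f_i == 0L, NA_real_, f_id / (2 * f_i - f_id))
  out <- data.frame(pattern = pats, f_i = as.integer(f_i),
                    f_id = as.integer(f_id), s_star = s_star,
                    stringsAsFactors = FALSE)
  attr(out, "combo") <- combo_label(combo)
  out
}

#' Ordinal similarity categories
#'
#' @return Character vector of the six category labels in increasing order
#'   of similarity.
#' @export
similarity_categories <- function() {
  c("No similarity", "Negligible", "Weak", "Moderate", "Strong", "Perfect")
}

#' Categorize similarity values
#'
#' Similarity coefficients are categorized on the ordinal scale: 0.00 no
#' similarity; 0.01-0.20 negligible; 0.21-0.40 weak; 0.41-0.70 moderate;
#' 0.71-0.99 strong; 1.00 perfect. The printed bin edges are two-decimal
#' values, so `s` is first rounded half-up to two decimals, which makes the
#' bins exhaustive on `[0, 1]`.
#'
#' @param s Numeric vector of similarity values in `[0, 1]`; `NA` values
#'   (undefined similarity) stay `NA`.
#' @return Ordered factor with levels [similarity_categories()].
#' @examples
#' similarity_category(c(0, 0.204, 0.205, 1))
#' @export
similarity_category <- function(s) {
  if (any(!is.na(s) & (s < -1e-9 | s > 1 + 1e-9))) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  r <- round_half_up(s, 2L)
  idx <- ifelse(is.na(r), NA_integer_,
         ifelse(r <= 0, 1L,
         ifelse(r <= 0.20, 2L,
         ifelse(r <= 0.40, 3L,
         ifelse(r <= 0.70, 4L,
         ifelse(r <= 0.99, 5L, 6L))))))
  factor(similarity_categories()[idx], levels = similarity_categories(),
         ordered = TRUE)
}
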