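# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute-force set arithmetic, exhaustive pair enumeration) and never reuse
# the code paths they check.

# A hand-written 4-pattern dataset with known overlap structure.
toy_dataset <- function() {
  pattern_dataset(list(
    "heart qi deficiency" = list(
      Ip = c("pale face", "listlessness"),
      Iq = c("palpitation", "spontaneous sweating", "fatigue"),
      P  = c("weak pulse")),
    "heart yang deficiency" = list(
      Ip = c("pale face", "cold limbs"),
      Iq = c("palpitation", "fatigue", "aversion to cold"),
      P  = c("weak pulse", "deep pulse")),
    "liver qi stagnation" = list(
      Ip = c("red eyes"),
      AO = c("sighing"),
      Iq = c("hypochondriac pain", "irritability", "fatigue")),
    "kidney yin deficiency" = list(
      Iq = c("night sweating", "dizziness", "tinnitus"),
      P  = c("thready pulse"))
  ))
}

# A small dataset of mutually disjoint patterns.
disjoint_dataset <- function(n = 3L, terms_per = 3L) {
  pats <- lapply(seq_len(n), function(k) {
    list(Iq = sprintf("symptom %d %d", k, seq_len(terms_per)))
  })
  names(pats) <- sprintf("pattern %d", seq_len(n))
  pattern_dataset(pats)
}

# Random small dataset for property tests (may contain shared terms).
random_toy_dataset <- function(n_patterns = 4L, vocab = 12L) {
  terms <- sprintf("sign %02d", seq_len(vocab))
  pats <- lapply(seq_len(n_patterns), function(k) {
    # assign each drawn term to one random method, keeping methods disjoint
    drawn <- sample(terms, sample(3:6, 1L))
    meth <- sample(exam_methods(), length(drawn), replace = TRUE)
    out <- lapply(exam_methods(), function(m) drawn[meth == m])
    names(out) <- exam_methods()
    out
  })
  names(pats) <- sprintf("pattern %d", seq_len(n_patterns))
  pattern_dataset(pats)
}

# --- independent oracles -----------------------------------------------

# Goodman-Kruskal gamma by exhaustive enumeration over all ordered pairs of
# cells, with explicit sign comparison of the coordinates.
gamma_cellpair_oracle <- function(m) {
  r <- nrow(m); c <- ncol(m)
  conc <- 0; disc <- 0
  for (i1 in 1:r) for (j1 in 1:c) for (i2 in 1:r) for (j2 in 1:c) {
    s <- sign(i2 - i1) * sign(j2 - j1)
    if (s == 1) conc <- conc + m[i1, j1] * m[i2, j2]
    if (s == -1) disc <- disc + m[i1, j1] * m[i2, j2]
  }
  # each unordered record pair is counted twice
  (conc - disc) / (conc + disc)
}

# Gamma by enumeration over individual record pairs (small n only).
gamma_records_oracle <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  rows <- rep(idx[, 1L], m[idx])
  cols <- rep(idx[, 2L], m[idx])
  n <- length(rows)
  conc <- 0; disc <- 0
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    s <- sign(rows[b] - rows[a]) * sign(cols[b] - cols[a])
    if (s == 1) conc <- conc + 1
    if (s == -1) disc <- disc + 1
  }
  (conc - disc) / (conc + disc)
}

# Explained-manifestation counts by direct set arithmetic.
candidates_oracle <- function(terms, d, combo) {
  counts <- vapply(pattern_names(d), function(p) {
    length(intersect(unique(terms), unique(pattern_terms(d, p, combo))))
  }, integer(1L))
  counts[counts > 0L]
}

random_crosstable <- function(max_rows = 5L, max_cols = 6L, max_n = 10000L) {
  r <- sample(2:max_rows, 1L)
  c <- sample(2:max_cols, 1L)
  n <- sample(50:max_n, 1L)
  cells <- stats::rmultinom(1L, n, prob = stats::runif(r * c))
  matrix(as.integer(cells), nrow = r)
}
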