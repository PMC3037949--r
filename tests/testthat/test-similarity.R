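test_that("Jaccard similarity equals intersection over union", {
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("a", "b"), c("b", "a")), 1)
  expect_error(jaccard_similarity(character(0), character(0)), "empty")

  set.seed(17)
  pool <- sprintf("t%02d", 1:15)
  for (rep in 1:20) {
    x <- sample(pool, sample(1:8, 1L))
    y <- sample(pool, sample(1:8, 1L))
    expect_equal(jaccard_similarity(x, y),
                 length(intersect(x, y)) / length(union(x, y)))
    expect_equal(jaccard_similarity(x, y), jaccard_similarity(y, x))
  }
})

test_that("pattern-dataset similarity hits its boundary cases", {
  # every term of "a" shared -> S* = 1; pathognomonic "c" -> S* = 0
  d <- pattern_dataset(list(
    a = list(Iq = c("fatigue", "thirst")),
    b = list(Ip = c("pale face"), Iq = c("fatigue", "thirst")),
    c = list(P = c("weak pulse"))))
  ss <- pattern_dataset_similarity(d)
  expect_equal(ss$s_star[ss$pattern == "a"], 1)
  expect_equal(ss$s_star[ss$pattern == "c"], 0)
  # F_i = 3, F_id = 2 -> 2 / (6 - 2)
  d2 <- pattern_dataset(list(
    a = list(Iq = c("fatigue", "thirst", "rare sign")),
    b = list(Iq = c("fatigue", "thirst"))))
  ss2 <- pattern_dataset_similarity(d2)
  expect_equal(ss2$s_star[ss2$pattern == "a"], 2 / 4)
  expect_identical(ss2$f_id[ss2$pattern == "a"], 2L)
  # empty under combo -> undefined
  ss3 <- pattern_dataset_similarity(d, "Ip")
  expect_true(is.na(ss3$s_star[ss3$pattern == "a"]))
})

test_that("the dual matrix holds n(n-1)/2 symmetric entries", {
  d3 <- disjoint_dataset(n = 3)
  expect_identical(nrow(dual_similarity_matrix(d3)), 3L)

  d <- toy_dataset()
  sm <- dual_similarity_matrix(d, c("Ip", "AO"))
  expect_identical(nrow(sm), 6L)
  # symmetry and agreement with the scalar definition, argument order swapped
  for (k in seq_len(nrow(sm))) {
    ti <- pattern_terms(d, sm$pattern_i[k], c("Ip", "AO"))
    tj <- pattern_terms(d, sm$pattern_j[k], c("Ip", "AO"))
    if (length(ti) == 0L || length(tj) == 0L) {
      expect_true(is.na(sm$s[k]))
    } else {
      expect_equal(sm$s[k], jaccard_similarity(tj, ti))
    }
  }
  # pairs with an empty pattern are undefined, not zero
  expect_true(any(is.na(sm$s)))
})

test_that("similarity categorization rounds half-up to the printed bins", {
  expect_identical(as.character(similarity_category(0)), "No similarity")
  expect_identical(as.character(similarity_category(1)), "Perfect")
  expect_identical(as.character(similarity_category(0.204)), "Negligible")
  expect_identical(as.character(similarity_category(0.205)), "Weak")
  expect_identical(as.character(similarity_category(c(0.004, 0.005))),
                   c("No similarity", "Negligible"))
  expect_identical(as.character(similarity_category(c(0.405, 0.705, 0.995))),
                   c("Moderate", "Strong", "Perfect"))
  expect_true(is.na(similarity_category(NA_real_)))
  expect_error(similarity_category(1.2), "\\[0, 1\\]")
  expect_true(is.ordered(similarity_category(0.5)))
})

test_that("no perfect dual similarity survives under the full combination", {
  d <- generate_dataset(generator_config(sharing = 0.8, seed = 21))
  expect_true(validate_dataset(d)$valid)
  sm <- dual_similarity_matrix(d, exam_methods())
  expect_true(all(sm$s[!is.na(sm$s)] < 1))
})

test_that("raw overlap counts are monotone under combination refinement", {
  d <- generate_dataset(generator_config(sharing = 0.5, seed = 12,
                                         n_patterns = 12,
                                         vocab_sizes = c(Ip = 20, AO = 8,
                                                         Iq = 40, P = 8)))
  combos <- canonical_combos()
  prev <- NULL
  for (combo in combos) {
    sm <- dual_similarity_matrix(d, combo)
    if (!is.null(prev)) {
      expect_true(all(sm$f_ij >= prev$f_ij))
      expect_true(all(sm$f_i >= prev$f_i))
      expect_true(all(sm$f_j >= prev$f_j))
    }
    expect_true(all(sm$s[!is.na(sm$s)] >= 0 & sm$s[!is.na(sm$s)] <= 1))
    prev <- sm
  }
})
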