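test_that("scores implement explained and available information", {
  expect_equal(score_F(2, 4), 50)
  expect_equal(score_F(4, 4), 100)
  expect_equal(score_F(0, 7), 0)
  expect_error(score_F(1, 0), "N_P")
  expect_equal(score_N(5, 10, 26.5), 23.5)
  expect_equal(score_N(5, 10, 50), 0)
  expect_equal(score_N(1, 4, 24.5), 0.5)
  expect_error(score_N(1, 0, 10), "empty")
})

test_that("candidate generation matches brute-force set intersection", {
  d <- toy_dataset()
  cand <- find_candidates("weak pulse", d)
  expect_setequal(cand$pattern, c("heart qi deficiency", "heart yang deficiency"))
  expect_true(all(cand$n_e == 1L))

  cand <- find_candidates("sighing", d)
  expect_identical(cand$pattern, "liver qi stagnation")

  # unmatched terms stay in N_P but are explained by nobody
  cand <- find_candidates(c("weak pulse", "no such sign"), d)
  expect_true(all(cand$n_e == 1L))

  expect_error(find_candidates(character(0), d), "missing")

  set.seed(13)
  for (rep in 1:10) {
    d <- random_toy_dataset()
    combo <- sample(canonical_combos(), 1L)[[1L]]
    terms <- sample(dataset_vocabulary(d), 5L)
    got <- find_candidates(terms, d, combo)
    want <- candidates_oracle(terms, d, combo)
    expect_setequal(got$pattern, names(want))
    expect_identical(stats::setNames(got$n_e, got$pattern)[names(want)], want)
  }
})

test_that("ranking identifies a unique top pair and ties are undiagnosed", {
  cand <- data.frame(pattern = c("A", "B"), n_e = c(4L, 2L), n_t = c(8L, 4L))
  r <- rank_and_identify(cand, n_p = 4L, cutoff = 10)
  expect_identical(r$status, "identified")
  expect_identical(r$identified, "A")

  # exact tie on the (F, N - cutoff) pair
  tie <- data.frame(pattern = c("A", "B"), n_e = c(2L, 2L), n_t = c(5L, 5L))
  r <- rank_and_identify(tie, n_p = 4L, cutoff = 10)
  expect_identical(r$status, "undiagnosed")
  expect_true(is.na(r$identified))

  r <- rank_and_identify(cand[0L, ], n_p = 3L, cutoff = 0)
  expect_identical(r$status, "undiagnosed")

  # literal mode removes candidates whose available information is below cutoff
  cand <- data.frame(pattern = c("A", "B"), n_e = c(3L, 3L), n_t = c(4L, 20L))
  r <- rank_and_identify(cand, n_p = 3L, cutoff = 30)
  expect_identical(r$ranked$pattern, "A")  # B has N% = 15 < 30
  expect_identical(r$identified, "A")
  # absdev mode keeps B and prefers the closest to the cutoff
  r2 <- rank_and_identify(cand, n_p = 3L, cutoff = 30, mode = "absdev")
  expect_identical(nrow(r2$ranked), 2L)
  expect_identical(r2$identified, "B")  # |15 - 30| ... both F = 100; |N - c|: A 45, B 15
})

test_that("shifting the cutoff never reorders surviving candidates in literal mode", {
  set.seed(29)
  for (rep in 1:20) {
    k <- sample(2:6, 1L)
    cand <- data.frame(pattern = LETTERS[seq_len(k)],
                       n_e = sample(1:5, k, replace = TRUE),
                       n_t = sample(5:15, k, replace = TRUE))
    n_p <- max(cand$n_e) + sample(0:3, 1L)
    base <- rank_and_identify(cand, n_p, cutoff = 0)
    shifted <- rank_and_identify(cand, n_p, cutoff = 25)
    surviving <- shifted$ranked$pattern
    expect_identical(base$ranked$pattern[base$ranked$pattern %in% surviving],
                     surviving)
  }
})

test_that("a pattern sharing no terms is identified from its full profile at any cutoff", {
  d <- disjoint_dataset(n = 4, terms_per = 3)
  for (cut in c(0, 24.5, 51.5, 100)) {
    r <- differentiate(pattern_terms(d, "pattern 2"), d, cutoff = cut)
    expect_identical(r$status, "identified")
    expect_identical(r$identified, "pattern 2")
    expect_equal(r$ranked$f_pct[1L], 100)
  }
})

test_that("batch differentiation skips missing profiles and is deterministic", {
  d <- generate_dataset(generator_config(seed = 4))
  pr <- simulate_run(d, "Ip", 5, 5, seed = 8)
  res <- differentiate_profiles(pr, d, "Ip", cutoff = 20)
  expect_identical(res$status[res$missing], rep("missing", sum(res$missing)))
  expect_true(all(res$status[!res$missing] %in% c("identified", "undiagnosed")))
  res2 <- differentiate_profiles(pr, d, "Ip", cutoff = 20)
  expect_identical(res, res2)
  # single-profile path agrees with the batch path
  i <- which(!res$missing)[1L]
  single <- differentiate(pr$terms[[i]], d, "Ip", cutoff = 20)
  expect_identical(single$status, res$status[i])
  if (single$status == "identified") {
    expect_identical(single$identified, res$identified[i])
  }
})

test_that("cutoff estimation maximizes accuracy and matches exhaustive search", {
  # flat accuracy on a disjoint dataset -> smallest grid value wins
  d <- disjoint_dataset(n = 5, terms_per = 4)
  est <- estimate_cutoff(d, "Iq", n_cases = 5, n_controls = 5, seed = 2,
                         grid = seq(0, 100, by = 0.5))
  expect_identical(est$cutoff, 0)
  expect_true(est$cutoff %% 0.5 == 0)

  # brute-force oracle: rerun the grid by scoring each profile independently
  d <- toy_dataset()
  grid <- seq(0, 100, by = 10)
  est <- estimate_cutoff(d, exam_methods(), n_cases = 20, n_controls = 20,
                         seed = 6, grid = grid)
  profiles <- simulate_run(d, exam_methods(), 20, 20, seed = 6)
  profiles <- profiles[!profiles$missing, ]
  acc <- vapply(grid, function(cut) {
    ok <- vapply(seq_len(nrow(profiles)), function(i) {
      r <- differentiate(profiles$terms[[i]], d, exam_methods(), cutoff = cut)
      if (profiles$truth_class[[i]] == "case") {
        r$status == "identified" && r$identified == profiles$pattern[[i]]
      } else {
        r$status == "identified" && r$identified != profiles$pattern[[i]]
      }
    }, logical(1L))
    mean(ok)
  }, numeric(1L))
  expect_equal(est$curve$accuracy, acc)
  expect_identical(est$cutoff, grid[[which.max(acc)]])
})
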