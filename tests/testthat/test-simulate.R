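test_that("case profiles are drawn without replacement from the source pattern", {
  d <- toy_dataset()
  set.seed(7)
  for (rep in 1:25) {
    p <- sample(pattern_names(d), 1L)
    combo <- sample(canonical_combos(), 1L)[[1L]]
    prof <- simulate_case(d, p, combo)
    terms <- prof$terms[[1L]]
    restricted <- pattern_terms(d, p, combo)
    if (length(restricted) == 0L) {
      expect_true(prof$missing)
      expect_identical(prof$n_r, 0L)
    } else {
      expect_false(prof$missing)
      expect_true(all(terms %in% restricted))
      expect_identical(anyDuplicated(terms), 0L)
      expect_identical(prof$n_r, length(terms))
      expect_true(prof$n_r >= 1L && prof$n_r <= length(restricted))
    }
  }
  # forced outcome: single restricted term
  one <- pattern_dataset(list(a = list(Ip = "pale face"),
                              b = list(Iq = "fatigue")))
  prof <- simulate_case(one, "a", "Ip")
  expect_identical(prof$terms[[1L]], "pale face")
  expect_identical(prof$n_r, 1L)
  expect_error(simulate_case(d, "no such pattern"), "unknown pattern")
})

test_that("control profiles come from an eligible donor other than the source", {
  two <- pattern_dataset(list(a = list(Ip = c("pale face", "listlessness")),
                              b = list(Iq = c("fatigue", "thirst"))))
  set.seed(3)
  for (rep in 1:10) {
    prof <- simulate_control(two, "a")
    expect_identical(prof$donor, "b")
    expect_true(all(prof$terms[[1L]] %in% pattern_terms(two, "b")))
  }
  # no eligible donor under a combo where the other pattern is empty
  prof <- simulate_control(two, "b", "Iq")
  expect_true(prof$missing)
  expect_true(is.na(prof$donor))
})

test_that("runs have the designed size, flag missing cases, and are reproducible", {
  d <- generate_dataset(generator_config(seed = 2))
  pr <- simulate_run(d, "Ip", n_cases = 3, n_controls = 2, seed = 5)
  expect_identical(nrow(pr), 73L * 5L)
  expect_identical(sum(pr$truth_class == "case"), 73L * 3L)

  # the one Ip-empty pattern contributes exactly n_cases missing cases
  ip_empty <- empty_patterns(d, "Ip")
  expect_length(ip_empty, 1L)
  miss <- pr[pr$missing & pr$truth_class == "case", ]
  expect_identical(nrow(miss), 3L)
  expect_true(all(miss$pattern == ip_empty))

  pr2 <- simulate_run(d, "Ip", n_cases = 3, n_controls = 2, seed = 5)
  expect_identical(pr, pr2)
  pr3 <- simulate_run(d, "Ip", n_cases = 3, n_controls = 2, seed = 6)
  expect_false(identical(pr$terms, pr3$terms))

  expect_identical(nrow(simulate_run(d, "Ip", 0, 0, seed = 1)), 0L)
})

test_that("reverse engineering classifies coverage per pattern", {
  d <- toy_dataset()
  empty <- simulate_run(d, exam_methods(), 0, 0, seed = 1)
  rep0 <- reverse_engineer_check(empty, d)
  expect_true(all(rep0$per_pattern$status == "not used"))
  expect_false(rep0$complete)

  # profiles = each full term set once -> complete coverage
  full <- do.call(rbind, lapply(pattern_names(d), function(p) {
    data.frame(pattern = p, truth_class = "case", combo = "Ip+AO+Iq+P",
               donor = NA_character_,
               n_r = length(pattern_terms(d, p)),
               missing = FALSE, terms = I(list(pattern_terms(d, p))),
               stringsAsFactors = FALSE)
  }))
  repf <- reverse_engineer_check(full, d)
  expect_true(repf$complete)
  expect_true(all(repf$per_pattern$status == "completely simulated"))
  expect_true(all(lengths(repf$unused_terms) == 0L))

  # partial coverage: only one term of one pattern
  part <- full[1L, ]
  part$terms <- I(list(pattern_terms(d, part$pattern)[1L]))
  repp <- reverse_engineer_check(part, d)
  st <- repp$per_pattern$status
  expect_identical(st[repp$per_pattern$pattern == part$pattern],
                   "partially simulated")
  expect_true(all(st[repp$per_pattern$pattern != part$pattern] == "not used"))

  bogus <- full[1L, ]
  bogus$pattern <- "no such pattern"
  expect_error(reverse_engineer_check(bogus, d), "unknown pattern")
})
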