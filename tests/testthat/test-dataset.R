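test_that("term normalization case-folds, trims, collapses whitespace and is idempotent", {
  expect_identical(normalize_term("Dry Tongue "), "dry tongue")
  expect_identical(normalize_term("  Pale\t FACE"), "pale face")
  expect_identical(normalize_term("dry tongue"), "dry tongue")
  x <- normalize_term(c(" Acute  Headache", "TINNITUS "))
  expect_identical(normalize_term(x), x)
  expect_error(normalize_term("   "), "empty")
  expect_error(normalize_term("acute, headache"), "comma")
})

test_that("intra-pattern validation finds every duplicated method pair", {
  clean <- pattern_dataset(list(p = list(Ip = "a", Iq = "b")))
  expect_identical(nrow(validate_intra_pattern(clean)), 0L)

  dup <- pattern_dataset(list(p = list(Ip = "a", Iq = "a")))
  v <- validate_intra_pattern(dup)
  expect_identical(v$term, "a")
  expect_identical(c(v$method1, v$method2), c("Ip", "Iq"))

  # brute-force expectation: b occurs in Ip, AO and P -> all three pairs
  multi <- pattern_dataset(list(p = list(Ip = c("a", "b"), AO = "b", P = "b")))
  v <- validate_intra_pattern(multi)
  expect_identical(nrow(v), 3L)
  expect_setequal(paste(v$method1, v$method2), c("Ip AO", "Ip P", "AO P"))
})

test_that("inter-pattern validation matches brute-force profile comparison", {
  same <- list(Ip = c("a", "b"), Iq = "c")
  d2 <- pattern_dataset(list(p1 = same, p2 = same))
  expect_identical(nrow(validate_inter_pattern(d2)), 1L)

  d3 <- pattern_dataset(list(p1 = same, p2 = same, p3 = same))
  expect_identical(nrow(validate_inter_pattern(d3)), 3L)

  set.seed(41)
  for (rep in 1:5) {
    d <- random_toy_dataset(n_patterns = sample(4:8, 1L))
    got <- validate_inter_pattern(d)
    pats <- pattern_names(d)
    expected <- 0L
    for (i in seq_len(length(pats) - 1L)) for (j in seq(i + 1L, length(pats))) {
      identical_profile <- all(vapply(exam_methods(), function(m) {
        setequal(d$patterns[[pats[i]]][[m]], d$patterns[[pats[j]]][[m]])
      }, logical(1L)))
      if (identical_profile) expected <- expected + 1L
    }
    expect_identical(nrow(got), expected)
  }
  expect_identical(nrow(validate_inter_pattern(toy_dataset())), 0L)
})

test_that("restriction keeps emptied patterns flagged and recomputes N_T", {
  d <- toy_dataset()
  full <- restrict_dataset(d, exam_methods())
  expect_identical(full$patterns, d$patterns)

  ip <- restrict_dataset(d, "Ip")
  expect_identical(empty_patterns(ip), "kidney yin deficiency")
  expect_identical(unname(n_manifestations(ip)["kidney yin deficiency"]), 0L)
  expect_identical(n_manifestations(d, "Ip"),
                   vapply(d$patterns, function(p) length(p$Ip), integer(1L)))
  # accounting: restricted N_T totals equal restricted long-form row count
  for (combo in canonical_combos()) {
    expect_identical(sum(n_manifestations(d, combo)),
                     nrow(as.data.frame(restrict_dataset(d, combo))))
  }
})

test_that("dataset summary reports counts, percentages and count ranges", {
  one <- pattern_dataset(list(p = list(Ip = "pale face")))
  s <- summarize_dataset(one)
  ip <- s[s$method == "Ip", ]
  expect_identical(ip$n_terms, 1L)
  expect_equal(ip$pct, 100)
  expect_equal(c(ip$median, ip$min, ip$max), c(1, 1, 1))
  ao <- s[s$method == "AO", ]
  expect_identical(ao$n_terms, 0L)
  expect_equal(ao$pct, 0)
  expect_equal(c(ao$median, ao$min, ao$max), c(0, 0, 0))
})

test_that("serialization round-trips through TSV and JSON", {
  d <- toy_dataset()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_dataset(d, tsv)
  expect_identical(read_pattern_dataset(tsv)$patterns, d$patterns)

  js <- withr::local_tempfile(fileext = ".json")
  write_pattern_dataset(d, js)
  expect_identical(read_pattern_dataset(js)$patterns, d$patterns)
})

test_that("malformed files are rejected and duplicate records deduplicated", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pattern\tmethod\tmanifestation", "p1\tXX\tpale face"), bad)
  expect_error(read_pattern_dataset(bad), "unknown method")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pattern\tmethod\tmanifestation",
               "p1\tIp\tpale face", "p1\tIp\tpale face", "p1\tIq\tfatigue"),
             dup)
  expect_warning(d <- read_pattern_dataset(dup), "duplicated")
  # set-union oracle: the deduplicated sets
  expect_identical(d$patterns$p1$Ip, "pale face")
  expect_identical(d$patterns$p1$Iq, "fatigue")
  expect_identical(sum(n_manifestations(d)), 2L)
})

test_that("examination combinations parse, order and reject bad input", {
  expect_identical(exam_combo("Ip+AO"), c("Ip", "AO"))
  expect_identical(exam_combo(c("Iq", "Ip")), c("Ip", "Iq"))
  expect_identical(combo_label(c("P", "Ip")), "Ip+P")
  expect_error(exam_combo("Ip+XX"), "unknown")
  expect_error(exam_combo(c("Ip", "Ip")), "duplicate")
  expect_identical(names(canonical_combos()),
                   c("Ip", "Ip+AO", "Ip+AO+Iq", "Ip+AO+Iq+P"))
})
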