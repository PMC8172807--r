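# Instrument scoring: ranges, reverse keying, skip logic, completeness.

test_that("all-min and all-max answers hit the declared range endpoints", {
  # (scale, minimising answer pattern, maximising answer pattern)
  cases <- list(
    cpss = list(min = 0, max = 3),
    phqa = list(min = 0, max = 3),
    hads = list(min = c(3, 3, 3, 0, 0, 3, 3), max = c(0, 0, 0, 3, 3, 0, 0)),
    rosenberg = list(min = c(3, 0, 3, 3, 0, 0, 3, 0, 0, 3),
                     max = c(0, 3, 0, 0, 3, 3, 0, 3, 3, 0)),
    kidscreen = list(min = c(0, 0, 4, 4, 0, 0, 0, 0, 0, 0, 4),
                     max = c(4, 4, 0, 0, 4, 4, 4, 4, 4, 4, 0)),
    cyrm = list(min = 0, max = 4)
  )
  for (id in names(cases)) {
    def <- scale_def(id)
    s_min <- set_items(blank_survey(), id, cases[[id]]$min,
                       items = def$scored)
    s_max <- set_items(blank_survey(), id, cases[[id]]$max,
                       items = def$scored)
    expect_identical(score_scale(s_min, def)$total, def$range[1],
                     label = paste(id, "min"))
    expect_identical(score_scale(s_max, def)$total, def$range[2],
                     label = paste(id, "max"))
  }
  # CRAFFT endpoints through its own scorer
  s0 <- set_items(blank_survey(), "crafft", 1, items = 1:4)
  expect_identical(score_crafft(s0)$total, 0L)
  s6 <- set_items(blank_survey(), "crafft", 0, items = 1:9)
  expect_identical(score_crafft(s6)$total, 6L)
})

test_that("random complete responses stay within the declared range", {
  set.seed(71)
  defs <- scale_definitions()
  for (id in setdiff(scale_ids(), c("crafft", "tobacco"))) {
    def <- defs[[id]]
    for (rep in 1:25) {
      ans <- vapply(def$levels[def$scored],
                    function(L) sample.int(L, 1L) - 1L, integer(1))
      s <- blank_survey()
      s[, paste0(id, "_q", def$scored)] <- as.list(ans)
      tot <- score_scale(s, def)$total
      expect_true(tot >= def$range[1] && tot <= def$range[2])
    }
  }
})

test_that("worked examples: Rosenberg all-agree and PHQ-A all-several-days", {
  # all "Strongly agree": positives 3 each, negatives reverse to 0
  s <- set_items(blank_survey(), "rosenberg", 0)
  expect_identical(score_scale(s, "rosenberg")$total, 15L)
  # PHQ-A items 1-9 all "Several days" -> 9 x 1
  s <- set_items(blank_survey(), "phqa", 1, items = 1:9)
  expect_identical(score_scale(s, "phqa")$total, 9L)
})

test_that("reverse-keying involution: flipping an answer flips the score", {
  set.seed(72)
  defs <- scale_definitions()
  for (id in c("hads", "rosenberg", "kidscreen")) {
    def <- defs[[id]]
    for (j in def$reverse) {
      L <- def$levels[j]
      map <- def$score_maps[[j]]
      a <- sample.int(L, 1L) - 1L
      expect_identical(map[a + 1L] + map[(L - 1L - a) + 1L], L - 1L)
    }
  }
})

test_that("missing scored items break completeness; skipped items do not", {
  s <- set_items(blank_survey(), "phqa", 2, items = 1:9)
  s$phqa_q5 <- NA_integer_
  sc <- score_scale(s, "phqa")
  expect_false(sc$complete)
  expect_true(is.na(sc$total))

  # PHQ-A q10/q11 unasked when q9 = 0: total still complete
  s <- set_items(blank_survey(), "phqa", 0, items = 1:9)
  expect_true(score_scale(s, "phqa")$complete)

  # CRAFFT part B skipped: scoreable from item 4 alone
  s <- set_items(blank_survey(), "crafft", 1, items = 1:3)
  s$crafft_q4 <- 0L
  sc <- score_crafft(s)
  expect_identical(sc$total, 1L)
  expect_true(sc$complete)
})

test_that("CRAFFT counts stray part-B answers with a warning", {
  s <- set_items(blank_survey(), "crafft", 1, items = 1:4)
  s$crafft_q7 <- 0L                    # answered despite all-'no' part A
  expect_warning(sc <- score_crafft(s), "despite")
  expect_identical(sc$total, 1L)
})

test_that("scoring is deterministic and ignores answer-entry order", {
  set.seed(73)
  s <- set_items(blank_survey(), "cpss", sample(0:3, 17, replace = TRUE),
                 items = 3:19)
  t1 <- score_scale(s, "cpss")$total
  shuffled <- s[, sample(names(s))]
  expect_identical(score_scale(shuffled, "cpss")$total, t1)
  expect_identical(score_scale(s, "cpss")$total, t1)
})

test_that("tobacco use tri-state logic", {
  s <- blank_survey()
  s$tobacco_q1 <- 0L; s$tobacco_q2 <- 1L
  expect_true(assess_tobacco_use(s))
  s$tobacco_q1 <- 1L
  expect_false(assess_tobacco_use(s))
  s$tobacco_q1 <- NA_integer_; s$tobacco_q2 <- 0L
  expect_true(assess_tobacco_use(s))        # "either" satisfiable
  s$tobacco_q2 <- NA_integer_
  expect_true(is.na(assess_tobacco_use(s)))
  s$tobacco_q2 <- 1L
  expect_true(is.na(assess_tobacco_use(s))) # one missing, other not yes
})

test_that("suicidal thinking skip logic", {
  s <- blank_survey()
  s$phqa_q9 <- 0L
  expect_false(assess_suicidal_thinking(s))  # q10 unasked
  s$phqa_q9 <- 1L; s$phqa_q10 <- 0L
  expect_true(assess_suicidal_thinking(s))
  s$phqa_q10 <- 1L
  expect_false(assess_suicidal_thinking(s))
  s$phqa_q10 <- NA_integer_
  expect_true(is.na(assess_suicidal_thinking(s)))
  # stray q10 despite q9 = "Not at all": ignored with a warning
  s$phqa_q9 <- 0L; s$phqa_q10 <- 0L
  expect_warning(res <- assess_suicidal_thinking(s), "ignored")
  expect_false(res)
})

test_that("out-of-range answer indices are rejected", {
  s <- blank_survey()
  s$phqa_q1 <- 4L
  expect_error(score_scale(s, "phqa"), "out of range")
  expect_error(scale_def("nope"), "unknown scale id")
})

test_that("per-item maxima sum to the declared range for every scale", {
  for (id in setdiff(scale_ids(), "tobacco")) {
    def <- scale_def(id)
    maxima <- vapply(def$score_maps[def$scored], max, integer(1))
    minima <- vapply(def$score_maps[def$scored], min, integer(1))
    expect_identical(sum(maxima), def$range[2], label = id)
    expect_identical(sum(minima), def$range[1], label = id)
  }
})
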