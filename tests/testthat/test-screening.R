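# Exclusion criteria and cut-off diagnoses.

test_that("age extremes are excluded, plain ages retained", {
  s1 <- consistent_survey(age = "10 years or less")
  s2 <- consistent_survey(age = "20 years or more")
  s3 <- consistent_survey(age = "14")
  rep <- apply_exclusions(rbind(s1, s2, s3))
  expect_identical(rep$decision, c("age_low", "age_high", "included"))
  expect_identical(rep$included$age, 14L)
  expect_identical(rep$ledger$count[rep$ledger$criterion == "included"], 1L)
})

test_that("contradictory Rosenberg straight-lining is excluded", {
  s <- consistent_survey()
  s <- set_items(s, "rosenberg", 0)          # endorse everything
  rep <- apply_exclusions(s)
  expect_identical(rep$decision, "rosenberg_inconsistent")
  s <- set_items(s, "rosenberg", 3)          # reject everything
  expect_identical(apply_exclusions(s)$decision, "rosenberg_inconsistent")
  # honest mixed pattern is retained
  expect_identical(apply_exclusions(consistent_survey())$decision,
                   "included")
})

test_that("Rosenberg/Kidscreen discordance rule fires in both directions", {
  s <- consistent_survey()
  s <- set_items(s, "rosenberg", 0, items = c(1, 3, 4, 7, 10))  # top SE
  s <- set_items(s, "rosenberg", 3, items = c(2, 5, 6, 8, 9))
  s <- set_items(s, "kidscreen", 0, items = setdiff(1:11, c(3, 4, 11)))
  s <- set_items(s, "kidscreen", 4, items = c(3, 4, 11))        # bottom QoL
  expect_identical(apply_exclusions(s)$decision,
                   "rosenberg_kidscreen_inconsistent")
  s2 <- consistent_survey()
  s2 <- set_items(s2, "rosenberg", 3, items = c(1, 3, 4, 7, 10)) # bottom SE
  s2 <- set_items(s2, "rosenberg", 0, items = c(2, 5, 6, 8, 9))
  s2 <- set_items(s2, "kidscreen", 4, items = setdiff(1:11, c(3, 4, 11)))
  s2 <- set_items(s2, "kidscreen", 0, items = c(3, 4, 11))       # top QoL
  expect_identical(apply_exclusions(s2)$decision,
                   "rosenberg_kidscreen_inconsistent")
})

test_that("HADS reversed-key straight-lining is excluded", {
  s <- consistent_survey()
  s <- set_items(s, "hads", 0)
  expect_identical(apply_exclusions(s)$decision, "hads_inconsistent")
  s <- set_items(s, "hads", 3)
  expect_identical(apply_exclusions(s)$decision, "hads_inconsistent")
  # straight-lining at an interior position scores a gap of 1, not 3
  s <- set_items(s, "hads", 1)
  expect_identical(apply_exclusions(s)$decision, "included")
})

test_that("criterion precedence: first matching criterion is recorded", {
  s <- consistent_survey(age = "10 years or less")
  s <- set_items(s, "rosenberg", 0)
  expect_identical(apply_exclusions(s)$decision, "age_low")
  s2 <- consistent_survey()
  s2 <- set_items(s2, "rosenberg", 0)
  s2 <- set_items(s2, "hads", 0)
  expect_identical(apply_exclusions(s2)$decision, "rosenberg_inconsistent")
})

test_that("ledger conservation and idempotence on random cohorts", {
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_config(n_per_year = c(150, 150, 150),
                                         seed = seed,
                                         inconsistent_rate = 0.1,
                                         age_oor_rate = 0.05))
    rep <- apply_exclusions(coh)
    lg <- rep$ledger
    cnt <- function(id) lg$count[lg$criterion == id]
    expect_identical(cnt("collected"),
                     cnt("included") +
                       sum(lg$count[!lg$criterion %in%
                                      c("collected", "included")]))
    expect_identical(nrow(rep$included), cnt("included"))
    # idempotence: re-screening the included subset excludes nothing
    inc <- rep$included
    inc$age <- as.character(inc$age)
    rep2 <- apply_exclusions(inc)
    expect_identical(nrow(rep2$included), nrow(inc))
  }
})

test_that("cut-off boundary exactness for every flag", {
  th <- diagnosis_thresholds()
  mk <- function(col, tot) {
    df <- data.frame(x = c(tot - 1L, tot, NA_integer_))
    names(df) <- col
    df
  }
  cases <- list(
    c("cpss_total", "probable_ptsd", th$cpss_ptsd),
    c("phqa_total", "probable_depression", th$phqa_depression),
    c("phqa_total", "probable_msd", th$phqa_moderately_severe),
    c("hads_total", "probable_anxiety", th$hads_anxiety),
    c("crafft_total", "probable_sud", th$crafft_disorder)
  )
  base <- data.frame(cpss_total = NA_integer_, phqa_total = NA_integer_,
                     hads_total = NA_integer_, crafft_total = NA_integer_)
  for (cs in cases) {
    df <- base[rep(1, 3), ]
    df[[cs[1]]] <- c(as.integer(cs[3]) - 1L, as.integer(cs[3]), NA_integer_)
    out <- derive_diagnoses(df, th)
    expect_identical(out[[cs[2]]], c(FALSE, TRUE, NA), label = cs[2])
  }
})

test_that("raising a threshold never increases positives", {
  sc <- small_cohort(n = 450, seed = 4)
  n_pos <- function(cut) {
    sum(derive_diagnoses(sc, diagnosis_thresholds(cpss_ptsd = cut))
        $probable_ptsd, na.rm = TRUE)
  }
  counts <- vapply(c(10L, 15L, 20L, 25L), n_pos, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("any-of-4 union logic with partial batteries", {
  df <- data.frame(
    cpss_total = c(20L, NA, NA, 5L),
    phqa_total = c(5L, 5L, NA, 5L),
    hads_total = c(NA, 5L, NA, 5L),
    crafft_total = c(0L, 0L, NA, 0L)
  )
  out <- derive_diagnoses(df)
  # one positive suffices even with HADS missing
  expect_identical(out$any_of_4, c(TRUE, NA, NA, FALSE))
  # implication: moderately severe depression => depression
  sc <- small_cohort(n = 450, seed = 5)
  msd <- sc$probable_msd %in% TRUE
  expect_true(all(sc$probable_depression[msd] %in% TRUE))
  # any-of-4 positive implies a positive component
  pos4 <- sc$any_of_4 %in% TRUE
  comp <- cbind(sc$probable_ptsd, sc$probable_depression,
                sc$probable_anxiety, sc$probable_sud)[pos4, , drop = FALSE]
  expect_true(all(rowSums(comp, na.rm = TRUE) > 0))
})

test_that("thresholds outside the scale range are rejected", {
  expect_error(diagnosis_thresholds(cpss_ptsd = 60L), "outside")
  expect_error(diagnosis_thresholds(crafft_disorder = 0L), "outside")
})
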