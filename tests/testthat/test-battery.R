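# Battery orchestration: shape, determinism, complete-case Ns, FDR family,
# the age-restricted sensitivity run, and descriptive summaries.

test_that("default battery enumerates exactly 15 x 5 = 75 tests", {
  sc <- small_cohort(n = 1800, seed = 11)   # all gender cells above floor
  rep <- run_battery(sc, permutations = 99, seed = 12)
  expect_identical(nrow(rep$tests), 75L)
  expect_identical(nrow(unique(rep$tests[, c("measure", "effect")])), 75L)
  expect_identical(sum(rep$tests$kind == "continuous"), 35L)  # 7 x 5
  expect_identical(sum(rep$tests$kind == "binary"), 40L)      # 8 x 5
  expect_true(all(rep$tests$n <= nrow(sc)))
  # FDR is one family across the whole battery
  expect_identical(rep$fdr$m, 75L)
  expect_identical(sum(rep$tests$fdr_rejected, na.rm = TRUE),
                   rep$fdr$n_rejected)
})

test_that("identical input and seed give identical reports", {
  sc <- small_cohort(n = 400, seed = 13)
  r1 <- run_battery(sc, permutations = 199, seed = 14)
  r2 <- run_battery(sc, permutations = 199, seed = 14)
  expect_identical(r1$tests, r2$tests)
})

test_that("per-measure Ns differ when item missingness is planted", {
  sc <- small_cohort(n = 2000, seed = 15)
  rep <- run_battery(sc, permutations = 9, seed = 16, effects = "time")
  ns <- rep$tests$n[rep$tests$kind == "continuous"]
  expect_gt(length(unique(ns)), 3)
  # heaviest-missingness scale has the smallest complete-case N
  expect_identical(rep$tests$measure[which.min(rep$tests$n)], "cpss")
})

test_that("nuisance column order does not change slope or p", {
  sc <- small_cohort(n = 500, seed = 17)
  y <- as.numeric(sc$phqa_total)
  d <- build_design(sc, "time", y)
  perm <- c(1L, 4L, 6L, 2L, 5L, 3L)       # effect stays first
  d2 <- d
  d2$X <- d$X[, perm]
  expect_equal(fit_slope(d), fit_slope(d2), tolerance = 1e-10)
  p1 <- permutation_test(d, perm_config(499, 18))$p
  p2 <- permutation_test(d2, perm_config(499, 18))$p
  expect_lt(abs(p1 - p2), 2 / 500)
})

test_that("tests under the N floor are skipped and leave the FDR family", {
  sc <- small_cohort(n = 500, seed = 19)
  sc <- sc[sc$gender != "other", ]        # empty comparison group
  expect_message(
    rep <- run_battery(sc, permutations = 49, seed = 20),
    "skipped"
  )
  sk <- rep$tests$effect == "other_vs_fm"
  expect_true(all(is.na(rep$tests$p[sk])))
  expect_identical(rep$fdr$m, 60L)
  expect_identical(length(rep$skipped), 15L)
})

test_that("age-restricted run: no extreme ages means identical slopes", {
  sc <- small_cohort(n = 600, seed = 21)
  mid <- sc[sc$age >= 12 & sc$age <= 17, ]
  full <- run_battery(mid, permutations = 99, seed = 22, effects = "age")
  restr <- run_age_restricted(mid, permutations = 99, seed = 22)
  expect_equal(restr$tests$slope, full$tests$slope)
  expect_identical(restr$tests$n, full$tests$n)
})

test_that("an 18-19-only suicidality excess vanishes when ages restricted", {
  # null plants: no age trend anywhere except the constructed 18-19 excess
  cfg <- null_cohort_config(n_per_year = c(2000, 2000, 2000), seed = 23)
  coh <- generate_cohort(cfg)
  old <- parse_age_years(coh$age) >= 18
  # plant: most 18-19-year-olds with any item-9 signal endorse item 10
  boost <- old & !is.na(coh$phqa_q9) & coh$phqa_q9 >= 1
  coh$phqa_q10[boost] <- 0L
  sc <- prepare_surveys(coh)$data
  y <- 100 * as.numeric(sc$suicidal_thinking)
  p_full <- permutation_test(build_design(sc, "age", y),
                             perm_config(999, 24))$p
  sub <- sc[sc$age <= 17, ]
  p_restr <- permutation_test(build_design(sub, "age",
                                           100 * as.numeric(
                                             sub$suicidal_thinking)),
                              perm_config(999, 24))$p
  expect_lt(p_full, 0.01)
  expect_gt(p_restr, 0.05)
})

test_that("summaries: single survey, percentage sums, analytic mean age", {
  one <- consistent_survey(year = 2018L, age = "16", gender = "other")
  one$age <- 16L
  sm <- summarize_cohort(one)
  expect_equal(as.numeric(sm$gender_pct["other"]), 100)
  expect_equal(as.numeric(sm$age_pct["16"]), 100)

  sc <- small_cohort(n = 900, seed = 25)
  sm <- summarize_cohort(sc)
  expect_equal(sum(sm$gender_pct), 100)
  expect_equal(sum(sm$age_pct), 100)
  expect_equal(unname(rowSums(sm$age_by_gender_pct)), rep(100, 4))

  # realised mean age tracks the analytic mean of the sampling mixture
  coh <- generate_cohort(cohort_config(seed = 26, inconsistent_rate = 0,
                                       age_oor_rate = 0))
  ap <- schoolmh:::AGE_PCT
  ny <- c(3070, 3265, 3041)
  analytic <- sum(vapply(1:3, function(i) {
    ny[i] * sum(11:19 * ap[i + 1, ] / sum(ap[i + 1, ]))
  }, numeric(1))) / sum(ny)
  expect_lt(abs(mean(parse_age_years(coh$age)) - analytic), 0.05)
})

test_that("command-line interface round trip", {
  out <- file.path(tempdir(), "cli_test")
  on.exit(unlink(out, recursive = TRUE))
  cohort <- generate_cohort(cohort_config(n_per_year = c(120, 120, 120),
                                          seed = 27))
  dir.create(out, showWarnings = FALSE)
  csv <- file.path(out, "in.csv")
  write_surveys(cohort, csv)
  suppressMessages(schoolmh_main(c("screen", "--input", csv,
                                   "--output-dir", out)))
  expect_true(file.exists(file.path(out, "exclusion_ledger.tsv")))
  suppressMessages(schoolmh_main(c("analyze", "--input", csv,
                                   "--output-dir", out,
                                   "--permutations", "49",
                                   "--seed", "3")))
  bt <- utils::read.delim(file.path(out, "battery.tsv"))
  expect_identical(nrow(bt), 75L)
  expect_true(file.exists(file.path(out, "run_metadata.json")))
})
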