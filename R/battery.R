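# Orchestration of the full analysis: 15 dependent measures x 5 effects =
# 75 permutation tests with per-measure complete-case filtering, one
# Benjamini-Hochberg correction across the whole battery, descriptive
# tables, and the age-restricted sensitivity re-run.

CONTINUOUS_MEASURES <- c("cpss", "phqa", "hads", "crafft", "rosenberg",
                         "kidscreen", "cyrm")
BINARY_MEASURES <- c("probable_ptsd", "probable_depression", "probable_msd",
                     "suicidal_thinking", "probable_anxiety", "probable_sud",
                     "tobacco_use", "any_of_4")

#' The default battery of dependent measures
#'
#' @return Data frame with columns `measure` (id), `kind` (`"continuous"` or
#'   `"binary"`) and `column` (source column in a scored survey table):
#'   seven instrument totals and eight screening rates, 15 measures in all.
#' @export
measure_specs <- function() {
  data.frame(
    measure = c(CONTINUOUS_MEASURES, BINARY_MEASURES),
    kind = c(rep("continuous", length(CONTINUOUS_MEASURES)),
             rep("binary", length(BINARY_MEASURES))),
    column = c(paste0(CONTINUOUS_MEASURES, "_total"), BINARY_MEASURES)
  )
}

# Dependent-variable vector for one measure: instrument total, or the
# tri-state flag coded 0/100 so slopes are in percentage points.
measure_values <- function(scored, measure) {
  spec <- measure_specs()
  row <- spec[spec$measure == measure, ]
  if (nrow(row) != 1L) stop("unknown measure: ", measure, call. = FALSE)
  v <- scored[[row$column]]
  if (row$kind == "binary") as.numeric(v) * 100 else as.numeric(v)
}

#' Screen and score raw surveys
#'
#' Pipeline front end: applies the exclusion criteria, scores every
#' instrument and derives the diagnosis flags.
#'
#' @param raw Raw parsed surveys (see [read_surveys()] or
#'   [generate_cohort()]).
#' @param rules Consistency-rule parameters ([consistency_rules()]).
#' @param thresholds Diagnosis cut-offs ([diagnosis_thresholds()]).
#' @return List with `data` (screened + scored surveys) and `exclusions`
#'   (the `exclusion_report`).
#' @export
prepare_surveys <- function(raw, rules = consistency_rules(),
                            thresholds = diagnosis_thresholds()) {
  excl <- apply_exclusions(raw, rules)
  scored <- derive_diagnoses(score_surveys(excl$included), thresholds)
  list(data = scored, exclusions = excl)
}

# Deterministic per-test seed table: one master seed, one stream per
# (measure, effect) cell of the canonical grid, so battery results do not
# depend on evaluation order.
test_seeds <- function(seed, measures, effects) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  grid <- expand.grid(measure = measures, effect = effects,
                      stringsAsFactors = FALSE)
  grid$seed <- sample.int(2147483646L, nrow(grid))
  grid
}

#' Run the permutation-test battery
#'
#' For every (measure, effect) pair: applies the effect's gender inclusion
#' filter and the measure's complete-case filter, builds the design matrix,
#' fits the slope, computes the permutation p-value, then applies one
#' Benjamini-Hochberg correction across all retained tests. Tests whose
#' complete-case sample is below `n_floor` are skipped with a logged reason
#' and excluded from the FDR family.
#'
#' @param scored Screened, scored surveys (from [prepare_surveys()]).
#' @param permutations Permutation count B per test (default 100000).
#' @param seed Master seed; per-test streams are derived from it.
#' @param alpha FDR level (default 0.05).
#' @param scheme Permutation scheme (see [perm_config()]).
#' @param n_floor Minimum per-test N (default 10).
#' @param effects Effect ids to test (default all five).
#' @param measures Measure ids to test (default all 15).
#' @return A list of class `battery_report`: `tests` (one row per test:
#'   measure, effect, kind, n, slope, p, fdr flag), `fdr` (the
#'   `fdr_result`), `skipped`, `demographics` (from [summarize_cohort()]),
#'   and `meta` (seed, B, alpha, scheme, age range).
#' @export
run_battery <- function(scored, permutations = 100000L, seed = 1L,
                        alpha = 0.05, scheme = "effect", n_floor = 10L,
                        effects = EFFECT_IDS,
                        measures = measure_specs()$measure) {
  spec <- measure_specs()
  spec <- spec[spec$measure %in% measures, ]
  seeds <- test_seeds(seed, spec$measure, effects)
  rows <- vector("list", nrow(seeds))
  skipped <- character(0)
  for (k in seq_len(nrow(seeds))) {
    ms <- seeds$measure[k]
    ef <- seeds$effect[k]
    y <- measure_values(scored, ms)
    es <- effect_spec(ef)
    usable <- scored$gender %in% es$genders & !is.na(y) &
      !is.na(scored$age)
    # the floor applies to the smallest cell of the comparison: for gender
    # contrasts that is the comparison group itself vs the reference
    n_ok <- if (ef %in% c("time", "age")) {
      sum(usable)
    } else {
      x <- effect_values(scored, ef)
      min(sum(usable & x == 1), sum(usable & x == 0))
    }
    if (n_ok < n_floor) {
      skipped <- c(skipped, sprintf("%s/%s: smallest cell n=%d below floor %d",
                                    ms, ef, n_ok, n_floor))
      rows[[k]] <- data.frame(measure = ms, effect = ef,
                              kind = spec$kind[spec$measure == ms],
                              n = n_ok, slope = NA_real_, p = NA_real_)
      next
    }
    design <- build_design(scored, es, y)
    res <- permutation_test(design,
                            perm_config(permutations, seeds$seed[k],
                                        scheme))
    rows[[k]] <- data.frame(measure = ms, effect = ef,
                            kind = spec$kind[spec$measure == ms],
                            n = res$n, slope = res$beta1, p = res$p)
  }
  tests <- do.call(rbind, rows)
  # canonical table order: effect blocks, continuous measures first
  tests <- tests[order(match(tests$effect, EFFECT_IDS),
                       match(tests$measure, spec$measure)), ]
  rownames(tests) <- NULL
  tested <- !is.na(tests$p)
  fdr <- bh_fdr(tests$p[tested], alpha)
  tests$fdr_rejected <- NA
  tests$fdr_rejected[tested] <- fdr$rejected
  if (length(skipped) > 0L) {
    message("skipped tests (excluded from FDR family):\n  ",
            paste(skipped, collapse = "\n  "))
  }
  structure(list(tests = tests, fdr = fdr, skipped = skipped,
                 demographics = summarize_cohort(scored),
                 meta = list(seed = seed, permutations = permutations,
                             alpha = alpha, scheme = scheme,
                             age_range = range(scored$age, na.rm = TRUE),
                             n_surveys = nrow(scored))),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("Permutation-test battery: %d tests on %d surveys (B = %d)\n",
              nrow(x$tests), x$meta$n_surveys, x$meta$permutations))
  cat(sprintf("FDR (Benjamini-Hochberg, alpha = %.3g): %d rejected, ",
              x$meta$alpha, x$fdr$n_rejected))
  cat(sprintf("realised threshold p = %.5g\n", x$fdr$threshold))
  df <- x$tests
  df$slope <- round(df$slope, 2)
  df$p <- round(df$p, 5)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Age-restricted sensitivity re-run of the age effect
#'
#' Re-runs the 15 age-effect tests on the subset within `age_range`
#' (default 12-17, dropping the sparse extremes) and flags which
#' conclusions change relative to a baseline report.
#'
#' @param scored Screened, scored surveys.
#' @param baseline Optional `battery_report` whose age-effect conclusions
#'   are compared against.
#' @param age_range Inclusive integer age range (default `c(12, 17)`).
#' @inheritParams run_battery
#' @return A `battery_report` over the 15 age tests, with an extra
#'   `changes` element when `baseline` is supplied (measures whose FDR
#'   conclusion flipped).
#' @export
run_age_restricted <- function(scored, baseline = NULL,
                               age_range = c(12L, 17L),
                               permutations = 100000L, seed = 1L,
                               alpha = 0.05, scheme = "effect",
                               n_floor = 10L) {
  sub <- scored[!is.na(scored$age) & scored$age >= age_range[1] &
                  scored$age <= age_range[2], , drop = FALSE]
  rep <- run_battery(sub, permutations = permutations, seed = seed,
                     alpha = alpha, scheme = scheme, n_floor = n_floor,
                     effects = "age")
  rep$meta$age_range <- age_range
  if (!is.null(baseline)) {
    base_age <- baseline$tests[baseline$tests$effect == "age", ]
    m <- merge(rep$tests[, c("measure", "fdr_rejected")],
               base_age[, c("measure", "fdr_rejected")],
               by = "measure", suffixes = c("_restricted", "_full"))
    rep$changes <- m[xor(m$fdr_rejected_restricted, m$fdr_rejected_full) %in%
                       TRUE, ]
  }
  rep
}

# --- descriptive summaries --------------------------------------------------

pct <- function(x) 100 * x / sum(x)

mean_sd <- function(v) {
  v <- v[!is.na(v)]
  c(n = length(v), mean = mean(v), sd = stats::sd(v))
}

#' Descriptive demographic and measure summaries
#'
#' Emits the demographic distribution tables (per year, per gender, per age,
#' age by gender, as percentages) and per-group measure descriptives
#' (mean and SD per year/age/gender for the instrument totals; rate percent
#' per group for the binary measures).
#'
#' @param scored Screened (and possibly scored) surveys.
#' @return List with `n`, `gender_pct`, `age_pct`, `age_by_gender_pct`,
#'   `year_n`, and (when score columns are present) `by_year`, `by_age`,
#'   `by_gender` data frames of group descriptives.
#' @export
summarize_cohort <- function(scored) {
  out <- list(n = nrow(scored))
  out$year_n <- table(factor(scored$year, levels = c(2017, 2018, 2019)))
  g <- factor(scored$gender, levels = GENDERS)
  a <- factor(scored$age, levels = 11:19)
  out$gender_pct <- pct(table(g))
  out$age_pct <- pct(table(a))
  out$age_by_gender_pct <- t(apply(table(g, a), 1L, pct))

  spec <- measure_specs()
  if (all(spec$column %in% names(scored))) {
    grp_tab <- function(group) {
      groups <- sort(unique(stats::na.omit(group)))
      do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
        v <- measure_values(scored, spec$measure[i])
        do.call(rbind, lapply(groups, function(gv) {
          sel <- !is.na(group) & group == gv & !is.na(v)
          if (spec$kind[i] == "continuous") {
            data.frame(measure = spec$measure[i], group = as.character(gv),
                       n = sum(sel), mean = mean(v[sel]),
                       sd = stats::sd(v[sel]), rate = NA_real_)
          } else {
            data.frame(measure = spec$measure[i], group = as.character(gv),
                       n = sum(sel), mean = NA_real_, sd = NA_real_,
                       rate = mean(v[sel]))
          }
        }))
      }))
    }
    out$by_year <- grp_tab(scored$year)
    out$by_age <- grp_tab(scored$age)
    out$by_gender <- grp_tab(scored$gender)
  }
  out
}

#' Mean and SD of a categorical age distribution
#'
#' Weighted moments of integer ages under a percentage (or count)
#' distribution; the SD is the population standard deviation of the
#' categorical distribution.
#'
#' @param weights Numeric vector of weights, named by age or aligned with
#'   `ages`.
#' @param ages Integer ages (default taken from `names(weights)`).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
age_distribution_moments <- function(weights, ages = NULL) {
  if (is.null(ages)) ages <- as.numeric(names(weights))
  stopifnot(length(ages) == length(weights), all(weights >= 0))
  w <- weights / sum(weights)
  m <- sum(w * ages)
  c(mean = m, sd = sqrt(sum(w * (ages - m)^2)))
}

# --- published calibration fixtures ----------------------------------------

#' Published battery p-values
#'
#' The 75 p-values printed in the published results tables of the 2017-2019
#' Fort McMurray school survey analysis (15 measures x 5 effects), shipped
#' as a package fixture for exercising the FDR step alone.
#'
#' @return Data frame with columns `effect`, `measure`, `p`, `published_fdr`
#'   (whether the published table marks the test significant).
#' @export
published_pvalues <- function() {
  path <- system.file("extdata", "published_battery_pvalues.tsv",
                      package = "schoolmh", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published survey counts and demographic distributions
#'
#' @return List with `counts` (collected / included / enrolled per year),
#'   `gender_pct` and `age_pct` matrices (rows: all, 2017, 2018, 2019).
#' @export
published_demographics <- function() {
  list(counts = SURVEY_COUNTS, gender_pct = GENDER_PCT, age_pct = AGE_PCT)
}
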