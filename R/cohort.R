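# Synthetic survey cohort generator.
#
# The generator emulates the published 2017-2019 Fort McMurray school survey
# at the item level: demographic structure (per-year sample sizes, age and
# gender distributions) matching the published demographic table; per-measure
# latent severities that are linear in time, age and gender-identity offsets
# with Gaussian noise on the total-score axis; item answers produced from the
# latent totals by largest-remainder allocation honouring skip rules and
# reverse keying; and configurable rates of item missingness, inconsistent
# responders (violating the screening rules) and out-of-range ages.

# --- published calibration constants ---------------------------------------

# Survey counts and enrolment (recruitment = included / enrolled).
SURVEY_COUNTS <- data.frame(
  year = c("all", "2017", "2018", "2019"),
  collected = c(9920L, 3252L, 3451L, 3217L),
  included = c(9376L, 3070L, 3265L, 3041L),
  enrolled = c(13848L, 4407L, 4592L, 4849L)
)

# Gender shares (%) per collection year.
GENDER_PCT <- rbind(
  all    = c(female = 47.3, male = 48.6, other = 1.7, prefer_not_say = 2.4),
  `2017` = c(48.3, 47.8, 1.6, 2.4),
  `2018` = c(46.6, 49.9, 1.6, 2.0),
  `2019` = c(47.0, 48.0, 1.9, 3.0)
)

# Age shares (%) per collection year, ages 11-19.
AGE_PCT <- rbind(
  all    = c(2.7, 18.1, 17.7, 17.2, 16.4, 14.5, 11.0, 1.9, 0.6),
  `2017` = c(2.4, 17.9, 17.2, 17.7, 15.5, 14.4, 12.2, 2.0, 0.7),
  `2018` = c(2.6, 17.7, 17.2, 16.3, 17.9, 15.4, 10.2, 2.2, 0.6),
  `2019` = c(3.0, 18.7, 18.8, 17.7, 15.7, 13.7, 10.6, 1.5, 0.4)
)
colnames(AGE_PCT) <- as.character(11:19)

AGE_CENTRE <- 14.3   # published mean age; centring constant for the plants

# Default generative plants for the seven continuous measures: 2017 baseline
# level and SD, per-year time slope, per-year age slope, and gender offsets
# (female vs male difference; other and prefer-not-say vs the female/male
# mean), all taken from the published results tables.
MEASURE_PLANTS <- data.frame(
  scale = c("cpss", "phqa", "hads", "crafft", "rosenberg", "kidscreen",
            "cyrm"),
  baseline = c(12.83, 8.02, 7.74, 0.55, 18.22, 26.97, 46.48),
  sd = c(11.47, 6.47, 4.72, 1.26, 6.57, 8.19, 9.17),
  b_time = c(0.47, 0.36, 0.14, 0.04, -0.33, -0.33, 0.12),
  b_age = c(0.42, 0.60, 0.27, 0.22, -0.33, -0.97, -0.25),
  off_female = c(4.79, 2.90, 2.50, 0.12, -3.02, -4.20, -0.62),
  off_other = c(6.30, 4.18, 2.13, 0.52, -3.74, -3.64, -6.64),
  off_pnts = c(4.11, 2.14, 1.40, 0.41, -2.56, -2.70, -5.40)
)

# Tobacco-use probability model (percentage points): published 2017 rate and
# slopes. The two yes/no items are drawn from the resulting Bernoulli rate.
TOBACCO_PLANT <- c(baseline = 13, b_time = -0.16, b_age = 4.01,
                   off_female = 2.05, off_other = 10.13, off_pnts = 7.44)

# Per-scale probability that a survey is missing one item of that scale.
# Calibrated so per-measure complete-case Ns track the published 2017 column
# (1 - N_measure / N_included).
MISS_RATES <- c(cpss = 0.0655, phqa = 0.0345, hads = 0.0283,
                crafft = 0.0248, rosenberg = 0.0336, kidscreen = 0.0303,
                cyrm = 0.0459, tobacco = 0.0215)

#' Cohort generator configuration
#'
#' Defaults reproduce the published demographic structure: per-year sample
#' sizes 3,070 / 3,265 / 3,041 (the included counts), per-year age and gender
#' distributions, measure plants equal to the published slopes, and exclusion
#' pressure calibrated so that roughly 5.5% of generated surveys trip the
#' screening rules (split between out-of-range ages and planted inconsistent
#' responders).
#'
#' @param n_per_year Named or positional integer vector of surveys per year
#'   (2017, 2018, 2019).
#' @param plants Data frame of per-measure generative parameters (see
#'   `MEASURE_PLANTS` layout: `scale`, `baseline`, `sd`, `b_time`, `b_age`,
#'   `off_female`, `off_other`, `off_pnts`).
#' @param tobacco Named numeric vector of the tobacco rate model.
#' @param miss_rates Named per-scale item-missingness probabilities.
#' @param inconsistent_rate Fraction of surveys overwritten with an
#'   inconsistency pattern that trips one of the screening rules.
#' @param age_oor_rate Fraction of surveys given an out-of-range age answer.
#' @param seed Master RNG seed.
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_year = c(`2017` = 3070L, `2018` = 3265L,
                                         `2019` = 3041L),
                          plants = MEASURE_PLANTS,
                          tobacco = TOBACCO_PLANT,
                          miss_rates = MISS_RATES,
                          inconsistent_rate = 0.015,
                          age_oor_rate = 0.022,
                          seed = 1L) {
  stopifnot(length(n_per_year) == 3L, all(n_per_year >= 0),
            all(plants$sd >= 0), inconsistent_rate >= 0, age_oor_rate >= 0)
  structure(list(n_per_year = as.integer(n_per_year), plants = plants,
                 tobacco = tobacco, miss_rates = miss_rates,
                 inconsistent_rate = inconsistent_rate,
                 age_oor_rate = age_oor_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Null-cohort configuration
#'
#' Convenience wrapper: all time/age slopes and gender offsets set to zero
#' (baselines and SDs kept), no inconsistent responders and no out-of-range
#' ages, for type-I-error calibration.
#'
#' @param n_per_year Surveys per year.
#' @param seed Master RNG seed.
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(n_per_year = c(334L, 333L, 333L), seed = 1L) {
  plants <- MEASURE_PLANTS
  plants[, c("b_time", "b_age", "off_female", "off_other", "off_pnts")] <- 0
  tob <- TOBACCO_PLANT
  tob[c("b_time", "b_age", "off_female", "off_other", "off_pnts")] <- 0
  cohort_config(n_per_year = n_per_year, plants = plants, tobacco = tob,
                inconsistent_rate = 0, age_oor_rate = 0, seed = seed)
}

# Largest-remainder allocation of integer totals across items. `total` is a
# vector (one survey per element); returns an n x n_items matrix of item
# scores in [min_s, max_s] whose rows sum to `total`. The remainder goes to
# a uniformly random subset of items (seeded jitter via the current RNG).
allocate_total <- function(total, n_items, min_s, max_s) {
  n <- length(total)
  cap <- max_s - min_s
  t2 <- total - n_items * min_s
  stopifnot(all(t2 >= 0), all(t2 <= n_items * cap))
  base <- t2 %/% n_items
  rem <- t2 %% n_items
  u <- matrix(stats::runif(n * n_items), n, n_items)
  rk <- integer(n * n_items)
  ord <- order(row(u), u)
  rk[ord] <- rep(seq_len(n_items), times = n)
  rk <- matrix(rk, n, n_items)
  s <- matrix(base, n, n_items) + (rk <= rem) + min_s
  storage.mode(s) <- "integer"
  s
}

# Invert a per-item score map: item scores -> 0-based answer indices.
scores_to_indices <- function(scores, map) {
  match(scores, map) - 1L
}

#' Item answers realising a latent severity
#'
#' Clamps and rounds a latent severity to the instrument's total-score range
#' and distributes it across the scored items by largest-remainder
#' allocation, honouring reverse keying. Re-scoring the emitted items with
#' [score_scale()] recovers `clamp(round(severity))` exactly. Only the
#' generic summed instruments are handled here; CRAFFT, the PHQ-A
#' suicidality probes and tobacco have dedicated paths in
#' [generate_cohort()].
#'
#' @param severity Numeric vector of latent severities on the total-score
#'   axis (one survey per element).
#' @param def A `scale_def` for one of cpss, phqa, hads, rosenberg,
#'   kidscreen, cyrm.
#' @return Integer matrix of 0-based answer indices, one column per scored
#'   item, with attribute `"clamped"` counting out-of-range severities.
#' @export
items_from_severity <- function(severity, def) {
  if (!inherits(def, "scale_def")) def <- scale_def(def)
  total <- as.integer(round(severity))
  clamped <- sum(total < def$range[1] | total > def$range[2])
  total <- pmin(pmax(total, def$range[1]), def$range[2])
  maps <- def$score_maps[def$scored]
  min_s <- min(maps[[1L]])
  max_s <- max(maps[[1L]])
  s <- allocate_total(total, length(def$scored), min_s, max_s)
  idx <- s
  for (j in seq_along(maps)) {
    idx[, j] <- scores_to_indices(s[, j], maps[[j]])
  }
  colnames(idx) <- paste0(def$id, "_q", def$scored)
  attr(idx, "clamped") <- clamped
  idx
}

# CRAFFT items from a latent total (0-6): a yes-count over items 4-9 with
# the part-B gate. total 1 is split between "car ride only" (part B unasked)
# and "single part-B symptom" patterns.
crafft_items <- function(total) {
  n <- length(total)
  a <- matrix(NA_integer_, n, 9L,
              dimnames = list(NULL, paste0("crafft_q", 1:9)))
  a[, 1:4] <- 1L                              # default: all no
  user <- total >= 2L |
    (total == 1L & stats::runif(n) < 0.5)     # part A triggered
  a[user, 1L] <- 0L
  a[user, 2L] <- ifelse(stats::runif(sum(user)) < 0.3, 0L, 1L)
  a[user, 3L] <- ifelse(stats::runif(sum(user)) < 0.1, 0L, 1L)
  # part B shown only for users; distribute the yes-count over items 4-9
  yes <- allocate_total(total[user], 6L, 0L, 1L)
  a[user, 4:9] <- ifelse(yes == 1L, 0L, 1L)
  # non-users with total 1: the car-ride item alone carries the score
  ride <- !user & total == 1L
  a[ride, 4L] <- 0L
  a
}

# Tobacco items from a per-survey use probability.
tobacco_items <- function(p) {
  n <- length(p)
  smoker <- stats::runif(n) < p
  q1 <- rep(1L, n)
  q2 <- rep(1L, n)
  q1[smoker] <- ifelse(stats::runif(sum(smoker)) < 0.9, 0L, 1L)
  q2[smoker] <- ifelse(stats::runif(sum(smoker)) < 0.25, 0L, 1L)
  # guarantee a user answers yes at least once
  fix <- smoker & q1 == 1L & q2 == 1L
  q2[fix] <- 0L
  cbind(tobacco_q1 = q1, tobacco_q2 = q2)
}

# Probability of a serious-thoughts "yes" (item 10) given the item-9
# answer, increasing with item-9 frequency; level set so the overall
# suicidal-thinking rate lands near the published 16-18% band.
SUICIDE_Q10_P <- c(0.20, 0.30, 0.40)

#' Generate a synthetic survey cohort
#'
#' Samples (year, age, gender) from the configured distributions, draws each
#' instrument's latent severity as
#' `baseline + b_time * t + b_age * (age - 14.3) + gender offset + noise`,
#' converts severities to item-level answers (skip rules and reverse keying
#' included), then injects item missingness, inconsistent responders and
#' out-of-range ages at the configured rates. Deterministic given the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame in the survey CSV schema (`year`, `age` as character,
#'   `gender`, item columns), with attribute `"clamped"` counting latent
#'   severities clamped to their scale range.
#' @export
generate_cohort <- function(config = cohort_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  years <- c(2017L, 2018L, 2019L)
  year <- rep(years, times = config$n_per_year)
  n <- length(year)
  age <- integer(n)
  gender <- character(n)
  for (i in seq_along(years)) {
    sel <- year == years[i]
    yk <- as.character(years[i])
    age[sel] <- sample(11:19, sum(sel), replace = TRUE,
                       prob = AGE_PCT[yk, ])
    gender[sel] <- sample(GENDERS, sum(sel), replace = TRUE,
                          prob = GENDER_PCT[yk, ])
  }
  t_val <- year - 2017L
  age_c <- age - AGE_CENTRE
  goff <- function(off_f, off_o, off_p) {
    off_f <- as.numeric(off_f)
    off_o <- as.numeric(off_o)
    off_p <- as.numeric(off_p)
    unname(c(female = off_f / 2, male = -off_f / 2, other = off_o,
             prefer_not_say = off_p)[gender])
  }

  out <- data.frame(year = year, age = as.character(age), gender = gender,
                    stringsAsFactors = FALSE)
  clamped <- 0L
  defs <- scale_definitions()

  for (k in seq_len(nrow(config$plants))) {
    pl <- config$plants[k, ]
    sev <- pl$baseline + pl$b_time * t_val + pl$b_age * age_c +
      goff(pl$off_female, pl$off_other, pl$off_pnts) +
      stats::rnorm(n, 0, pl$sd)
    def <- defs[[pl$scale]]
    if (pl$scale == "crafft") {
      total <- pmin(pmax(as.integer(round(sev)), 0L), 6L)
      clamped <- clamped + sum(round(sev) < 0 | round(sev) > 6)
      items <- crafft_items(total)
    } else {
      items <- items_from_severity(sev, def)
      clamped <- clamped + attr(items, "clamped")
    }
    out <- cbind(out, as.data.frame(items))
  }

  # CPSS context items (unscored): distressing event and time since event
  out$cpss_q1 <- sample(0:5, n, replace = TRUE,
                        prob = c(0.55, 0.12, 0.08, 0.05, 0.05, 0.15))
  out$cpss_q2 <- sample(0:7, n, replace = TRUE)

  # PHQ-A suicidality probes, gated on item 9
  q9_score <- scale_def("phqa")$score_maps[[9L]][out$phqa_q9 + 1L]
  asked <- !is.na(q9_score) & q9_score >= 1L
  out$phqa_q10 <- NA_integer_
  out$phqa_q11 <- NA_integer_
  p10 <- SUICIDE_Q10_P[q9_score[asked]]
  out$phqa_q10[asked] <- ifelse(stats::runif(sum(asked)) < p10, 0L, 1L)
  out$phqa_q11[asked] <- ifelse(stats::runif(sum(asked)) < 0.4, 0L, 1L)

  # Tobacco
  tb <- config$tobacco
  p <- (tb["baseline"] + tb["b_time"] * t_val + tb["b_age"] * age_c +
          goff(tb["off_female"], tb["off_other"], tb["off_pnts"])) / 100
  p <- pmin(pmax(p, 0.001), 0.99)
  out <- cbind(out, as.data.frame(tobacco_items(p)))

  # Item missingness: drop one asked, scored item per affected survey
  for (id in names(config$miss_rates)) {
    hitn <- which(stats::runif(n) < config$miss_rates[[id]])
    if (length(hitn) == 0L) next
    def <- defs[[id]]
    cols <- paste0(id, "_q", def$scored)
    for (i in hitn) {
      asked_items <- cols[!is.na(unlist(out[i, cols]))]
      if (length(asked_items) == 0L) next
      out[i, sample(asked_items, 1L)] <- NA_integer_
    }
  }

  # Inconsistent responders: overwrite with a pattern violating one rule
  if (config$inconsistent_rate > 0) {
    bad <- which(stats::runif(n) < config$inconsistent_rate)
    if (length(bad) > 0L) {
      type <- sample(c("a", "b", "c"), length(bad), replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
      ros_cols <- paste0("rosenberg_q", 1:10)
      kid_cols <- paste0("kidscreen_q", 1:11)
      hads_cols <- paste0("hads_q", 1:7)
      ia <- bad[type == "a"]
      out[ia, ros_cols] <- sample(c(0L, 3L), length(ia),
                                  replace = TRUE)        # straight-line
      ib <- bad[type == "b"]
      # top self-esteem, bottom quality of life
      out[ib, paste0("rosenberg_q", c(1, 3, 4, 7, 10))] <- 0L
      out[ib, paste0("rosenberg_q", c(2, 5, 6, 8, 9))] <- 3L
      out[ib, paste0("kidscreen_q", setdiff(1:11, c(3, 4, 11)))] <- 0L
      out[ib, paste0("kidscreen_q", c(3, 4, 11))] <- 4L
      ic <- bad[type == "c"]
      out[ic, hads_cols] <- sample(c(0L, 3L), length(ic), replace = TRUE)
    }
  }

  # Out-of-range ages
  if (config$age_oor_rate > 0) {
    oor <- which(stats::runif(n) < config$age_oor_rate)
    if (length(oor) > 0L) {
      out$age[oor] <- sample(c(AGE_LOW_TEXT, AGE_HIGH_TEXT), length(oor),
                             replace = TRUE)
    }
  }

  attr(out, "clamped") <- clamped
  out
}
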