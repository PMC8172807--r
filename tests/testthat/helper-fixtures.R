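# Fixture builders: construct survey rows programmatically.

# One survey row with every item column present (NA unless set).
blank_survey <- function(year = 2018L, age = "14", gender = "female") {
  defs <- scale_definitions()
  cols <- unlist(lapply(defs, function(d) {
    paste0(d$id, "_q", seq_len(d$n_items))
  }), use.names = FALSE)
  row <- as.data.frame(setNames(as.list(rep(NA_integer_, length(cols))),
                                cols))
  cbind(data.frame(year = year, age = age, gender = gender,
                   stringsAsFactors = FALSE), row)
}

# Set a scale's items to given answer indices. `answers` is recycled; names
# like "q3" select individual items.
set_items <- function(survey, scale, answers, items = NULL) {
  def <- scale_def(scale)
  if (is.null(items)) items <- seq_len(def$n_items)
  cols <- paste0(scale, "_q", items)
  survey[, cols] <- as.list(as.integer(rep(answers, length.out =
                                             length(items))))
  survey
}

# A consistent "all fine" respondent: mild answers everywhere, complete.
consistent_survey <- function(year = 2018L, age = "14", gender = "male") {
  s <- blank_survey(year, age, gender)
  s <- set_items(s, "cpss", 0)                 # incl. context items
  s <- set_items(s, "phqa", 0, items = 1:9)    # q9 = 0 so q10/11 unasked
  s <- set_items(s, "hads", c(3, 3, 3, 0, 0, 3, 3))  # all score 0
  s <- set_items(s, "crafft", 1, items = 1:4)  # all no, part B skipped
  s <- set_items(s, "tobacco", 1)
  # rosenberg: positives agree (idx 1), negatives disagree (idx 2)
  s <- set_items(s, "rosenberg", 1, items = c(1, 3, 4, 7, 10))
  s <- set_items(s, "rosenberg", 2, items = c(2, 5, 6, 8, 9))
  # kidscreen: positives "Quite often" (idx 2), reverse items "Seldom"
  s <- set_items(s, "kidscreen", 2, items = setdiff(1:11, c(3, 4, 11)))
  s <- set_items(s, "kidscreen", 1, items = c(3, 4, 11))
  s <- set_items(s, "cyrm", 3)
  s
}

# Small screened + scored cohort for battery-level tests.
small_cohort <- function(n = 600, seed = 1, ...) {
  cfg <- cohort_config(n_per_year = rep(ceiling(n / 3), 3), seed = seed, ...)
  prepare_surveys(generate_cohort(cfg))$data
}

# Independent step-up FDR oracle: literal textbook loop.
fdr_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kstar <- 0
  for (k in seq_len(m)) if (ps[k] <= k / m * alpha) kstar <- k
  rej <- rep(FALSE, m)
  if (kstar > 0) rej <- p <= ps[kstar]
  rej
}

# Minimal permutations generator for the enumeration oracle (independent of
# the code under test).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}
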