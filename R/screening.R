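# Exclusion of ambiguous-age and inconsistent surveys, and derivation of the
# eight binary outcome measures from scale totals via screening cut-offs.
#
# Criterion precedence is fixed (deterministic ledger): age_low, age_high,
# then the three consistency rules. Each excluded survey records the first
# criterion it failed.

EXCLUSION_CRITERIA <- c("age_low", "age_high", "rosenberg_inconsistent",
                        "rosenberg_kidscreen_inconsistent",
                        "hads_inconsistent")

#' Default consistency-rule configuration
#'
#' Concrete, configurable instantiations of the three inconsistent-answering
#' exclusion rules:
#' \describe{
#'   \item{rosenberg}{straight-line contradiction: the respondent endorses
#'     (Strongly agree / Agree) all five positively-phrased AND all five
#'     negatively-phrased self-esteem items, or rejects all ten.}
#'   \item{rosenberg_kidscreen}{cross-instrument contradiction: mean item
#'     score on the Rosenberg positive items in the top quartile of its 0-3
#'     range while the mean of the Kidscreen positively-phrased items is in
#'     the bottom quartile of its 0-4 range, or vice versa.}
#'   \item{hads}{reversed-key straight-lining: all seven anxiety answers at
#'     the same printed position with the scored severity of the
#'     reverse-printed items differing from the rest by the maximum 3
#'     points.}
#' }
#'
#' @param rosenberg_endorse_max Highest answer index counted as endorsement
#'   (default 1 = "Agree").
#' @param quartile Fraction of an item-score range defining the extreme
#'   quartiles of the cross-instrument rule (default 0.25).
#' @return A named list of rule parameters for [apply_exclusions()].
#' @export
consistency_rules <- function(rosenberg_endorse_max = 1L, quartile = 0.25) {
  list(rosenberg_endorse_max = as.integer(rosenberg_endorse_max),
       quartile = quartile)
}

# Rule (a): contradictory Rosenberg straight-lining. Requires all 10 answers
# present; fires when all items are endorsed or all rejected.
rule_rosenberg <- function(surveys, rules) {
  a <- answer_matrix(surveys, scale_def("rosenberg"))
  endorsed <- a <= rules$rosenberg_endorse_max
  all_present <- rowSums(is.na(a)) == 0L
  all_present & (rowSums(endorsed) == 10L | rowSums(!endorsed) == 10L)
}

# Rule (b): Rosenberg positive items vs Kidscreen positively-phrased items
# at opposite extremes of their ranges.
rule_rosenberg_kidscreen <- function(surveys, rules) {
  dr <- scale_def("rosenberg")
  dk <- scale_def("kidscreen")
  ar <- answer_matrix(surveys, dr)
  ak <- answer_matrix(surveys, dk)
  pos_r <- dr$reverse                       # positively-phrased = reverse-keyed
  pos_k <- setdiff(1:11, dk$reverse)
  sr <- sapply(pos_r, function(j) dr$score_maps[[j]][ar[, j] + 1L])
  sk <- sapply(pos_k, function(j) dk$score_maps[[j]][ak[, j] + 1L])
  if (nrow(surveys) == 1L) { sr <- matrix(sr, 1L); sk <- matrix(sk, 1L) }
  mr <- rowMeans(sr)
  mk <- rowMeans(sk)
  q <- rules$quartile
  hit <- (mr >= 3 * (1 - q) & mk <= 4 * q) |
         (mr <= 3 * q & mk >= 4 * (1 - q))
  hit & !is.na(hit)
}

# Rule (c): HADS straight-lining at a printed position where the reversed
# and non-reversed keys disagree maximally (positions 0 and 3).
rule_hads <- function(surveys, rules) {
  d <- scale_def("hads")
  a <- answer_matrix(surveys, d)
  all_present <- rowSums(is.na(a)) == 0L
  same <- all_present &
    apply(a, 1L, function(r) length(unique(r)) == 1L)
  s <- sapply(1:7, function(j) d$score_maps[[j]][a[, j] + 1L])
  if (nrow(surveys) == 1L) s <- matrix(s, 1L)
  fwd <- setdiff(1:7, d$reverse)
  gap <- abs(rowMeans(s[, d$reverse, drop = FALSE]) -
               rowMeans(s[, fwd, drop = FALSE]))
  same & !is.na(gap) & gap == 3
}

#' Apply the five exclusion criteria
#'
#' Excludes surveys whose age answer was one of the open-ended extremes
#' ("10 years or less" / "20 years or more") and surveys failing any of the
#' three consistency rules. Criteria are checked in the fixed order
#' `age_low`, `age_high`, `rosenberg_inconsistent`,
#' `rosenberg_kidscreen_inconsistent`, `hads_inconsistent`; the first hit is
#' recorded.
#'
#' @param surveys Raw parsed surveys (see [read_surveys()]); `age` may hold
#'   the categorical extremes.
#' @param rules Rule parameters from [consistency_rules()].
#' @return A list of class `exclusion_report` with elements `included`
#'   (retained surveys, with integer `age` 11-19), `decision` (per input
#'   row: `"included"` or the triggering criterion), and `ledger` (data frame
#'   of counts: total collected, excluded per criterion, final included).
#' @export
apply_exclusions <- function(surveys, rules = consistency_rules()) {
  n <- nrow(surveys)
  age_chr <- canonical_age(surveys$age)
  crit <- rep(NA_character_, n)
  hit <- function(current, new_hit, id) {
    ifelse(is.na(current) & new_hit, id, current)
  }
  crit <- hit(crit, !is.na(age_chr) & age_chr == AGE_LOW_TEXT, "age_low")
  crit <- hit(crit, !is.na(age_chr) & age_chr == AGE_HIGH_TEXT, "age_high")
  crit <- hit(crit, rule_rosenberg(surveys, rules), "rosenberg_inconsistent")
  crit <- hit(crit, rule_rosenberg_kidscreen(surveys, rules),
              "rosenberg_kidscreen_inconsistent")
  crit <- hit(crit, rule_hads(surveys, rules), "hads_inconsistent")

  keep <- is.na(crit)
  included <- surveys[keep, , drop = FALSE]
  included$age <- parse_age_years(included$age)
  if (any(!is.na(included$age) &
            (included$age < 11L | included$age > 19L))) {
    stop("retained survey with age outside 11-19", call. = FALSE)
  }
  counts <- vapply(EXCLUSION_CRITERIA,
                   function(id) sum(crit == id, na.rm = TRUE), integer(1))
  ledger <- data.frame(criterion = c("collected", EXCLUSION_CRITERIA,
                                     "included"),
                       count = c(n, unname(counts), sum(keep)))
  structure(list(included = included,
                 decision = ifelse(keep, "included", crit),
                 ledger = ledger),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  print(x$ledger, row.names = FALSE)
  invisible(x)
}

#' Screening cut-offs for the probable diagnoses
#'
#' @param cpss_ptsd CPSS total at or above which PTSD is probable (15).
#' @param phqa_depression PHQ-A total for probable depression (11).
#' @param phqa_moderately_severe PHQ-A total for probable moderately severe
#'   depression (15).
#' @param hads_anxiety HADS total for probable anxiety (11).
#' @param crafft_disorder CRAFFT total for probable alcohol/substance use
#'   disorder (2).
#' @return Named list of integer thresholds.
#' @export
diagnosis_thresholds <- function(cpss_ptsd = 15L, phqa_depression = 11L,
                                 phqa_moderately_severe = 15L,
                                 hads_anxiety = 11L, crafft_disorder = 2L) {
  th <- list(cpss_ptsd = cpss_ptsd, phqa_depression = phqa_depression,
             phqa_moderately_severe = phqa_moderately_severe,
             hads_anxiety = hads_anxiety, crafft_disorder = crafft_disorder)
  ranges <- list(cpss_ptsd = c(0, 51), phqa_depression = c(0, 27),
                 phqa_moderately_severe = c(0, 27), hads_anxiety = c(0, 21),
                 crafft_disorder = c(0, 6))
  for (nm in names(th)) {
    r <- ranges[[nm]]
    if (th[[nm]] <= 0 || th[[nm]] < r[1] || th[[nm]] > r[2]) {
      stop("threshold ", nm, " outside scale range", call. = FALSE)
    }
  }
  lapply(th, as.integer)
}

# Tri-state threshold flag: positive iff complete and total >= cut; negative
# iff complete and below; NA when the scale is incomplete.
flag_at <- function(total, cut) {
  ifelse(is.na(total), NA, total >= cut)
}

#' Derive the eight binary outcome measures
#'
#' Applies the screening cut-offs to scored surveys. Each flag is tri-state:
#' `TRUE` (positive), `FALSE` (negative), `NA` (not evaluable because the
#' underlying scale is incomplete). The composite "any of 4" flag is positive
#' when at least one of probable PTSD, depression, anxiety or
#' alcohol/substance use disorder is positive; negative only when all four
#' are evaluable and negative; `NA` otherwise (so a partially complete
#' battery with one positive component is still evaluable).
#'
#' @param scored Data frame from [score_surveys()].
#' @param thresholds Cut-offs from [diagnosis_thresholds()].
#' @return `scored` with appended tri-state columns `probable_ptsd`,
#'   `probable_depression`, `probable_msd` (moderately severe depression),
#'   `probable_anxiety`, `probable_sud` (alcohol/substance use disorder) and
#'   `any_of_4`. (`suicidal_thinking` and `tobacco_use` are produced by
#'   [score_surveys()].)
#' @export
derive_diagnoses <- function(scored, thresholds = diagnosis_thresholds()) {
  out <- scored
  out$probable_ptsd <- flag_at(scored$cpss_total, thresholds$cpss_ptsd)
  out$probable_depression <- flag_at(scored$phqa_total,
                                     thresholds$phqa_depression)
  out$probable_msd <- flag_at(scored$phqa_total,
                              thresholds$phqa_moderately_severe)
  out$probable_anxiety <- flag_at(scored$hads_total,
                                  thresholds$hads_anxiety)
  out$probable_sud <- flag_at(scored$crafft_total,
                              thresholds$crafft_disorder)
  four <- cbind(out$probable_ptsd, out$probable_depression,
                out$probable_anxiety, out$probable_sud)
  any_pos <- rowSums(four, na.rm = TRUE) > 0L
  all_eval_neg <- rowSums(is.na(four)) == 0L & rowSums(four) == 0L
  out$any_of_4 <- ifelse(any_pos, TRUE, ifelse(all_eval_neg, FALSE, NA))
  out
}
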