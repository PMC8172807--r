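# Machine-readable item schema: every survey item with its printed answer
# choices, in printed order. The 0-based answer index stored on disk refers
# to positions in these lists. The demographics and impact-of-fire
# questionnaires are parse-only (never scored).

phqa_freq <- c("Not at all", "Several days", "More than half the days",
               "Nearly every day")
yes_no <- c("Yes", "No")
cpss_freq <- c("Not at all or only at one time",
               "Once a week or less/once in a while",
               "2 to 4 times a week/half the time",
               "5 or more times a week/almost always")
agree4 <- c("Strongly agree", "Agree", "Disagree", "Strongly disagree")
kid_extent <- c("Not at all", "Slightly", "Moderately", "Very", "Extremely")
kid_freq <- c("Never", "Seldom", "Quite often", "Very often", "Always")
cyrm_extent <- c("Not at all", "A little", "Some-what", "Quite a bit",
                 "A lot")

#' Printed answer choices for every survey item
#'
#' @return Named list keyed by item column name (e.g. `"phqa_q3"`,
#'   `"demographics_q4"`); each element is the character vector of printed
#'   answer choices in printed order. Free-list items (school names) map to
#'   `NULL`.
#' @export
answer_choices <- function() {
  ch <- list()

  ch$demographics_q1 <- yes_no
  ch$demographics_q2 <- yes_no
  ch$demographics_q3 <- c("Female", "Male", "Other", "Prefer not to say")
  ch$demographics_q4 <- c("10 years or less", paste(11:19, "years"),
                          "20 years or more")
  ch$demographics_q5 <- NULL
  ch$demographics_q6 <- c(as.character(7:12), "other")
  ch$demographics_q7 <- NULL

  for (k in 1:4) ch[[paste0("iof_q", k)]] <- yes_no
  ch$iof_q5 <- NULL
  ch$iof_q6 <- c(as.character(7:12), "other")

  ch$cpss_q1 <- c("2016 Fort McMurray wildfire",
                  "Death of someone close to you",
                  "Injury that you suffered", "Physical assault against you",
                  "Sexual assault", "Other")
  ch$cpss_q2 <- c("<1 month", "2-5 months", "6-11 months", "1 year",
                  "2 years", "3-5 years", "6-10 years", "11 or more years")
  for (k in 3:19) ch[[paste0("cpss_q", k)]] <- cpss_freq

  for (k in 1:9) ch[[paste0("phqa_q", k)]] <- phqa_freq
  ch$phqa_q10 <- yes_no
  ch$phqa_q11 <- yes_no

  ch$hads_q1 <- c("Most of the time", "A lot of the time",
                  "From time to time, occasionally", "Not at all")
  ch$hads_q2 <- c("Very definitely and quite badly", "Yes, but not too badly",
                  "A little, but it doesn't worry me", "Not at all")
  ch$hads_q3 <- c("A great deal of the time", "A lot of the time",
                  "From time to time, but not too often", "Only occasionally")
  ch$hads_q4 <- c("Definitely", "Usually", "Not often", "Not at all")
  ch$hads_q5 <- c("Not at all", "Occasionally", "Quite often", "Very often")
  ch$hads_q6 <- c("Very much indeed", "Quite a lot", "Not very much",
                  "Not at all")
  ch$hads_q7 <- c("Very often indeed", "Quite often", "Not very often",
                  "Not at all")

  for (k in 1:9) ch[[paste0("crafft_q", k)]] <- yes_no
  for (k in 1:2) ch[[paste0("tobacco_q", k)]] <- yes_no
  for (k in 1:10) ch[[paste0("rosenberg_q", k)]] <- agree4

  for (k in 1:11) {
    ch[[paste0("kidscreen_q", k)]] <-
      if (k %in% c(1L, 9L)) kid_extent
      else if (k == 11L) c("Excellent", "Very good", "Good", "Fair", "Poor")
      else kid_freq
  }

  for (k in 1:12) ch[[paste0("cyrm_q", k)]] <- cyrm_extent

  ch
}

#' Full survey item schema
#'
#' Combines the printed answer choices with the scoring metadata of the
#' scored instruments into one machine-readable structure (also shipped as
#' `inst/extdata/survey_schema.json`).
#'
#' @return A list with elements `items` (per item: questionnaire, item index,
#'   answer choices) and `scales` (per scored instrument: scored items,
#'   per-item score maps, reverse-keyed items, total range).
#' @export
survey_item_schema <- function() {
  ch <- answer_choices()
  items <- lapply(names(ch), function(nm) {
    parts <- strsplit(nm, "_q", fixed = TRUE)[[1L]]
    list(column = nm, questionnaire = parts[1L],
         item = as.integer(parts[2L]), choices = ch[[nm]])
  })
  defs <- scale_definitions()
  scales <- lapply(defs, function(d) {
    list(id = d$id, n_items = d$n_items, scored_items = d$scored,
         reverse_keyed = d$reverse, range = d$range,
         score_maps = d$score_maps[d$scored])
  })
  list(items = items, scales = scales)
}
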