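# Declarative definitions and scoring for the eight scored survey instruments.
#
# Answers are stored as 0-based indices into each item's printed answer-choice
# list, so "Yes, No" items code yes = 0, no = 1, and a four-level frequency
# item codes its first printed choice as 0. Per-item score maps translate the
# answer index into the instrument's conventional item score; reverse-keyed
# items are expressed directly in the map.

#' Identifiers of the scored instruments
#'
#' @return Character vector of the eight instrument ids used throughout the
#'   package: `"cpss"`, `"phqa"`, `"hads"`, `"crafft"`, `"tobacco"`,
#'   `"rosenberg"`, `"kidscreen"`, `"cyrm"`.
#' @export
scale_ids <- function() {
  c("cpss", "phqa", "hads", "crafft", "tobacco", "rosenberg", "kidscreen",
    "cyrm")
}

# Build one scale definition. score_maps is a list with one integer vector per
# item giving the item score for each 0-based answer index; NULL entries mark
# unscored (context) items. Skip rules name condition items, a predicate over
# their answers, and the dependent items that are then unasked.
new_scale_def <- function(id, n_items, levels, score_maps, scored, reverse,
                          range, skip = NULL) {
  stopifnot(length(levels) == n_items, length(score_maps) == n_items)
  def <- list(id = id, n_items = n_items, levels = levels,
              score_maps = score_maps, scored = scored, reverse = reverse,
              range = range, skip = skip)
  class(def) <- "scale_def"
  def
}

asc <- function(L) 0:(L - 1L)          # score = answer index
desc <- function(L) (L - 1L):0         # reverse-keyed item

#' Built-in instrument definitions
#'
#' Returns the declarative schema of every scored instrument: item counts,
#' answer-level counts, per-item score maps (reverse keying included), the
#' scored item subset, skip rules, and the total-score range.
#'
#' Conventions: every ordinal item scores `0..(levels - 1)` in printed answer
#' order unless reverse-keyed. HADS items 1, 2, 3, 6 and 7 are printed from
#' the severe end to the mild end and are reverse-keyed so that a higher item
#' score always means more anxiety; items 4 and 5 are printed mild-first and
#' score ascending. Kidscreen items 3, 4 and 11 are reverse-keyed so a higher
#' total means better quality of life. Rosenberg negatively-phrased items
#' (2, 5, 6, 8, 9) score ascending with disagreement while the positive items
#' (1, 3, 4, 7, 10) are reverse-keyed, so a higher total means higher
#' self-esteem. CYRM-12 items score 1..5. CPSS items 1-2 and PHQ-A items
#' 10-11 are context items excluded from the totals.
#'
#' @return Named list of `scale_def` objects, one per id in [scale_ids()].
#' @export
scale_definitions <- function() {
  defs <- list()

  # CPSS: 19 items; items 1-2 are context (event type, time since event);
  # items 3-19 are the 17 symptom items, 4 levels each, total 0-51.
  lv <- c(6L, 8L, rep(4L, 17L))
  maps <- c(list(NULL, NULL), rep(list(asc(4L)), 17L))
  defs$cpss <- new_scale_def("cpss", 19L, lv, maps, scored = 3:19,
                             reverse = integer(0), range = c(0L, 51L))

  # PHQ-A: items 1-9 scored 0-3 (total 0-27); items 10-11 are yes/no
  # suicidality probes gated on item 9 and never enter the total.
  lv <- c(rep(4L, 9L), 2L, 2L)
  maps <- c(rep(list(asc(4L)), 9L), list(NULL, NULL))
  defs$phqa <- new_scale_def(
    "phqa", 11L, lv, maps, scored = 1:9, reverse = integer(0),
    range = c(0L, 27L),
    skip = list(list(cond_items = 9L,
                     predicate = function(a) !is.na(a[, 1L]) & a[, 1L] == 0L,
                     dep_items = c(10L, 11L))))

  # HADS anxiety subscale: 7 items, 4 levels, total 0-21. Items printed
  # severe-first are reverse-keyed; items 4 and 5 are printed mild-first.
  lv <- rep(4L, 7L)
  maps <- list(desc(4L), desc(4L), desc(4L), asc(4L), asc(4L), desc(4L),
               desc(4L))
  defs$hads <- new_scale_def("hads", 7L, lv, maps, scored = 1:7,
                             reverse = c(1L, 2L, 3L, 6L, 7L),
                             range = c(0L, 21L))

  # CRAFFT: 9 yes/no items; score = yes-count over items 4-9 (total 0-6);
  # items 5-9 asked only if any of items 1-3 is "yes".
  lv <- rep(2L, 9L)
  yes1 <- c(1L, 0L)                    # yes (index 0) scores 1
  maps <- c(rep(list(NULL), 3L), rep(list(yes1), 6L))
  defs$crafft <- new_scale_def(
    "crafft", 9L, lv, maps, scored = 4:9, reverse = integer(0),
    range = c(0L, 6L),
    skip = list(list(cond_items = 1:3,
                     predicate = function(a) {
                       !is.na(a[, 1L]) & !is.na(a[, 2L]) & !is.na(a[, 3L]) &
                         a[, 1L] == 1L & a[, 2L] == 1L & a[, 3L] == 1L
                     },
                     dep_items = 5:9)))

  # Tobacco use: two yes/no items; assessed as a binary flag, not a total.
  defs$tobacco <- new_scale_def("tobacco", 2L, rep(2L, 2L),
                                rep(list(yes1), 2L), scored = 1:2,
                                reverse = integer(0), range = c(0L, 2L))

  # Rosenberg self-esteem: 10 items, 4 levels (strongly agree ..
  # strongly disagree), total 0-30, higher = higher self-esteem.
  lv <- rep(4L, 10L)
  pos <- c(1L, 3L, 4L, 7L, 10L)
  maps <- lapply(1:10, function(i) if (i %in% pos) desc(4L) else asc(4L))
  defs$rosenberg <- new_scale_def("rosenberg", 10L, lv, maps, scored = 1:10,
                                  reverse = pos, range = c(0L, 30L))

  # Kidscreen-10 (11 scored items, 5 levels, total 0-44, higher = better
  # quality of life); "felt sad", "felt lonely" and the global health item
  # are reverse-keyed.
  lv <- rep(5L, 11L)
  rev_k <- c(3L, 4L, 11L)
  maps <- lapply(1:11, function(i) if (i %in% rev_k) desc(5L) else asc(5L))
  defs$kidscreen <- new_scale_def("kidscreen", 11L, lv, maps, scored = 1:11,
                                  reverse = rev_k, range = c(0L, 44L))

  # CYRM-12: 12 items scored 1-5, total 12-60, higher = more resilient.
  lv <- rep(5L, 12L)
  maps <- rep(list(1:5), 12L)
  defs$cyrm <- new_scale_def("cyrm", 12L, lv, maps, scored = 1:12,
                             reverse = integer(0), range = c(12L, 60L))

  defs
}

#' Look up a single built-in instrument definition
#'
#' @param id One of [scale_ids()].
#' @return A `scale_def` object.
#' @export
scale_def <- function(id) {
  defs <- scale_definitions()
  if (!id %in% names(defs)) {
    stop("unknown scale id: ", id, call. = FALSE)
  }
  defs[[id]]
}

# Column names holding a scale's item answers in a survey data frame.
item_cols <- function(def) paste0(def$id, "_q", seq_len(def$n_items))

# Extract the answer matrix (n x n_items, 0-based integer indices, NA for
# missing) for one scale from a survey data frame, validating ranges.
answer_matrix <- function(surveys, def) {
  cols <- item_cols(def)
  missing_cols <- setdiff(cols, names(surveys))
  a <- matrix(NA_integer_, nrow(surveys), def$n_items,
              dimnames = list(NULL, cols))
  present <- setdiff(cols, missing_cols)
  for (cn in present) {
    v <- surveys[[cn]]
    if (is.character(v)) v[!nzchar(v)] <- NA
    a[, cn] <- as.integer(v)
  }
  bad <- sweep(a, 2L, def$levels, ">=") | a < 0L
  if (any(bad, na.rm = TRUE)) {
    j <- which(apply(bad, 2L, any, na.rm = TRUE))[1L]
    stop(sprintf("answer index out of range for item %s (levels: %d)",
                 cols[j], def$levels[j]), call. = FALSE)
  }
  a
}

# Logical matrix marking items unasked under the definition's skip rules.
skip_matrix <- function(a, def) {
  sk <- matrix(FALSE, nrow(a), ncol(a))
  for (rule in def$skip) {
    cond <- rule$predicate(a[, rule$cond_items, drop = FALSE])
    cond[is.na(cond)] <- FALSE
    sk[cond, rule$dep_items] <- TRUE
  }
  sk
}

# Vectorised scoring core shared by score_scale() and score_surveys():
# returns list(total, complete) over the rows of `surveys`.
score_core <- function(surveys, def) {
  a <- answer_matrix(surveys, def)
  sk <- skip_matrix(a, def)
  s <- matrix(0L, nrow(a), ncol(a))
  for (j in def$scored) {
    m <- def$score_maps[[j]]
    v <- m[a[, j] + 1L]
    v[sk[, j]] <- 0L                   # legitimately skipped items score 0
    s[, j] <- v
  }
  req <- matrix(FALSE, nrow(a), ncol(a))
  req[, def$scored] <- TRUE
  req[sk] <- FALSE
  complete <- rowSums(req & is.na(a)) == 0L
  total <- rowSums(s[, def$scored, drop = FALSE])
  total[!complete] <- NA_integer_
  list(total = as.integer(total), complete = complete)
}

#' Score one survey response on one instrument
#'
#' Sums the per-item scores of the instrument's scored items, applying
#' reverse keying and skip logic. The total is `NA` unless every scored,
#' non-skipped item was answered; items legitimately unasked under a skip
#' rule contribute 0 and do not break completeness.
#'
#' @param response A one-row data frame (or coercible list) with the
#'   instrument's item columns named `<id>_q<k>`, holding 0-based answer
#'   indices (`NA` = unanswered).
#' @param def A `scale_def`, e.g. from [scale_def()].
#' @return A list of class `scale_score` with elements `scale` (id), `total`
#'   (integer or `NA`) and `complete` (logical).
#' @examples
#' r <- as.data.frame(setNames(as.list(rep(3L, 17)), paste0("cpss_q", 3:19)))
#' score_scale(r, scale_def("cpss"))$total  # 51
#' @export
score_scale <- function(response, def) {
  if (!inherits(def, "scale_def")) def <- scale_def(def)
  response <- as.data.frame(response)
  res <- score_core(response, def)
  structure(list(scale = def$id, total = res$total[1L],
                 complete = res$complete[1L]),
            class = "scale_score")
}

#' Score the CRAFFT alcohol/substance-use screen
#'
#' The total is the count of "yes" answers over items 4-9 (range 0-6). When
#' items 1-3 are all "no", items 5-9 are unasked and contribute 0, so the
#' screen is still scoreable from item 4 alone. Answers given to items 5-9
#' despite an all-"no" part A are counted, with a warning.
#'
#' @param response One-row data frame with `crafft_q1`..`crafft_q9` columns.
#' @return A `scale_score` (see [score_scale()]).
#' @export
score_crafft <- function(response) {
  res <- crafft_core(as.data.frame(response))
  structure(list(scale = "crafft", total = res$total[1L],
                 complete = res$complete[1L]),
            class = "scale_score")
}

# Vectorised CRAFFT scoring with the stray-answer rule: items 5-9 answered
# despite an all-'no' part A are counted (with one warning).
crafft_core <- function(surveys) {
  def <- scale_def("crafft")
  a <- answer_matrix(surveys, def)
  sk <- skip_matrix(a, def)
  stray <- sk & !is.na(a)
  if (any(stray[, 5:9])) {
    warning("CRAFFT items 5-9 answered despite all-'no' items 1-3; ",
            "answers counted", call. = FALSE)
    sk[stray] <- FALSE
  }
  s <- matrix(0L, nrow(a), ncol(a))
  for (j in def$scored) {
    v <- def$score_maps[[j]][a[, j] + 1L]
    v[sk[, j]] <- 0L
    s[, j] <- v
  }
  req <- matrix(FALSE, nrow(a), ncol(a))
  req[, def$scored] <- TRUE
  req[sk] <- FALSE
  complete <- rowSums(req & is.na(a)) == 0L
  total <- as.integer(rowSums(s[, def$scored, drop = FALSE]))
  total[!complete] <- NA_integer_
  list(total = total, complete = complete)
}

# Tri-state logicals: TRUE = positive, FALSE = negative, NA = not evaluable.

#' Assess tobacco use from the two tobacco items
#'
#' Positive if either item is "yes"; negative if both are answered "no";
#' not evaluable (`NA`) if an item is missing and the other is not "yes".
#'
#' @param response Data frame with `tobacco_q1`, `tobacco_q2` columns
#'   (0 = yes, 1 = no). May have any number of rows.
#' @return Tri-state logical vector, one element per row.
#' @export
assess_tobacco_use <- function(response) {
  response <- as.data.frame(response)
  a <- answer_matrix(response, scale_def("tobacco"))
  q1 <- a[, 1L]
  q2 <- a[, 2L]
  out <- rep(NA, nrow(a))
  pos <- (!is.na(q1) & q1 == 0L) | (!is.na(q2) & q2 == 0L)
  neg <- !is.na(q1) & !is.na(q2) & q1 == 1L & q2 == 1L
  out[pos] <- TRUE
  out[neg & !pos] <- FALSE
  out
}

#' Assess suicidal thinking from PHQ-A items 9 and 10
#'
#' Positive iff item 9 is "Several days", "More than half the days" or
#' "Nearly every day" AND item 10 is "Yes". Negative if item 9 is
#' "Not at all" (item 10 is then unasked) or item 9 is elevated but item 10
#' is "No". Item 11 is ignored. `NA` when the required answers are missing.
#' An item-10 answer present despite item 9 = "Not at all" is ignored with a
#' warning.
#'
#' @param response Data frame with `phqa_q9` (0-3) and `phqa_q10`
#'   (0 = yes, 1 = no) columns. May have any number of rows.
#' @return Tri-state logical vector, one element per row.
#' @export
assess_suicidal_thinking <- function(response) {
  response <- as.data.frame(response)
  a <- answer_matrix(response, scale_def("phqa"))
  q9 <- a[, 9L]
  q10 <- a[, 10L]
  stray <- !is.na(q9) & q9 == 0L & !is.na(q10)
  if (any(stray)) {
    warning("PHQ-A item 10 answered despite item 9 = 'Not at all'; ignored",
            call. = FALSE)
    q10[stray] <- NA_integer_
  }
  out <- rep(NA, length(q9))
  out[!is.na(q9) & q9 == 0L] <- FALSE
  elev <- !is.na(q9) & q9 >= 1L
  out[elev & !is.na(q10) & q10 == 0L] <- TRUE
  out[elev & !is.na(q10) & q10 == 1L] <- FALSE
  out
}

#' Score every instrument for a table of surveys
#'
#' Vectorised scoring of all eight instruments plus the two derived tri-state
#' assessments. Totals are `NA` for incomplete instruments (complete-case
#' convention).
#'
#' @param surveys Data frame with `year`, `age`, `gender` and item columns
#'   `<scale>_q<k>` holding 0-based answer indices.
#' @return `surveys` with appended columns `<scale>_total` and
#'   `<scale>_complete` for the seven summed instruments, plus tri-state
#'   `suicidal_thinking` and `tobacco_use`.
#' @export
score_surveys <- function(surveys) {
  defs <- scale_definitions()
  out <- surveys
  for (id in setdiff(scale_ids(), "tobacco")) {
    res <- if (id == "crafft") crafft_core(surveys)
           else score_core(surveys, defs[[id]])
    out[[paste0(id, "_total")]] <- res$total
    out[[paste0(id, "_complete")]] <- res$complete
  }
  out$suicidal_thinking <- assess_suicidal_thinking(surveys)
  out$tobacco_use <- assess_tobacco_use(surveys)
  out
}
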