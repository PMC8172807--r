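# Reading and writing the survey CSV schema: one row per anonymous survey;
# columns year, age, gender, then one column per item (<scale>_q<k>) holding
# the 0-based index of the printed answer choice. Empty cell = missing.
# Verbatim answer text is also accepted and mapped through the item schema.

GENDERS <- c("female", "male", "other", "prefer_not_say")
AGE_LOW_TEXT <- "10 years or less"
AGE_HIGH_TEXT <- "20 years or more"

canonical_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("prefer not to say", "prefer_not_to_say", "did not say",
             "pnts")] <- "prefer_not_say"
  bad <- !is.na(x) & !x %in% GENDERS
  if (any(bad)) {
    stop("unrecognised gender value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

# Age answers arrive either as integers or as the verbatim choices
# ("11 years" .. "19 years" plus the two open-ended extremes). Returns a
# character vector preserving the extremes; parse_age_years() extracts the
# integer years (NA for the extremes).
canonical_age <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA
  x <- sub("^([0-9]+) years$", "\\1", x)
  x
}

#' Integer age in years from a raw age answer
#'
#' @param age Character vector of raw age answers (integer text, `"NN years"`,
#'   or the categorical extremes `"10 years or less"` / `"20 years or more"`).
#' @return Integer vector; `NA` for the categorical extremes and for missing.
#' @export
parse_age_years <- function(age) {
  age <- canonical_age(age)
  suppressWarnings(as.integer(age))
}

#' Read a survey CSV
#'
#' Reads one survey per row. Item columns may hold 0-based answer indices or
#' verbatim printed answer text (mapped through [answer_choices()],
#' case-insensitively). Empty cells are missing. Unknown columns are kept
#' untouched.
#'
#' @param path Path to a CSV file with columns `year`, `age`, `gender` and
#'   item columns `<scale>_q<k>`.
#' @return Data frame with integer `year`, character `age` (verbatim extremes
#'   preserved), canonical `gender` and integer item columns.
#' @export
read_surveys <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = c("", "NA"))
  for (req in c("year", "age", "gender")) {
    if (!req %in% names(df)) stop("missing column: ", req, call. = FALSE)
  }
  df$year <- as.integer(df$year)
  if (any(!df$year %in% c(2017L, 2018L, 2019L), na.rm = TRUE)) {
    stop("year must be one of 2017, 2018, 2019", call. = FALSE)
  }
  df$age <- canonical_age(df$age)
  df$gender <- canonical_gender(df$gender)
  ch <- answer_choices()
  item_rx <- "_q[0-9]+$"
  for (cn in grep(item_rx, names(df), value = TRUE)) {
    v <- df[[cn]]
    num <- suppressWarnings(as.integer(v))
    txt <- !is.na(v) & is.na(num)
    if (any(txt)) {
      choices <- ch[[cn]]
      if (is.null(choices)) {
        stop("non-numeric answers in free-list column ", cn, call. = FALSE)
      }
      idx <- match(tolower(trimws(v[txt])), tolower(choices)) - 1L
      if (anyNA(idx)) {
        stop("unrecognised answer text in column ", cn, ": ",
             v[txt][which(is.na(idx))[1L]], call. = FALSE)
      }
      num[txt] <- idx
    }
    df[[cn]] <- num
  }
  df
}

#' Write a survey or scored-survey table as CSV
#'
#' @param surveys Data frame as produced by [read_surveys()],
#'   [score_surveys()] or [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE, na = "")
  invisible(path)
}
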