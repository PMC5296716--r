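#' Construct a validated table of ADL episodes
#'
#' An episode is one occurrence of an activity: a subject, a category, a
#' 1-based day index, an onset in minutes after local midnight, a positive
#' duration in minutes, and a provenance flag (`truth` for scripted /
#' ground-truth schedules, `recognised` for classifier output). Sleeping
#' episodes may cross midnight (`onset + duration > 1440`) and keep a single
#' record; any other category must be split at the day boundary (see
#' [split_at_midnight()]).
#'
#' @param subject_id Character or factor, recycled to the common length.
#' @param category ADL category label, one of `adl_categories()$category`.
#' @param day_index Integer day of measurement, 1-based.
#' @param onset Minutes after local midnight, in `[0, 1440)`.
#' @param duration Positive duration in minutes.
#' @param source `"truth"` or `"recognised"`.
#' @return A tibble with the six columns above, validated.
#' @export
#' @examples
#' adl_episodes("s1", "Cooking", 1, 690, 40)
adl_episodes <- function(subject_id, category, day_index, onset, duration,
                         source = "truth") {
  x <- tibble::tibble(
    subject_id = as.character(subject_id),
    category = as.character(category),
    day_index = as.integer(day_index),
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    source = as.character(source)
  )
  validate_episodes(x)
}

#' Validate an episode table
#'
#' Checks column presence and types, category labels, day/onset/duration
#' ranges, the midnight-crossing rule (only Sleeping may span the day
#' boundary) and absence of same-category overlaps per subject.
#'
#' @param x A data frame of episodes (see [adl_episodes()]).
#' @return `x` as a tibble, invisibly validated (errors otherwise).
#' @export
validate_episodes <- function(x) {
  needed <- c("subject_id", "category", "day_index", "onset", "duration",
              "source")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("episode table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "adl_format_error")
  }
  x <- tibble::as_tibble(x)[needed]
  if (nrow(x) == 0) {
    return(x)
  }
  bad_cat <- setdiff(unique(x$category), adl_categories()$category)
  if (length(bad_cat) > 0) {
    rlang::abort(paste0("unknown ADL category: ",
                        paste(bad_cat, collapse = ", ")),
                 class = "adl_format_error")
  }
  if (any(x$day_index < 1)) {
    rlang::abort("day_index must be >= 1", class = "adl_format_error")
  }
  if (any(x$onset < 0 | x$onset >= 1440)) {
    rlang::abort("onset must lie in [0, 1440)", class = "adl_format_error")
  }
  if (any(x$duration <= 0)) {
    rlang::abort("duration must be > 0", class = "adl_format_error")
  }
  crosses <- x$onset + x$duration > 1440
  if (any(crosses & x$category != "Sleeping")) {
    rlang::abort(
      "only Sleeping episodes may cross midnight; split others at the day boundary",
      class = "adl_format_error")
  }
  # same-category overlap check on the absolute-time axis
  x2 <- x[order(x$subject_id, x$category, abs_start_min(x)), ]
  key <- paste(x2$subject_id, x2$category)
  s <- abs_start_min(x2)
  e <- abs_end_min(x2)
  same_prev <- c(FALSE, key[-1] == key[-length(key)])
  overlap <- same_prev & s < c(-Inf, e[-length(e)])
  if (any(overlap)) {
    rlang::abort(
      paste0("overlapping same-category episodes for: ",
             paste(unique(key[overlap]), collapse = "; ")),
      class = "adl_format_error")
  }
  x
}

#' Split non-Sleeping episodes at midnight
#'
#' Episodes other than Sleeping whose span crosses the day boundary are cut
#' into two records at midnight (the second dropped if it would fall past
#' `n_days`). Sleeping records are returned unchanged.
#'
#' @param x Episode table (not yet required to satisfy the midnight rule).
#' @param n_days Last day of the study; trailing fragments beyond it are
#'   dropped. `NULL` keeps them.
#' @return Episode table obeying the midnight-crossing invariant.
#' @export
split_at_midnight <- function(x, n_days = NULL) {
  x <- tibble::as_tibble(x)
  repeat {
    crosses <- x$onset + x$duration > 1440 & x$category != "Sleeping"
    if (!any(crosses)) break
    head_part <- x[crosses, ]
    tail_part <- head_part
    tail_part$day_index <- head_part$day_index + 1L
    tail_part$onset <- 0
    tail_part$duration <- head_part$onset + head_part$duration - 1440
    head_part$duration <- 1440 - head_part$onset
    if (!is.null(n_days)) {
      tail_part <- tail_part[tail_part$day_index <= n_days, ]
    }
    x <- dplyr::bind_rows(x[!crosses, ], head_part, tail_part)
  }
  x[order(x$subject_id, abs_start_min(x), x$category), ]
}

#' Write an episode table to CSV or JSON
#'
#' The on-disk representation is lossless: [read_episodes()] on the written
#' file reproduces the table (identifiers bit-exact, reals to full double
#' precision).
#'
#' @param episodes Episode table (validated on the way out).
#' @param path Output file path; the extension picks the format when
#'   `format = "auto"`.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  episodes <- validate_episodes(episodes)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- dplyr::rename(episodes, onset_min = "onset", duration_min = "duration")
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read an episode table written by [write_episodes()]
#'
#' @param path File path (`.csv` or `.json`).
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return A validated episode tibble.
#' @export
read_episodes <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "adl_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    x <- readr::read_csv(path, col_types = readr::cols(
      subject_id = readr::col_character(),
      category = readr::col_character(),
      day_index = readr::col_integer(),
      onset_min = readr::col_double(),
      duration_min = readr::col_double(),
      source = readr::col_character()
    ))
  } else {
    x <- tibble::as_tibble(jsonlite::fromJSON(path))
    if (nrow(x) == 0) {
      x <- tibble::tibble(subject_id = character(0), category = character(0),
                          day_index = integer(0), onset_min = numeric(0),
                          duration_min = numeric(0), source = character(0))
    }
  }
  x <- dplyr::rename(x, onset = "onset_min", duration = "duration_min")
  x$day_index <- as.integer(x$day_index)
  validate_episodes(x)
}
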