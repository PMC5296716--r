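# Lag-24 h Poincare-plot quantification of day-to-day ADL heterogeneity.
# For each subject and activity, a daily feature series s_1..s_N (one value
# per day the activity occurred) is paired with its one-day-lagged self,
# (x_i, y_i) = (s_i, s_{i+1}); the cloud is summarised by ellipse fitting:
# centroid (on the identity line), long axis (dispersion along it, SD2)
# and short axis (dispersion perpendicular to it, SD1). Regular routines
# give tight clouds hugging the identity line; fragmented routines spread.

#' Extract a per-day feature series for one activity
#'
#' One value per day the category occurred (the first episode by onset on
#' days with several); missing days are skipped, order preserved. The
#' default feature, `onset_deviation_min`, is the absolute deviation of
#' each day's onset from the subject's median onset for that category over
#' the retained days -- a genuine irregularity measure whose Poincare
#' centroid grows with routine fragmentation. `onset_min` and
#' `duration_min` pass the raw values through.
#'
#' @param episodes Episode table of one subject.
#' @param category ADL category to extract.
#' @param feature_kind `"onset_deviation_min"`, `"onset_min"` or
#'   `"duration_min"`.
#' @param day_limit Use only days `1..day_limit` (`NULL` = all).
#' @param source Restrict to `"truth"` or `"recognised"` rows (`NULL` = all).
#' @return A `daily_series` list with fields `subject_id`, `category`,
#'   `feature_kind`, `days`, `values`, and `insufficient` (`TRUE` when
#'   fewer than 2 occupied days remain, i.e. no lag pair is possible).
#' @export
extract_daily_feature <- function(episodes,
                                  category,
                                  feature_kind = c("onset_deviation_min",
                                                   "onset_min",
                                                   "duration_min"),
                                  day_limit = NULL, source = NULL) {
  feature_kind <- match.arg(feature_kind)
  ep <- tibble::as_tibble(episodes)
  if (length(unique(ep$subject_id)) > 1) {
    rlang::abort("extract_daily_feature expects episodes of one subject",
                 class = "adl_argument_error")
  }
  ep <- ep[ep$category == category, ]
  if (!is.null(source)) ep <- ep[ep$source == source, ]
  if (!is.null(day_limit)) ep <- ep[ep$day_index <= day_limit, ]
  o <- order(ep$day_index, ep$onset)
  ep <- ep[o, ]
  first <- !duplicated(ep$day_index)
  days <- ep$day_index[first]
  base <- switch(feature_kind,
                 onset_deviation_min = ,
                 onset_min = ep$onset[first],
                 duration_min = ep$duration[first])
  values <- if (feature_kind == "onset_deviation_min") {
    if (length(base) > 0) abs(base - stats::median(base)) else numeric(0)
  } else {
    base
  }
  structure(list(
    subject_id = if (nrow(ep) > 0) ep$subject_id[1] else NA_character_,
    category = category,
    feature_kind = feature_kind,
    days = days,
    values = values,
    insufficient = length(values) < 2
  ), class = "daily_series")
}

#' Build lagged Poincare pairs from a daily series
#'
#' Pairs each retained value with the value `lag` steps later:
#' `(x_i, y_i) = (s_i, s_(i+lag))`, giving `N - lag` points. With no
#' missing days and `lag = 1` this is the classical 24-hour-delay plot;
#' when days are missing, adjacency is defined on the retained sequence.
#'
#' @param series A `daily_series` (see [extract_daily_feature()]) or a
#'   numeric vector.
#' @param lag Positive integer lag in sequence steps (default 1 = one day).
#' @return Tibble of pairs `x`, `y`.
#' @export
build_pairs <- function(series, lag = 1L) {
  v <- if (inherits(series, "daily_series")) series$values else
    as.numeric(series)
  stopifnot(lag >= 1)
  if (length(v) < lag + 1) {
    rlang::abort(
      paste0("need at least ", lag + 1,
             " values to build lag-", lag, " pairs (got ", length(v), ")"),
      class = "adl_insufficient_data")
  }
  n <- length(v)
  tibble::tibble(x = v[seq_len(n - lag)], y = v[seq_len(n - lag) + lag])
}

#' Ellipse-fit descriptors of a Poincare point cloud
#'
#' Rotating the cloud by 45 degrees decomposes each pair into an
#' identity-line coordinate `a_i = (x_i + y_i) / sqrt(2)` and a
#' perpendicular coordinate `d_i = (x_i - y_i) / sqrt(2)`. The short axis
#' (SD1) is the population SD of `d_i`, the long axis (SD2) the population
#' SD of `a_i`; the centroid point is the cloud's centre of mass and the
#' scalar centroid is its identity-line coordinate `(x_bar + y_bar) / 2`,
#' in feature units.
#'
#' @param pairs Pair tibble from [build_pairs()] (or anything with `x`,
#'   `y` columns), with at least 1 row. A single pair gives a well-defined
#'   centroid with degenerate (zero) axes; this keeps two-day observation
#'   windows quantifiable.
#' @return A `poincare_descriptors` list: `centroid_point` (length-2),
#'   `centroid`, `long_axis`, `short_axis`, `n_points`.
#' @export
fit_ellipse <- function(pairs) {
  x <- pairs$x
  y <- pairs$y
  if (length(x) < 1) {
    rlang::abort("need at least 1 pair to fit the ellipse",
                 class = "adl_insufficient_data")
  }
  d <- (x - y) / sqrt(2)
  a <- (x + y) / sqrt(2)
  structure(list(
    centroid_point = c(x = mean(x), y = mean(y)),
    centroid = (mean(x) + mean(y)) / 2,
    long_axis = pop_sd(a),
    short_axis = pop_sd(d),
    n_points = length(x)
  ), class = "poincare_descriptors")
}

#' @export
print.poincare_descriptors <- function(x, ...) {
  cat(sprintf(
    "Poincare descriptors (%d points): centroid %.3f, long axis %.3f, short axis %.3f\n",
    x$n_points, x$centroid, x$long_axis, x$short_axis))
  invisible(x)
}

#' Per-category Poincare descriptor table for one subject
#'
#' Applies [extract_daily_feature()], [build_pairs()] and [fit_ellipse()]
#' to every requested category; categories with fewer than `lag + 1`
#' occupied days are reported with `NA` descriptors.
#'
#' @param episodes Episode table of one subject.
#' @param feature_kind,day_limit,source See [extract_daily_feature()].
#' @param categories Categories to quantify (default: the 8 core ADL).
#' @param lag See [build_pairs()].
#' @return Tibble: `subject_id`, `category`, `n_points`, `centroid`,
#'   `long_axis`, `short_axis`.
#' @export
poincare_descriptors <- function(episodes,
                                 feature_kind = "onset_deviation_min",
                                 day_limit = NULL, source = NULL,
                                 categories = core_adl(), lag = 1L) {
  sid <- unique(tibble::as_tibble(episodes)$subject_id)
  rows <- lapply(categories, function(cat) {
    ser <- extract_daily_feature(episodes, cat, feature_kind,
                                 day_limit = day_limit, source = source)
    if (length(ser$values) < lag + 1) {
      return(tibble::tibble(subject_id = sid[1], category = cat,
                            n_points = NA_integer_, centroid = NA_real_,
                            long_axis = NA_real_, short_axis = NA_real_))
    }
    de <- fit_ellipse(build_pairs(ser, lag = lag))
    tibble::tibble(subject_id = sid[1], category = cat,
                   n_points = de$n_points, centroid = de$centroid,
                   long_axis = de$long_axis, short_axis = de$short_axis)
  })
  dplyr::bind_rows(rows)
}

#' Mean Poincare-centroid heterogeneity of one subject
#'
#' The classification feature: the unweighted mean of the available
#' per-category centroid scalars over the core ADL, computed from episodes
#' of days `1..day_limit`. Categories with insufficient data are excluded
#' and reported in the attributes.
#'
#' @inheritParams poincare_descriptors
#' @param day_limit Last observation day entering the feature.
#' @return Numeric scalar with attributes `categories_used` and
#'   `categories_excluded`. Errors when no category has enough data.
#' @export
subject_heterogeneity <- function(episodes, day_limit = NULL,
                                  feature_kind = "onset_deviation_min",
                                  source = NULL, categories = core_adl(),
                                  lag = 1L) {
  de <- poincare_descriptors(episodes, feature_kind = feature_kind,
                             day_limit = day_limit, source = source,
                             categories = categories, lag = lag)
  ok <- !is.na(de$centroid)
  if (!any(ok)) {
    rlang::abort("no category has enough occupied days for a Poincare pair",
                 class = "adl_insufficient_data")
  }
  structure(mean(de$centroid[ok]),
            categories_used = de$category[ok],
            categories_excluded = de$category[!ok])
}

#' Cumulative per-day heterogeneity for a whole cohort
#'
#' For every subject and every observation duration `d` in `days`,
#' recomputes the heterogeneity feature from episodes of days `1..d`
#' (cumulative, not sliding). Implemented directly on the daily series for
#' speed; it is numerically identical to calling [subject_heterogeneity()]
#' at each `d`.
#'
#' @param episodes Episode table of one or more subjects.
#' @param days Observation durations to evaluate (default `2:max(day)`;
#'   day 1 admits no lag pair).
#' @param feature_kind,source,categories As in [poincare_descriptors()].
#' @return Tibble: `subject_id`, `day`, `heterogeneity`, `n_categories`.
#' @export
heterogeneity_by_day <- function(episodes, days = NULL,
                                 feature_kind = "onset_deviation_min",
                                 source = NULL, categories = core_adl()) {
  ep <- tibble::as_tibble(episodes)
  if (!is.null(source)) ep <- ep[ep$source == source, ]
  ep <- ep[ep$category %in% categories, ]
  days <- days %||% seq(2L, max(ep$day_index, 2L))
  subs <- unique(tibble::as_tibble(episodes)$subject_id)
  acc_sum <- matrix(0, length(subs), length(days),
                    dimnames = list(subs, NULL))
  acc_n <- matrix(0L, length(subs), length(days))
  ep <- ep[order(ep$day_index, ep$onset), ]
  by_sub <- split(ep, ep$subject_id)
  for (s in names(by_sub)) {
    si <- match(s, subs)
    by_cat <- split(by_sub[[s]], by_sub[[s]]$category)
    for (d0 in by_cat) {
      first <- !duplicated(d0$day_index)
      dd <- d0$day_index[first]
      vv <- if (feature_kind == "duration_min") d0$duration[first] else
        d0$onset[first]
      for (j in seq_along(days)) {
        v <- vv[dd <= days[j]]
        if (length(v) < 2) next
        f <- if (feature_kind == "onset_deviation_min")
          abs(v - stats::median(v)) else v
        n <- length(f)
        centroid <- (mean(f[-n]) + mean(f[-1])) / 2
        acc_sum[si, j] <- acc_sum[si, j] + centroid
        acc_n[si, j] <- acc_n[si, j] + 1L
      }
    }
  }
  out <- tidyr::expand_grid(subject_id = subs, day = as.integer(days))
  idx <- cbind(match(out$subject_id, subs), match(out$day, days))
  out$heterogeneity <- ifelse(acc_n[idx] > 0, acc_sum[idx] / acc_n[idx],
                              NA_real_)
  out$n_categories <- acc_n[idx]
  out
}
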