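# Training-free rule/template ADL recognition over room-sorted presence
# streams. The classifier assumes that, irrespective of cognitive status,
# specific activities recur daily with characteristic room, timing and
# duration; each presence interval is matched against a documented template
# table, with acceleration markers (fridge door, flush handle) and a
# low-luminescence cue disambiguating same-room activities. The template
# table is a documented reconstruction in that spirit and ships as
# editable configuration.

#' Classifier thresholds
#'
#' @param gap_close_s Presence triggers closer than this (seconds) are
#'   merged into one interval (default 300 s).
#' @param absence_min Whole-home absence of at least this many minutes is
#'   reported as OutOfHome (default 30).
#' @param visitor_overlap_min Simultaneous presence in >= 2 rooms for at
#'   least this many minutes is reported as Visitors (default 10).
#' @param accel_marker_min Acceleration magnitude (m/s2) above which a
#'   fridge/flush sample counts as a marker event (default 0.5; configure
#'   as roughly 3x the channel noise SD).
#' @param lux_low Median interval luminescence (lx) below which the
#'   low-light cue holds (default 50).
#' @param eating_after_cooking_min Eating must start within this many
#'   minutes after a recognised Cooking end (default 45).
#' @param bed_before_sleep_min GettingReadyForBed must end within this many
#'   minutes before a recognised Sleeping onset (default 90).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(gap_close_s = 300, absence_min = 30,
                              visitor_overlap_min = 10,
                              accel_marker_min = 0.5, lux_low = 50,
                              eating_after_cooking_min = 45,
                              bed_before_sleep_min = 90) {
  structure(list(gap_close_s = gap_close_s, absence_min = absence_min,
                 visitor_overlap_min = visitor_overlap_min,
                 accel_marker_min = accel_marker_min, lux_low = lux_low,
                 eating_after_cooking_min = eating_after_cooking_min,
                 bed_before_sleep_min = bed_before_sleep_min),
            class = "classifier_params")
}

#' Default ADL template table
#'
#' One row per core activity: allowed rooms (pipe-separated), clock onset
#' window in minutes after midnight (`window_start > window_end` wraps
#' midnight), duration bounds in minutes, required markers, an optional
#' temporal anchor (`after_cooking`, `before_sleep`), and a priority used
#' to resolve multiple matches (higher wins).
#'
#' @return Template tibble.
#' @export
default_adl_templates <- function() {
  tibble::tribble(
    ~category, ~rooms, ~window_start, ~window_end, ~min_duration,
    ~max_duration, ~fridge_marker, ~flush_marker, ~low_lux, ~anchor,
    ~priority,
    "Sleeping", "bedroom", 1200, 120, 240, 840, FALSE, FALSE, TRUE,
    NA_character_, 10,
    "Toileting", "bathroom", 0, 1440, 2, 15, FALSE, TRUE, FALSE,
    NA_character_, 9,
    "Cooking", "kitchen", 0, 1440, 10, 120, TRUE, FALSE, FALSE,
    NA_character_, 8,
    "GettingReadyForBed", "bathroom|bedroom", 1140, 180, 15, 60, FALSE,
    FALSE, FALSE, "before_sleep", 7,
    "Grooming", "bathroom", 300, 720, 5, 45, FALSE, FALSE, FALSE,
    NA_character_, 6,
    "Eating", "kitchen|living", 360, 1320, 10, 60, FALSE, FALSE, FALSE,
    "after_cooking", 5,
    "WatchingTV", "living", 1140, 1439, 20, 300, FALSE, FALSE, FALSE,
    NA_character_, 4,
    "SeatedActivity", "living", 360, 1140, 20, 240, FALSE, FALSE, FALSE,
    NA_character_, 3
  )
}

#' Aggregate presence triggers into room-presence intervals
#'
#' Successive triggers no more than `gap_close_s` apart are merged; each
#' interval spans first to last trigger of its run.
#'
#' @param room_stream Chronologically sorted sample tibble for one room
#'   (or a numeric vector of trigger times in seconds).
#' @param gap_close_s Merge threshold, seconds.
#' @return Tibble with `start_s`, `end_s`, `trigger_count`.
#' @export
detect_presence_intervals <- function(room_stream, gap_close_s = 300) {
  tr <- if (is.numeric(room_stream)) {
    sort(room_stream)
  } else {
    room_stream$timestamp_s[room_stream$presence > 0]
  }
  if (length(tr) == 0L) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          trigger_count = integer(0)))
  }
  grp <- cumsum(c(TRUE, diff(tr) > gap_close_s))
  tibble::tibble(
    start_s = as.numeric(tapply(tr, grp, min)),
    end_s = as.numeric(tapply(tr, grp, max)),
    trigger_count = as.integer(tapply(tr, grp, length))
  )
}

# clock window containment with midnight wrap
in_clock_window <- function(onset_min, w0, w1) {
  if (w0 <= w1) onset_min >= w0 & onset_min <= w1
  else onset_min >= w0 | onset_min <= w1
}

# convert assigned intervals (absolute seconds) to recognised episodes
intervals_to_episodes <- function(subject_id, category, start_s, end_s,
                                  n_days) {
  ep <- tibble::tibble(
    subject_id = subject_id,
    category = category,
    day_index = as.integer(start_s %/% 86400) + 1L,
    onset = (start_s / 60) %% 1440,
    duration = (end_s - start_s) / 60,
    source = "recognised"
  )
  split_at_midnight(ep[ep$duration > 0, ], n_days = n_days)
}

#' Recognise ADL episodes from presence intervals and marker events
#'
#' Implements the decision table of [default_adl_templates()]: Visitors is
#' emitted wherever two or more rooms show overlapping presence for at
#' least `visitor_overlap_min` (such intervals are withheld from template
#' matching); OutOfHome wherever the whole home is silent for at least
#' `absence_min`; remaining intervals are offered to the templates in
#' priority order and consume at most one episode each. Toileting requires
#' a flush-handle marker, Cooking a fridge-door marker, Sleeping the
#' low-light cue; Eating and GettingReadyForBed are anchored to recognised
#' Cooking and Sleeping episodes respectively.
#'
#' @param intervals Tibble of presence intervals with columns `room`,
#'   `start_s`, `end_s` and optionally `median_lux`.
#' @param markers Tibble of marker events with columns `kind`
#'   (`"fridge_door"`/`"flush_handle"`) and `time_s`.
#' @param templates Template table; must be non-empty.
#' @param params [classifier_params()].
#' @param study_end_s End of the observation window in seconds (for
#'   trailing-absence detection).
#' @param subject_id Identifier attached to the output episodes.
#' @return Recognised episode tibble.
#' @export
recognize_adl <- function(intervals, markers = NULL,
                          templates = default_adl_templates(),
                          params = classifier_params(),
                          study_end_s = NULL, subject_id = "subject") {
  if (is.null(templates) || nrow(templates) == 0L) {
    rlang::abort("empty template set", class = "adl_config_error")
  }
  intervals <- tibble::as_tibble(intervals)
  if (!"median_lux" %in% names(intervals)) intervals$median_lux <- NA_real_
  markers <- markers %||% tibble::tibble(kind = character(0),
                                         time_s = numeric(0))
  study_end_s <- study_end_s %||%
    (if (nrow(intervals) > 0) max(intervals$end_s) else 0)
  n_days <- max(1L, ceiling(study_end_s / 86400))
  out <- list()

  # --- whole-home absence -> OutOfHome
  gaps <- complement_intervals(intervals$start_s, intervals$end_s,
                               0, study_end_s)
  long_gap <- (gaps$end - gaps$start) >= params$absence_min * 60
  if (any(long_gap)) {
    out$away <- intervals_to_episodes(subject_id, "OutOfHome",
                                      gaps$start[long_gap],
                                      gaps$end[long_gap], n_days)
  }

  # --- multi-room simultaneous presence -> Visitors
  visitor_iv <- list(start = numeric(0), end = numeric(0))
  if (nrow(intervals) > 1) {
    ev_t <- c(intervals$start_s, intervals$end_s)
    ev_d <- c(rep(1L, nrow(intervals)), rep(-1L, nrow(intervals)))
    o <- order(ev_t, -ev_d)
    depth <- cumsum(ev_d[o])
    seg_start <- ev_t[o][-length(o)]
    seg_end <- ev_t[o][-1]
    multi <- depth[-length(depth)] >= 2 & seg_end > seg_start
    if (any(multi)) {
      m <- merge_intervals(seg_start[multi], seg_end[multi])
      keep <- (m$end - m$start) >= params$visitor_overlap_min * 60
      visitor_iv <- list(start = m$start[keep], end = m$end[keep])
      if (any(keep)) {
        out$visitors <- intervals_to_episodes(subject_id, "Visitors",
                                              m$start[keep], m$end[keep],
                                              n_days)
      }
    }
  }

  if (nrow(intervals) > 0) {
    iv <- intervals
    iv$dur_min <- (iv$end_s - iv$start_s) / 60
    iv$onset_clock <- (iv$start_s / 60) %% 1440
    # overlap of each interval with visitor periods
    ol <- vapply(seq_len(nrow(iv)), function(i) {
      if (length(visitor_iv$start) == 0L) return(0)
      sum(pmax(0, pmin(iv$end_s[i], visitor_iv$end) -
                 pmax(iv$start_s[i], visitor_iv$start)))
    }, 0)
    iv$in_visit <- ol > 0.5 * (iv$end_s - iv$start_s)
    has_marker <- function(kind, s, e) {
      mt <- markers$time_s[markers$kind == kind]
      vapply(seq_along(s), function(i) any(mt >= s[i] & mt <= e[i]), TRUE)
    }
    iv$fridge <- has_marker("fridge_door", iv$start_s, iv$end_s)
    iv$flush <- has_marker("flush_handle", iv$start_s, iv$end_s)

    assigned <- rep(NA_character_, nrow(iv))
    cooking_ends <- numeric(0)
    tmpl <- templates[order(-templates$priority), ]
    # bedtime anchor: retiring to the (dark) bedroom in the sleep window,
    # with no duration bound, so a study-end-truncated night still anchors
    # GettingReadyForBed
    sleep_onsets <- numeric(0)
    ts <- tmpl[tmpl$category == "Sleeping", ]
    if (nrow(ts) == 1) {
      cand <- iv$room %in% strsplit(ts$rooms, "|", fixed = TRUE)[[1]] &
        in_clock_window(iv$onset_clock, ts$window_start, ts$window_end)
      if (ts$low_lux) {
        cand <- cand & !is.na(iv$median_lux) & iv$median_lux < params$lux_low
      }
      sleep_onsets <- iv$start_s[cand]
    }
    for (k in seq_len(nrow(tmpl))) {
      tk <- tmpl[k, ]
      rooms <- strsplit(tk$rooms, "|", fixed = TRUE)[[1]]
      ok <- is.na(assigned) & !iv$in_visit &
        iv$room %in% rooms &
        iv$dur_min >= tk$min_duration & iv$dur_min <= tk$max_duration &
        in_clock_window(iv$onset_clock, tk$window_start, tk$window_end)
      if (tk$fridge_marker) ok <- ok & iv$fridge
      if (tk$flush_marker) ok <- ok & iv$flush
      if (tk$low_lux) ok <- ok & !is.na(iv$median_lux) &
          iv$median_lux < params$lux_low
      if (!is.na(tk$anchor) && tk$anchor == "after_cooking") {
        ok <- ok & vapply(iv$start_s, function(s) {
          any(cooking_ends <= s &
                s <= cooking_ends + params$eating_after_cooking_min * 60)
        }, TRUE)
      }
      if (!is.na(tk$anchor) && tk$anchor == "before_sleep") {
        ok <- ok & vapply(iv$end_s, function(e) {
          any(e <= sleep_onsets + 300 &
                e >= sleep_onsets - params$bed_before_sleep_min * 60)
        }, TRUE)
      }
      assigned[ok] <- tk$category
      if (tk$category == "Cooking") {
        cooking_ends <- c(cooking_ends, iv$end_s[ok])
      }
    }
    hit <- !is.na(assigned)
    if (any(hit)) {
      out$core <- intervals_to_episodes(subject_id, assigned[hit],
                                        iv$start_s[hit], iv$end_s[hit],
                                        n_days)
    }
  }
  ep <- dplyr::bind_rows(out)
  if (nrow(ep) == 0L) {
    return(adl_episodes(character(0), character(0), integer(0),
                        numeric(0), numeric(0), character(0)))
  }
  ep <- dedupe_same_category(ep)
  ep <- ep[order(abs_start_min(ep), ep$category), ]
  validate_episodes(ep)
}

#' Classify a full sensor stream into recognised ADL episodes
#'
#' End-to-end recognition: room-sorts the stream, aggregates presence
#' intervals per room, extracts acceleration marker events and per-interval
#' median luminescence, and applies [recognize_adl()].
#'
#' @param samples Sensor sample tibble (one subject).
#' @param layout Home layout.
#' @param templates,params See [recognize_adl()].
#' @param subject_id Identifier for the output episodes.
#' @param study_end_s Observation window end; default spans the samples.
#' @return Recognised episode tibble.
#' @export
classify_stream <- function(samples, layout = default_home_layout(),
                            templates = default_adl_templates(),
                            params = classifier_params(),
                            subject_id = "subject", study_end_s = NULL) {
  rooms <- sort_room_chronological(samples, layout)
  study_end_s <- study_end_s %||% (max(samples$timestamp_s) +
                                     sampling_period_s())
  iv_list <- lapply(names(rooms), function(rm) {
    d <- rooms[[rm]]
    iv <- detect_presence_intervals(d, params$gap_close_s)
    if (nrow(iv) == 0L) return(NULL)
    iv$room <- rm
    # median luminescence over each interval, from the room's sorted stream
    i1 <- findInterval(iv$start_s - 1e-9, d$timestamp_s) + 1L
    i2 <- findInterval(iv$end_s + 1e-9, d$timestamp_s)
    iv$median_lux <- vapply(seq_len(nrow(iv)), function(i) {
      stats::median(d$luminescence_lx[i1[i]:max(i1[i], i2[i])])
    }, 0)
    iv
  })
  intervals <- dplyr::bind_rows(iv_list)
  mount <- layout$mount[match(samples$box_id, layout$box_id)]
  hot <- samples$acceleration_m_s2 >= params$accel_marker_min &
    mount %in% c("fridge_door", "flush_handle")
  markers <- tibble::tibble(kind = mount[hot], time_s = samples$timestamp_s[hot])
  recognize_adl(intervals, markers, templates, params,
                study_end_s = study_end_s, subject_id = subject_id)
}

#' Episode-level recognition performance against ground truth
#'
#' A truth episode counts as detected when a recognised episode of the same
#' category either overlaps at least half of it or starts within
#' `tolerance_min` of it. Sensitivity is the detected fraction of truth
#' episodes. Specificity is computed on a 15-minute occupancy grid per
#' category: a bin is a false positive when recognised activity covers it
#' but truth does not; specificity = TN / (TN + FP).
#'
#' @param recognised,truth Episode tables for the same subject-days.
#' @param tolerance_min Onset tolerance in minutes (>= 0).
#' @param bin_min Grid resolution for specificity, minutes.
#' @return List with `sensitivity`, `specificity`, counts, and a
#'   `per_category` tibble.
#' @export
evaluate_recognition <- function(recognised, truth, tolerance_min = 15,
                                 bin_min = 15) {
  if (tolerance_min < 0) {
    rlang::abort("tolerance_min must be >= 0", class = "adl_argument_error")
  }
  truth <- tibble::as_tibble(truth)
  recognised <- tibble::as_tibble(recognised)
  n_days <- max(c(truth$day_index, recognised$day_index, 1L))
  detected <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- recognised[recognised$category == truth$category[i] &
                      recognised$subject_id == truth$subject_id[i], ]
    if (nrow(r) == 0L) next
    ts <- abs_start_min(truth[i, ])
    te <- abs_end_min(truth[i, ])
    ov <- pmax(0, pmin(abs_end_min(r), te) - pmax(abs_start_min(r), ts))
    detected[i] <- any(ov >= 0.5 * (te - ts)) ||
      any(abs(abs_start_min(r) - ts) <= tolerance_min)
  }
  n_bins <- ceiling(n_days * 1440 / bin_min)
  bin_cover <- function(ep) {
    m <- matrix(FALSE, n_bins, length(adl_categories()$category),
                dimnames = list(NULL, adl_categories()$category))
    for (i in seq_len(nrow(ep))) {
      b1 <- floor(abs_start_min(ep[i, ]) / bin_min) + 1
      b2 <- ceiling(abs_end_min(ep[i, ]) / bin_min)
      m[max(1, b1):min(n_bins, b2), ep$category[i]] <- TRUE
    }
    m
  }
  tm <- bin_cover(truth)
  rm_ <- bin_cover(recognised)
  fp <- sum(rm_ & !tm)
  tn <- sum(!rm_ & !tm)
  per_cat <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(category = truth$category, detected = detected),
      .data$category),
    n_truth = dplyr::n(), detected = sum(.data$detected))
  list(
    sensitivity = if (nrow(truth) > 0) mean(detected) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_truth = nrow(truth), n_detected = sum(detected),
    fp_bins = fp, tn_bins = tn,
    per_category = per_cat
  )
}
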