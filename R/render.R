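# Render ambient sensor streams (5 channels, 0.2 Hz, one stream per box)
# from a ground-truth episode schedule. The resident occupies the room of
# the current episode; between scheduled activities they potter about the
# hallway (a room bound to no recognition template); during OutOfHome
# nobody is home; during Visitors a second presence source appears in the
# visit room while the resident remains in the hallway.

#' Sensor noise parameters for stream rendering
#'
#' @param fire_prob Probability a presence (PIR) sample inside an occupied
#'   room actually fires.
#' @param false_rate Per-sample probability of a spurious presence trigger
#'   in an unoccupied room.
#' @param dropout Per-sample probability a sample is lost in transmission.
#' @param temp_sd,hum_sd,lux_sd,accel_sd Gaussian channel noise SDs
#'   (degrees C, g/m3, lx, m/s2). The classifier's acceleration marker
#'   threshold is `max(0.5, 3 * accel_sd)`.
#' @return A `sensor_noise` list.
#' @export
sensor_noise <- function(fire_prob = 0.95, false_rate = 0.002, dropout = 0,
                         temp_sd = 0.2, hum_sd = 1, lux_sd = 5,
                         accel_sd = 0.05) {
  stopifnot(fire_prob >= 0, fire_prob <= 1, false_rate >= 0, false_rate <= 1,
            dropout >= 0, dropout < 1, temp_sd >= 0, hum_sd >= 0,
            lux_sd >= 0, accel_sd >= 0)
  structure(list(fire_prob = fire_prob, false_rate = false_rate,
                 dropout = dropout, temp_sd = temp_sd, hum_sd = hum_sd,
                 lux_sd = lux_sd, accel_sd = accel_sd),
            class = "sensor_noise")
}

#' Noise-free sensor rendering parameters
#'
#' Deterministic presence (every in-room sample fires, no false triggers,
#' no dropout) and zero channel noise; used for generator-classifier
#' consistency checks.
#'
#' @return A `sensor_noise` list.
#' @export
sensor_noise_free <- function() {
  sensor_noise(fire_prob = 1, false_rate = 0, dropout = 0,
               temp_sd = 0, hum_sd = 0, lux_sd = 0, accel_sd = 0)
}

# map categories to the room they are rendered in
room_map_from_template <- function(template) {
  stats::setNames(template$room, template$category)
}

#' Render a subject's ambient sensor stream from truth episodes
#'
#' Produces one five-channel sample every 5 s for every box in the layout
#' over `n_days` days. Presence follows room occupancy as described above;
#' luminescence follows a day/night curve (near-dark nights, ~250 lx midday)
#' with a +150 lx boost in the occupied room during waking hours; Cooking
#' adds fridge-door acceleration spikes and Toileting a flush-handle spike;
#' temperature and humidity follow gentle diurnal curves plus noise.
#'
#' @param truth Truth episode table for one subject.
#' @param layout Home layout ([home_layout()]); must contain the idle room.
#' @param noise [sensor_noise()] parameters.
#' @param seed Integer seed; the stream is deterministic given it.
#' @param n_days Days to render (default: last day in `truth`).
#' @param room_map Named character vector category -> room; defaults to the
#'   rooms of [default_template_schedule()].
#' @param idle_room Room holding between-activity presence (default
#'   `"hallway"`).
#' @return Sensor sample tibble with the documented columns.
#' @export
render_sensor_stream <- function(truth, layout = default_home_layout(),
                                 noise = sensor_noise(), seed = 1L,
                                 n_days = NULL, room_map = NULL,
                                 idle_room = "hallway") {
  stopifnot(inherits(noise, "sensor_noise"))
  n_days <- n_days %||% max(truth$day_index, 1L)
  room_map <- room_map %||% room_map_from_template(default_template_schedule())
  study_end <- n_days * 86400
  period <- sampling_period_s()

  ep <- tibble::as_tibble(truth)
  ep$room <- unname(room_map[ep$category])
  unknown <- setdiff(stats::na.omit(unique(ep$room)), layout$room)
  if (length(unknown) > 0 || !(idle_room %in% layout$room)) {
    rlang::abort(paste0("episode room(s) not in layout: ",
                        paste(c(unknown, setdiff(idle_room, layout$room)),
                              collapse = ", ")),
                 class = "adl_config_error")
  }
  ep$start_s <- abs_start_min(ep) * 60
  ep$end_s <- pmin(abs_end_min(ep) * 60, study_end)
  ep <- ep[ep$start_s < study_end & ep$end_s > ep$start_s, ]

  is_visit <- ep$category == "Visitors"
  is_away <- ep$category == "OutOfHome"
  resident <- ep[!is_visit & !is_away, ]
  # idle = at home but not in a scheduled activity (and not away)
  occupied <- merge_intervals(c(resident$start_s, ep$start_s[is_away]),
                              c(resident$end_s, ep$end_s[is_away]))
  # an empty schedule means a vacant home: no idle presence either
  idle <- if (nrow(ep) == 0) {
    list(start = numeric(0), end = numeric(0))
  } else {
    complement_intervals(occupied$start, occupied$end, 0, study_end)
  }

  room_presence <- dplyr::bind_rows(
    tibble::tibble(room = resident$room, start = resident$start_s,
                   end = resident$end_s),
    tibble::tibble(room = ep$room[is_visit], start = ep$start_s[is_visit],
                   end = ep$end_s[is_visit]),
    tibble::tibble(room = idle_room, start = idle$start, end = idle$end)
  )
  room_presence <- room_presence[!is.na(room_presence$room), ]
  presence_by_room <- lapply(split(room_presence, room_presence$room),
                             function(d) merge_intervals(d$start, d$end))

  cook <- ep[ep$category == "Cooking", ]
  toilet <- ep[ep$category == "Toileting", ]
  t <- seq(0, study_end - period, by = period)
  nt <- length(t)
  clock_h <- (t %% 86400) / 3600
  lux_day <- 250 * pmax(0, sin(pi * (clock_h - 6) / 16))
  waking <- clock_h >= 6 & clock_h < 22

  withr::with_seed(as.integer(seed), {
    streams <- vector("list", nrow(layout))
    for (b in seq_len(nrow(layout))) {
      iv <- presence_by_room[[layout$room[b]]]
      active <- if (is.null(iv)) rep(FALSE, nt) else
        in_intervals(t, iv$start, iv$end)
      fired <- active & stats::runif(nt) < noise$fire_prob
      if (noise$false_rate > 0) {
        fired <- fired | (!active & stats::runif(nt) < noise$false_rate)
      }
      lux <- 1 + lux_day + 150 * (active & waking) +
        stats::rnorm(nt, 0, noise$lux_sd)
      accel <- abs(stats::rnorm(nt, 0, noise$accel_sd))
      if (layout$mount[b] == "fridge_door" && nrow(cook) > 0) {
        # a couple of fridge openings per cooking episode
        spikes <- c(cook$start_s + 10, (cook$start_s + cook$end_s) / 2)
        idx <- floor(spikes / period) + 1L
        idx <- idx[idx >= 1L & idx <= nt]
        accel[idx] <- accel[idx] + 2.5
      }
      if (layout$mount[b] == "flush_handle" && nrow(toilet) > 0) {
        spikes <- toilet$end_s - 10
        idx <- floor(spikes / period) + 1L
        idx <- idx[idx >= 1L & idx <= nt]
        accel[idx] <- accel[idx] + 2.5
      }
      streams[[b]] <- tibble::tibble(
        timestamp_s = t,
        box_id = layout$box_id[b],
        temperature_c = 21 + 1.5 * sin(2 * pi * (clock_h - 15) / 24) +
          stats::rnorm(nt, 0, noise$temp_sd),
        humidity_g_m3 = 50 + 5 * sin(2 * pi * (clock_h - 16) / 24) +
          stats::rnorm(nt, 0, noise$hum_sd),
        luminescence_lx = pmax(0, lux),
        presence = as.integer(fired),
        acceleration_m_s2 = accel
      )
      if (noise$dropout > 0) {
        streams[[b]] <-
          streams[[b]][stats::runif(nt) >= noise$dropout, ]
      }
    }
  })
  dplyr::bind_rows(streams)
}
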