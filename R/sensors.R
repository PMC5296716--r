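# Sensor-stream data model: five-channel ambient sensor boxes sampled at
# 0.2 Hz (one sample every 5 s), identified by box and bound to a room via
# the home layout.

SENSOR_COLUMNS <- c("timestamp_s", "box_id", "temperature_c",
                    "humidity_g_m3", "luminescence_lx", "presence",
                    "acceleration_m_s2")

#' Nominal sampling period of the sensor boxes, in seconds
#'
#' The boxes sample all five channels at 0.2 Hz.
#'
#' @return 5 (seconds).
#' @export
sampling_period_s <- function() 5

#' Describe the sensor boxes installed in a home
#'
#' @param box_id Unique box identifiers.
#' @param room Room label each box observes (e.g. `"kitchen"`).
#' @param mount `"wall"`, `"fridge_door"` or `"flush_handle"`. Fridge-door
#'   boxes must sit in the kitchen and flush-handle boxes in the bathroom.
#' @return A validated layout tibble.
#' @export
home_layout <- function(box_id, room, mount = "wall") {
  x <- tibble::tibble(box_id = as.character(box_id),
                      room = as.character(room),
                      mount = as.character(mount))
  if (anyDuplicated(x$box_id)) {
    rlang::abort("box_id must be unique within a home",
                 class = "adl_config_error")
  }
  bad_mount <- setdiff(unique(x$mount), c("wall", "fridge_door", "flush_handle"))
  if (length(bad_mount) > 0) {
    rlang::abort(paste0("unknown mount: ", paste(bad_mount, collapse = ", ")),
                 class = "adl_config_error")
  }
  if (any(x$mount == "fridge_door" & x$room != "kitchen")) {
    rlang::abort("fridge_door boxes must be in the kitchen",
                 class = "adl_config_error")
  }
  if (any(x$mount == "flush_handle" & x$room != "bathroom")) {
    rlang::abort("flush_handle boxes must be in the bathroom",
                 class = "adl_config_error")
  }
  x
}

#' Default ten-box home layout
#'
#' Eight wall-mounted boxes spread over the rooms of a one-person apartment
#' plus one box in the fridge door and one on the toilet flush handle.
#'
#' @return Layout tibble with 10 boxes.
#' @export
default_home_layout <- function() {
  home_layout(
    box_id = c("B01", "B02", "B03", "B04", "B05", "B06", "B07", "B08",
               "B09", "B10"),
    room = c("bedroom", "bathroom", "kitchen", "living", "hallway",
             "entrance", "study", "dining", "kitchen", "bathroom"),
    mount = c(rep("wall", 8), "fridge_door", "flush_handle")
  )
}

#' Read a long-format ambient sensor CSV
#'
#' Expects the documented header `timestamp_s, box_id, temperature_c,
#' humidity_g_m3, luminescence_lx, presence, acceleration_m_s2`. All rows
#' are parsed or an error is raised listing the offending line numbers.
#' Row order (and therefore duplicate timestamps) is preserved; rows are
#' returned grouped by box in order of first appearance.
#'
#' @param path CSV file path.
#' @return A tibble of sensor samples, rows ordered by box then original
#'   file order.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "adl_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  missing <- setdiff(SENSOR_COLUMNS, header)
  if (length(missing) > 0) {
    rlang::abort(paste0("sensor CSV is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "adl_format_error")
  }
  # parse failures become a structured error below, not a readr warning
  x <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    timestamp_s = readr::col_double(),
    box_id = readr::col_character(),
    temperature_c = readr::col_double(),
    humidity_g_m3 = readr::col_double(),
    luminescence_lx = readr::col_double(),
    presence = readr::col_double(),
    acceleration_m_s2 = readr::col_double()
  ), progress = FALSE, lazy = FALSE))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    rlang::abort(paste0("non-numeric or malformed value(s) at line(s): ",
                        paste(unique(probs$row + 1L), collapse = ", ")),
                 class = "adl_parse_error")
  }
  x <- x[SENSOR_COLUMNS]
  # stable grouping by box in order of first appearance
  x[order(match(x$box_id, unique(x$box_id))), ]
}

#' Write a sensor sample table to CSV
#'
#' Inverse of [read_sensor_csv()]; round trip preserves identifiers exactly
#' and reals to double precision.
#'
#' @param samples Sensor sample tibble with the documented columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(samples, path) {
  missing <- setdiff(SENSOR_COLUMNS, names(samples))
  if (length(missing) > 0) {
    rlang::abort(paste0("sensor table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "adl_format_error")
  }
  readr::write_csv(tibble::as_tibble(samples)[SENSOR_COLUMNS], path)
  invisible(path)
}

#' Sort sensor samples room-wise, then chronologically
#'
#' The pre-analysis step of the pipeline: samples are grouped by the room
#' their box observes and each room's stream is sorted by timestamp
#' (stably, so duplicated timestamps keep their input order). Sample count
#' is conserved and the operation is idempotent.
#'
#' @param samples Sensor sample tibble.
#' @param layout Home layout mapping every `box_id` to a room.
#' @return Named list of per-room tibbles (samples plus a `room` column),
#'   each chronologically ordered, names sorted alphabetically.
#' @export
sort_room_chronological <- function(samples, layout) {
  samples <- tibble::as_tibble(samples)
  unknown <- setdiff(unique(samples$box_id), layout$box_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("box_id not in layout: ",
                        paste(unknown, collapse = ", ")),
                 class = "adl_config_error")
  }
  samples$room <- layout$room[match(samples$box_id, layout$box_id)]
  samples <- samples[order(samples$room, samples$timestamp_s,
                           method = "radix"), ]
  out <- split(samples, samples$room)
  out[sort(names(out))]
}
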