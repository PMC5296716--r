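test_that("sensor CSV reading handles empty files, grouping and duplicates", {
  hdr <- paste(c("timestamp_s", "box_id", "temperature_c", "humidity_g_m3",
                 "luminescence_lx", "presence", "acceleration_m_s2"),
               collapse = ",")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, f)
  expect_equal(nrow(read_sensor_csv(f)), 0)

  writeLines(c(hdr,
               "0,B01,21,50,100,1,0",
               "5,B01,21,50,100,0,0",
               "10,B01,21,50,100,1,0"), f)
  x <- read_sensor_csv(f)
  expect_equal(nrow(x), 3)
  expect_equal(unique(x$box_id), "B01")

  # duplicated timestamp for one box: both rows kept through a round trip
  writeLines(c(hdr,
               "5,B01,21,50,100,1,0",
               "5,B01,22,51,101,0,0",
               "0,B02,20,49,90,0,0"), f)
  x <- read_sensor_csv(f)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(x, f2)
  y <- read_sensor_csv(f2)
  expect_equal(nrow(y), 3)
  expect_equal(y, x)
})

test_that("sensor CSV errors name the problem", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp_s,box_id,temperature_c", f)
  expect_error(read_sensor_csv(f), "missing column",
               class = "adl_format_error")
  hdr <- paste(c("timestamp_s", "box_id", "temperature_c", "humidity_g_m3",
                 "luminescence_lx", "presence", "acceleration_m_s2"),
               collapse = ",")
  writeLines(c(hdr, "0,B01,21,50,100,1,0", "5,B01,oops,50,100,1,0"), f)
  expect_error(read_sensor_csv(f), "line", class = "adl_parse_error")
})

test_that("room-chronological sort matches a brute-force oracle and conserves samples", {
  layout <- home_layout(c("b1", "b2", "b3", "b4"),
                        c("kitchen", "kitchen", "bedroom", "living"))
  set.seed(11)
  n <- 1000
  samples <- tibble::tibble(
    timestamp_s = round(runif(n, 0, 86400), 1),
    box_id = sample(layout$box_id, n, replace = TRUE),
    temperature_c = 21, humidity_g_m3 = 50, luminescence_lx = 100,
    presence = rbinom(n, 1, 0.3), acceleration_m_s2 = 0)
  out <- sort_room_chronological(samples, layout)

  # oracle: sort everything once, then partition by room
  all_sorted <- samples
  all_sorted$room <- layout$room[match(all_sorted$box_id, layout$box_id)]
  all_sorted <- all_sorted[order(all_sorted$room, all_sorted$timestamp_s), ]
  oracle <- split(all_sorted, all_sorted$room)
  expect_equal(names(out), sort(names(oracle)))
  for (rm in names(out)) {
    expect_equal(out[[rm]]$timestamp_s, oracle[[rm]]$timestamp_s)
    expect_false(is.unsorted(out[[rm]]$timestamp_s))
  }
  expect_equal(sum(vapply(out, nrow, 0L)), n)

  # idempotence: resorting the concatenated output changes nothing
  again <- sort_room_chronological(dplyr::bind_rows(out), layout)
  expect_equal(dplyr::bind_rows(again), dplyr::bind_rows(out))

  # single sample, and unknown boxes are named in the error
  one <- samples[1, ]
  expect_equal(nrow(sort_room_chronological(one, layout)[[1]]), 1)
  bad <- samples
  bad$box_id[1] <- "ghost"
  expect_error(sort_room_chronological(bad, layout), "ghost",
               class = "adl_config_error")
})

test_that("episode round trips are lossless in both formats", {
  ep <- adl_episodes(
    subject_id = rep("s1", 3),
    category = c("Cooking", "Sleeping", "Toileting"),
    day_index = c(1, 1, 2),
    onset = c(690, 1439.5, 600.25),
    duration = c(40, 45, 7.5),
    source = "truth")
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_episodes(ep, f)
    back <- read_episodes(f)
    expect_equal(back$subject_id, ep$subject_id)
    expect_equal(back$onset, ep$onset, tolerance = 1e-9)
    expect_equal(back$duration, ep$duration, tolerance = 1e-9)
  }
  # empty table round trip
  empty <- ep[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_episodes(empty, f)
  expect_equal(nrow(read_episodes(f)), 0)
})

test_that("episode validation enforces the domain invariants", {
  expect_error(adl_episodes("s", "Napping", 1, 0, 10),
               class = "adl_format_error")
  expect_error(adl_episodes("s", "Cooking", 0, 0, 10),
               class = "adl_format_error")
  expect_error(adl_episodes("s", "Cooking", 1, 1500, 10),
               class = "adl_format_error")
  # only Sleeping may cross midnight
  expect_error(adl_episodes("s", "Cooking", 1, 1430, 60),
               class = "adl_format_error")
  expect_silent(adl_episodes("s", "Sleeping", 1, 1430, 480))
  # same-category overlap
  expect_error(
    adl_episodes(c("s", "s"), c("Cooking", "Cooking"), c(1, 1),
                 c(600, 620), c(40, 10)),
    "overlap", class = "adl_format_error")
})

test_that("midnight splitting cuts non-Sleeping episodes at the boundary", {
  raw <- tibble::tibble(subject_id = "s", category = "WatchingTV",
                        day_index = 1L, onset = 1400, duration = 100,
                        source = "truth")
  out <- split_at_midnight(raw)
  expect_equal(nrow(out), 2)
  expect_equal(out$duration, c(40, 60))
  expect_equal(out$day_index, c(1L, 2L))
  expect_equal(out$onset, c(1400, 0))
  # trailing fragment beyond the study is dropped
  expect_equal(nrow(split_at_midnight(raw, n_days = 1)), 1)
})
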