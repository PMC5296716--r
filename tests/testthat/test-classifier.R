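test_that("presence intervals merge triggers within the gap threshold", {
  iv <- detect_presence_intervals(c(0, 60, 120), gap_close_s = 300)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start_s, iv$end_s, iv$trigger_count), c(0, 120, 3))

  iv2 <- detect_presence_intervals(c(0, 1000), gap_close_s = 300)
  expect_equal(nrow(iv2), 2)

  expect_equal(nrow(detect_presence_intervals(numeric(0))), 0)
})

test_that("interval aggregation equals a single-pass scan oracle", {
  set.seed(42)
  tr <- sort(round(runif(500, 0, 86400)))
  gap <- 180
  got <- detect_presence_intervals(tr, gap)
  # oracle: explicit scan over the sorted trigger list
  starts <- ends <- counts <- numeric(0)
  cur_s <- tr[1]; cur_e <- tr[1]; cur_n <- 1
  for (t in tr[-1]) {
    if (t - cur_e > gap) {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      counts <- c(counts, cur_n)
      cur_s <- t; cur_n <- 0
    }
    cur_e <- t; cur_n <- cur_n + 1
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e); counts <- c(counts, cur_n)
  expect_equal(got$start_s, starts)
  expect_equal(got$end_s, ends)
  expect_equal(got$trigger_count, as.integer(counts))
})

test_that("template matching recognises scripted intervals", {
  # kitchen presence 12:00-12:25 with two fridge markers -> Cooking
  iv <- tibble::tibble(room = "kitchen", start_s = 720 * 60,
                       end_s = 745 * 60, trigger_count = 300L,
                       median_lux = 300)
  mk <- tibble::tibble(kind = "fridge_door",
                       time_s = c(721, 735) * 60)
  rec <- recognize_adl(iv, mk, study_end_s = 86400)
  cooking <- rec[rec$category == "Cooking", ]
  expect_equal(nrow(cooking), 1)
  expect_equal(cooking$onset, 720)
  expect_equal(cooking$duration, 25)

  # same interval without a fridge marker is not Cooking
  rec2 <- recognize_adl(iv, NULL, study_end_s = 86400)
  expect_false("Cooking" %in% rec2$category)
})

test_that("marker rules dominate same-room alternatives", {
  # 10-minute morning bathroom presence matches both Toileting and
  # Grooming templates; the flush marker plus priority resolves it
  iv <- tibble::tibble(room = "bathroom", start_s = 600 * 60,
                       end_s = 610 * 60, trigger_count = 120L,
                       median_lux = 200)
  with_flush <- tibble::tibble(kind = "flush_handle", time_s = 609 * 60)
  rec <- recognize_adl(iv, with_flush, study_end_s = 86400)
  expect_true("Toileting" %in% rec$category)
  expect_false("Grooming" %in% rec$category)
  rec2 <- recognize_adl(iv, NULL, study_end_s = 86400)
  expect_true("Grooming" %in% rec2$category)
})

test_that("whole-home absence is reported as OutOfHome", {
  rec <- recognize_adl(
    tibble::tibble(room = character(0), start_s = numeric(0),
                   end_s = numeric(0)),
    study_end_s = 86400)
  expect_equal(rec$category, "OutOfHome")
  expect_equal(rec$duration, 1440)
  expect_error(recognize_adl(tibble::tibble(), templates = NULL),
               class = "adl_config_error")
})

test_that("recognition metrics behave on constructed cases", {
  tr <- adl_episodes(rep("s", 2), c("Cooking", "Grooming"), c(1, 1),
                     c(690, 420), c(40, 20))
  ident <- tr
  ident$source <- "recognised"
  ev <- evaluate_recognition(ident, tr)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  ev0 <- evaluate_recognition(ident[0, ], tr)
  expect_equal(ev0$sensitivity, 0)

  shifted <- tr
  shifted$onset <- shifted$onset + 10
  shifted$source <- "recognised"
  expect_equal(evaluate_recognition(shifted, tr, tolerance_min = 15)$sensitivity, 1)

  expect_error(evaluate_recognition(ident, tr, tolerance_min = -1),
               class = "adl_argument_error")
})

test_that("noise-free rendered streams are recognised consistently with truth", {
  tr <- noise_free_schedule(n_days = 3)
  st <- render_sensor_stream(tr, noise = sensor_noise_free(), seed = 2,
                             n_days = 3)
  rec <- classify_stream(st, subject_id = "s0", study_end_s = 3 * 86400)
  rec2 <- classify_stream(st, subject_id = "s0", study_end_s = 3 * 86400)
  expect_identical(rec, rec2)  # deterministic

  ev <- evaluate_recognition(rec, tr)
  expect_gte(ev$sensitivity, 0.95)
  expect_gte(ev$specificity, 0.95)

  # recognised core episodes respect their template duration bounds
  tmpl <- default_adl_templates()
  core <- rec[rec$category %in% tmpl$category, ]
  lo <- tmpl$min_duration[match(core$category, tmpl$category)]
  hi <- tmpl$max_duration[match(core$category, tmpl$category)]
  # midnight-split fragments are legitimately shorter than the template
  whole <- core$category == "Sleeping" |
    (core$onset > 0 & core$onset + core$duration < 1440)
  expect_true(all(core$duration[whole] >= lo[whole] - 1e-9))
  expect_true(all(core$duration[whole] <= hi[whole] + 1e-9))
})
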