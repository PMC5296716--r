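test_that("daily feature extraction computes median deviations and pass-throughs", {
  ep <- adl_episodes(rep("s", 3), "Grooming", 1:3, c(480, 480, 480),
                     c(20, 20, 20))
  s <- extract_daily_feature(ep, "Grooming")
  expect_equal(s$values, c(0, 0, 0))

  ep2 <- adl_episodes(rep("s", 3), "Grooming", 1:3, c(420, 480, 540),
                      c(20, 20, 20))
  expect_equal(extract_daily_feature(ep2, "Grooming")$values, c(60, 0, 60))

  ep3 <- adl_episodes(rep("s", 2), "Cooking", 1:2, c(690, 700), c(30, 45))
  expect_equal(extract_daily_feature(ep3, "Cooking", "duration_min")$values,
               c(30, 45))

  # multiple episodes on a day: the first by onset is used
  ep4 <- adl_episodes(rep("s", 3), "Cooking", c(1, 1, 2),
                      c(700, 690, 695), c(30, 5, 30))
  expect_equal(extract_daily_feature(ep4, "Cooking", "onset_min")$values,
               c(690, 695))

  # fewer than two occupied days: flagged, no pairs possible
  one <- extract_daily_feature(ep[1, ], "Grooming")
  expect_true(one$insufficient)
  expect_error(build_pairs(one), class = "adl_insufficient_data")
})

test_that("lagged pairs follow the index-shift construction", {
  expect_equal(build_pairs(c(7, 7, 7)),
               tibble::tibble(x = c(7, 7), y = c(7, 7)))
  expect_equal(build_pairs(c(10, 20, 15)),
               tibble::tibble(x = c(10, 20), y = c(20, 15)))
  set.seed(1)
  v <- rnorm(50)
  p <- build_pairs(v)
  expect_equal(nrow(p), 49)
  for (i in seq_len(49)) {
    expect_identical(c(p$x[i], p$y[i]), c(v[i], v[i + 1]))
  }
  # configurable lag in sequence steps
  p2 <- build_pairs(v, lag = 2)
  expect_equal(p2$y, v[3:50])
})

test_that("ellipse descriptors match hand-worked and degenerate cases", {
  de <- fit_ellipse(tibble::tibble(x = c(5, 5, 5), y = c(5, 5, 5)))
  expect_equal(de$short_axis, 0)
  expect_equal(de$long_axis, 0)
  expect_equal(de$centroid, 5)
  expect_equal(unname(de$centroid_point), c(5, 5))

  de2 <- fit_ellipse(tibble::tibble(x = c(0, 2), y = c(2, 0)))
  expect_equal(de2$short_axis, sqrt(2))
  expect_equal(de2$long_axis, 0)
  expect_equal(de2$centroid, 1)

  # a single pair is degenerate but well-defined; zero pairs error
  one <- fit_ellipse(tibble::tibble(x = 3, y = 5))
  expect_equal(one$centroid, 4)
  expect_equal(c(one$long_axis, one$short_axis), c(0, 0))
  expect_error(fit_ellipse(tibble::tibble(x = numeric(0), y = numeric(0))),
               class = "adl_insufficient_data")
})

test_that("ellipse fit agrees with the rotation oracle on random clouds", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    x <- rnorm(n, runif(1, -50, 50), runif(1, 0.1, 20))
    y <- rnorm(n, runif(1, -50, 50), runif(1, 0.1, 20))
    de <- fit_ellipse(tibble::tibble(x = x, y = y))
    or <- ellipse_oracle(x, y)
    expect_equal(de$short_axis, or$short, tolerance = 1e-9)
    expect_equal(de$long_axis, or$long, tolerance = 1e-9)
    expect_equal(de$centroid, or$centroid, tolerance = 1e-9)
  }
})

test_that("large i.i.d. clouds recover the generating parameters", {
  set.seed(5)
  mu <- 40; sigma <- 7
  p <- tibble::tibble(x = rnorm(1000, mu, sigma), y = rnorm(1000, mu, sigma))
  de <- fit_ellipse(p)
  expect_equal(de$centroid, mu, tolerance = 0.05 * mu)
  expect_equal(de$long_axis, sigma, tolerance = 0.1 * sigma)
  expect_equal(de$short_axis, sigma, tolerance = 0.1 * sigma)
})

test_that("adding a constant shifts the centroid and leaves the short axis", {
  set.seed(9)
  v <- rnorm(30, 50, 10)
  d1 <- fit_ellipse(build_pairs(v))
  d2 <- fit_ellipse(build_pairs(v + 12.5))
  expect_equal(d2$short_axis, d1$short_axis, tolerance = 1e-12)
  expect_equal(d2$long_axis, d1$long_axis, tolerance = 1e-12)
  expect_equal(d2$centroid, d1$centroid + 12.5, tolerance = 1e-12)
})

test_that("subject heterogeneity averages the available core centroids", {
  # two categories with constant durations give known centroids 40 and 60;
  # the rest have a single day and are excluded
  ep <- dplyr::bind_rows(
    adl_episodes(rep("s", 2), "Cooking", 1:2, c(690, 690), c(40, 40)),
    adl_episodes(rep("s", 2), "Eating", 1:2, c(740, 740), c(60, 60)),
    adl_episodes("s", "Grooming", 1, 420, 20))
  h <- subject_heterogeneity(ep, feature_kind = "duration_min")
  expect_equal(as.numeric(h), 50)
  expect_setequal(attr(h, "categories_used"), c("Cooking", "Eating"))
  expect_true("Grooming" %in% attr(h, "categories_excluded"))

  expect_error(subject_heterogeneity(ep[5, ]),
               class = "adl_insufficient_data")

  # brute-force mean oracle on a random cohort member
  tr <- generate_schedule(subject_profile("r", "dementia", seed = 31),
                          cohort_config(0, 1, 12))
  de <- poincare_descriptors(tr)
  expect_equal(as.numeric(subject_heterogeneity(tr)),
               sum(de$centroid, na.rm = TRUE) / sum(!is.na(de$centroid)))
})

test_that("per-day heterogeneity equals the one-shot computation at each day", {
  tr <- generate_schedule(subject_profile("m", "dementia", seed = 13),
                          cohort_config(0, 1, 10))
  hbd <- heterogeneity_by_day(tr)
  for (d in c(3, 6, 10)) {
    expect_equal(hbd$heterogeneity[hbd$day == d],
                 as.numeric(subject_heterogeneity(tr, day_limit = d)))
  }
})

test_that("day-periodic schedules give zero short axis and zero deviation centroid", {
  tr <- noise_free_schedule(n_days = 8)
  de <- poincare_descriptors(tr)
  expect_true(all(de$short_axis == 0))
  expect_true(all(de$centroid == 0))
  expect_true(all(de$long_axis == 0))
})

test_that("dementia profiles have larger heterogeneity than healthy ones", {
  hets <- function(group, seeds) {
    vapply(seeds, function(s) {
      tr <- generate_schedule(subject_profile("x", group, seed = s),
                              cohort_config(1, 1, 20))
      as.numeric(subject_heterogeneity(tr))
    }, 0)
  }
  h <- hets("healthy", 1:50)
  d <- hets("dementia", 101:150)
  expect_gt(mean(d), mean(h))
  expect_lt(mann_whitney_u(h, d)$p.value, 0.01)
})
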