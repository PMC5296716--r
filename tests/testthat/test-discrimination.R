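test_that("midpoint cutoff is the mean of the two group means", {
  expect_equal(midpoint_cutoff(rep(50, 5), rep(100, 5)), 75)
  expect_equal(midpoint_cutoff(7, 7), 7)
  expect_error(midpoint_cutoff(numeric(0), 1), class = "adl_argument_error")

  # midpoint of the reference cohort's per-category centroid group means
  ref <- reference_cohort_summary()$categories
  cut <- midpoint_cutoff(ref$centroid_healthy_mean[ref$core],
                         ref$centroid_dementia_mean[ref$core])
  expect_equal(round(cut, 2), 75.48)
})

test_that("classification uses strictly-greater with ties healthy", {
  expect_equal(classify_subject(80, 75), "dementia")
  expect_equal(classify_subject(75, 75), "healthy")
  set.seed(2)
  v <- runif(100, 0, 100)
  cut <- 50
  expect_equal(classify_subject(v, cut),
               ifelse(v > cut, "dementia", "healthy"))
})

test_that("confusion metrics implement the standard definitions", {
  m <- confusion_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))
  m2 <- confusion_metrics(tp = 0, fp = 0, tn = 10, fn = 10)
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(0, 1, 0.5))
  # zero denominators are flagged, not silently zero
  m3 <- confusion_metrics(tp = 3, fp = 0, tn = 0, fn = 1)
  expect_true(is.na(m3$specificity))
  expect_true("specificity" %in% m3$undefined)
})

test_that("LOOCV equals an exhaustive fold enumeration oracle", {
  het <- tibble::tibble(
    subject_id = c("h1", "h2", "p1", "p2"),
    group = c("healthy", "healthy", "dementia", "dementia"),
    day = 1L,
    heterogeneity = c(40, 60, 100, 120))
  got <- loocv_curve(het)
  expect_equal(got$accuracy, 1)
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)

  # independent enumeration on a random 3+3 cohort
  set.seed(8)
  het2 <- tibble::tibble(
    subject_id = paste0("s", 1:6),
    group = rep(c("healthy", "dementia"), each = 3),
    day = 1L,
    heterogeneity = c(rnorm(3, 30, 20), rnorm(3, 60, 20)))
  got2 <- loocv_curve(het2)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:6) {
    tr <- het2[-i, ]
    cut <- (mean(tr$heterogeneity[tr$group == "healthy"]) +
              mean(tr$heterogeneity[tr$group == "dementia"])) / 2
    pred <- if (het2$heterogeneity[i] > cut) "dementia" else "healthy"
    truth <- het2$group[i]
    if (pred == "dementia" && truth == "dementia") tp <- tp + 1
    if (pred == "dementia" && truth == "healthy") fp <- fp + 1
    if (pred == "healthy" && truth == "healthy") tn <- tn + 1
    if (pred == "healthy" && truth == "dementia") fn <- fn + 1
  }
  expect_equal(got2$sensitivity, tp / (tp + fn))
  expect_equal(got2$specificity, tn / (tn + fp))
  expect_equal(got2$accuracy, (tp + tn) / 6)

  expect_error(loocv_curve(het[-1, ]), class = "adl_argument_error")
})

test_that("LOOCV predictions are invariant to a constant shift", {
  het <- cohort_het(4, 4, 6, master_seed = 3)
  base <- loocv_curve(het)
  shifted <- het
  shifted$heterogeneity <- shifted$heterogeneity + 123.4
  expect_equal(loocv_curve(shifted)[c("day", "sensitivity", "specificity",
                                      "accuracy")],
               base[c("day", "sensitivity", "specificity", "accuracy")],
               ignore_attr = TRUE)
})

test_that("mirroring the feature axis and exchanging groups swaps sensitivity and specificity", {
  het <- tibble::tibble(
    subject_id = paste0("s", 1:8),
    group = rep(c("healthy", "dementia"), each = 4),
    day = 1L,
    heterogeneity = c(10, 20, 30, 95, 70, 80, 90, 15))
  sw <- het
  sw$group <- ifelse(het$group == "healthy", "dementia", "healthy")
  sw$heterogeneity <- -het$heterogeneity
  a <- loocv_curve(het)
  b <- loocv_curve(sw)
  expect_equal(b$sensitivity, a$specificity)
  expect_equal(b$specificity, a$sensitivity)
})

test_that("Mann-Whitney test matches exact and permutation oracles", {
  null_case <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(null_case$p.value, 1)

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p.value, 0.1)

  # agreement with the standard exact test on untied small samples
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(5)
    b <- rnorm(6, 0.8)
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }

  # large-sample approximation vs a 100,000-draw permutation estimate
  set.seed(6)
  a <- rnorm(10, 0, 1)
  b <- rnorm(10, 1, 1)
  got <- mann_whitney_u(a, b)
  pooled <- c(a, b)
  r <- rank(pooled)
  centre <- 10 * 10 / 2
  obs <- abs(sum(r[1:10]) - 55 - centre)
  perm <- replicate(100000, {
    ix <- sample.int(20, 10)
    abs(sum(r[ix]) - 55 - centre)
  })
  expect_lt(abs(got$p.value - mean(perm >= obs - 1e-9)), 0.005)

  expect_warning(mann_whitney_u(c(2, 2), c(2, 2, 2)), "tied")
})

test_that("ROC analysis separates well-separated groups", {
  set.seed(10)
  het <- c(rnorm(10, 15, 5), rnorm(10, 60, 10))
  grp <- rep(c("healthy", "dementia"), each = 10)
  r <- roc_analysis(het, grp)
  expect_gt(r$auc, 0.95)
  expect_true(all(c("threshold", "sensitivity", "specificity") %in%
                    names(r$best)))
})

test_that("the group comparison table mirrors per-category descriptors", {
  co <- generate_cohort(cohort_config(3, 3, 10, master_seed = 5))
  desc <- dplyr::bind_rows(lapply(split(co$truth, co$truth$subject_id),
                                  poincare_descriptors))
  tab <- group_comparison_table(desc, co$groups)
  expect_setequal(tab$category, core_adl())
  expect_true(all(tab$dementia_mean > tab$healthy_mean))
  expect_true(all(tab$p_value <= 1 & tab$p_value >= 0, na.rm = TRUE))
})
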