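# Discrimination stage: dynamic midpoint cutoff on the heterogeneity
# feature, leave-one-out cross-validation, confusion-matrix metrics, and
# the accuracy/sensitivity/specificity curve as a function of observation
# duration. The positive class is "dementia" (higher heterogeneity).

#' Midpoint cutoff between two groups' heterogeneity values
#'
#' The arithmetic mean of the two groups' average heterogeneities
#' (Poincare centroids): `cutoff = (mean(healthy) + mean(patient)) / 2`.
#'
#' @param healthy,patient Non-empty numeric vectors of per-subject
#'   heterogeneity values.
#' @return Cutoff scalar, in feature units.
#' @export
midpoint_cutoff <- function(healthy, patient) {
  if (length(healthy) == 0 || length(patient) == 0) {
    rlang::abort("both groups must be non-empty",
                 class = "adl_argument_error")
  }
  (mean(healthy) + mean(patient)) / 2
}

#' Classify a subject by heterogeneity cutoff
#'
#' `"dementia"` iff heterogeneity is strictly greater than the cutoff
#' (higher heterogeneity = more irregular routine); a tie at exactly the
#' cutoff classifies as `"healthy"`.
#'
#' @param heterogeneity Numeric vector of heterogeneity values.
#' @param cutoff Cutoff scalar.
#' @return Character vector of `"healthy"` / `"dementia"`.
#' @export
classify_subject <- function(heterogeneity, cutoff) {
  ifelse(heterogeneity > cutoff, "dementia", "healthy")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`; positive class =
#' dementia. A zero denominator yields `NA` and the metric's name in the
#' `undefined` field, never a silent zero.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `undefined` (character vector of undefined metrics).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  acc <- if (tp + fp + tn + fn > 0) (tp + tn) / (tp + fp + tn + fn) else {
    undefined <- c(undefined, "accuracy"); NA_real_
  }
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       undefined = undefined)
}

#' Leave-one-out discrimination curve over observation duration
#'
#' For each observation day `d` and each held-out subject, the cutoff is
#' recomputed ("dynamically") from the remaining subjects' day-`d`
#' heterogeneities via [midpoint_cutoff()] and the held-out subject is
#' classified with [classify_subject()]; the per-day confusion counts give
#' sensitivity, specificity and accuracy.
#'
#' @param het Tibble with columns `subject_id`, `group`
#'   (`"healthy"`/`"dementia"`), `day`, `heterogeneity` -- one finite value
#'   per subject per day (see [heterogeneity_by_day()]).
#' @param days Days to evaluate (default: all days present in `het`).
#' @return Tibble: `day`, `sensitivity`, `specificity`, `accuracy`,
#'   `mean_cutoff`, plus a `fold_cutoffs` attribute (list of per-day
#'   numeric vectors, one cutoff per held-out subject).
#' @export
loocv_curve <- function(het, days = NULL) {
  het <- tibble::as_tibble(het)
  stopifnot(all(c("subject_id", "group", "day", "heterogeneity") %in%
                  names(het)))
  days <- days %||% sort(unique(het$day))
  fold_cutoffs <- vector("list", length(days))
  names(fold_cutoffs) <- as.character(days)
  rows <- vector("list", length(days))
  for (j in seq_along(days)) {
    d <- het[het$day == days[j], ]
    if (any(!is.finite(d$heterogeneity))) {
      rlang::abort(paste0("missing heterogeneity values on day ", days[j],
                          " for: ",
                          paste(d$subject_id[!is.finite(d$heterogeneity)],
                                collapse = ", ")),
                   class = "adl_argument_error")
    }
    if (sum(d$group == "healthy") < 2 || sum(d$group == "dementia") < 2) {
      rlang::abort("LOOCV needs at least 2 subjects per group",
                   class = "adl_argument_error")
    }
    cutoffs <- numeric(nrow(d))
    pred <- character(nrow(d))
    for (i in seq_len(nrow(d))) {
      train <- d[-i, ]
      cutoffs[i] <- midpoint_cutoff(
        train$heterogeneity[train$group == "healthy"],
        train$heterogeneity[train$group == "dementia"])
      pred[i] <- classify_subject(d$heterogeneity[i], cutoffs[i])
    }
    tp <- sum(pred == "dementia" & d$group == "dementia")
    fp <- sum(pred == "dementia" & d$group == "healthy")
    tn <- sum(pred == "healthy" & d$group == "healthy")
    fn <- sum(pred == "healthy" & d$group == "dementia")
    m <- confusion_metrics(tp, fp, tn, fn)
    fold_cutoffs[[j]] <- stats::setNames(cutoffs, d$subject_id)
    rows[[j]] <- tibble::tibble(day = days[j], sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                accuracy = m$accuracy,
                                mean_cutoff = mean(cutoffs))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fold_cutoffs") <- fold_cutoffs
  out
}

#' Mann-Whitney U test (exact for small samples, tie-aware otherwise)
#'
#' Two-sided rank-sum test. For combined sample sizes up to 12 the p-value
#' is computed by exhaustive enumeration of all group assignments of the
#' pooled values (valid under ties); for larger samples the tie-corrected
#' normal approximation with continuity correction is used. When all
#' values are tied across both groups the test is vacuous and p = 1 (with
#' a warning).
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `statistic` (U of group `a`), `p.value`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("both groups must be non-empty",
                 class = "adl_argument_error")
  }
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    r <- rank(pooled)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  u <- u_of(seq_len(n))
  centre <- n * m / 2
  if (length(unique(pooled)) == 1L) {
    rlang::warn("all values tied across both groups; test is vacuous")
    return(list(statistic = u, p.value = 1,
                method = "Mann-Whitney U (degenerate ties)"))
  }
  if (n + m <= 12) {
    combos <- utils::combn(n + m, n)
    r <- rank(pooled)
    u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
    p <- mean(abs(u_all - centre) >= abs(u - centre) - 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    # tie-corrected normal approximation with continuity correction
    nt <- n + m
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((nt^3 - nt - sum(ties^3 - ties)) / (nt * (nt - 1)))
    z <- (u - centre - sign(u - centre) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  list(statistic = u, p.value = p, method = method)
}

#' Empirical ROC analysis of the heterogeneity feature
#'
#' Full cutoff sweep with AUC, complementing the operational midpoint
#' cutoff: reports the empirical ROC curve and the Youden-optimal
#' threshold.
#'
#' @param heterogeneity Per-subject feature values.
#' @param group `"healthy"`/`"dementia"` labels, parallel to
#'   `heterogeneity`.
#' @return List with `auc`, `best` (Youden-optimal threshold with its
#'   sensitivity/specificity), and the underlying `pROC::roc` object.
#' @export
roc_analysis <- function(heterogeneity, group) {
  r <- pROC::roc(response = factor(group, levels = c("healthy", "dementia")),
                 predictor = heterogeneity, direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)), best = tibble::as_tibble(best),
       roc = r)
}

#' Per-category group comparison of Poincare centroids
#'
#' For every category: group means and standard errors of the per-subject
#' centroid scalars, with the two-sided Mann-Whitney p-value -- the
#' reproducible analogue of a cohort summary table.
#'
#' @param descriptors Row-bound [poincare_descriptors()] tables of all
#'   subjects.
#' @param groups Tibble `subject_id`, `group`.
#' @return Tibble: `category`, `n_healthy`, `n_dementia`, group mean and
#'   SEM columns, `p_value`.
#' @export
group_comparison_table <- function(descriptors, groups) {
  d <- dplyr::left_join(tibble::as_tibble(descriptors), groups,
                        by = "subject_id")
  d <- d[!is.na(d$centroid), ]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(split(d, d$category), function(g) {
    h <- g$centroid[g$group == "healthy"]
    p <- g$centroid[g$group == "dementia"]
    tibble::tibble(
      category = g$category[1],
      n_healthy = length(h), n_dementia = length(p),
      healthy_mean = mean(h), healthy_sem = sem(h),
      dementia_mean = mean(p), dementia_sem = sem(p),
      p_value = if (length(h) > 0 && length(p) > 0)
        mann_whitney_u(h, p)$p.value else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(match(out$category, adl_categories()$category)), ]
}
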