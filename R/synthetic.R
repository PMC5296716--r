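# Synthetic smart-home cohort generator. Real deployments of the kind this
# package analyses (20 single-resident homes instrumented for 20 days) do
# not publish raw streams, so the statistical stages are exercised on
# simulated subjects whose day-to-day regularity is controlled explicitly:
# "healthy" profiles follow a daily template closely; "dementia" profiles
# jitter, omit, fragment and intersperse activities, producing the
# unorganised routines the heterogeneity feature is designed to detect.

#' Behavioural noise profile of one synthetic subject
#'
#' @param subject_id Identifier.
#' @param group `"healthy"` or `"dementia"`; selects the default noise
#'   levels below when a parameter is not supplied.
#' @param onset_jitter_sd Day-to-day SD of episode onsets, minutes
#'   (healthy 15, dementia 75).
#' @param duration_jitter_sd SD of episode durations, minutes (5 / 20).
#' @param fragmentation_prob Probability an episode is interrupted and
#'   split in two with a short gap (0.05 / 0.35).
#' @param omission_prob Probability a scheduled episode is skipped
#'   (0.02 / 0.15).
#' @param spurious_rate Expected extra unscheduled episodes per day
#'   (0.2 / 1.5).
#' @param seed Integer RNG seed for this subject.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id, group = c("healthy", "dementia"),
                            onset_jitter_sd = NULL, duration_jitter_sd = NULL,
                            fragmentation_prob = NULL, omission_prob = NULL,
                            spurious_rate = NULL, seed = 1L) {
  group <- match.arg(group)
  defaults <- if (group == "healthy") {
    list(onset_jitter_sd = 15, duration_jitter_sd = 5,
         fragmentation_prob = 0.05, omission_prob = 0.02, spurious_rate = 0.2)
  } else {
    list(onset_jitter_sd = 75, duration_jitter_sd = 20,
         fragmentation_prob = 0.35, omission_prob = 0.15, spurious_rate = 1.5)
  }
  p <- list(
    subject_id = as.character(subject_id),
    group = group,
    onset_jitter_sd = onset_jitter_sd %||% defaults$onset_jitter_sd,
    duration_jitter_sd = duration_jitter_sd %||% defaults$duration_jitter_sd,
    fragmentation_prob = fragmentation_prob %||% defaults$fragmentation_prob,
    omission_prob = omission_prob %||% defaults$omission_prob,
    spurious_rate = spurious_rate %||% defaults$spurious_rate,
    seed = as.integer(seed)
  )
  stopifnot(p$onset_jitter_sd >= 0, p$duration_jitter_sd >= 0,
            p$fragmentation_prob >= 0, p$fragmentation_prob <= 1,
            p$omission_prob >= 0, p$omission_prob <= 1,
            p$spurious_rate >= 0)
  structure(p, class = "subject_profile")
}

#' Nominal daily activity template
#'
#' One row per scheduled activity: the clock onset (minutes after
#' midnight), nominal duration (minutes) and the room it happens in.
#' Covers all eight core ADL once per day plus a daily visit and a daily
#' out-of-home errand. Sleeping crosses midnight (22:30 + 8 h).
#'
#' @return Tibble with columns `category`, `onset`, `duration`, `room`.
#' @export
default_template_schedule <- function() {
  tibble::tibble(
    category = c("Sleeping", "Grooming", "Toileting", "GettingReadyForBed",
                 "Cooking", "Eating", "WatchingTV", "SeatedActivity",
                 "Visitors", "OutOfHome"),
    onset = c(1350, 420, 840, 1320, 690, 740, 1200, 930, 870, 1020),
    duration = c(480, 20, 8, 20, 40, 30, 90, 60, 40, 60),
    room = c("bedroom", "bathroom", "bathroom", "bathroom", "kitchen",
             "living", "living", "living", "living", NA_character_)
  )
}

#' Cohort-level simulation settings
#'
#' @param n_healthy,n_dementia Group sizes.
#' @param n_days Days of measurement per subject (>= 1).
#' @param template Daily template schedule; must cover all eight core ADL
#'   at least once per day, with no same-category nominal overlaps.
#' @param master_seed Seed from which all per-subject seeds are spawned.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 10, n_dementia = 10, n_days = 20,
                          template = default_template_schedule(),
                          master_seed = 1L) {
  stopifnot(n_healthy >= 0, n_dementia >= 0, n_days >= 1)
  template <- tibble::as_tibble(template)
  missing <- setdiff(core_adl(), template$category)
  if (length(missing) > 0) {
    rlang::abort(paste0("template must cover every core ADL; missing: ",
                        paste(missing, collapse = ", ")),
                 class = "adl_config_error")
  }
  # same-category nominal overlap makes the schedule infeasible
  for (cat in unique(template$category)) {
    rows <- template[template$category == cat, ]
    if (nrow(rows) > 1) {
      o <- order(rows$onset)
      if (any(rows$onset[o][-1] < (rows$onset + rows$duration)[o][-nrow(rows)])) {
        rlang::abort(paste0("template has overlapping nominal episodes for ",
                            cat), class = "adl_config_error")
      }
    }
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_dementia = as.integer(n_dementia),
                 n_days = as.integer(n_days),
                 template = template,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Generate a subject's ground-truth episode schedule
#'
#' Each day, every template row is realised through four noise processes
#' governed by the subject's profile: omission (the episode is skipped),
#' Gaussian onset and duration jitter (truncated so the episode stays
#' inside the day; Sleeping onsets are kept in the late evening so they
#' never wrap past midnight), fragmentation (the episode is interrupted at
#' a uniform point and resumes after a 5-30 min gap), and spurious
#' episodes (Poisson-many extra daytime core activities). Same-category
#' overlaps are resolved greedily in onset order. Deterministic given the
#' profile's seed.
#'
#' @param profile A [subject_profile()].
#' @param config A [cohort_config()].
#' @return A validated episode tibble with `source = "truth"`.
#' @export
generate_schedule <- function(profile, config) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  tmpl <- config$template
  n_days <- config$n_days
  withr::with_seed(profile$seed, {
    parts <- vector("list", nrow(tmpl) + 1L)
    for (i in seq_len(nrow(tmpl))) {
      keep <- stats::runif(n_days) >= profile$omission_prob
      days <- which(keep)
      if (length(days) == 0L) next
      onset <- tmpl$onset[i] +
        stats::rnorm(length(days), 0, profile$onset_jitter_sd)
      duration <- pmax(3, tmpl$duration[i] +
                         stats::rnorm(length(days), 0, profile$duration_jitter_sd))
      if (tmpl$category[i] == "Sleeping") {
        # keep sleep onsets in the late evening: deviations never wrap the
        # clock, so onset medians/deviations stay well defined
        onset <- pmin(pmax(onset, 1210), 1435)
        duration <- pmin(pmax(duration, 240), 600)
      } else {
        onset <- pmin(pmax(onset, 0), 1410)
        duration <- pmin(duration, 1439 - onset)
      }
      parts[[i]] <- tibble::tibble(category = tmpl$category[i],
                                   day_index = days,
                                   onset = onset, duration = duration)
    }
    # spurious extra daytime core activities
    n_sp <- stats::rpois(n_days, profile$spurious_rate)
    if (sum(n_sp) > 0) {
      parts[[nrow(tmpl) + 1L]] <- tibble::tibble(
        category = sample(core_adl()[core_adl() != "Sleeping"],
                          sum(n_sp), replace = TRUE),
        day_index = rep(seq_len(n_days), n_sp),
        onset = stats::runif(sum(n_sp), 480, 1230),
        duration = stats::runif(sum(n_sp), 10, 40)
      )
    }
    ep <- dplyr::bind_rows(parts)
    # fragmentation: split the episode and resume after a short gap
    if (nrow(ep) > 0 && profile$fragmentation_prob > 0) {
      frag <- stats::runif(nrow(ep)) < profile$fragmentation_prob &
        ep$category != "Sleeping" & ep$duration >= 10
      if (any(frag)) {
        cut <- stats::runif(sum(frag), 0.3, 0.7) * ep$duration[frag]
        gap <- stats::runif(sum(frag), 5, 30)
        second <- ep[frag, ]
        second$onset <- ep$onset[frag] + cut + gap
        second$duration <- ep$duration[frag] - cut - gap
        ep$duration[frag] <- cut
        second <- second[second$duration >= 3 &
                           second$onset + second$duration <= 1439, ]
        ep <- dplyr::bind_rows(ep, second)
      }
    }
  })
  if (nrow(ep) == 0L) {
    return(adl_episodes(character(0), character(0), integer(0),
                        numeric(0), numeric(0), character(0)))
  }
  ep$subject_id <- profile$subject_id
  ep$source <- "truth"
  ep <- split_at_midnight(ep, n_days = n_days)
  ep <- dedupe_same_category(ep)
  ep <- ep[order(abs_start_min(ep), ep$category), ]
  validate_episodes(ep)
}

#' Generate a full synthetic cohort
#'
#' Spawns per-subject seeds from the master seed, realises each subject's
#' ground-truth schedule, and (optionally) renders the corresponding
#' ambient sensor streams. Byte-identical outputs for identical
#' `master_seed`.
#'
#' @param config A [cohort_config()].
#' @param profiles Optional list of [subject_profile()]s overriding the
#'   defaults (their seeds are still respawned from the master seed for
#'   reproducibility unless `respawn_seeds = FALSE`).
#' @param render If `TRUE`, also render sensor streams for every subject
#'   (slow; the statistical stages only need the episode-level fast path).
#' @param layout Home layout used for rendering.
#' @param noise [sensor_noise()] parameters used for rendering.
#' @param respawn_seeds Respawn profile seeds from `master_seed`.
#' @return A list with elements `config`, `subjects` (list per subject of
#'   `profile`, `truth`, and optionally `stream`), and `truth` (all truth
#'   episodes bound together with a `group` attribute table).
#' @export
generate_cohort <- function(config, profiles = NULL, render = FALSE,
                            layout = default_home_layout(),
                            noise = sensor_noise(), respawn_seeds = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_healthy + config$n_dementia
  if (is.null(profiles)) {
    ids <- c(sprintf("H%02d", seq_len(config$n_healthy)),
             sprintf("D%02d", seq_len(config$n_dementia)))
    groups <- c(rep("healthy", config$n_healthy),
                rep("dementia", config$n_dementia))
    profiles <- Map(function(id, g) subject_profile(id, g), ids, groups)
  }
  stopifnot(length(profiles) == n)
  seeds <- spawn_seeds(config$master_seed, 2L * n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    if (respawn_seeds) p$seed <- seeds[2L * i - 1L]
    truth <- generate_schedule(p, config)
    sub <- list(profile = p, truth = truth)
    if (render) {
      sub$stream <- render_sensor_stream(truth, layout = layout,
                                         noise = noise,
                                         seed = seeds[2L * i],
                                         n_days = config$n_days)
    }
    subjects[[i]] <- sub
  }
  names(subjects) <- vapply(subjects, function(s) s$profile$subject_id, "")
  truth_all <- dplyr::bind_rows(lapply(subjects, `[[`, "truth"))
  groups <- tibble::tibble(
    subject_id = names(subjects),
    group = unname(vapply(subjects, function(s) s$profile$group, ""))
  )
  list(config = config, subjects = subjects, truth = truth_all,
       groups = groups)
}
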