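# End-to-end orchestration: simulate -> recognise -> quantify ->
# discriminate -> report, driven by one nested configuration document.
# Every stage is a pure function of its inputs and the seed, so reruns
# with the same configuration produce identical tables.

#' Default pipeline configuration
#'
#' One nested list holding every tunable of every stage, with the
#' documented defaults. Serialisable to/from YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_healthy,n_dementia,n_days Cohort dimensions.
#' @param seed Master seed; all stage seeds derive from it.
#' @param fast_path If `TRUE` (default) the quantification stages consume
#'   the ground-truth episodes directly; if `FALSE` sensor streams are
#'   rendered and classified first (slow, but exercises recognition).
#' @param feature_kind Daily feature for the Poincare stage.
#' @param outdir Output directory (`NULL` until [run_pipeline()] is given
#'   one).
#' @param figures Write figures for the first subject of each group.
#' @return A nested `pipeline_config` list.
#' @export
default_pipeline_config <- function(n_healthy = 10, n_dementia = 10,
                                    n_days = 20, seed = 1L,
                                    fast_path = TRUE,
                                    feature_kind = "onset_deviation_min",
                                    outdir = NULL, figures = TRUE) {
  structure(list(
    cohort = list(n_healthy = n_healthy, n_dementia = n_dementia,
                  n_days = n_days, master_seed = as.integer(seed)),
    fast_path = fast_path,
    noise = unclass(sensor_noise()),
    classifier = unclass(classifier_params()),
    analysis = list(feature_kind = feature_kind, lag = 1L),
    figures = figures,
    outdir = outdir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "adl_io_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], as.list(cfg[[nm]]))
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  structure(base, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages: *simulate* a synthetic cohort; *recognise* episodes (fast path:
#' use truth directly; otherwise render sensor streams and classify them);
#' *quantify* per-subject Poincare descriptors and the cumulative per-day
#' heterogeneity; *discriminate* with the LOOCV midpoint-cutoff curve,
#' Mann-Whitney group comparison and ROC; *report* CSV tables, figures, a
#' run log and a checksum manifest to `outdir`. Deterministic given the
#' configuration seed. Any stage failure raises an error naming the stage.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return (Invisibly) a list with the episode tables, descriptor and
#'   heterogeneity tables, discrimination curve, group comparison, ROC
#'   summary and manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  outdir <- outdir %||% config$outdir
  stopifnot(!is.null(outdir))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_line(log_con, "stage ", name, " FAILED: ", conditionMessage(e))
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "adl_pipeline_error", parent = e)
    })
    log_line(log_con, "stage ", name, " done in ",
             sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cc <- config$cohort
  log_line(log_con, "master seed ", cc$master_seed, "; cohort ",
           cc$n_healthy, "+", cc$n_dementia, " x ", cc$n_days, " days; ",
           if (isTRUE(config$fast_path)) "event-level fast path"
           else "sensor rendering + recognition")

  cohort <- stage("simulate", {
    cfg <- cohort_config(cc$n_healthy, cc$n_dementia, cc$n_days,
                         master_seed = cc$master_seed)
    generate_cohort(cfg, render = !isTRUE(config$fast_path),
                    noise = do.call(sensor_noise, config$noise))
  })

  analysed <- stage("recognise", {
    if (isTRUE(config$fast_path)) {
      cohort$truth
    } else {
      params <- do.call(classifier_params, config$classifier)
      rec <- lapply(cohort$subjects, function(s) {
        classify_stream(s$stream, params = params,
                        subject_id = s$profile$subject_id,
                        study_end_s = cc$n_days * 86400)
      })
      dplyr::bind_rows(rec)
    }
  })
  per_cat <- table(analysed$category)
  log_line(log_con, "episodes per category: ",
           paste(names(per_cat), per_cat, sep = "=", collapse = ", "))

  quant <- stage("quantify", {
    fk <- config$analysis$feature_kind
    desc <- dplyr::bind_rows(lapply(split(analysed, analysed$subject_id),
                                    poincare_descriptors,
                                    feature_kind = fk,
                                    lag = config$analysis$lag))
    het <- heterogeneity_by_day(analysed, feature_kind = fk)
    list(desc = desc, het = het)
  })

  disc <- stage("discriminate", {
    het <- dplyr::left_join(quant$het, cohort$groups, by = "subject_id")
    usable <- !vapply(split(het$heterogeneity, het$day),
                      function(v) any(!is.finite(v)), TRUE)
    days <- sort(unique(het$day))[usable[as.character(sort(unique(het$day)))]]
    curve <- loocv_curve(het, days = days)
    last <- het[het$day == max(days), ]
    mw <- mann_whitney_u(last$heterogeneity[last$group == "healthy"],
                         last$heterogeneity[last$group == "dementia"])
    roc <- roc_analysis(last$heterogeneity, last$group)
    comparison <- group_comparison_table(quant$desc, cohort$groups)
    list(curve = curve, mw = mw, roc = roc, comparison = comparison,
         het = het)
  })

  manifest <- stage("report", {
    paths <- c(
      truth = file.path(outdir, "episodes_truth.csv"),
      analysed = file.path(outdir, "episodes_analysed.csv"),
      descriptors = file.path(outdir, "poincare_descriptors.csv"),
      heterogeneity = file.path(outdir, "heterogeneity_by_day.csv"),
      curve = file.path(outdir, "discrimination_curve.csv"),
      comparison = file.path(outdir, "group_comparison.csv"))
    write_episodes(cohort$truth, paths[["truth"]])
    write_episodes(analysed, paths[["analysed"]])
    readr::write_csv(quant$desc, paths[["descriptors"]])
    readr::write_csv(disc$het, paths[["heterogeneity"]])
    readr::write_csv(disc$curve, paths[["curve"]])
    readr::write_csv(disc$comparison, paths[["comparison"]])
    if (isTRUE(config$figures)) {
      first_each <- cohort$groups$subject_id[!duplicated(cohort$groups$group)]
      for (sid in first_each) {
        render_activity_map(
          analysed[analysed$subject_id == sid, ],
          file.path(outdir, paste0("activity_map_", sid, ".pdf")),
          n_days = cc$n_days)
        ser <- lapply(core_adl(), function(cat) {
          s <- extract_daily_feature(analysed[analysed$subject_id == sid, ],
                                     cat, config$analysis$feature_kind)
          if (s$insufficient) NULL else build_pairs(s, config$analysis$lag)
        })
        pairs <- dplyr::bind_rows(ser)
        if (nrow(pairs) >= 2) {
          ggplot2::ggsave(file.path(outdir, paste0("poincare_", sid, ".pdf")),
                          plot_poincare(pairs), width = 5, height = 5)
        }
      }
      ggplot2::ggsave(file.path(outdir, "discrimination_curve.pdf"),
                      plot_discrimination_curve(disc$curve),
                      width = 6, height = 4)
    }
    files <- list.files(outdir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$|run\\.log$", files)]
    mf <- tibble::tibble(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    mf
  })

  invisible(list(config = config, cohort = cohort, analysed = analysed,
                 descriptors = quant$desc, heterogeneity = disc$het,
                 curve = disc$curve, mann_whitney = disc$mw,
                 roc = disc$roc, comparison = disc$comparison,
                 manifest = manifest, outdir = outdir))
}
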