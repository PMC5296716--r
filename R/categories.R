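#' The ten activity-of-daily-living categories
#'
#' Ten ADL are tracked: eight "core" activities of clinical interest
#' (Sleeping, Grooming, Toileting, GettingReadyForBed, Cooking, Eating,
#' WatchingTV, SeatedActivity) whose day-to-day regularity enters the
#' heterogeneity feature, plus two socially informative activities
#' (Visitors, OutOfHome) that are recognised for completeness of the
#' activity map but excluded from quantification.
#'
#' @return A tibble with columns `category` (character) and `core`
#'   (logical); exactly 10 rows, exactly 8 of them core.
#' @export
#' @examples
#' adl_categories()
adl_categories <- function() {
  tibble::tibble(
    category = c("Sleeping", "Grooming", "Toileting", "GettingReadyForBed",
                 "Cooking", "Eating", "WatchingTV", "SeatedActivity",
                 "Visitors", "OutOfHome"),
    core = c(rep(TRUE, 8), FALSE, FALSE)
  )
}

#' The eight core ADL category labels
#'
#' @return Character vector of the eight core categories, in canonical order.
#' @export
core_adl <- function() {
  cats <- adl_categories()
  cats$category[cats$core]
}

#' Fixed colour palette for activity maps
#'
#' One colour per ADL category, stable across figures so that activity maps
#' of different subjects are directly comparable.
#'
#' @return Named character vector of 10 hex colours.
#' @export
adl_palette <- function() {
  c(Sleeping = "#1f77b4", Grooming = "#ff7f0e", Toileting = "#2ca02c",
    GettingReadyForBed = "#d62728", Cooking = "#9467bd", Eating = "#8c564b",
    WatchingTV = "#e377c2", SeatedActivity = "#7f7f7f",
    Visitors = "#bcbd22", OutOfHome = "#17becf")
}
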