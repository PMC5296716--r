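# shared internal helpers

#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic operation in the package takes an explicit integer seed;
#' this helper spawns independent child seeds without disturbing the
#' caller's RNG state.
#'
#' @param master_seed Integer scalar.
#' @param n Number of child seeds to draw.
#' @return Integer vector of length `n`; each element is a valid
#'   `set.seed()` input.
#' @export
spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed), n >= 1)
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# population (biased) standard deviation; the descriptor convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# absolute start/end of episodes in minutes since study start
abs_start_min <- function(episodes) {
  (episodes$day_index - 1) * 1440 + episodes$onset
}
abs_end_min <- function(episodes) {
  abs_start_min(episodes) + episodes$duration
}

# greedy removal of same-category overlaps (per subject, absolute-time
# order); keeps the earlier episode
dedupe_same_category <- function(ep) {
  if (nrow(ep) < 2) return(ep)
  ep <- ep[order(ep$subject_id, ep$category, abs_start_min(ep)), ]
  s <- abs_start_min(ep)
  e <- abs_end_min(ep)
  key <- paste(ep$subject_id, ep$category)
  keep <- rep(TRUE, nrow(ep))
  last_end <- -Inf
  last_key <- ""
  for (i in seq_len(nrow(ep))) {
    if (key[i] != last_key) {
      last_end <- -Inf
      last_key <- key[i]
    }
    if (s[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- e[i]
    }
  }
  ep[keep, ]
}

# --- interval arithmetic on (start, end) matrices/data frames, units agnostic

# merge possibly-overlapping intervals into a disjoint sorted set
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(list(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  run_end <- cummax(end)
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)])
  grp <- cumsum(new_run)
  list(start = as.numeric(tapply(start, grp, min)),
       end = as.numeric(tapply(end, grp, max)))
}

# complement of a disjoint sorted interval set within [lo, hi]
complement_intervals <- function(start, end, lo, hi) {
  m <- merge_intervals(pmax(start, lo), pmin(end, hi))
  keep <- m$end > m$start
  s <- m$start[keep]
  e <- m$end[keep]
  gap_start <- c(lo, e)
  gap_end <- c(s, hi)
  keep <- gap_end > gap_start
  list(start = gap_start[keep], end = gap_end[keep])
}

# which of the (sorted) times t fall inside the disjoint sorted intervals
in_intervals <- function(t, start, end) {
  if (length(start) == 0L) {
    return(rep(FALSE, length(t)))
  }
  idx <- findInterval(t, start)
  idx > 0L & t < end[pmax(idx, 1L)]
}
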