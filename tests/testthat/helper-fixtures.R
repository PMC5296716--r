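# fixtures built in code: noise-free and default synthetic subjects

noise_free_profile <- function(id = "s0", group = "healthy", seed = 1L) {
  subject_profile(id, group, onset_jitter_sd = 0, duration_jitter_sd = 0,
                  fragmentation_prob = 0, omission_prob = 0,
                  spurious_rate = 0, seed = seed)
}

noise_free_schedule <- function(n_days = 5, id = "s0", seed = 1L) {
  generate_schedule(noise_free_profile(id, seed = seed),
                    cohort_config(1, 0, n_days))
}

# cohort heterogeneity table with group labels, event-level fast path
cohort_het <- function(n_healthy, n_dementia, n_days, master_seed,
                       days = NULL) {
  co <- generate_cohort(cohort_config(n_healthy, n_dementia, n_days,
                                      master_seed = master_seed))
  dplyr::left_join(heterogeneity_by_day(co$truth, days = days),
                   co$groups, by = "subject_id")
}

# independent rotation oracle for the ellipse descriptors: rotate the cloud
# by -45 degrees with an explicit matrix product, then take population SDs
ellipse_oracle <- function(x, y) {
  rot <- matrix(c(1, -1, 1, 1), 2, 2) / sqrt(2)  # rows: a = (x+y), d = (y-x)
  z <- cbind(x, y) %*% t(rot)
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  list(long = psd(z[, 1]), short = psd(z[, 2]),
       centroid = (mean(x) + mean(y)) / 2)
}
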