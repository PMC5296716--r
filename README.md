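# adlpoincare

Cognitive impairment erodes the regularity of activities of daily living
(ADL): people with dementia start activities, interrupt them, and drift
into fragmented daily routines. Ambient in-home sensors (passive-infrared
presence, luminescence, temperature, humidity and acceleration boxes
distributed over the rooms of a home) can record those routines
unobtrusively over weeks. `adlpoincare` is an R package for the full
analysis chain on such recordings: recognising ADL episodes from the raw
multi-room streams, visualising them as day-by-time activity maps,
quantifying the day-to-day heterogeneity of each activity with lagged
Poincaré-plot descriptors, and asking how many days of observation are
needed before that heterogeneity separates dementia-like from healthy-like
routines. It is aimed at researchers in digital phenotyping and
gerontechnology who need a tested, reproducible reference pipeline — and,
since raw home-sensor datasets are rarely shareable, it ships a synthetic
smart-home cohort generator that emulates the statistical structure of
such studies.

## The method

For each subject and each of eight core activities (Sleeping, Grooming,
Toileting, Getting ready for bed, Cooking, Eating, Watching TV, Seated
activity), a daily feature series *s*₁…*s*ₙ is extracted — by default the
absolute deviation of each day's onset from the subject's median onset, in
minutes. The series is paired with its one-day-lagged self,

> (xᵢ, yᵢ) = (sᵢ, sᵢ₊₁),  i = 1…N−1  (Δt = 24 h),

and the scatter is summarised by ellipse fitting in the 45°-rotated frame:
with aᵢ = (xᵢ+yᵢ)/√2 and dᵢ = (xᵢ−yᵢ)/√2, the **long axis** (SD2) is the
population SD of aᵢ, the **short axis** (SD1) the population SD of dᵢ, and
the **centroid** (x̄+ȳ)/2 is the cloud's centre of mass on the identity
line. A perfectly periodic routine collapses onto the identity line with
zero axes and zero deviation centroid; fragmented routines spread.

The per-subject **heterogeneity** is the mean centroid over the core
activities. Discrimination uses a dynamic midpoint cutoff — the arithmetic
mean of the two groups' average heterogeneities, recomputed inside every
leave-one-out fold and at every observation duration *d* (episodes of days
1…*d*, cumulatively) — giving sensitivity = TP/(TP+FN), specificity =
TN/(TN+FP) and accuracy = (TP+TN)/all as functions of *d* (positive class
= dementia). Group differences in centroids are tested with the
Mann-Whitney U test, and a full ROC sweep with AUC complements the
midpoint cutoff.

Episode recognition is training-free: presence triggers are aggregated
into room-presence intervals, and a documented template table (allowed
rooms, clock windows, duration bounds, fridge-door / flush-handle
acceleration markers, low-light cue, priorities) assigns at most one
activity per interval; whole-home silence becomes OutOfHome and
simultaneous presence in several rooms becomes Visitors.

## Worked example

```r
library(adlpoincare)

co  <- generate_cohort(cohort_config(n_healthy = 10, n_dementia = 10,
                                     n_days = 20, master_seed = 1))
het <- dplyr::left_join(heterogeneity_by_day(co$truth), co$groups,
                        by = "subject_id")

dplyr::group_by(het[het$day == 20, ], group) |>
  dplyr::summarise(mean_heterogeneity = mean(heterogeneity))
#>   group    mean_heterogeneity
#> 1 dementia               86.3
#> 2 healthy                14.8

curve <- loocv_curve(het)
tail(curve, 3)
#>     day sensitivity specificity accuracy mean_cutoff
#> 1    18           1           1        1        50.2
#> 2    19           1           1        1        50.4
#> 3    20           1           1        1        50.5

mann_whitney_u(het$heterogeneity[het$group == "healthy" & het$day == 20],
               het$heterogeneity[het$group == "dementia" & het$day == 20])
#> $statistic 0    $p.value 0.000183
```

After 20 days the default synthetic groups (onset jitter SD 15 min for
healthy vs 75 min for dementia profiles, plus omission, fragmentation and
spurious-activity noise) are perfectly separated by the dynamic midpoint
cutoff (accuracy 1.0 from about day 8), and the Mann-Whitney test rejects
equality of centroids at p < 0.001. Per-subject, per-activity descriptor
tables come from `poincare_descriptors()`, figures from
`plot_activity_map()`, `plot_poincare()` and
`plot_discrimination_curve()`, and `run_pipeline()` writes all tables,
figures, a log and a checksum manifest in one call (a thin command-line
wrapper lives in `inst/cli/adlpipeline.R`).

`reference_cohort_summary()` ships the published per-category episode
counts and centroid group summaries of a real 20-home deployment for
bookkeeping checks and benchmarking.

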