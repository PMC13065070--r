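# Shared fixtures: printed-table style reference compositions and a
# convenience wrapper that simulates a cohort and fits the attainment model
# without the diary layer.

weekday_gm <- c(sleep = 897, physical_activity = 23, media = 143,
                school = 50, hobbies = 61, domestic = 266)
weekend_gm <- c(sleep = 852, media = 202, hobbies = 114, domestic = 272)

fit_synthetic <- function(n, noise_sd = 15, seed = 42,
                          day_type = "weekday", pivot_order = NULL, ...) {
  truth <- synthetic_truth(day_type = day_type, noise_sd = noise_sd,
                           seed = seed, ...)
  cohort <- simulate_cohort(truth, n, expand_diaries = FALSE)
  sample <- cohort_analytic_sample(cohort)
  basis <- pivot_basis(sample$parts, pivot_order = pivot_order)
  list(truth = truth, cohort = cohort, sample = sample,
       model = fit_outcome_model(sample, basis = basis))
}

# A hand-built complete diary with known slot counts per behaviour set.
make_counted_diary <- function(counts, participant_id = "P1",
                               day_type = "weekday") {
  codes <- c(sleep = "sleeping", physical_activity = "sports_exercise",
             media = "tv_films", school = "homework",
             hobbies = "reading_pleasure", domestic = "eating_drinking")
  stopifnot(sum(counts) == 144)
  slots <- unlist(mapply(function(set, k) rep(codes[[set]], k),
                         names(counts), counts, SIMPLIFY = FALSE),
                  use.names = FALSE)
  time_use_diary(participant_id, day_type, slots)
}
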