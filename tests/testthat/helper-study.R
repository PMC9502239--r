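# The end-to-end study cohort shared by the heavier acceptance checks:
# 4 HC + 4 PD subjects, 12 training-range days plus 5-day holdout blocks at
# days 30/60/90, reduced daily wear so a full LOGO-CV with per-fold CNN
# training runs on one CPU. Computed once per test run.

study_seed <- 1000L
study_cnn_seed <- 1500L

study_cohort <- function() cached("study_cohort", {
  cfg <- simulation_config(n_hc = 4L, n_pd = 4L,
                           day_offsets = c(0:11, 30:34, 60:64, 90:94),
                           wear_hours_per_day = 0.15, seed = study_seed)
  cohort <- simulate_cohort(cfg)
  det <- detect_walks(cohort$recordings)
  list(cohort = cohort, det = det,
       truth = window_truth(det$windows, cohort$truth))
})

study_logo <- function() cached("study_logo", {
  x <- study_cohort()
  folds <- make_logo_folds(x$cohort$subjects)
  run_logo_cv(x$det$walk_windows, folds, cnn_config(seed = study_cnn_seed))
})

null_study_logo <- function() cached("null_study_logo", {
  cfg <- simulation_config(n_hc = 4L, n_pd = 4L, day_offsets = 0:11,
                           wear_hours_per_day = 0.15,
                           pd_effects = null_pd_effects(), seed = study_seed)
  cohort <- simulate_cohort(cfg)
  det <- detect_walks(cohort$recordings)
  run_logo_cv(det$walk_windows, make_logo_folds(cohort$subjects),
              cnn_config(seed = study_cnn_seed))
})
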