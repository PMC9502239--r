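test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- simulation_config(n_hc = 1, n_pd = 1, days_per_subject = 1,
                           wear_hours_per_day = 0.02, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_cohort(simulation_config(n_hc = 0, n_pd = 0))$
                     recordings, list())
})

test_that("the fixture is non-degenerate and stable", {
  fx <- fixture_cohort()
  expect_equal(nrow(fx$subjects), 4L)
  expect_length(fx$recordings, 8L)
  det <- fixture_detection()
  # windows exist for every subject-day
  tab <- table(det$windows$subject_id, det$windows$day_index)
  expect_true(all(tab > 0))
  # at least one walk-like window per subject
  walk <- det$annotations[det$annotations$label == "walk_like", ]
  expect_setequal(unique(walk$subject_id), fx$subjects$subject_id)
  # frozen checksum of the serialized fixture (regenerated at test time)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(fx$recordings[[1]], f)
  expect_identical(unname(tools::md5sum(f)),
                   "ebd76946519f53a8030506d30d8dfee6")
})

test_that("labeled walk segments pass the detector at default effect sizes", {
  det <- fixture_detection()
  fx <- fixture_cohort()
  tr <- window_truth(det$windows, fx$truth)
  lab <- det$annotations$label
  expect_gte(mean(lab[tr == "walk"] == "walk_like"), 0.95)
  expect_gte(mean(lab[tr %in% c("rest", "nonwalk_dynamic")] != "walk_like"),
             0.95)
})

test_that("PD walk windows carry more 4-9 Hz accelerometer power than HC", {
  det <- fixture_detection()
  fx <- fixture_cohort()
  diag <- setNames(fx$subjects$diagnosis, fx$subjects$subject_id)
  w <- det$walk_windows
  mid <- sapply(seq_len(length(w)), function(i)
    sum(sapply(1:3, function(a)
      band_power_tapered(w$samples[a, , i], w$sample_rate, 4, 9))))
  grp <- diag[w$subject_id]
  expect_gt(mean(mid[grp == "PD"]), mean(mid[grp == "HC"]))
})

test_that("tremor amplitude monotonically raises PD tremor-band power", {
  powers <- sapply(c(5, 15, 45), function(ta) {
    cfg <- simulation_config(n_hc = 0, n_pd = 1, days_per_subject = 1,
                             wear_hours_per_day = 0.03, walk_bout_rate = 120,
                             pd_effects = list(tremor_amplitude = ta),
                             seed = 13)
    sim <- simulate_cohort(cfg)
    det <- detect_walks(sim$recordings)
    tr <- window_truth(det$windows, sim$truth)
    w <- det$windows[tr == "walk"]
    mean(sapply(seq_len(length(w)), function(i)
      sum(sapply(4:6, function(a)
        band_power_tapered(w$samples[a, , i], w$sample_rate, 4, 9)))))
  })
  expect_true(all(diff(powers) > 0))
})

test_that("ground-truth walk occupancy tracks the configured bout rate", {
  cfg <- simulation_config(n_hc = 1, n_pd = 0, days_per_subject = 1,
                           wear_hours_per_day = 3, walk_bout_rate = 20,
                           seed = 17)
  sim <- simulate_cohort(cfg)
  walk_s <- sum(sim$truth$end_ms[sim$truth$activity == "walk"] -
                  sim$truth$start_ms[sim$truth$activity == "walk"]) / 1000
  expected <- 20 * 3 * exp(log(50) + 0.5^2 / 2)     # rate x hours x E[dur]
  expect_lt(abs(walk_s - expected) / expected, 0.25)
})

test_that("null PD effects make the groups exchangeable in tremor-band power", {
  cfg <- simulation_config(n_hc = 2, n_pd = 2, days_per_subject = 1,
                           wear_hours_per_day = 0.05, walk_bout_rate = 120,
                           pd_effects = null_pd_effects(), seed = 19)
  sim <- simulate_cohort(cfg)
  det <- detect_walks(sim$recordings)
  diag <- setNames(sim$subjects$diagnosis, sim$subjects$subject_id)
  w <- det$walk_windows
  mid <- sapply(seq_len(length(w)), function(i)
    sum(sapply(4:6, function(a)
      band_power_tapered(w$samples[a, , i], w$sample_rate, 4, 9))))
  grp <- diag[w$subject_id]
  # same generative law: ratio of group means near 1
  expect_lt(abs(log(mean(mid[grp == "PD"]) / mean(mid[grp == "HC"]))),
            log(2.5))
})
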