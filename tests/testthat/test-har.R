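test_that("mean absolute value matches the direct formula", {
  expect_equal(mean_absolute_value(rep(3.7, 50)), 0)
  expect_equal(mean_absolute_value(c(1, -1, 1, -1)), 1)
  expect_error(mean_absolute_value(numeric(0)), "empty")
  set.seed(11)
  for (k in 1:5) {
    x <- rnorm(97, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    expect_equal(mean_absolute_value(x), brute_mav(x))
    expect_equal(mean_absolute_value(x, detrend = FALSE),
                 brute_mav(x, detrend = FALSE))
  }
})

test_that("dominant axis is the argmax of per-axis detrended MAV", {
  L <- 100
  zero <- matrix(0, 1, L)
  sig <- matrix(sin(2 * pi * 1.5 * (1:L) / 20), 1, L)
  w <- windows_from(list(rbind(zero, sig, zero, zero, sig, zero)))
  expect_equal(dominant_axis(w, "acc"), "y")
  expect_equal(dominant_axis(w, "gyro"), "y")
  # exact tie -> lowest axis index
  w2 <- windows_from(list(rbind(sig, sig, sig, sig, sig, sig)))
  expect_equal(dominant_axis(w2, "acc"), "x")
  set.seed(21)
  for (k in 1:8) {
    m <- matrix(rnorm(6 * L, sd = runif(6, 0.1, 2)), 6, L)
    w3 <- windows_from(list(m))
    expect_equal(dominant_axis(w3, "acc"),
                 c("x", "y", "z")[brute_dominant_axis(m[1:3, ])])
    expect_equal(dominant_axis(w3, "gyro"),
                 c("x", "y", "z")[brute_dominant_axis(m[4:6, ])])
  }
})

test_that("adaptive threshold is half the max dominant-axis MAV over day-1 windows", {
  # three windows engineered to MAVs 0.2, 0.8, 0.4 on the acc dominant axis
  L <- 100
  mk <- function(a) {
    m <- matrix(0, 6, L)
    m[1, ] <- a * rep(c(1, -1), L / 2)   # detrended MAV == a
    m
  }
  w <- windows_from(lapply(c(0.2, 0.8, 0.4), mk))
  expect_equal(compute_adaptive_threshold(w, "acc"), 0.4)
  expect_equal(compute_adaptive_threshold(w[2], "acc"), 0.4)
  expect_equal(compute_adaptive_threshold(w[1], "acc"), 0.1)
  expect_error(compute_adaptive_threshold(w[integer(0)], "acc"), "no windows")
})

test_that("thresholds, dominant axes and the dynamic gate match brute force on a synthetic day", {
  sim <- oracle_day()
  det <- detect_walks(sim$recordings)
  w <- det$windows
  thr <- det$thresholds[["S01"]]
  # brute force: loop every window, every axis, plain sums
  n <- length(w)
  acc_mav <- numeric(n)
  acc_ax <- integer(n)
  gyro_mav <- numeric(n)
  for (i in seq_len(n)) {
    a <- brute_dominant_axis(w$samples[1:3, , i])
    acc_ax[i] <- a
    acc_mav[i] <- brute_mav(w$samples[a, , i])
    g <- brute_dominant_axis(w$samples[4:6, , i])
    gyro_mav[i] <- brute_mav(w$samples[3 + g, , i])
  }
  expect_equal(thr$acc_threshold, 0.5 * max(acc_mav), tolerance = 1e-12)
  expect_equal(thr$gyro_threshold, 0.5 * max(gyro_mav), tolerance = 1e-12)
  expect_equal(thr$source_day, min(w$day_index))
  ann <- det$annotations
  expect_equal(ann$label != "static", acc_mav > thr$acc_threshold)
  expect_equal(ann$dom_acc_axis, c("x", "y", "z")[acc_ax])
  for (i in sample(n, 10))
    expect_equal(is_dynamic(w, thr, i), acc_mav[i] > thr$acc_threshold)
})

test_that("dynamic gate uses a strict inequality and rejects subject mismatch", {
  L <- 100
  m <- matrix(0, 6, L)
  m[1, ] <- 0.3 * rep(c(1, -1), L / 2)
  w <- windows_from(list(m))
  thr <- structure(list(subject_id = "S", acc_threshold = 0.3,
                        gyro_threshold = 1, source_day = 0L),
                   class = "subject_thresholds")
  expect_false(is_dynamic(w, thr))          # MAV == threshold -> static
  thr$acc_threshold <- 0.2999
  expect_true(is_dynamic(w, thr))
  zeroes <- windows_from(list(matrix(0, 6, L)))
  thr$acc_threshold <- 0.01
  expect_false(is_dynamic(zeroes, thr))
  thr$subject_id <- "OTHER"
  expect_error(is_dynamic(w, thr), "different subject")
})

test_that("Welch PSD matches an independent reference and Parseval", {
  tt <- (0:99) / 20
  x <- sin(2 * pi * 1.5 * tt) + 0.5 * cos(2 * pi * 3 * tt + 0.3)
  est <- welch_psd(x, 20)
  expect_equal(est$frequencies, seq(0, 10, by = 0.5))
  # frozen reference values (scipy.signal.welch, hann, nperseg=40, 50% ovl)
  expect_equal(est$psd[3:8],
               c(0.1666666667, 0.6666666667, 0.1666666667, 0.0416666667,
                 0.1666666667, 0.0416666667), tolerance = 1e-8)
  expect_equal(which.max(est$psd), which.min(abs(est$frequencies - 1.5)))

  expect_lt(max(welch_psd(rep(2.5, 100), 20)$psd), 1e-12)

  set.seed(31)
  x <- rnorm(4000)
  est <- welch_psd(x, 20)
  df <- est$frequencies[2]
  expect_lt(abs(sum(est$psd) * df - var(x)) / var(x), 0.05)
  expect_true(all(est$psd >= 0))
  expect_error(welch_psd(rnorm(10), 20), "shorter")
})

walk_test_window <- function(amp, freq, L = 100, rate = 20) {
  m <- matrix(0, 6, L)
  m[5, ] <- amp * sin(2 * pi * freq * (seq_len(L) - 1) / rate)
  windows_from(list(m), rate = rate)
}

test_that("walk-like gate needs both band dominance and the power floor", {
  strong <- walk_test_window(100, 1.5)
  res <- is_walk_like(strong)
  expect_true(res$walk_like)
  expect_equal(res$dominant_gyro_axis, "y")
  expect_gt(res$walking_band_power, res$rest_band_power)

  # scaled so the mean band PSD drops below the floor of 100
  weak <- walk_test_window(5, 1.5)
  resw <- is_walk_like(weak)
  expect_false(resw$walk_like)
  expect_lt(resw$walking_band_power, 100)
  expect_gt(resw$walking_band_power, resw$rest_band_power)

  # high-amplitude tone outside the walking band
  out <- is_walk_like(walk_test_window(100, 5))
  expect_false(out$walk_like)
  expect_lt(out$walking_band_power, out$rest_band_power)
})

test_that("every dynamic window gets exactly one walk label; static never reaches the walk test", {
  det <- fixture_detection()
  ann <- det$annotations
  expect_true(all(ann$label %in% c("static", "dynamic_nonwalk", "walk_like")))
  expect_true(all(is.na(ann$band_power[ann$label == "static"])))
  expect_true(all(!is.na(ann$band_power[ann$label != "static"])))
})

test_that("axis permutation leaves the walk-like set unchanged", {
  sim <- oracle_day()
  rec <- sim$recordings[[1]]
  perm <- c(3, 1, 2)
  rec2 <- inertial_recording(rec$subject_id, rec$sample_rate, rec$timestamps,
                             rec$acc[, perm], rec$gyro[, perm])
  a1 <- detect_walks(list(rec))$annotations
  a2 <- detect_walks(list(rec2))$annotations
  expect_identical(a1$start_time[a1$label == "walk_like"],
                   a2$start_time[a2$label == "walk_like"])
})

test_that("gyroscope gain never demotes a strictly band-dominant walk window", {
  set.seed(41)
  for (amp in c(40, 80, 160)) {
    w <- walk_test_window(amp, 1.2)
    base <- is_walk_like(w)
    if (base$walk_like &&
        base$walking_band_power > base$rest_band_power) {
      w2 <- w
      w2$samples[4:6, , ] <- w2$samples[4:6, , ] * 3
      expect_true(is_walk_like(w2)$walk_like)
    }
  }
})
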