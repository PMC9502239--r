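sim_sine_recording <- function(n, rate, freq, amp = 1, t0 = 1.7e12) {
  tt <- (seq_len(n) - 1) / rate
  s <- amp * sin(2 * pi * freq * tt)
  inertial_recording("S", rate, t0 + 1000 * tt,
                     cbind(s, s, s), cbind(s, s, s))
}

write_rec_csv <- function(path, n, rate = 100, gap_after = NULL,
                          gap_ms = 5000, t0 = 1.7e12) {
  step <- 1000 / rate
  ts <- t0 + step * (seq_len(n) - 1)
  if (!is.null(gap_after))
    ts[(gap_after + 1):n] <- ts[(gap_after + 1):n] + gap_ms
  df <- data.frame(timestamp = ts,
                   acc_x = rnorm(n), acc_y = rnorm(n), acc_z = rnorm(n),
                   gyro_x = rnorm(n), gyro_y = rnorm(n), gyro_z = rnorm(n))
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_recording parses, splits at gaps, and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_rec_csv(f, 500)
  segs <- read_recording(f)
  expect_length(segs, 1L)
  expect_equal(length(segs[[1]]), 500L)
  expect_equal(segs[[1]]$sample_rate, 100)

  write_rec_csv(f, 500, gap_after = 200)
  segs <- read_recording(f)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, length, 1L), c(200L, 300L))

  # header-only file -> one empty recording
  writeLines("timestamp,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z", f)
  segs <- read_recording(f)
  expect_equal(length(segs[[1]]), 0L)

  # NA runs longer than the gap limit split the recording
  write_rec_csv(f, 500)
  df <- read.csv(f)
  df$acc_x[201:350] <- NA
  write.csv(df, f, row.names = FALSE)
  segs <- read_recording(f)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, length, 1L), c(200L, 150L))

  writeLines("timestamp,acc_x,acc_y", f)
  expect_error(read_recording(f), "schema error")
  write_rec_csv(f, 50)
  df <- read.csv(f)
  df$timestamp <- rev(df$timestamp)
  write.csv(df, f, row.names = FALSE)
  expect_error(read_recording(f), "format error")
})

test_that("downsampling gives floor(n/factor) samples and identity at equal rates", {
  rec <- sim_sine_recording(500, 100, freq = 1)
  out <- downsample_recording(rec, 20)
  expect_equal(length(out), 100L)
  expect_equal(out$sample_rate, 20)
  same <- downsample_recording(rec, 100)
  expect_identical(same$acc, rec$acc)
  expect_error(downsample_recording(rec, 30), "unsupported rate")
})

test_that("downsampled sinusoid matches the analytic signal at the target rate", {
  n <- 3000                       # 30 s at 100 Hz
  rec <- sim_sine_recording(n, 100, freq = 1)
  out <- downsample_recording(rec, 20)
  tt20 <- (seq_len(length(out)) - 1) / 20
  ref <- sin(2 * pi * 1 * tt20)
  core <- 41:(length(out) - 40)   # skip 2 s of filter transient each side
  expect_lt(max(abs(out$acc[core, 1] - ref[core])), 0.01)
})

test_that("content above the target Nyquist is attenuated by >= 40 dB", {
  rec <- sim_sine_recording(3000, 100, freq = 15)
  out <- downsample_recording(rec, 20)
  core <- 41:(length(out) - 40)
  expect_lt(max(abs(out$acc[core, 1])), 0.01)   # -40 dB of unit amplitude
})

test_that("downsampling to an already-reached rate is idempotent", {
  rec <- sim_sine_recording(2000, 100, freq = 1.4)
  once <- downsample_recording(rec, 20)
  twice <- downsample_recording(once, 20)
  expect_identical(once$acc, twice$acc)
})

test_that("windowing drops trailing partials and respects day boundaries", {
  mk <- function(n, t0) inertial_recording(
    "S", 20, t0 + 50 * (seq_len(n) - 1),
    matrix(rnorm(3 * n), n), matrix(rnorm(3 * n), n))
  expect_equal(length(segment_windows(mk(1000, 1.7e12))), 10L)
  expect_equal(length(segment_windows(mk(1050, 1.7e12))), 10L)
  expect_equal(length(segment_windows(mk(99, 1.7e12))), 0L)

  # recording straddling midnight: windows never span the boundary
  day_ms <- 86400000
  t0 <- 123 * day_ms - 10250     # 205 samples before midnight, 295 after
  w <- segment_windows(mk(500, t0))
  n_before <- 205 %/% 100
  n_after <- 295 %/% 100
  expect_equal(length(w), n_before + n_after)
  expect_equal(sort(unique(w$day_index)), c(0L, 1L))
  expect_equal(sum(w$day_index == 0L), n_before)
})

test_that("window samples reproduce per-day prefixes of the recording", {
  set.seed(5)
  n <- 437
  rec <- inertial_recording("S", 20, 1.7e12 + 50 * (seq_len(n) - 1),
                            matrix(rnorm(3 * n), n), matrix(rnorm(3 * n), n))
  w <- segment_windows(rec)
  expect_equal(length(w), n %/% 100)
  flat <- matrix(w$samples, 6, 100 * length(w))
  ref <- t(cbind(rec$acc, rec$gyro))[, seq_len(100 * length(w))]
  expect_equal(flat, ref, ignore_attr = TRUE)
})
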