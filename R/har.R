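#' Mean absolute value of a signal segment
#'
#' The amplitude statistic used throughout the activity-recognition rules.
#' With `detrend = TRUE` (the default everywhere in the pipeline) the segment
#' mean is subtracted first, which removes the gravity component from
#' accelerometer windows and bias from gyroscope windows; without detrending a
#' resting wrist has an accelerometer MAV near 1 g and amplitude thresholds
#' lose meaning.
#'
#' @param x numeric vector, non-empty.
#' @param detrend subtract the segment mean before the absolute value.
#' @return a non-negative scalar.
#' @export
mean_absolute_value <- function(x, detrend = TRUE) {
  if (length(x) == 0L) stop("mean_absolute_value: empty sequence")
  if (detrend) x <- x - mean(x)
  mean(abs(x))
}

# per-axis detrended MAV for one window slice; m is 3 x L
axis_mavs <- function(m) {
  m <- m - rowMeans(m)
  rowMeans(abs(m))
}

sensor_rows <- function(sensor) {
  switch(match.arg(sensor, c("acc", "gyro")), acc = 1:3, gyro = 4:6)
}

#' Dominant axis of a window
#'
#' The sensor axis with the highest detrended mean absolute value. Selecting
#' amplitude per-axis makes the downstream rules insensitive to how the watch
#' was worn. Ties break toward the lowest axis index (x < y < z).
#'
#' @param window an `event_windows` object.
#' @param sensor `"acc"` or `"gyro"`.
#' @param i window index within `window` (default 1).
#' @return axis label, one of `"x" "y" "z"`.
#' @export
dominant_axis <- function(window, sensor = c("acc", "gyro"), i = 1L) {
  m <- window$samples[sensor_rows(sensor), , i]
  c("x", "y", "z")[which.max(axis_mavs(m))]
}

# vectorized: per-window dominant-axis index (1..3) and its MAV
dominant_axis_stats <- function(windows, sensor) {
  rows <- sensor_rows(sensor)
  n <- length(windows)
  ax <- integer(n)
  mav <- numeric(n)
  for (i in seq_len(n)) {
    m <- axis_mavs(windows$samples[rows, , i])
    ax[i] <- which.max(m)
    mav[i] <- m[ax[i]]
  }
  list(axis = ax, mav = mav)
}

#' Per-subject adaptive amplitude threshold
#'
#' Half of the maximum dominant-axis detrended MAV over all non-overlapping
#' 5-s windows of a subject's first recorded day. Computed once per subject
#' per sensor and reused for all later days.
#'
#' @param day1_windows `event_windows` from the subject's first recorded day.
#' @param sensor `"acc"` or `"gyro"`.
#' @return scalar threshold (g for acc, deg/s for gyro).
#' @export
compute_adaptive_threshold <- function(day1_windows, sensor = c("acc", "gyro")) {
  if (length(day1_windows) == 0L)
    stop("compute_adaptive_threshold: no windows")
  0.5 * max(dominant_axis_stats(day1_windows, match.arg(sensor))$mav)
}

#' Adaptive thresholds for one subject
#'
#' Computes both the accelerometer and gyroscope half-of-max thresholds from
#' the subject's first recorded day. Only the accelerometer threshold gates
#' the dynamic/static decision; the gyroscope threshold is retained for audit.
#'
#' @param windows `event_windows` for one subject (any span of days).
#' @return a `subject_thresholds` list with fields `subject_id`,
#'   `acc_threshold`, `gyro_threshold`, `source_day`.
#' @export
subject_thresholds <- function(windows) {
  sid <- unique(windows$subject_id)
  if (length(sid) != 1L) stop("subject_thresholds: windows must be one subject")
  d0 <- min(windows$day_index)
  day1 <- windows[windows$day_index == d0]
  structure(list(subject_id = sid,
                 acc_threshold = compute_adaptive_threshold(day1, "acc"),
                 gyro_threshold = compute_adaptive_threshold(day1, "gyro"),
                 source_day = d0),
            class = "subject_thresholds")
}

#' Dynamic-activity gate
#'
#' A window is dynamic iff its dominant-axis accelerometer detrended MAV is
#' strictly greater than the subject's adaptive accelerometer threshold.
#'
#' @param window an `event_windows` object.
#' @param thresholds a `subject_thresholds` object for the same subject.
#' @param i window index (default 1).
#' @return logical scalar.
#' @export
is_dynamic <- function(window, thresholds, i = 1L) {
  if (window$subject_id[i] != thresholds$subject_id)
    stop("is_dynamic: thresholds belong to a different subject")
  m <- axis_mavs(window$samples[1:3, , i])
  max(m) > thresholds$acc_threshold
}

#' Welch power spectral density estimate
#'
#' Averaged periodograms over Hann-tapered, 50%-overlapping, mean-detrended
#' segments (default 2 s, i.e. 40 samples at the 20 Hz analysis rate), with
#' one-sided density normalization: `sum(psd) * df` approximates the signal
#' variance. The 2-s segment gives 0.5 Hz resolution, enough to separate the
#' 0.6-2 Hz walking band from its complement.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param seg_seconds Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return list with `frequencies` (Hz, ascending in `[0, rate/2]`) and `psd`
#'   (non-negative, units^2/Hz).
#' @export
welch_psd <- function(x, rate, seg_seconds = 2, overlap = 0.5) {
  nper <- as.integer(round(seg_seconds * rate))
  n <- length(x)
  if (n < nper) stop("welch_psd: signal shorter than one Welch segment")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  w <- hann_periodic(nper)
  scale <- 1 / (rate * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2 * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  psd <- psd * dbl
  list(frequencies = (seq_len(nfreq) - 1L) * rate / nper, psd = psd)
}

hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

#' Walk-like gate for a dynamic window
#'
#' Estimates the Welch PSD of the dominant gyroscope axis and labels the
#' window walk-like iff the mean PSD over the walking band (default
#' 0.6-2 Hz) strictly exceeds the mean PSD over all other non-DC bins, and
#' the mean band PSD is at least `power_floor` (default 100 (deg/s)^2/Hz),
#' which rejects low-energy quasi-periodic motion.
#'
#' @param window an `event_windows` object.
#' @param band walking frequency band in Hz, length-2.
#' @param power_floor minimum mean band PSD.
#' @param i window index (default 1).
#' @return list with `walk_like` (logical), `dominant_gyro_axis`,
#'   `walking_band_power`, `rest_band_power`.
#' @export
is_walk_like <- function(window, band = c(0.6, 2), power_floor = 100, i = 1L) {
  rows <- sensor_rows("gyro")
  m <- axis_mavs(window$samples[rows, , i])
  ax <- which.max(m)
  x <- window$samples[rows[ax], , i]
  est <- welch_psd(x, window$sample_rate)
  in_band <- est$frequencies >= band[1] & est$frequencies <= band[2]
  rest <- est$frequencies > 0 & !in_band
  bp <- mean(est$psd[in_band])
  rp <- mean(est$psd[rest])
  list(walk_like = (bp > rp) && (bp >= power_floor),
       dominant_gyro_axis = c("x", "y", "z")[ax],
       walking_band_power = bp, rest_band_power = rp)
}

#' Annotate windows as static / dynamic-non-walk / walk-like
#'
#' Applies the full activity-recognition rule set to every window: per-subject
#' adaptive thresholds (computed from each subject's first recorded day unless
#' supplied), the dominant-axis accelerometer dynamic gate, and the
#' gyroscope spectral walk test on dynamic windows only.
#'
#' @param windows an `event_windows` object (one or more subjects).
#' @param thresholds optional named list of `subject_thresholds` keyed by
#'   subject id; computed from day-1 windows when `NULL`.
#' @param band walking band in Hz.
#' @param power_floor minimum mean walking-band PSD.
#' @return a data.frame with one row per window: `subject_id, day_index,
#'   start_time, label, dom_acc_axis, dom_gyro_axis, band_power, rest_power`.
#' @export
annotate_windows <- function(windows, thresholds = NULL,
                             band = c(0.6, 2), power_floor = 100) {
  n <- length(windows)
  sids <- unique(windows$subject_id)
  if (is.null(thresholds)) {
    thresholds <- lapply(sids, function(s)
      subject_thresholds(windows[windows$subject_id == s]))
    names(thresholds) <- sids
  }
  acc_stats <- dominant_axis_stats(windows, "acc")
  thr <- vapply(thresholds, `[[`, 0, "acc_threshold")[windows$subject_id]
  dynamic <- acc_stats$mav > thr
  label <- rep("static", n)
  dom_gyro <- rep(NA_character_, n)
  band_power <- rep(NA_real_, n)
  rest_power <- rep(NA_real_, n)
  for (i in which(dynamic)) {
    res <- is_walk_like(windows, band = band, power_floor = power_floor, i = i)
    label[i] <- if (res$walk_like) "walk_like" else "dynamic_nonwalk"
    dom_gyro[i] <- res$dominant_gyro_axis
    band_power[i] <- res$walking_band_power
    rest_power[i] <- res$rest_band_power
  }
  data.frame(subject_id = windows$subject_id,
             day_index = windows$day_index,
             start_time = windows$start_time,
             label = label,
             dom_acc_axis = c("x", "y", "z")[acc_stats$axis],
             dom_gyro_axis = dom_gyro,
             band_power = band_power,
             rest_power = rest_power,
             stringsAsFactors = FALSE)
}
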