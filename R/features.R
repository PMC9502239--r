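#' Canonical feature names, in fixed order
#'
#' 35 features per 5-s window: for each sensor (acc then gyro) the per-axis
#' mean, variance, skewness and excess kurtosis (12 each) plus the maximum
#' absolute amplitude across axes (1 each); then accelerometer band powers
#' for the low (0-4 Hz), tremor (4-9 Hz) and high (9 Hz-Nyquist) bands per
#' axis (9).
#'
#' @return character vector of length 35.
#' @export
feature_names <- function() {
  ax <- c("x", "y", "z")
  sensor_block <- function(s)
    c(paste0(s, "_mean_", ax), paste0(s, "_var_", ax),
      paste0(s, "_skew_", ax), paste0(s, "_kurt_", ax),
      paste0(s, "_max"))
  c(sensor_block("acc"), sensor_block("gyro"),
    paste0("acc_bp_low_", ax), paste0("acc_bp_mid_", ax),
    paste0("acc_bp_high_", ax))
}

# biased sample central moments (skew = m3/m2^1.5, excess kurt = m4/m2^2 - 3);
# zero-variance axes yield 0 for both
moment_stats <- function(x) {
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 <= 0)
    return(c(mean = mu, var = 0, skew = 0, kurt = 0))
  c(mean = mu, var = m2, skew = mean(d^3) / m2^1.5,
    kurt = mean(d^4) / m2^2 - 3)
}

#' Hann-tapered band power of a signal segment
#'
#' Mean-detrends, applies a Hann taper, takes the discrete Fourier transform
#' and sums the one-sided power over bins with `lo <= f < hi` (half-open;
#' when `hi` equals the Nyquist frequency the Nyquist bin is included, so the
#' three canonical bands partition the full non-DC spectrum). Power is
#' normalized so that the bands sum to the Hann-weighted signal variance.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param lo,hi band edges in Hz, `0 <= lo < hi <= rate/2`.
#' @return non-negative scalar.
#' @export
band_power_tapered <- function(x, rate, lo, hi) {
  nyq <- rate / 2
  if (!(lo >= 0 && lo < hi && hi <= nyq + 1e-9))
    stop("band_power_tapered: invalid band [", lo, ", ", hi, ")")
  n <- length(x)
  w <- hann_periodic(n)
  X <- stats::fft((x - mean(x)) * w)
  nfreq <- n %/% 2L + 1L
  f <- (seq_len(nfreq) - 1L) * rate / n
  p <- Mod(X[seq_len(nfreq)])^2 / (n * sum(w^2) / n)   # = |X|^2 / sum(w^2)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl / n
  sel <- f >= lo & f < hi
  if (hi >= nyq - 1e-9) sel <- sel | (f >= nyq - 1e-9)
  sel[1L] <- FALSE                                     # DC never in a band
  sum(p[sel])
}

#' Extract the 35-feature vector from one window
#'
#' Moments use the standard biased sample formulas with Fisher (excess)
#' kurtosis; "maximum across axes" is the largest absolute sample over the
#' three axes of each sensor; band powers are Hann-tapered accelerometer
#' powers over 0-4, 4-9 and 9-Nyquist Hz per axis (DC excluded — the mean is
#' already its own feature).
#'
#' @param window an `event_windows` object.
#' @param i window index (default 1).
#' @return named numeric vector of length 35 in `feature_names()` order.
#' @export
extract_features <- function(window, i = 1L) {
  rate <- window$sample_rate
  nyq <- rate / 2
  out <- numeric(35)
  k <- 0L
  for (rows in list(1:3, 4:6)) {
    m <- window$samples[rows, , i]
    stats <- apply(m, 1L, moment_stats)           # 4 x 3
    out[k + 1:12] <- as.numeric(t(stats))          # means xyz, vars xyz, ...
    out[k + 13L] <- max(abs(m))
    k <- k + 13L
  }
  bands <- list(c(0, 4), c(4, 9), c(9, nyq))
  for (b in seq_along(bands))
    for (a in 1:3)
      out[26L + (b - 1L) * 3L + a] <-
        band_power_tapered(window$samples[a, , i], rate,
                           bands[[b]][1], bands[[b]][2])
  names(out) <- feature_names()
  out
}

#' Feature matrix for a window collection
#'
#' @param windows an `event_windows` object.
#' @return data.frame with `subject_id, day_index, start_time` plus the 35
#'   canonical feature columns, one row per window.
#' @export
feature_matrix <- function(windows) {
  n <- length(windows)
  X <- matrix(0, n, 35, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) X[i, ] <- extract_features(windows, i)
  cbind(data.frame(subject_id = windows$subject_id,
                   day_index = windows$day_index,
                   start_time = windows$start_time,
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}
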