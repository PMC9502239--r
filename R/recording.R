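#' Inertial recording objects
#'
#' An `inertial_recording` holds one contiguous span of 6-channel IMU data for
#' a single subject: epoch-millisecond timestamps, a 3-column accelerometer
#' matrix (unit g) and a 3-column gyroscope matrix (unit deg/s), all of one
#' length, sampled at a nominal fixed rate.
#'
#' @param subject_id character scalar.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param timestamps numeric vector of epoch milliseconds, monotone
#'   non-decreasing.
#' @param acc,gyro numeric matrices with 3 columns (axes x, y, z) and one row
#'   per sample; accelerometer in g, gyroscope in deg/s.
#' @param validate check invariants (length agreement, monotone timestamps,
#'   sample spacing within 1% of `1/sample_rate`).
#' @return an object of class `inertial_recording`.
#' @export
inertial_recording <- function(subject_id, sample_rate, timestamps, acc, gyro,
                               validate = TRUE) {
  acc <- as_axis_matrix(acc)
  gyro <- as_axis_matrix(gyro)
  rec <- structure(
    list(subject_id = as.character(subject_id),
         sample_rate = as.numeric(sample_rate),
         timestamps = as.numeric(timestamps),
         acc = acc, gyro = gyro),
    class = "inertial_recording")
  if (validate) validate_recording(rec)
  rec
}

as_axis_matrix <- function(m) {
  if (is.null(m) || length(m) == 0L) return(matrix(numeric(0), 0L, 3L,
    dimnames = list(NULL, c("x", "y", "z"))))
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("axis matrix must have 3 columns (x, y, z)")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

validate_recording <- function(rec) {
  n <- length(rec$timestamps)
  if (nrow(rec$acc) != n || nrow(rec$gyro) != n)
    stop("all six channels and timestamps must share one length")
  if (rec$sample_rate <= 0) stop("sample_rate must be positive")
  if (n > 1L) {
    dt <- diff(rec$timestamps)
    if (any(dt < 0)) stop("timestamps must be monotone non-decreasing")
    expected <- 1000 / rec$sample_rate
    # spacing check on the typical step; gaps are handled at read time
    if (abs(stats::median(dt) - expected) > 0.01 * expected)
      stop("median sample spacing inconsistent with sample_rate (>1% off)")
  }
  invisible(rec)
}

#' @export
length.inertial_recording <- function(x) length(x$timestamps)

#' @export
print.inertial_recording <- function(x, ...) {
  n <- length(x)
  secs <- if (n > 1) (x$timestamps[n] - x$timestamps[1]) / 1000 else 0
  cat(sprintf("<inertial_recording> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n, x$sample_rate, secs))
  invisible(x)
}

#' Read a 6-channel inertial recording from a delimited text file
#'
#' Expects a header with a timestamp column (integer epoch milliseconds) and
#' six channel columns. Timestamp gaps longer than `max_gap_s` (non-wear,
#' charging) split the file into multiple recording segments; rows whose six
#' channels contain any NA are dropped before gap detection, so NA runs longer
#' than the gap limit also split the recording.
#'
#' @param path path to a CSV file.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param sample_rate nominal sampling rate in Hz.
#' @param schema named character vector mapping the canonical names
#'   `timestamp, acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z` to the column
#'   names present in the file.
#' @param max_gap_s gaps longer than this many seconds split the recording.
#' @return a list of `inertial_recording` segments (often of length one).
#' @export
read_recording <- function(path, subject_id = NULL, sample_rate = 100,
                           schema = default_schema(), max_gap_s = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  canon <- c("timestamp", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  schema <- schema[canon]
  missing <- canon[!(schema %in% names(df))]
  if (length(missing))
    stop("schema error: missing column(s): ",
         paste(schema[missing], collapse = ", "))
  df <- df[, schema]
  names(df) <- canon
  if (nrow(df) == 0L)
    return(list(inertial_recording(subject_id, sample_rate,
                                   numeric(0), NULL, NULL)))
  if (is.unsorted(df$timestamp))
    stop("format error: non-monotonic timestamps")
  keep <- stats::complete.cases(df[, -1L])
  df <- df[keep, , drop = FALSE]
  recording_segments(df, subject_id, sample_rate, max_gap_s)
}

default_schema <- function() {
  canon <- c("timestamp", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  stats::setNames(canon, canon)
}

recording_segments <- function(df, subject_id, sample_rate, max_gap_s) {
  n <- nrow(df)
  if (n == 0L)
    return(list(inertial_recording(subject_id, sample_rate,
                                   numeric(0), NULL, NULL)))
  cut <- which(diff(df$timestamp) > max_gap_s * 1000)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  lapply(seq_along(starts), function(i) {
    seg <- df[starts[i]:ends[i], , drop = FALSE]
    inertial_recording(subject_id, sample_rate, seg$timestamp,
                       as.matrix(seg[, 2:4]), as.matrix(seg[, 5:7]))
  })
}

#' Write a recording to the canonical CSV layout
#'
#' @param rec an `inertial_recording`.
#' @param path output file.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(timestamp = rec$timestamps,
                   acc_x = rec$acc[, 1], acc_y = rec$acc[, 2],
                   acc_z = rec$acc[, 3],
                   gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2],
                   gyro_z = rec$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Down-sample a recording by an integer factor with anti-alias filtering
#'
#' A zero-phase low-pass FIR filter (Hamming-windowed, cutoff at 0.45 x the
#' target rate) is applied before taking every k-th sample, so content above
#' the target Nyquist is attenuated by at least 40 dB. The symmetric
#' (linear-phase) kernel is applied centred, which makes the single pass
#' exactly zero-phase; edges are reflection-padded.
#'
#' @param rec an `inertial_recording`.
#' @param target_rate target sampling rate in Hz; the source rate must be an
#'   integer multiple of it.
#' @return the down-sampled `inertial_recording` of length
#'   `floor(length(rec) / factor)`.
#' @export
downsample_recording <- function(rec, target_rate = 20) {
  factor <- rec$sample_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("unsupported rate: source rate must be an integer multiple of target_rate")
  factor <- as.integer(round(factor))
  n <- length(rec)
  if (factor == 1L) return(rec)
  n_out <- n %/% factor
  idx <- seq.int(1L, by = factor, length.out = n_out)
  if (n_out == 0L)
    return(inertial_recording(rec$subject_id, target_rate, numeric(0),
                              NULL, NULL))
  b <- antialias_fir(rec$sample_rate, target_rate)
  acc <- apply(rec$acc, 2L, zero_phase_fir, b = b)
  gyro <- apply(rec$gyro, 2L, zero_phase_fir, b = b)
  inertial_recording(rec$subject_id, target_rate, rec$timestamps[idx],
                     acc[idx, , drop = FALSE], gyro[idx, , drop = FALSE],
                     validate = FALSE)
}

# Hamming-window FIR whose transition band fits between 0.45x and 0.5x the
# target rate, giving >= 40 dB stopband attenuation above the target Nyquist.
antialias_fir <- function(sample_rate, target_rate) {
  cutoff <- 0.45 * target_rate / (sample_rate / 2)   # normalized to Nyquist
  trans <- 0.1 * target_rate / sample_rate           # full width, units of fs
  ord <- ceiling(3.3 / trans)
  if (ord %% 2L == 1L) ord <- ord + 1L               # even order, type-I FIR
  as.numeric(signal::fir1(ord, cutoff))
}

# Centred application of a symmetric odd-length FIR kernel: exactly zero
# phase. Reflection padding removes boundary NAs.
zero_phase_fir <- function(x, b) {
  n <- length(x)
  half <- (length(b) - 1L) %/% 2L
  if (n == 0L) return(x)
  pad <- pmin(half, n - 1L)
  left <- if (pad > 0L) x[(pad + 1L):2L] else numeric(0)
  right <- if (pad > 0L) x[(n - 1L):(n - pad)] else numeric(0)
  xp <- c(left, x, right, double(2L * (half - pad)))
  y <- stats::filter(xp, b, method = "convolution", sides = 2L)
  as.numeric(y)[(pad + 1L):(pad + n)]
}

#' Segment a recording into non-overlapping fixed-length windows
#'
#' Windows are cut within calendar days (so that daily majority votes are
#' well-defined): each day's samples are split into consecutive windows of
#' `window_seconds`, and the trailing partial window of each day is dropped.
#' `day_index` is the calendar-day offset from the subject's first sample,
#' computed in a fixed UTC offset.
#'
#' @param rec an `inertial_recording` at the analysis rate.
#' @param window_seconds window length in seconds (default 5).
#' @param utc_offset_hours fixed offset applied before taking calendar days.
#' @param day_origin `"recording"` (default) indexes days from the
#'   recording's own first sample; `"absolute"` keeps raw calendar-day
#'   numbers so that windows from multiple recordings of one subject can be
#'   rebased jointly (see [rebase_days()]).
#' @return an `event_windows` object (possibly with zero windows).
#' @export
segment_windows <- function(rec, window_seconds = 5, utc_offset_hours = 0,
                            day_origin = c("recording", "absolute")) {
  day_origin <- match.arg(day_origin)
  L <- as.integer(round(rec$sample_rate * window_seconds))
  n <- length(rec)
  day_ms <- 86400000
  if (n == 0L) return(empty_event_windows(L, rec$sample_rate))
  day <- floor((rec$timestamps + utc_offset_hours * 3600000) / day_ms)
  day0 <- if (day_origin == "recording") day[1L] else 0
  runs <- rle(day)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  starts <- integer(0)
  days <- integer(0)
  for (i in seq_along(runs$lengths)) {
    k <- runs$lengths[i] %/% L
    if (k > 0L) {
      s <- run_start[i] + L * (seq_len(k) - 1L)
      starts <- c(starts, s)
      days <- c(days, rep.int(as.integer(runs$values[i] - day0), k))
    }
  }
  nw <- length(starts)
  samples <- array(0, dim = c(6L, L, nw))
  ch <- t(cbind(rec$acc, rec$gyro))           # 6 x n, rows acc xyz, gyro xyz
  for (i in seq_len(nw))
    samples[, , i] <- ch[, starts[i]:(starts[i] + L - 1L)]
  event_windows(subject_id = rep(rec$subject_id, nw),
                day_index = days,
                start_time = rec$timestamps[starts],
                samples = samples, sample_rate = rec$sample_rate)
}

#' Event window collections
#'
#' `event_windows` stores a batch of fixed-length 6-channel windows as a
#' `6 x L x n` array (rows: acc x,y,z then gyro x,y,z) together with
#' per-window subject, calendar-day index and start time.
#'
#' @param subject_id character vector, one per window.
#' @param day_index integer vector of calendar-day offsets.
#' @param start_time numeric vector of epoch-millisecond window starts.
#' @param samples numeric array `6 x L x n`.
#' @param sample_rate analysis sampling rate in Hz.
#' @return an object of class `event_windows`.
#' @export
event_windows <- function(subject_id, day_index, start_time, samples,
                          sample_rate) {
  n <- dim(samples)[3]
  stopifnot(dim(samples)[1] == 6L,
            length(subject_id) == n,
            length(day_index) == n,
            length(start_time) == n)
  structure(list(subject_id = as.character(subject_id),
                 day_index = as.integer(day_index),
                 start_time = as.numeric(start_time),
                 samples = samples,
                 sample_rate = as.numeric(sample_rate)),
            class = "event_windows")
}

empty_event_windows <- function(L, sample_rate) {
  event_windows(character(0), integer(0), numeric(0),
                array(0, dim = c(6L, L, 0L)), sample_rate)
}

#' @export
length.event_windows <- function(x) dim(x$samples)[3]

#' @export
print.event_windows <- function(x, ...) {
  cat(sprintf("<event_windows> %d windows of %d samples @ %g Hz, %d subject(s)\n",
              length(x), dim(x$samples)[2], x$sample_rate,
              length(unique(x$subject_id))))
  invisible(x)
}

#' Rebase day indices to each subject's first recorded day
#'
#' Subtracts, per subject, the smallest day index, so that `day_index` is the
#' calendar-day offset from that subject's first sample even when the
#' subject's data arrived as many per-day recordings.
#'
#' @param windows an `event_windows` object.
#' @return the same collection with rebased `day_index`.
#' @export
rebase_days <- function(windows) {
  for (s in unique(windows$subject_id)) {
    sel <- windows$subject_id == s
    windows$day_index[sel] <- windows$day_index[sel] -
      min(windows$day_index[sel])
  }
  windows
}

#' Concatenate window collections
#'
#' @param ... `event_windows` objects with identical window length and rate.
#' @return a single `event_windows` object.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && is.list(ws[[1]]) && !inherits(ws[[1]], "event_windows"))
    ws <- ws[[1]]
  L <- dim(ws[[1]]$samples)[2]
  rate <- ws[[1]]$sample_rate
  for (w in ws) stopifnot(dim(w$samples)[2] == L, w$sample_rate == rate)
  event_windows(
    subject_id = unlist(lapply(ws, `[[`, "subject_id")),
    day_index = unlist(lapply(ws, `[[`, "day_index")),
    start_time = unlist(lapply(ws, `[[`, "start_time")),
    samples = array(unlist(lapply(ws, function(w) w$samples)),
                    dim = c(6L, L, sum(vapply(ws, length, 1L)))),
    sample_rate = rate)
}

#' Subset a window collection
#'
#' @param x an `event_windows` object.
#' @param i index vector (integer or logical) over windows.
#' @param ... unused.
#' @return the subsetted `event_windows`.
#' @export
`[.event_windows` <- function(x, i, ...) {
  i <- seq_len(length(x))[i]
  event_windows(x$subject_id[i], x$day_index[i], x$start_time[i],
                x$samples[, , i, drop = FALSE], x$sample_rate)
}
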