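#' Configuration for the synthetic free-living cohort generator
#'
#' Generates multi-day, 6-channel wrist IMU recordings that emulate
#' unconstrained wear: long mostly-static days with gravity on a slowly
#' re-orienting accelerometer axis, broadband non-walk movement bursts, and
#' quasi-periodic walk bouts whose dominant gyroscope axis oscillates at a
#' per-subject step frequency in the walking band (fundamental plus one
#' harmonic). PD subjects express bradykinetic amplitude attenuation, an
#' added tremor tone inside the 4-9 Hz tremor range, elevated cycle-to-cycle
#' timing jitter, and a reduced walk bout rate.
#'
#' @param n_hc,n_pd subject counts (defaults 4 and 7, the study cohort).
#' @param days_per_subject number of consecutive recorded days, or use
#'   `day_offsets` for a sparse schedule.
#' @param day_offsets optional integer vector of calendar-day offsets to
#'   record (overrides `days_per_subject`).
#' @param sample_rate raw sampling rate in Hz (default 100).
#' @param wear_hours_per_day daily wear span in hours (default 18).
#' @param walk_bout_rate walk bouts per wear-hour for HC subjects.
#' @param bout_duration_meanlog,bout_duration_sdlog log-normal walk bout
#'   duration parameters in seconds (mean ~57 s).
#' @param step_frequency_range per-subject uniform draw range, Hz, inside the
#'   0.6-2 Hz walking band.
#' @param cadence_bout_sd relative sd of bout-level cadence variation about
#'   the subject's mean step frequency (people speed up and slow down
#'   between bouts).
#' @param walk_amplitude_gyro gyroscope gait oscillation amplitude, deg/s.
#' @param walk_amplitude_acc accelerometer gait oscillation amplitude, g.
#' @param subject_scale_sdlog log-normal spread of the per-subject overall
#'   movement-vigor factor.
#' @param axis_spread spread of per-subject gait axes around the canonical
#'   wrist orientation (0 = identical axes for everyone; larger values
#'   approach fully random orientations). Watches sit in a roughly
#'   consistent device frame, so gait axes cluster rather than scatter.
#' @param bout_axis_spread additional per-bout wobble of the gait axes about
#'   the subject's mean orientation (carrying objects, pockets, terrain all
#'   change the swing plane from bout to bout).
#' @param cycle_jitter_hc HC cycle-to-cycle relative frequency jitter (sd).
#' @param burst_rate non-walk dynamic bursts per wear-hour.
#' @param burst_duration_meanlog,burst_duration_sdlog log-normal burst
#'   duration parameters, seconds.
#' @param burst_acc_sd,burst_gyro_sd burst broadband amplitudes (g, deg/s).
#' @param noise_acc_sd,noise_gyro_sd sensor noise (g, deg/s).
#' @param pd_effects list with `amplitude_attenuation` (multiplies gait
#'   amplitudes, in `[0, 1]`), `tremor_band` (Hz), `tremor_amplitude` (gyro
#'   deg/s), `tremor_amplitude_acc` (g), `cycle_time_jitter_sd`,
#'   `bout_rate_factor` (PD walk-bout rate relative to HC, ~4.3/5.65).
#' @param seed RNG seed; cohorts are bit-identical given the seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_hc = 4L, n_pd = 7L, days_per_subject = 10L,
                              day_offsets = NULL,
                              sample_rate = 100, wear_hours_per_day = 18,
                              walk_bout_rate = 20,
                              bout_duration_meanlog = log(50),
                              bout_duration_sdlog = 0.5,
                              step_frequency_range = c(0.8, 1.8),
                              cadence_bout_sd = 0.07,
                              walk_amplitude_gyro = 120,
                              walk_amplitude_acc = 0.6,
                              subject_scale_sdlog = 0.15,
                              axis_spread = 0.4,
                              bout_axis_spread = 0.25,
                              cycle_jitter_hc = 0.02,
                              burst_rate = 30,
                              burst_duration_meanlog = log(15),
                              burst_duration_sdlog = 0.5,
                              burst_acc_sd = 0.25, burst_gyro_sd = 40,
                              noise_acc_sd = 0.01, noise_gyro_sd = 1,
                              pd_effects = list(),
                              seed = 1L) {
  pd_defaults <- list(amplitude_attenuation = 0.6,
                      tremor_band = c(4, 6),
                      tremor_amplitude = 30,
                      tremor_amplitude_acc = 0.1,
                      cycle_time_jitter_sd = 0.08,
                      bout_rate_factor = 4.3 / 5.65)
  pd <- utils::modifyList(pd_defaults, pd_effects)
  stopifnot(n_hc >= 0, n_pd >= 0, wear_hours_per_day > 0,
            pd$amplitude_attenuation >= 0, pd$amplitude_attenuation <= 1)
  if (is.null(day_offsets)) day_offsets <- seq_len(days_per_subject) - 1L
  structure(list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
                 day_offsets = as.integer(day_offsets),
                 sample_rate = sample_rate,
                 wear_hours_per_day = wear_hours_per_day,
                 walk_bout_rate = walk_bout_rate,
                 bout_duration_meanlog = bout_duration_meanlog,
                 bout_duration_sdlog = bout_duration_sdlog,
                 step_frequency_range = step_frequency_range,
                 cadence_bout_sd = cadence_bout_sd,
                 walk_amplitude_gyro = walk_amplitude_gyro,
                 walk_amplitude_acc = walk_amplitude_acc,
                 subject_scale_sdlog = subject_scale_sdlog,
                 axis_spread = axis_spread,
                 bout_axis_spread = bout_axis_spread,
                 cycle_jitter_hc = cycle_jitter_hc,
                 burst_rate = burst_rate,
                 burst_duration_meanlog = burst_duration_meanlog,
                 burst_duration_sdlog = burst_duration_sdlog,
                 burst_acc_sd = burst_acc_sd, burst_gyro_sd = burst_gyro_sd,
                 noise_acc_sd = noise_acc_sd, noise_gyro_sd = noise_gyro_sd,
                 pd_effects = pd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Null PD effects (exchangeable groups)
#'
#' Convenience constructor for the chance-calibration setting: PD subjects
#' are generated with exactly the HC effect values, making the two groups
#' statistically exchangeable.
#'
#' @param cfg a `simulation_config` whose HC parameters are reused.
#' @return a pd_effects list with all effects disabled.
#' @export
null_pd_effects <- function(cfg = simulation_config()) {
  list(amplitude_attenuation = 1, tremor_amplitude = 0,
       tremor_amplitude_acc = 0,
       cycle_time_jitter_sd = cfg$cycle_jitter_hc, bout_rate_factor = 1)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# canonical axis perturbed by gaussian noise and renormalized: per-subject
# sensor frames cluster around the common wrist-worn orientation
jittered_axis <- function(e, spread) {
  v <- e + stats::rnorm(3, 0, spread)
  v / sqrt(sum(v^2))
}

# sequential marked event process: Poisson-like starts (interarrival
# Exp(1/rate), floored at the previous duration so events never overlap);
# realized occupancy stays close to rate * mean duration
draw_intervals <- function(total_s, rate_per_h, meanlog, sdlog) {
  if (rate_per_h <= 0) return(cbind(start = numeric(0), end = numeric(0)))
  rate_s <- rate_per_h / 3600
  starts <- numeric(0)
  ends <- numeric(0)
  t <- stats::rexp(1, rate_s)
  while (t < total_s) {
    d <- stats::rlnorm(1, meanlog, sdlog)
    if (t + d > total_s) d <- total_s - t
    starts <- c(starts, t)
    ends <- c(ends, t + d)
    t <- t + max(d, stats::rexp(1, rate_s))
  }
  cbind(start = starts, end = ends)
}

# quasi-periodic gait oscillation: per-cycle frequency f0*(1+eps), one
# harmonic at 0.4x amplitude; returns the oscillation time course (unit amp)
gait_oscillation <- function(n, fs, f0, jitter_sd, harmonic_phase) {
  # draw per-cycle frequencies until total duration covers the bout
  freqs <- numeric(0)
  covered <- 0
  while (covered < n / fs) {
    f <- f0 * (1 + stats::rnorm(1, 0, jitter_sd))
    f <- max(f, 0.2)
    freqs <- c(freqs, f)
    covered <- covered + 1 / f
  }
  cyc_samples <- pmax(1L, round(fs / freqs))
  f_inst <- rep(freqs, times = cyc_samples)
  if (length(f_inst) < n)
    f_inst <- c(f_inst, rep(freqs[length(freqs)], n - length(f_inst)))
  f_inst <- f_inst[seq_len(n)]
  phi <- 2 * pi * cumsum(f_inst) / fs
  sin(phi) + 0.4 * sin(2 * phi + harmonic_phase)
}

simulate_subject_day <- function(cfg, sp, day_offset, t0_ms) {
  fs <- cfg$sample_rate
  total_s <- cfg$wear_hours_per_day * 3600
  n <- as.integer(round(total_s * fs))
  acc <- matrix(stats::rnorm(3L * n, 0, cfg$noise_acc_sd), n, 3L)
  gyro <- matrix(stats::rnorm(3L * n, 0, cfg$noise_gyro_sd), n, 3L)
  walk_iv <- draw_intervals(total_s, sp$bout_rate,
                            cfg$bout_duration_meanlog, cfg$bout_duration_sdlog)
  burst_iv <- draw_intervals(total_s, cfg$burst_rate,
                             cfg$burst_duration_meanlog,
                             cfg$burst_duration_sdlog)
  # drop bursts overlapping a walk bout
  if (nrow(burst_iv) && nrow(walk_iv)) {
    keep <- vapply(seq_len(nrow(burst_iv)), function(i)
      !any(burst_iv[i, "start"] < walk_iv[, "end"] &
             burst_iv[i, "end"] > walk_iv[, "start"]), TRUE)
    burst_iv <- burst_iv[keep, , drop = FALSE]
  }
  # gravity: 1 g along a direction that drifts slowly across activity
  # boundaries (exercises detrending and dominant-axis selection)
  knots_t <- c(0, sort(c(walk_iv[, "start"], burst_iv[, "start"])), total_s)
  dirs <- matrix(0, length(knots_t), 3L)
  dirs[1, ] <- sp$gravity
  for (i in seq_len(nrow(dirs) - 1L)) {
    d <- dirs[i, ] + stats::rnorm(3, 0, 0.1)
    dirs[i + 1L, ] <- d / sqrt(sum(d^2))
  }
  tt <- (seq_len(n) - 1L) / fs
  g <- sapply(1:3, function(a) stats::approx(knots_t, dirs[, a], tt,
                                             rule = 2)$y)
  g <- g / sqrt(rowSums(g^2))
  acc <- acc + g
  sample_of <- function(s) pmin(pmax(as.integer(floor(s * fs)) + 1L, 1L), n)
  # non-walk dynamic bursts: broadband noise + an off-band tone (3-8 Hz,
  # clear of the walking band even after spectral leakage) at 2x the
  # broadband amplitude so bursts stay dynamic after anti-alias filtering
  for (i in seq_len(nrow(burst_iv))) {
    idx <- sample_of(burst_iv[i, "start"]):sample_of(burst_iv[i, "end"])
    m <- length(idx)
    f_tone <- stats::runif(1, 3, 8)
    ph <- stats::runif(1, 0, 2 * pi)
    tone <- sin(2 * pi * f_tone * tt[idx] + ph)
    acc[idx, ] <- acc[idx, ] +
      matrix(stats::rnorm(3L * m, 0, sp$scale * cfg$burst_acc_sd), m, 3L) +
      outer(tone, sp$burst_dir) * 2 * sp$scale * cfg$burst_acc_sd
    gyro[idx, ] <- gyro[idx, ] +
      matrix(stats::rnorm(3L * m, 0, sp$scale * cfg$burst_gyro_sd), m, 3L) +
      outer(tone, sp$burst_dir) * 2 * sp$scale * cfg$burst_gyro_sd
  }
  # walk bouts (cadence varies bout to bout about the subject mean)
  for (i in seq_len(nrow(walk_iv))) {
    idx <- sample_of(walk_iv[i, "start"]):sample_of(walk_iv[i, "end"])
    m <- length(idx)
    f_bout <- sp$step_freq * (1 + stats::rnorm(1, 0, cfg$cadence_bout_sd))
    f_bout <- min(max(f_bout, 0.65), 1.95)
    ph <- stats::runif(3, 0, 2 * pi)     # gait/tremor phases vary per bout
    ax_g <- jittered_axis(sp$axis_gyro, cfg$bout_axis_spread)
    ax_a <- jittered_axis(sp$axis_acc, cfg$bout_axis_spread)
    ax_t <- jittered_axis(sp$axis_tremor, cfg$bout_axis_spread)
    osc_g <- gait_oscillation(m, fs, f_bout, sp$jitter, ph[1])
    osc_a <- gait_oscillation(m, fs, f_bout, sp$jitter, ph[2])
    gyro[idx, ] <- gyro[idx, ] + outer(osc_g * sp$amp_gyro, ax_g)
    acc[idx, ] <- acc[idx, ] + outer(osc_a * sp$amp_acc, ax_a)
    if (sp$tremor_gyro > 0 || sp$tremor_acc > 0) {
      tone <- sin(2 * pi * sp$tremor_freq * tt[idx] + ph[3])
      gyro[idx, ] <- gyro[idx, ] + outer(tone * sp$tremor_gyro, ax_t)
      acc[idx, ] <- acc[idx, ] + outer(tone * sp$tremor_acc, ax_t)
    }
  }
  ts <- t0_ms + round(tt * 1000)
  truth_rows <- function(iv, act) if (nrow(iv))
    data.frame(subject_id = sp$id,
               start_ms = t0_ms + round(iv[, "start"] * 1000),
               end_ms = t0_ms + round(iv[, "end"] * 1000),
               activity = act, stringsAsFactors = FALSE) else NULL
  truth <- rbind(truth_rows(walk_iv, "walk"),
                 truth_rows(burst_iv, "nonwalk_dynamic"))
  list(recording = inertial_recording(sp$id, fs, ts, acc, gyro,
                                      validate = FALSE),
       truth = truth)
}

#' Simulate a labeled free-living cohort
#'
#' Fully reproducible from `cfg$seed`. Each subject draws a step frequency,
#' movement-vigor scale, sensor orientation and (for PD) tremor frequency and
#' amplitude once; each recorded day is then generated independently with
#' walk bouts, non-walk bursts, drifting gravity and sensor noise.
#'
#' @param cfg a `simulation_config`.
#' @return list with `recordings` (list of one `inertial_recording` per
#'   subject-day), `subjects` (data.frame `subject_id, diagnosis`), `truth`
#'   (data.frame `subject_id, start_ms, end_ms, activity` for walk and burst
#'   intervals; unlisted time is rest), and `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  n_subj <- cfg$n_hc + cfg$n_pd
  if (n_subj == 0L)
    return(list(recordings = list(),
                subjects = data.frame(subject_id = character(0),
                                      diagnosis = character(0)),
                truth = NULL, config = cfg))
  ids <- sprintf("S%02d", seq_len(n_subj))
  diagnosis <- c(rep("HC", cfg$n_hc), rep("PD", cfg$n_pd))
  pd <- cfg$pd_effects
  base_ms <- 1.6e12                       # arbitrary epoch origin (UTC)
  start_in_day_h <- max(0, (24 - cfg$wear_hours_per_day) / 2)
  recordings <- list()
  truth <- NULL
  for (s in seq_len(n_subj)) {
    is_pd <- diagnosis[s] == "PD"
    att <- if (is_pd) pd$amplitude_attenuation else 1
    sp <- list(
      id = ids[s],
      step_freq = stats::runif(1, cfg$step_frequency_range[1],
                               cfg$step_frequency_range[2]),
      scale = stats::rlnorm(1, 0, cfg$subject_scale_sdlog),
      gravity = random_unit_vector(),
      axis_gyro = jittered_axis(c(0, 1, 0), cfg$axis_spread),
      axis_acc = jittered_axis(c(1, 0, 0), cfg$axis_spread),
      axis_tremor = jittered_axis(c(0, 0, 1), cfg$axis_spread),
      burst_dir = random_unit_vector(),
      jitter = if (is_pd) pd$cycle_time_jitter_sd else cfg$cycle_jitter_hc,
      bout_rate = cfg$walk_bout_rate *
        (if (is_pd) pd$bout_rate_factor else 1),
      tremor_freq = stats::runif(1, pd$tremor_band[1], pd$tremor_band[2]),
      tremor_gyro = if (is_pd && pd$tremor_amplitude > 0)
        stats::rlnorm(1, log(pd$tremor_amplitude), 0.2) else 0,
      tremor_acc = 0)
    sp$tremor_acc <- if (is_pd && (pd$tremor_amplitude_acc %||% 0) > 0)
      sp$tremor_gyro / max(pd$tremor_amplitude, 1e-9) *
        pd$tremor_amplitude_acc else 0
    sp$amp_gyro <- att * sp$scale * cfg$walk_amplitude_gyro
    sp$amp_acc <- att * sp$scale * cfg$walk_amplitude_acc
    for (d in cfg$day_offsets) {
      t0 <- base_ms + d * 86400000 + start_in_day_h * 3600000
      sim <- simulate_subject_day(cfg, sp, d, t0)
      recordings[[length(recordings) + 1L]] <- sim$recording
      truth <- rbind(truth, sim$truth)
    }
  }
  list(recordings = recordings,
       subjects = data.frame(subject_id = ids, diagnosis = diagnosis,
                             stringsAsFactors = FALSE),
       truth = truth, config = cfg)
}

#' Window-level ground truth
#'
#' A window's true activity is the activity covering its entire span (rest if
#' no walk/burst interval intersects it); windows straddling an activity
#' boundary are labeled `"mixed"`.
#'
#' @param windows an `event_windows` object.
#' @param truth the interval table from [simulate_cohort()].
#' @return character vector: `"rest"`, `"walk"`, `"nonwalk_dynamic"` or
#'   `"mixed"`, one per window.
#' @export
window_truth <- function(windows, truth) {
  n <- length(windows)
  L <- dim(windows$samples)[2]
  dur_ms <- L / windows$sample_rate * 1000
  out <- rep("rest", n)
  for (s in unique(windows$subject_id)) {
    iv <- truth[truth$subject_id == s, , drop = FALSE]
    wi <- which(windows$subject_id == s)
    for (i in wi) {
      w0 <- windows$start_time[i]
      w1 <- w0 + dur_ms
      hit <- which(iv$start_ms < w1 & iv$end_ms > w0)
      if (length(hit) == 0L) next
      covered <- any(iv$start_ms[hit] <= w0 & iv$end_ms[hit] >= w1)
      out[i] <- if (length(hit) == 1L && covered) iv$activity[hit]
                else if (covered) iv$activity[hit[iv$start_ms[hit] <= w0 &
                                                    iv$end_ms[hit] >= w1][1]]
                else "mixed"
    }
  }
  out
}

#' Tiny packaged cohort for end-to-end smoke tests
#'
#' 2 HC + 2 PD subjects, 2 minutes-long "days" each, with walk bouts frequent
#' enough that every subject-day contains walk-like events. Runs the full
#' pipeline end-to-end in well under a minute.
#'
#' @param seed RNG seed (fixed default so the fixture is reproducible).
#' @return the [simulate_cohort()] output list.
#' @export
make_fixture <- function(seed = 42L) {
  simulate_cohort(simulation_config(
    n_hc = 2L, n_pd = 2L, days_per_subject = 2L,
    wear_hours_per_day = 0.05, walk_bout_rate = 120, burst_rate = 60,
    seed = seed))
}
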