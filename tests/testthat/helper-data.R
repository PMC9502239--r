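# shared fixtures, built in code and cached for the duration of the run

.pdwear_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pdwear_cache[[key]])) assign(key, force(expr), .pdwear_cache)
  .pdwear_cache[[key]]
}

# windows whose six channels are tones at `freq` Hz with random phases plus
# gaussian noise; useful for separable-class problems
tone_windows <- function(n, freq, ids, rate = 20, L = 100, noise = 0.3,
                         day = 0L) {
  a <- array(0, c(6, L, n))
  tt <- (seq_len(L) - 1) / rate
  for (i in seq_len(n))
    a[, , i] <- t(sapply(1:6, function(c)
      sin(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(L, 0, noise)))
  event_windows(rep_len(ids, n), rep_len(day, n),
                seq_len(n) * 5000, a, rate)
}

# a window collection from raw channel matrices (list of 6 x L)
windows_from <- function(mats, rate = 20, id = "S", day = 0L) {
  L <- ncol(mats[[1]])
  a <- array(unlist(mats), c(6, L, length(mats)))
  event_windows(rep(id, length(mats)), rep(day, length(mats)),
                seq_along(mats) * L / rate * 1000, a, rate)
}

fixture_cohort <- function() cached("fixture", make_fixture())

fixture_detection <- function() cached("fixture_det", {
  detect_walks(fixture_cohort()$recordings)
})

# single-subject, single-day synthetic recording for HAR oracle checks
oracle_day <- function() cached("oracle_day", {
  cfg <- simulation_config(n_hc = 1, n_pd = 0, days_per_subject = 1,
                           wear_hours_per_day = 0.1, walk_bout_rate = 60,
                           seed = 7)
  simulate_cohort(cfg)
})

# independent brute-force re-implementations used as oracles ----------------

brute_mav <- function(x, detrend = TRUE) {
  if (detrend) {
    s <- 0
    for (v in x) s <- s + v
    xbar <- s / length(x)
  } else xbar <- 0
  tot <- 0
  for (v in x) tot <- tot + abs(v - xbar)
  tot / length(x)
}

brute_dominant_axis <- function(mat3) {
  best <- -Inf
  best_i <- 0L
  for (a in 1:3) {
    m <- brute_mav(mat3[a, ])
    if (m > best) {
      best <- m
      best_i <- a
    }
  }
  best_i
}
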