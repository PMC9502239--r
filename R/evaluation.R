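#' Leave-one-subject-out fold plan
#'
#' One fold per subject: that subject is the validation group and every other
#' subject trains. All training and validation windows are restricted to each
#' subject's first `train_day_limit` recorded days.
#'
#' @param subjects data.frame with columns `subject_id` and `diagnosis`
#'   (`"HC"`/`"PD"`).
#' @param train_day_limit number of initial recorded days used for training
#'   and validation (default 10).
#' @return a `fold_plan`: list of `(train, validation)` subject sets plus the
#'   day limit.
#' @export
make_logo_folds <- function(subjects, train_day_limit = 10L) {
  ids <- as.character(subjects$subject_id)
  if (length(ids) < 2L) stop("cannot fold: need at least 2 subjects")
  if (length(unique(subjects$diagnosis)) < 2L)
    stop("cannot fold: both classes must be present")
  folds <- lapply(ids, function(s)
    list(train = setdiff(ids, s), validation = s))
  structure(list(folds = folds,
                 train_day_limit = as.integer(train_day_limit),
                 diagnosis = stats::setNames(as.character(subjects$diagnosis),
                                             ids)),
            class = "fold_plan")
}

# mask of windows lying in each subject's first k *recorded* days
first_k_days_mask <- function(windows, k) {
  mask <- logical(length(windows))
  for (s in unique(windows$subject_id)) {
    sel <- windows$subject_id == s
    days <- sort(unique(windows$day_index[sel]))
    keep_days <- days[seq_len(min(k, length(days)))]
    mask[sel] <- windows$day_index[sel] %in% keep_days
  }
  mask
}

#' Daily majority vote over event predictions
#'
#' @param preds data.frame of event predictions for one subject-day (columns
#'   `predicted`, and `subject_id`/`day_index` if present).
#' @return a `daily_decision` list: `n_events`, `pd_vote_fraction`, `decided`
#'   (`"PD"` iff the PD vote fraction is >= 0.5; the tie goes to PD).
#' @export
daily_majority_vote <- function(preds) {
  if (nrow(preds) == 0L) stop("no-decision: empty day")
  frac <- mean(preds$predicted == "PD")
  list(subject_id = preds$subject_id[1] %||% NA_character_,
       day_index = preds$day_index[1] %||% NA_integer_,
       n_events = nrow(preds),
       pd_vote_fraction = frac,
       decided = if (frac >= 0.5) "PD" else "HC")
}

#' Daily decisions for a prediction table
#'
#' @param preds event-prediction data.frame with `subject_id, day_index,
#'   predicted`.
#' @return data.frame with one row per subject-day.
#' @export
daily_decisions <- function(preds) {
  if (nrow(preds) == 0L)
    return(data.frame(subject_id = character(0), day_index = integer(0),
                      n_events = integer(0), pd_vote_fraction = numeric(0),
                      decided = character(0), stringsAsFactors = FALSE))
  key <- split(seq_len(nrow(preds)),
               list(preds$subject_id, preds$day_index), drop = TRUE)
  rows <- lapply(key, function(i) {
    d <- daily_majority_vote(preds[i, , drop = FALSE])
    data.frame(subject_id = d$subject_id, day_index = d$day_index,
               n_events = d$n_events, pd_vote_fraction = d$pd_vote_fraction,
               decided = d$decided, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$day_index), , drop = FALSE]
}

#' Leave-one-subject-out cross-validation of the CNN event classifier
#'
#' For each fold, a fresh CNN is trained on the training subjects' first
#' `train_day_limit` recorded days; the held-out subject's windows from the
#' same day range serve as the fold's validation set, both for early
#' stopping during training and for the reported validation accuracy (the
#' standard protocol for this design: the truly untouched test data are the
#' later temporal-holdout blocks, see [temporal_holdout_eval()]). Leakage
#' guard: no window from the validation subject enters the gradient
#' training set.
#'
#' @param windows walk-like `event_windows` for the whole cohort.
#' @param folds a `fold_plan` from [make_logo_folds()].
#' @param cfg a `cnn_config`; fold f uses seed `cfg$seed + f`.
#' @param sensors channel subset: `"both"`, `"acc"` or `"gyro"`.
#' @return list with `predictions` (event-level data.frame with `truth`),
#'   `daily` (daily decisions with `truth`), `subject_event_accuracy`,
#'   `models` (one trained model per fold), `sensors`.
#' @export
run_logo_cv <- function(windows, folds, cfg = cnn_config(), sensors = "both") {
  diagnosis <- folds$diagnosis
  keep <- first_k_days_mask(windows, folds$train_day_limit)
  preds <- NULL
  models <- vector("list", length(folds$folds))
  names(models) <- vapply(folds$folds, `[[`, "", "validation")
  n_ch <- length(sensor_channel_rows(sensors))
  for (f in seq_along(folds$folds)) {
    fold <- folds$folds[[f]]
    tr_sel <- keep & windows$subject_id %in% fold$train
    va_sel <- keep & windows$subject_id == fold$validation
    stopifnot(!any(windows$subject_id[tr_sel] == fold$validation))
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- build_cnn(fold_cfg, n_channels = n_ch,
                       L = dim(windows$samples)[2])
    model <- train_cnn(model, windows[tr_sel],
                       diagnosis[windows$subject_id[tr_sel]],
                       windows[va_sel],
                       diagnosis[windows$subject_id[va_sel]],
                       sensors = sensors)
    models[[fold$validation]] <- model
    if (any(va_sel)) {
      p <- predict_events(model, windows[va_sel])
      p$truth <- unname(diagnosis[p$subject_id])
      preds <- rbind(preds, p)
    }
  }
  daily <- daily_decisions(preds)
  daily$truth <- unname(diagnosis[daily$subject_id])
  acc <- tapply(preds$predicted == preds$truth, preds$subject_id, mean)
  list(predictions = preds, daily = daily,
       subject_event_accuracy = acc, models = models, sensors = sensors,
       folds = folds)
}

#' Temporal holdout evaluation of per-fold models
#'
#' Applies each fold's trained model to the validation subject's windows in
#' 5-day blocks starting `month_starts` days after that subject's first
#' recorded day (default 30/60/90 — one, two and three months out). Blocks
#' overlapping the training day range are rejected; subject-months with no
#' windows are reported as absent.
#'
#' @param logo result of [run_logo_cv()].
#' @param windows full-span walk-like `event_windows` (including holdout days).
#' @param month_starts day offsets of each holdout block.
#' @param block_days block length in days (default 5).
#' @return list with `events` (per subject-month event accuracy, NA when
#'   absent), `daily` (per subject-month daily-vote accuracy), `predictions`.
#' @export
temporal_holdout_eval <- function(logo, windows, month_starts = c(30, 60, 90),
                                  block_days = 5L) {
  folds <- logo$folds
  diagnosis <- folds$diagnosis
  if (min(month_starts) < folds$train_day_limit)
    stop("temporal leakage: holdout block overlaps the training day range")
  rows <- NULL
  preds_all <- NULL
  for (fold in folds$folds) {
    s <- fold$validation
    model <- logo$models[[s]]
    sel_s <- windows$subject_id == s
    d0 <- if (any(sel_s)) min(windows$day_index[sel_s]) else 0L
    for (m in seq_along(month_starts)) {
      lo <- d0 + month_starts[m]
      sel <- sel_s & windows$day_index >= lo &
        windows$day_index < lo + block_days
      if (!any(sel)) {
        rows <- rbind(rows, data.frame(
          subject_id = s, month = m, n_events = 0L,
          event_accuracy = NA_real_, daily_vote_accuracy = NA_real_,
          stringsAsFactors = FALSE))
        next
      }
      p <- predict_events(model, windows[sel])
      p$truth <- unname(diagnosis[p$subject_id])
      p$month <- m
      preds_all <- rbind(preds_all, p)
      daily <- daily_decisions(p)
      rows <- rbind(rows, data.frame(
        subject_id = s, month = m, n_events = nrow(p),
        event_accuracy = mean(p$predicted == p$truth),
        daily_vote_accuracy = mean(daily$decided == diagnosis[s]),
        stringsAsFactors = FALSE))
    }
  }
  list(events = rows, predictions = preds_all)
}

#' Daily walk-like duration summary and group comparison
#'
#' Converts per-day walk-like window counts into hours
#' (`count * window_seconds / 3600`), summarizes per subject and per group,
#' and runs a Welch two-sample t-test on the daily values between groups.
#'
#' @param annotations annotation data.frame from [annotate_windows()].
#' @param diagnosis named character vector mapping subject id to
#'   `"HC"`/`"PD"`.
#' @param window_seconds window length in seconds.
#' @return list with `daily` (subject-day hours), `subject_means`,
#'   `group_means`, and `test` (the `htest`, or `NULL` with one group).
#' @export
walk_duration_summary <- function(annotations, diagnosis, window_seconds = 5) {
  walk <- annotations[annotations$label == "walk_like", , drop = FALSE]
  all_days <- unique(annotations[, c("subject_id", "day_index")])
  counts <- merge(all_days,
                  stats::aggregate(list(n = rep(1L, nrow(walk))),
                                   walk[, c("subject_id", "day_index")], sum),
                  by = c("subject_id", "day_index"), all.x = TRUE)
  counts$n[is.na(counts$n)] <- 0L
  counts$hours <- counts$n * window_seconds / 3600
  counts$diagnosis <- unname(diagnosis[counts$subject_id])
  subject_means <- stats::aggregate(hours ~ subject_id + diagnosis,
                                    counts, mean)
  group_means <- stats::aggregate(hours ~ diagnosis, counts, mean)
  test <- NULL
  if (length(unique(counts$diagnosis)) == 2L)
    test <- tryCatch(stats::t.test(hours ~ diagnosis, counts),
                     error = function(e) NULL)   # e.g. one day per group
  list(daily = counts, subject_means = subject_means,
       group_means = group_means, test = test)
}
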