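#' Configuration for the 1D convolutional event classifier
#'
#' Four convolutional blocks (conv -> L2 penalty -> batch normalization ->
#' ReLU) with a 5-point kernel, stride 2 and no pooling, channel widths
#' (8, 16, 32, 64), "same" padding so the temporal length halves per layer;
#' dropout 0.5 after the last block, then flatten and a 2-unit softmax read
#' out with categorical cross-entropy (the two-class form of binary
#' cross-entropy) trained by Adam.
#'
#' @param kernel convolution kernel size (samples).
#' @param stride convolution stride.
#' @param channels integer vector of per-layer channel counts; its length is
#'   the number of convolutional layers.
#' @param l2 L2 penalty coefficient on convolution kernels.
#' @param dropout dropout rate after the final convolutional block, in [0, 1).
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); best weights are restored.
#' @param lr Adam learning rate.
#' @param class_weights weight classes inversely to their training frequency.
#'   Leave-one-subject-out folds are structurally imbalanced (removing one
#'   subject's windows), and without reweighting a no-signal fit collapses to
#'   the training-majority class; weighting keeps the no-signal fixed point at
#'   chance.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(kernel = 5L, stride = 2L, channels = c(8L, 16L, 32L, 64L),
                       l2 = 1e-4, dropout = 0.5, batch_size = 64L,
                       epochs = 50L, patience = 12L, lr = 1e-3,
                       class_weights = TRUE, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, l2 >= 0, length(channels) >= 1)
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 channels = as.integer(channels), l2 = l2, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

conv_out_len <- function(l_in, stride) as.integer(ceiling(l_in / stride))

same_padding <- function(l_in, kernel, stride) {
  l_out <- conv_out_len(l_in, stride)
  total <- max((l_out - 1L) * stride + kernel - l_in, 0L)
  c(left = total %/% 2L, right = total - total %/% 2L)
}

#' Temporal lengths of every convolutional layer output
#'
#' @param L input window length in samples.
#' @param cfg a `cnn_config`.
#' @return integer vector, one length per layer (e.g. 50, 25, 13, 7 for
#'   L = 100 with stride 2).
#' @export
cnn_layer_lengths <- function(L, cfg = cnn_config()) {
  out <- integer(length(cfg$channels))
  l <- as.integer(L)
  for (i in seq_along(out)) {
    l <- conv_out_len(l, cfg$stride)
    out[i] <- l
  }
  out
}

#' Receptive field of one final-layer time step
#'
#' Iterative recurrence `r_l = r_{l-1} + (k - 1) * prod(strides before l)`:
#' the number of input samples that influence a single output unit of the
#' strided convolutional stack.
#'
#' @param cfg a `cnn_config`.
#' @return integer (61 for the default 4-layer, kernel-5, stride-2 stack).
#' @export
cnn_receptive_field <- function(cfg = cnn_config()) {
  r <- 1L
  jump <- 1L
  for (i in seq_along(cfg$channels)) {
    r <- r + (cfg$kernel - 1L) * jump
    jump <- jump * cfg$stride
  }
  r
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained 1D-CNN event classifier
#'
#' Initializes convolution kernels (He), batch-norm parameters and the dense
#' softmax head for a given input shape. The model records the layer geometry
#' (temporal lengths, paddings, flatten width) so that inference is a pure
#' function of the weights.
#'
#' @param cfg a `cnn_config`.
#' @param n_channels input channel count (6 for acc+gyro, 3 for one sensor).
#' @param L input window length in samples (>= 16).
#' @return an object of class `cnn_model`.
#' @export
build_cnn <- function(cfg = cnn_config(), n_channels = 6L, L = 100L) {
  if (L < 16L) stop("configuration error: window length L must be >= 16")
  if (n_channels < 1L) stop("configuration error: need >= 1 input channel")
  set.seed(cfg$seed)
  n_layers <- length(cfg$channels)
  layers <- vector("list", n_layers)
  c_in <- as.integer(n_channels)
  l_in <- as.integer(L)
  for (i in seq_len(n_layers)) {
    c_out <- cfg$channels[i]
    pad <- same_padding(l_in, cfg$kernel, cfg$stride)
    layers[[i]] <- list(
      W = he_init(c_out, c_in * cfg$kernel, c_in * cfg$kernel),
      b = numeric(c_out),
      gamma = rep(1, c_out), beta = numeric(c_out),
      run_mean = numeric(c_out), run_var = rep(1, c_out),
      c_in = c_in, c_out = c_out, l_in = l_in,
      l_out = conv_out_len(l_in, cfg$stride), pad = pad)
    c_in <- c_out
    l_in <- layers[[i]]$l_out
  }
  flat <- c_in * l_in
  structure(list(cfg = cfg, n_channels = as.integer(n_channels),
                 L = as.integer(L), layers = layers, flat_width = flat,
                 dense = list(W = he_init(2L, flat, flat), b = numeric(2)),
                 norm = NULL, classes = c("HC", "PD"), trained = FALSE),
            class = "cnn_model")
}

#' Number of trainable parameters of a built model
#'
#' @param model a `cnn_model`.
#' @return integer count (convolution kernels and biases, batch-norm gains
#'   and shifts, dense weights and biases).
#' @export
cnn_n_params <- function(model) {
  n <- sum(vapply(model$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), 0))
  n + length(model$dense$W) + length(model$dense$b)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d x %d input, conv channels (%s), flat %d, %s\n",
              x$n_channels, x$L, paste(x$cfg$channels, collapse = ", "),
              x$flat_width, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward primitives -----------------------------------------
# Activations travel as C x (L*N) matrices with column order: time fastest,
# then sample. im2col turns each convolution into one BLAS matmul; all
# gathers/scatters are flat-matrix column indexing (no 3D arrays) for speed.

# column indices of padded input (C x Lp*N) feeding kernel tap j
conv_geometry <- function(L, N, kernel, stride, pad, l_out) {
  Lp <- L + pad[1] + pad[2]
  sample_base <- rep((seq_len(N) - 1L) * Lp, each = l_out)
  inner <- rep((seq_len(N) - 1L) * Lp, each = L) +
    rep(pad[1] + seq_len(L), N)
  tap_cols <- lapply(seq_len(kernel), function(j)
    sample_base + rep((seq_len(l_out) - 1L) * stride + j, N))
  list(Lp = Lp, inner = inner, tap_cols = tap_cols)
}

im2col <- function(X, C, N, kernel, l_out, geo) {
  Xp <- matrix(0, C, geo$Lp * N)
  Xp[, geo$inner] <- X
  col <- matrix(0, C * kernel, l_out * N)
  for (j in seq_len(kernel))
    col[(j - 1L) * C + seq_len(C), ] <- Xp[, geo$tap_cols[[j]]]
  col
}

col2im <- function(dcol, C, N, kernel, geo) {
  dXp <- matrix(0, C, geo$Lp * N)
  for (j in seq_len(kernel)) {
    cols <- geo$tap_cols[[j]]
    dXp[, cols] <- dXp[, cols] + dcol[(j - 1L) * C + seq_len(C), ]
  }
  dXp[, geo$inner, drop = FALSE]
}

bn_eps <- 1e-5

conv_block_forward <- function(X, layer, cfg, N, training, momentum = 0.9,
                               geo = NULL) {
  if (is.null(geo))
    geo <- conv_geometry(layer$l_in, N, cfg$kernel, cfg$stride, layer$pad,
                         layer$l_out)
  col <- im2col(X, layer$c_in, N, cfg$kernel, layer$l_out, geo)
  Z <- layer$W %*% col + layer$b
  if (training) {
    mu <- rowMeans(Z)
    v <- rowMeans(Z^2) - mu^2
    layer$run_mean <- momentum * layer$run_mean + (1 - momentum) * mu
    layer$run_var <- momentum * layer$run_var + (1 - momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(v + bn_eps)
  Xhat <- (Z - mu) * inv_sd
  A <- layer$gamma * Xhat + layer$beta
  Y <- A * (A > 0)
  list(Y = Y, layer = layer,
       cache = if (training) list(col = col, geo = geo, mu = mu,
                                  inv_sd = inv_sd, Xhat = Xhat,
                                  relu_mask = (A > 0)) else NULL)
}

conv_block_backward <- function(dY, layer, cache, cfg, N, l2) {
  dA <- dY * cache$relu_mask
  # batch-norm backward, per channel over m = l_out * N columns
  m <- ncol(dA)
  dXhat <- dA * layer$gamma
  dgamma <- rowSums(dA * cache$Xhat)
  dbeta <- rowSums(dA)
  sum_dXhat <- rowSums(dXhat)
  sum_dXhat_xhat <- rowSums(dXhat * cache$Xhat)
  dZ <- cache$inv_sd *
    (dXhat - sum_dXhat / m - cache$Xhat * (sum_dXhat_xhat / m))
  dW <- tcrossprod(dZ, cache$col) + l2 * layer$W
  db <- rowSums(dZ)
  dcol <- crossprod(layer$W, dZ)
  dX <- col2im(dcol, layer$c_in, N, cfg$kernel, cache$geo)
  list(dX = dX, grads = list(W = dW, b = db, gamma = dgamma, beta = dbeta))
}

model_geometry <- function(model, N) {
  cfg <- model$cfg
  lapply(model$layers, function(l)
    conv_geometry(l$l_in, N, cfg$kernel, cfg$stride, l$pad, l$l_out))
}

cnn_forward <- function(model, X, N, training = FALSE, dropout_mask = NULL,
                        geos = NULL) {
  cfg <- model$cfg
  caches <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    fw <- conv_block_forward(A, model$layers[[i]], cfg, N, training,
                             geo = if (!is.null(geos)) geos[[i]])
    model$layers[[i]] <- fw$layer
    caches[[i]] <- fw$cache
    A <- fw$Y
  }
  last <- model$layers[[length(model$layers)]]
  Fmat <- matrix(array(A, dim = c(last$c_out, last$l_out, N)),
                 model$flat_width, N)
  if (training && !is.null(dropout_mask)) Fmat <- Fmat * dropout_mask
  logits <- model$dense$W %*% Fmat + model$dense$b
  mx <- apply(logits, 2L, max)
  E <- exp(sweep(logits, 2L, mx))
  P <- sweep(E, 2L, colSums(E), "/")
  list(model = model, P = P, Fmat = Fmat, caches = caches)
}

# one-hot Y (2 x N, rows HC then PD), per-sample weights w
cnn_loss <- function(P, Y, w) {
  -sum(w * log(pmax(colSums(P * Y), 1e-12))) / sum(w)
}

adam_init <- function(params) lapply(params, function(p) {
  list(m = p * 0, v = p * 0)
})

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

# labels as character vector of "HC"/"PD" -> one-hot 2 x N
one_hot <- function(labels) {
  y <- matrix(0, 2L, length(labels))
  y[1L, labels == "HC"] <- 1
  y[2L, labels == "PD"] <- 1
  y
}

# Input normalization. Per window: channel means are removed (gravity and
# gyro bias are orientation- and subject-specific DC levels that would leak
# subject identity across folds) and each sensor triplet is scaled to unit
# RMS (events are classified by waveform shape and spectral texture, in
# normalized units, not by absolute amplitude, which varies more between
# subjects than between classes). A per-channel sd computed on the training
# windows then balances the channels.
demean_windows <- function(samples) {
  d <- dim(samples)
  mu <- colMeans(aperm(samples, c(2, 1, 3)))          # C x N channel means
  samples - aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
}

normalize_windows <- function(samples) {
  samples <- demean_windows(samples)
  C <- dim(samples)[1]
  for (r0 in seq.int(1L, C, by = 3L)) {
    r <- r0:(r0 + 2L)
    rms <- sqrt(apply(samples[r, , , drop = FALSE]^2, 3L, mean))
    samples[r, , ] <- sweep(samples[r, , , drop = FALSE], 3L,
                            pmax(rms, 1e-8), "/")
  }
  samples
}

standardize_stats <- function(samples) {
  samples <- normalize_windows(samples)
  C <- dim(samples)[1]
  sd <- numeric(C)
  for (c in seq_len(C)) {
    sd[c] <- stats::sd(as.numeric(samples[c, , ]))
    if (!is.finite(sd[c]) || sd[c] == 0) sd[c] <- 1
  }
  list(sd = sd)
}

apply_standardize <- function(samples, norm) {
  normalize_windows(samples) / norm$sd
}

sensor_channel_rows <- function(sensors = c("both", "acc", "gyro")) {
  switch(match.arg(sensors), both = 1:6, acc = 1:3, gyro = 4:6)
}

#' Train the 1D-CNN on labeled event windows
#'
#' Per-channel standardization statistics are computed on the training windows
#' only and stored with the model. Training minimizes (optionally
#' class-weighted) cross-entropy with Adam, evaluates the validation loss
#' after every epoch (and once before training), and restores the best
#' weights after `patience` epochs without improvement. Deterministic given
#' `cfg$seed`.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param train_windows,val_windows `event_windows`; training and validation
#'   subjects must be disjoint.
#' @param train_labels,val_labels character vectors of `"HC"`/`"PD"`.
#' @param sensors which channels to use: `"both"`, `"acc"` or `"gyro"`.
#' @return the trained `cnn_model` with a `history` element (per-epoch train
#'   and validation loss).
#' @export
train_cnn <- function(model, train_windows, train_labels,
                      val_windows = NULL, val_labels = NULL,
                      sensors = "both") {
  cfg <- model$cfg
  rows <- sensor_channel_rows(sensors)
  if (length(rows) != model$n_channels)
    stop("model input channels do not match the sensor subset")
  if (length(unique(train_labels)) < 2L)
    stop("training error: training set contains a single class")
  if (!is.null(val_windows) &&
      length(intersect(unique(train_windows$subject_id),
                       unique(val_windows$subject_id))) > 0L)
    stop("training and validation subjects must be disjoint")
  set.seed(cfg$seed)
  Xtr_all <- train_windows$samples[rows, , , drop = FALSE]
  norm <- standardize_stats(Xtr_all)
  Xtr_all <- apply_standardize(Xtr_all, norm)
  model$norm <- norm
  model$sensors <- sensors
  Ytr <- one_hot(train_labels)
  ntr <- length(train_labels)
  cw <- c(HC = 1, PD = 1)
  if (cfg$class_weights) {
    tab <- table(factor(train_labels, c("HC", "PD")))
    cw <- as.numeric(ntr / (2 * tab))
    names(cw) <- c("HC", "PD")
  }
  wtr <- cw[train_labels]
  has_val <- !is.null(val_windows) && length(val_windows) > 0L
  if (has_val) {
    Xval <- apply_standardize(val_windows$samples[rows, , , drop = FALSE], norm)
    Yval <- one_hot(val_labels)
    wval <- cw[val_labels]
    nval <- length(val_labels)
  }
  eval_loss <- function(m, X, n, Y, w) {
    fw <- cnn_forward(m, matrix(X, model$n_channels, model$L * n), n,
                      training = FALSE)
    cnn_loss(fw$P, Y, w)
  }
  params_of <- function(m) {
    ps <- list()
    for (i in seq_along(m$layers))
      ps[[i]] <- m$layers[[i]][c("W", "b", "gamma", "beta")]
    ps$dense <- m$dense
    ps
  }
  opt <- lapply(params_of(model), adam_init)
  geos_full <- model_geometry(model, cfg$batch_size)
  t_step <- 0L
  best <- list(loss = if (has_val) eval_loss(model, Xval, nval, Yval, wval)
                       else Inf,
               snap = model, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(ntr)
    nb <- ceiling(ntr / cfg$batch_size)
    ep_loss <- 0
    ep_w <- 0
    for (bi in seq_len(nb)) {
      sel <- idx[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, ntr)]
      N <- length(sel)
      Xb <- matrix(Xtr_all[, , sel, drop = FALSE], model$n_channels,
                   model$L * N)
      Yb <- Ytr[, sel, drop = FALSE]
      wb <- wtr[sel]
      dmask <- NULL
      if (cfg$dropout > 0)
        dmask <- matrix(stats::rbinom(model$flat_width * N, 1L,
                                      1 - cfg$dropout) / (1 - cfg$dropout),
                        model$flat_width, N)
      fw <- cnn_forward(model, Xb, N, training = TRUE, dropout_mask = dmask,
                        geos = if (N == cfg$batch_size) geos_full)
      model <- fw$model
      loss <- cnn_loss(fw$P, Yb, wb)
      ep_loss <- ep_loss + loss * sum(wb)
      ep_w <- ep_w + sum(wb)
      # backward
      sw <- sum(wb)
      dlogits <- sweep(fw$P - Yb, 2L, wb / sw, "*")
      grads <- list()
      gd <- list(W = tcrossprod(dlogits, fw$Fmat), b = rowSums(dlogits))
      dF <- crossprod(model$dense$W, dlogits)
      if (!is.null(dmask)) dF <- dF * dmask
      last <- model$layers[[length(model$layers)]]
      dA <- matrix(array(dF, dim = c(last$c_out, last$l_out, N)),
                   last$c_out, last$l_out * N)
      for (i in rev(seq_along(model$layers))) {
        bw <- conv_block_backward(dA, model$layers[[i]], fw$caches[[i]],
                                  cfg, N, cfg$l2)
        grads[[i]] <- bw$grads
        dA <- bw$dX
      }
      grads$dense <- gd
      # adam update
      t_step <- t_step + 1L
      for (i in seq_along(model$layers)) {
        for (nm in c("W", "b", "gamma", "beta")) {
          up <- adam_step(model$layers[[i]][[nm]], grads[[i]][[nm]],
                          opt[[i]][[nm]], cfg$lr, t_step)
          model$layers[[i]][[nm]] <- up$p
          opt[[i]][[nm]] <- up$st
        }
      }
      for (nm in c("W", "b")) {
        up <- adam_step(model$dense[[nm]], grads$dense[[nm]],
                        opt$dense[[nm]], cfg$lr, t_step)
        model$dense[[nm]] <- up$p
        opt$dense[[nm]] <- up$st
      }
    }
    tr_loss <- ep_loss / ep_w
    v_loss <- if (has_val) eval_loss(model, Xval, nval, Yval, wval) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = v_loss))
    if (has_val) {
      if (v_loss < best$loss - 1e-6) {
        best <- list(loss = v_loss, snap = model, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (has_val && is.finite(best$loss)) model <- best$snap
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- if (has_val) best$epoch else nrow(history)
  model
}

#' Predict PD probability for event windows
#'
#' Applies the stored per-channel standardization, runs the network in
#' inference mode (dropout disabled, batch-norm running statistics) and
#' returns softmax class probabilities. `predicted` is `"PD"` iff
#' `p_pd >= 0.5`.
#'
#' @param model a trained `cnn_model`.
#' @param windows an `event_windows` object.
#' @return data.frame `subject_id, day_index, start_time, p_pd, predicted`.
#' @export
predict_events <- function(model, windows) {
  if (!isTRUE(model$trained)) stop("usage error: model is not trained")
  rows <- sensor_channel_rows(model$sensors %||% "both")
  X <- windows$samples[rows, , , drop = FALSE]
  if (dim(X)[1] != model$n_channels || dim(X)[2] != model$L)
    stop("usage error: window shape does not match the model input")
  n <- length(windows)
  X <- apply_standardize(X, model$norm)
  fw <- cnn_forward(model, matrix(X, model$n_channels, model$L * n), n,
                    training = FALSE)
  p_pd <- fw$P[2L, ]
  data.frame(subject_id = windows$subject_id,
             day_index = windows$day_index,
             start_time = windows$start_time,
             p_pd = p_pd,
             predicted = ifelse(p_pd >= 0.5, "PD", "HC"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
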