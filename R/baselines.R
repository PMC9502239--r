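#' Specification of a comparison classifier
#'
#' The four feature-based classifiers run against the CNN under the identical
#' leave-one-subject-out protocol: logistic regression, random forest,
#' gradient-boosted trees, and elastic net (penalized logistic classification,
#' alpha = 0.5). Hyperparameters stay at the implementations' documented
#' defaults unless overridden.
#'
#' @param method one of `"logistic_regression"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`, `"elastic_net"`.
#' @param params named list of overrides passed to the underlying fitter.
#' @param seed RNG seed.
#' @return a `baseline_spec` list.
#' @export
baseline_spec <- function(method = c("logistic_regression", "random_forest",
                                     "gradient_boosted_trees", "elastic_net"),
                          params = list(), seed = 1L) {
  structure(list(method = match.arg(method), params = params,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

std_apply <- function(X, st) sweep(sweep(X, 2L, st$mean), 2L, st$sd, "/")

#' Fit one comparison classifier on feature vectors
#'
#' Features are standardized with training statistics for the linear methods
#' (logistic regression, elastic net). Deterministic given `spec$seed`.
#'
#' @param spec a `baseline_spec`.
#' @param features numeric matrix (rows: windows, 35 columns) or data.frame
#'   of feature columns.
#' @param labels character vector of `"HC"`/`"PD"`.
#' @return a `baseline_model` usable with [predict_baseline()].
#' @export
fit_baseline <- function(spec, features, labels) {
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L)
    stop("training error: training set contains a single class")
  y <- as.integer(labels == "PD")
  set.seed(spec$seed)
  fit <- NULL
  st <- NULL
  maj <- if (mean(y) >= 0.5) "PD" else "HC"
  constant <- all(apply(X, 2L, function(v) length(unique(v)) == 1L))
  if (spec$method %in% c("logistic_regression", "elastic_net")) {
    st <- std_fit(X)
    Xs <- std_apply(X, st)
  }
  if (constant && spec$method %in% c("elastic_net", "random_forest")) {
    # tree splits and penalized fits are undefined on zero-variance
    # predictors; predictions fall back to the training majority class
  } else if (spec$method == "logistic_regression") {
    df <- as.data.frame(Xs)
    df$.y <- y
    fit <- suppressWarnings(
      do.call(stats::glm, c(list(formula = .y ~ ., data = df,
                                 family = stats::binomial()), spec$params)))
  } else if (spec$method == "elastic_net") {
    foldid <- sample(rep_len(seq_len(5L), length(y)))
    fit <- do.call(glmnet::cv.glmnet,
                   c(list(x = Xs, y = y, family = "binomial", alpha = 0.5,
                          foldid = foldid, standardize = FALSE),
                     spec$params))
  } else if (spec$method == "random_forest") {
    fit <- do.call(randomForest::randomForest,
                   c(list(x = X, y = factor(labels, c("HC", "PD"))),
                     spec$params))
  } else if (spec$method == "gradient_boosted_trees") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
    params <- utils::modifyList(list(objective = "binary:logistic",
                                     nthread = 1L), spec$params)
    fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 100,
                              verbose = 0)
  }
  structure(list(spec = spec, fit = fit, std = st, majority = maj,
                 feature_names = colnames(X)),
            class = "baseline_model")
}

#' Predict with a fitted comparison classifier
#'
#' @param model a `baseline_model`.
#' @param features feature matrix or data.frame matching the training columns.
#' @return data.frame with `p_pd` and `predicted` (`"PD"` iff `p_pd >= 0.5`).
#' @export
predict_baseline <- function(model, features) {
  X <- as.matrix(features)
  method <- model$spec$method
  if (is.null(model$fit)) {                      # degenerate constant features
    p <- rep(if (model$majority == "PD") 1 else 0, nrow(X))
  } else if (method == "logistic_regression") {
    p <- suppressWarnings(
      stats::predict(model$fit, newdata = as.data.frame(std_apply(X, model$std)),
                     type = "response"))
  } else if (method == "elastic_net") {
    p <- as.numeric(stats::predict(model$fit, newx = std_apply(X, model$std),
                                   s = "lambda.min", type = "response"))
  } else if (method == "random_forest") {
    p <- stats::predict(model$fit, newdata = X, type = "prob")[, "PD"]
  } else {
    p <- stats::predict(model$fit, newdata = xgboost::xgb.DMatrix(X, nthread = 1L))
  }
  p <- as.numeric(p)
  data.frame(p_pd = p, predicted = ifelse(p >= 0.5, "PD", "HC"),
             stringsAsFactors = FALSE)
}

#' Evaluate all comparison classifiers under shared LOGO folds
#'
#' Runs each method over the identical fold plan used for the CNN and reports
#' per-class mean single-event accuracies (mean over validation subjects of
#' each subject's event accuracy).
#'
#' @param specs list of `baseline_spec` objects.
#' @param features feature data.frame from [feature_matrix()] (metadata
#'   columns `subject_id, day_index, start_time` plus the 35 features).
#' @param labels named character vector mapping subject id to `"HC"`/`"PD"`.
#' @param folds a `fold_plan` from [make_logo_folds()].
#' @return data.frame `method, hc_mean_accuracy, pd_mean_accuracy`.
#' @export
evaluate_baselines <- function(specs, features, labels, folds) {
  meta_cols <- c("subject_id", "day_index", "start_time")
  feat_cols <- setdiff(names(features), meta_cols)
  keep <- features$day_index < folds$train_day_limit
  subj_acc <- stats::setNames(rep(NA_real_, length(folds$folds)),
                              vapply(folds$folds, `[[`, "", "validation"))
  out <- NULL
  for (spec in specs) {
    acc <- subj_acc
    for (fold in folds$folds) {
      tr <- keep & features$subject_id %in% fold$train
      va <- keep & features$subject_id == fold$validation
      if (!any(va)) next
      model <- fit_baseline(spec, features[tr, feat_cols],
                            labels[features$subject_id[tr]])
      pred <- predict_baseline(model, features[va, feat_cols])
      acc[fold$validation] <-
        mean(pred$predicted == labels[fold$validation])
    }
    cls <- labels[names(acc)]
    out <- rbind(out, data.frame(
      method = spec$method,
      hc_mean_accuracy = mean(acc[cls == "HC"], na.rm = TRUE),
      pd_mean_accuracy = mean(acc[cls == "PD"], na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  out
}
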