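# MMSE score estimation: regression from the 12-dimensional features,
# thresholding of the estimated score into the <24 / >=24 screening classes,
# and leave-one-subject-out evaluation. Regression-then-threshold is the
# primary route (it classifies better than direct two-class training on this
# kind of data); direct classification is intentionally not offered.

ID_COLS <- c("subject_id", "trial_index", "mmse")

feature_cols <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, TRUE)],
          c("trial_index", "mmse"))
}

#' Regressor specification
#'
#' @param family `"bayes_nn"` (Bayesian-regularized single-hidden-layer
#'   network, tanh hidden units, Levenberg--Marquardt second-order training
#'   with evidence re-estimation of the regularization; hidden-neuron count
#'   chosen from `neurons` by inner cross-validation minimizing RMSE),
#'   `"random_forest"` (500 trees, `floor(p/3)` candidate features per
#'   split), or `"linear_svr"` (epsilon-insensitive linear support vector
#'   regression: L2 regularization, absolute-error loss beyond epsilon).
#' @param neurons Hidden-neuron grid for `bayes_nn` (non-empty).
#' @param inner_folds Inner CV folds for the neuron grid search.
#' @param maxit,tol Levenberg--Marquardt iteration cap and step tolerance.
#' @param ntree,mtry Random-forest tree count (`>= 1`) and features per
#'   split (`NULL` = `floor(p/3)`).
#' @param cost,epsilon Linear SVR regularization constant and tube width.
#' @param standardize Standardize features with training-fold statistics
#'   (applies to `bayes_nn` and `linear_svr`; random forests are
#'   scale-equivariant and are fitted on raw features).
#' @return A list of class `regressor_spec`.
#' @export
regressor_spec <- function(family = c("bayes_nn", "random_forest",
                                      "linear_svr"),
                           neurons = 1:3, inner_folds = 10L,
                           maxit = 40L, tol = 1e-6,
                           ntree = 500L, mtry = NULL,
                           cost = 1, epsilon = 0.1,
                           standardize = TRUE) {
  family <- match.arg(family)
  if (length(neurons) == 0L)
    stop_dualgait("neuron grid must be non-empty", "dualgait_config_error")
  if (ntree < 1L)
    stop_dualgait("ntree must be >= 1", "dualgait_config_error")
  structure(list(family = family, neurons = as.integer(neurons),
                 inner_folds = as.integer(inner_folds),
                 maxit = as.integer(maxit), tol = tol,
                 ntree = as.integer(ntree), mtry = mtry,
                 cost = cost, epsilon = epsilon,
                 standardize = isTRUE(standardize) &&
                   family != "random_forest"),
            class = "regressor_spec")
}

# random initial weights for a network with d inputs and h hidden units;
# consumes the R RNG stream so fits are reproducible under set.seed()
brnn_init <- function(d, h) {
  c(rnorm(h * d, 0, 0.7 / sqrt(d)), rnorm(h, 0, 0.1),
    rnorm(h, 0, 0.5 / sqrt(h)), 0)
}

brnn_train <- function(x, y, h, maxit, tol) {
  fit <- brnn_fit_cpp(x, y, brnn_init(ncol(x), h), h, maxit, tol)
  fit$hidden <- h
  fit
}

brnn_fwd <- function(fit, x) {
  as.numeric(brnn_predict_cpp(x, fit$W1, fit$b1, fit$v, fit$b2))
}

# inner k-fold grid search over the hidden-neuron counts, minimizing RMSE;
# ties go to the smaller network
select_neurons <- function(x, y, spec) {
  n <- nrow(x)
  k <- min(spec$inner_folds, n)
  fold <- sample(rep_len(seq_len(k), n))
  rmse <- vapply(spec$neurons, function(h) {
    se <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- brnn_train(x[tr, , drop = FALSE], y[tr], h,
                        maxit = min(spec$maxit, 25L), tol = spec$tol)
      se <- se + sum((y[!tr] - brnn_fwd(fit, x[!tr, , drop = FALSE]))^2)
    }
    sqrt(se / n)
  }, 0)
  spec$neurons[which.min(rmse)]
}

#' Fit a score regressor
#'
#' Fits the configured regression family to a feature matrix and MMSE
#' targets. For `bayes_nn` the features are standardized and the targets
#' scaled to zero mean / unit variance internally, the hidden-neuron count
#' is chosen by the inner grid search, and the final network is trained on
#' all rows. Reproducible under `set.seed()`.
#'
#' @param features Feature tibble (or plain data frame) containing only the
#'   trial identifier columns plus numeric feature columns; alternatively a
#'   numeric matrix.
#' @param targets Numeric MMSE targets (at least two distinct values).
#' @param spec A [regressor_spec()].
#' @return A fitted model of class `dualgait_model`.
#' @export
fit_regressor <- function(features, targets, spec = regressor_spec()) {
  x <- if (is.matrix(features)) features else {
    cols <- setdiff(feature_cols(as_tibble(features)), ID_COLS)
    as.matrix(as_tibble(features)[cols])
  }
  y <- as.numeric(targets)
  if (nrow(x) != length(y))
    stop_dualgait("features and targets disagree in length",
                  "dualgait_validation_error")
  if (!all(is.finite(x)))
    stop_dualgait("non-finite feature values", "dualgait_validation_error")
  if (length(unique(y)) < 2L)
    stop_dualgait("constant targets: regression is degenerate",
                  "dualgait_degenerate_fit")
  center <- scale_ <- NULL
  xs <- x
  if (spec$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  fit <- switch(
    spec$family,
    bayes_nn = {
      ym <- mean(y); ys <- stats::sd(y)
      yn <- (y - ym) / ys
      h <- if (length(spec$neurons) > 1L) select_neurons(xs, yn, spec) else
        spec$neurons
      net <- brnn_train(xs, yn, h, spec$maxit, spec$tol)
      list(net = net, y_mean = ym, y_sd = ys, hidden = h)
    },
    random_forest = {
      mtry <- spec$mtry %||% max(1L, floor(ncol(x) / 3))
      randomForest::randomForest(x = x, y = y, ntree = spec$ntree,
                                 mtry = mtry)
    },
    linear_svr = e1071::svm(x = xs, y = y, type = "eps-regression",
                            kernel = "linear", cost = spec$cost,
                            epsilon = spec$epsilon, scale = FALSE)
  )
  structure(list(family = spec$family, fit = fit, spec = spec,
                 feature_names = colnames(x), center = center,
                 scale = scale_),
            class = "dualgait_model")
}

#' Predict MMSE scores
#'
#' Applies a fitted regressor to new feature rows. Columns are matched by
#' name against the training layout (a mismatch is a schema error) and
#' predictions are clipped to the MMSE range `[0, 30]`.
#'
#' @param model A `dualgait_model` from [fit_regressor()].
#' @param features Feature tibble or numeric matrix.
#' @return Numeric vector of predicted scores in `[0, 30]`.
#' @export
predict_scores <- function(model, features) {
  x <- if (is.matrix(features)) features else {
    tb <- as_tibble(features)
    missing <- setdiff(model$feature_names, names(tb))
    if (length(missing) > 0L)
      stop_dualgait(paste("feature columns missing:",
                          paste(missing, collapse = ", ")),
                    "dualgait_schema_error")
    as.matrix(tb[model$feature_names])
  }
  if (!identical(colnames(x), model$feature_names)) {
    if (!setequal(colnames(x), model$feature_names))
      stop_dualgait("feature columns do not match the training layout",
                    "dualgait_schema_error")
    x <- x[, model$feature_names, drop = FALSE]
  }
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  raw <- switch(
    model$family,
    bayes_nn = brnn_fwd(model$fit$net, x) * model$fit$y_sd + model$fit$y_mean,
    random_forest = as.numeric(predict(model$fit, x)),
    linear_svr = as.numeric(predict(model$fit, x))
  )
  pmin(30, pmax(0, raw))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: all trials of the held-out subject are predicted
#' by a model trained on every other subject's trials, so a subject's own
#' data never informs its prediction. Each fold runs on a random substream
#' derived from `seed` and the subject identifier, making the result
#' invariant to trial and subject ordering. Estimated scores below
#' `threshold` are labelled `"low"`, the screening-positive class.
#'
#' @param features Feature tibble with `subject_id`, `trial_index`, `mmse`
#'   and numeric feature columns (any subset of the canonical 12).
#' @param spec A [regressor_spec()].
#' @param seed Master seed for the per-fold substreams.
#' @param threshold Classification threshold on the MMSE score (default 24;
#'   scores `< 24` flag possible cognitive impairment).
#' @return An object of class `dualgait_estimation` with a `predictions`
#'   tibble (`subject_id`, `trial_index`, `mmse`, `predicted_mmse`,
#'   `true_class`, `predicted_class`).
#' @export
loso_cv <- function(features, spec = regressor_spec(), seed = 1L,
                    threshold = 24) {
  features <- as_tibble(features)
  need <- c("subject_id", "trial_index", "mmse")
  if (!all(need %in% names(features)))
    stop_dualgait("features must carry subject_id, trial_index and mmse",
                  "dualgait_validation_error")
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 2L)
    stop_dualgait("leave-one-subject-out needs at least 2 subjects",
                  "dualgait_validation_error")
  cols <- setdiff(feature_cols(features), ID_COLS)
  preds <- map_dfr(subjects, function(sid) {
    test <- features[features$subject_id == sid, ]
    train <- features[features$subject_id != sid, ]
    set.seed(derive_seed(seed, sid))
    model <- fit_regressor(as.matrix(train[cols]), train$mmse, spec)
    tibble(subject_id = test$subject_id,
           trial_index = test$trial_index,
           mmse = test$mmse,
           predicted_mmse = predict_scores(model, as.matrix(test[cols])))
  })
  preds <- preds %>%
    mutate(true_class = ifelse(.data$mmse < threshold, "low", "high"),
           predicted_class = ifelse(.data$predicted_mmse < threshold,
                                    "low", "high"))
  structure(list(predictions = preds, spec = spec, threshold = threshold,
                 seed = seed, features = cols),
            class = "dualgait_estimation")
}

#' Recall, specificity and their sum
#'
#' The positive (screened) class is `"low"` (MMSE below the threshold):
#' recall = TP / (TP + FN), specificity = TN / (TN + FP). The evaluation
#' unit is the trial by default; `aggregate = "subject"` first reduces each
#' subject to a majority-vote label. A truth class that is absent leaves
#' the corresponding metric `NA` with a warning.
#'
#' @param result A `dualgait_estimation` from [loso_cv()], or its
#'   `predictions` tibble.
#' @param aggregate `"trial"` (default) or `"subject"`.
#' @return One-row tibble: `recall`, `specificity`, `sum`.
#' @export
evaluate <- function(result, aggregate = c("trial", "subject")) {
  aggregate <- match.arg(aggregate)
  preds <- if (inherits(result, "dualgait_estimation"))
    result$predictions else as_tibble(result)
  if (nrow(preds) == 0L)
    stop_dualgait("empty estimation result", "dualgait_validation_error")
  if (aggregate == "subject") {
    preds <- preds %>%
      group_by(.data$subject_id) %>%
      summarise(
        true_class = .data$true_class[1],
        predicted_class = ifelse(mean(.data$predicted_class == "low") >= 0.5,
                                 "low", "high"),
        .groups = "drop")
  }
  truth_low <- preds$true_class == "low"
  pred_low <- preds$predicted_class == "low"
  recall <- if (!any(truth_low)) {
    warn("no low-MMSE trials in truth: recall undefined")
    NA_real_
  } else sum(truth_low & pred_low) / sum(truth_low)
  specificity <- if (!any(!truth_low)) {
    warn("no high-MMSE trials in truth: specificity undefined")
    NA_real_
  } else sum(!truth_low & !pred_low) / sum(!truth_low)
  tibble(recall = recall, specificity = specificity,
         sum = recall + specificity)
}

#' @export
print.dualgait_estimation <- function(x, ...) {
  m <- evaluate(x)
  cat(sprintf(
    "Leave-one-subject-out MMSE estimation (%s)\n  %d trials, %d subjects; threshold < %g\n  recall %.3f, specificity %.3f, sum %.3f\n",
    x$spec$family, nrow(x$predictions),
    length(unique(x$predictions$subject_id)), x$threshold,
    m$recall, m$specificity, m$sum))
  invisible(x)
}

#' Tidy per-trial predictions
#'
#' @param x A `dualgait_estimation`.
#' @param ... Unused.
#' @return The per-trial prediction tibble.
#' @export
tidy.dualgait_estimation <- function(x, ...) x$predictions

#' One-row model summary
#'
#' @param x A `dualgait_estimation`.
#' @param ... Unused.
#' @return Tibble with family, sizes and the classification metrics.
#' @export
glance.dualgait_estimation <- function(x, ...) {
  m <- evaluate(x)
  tibble(family = x$spec$family,
         n_trials = nrow(x$predictions),
         n_subjects = length(unique(x$predictions$subject_id)),
         n_features = length(x$features),
         threshold = x$threshold,
         recall = m$recall, specificity = m$specificity, sum = m$sum)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
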