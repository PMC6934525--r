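# Regression families, score prediction, LOSO folding and the screening
# metrics.

linear_toy <- function(n = 60L, seed = 81L) {
  set.seed(seed)
  tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:6), each = n / 6),
    trial_index = rep(1:(n / 6), 6),
    x1 = runif(n, 0, 2), x2 = rnorm(n),
    mmse = 20 + 5 * x1
  )
}

test_that("linear SVR recovers a realizable linear target", {
  d <- linear_toy()
  spec <- regressor_spec("linear_svr")
  m <- fit_regressor(d[d$trial_index <= 8, ], d$mmse[d$trial_index <= 8], spec)
  held <- d[d$trial_index > 8, ]
  p <- predict_scores(m, held)
  expect_lt(max(abs(p - held$mmse)), spec$epsilon + 0.2)
})

test_that("predictions are clipped to the MMSE range", {
  d <- linear_toy()
  m <- fit_regressor(d, d$mmse, regressor_spec("linear_svr"))
  far <- tibble::tibble(x1 = 40, x2 = 0)  # raw prediction far above 30
  expect_identical(predict_scores(m, far), 30)
  far_low <- tibble::tibble(x1 = -40, x2 = 0)
  expect_identical(predict_scores(m, far_low), 0)
})

test_that("degenerate and malformed fits are refused", {
  d <- linear_toy()
  expect_error(fit_regressor(d, rep(24, nrow(d)), regressor_spec("linear_svr")),
               class = "dualgait_degenerate_fit")
  d2 <- d; d2$x1[1] <- Inf
  expect_error(fit_regressor(d2, d2$mmse, regressor_spec("linear_svr")),
               class = "dualgait_validation_error")
  m <- fit_regressor(d, d$mmse, regressor_spec("linear_svr"))
  expect_error(predict_scores(m, tibble::tibble(x1 = 1)),
               class = "dualgait_schema_error")
})

test_that("random forests do not hallucinate signal from noise", {
  set.seed(82)
  n <- 200L
  d <- tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:10), each = 20),
    trial_index = rep(1:20, 10))
  for (j in 1:6) d[[paste0("x", j)]] <- rnorm(n)
  d$mmse <- rep(sample(15:30, 10, replace = TRUE), each = 20)
  res <- loso_cv(d, regressor_spec("random_forest"), seed = 82L)
  p <- res$predictions
  r2 <- 1 - sum((p$mmse - p$predicted_mmse)^2) / sum((p$mmse - mean(p$mmse))^2)
  expect_lte(r2, 0.1)
})

test_that("forest in-sample error does not exceed held-out error", {
  set.seed(83)
  n <- 150L
  d <- tibble::tibble(x1 = runif(n, 0, 3), x2 = rnorm(n))
  y <- 18 + 3 * d$x1 + rnorm(n, sd = 1.5)
  tr <- 1:100; te <- 101:150
  m <- fit_regressor(as.matrix(d[tr, ]), y[tr], regressor_spec("random_forest"))
  rmse <- function(idx) sqrt(mean((predict_scores(m, as.matrix(d[idx, ])) - y[idx])^2))
  expect_lte(rmse(tr), rmse(te))
})

test_that("the inner grid search picks extra neurons when the target is nonlinear", {
  picks <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 150L
    x <- cbind(x1 = runif(n, -4, 4), x2 = rnorm(n), x3 = rnorm(n))
    y <- 15 + 7 * sin(x[, "x1"]) + rnorm(n, sd = 0.3)
    m <- fit_regressor(x, y, regressor_spec("bayes_nn"))
    m$fit$hidden
  }, 0L)
  expect_gte(mean(picks > 1L), 0.8)
})

test_that("LOSO folds partition the trials and never leak a subject", {
  d <- linear_toy(n = 84L, seed = 84L)
  d$subject_id <- rep(sprintf("P%02d", 1:7), each = 12)
  res <- loso_cv(d, regressor_spec("linear_svr"), seed = 84L)
  p <- res$predictions
  expect_equal(nrow(p), nrow(d))
  expect_equal(
    sort(paste(p$subject_id, p$trial_index)),
    sort(paste(d$subject_id, d$trial_index)))
  expect_error(loso_cv(d[d$subject_id == "P01", ], regressor_spec("linear_svr")),
               class = "dualgait_validation_error")
})

test_that("trial order does not change the cross-validated result", {
  d <- linear_toy()
  set.seed(85)
  shuffled <- d[sample(nrow(d)), ]
  r1 <- loso_cv(d, regressor_spec("bayes_nn", neurons = 1L), seed = 85L)
  r2 <- loso_cv(shuffled, regressor_spec("bayes_nn", neurons = 1L), seed = 85L)
  p1 <- dplyr::arrange(r1$predictions, subject_id, trial_index)
  p2 <- dplyr::arrange(r2$predictions, subject_id, trial_index)
  expect_equal(p1, p2)
})

test_that("an oracle feature yields perfect screening for every family", {
  set.seed(86)
  mm <- c(15, 18, 20, 21, 27, 28, 29, 30)
  d <- tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:8), each = 4),
    trial_index = rep(1:4, 8),
    mmse = rep(mm, each = 4))
  d$oracle <- d$mmse
  d$noise <- rnorm(nrow(d))
  for (fam in c("linear_svr", "random_forest", "bayes_nn")) {
    res <- loso_cv(d, regressor_spec(fam), seed = 86L)
    m <- evaluate(res)
    expect_equal(m$recall, 1, info = fam)
    expect_equal(m$specificity, 1, info = fam)
  }
})

test_that("metrics follow the confusion-matrix arithmetic", {
  p <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:9),
    true_class = c(rep("low", 4), rep("high", 5)),
    predicted_class = c("low", "low", "low", "high",
                        "high", "high", "high", "high", "low"))
  m <- evaluate(p)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$sum, 1.55)

  # degenerate labellings
  all_high <- dplyr::mutate(p, predicted_class = "high")
  expect_equal(evaluate(all_high)$recall, 0)
  one_class <- dplyr::filter(p, true_class == "low")
  expect_warning(m2 <- evaluate(one_class), "specificity undefined")
  expect_true(is.na(m2$specificity))
  expect_equal(m2$recall, 0.75)
})

test_that("tidy and glance expose the estimation result", {
  d <- linear_toy()
  res <- loso_cv(d, regressor_spec("linear_svr"), seed = 87L)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("predicted_mmse", "true_class") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(gl$n_trials, nrow(d))
  expect_equal(gl$family, "linear_svr")
  expect_equal(gl$sum, gl$recall + gl$specificity)
})
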