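# Feature importance, ablation, feature-set comparison, trial grouping and
# the experience contrasts.

test_that("importance is a univariate R-squared with its symmetries", {
  ft <- default_features()
  ft$noise_probe <- rnorm(nrow(ft))
  ft$dup_probe <- ft$knee_amplitude_mean_dual
  ft$const_probe <- 1
  spec <- regressor_spec("bayes_nn")
  expect_warning(imp <- feature_importance(ft, spec, seed = 91L),
                 "constant column")
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  get <- function(nm) unname(imp$importance[imp$feature == nm])
  # a duplicated column scores exactly like its original
  expect_equal(get("dup_probe"), get("knee_amplitude_mean_dual"))
  # pure noise explains essentially nothing of the fitted behaviour
  expect_lt(get("noise_probe"), 0.02)
  expect_identical(get("const_probe"), 0)
  # the planted links surface as important features
  expect_gt(get("knee_amplitude_mean_dual"), 0.3)
  expect_gt(get("step_interval_sd_dual"), 0.2)
})

test_that("an oracle feature has importance near one", {
  set.seed(92)
  d <- tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:8), each = 3),
    trial_index = rep(1:3, 8),
    mmse = rep(c(15, 17, 20, 22, 26, 27, 28, 30), each = 3))
  d$oracle <- d$mmse
  d$junk <- rnorm(nrow(d))
  imp <- feature_importance(d, regressor_spec("linear_svr"), seed = 92L)
  expect_gt(imp$importance[imp$feature == "oracle"], 0.95)
})

test_that("ablation removes one base feature from both contexts", {
  ft <- knee_only_features()
  spec <- regressor_spec("bayes_nn")
  full <- evaluate(loso_cv(ft, spec, seed = 93L))
  row <- ablate_feature(ft, "answer_rate", spec, seed = 93L,
                        full_metrics = full)
  expect_equal(row$n_features, 10L)
  expect_error(ablate_feature(ft, "knee_height", spec),
               class = "dualgait_validation_error")
  rep_ <- ablation_report(ft, spec, seed = 93L,
                          types = c("knee_amplitude_mean", "answer_rate"))
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$dropped, c("none", "knee_amplitude_mean", "answer_rate"))
  expect_equal(rep_$delta_sum[1], 0)
})

test_that("ablating the only informative feature collapses screening to chance", {
  ft <- knee_only_features()
  spec <- regressor_spec("bayes_nn")
  full <- evaluate(loso_cv(ft, spec, seed = 94L))
  expect_gt(full$sum, 1.4)  # the planted knee signal is recoverable
  drop_knee <- ablate_feature(ft, "knee_amplitude_mean", spec, seed = 94L,
                              full_metrics = full)
  expect_gte(drop_knee$sum, 0.8)
  expect_lte(drop_knee$sum, 1.2)
  # removing an uninformative feature barely moves the metric
  deltas <- vapply(95:97, function(s) {
    abs(ablate_feature(ft, "answer_rate", spec, seed = s)$delta_sum)
  }, 0)
  expect_lt(median(deltas), 0.1)
})

test_that("feature-set comparison ranks the informative context highest", {
  fs_struct <- compare_feature_sets(knee_only_features(),
                                    regressor_spec("bayes_nn"), seed = 98L)
  expect_equal(fs_struct$set, c("single_physical", "single_cognitive",
                                "single_all", "dual", "combined"))
  expect_equal(fs_struct$n_features, c(4L, 2L, 6L, 6L, 12L))

  ft <- suppressMessages(simulate_feature_table(dual_only_config(),
                                                seed = 99L))
  fs <- compare_feature_sets(ft, regressor_spec("bayes_nn"), seed = 99L)
  sum_of <- function(nm) fs$sum[fs$set == nm]
  expect_gt(sum_of("dual"), sum_of("single_all"))
  expect_gte(sum_of("combined"), max(sum_of("dual"), sum_of("single_all")) - 0.1)
})

test_that("trial grouping filters by experience and partitions trials 1-100", {
  set.seed(101)
  base <- synthetic_feature_table(4L, 1:104,
                                  mmse = c(18L, 20L, 28L, 29L))
  extra <- synthetic_feature_table(1L, 1:99, mmse = 27L)
  extra$subject_id <- "T99"
  ft <- dplyr::bind_rows(base, extra)
  ft$knee_amplitude_mean_dual <- ft$knee_amplitude_mean_dual + 0.2 * ft$mmse

  tg <- trial_group_analysis(ft, regressor_spec("bayes_nn", neurons = 1L),
                             seed = 101L)
  # the 99-trial subject fails the strict >100 filter
  expect_setequal(tg$subjects, unique(base$subject_id))
  expect_equal(tg$metrics$group, c("1-20", "21-40", "41-60", "61-80", "81-100"))
  # each subject with >=100 trials contributes 20 trials per group
  expect_equal(tg$metrics$n_trials, rep(80L, 5))
  expect_equal(nrow(tg$gait_means), 5L * 8L)
  # the inclusive switch admits a 100-trial subject
  ft100 <- dplyr::bind_rows(base,
                            dplyr::mutate(extra[extra$trial_index <= 99, ],
                                          subject_id = "U01"))
  tg2 <- trial_group_analysis(ft100,
                              regressor_spec("bayes_nn", neurons = 1L),
                              seed = 101L, min_trials = 99L,
                              inclusive = TRUE)
  expect_true("U01" %in% tg2$subjects)
})

test_that("knee importance grows with experience under the learning model", {
  cfg <- cohort_config(
    n_subjects = 6L, trials_per_subject = 104L,
    mmse_mean = 24, mmse_sd = 6, learn_gain = 0.006)
  ft <- suppressMessages(simulate_feature_table(cfg, seed = 102L))
  tg <- trial_group_analysis(ft, regressor_spec("bayes_nn"), seed = 102L)
  knee <- tg$importance %>%
    dplyr::filter(feature == "knee_amplitude_mean_dual")
  expect_equal(nrow(knee), 5L)
  early <- knee$importance[knee$group == "1-20"]
  late <- knee$importance[knee$group %in% c("41-60", "61-80", "81-100")]
  expect_gt(max(late), early)
})

test_that("Bonferroni adjustment and flags follow the correction arithmetic", {
  set.seed(103)
  ft <- synthetic_feature_table(12L, c(1L, 41:44))
  ct <- experience_contrast(ft)
  expect_equal(nrow(ct), 8L)
  m <- sum(!is.na(ct$p_raw))
  expect_equal(ct$p_adj, pmin(1, m * ct$p_raw))
  expect_equal(ct$sig_05, ct$p_adj < 0.05)
  expect_equal(ct$sig_001, ct$p_adj < 0.001)
  # raw p = 0.01 with m = 8 is not significant after correction
  expect_false(0.01 * 8 < 0.05)
})

test_that("the corrected contrasts keep their family-wise error under the null", {
  set.seed(104)
  hits <- vapply(1:100, function(i) {
    ft <- synthetic_feature_table(12L, c(1L, 41:44))
    any(experience_contrast(ft)$sig_05, na.rm = TRUE)
  }, TRUE)
  expect_lte(mean(hits), 0.10)
})

test_that("a stratum with too few subjects is flagged undefined", {
  set.seed(105)
  ft <- synthetic_feature_table(6L, c(1L, 41:42),
                                mmse = c(18L, rep(28L, 5)))
  ct <- experience_contrast(ft)
  low <- ct[ct$stratum == "low", ]
  expect_true(all(is.na(low$t)))
  expect_true(all(!is.na(ct$t[ct$stratum == "high"])))
})

test_that("the learning effect reproduces the experience significance pattern", {
  ft <- learning_features()
  ct <- experience_contrast(ft)
  hi_knee <- ct[ct$stratum == "high" &
                  grepl("knee_amplitude", ct$measure), ]
  lo_knee <- ct[ct$stratum == "low" &
                  grepl("knee_amplitude", ct$measure), ]
  # experienced high-MMSE subjects raise their knees significantly more
  expect_true(all(hi_knee$sig_05))
  expect_true(all(hi_knee$experienced_mean > hi_knee$first_mean))
  # no learning is planted below the gate
  expect_false(any(lo_knee$sig_05))
})
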