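# Shared fixtures, built once per test run and memoised.

.dg_memo <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.dg_memo[[key]])) .dg_memo[[key]] <- build()
  .dg_memo[[key]]
}

# the default study cohort: 60 subjects x 20 trials, default effect sizes
default_features <- function() {
  memo("default_features", function() {
    suppressMessages(simulate_feature_table(cohort_config(), seed = 20171L))
  })
}

# fully deterministic configuration: no noise anywhere, no dual-task cost,
# cadence and raise centers aligned to the 30 Hz frame grid so extracted
# dispersion features are exactly zero
noiseless_config <- function(...) {
  defaults <- list(
    step_interval_mean = 0.6, raise_halfwidth_s = 1 / 3,
    step_interval_subject_sd = 0, step_jitter = 0,
    step_jitter_subject_sdlog = 0, amp_subject_sd = 0, amp_cycle_sd = 0,
    acc_ref = 1, acc_slope = 0, acc_subject_sd = 0,
    answer_time_subject_sd = 0, answer_time_cv = 0,
    cost_jitter = 0, cost_accuracy = 0, cost_answer_time = 0,
    cost_amplitude = 0, learn_gain = 0, position_noise_m = 0
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# cohort whose only MMSE-linked signal is the knee-raise amplitude mean
knee_only_config <- function(...) {
  cohort_config(
    n_subjects = 24L, trials_per_subject = 8L,
    mmse_mean = 24, mmse_sd = 6,
    amp_slope = 0.025, amp_cycle_sd = 0.02, amp_min = 0.05,
    cost_jitter = 0, cost_accuracy = 0, cost_answer_time = 0,
    acc_slope = 0, answer_time_slope = 0, learn_gain = 0,
    ...
  )
}

knee_only_features <- function() {
  memo("knee_only_features", function() {
    suppressMessages(simulate_feature_table(knee_only_config(), seed = 4242L))
  })
}

# cohort whose MMSE signal lives only in the dual-task features
dual_only_config <- function(...) {
  cohort_config(
    n_subjects = 16L, trials_per_subject = 6L,
    mmse_mean = 24, mmse_sd = 6,
    amp_slope = 0, acc_slope = 0, answer_time_slope = 0, learn_gain = 0,
    cost_jitter = 0.12, cost_amplitude = 0.01,
    cost_accuracy = 0.006, cost_answer_time = 0.012,
    ...
  )
}

# learning cohort observed at the first trial and at experienced trials
learning_features <- function() {
  memo("learning_features", function() {
    cfg <- cohort_config(
      n_subjects = 20L, trials_per_subject = 5L,
      mmse_mean = 24, mmse_sd = 6,
      learn_gain = 0.006, amp_subject_sd = 0.05
    )
    suppressMessages(
      simulate_feature_table(cfg, seed = 777L, trial_indices = c(1L, 41:44)))
  })
}

# hand-built feature table (no simulation): n_subjects, with given trial
# indices; all feature columns standard normal noise unless overridden
synthetic_feature_table <- function(n_subjects, trial_indices,
                                    mmse = NULL) {
  subjects <- sprintf("T%02d", seq_len(n_subjects))
  if (is.null(mmse)) mmse <- sample(c(18L, 28L), n_subjects, replace = TRUE)
  rows <- expand.grid(subject_id = subjects, trial_index = trial_indices,
                      stringsAsFactors = FALSE)
  out <- tibble::as_tibble(rows)
  out$mmse <- mmse[match(out$subject_id, subjects)]
  for (nm in feature_names()) out[[nm]] <- rnorm(nrow(out))
  out[order(out$subject_id, out$trial_index), ]
}
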