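# Secondary cohort analyses: per-feature importance, leave-feature-out
# ablation, single/dual/combined feature-set comparison, trial-experience
# grouping, and first-trial vs experienced contrasts with Bonferroni
# correction.

# univariate coefficient of determination between a feature and the
# cross-validated predictions; a constant feature has importance 0
univariate_r2 <- function(feature, predictions) {
  if (stats::sd(feature) < 1e-12 || stats::sd(predictions) < 1e-12) {
    warn("constant column: importance set to 0")
    return(0)
  }
  cor(feature, predictions)^2
}

#' Per-feature importance scores
#'
#' Importance of a feature is the coefficient of determination (univariate
#' R-squared) between that feature and the model's cross-validated score
#' predictions — how much of the fitted behaviour each single feature can
#' explain on its own. Scores lie in `[0, 1]`; a constant feature scores 0
#' with a warning.
#'
#' @param features Feature tibble (see [loso_cv()]).
#' @param spec A [regressor_spec()].
#' @param seed Seed for the cross-validation substreams.
#' @param result Optional precomputed `dualgait_estimation` on the same
#'   table (skips refitting).
#' @return Tibble of class `dualgait_importance` with columns `feature`,
#'   `importance`, ordered as the feature columns.
#' @export
feature_importance <- function(features, spec = regressor_spec(), seed = 1L,
                               result = NULL) {
  features <- as_tibble(features)
  if (is.null(result)) result <- loso_cv(features, spec, seed)
  key <- features %>% select(all_of(c("subject_id", "trial_index")))
  preds <- result$predictions
  ord <- match(paste(key$subject_id, key$trial_index),
               paste(preds$subject_id, preds$trial_index))
  p <- preds$predicted_mmse[ord]
  cols <- result$features
  out <- tibble(
    feature = cols,
    importance = vapply(cols, function(cn) univariate_r2(features[[cn]], p), 0)
  )
  class(out) <- c("dualgait_importance", class(out))
  out
}

#' Leave-feature-out ablation
#'
#' Removes one base feature type from *both* task contexts (12 -> 10
#' columns), reruns the leave-one-subject-out pipeline on the reduced table,
#' and reports the metrics next to the full-model metrics.
#'
#' @param features Full 12-feature table.
#' @param feature_type One of [feature_base_names()].
#' @param spec,seed As in [loso_cv()].
#' @param full_metrics Optional precomputed full-model [evaluate()] row.
#' @return One-row tibble: `dropped`, `n_features`, `recall`, `specificity`,
#'   `sum`, `delta_sum`.
#' @export
ablate_feature <- function(features, feature_type, spec = regressor_spec(),
                           seed = 1L, full_metrics = NULL) {
  if (!feature_type %in% feature_base_names())
    stop_dualgait(sprintf("unknown feature type '%s'", feature_type),
                  "dualgait_validation_error")
  if (is.null(full_metrics))
    full_metrics <- evaluate(loso_cv(features, spec, seed))
  drop <- paste(feature_type, c("single", "dual"), sep = "_")
  reduced <- features %>% select(-all_of(drop))
  m <- evaluate(loso_cv(reduced, spec, seed))
  tibble(dropped = feature_type,
         n_features = length(setdiff(feature_names(), drop)),
         recall = m$recall, specificity = m$specificity, sum = m$sum,
         delta_sum = m$sum - full_metrics$sum)
}

#' Full ablation report
#'
#' Runs [ablate_feature()] for every base feature type; the first row holds
#' the full 12-feature model.
#'
#' @inheritParams ablate_feature
#' @param types Base feature types to ablate.
#' @return Tibble with one row per model of class `dualgait_ablation`.
#' @export
ablation_report <- function(features, spec = regressor_spec(), seed = 1L,
                            types = feature_base_names()) {
  full <- evaluate(loso_cv(features, spec, seed))
  rows <- map_dfr(types, function(ft)
    ablate_feature(features, ft, spec, seed, full_metrics = full))
  out <- bind_rows(
    tibble(dropped = "none", n_features = 12L, recall = full$recall,
           specificity = full$specificity, sum = full$sum, delta_sum = 0),
    rows)
  class(out) <- c("dualgait_ablation", class(out))
  out
}

feature_sets <- function() {
  list(
    single_physical = paste(c("step_interval_mean", "step_interval_sd",
                              "knee_amplitude_mean", "knee_amplitude_sd"),
                            "single", sep = "_"),
    single_cognitive = paste(c("answer_rate", "answer_time_mean"),
                             "single", sep = "_"),
    single_all = feature_names()[grepl("_single$", feature_names())],
    dual = feature_names()[grepl("_dual$", feature_names())],
    combined = feature_names()
  )
}

#' Compare single-task, dual-task and combined feature sets
#'
#' Reruns the leave-one-subject-out pipeline on five column subsets —
#' single physical (4 features), single cognitive (2), all single (6), dual
#' (6) and combined (12) — to separate what each task context contributes
#' to the screening performance.
#'
#' @inheritParams ablate_feature
#' @return Tibble of class `dualgait_feature_sets` with one row per set.
#' @export
compare_feature_sets <- function(features, spec = regressor_spec(),
                                 seed = 1L) {
  sets <- feature_sets()
  out <- imap(sets, function(cols, nm) {
    sub <- features %>% select(all_of(c(ID_COLS, cols)))
    m <- evaluate(loso_cv(sub, spec, seed))
    tibble(set = nm, n_features = length(cols), recall = m$recall,
           specificity = m$specificity, sum = m$sum)
  }) %>% bind_rows()
  class(out) <- c("dualgait_feature_sets", class(out))
  out
}

#' Performance and importance by trial-experience group
#'
#' Restricts the table to subjects who conducted more than `min_trials`
#' trials (strictly more by default; `inclusive = TRUE` relaxes to at
#' least), splits their trials 1--100 into five groups of twenty (1--20,
#' 21--40, 41--60, 61--80, 81--100), and computes per group the
#' leave-one-subject-out metrics, the feature importances, and the mean of
#' every gait feature (both task contexts).
#'
#' @inheritParams ablate_feature
#' @param min_trials Trial-count filter (default 100).
#' @param inclusive Use `>=` instead of `>` for the filter.
#' @return List of class `dualgait_trial_groups` with tibbles `metrics`,
#'   `importance` and `gait_means`, plus `subjects` (the retained ids).
#' @export
trial_group_analysis <- function(features, spec = regressor_spec(),
                                 seed = 1L, min_trials = 100L,
                                 inclusive = FALSE) {
  counts <- features %>% group_by(.data$subject_id) %>%
    summarise(n = n(), .groups = "drop")
  keep <- if (inclusive) counts$subject_id[counts$n >= min_trials] else
    counts$subject_id[counts$n > min_trials]
  if (length(keep) < 2L)
    stop_dualgait("fewer than 2 subjects pass the trial-count filter",
                  "dualgait_validation_error")
  dat <- features %>%
    filter(.data$subject_id %in% keep, .data$trial_index <= 100L) %>%
    mutate(group = cut(.data$trial_index, c(0, 20, 40, 60, 80, 100),
                       labels = c("1-20", "21-40", "41-60", "61-80",
                                  "81-100")))
  groups <- levels(dat$group)
  metrics <- list(); importance <- list(); gmeans <- list()
  for (g in groups) {
    sub <- dat %>% filter(.data$group == g) %>% select(-"group")
    res <- loso_cv(sub, spec, derive_seed(seed, g))
    m <- evaluate(res)
    metrics[[g]] <- tibble(group = g, n_trials = nrow(sub),
                           recall = m$recall,
                           specificity = m$specificity, sum = m$sum)
    imp <- feature_importance(sub, spec, result = res)
    importance[[g]] <- mutate(as_tibble(imp), group = g, .before = 1)
    gmeans[[g]] <- sub %>%
      summarise(across(all_of(gait_feature_names()), mean)) %>%
      tidyr::pivot_longer(dplyr::everything(), names_to = "feature",
                          values_to = "mean") %>%
      mutate(group = g, .before = 1)
  }
  structure(list(metrics = bind_rows(metrics),
                 importance = bind_rows(importance),
                 gait_means = bind_rows(gmeans),
                 subjects = sort(keep)),
            class = "dualgait_trial_groups")
}

contrast_measures <- function() {
  as.vector(t(outer(c("step_interval_mean", "knee_amplitude_mean"),
                    c("single", "dual"), paste, sep = "_")))
}

#' First-trial vs experienced-trial contrasts
#'
#' For each MMSE stratum (below / at-or-above the threshold) and each gait
#' measure (step interval and knee amplitude, single and dual context),
#' compares the subjects' first-trial values against their experienced
#' values (the per-subject mean over trials 41 and later) with a two-tailed
#' two-sample t-test (Welch by default; `var_equal = TRUE` pools the
#' variances). Raw p-values are Bonferroni-adjusted over all contrasts in
#' the report (`p_adj = min(1, m * p)`); significance is flagged at 0.05
#' and 0.001. Only subjects contributing both a first trial and at least
#' one trial `>= 41` are used; a stratum with fewer than two such subjects
#' yields an undefined (all-`NA`) contrast.
#'
#' @param features Feature tibble covering trial 1 and trials `>= 41`.
#' @param threshold MMSE stratum boundary (default 24).
#' @param experienced_from First trial index counted as experienced
#'   (default 41).
#' @param var_equal Pooled-variance (classic Student) t-test instead of
#'   Welch.
#' @return Tibble of class `dualgait_contrast`: one row per stratum and
#'   measure with group means, `t`, `p_raw`, `p_adj`, `sig_05`, `sig_001`.
#' @export
experience_contrast <- function(features, threshold = 24,
                                experienced_from = 41L, var_equal = FALSE) {
  features <- as_tibble(features)
  measures <- contrast_measures()
  strata <- c(low = TRUE, high = FALSE)
  rows <- list()
  for (snm in names(strata)) {
    in_stratum <- if (strata[[snm]]) features$mmse < threshold else
      features$mmse >= threshold
    sub <- features[in_stratum, ]
    first <- sub %>% filter(.data$trial_index == 1L)
    exper <- sub %>% filter(.data$trial_index >= experienced_from) %>%
      group_by(.data$subject_id) %>%
      summarise(across(all_of(measures), mean), .groups = "drop")
    both <- intersect(first$subject_id, exper$subject_id)
    first <- first %>% filter(.data$subject_id %in% both)
    exper <- exper %>% filter(.data$subject_id %in% both)
    for (ms in measures) {
      if (length(both) < 2L) {
        rows[[paste(snm, ms)]] <- tibble(
          stratum = snm, measure = ms, n_subjects = length(both),
          first_mean = NA_real_, experienced_mean = NA_real_,
          t = NA_real_, p_raw = NA_real_)
        next
      }
      tt <- t.test(first[[ms]], exper[[ms]], var.equal = var_equal)
      rows[[paste(snm, ms)]] <- tibble(
        stratum = snm, measure = ms, n_subjects = length(both),
        first_mean = mean(first[[ms]]),
        experienced_mean = mean(exper[[ms]]),
        t = unname(tt$statistic), p_raw = tt$p.value)
    }
  }
  out <- bind_rows(rows)
  m <- sum(!is.na(out$p_raw))
  out <- out %>%
    mutate(p_adj = pmin(1, m * .data$p_raw),
           sig_05 = .data$p_adj < 0.05,
           sig_001 = .data$p_adj < 0.001)
  class(out) <- c("dualgait_contrast", class(out))
  out
}
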