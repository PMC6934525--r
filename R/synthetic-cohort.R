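# Synthetic cohort generator: subjects with MMSE-linked latent behaviour
# parameters, and per-trial dual-task sessions (skeleton frames, floor
# contacts, calculation responses) carrying the statistical structure the
# downstream analyses assume.

#' Cohort simulation settings
#'
#' Defaults encode the study conditions the analyses are calibrated against:
#' a 60-subject, 20-trial desk-scale cohort; MMSE drawn from a rounded normal
#' with mean 24.6 and SD 5.24 clipped to `[0, 30]` (matching the deployed
#' cohort of 90 elderly subjects); gender mix 32:68 male:female with mean
#' ages 81.5/82.6; three phases of 30 s (cognitive), 20 s (physical) and
#' 30 s (dual); skeleton frames at 30 Hz (Kinect v2 nominal).
#'
#' MMSE-linked effects (the cognitive-motor interference model):
#' * knee-raise amplitude increases with MMSE (`amp_slope` rad per point);
#' * dual-task costs are multiplicative and vanish at MMSE 30, growing
#'   linearly in `(30 - mmse)`: step-timing jitter inflates
#'   (`cost_jitter`), answer accuracy drops (`cost_accuracy`), answer time
#'   lengthens (`cost_answer_time`), knee amplitude shrinks
#'   (`cost_amplitude`) — so the dual step-interval SD *decreases* with
#'   MMSE;
#' * subjects at or above `learn_gate_mmse` notice (via the printed result
#'   sheet) that higher knee raises score better and gain
#'   `learn_gain` rad of amplitude per trial up to trial `learn_plateau`
#'   (default 40), emulating the observed experience effect and plateau.
#'
#' @param n_subjects,trials_per_subject Cohort size. `trials_per_subject`
#'   may be a single integer or a function of `n` returning per-subject
#'   counts.
#' @param mmse_mean,mmse_sd Calibration of the MMSE distribution.
#' @param p_male,age_mean_male,age_mean_female,age_sd Demographic marginals.
#' @param cognitive_s,physical_s,dual_s Phase durations (seconds).
#' @param frame_rate_hz Skeleton frame rate.
#' @param extended_angle Knee angle of the extended leg at floor contact
#'   (radians).
#' @param amp_ref Knee-raise amplitude (rad) of an MMSE-24 subject before
#'   learning.
#' @param amp_slope Amplitude change per MMSE point (rad).
#' @param amp_subject_sd,amp_cycle_sd Between-subject and per-cycle amplitude
#'   noise (rad).
#' @param amp_min Floor on the per-cycle amplitude (rad).
#' @param raise_halfwidth_s Half-width of the flexion bump of one raise (s).
#' @param step_interval_mean,step_interval_subject_sd Mean inter-step
#'   interval and its between-subject SD (s).
#' @param step_jitter,step_jitter_subject_sdlog Within-trial SD of step
#'   intervals (s) and its between-subject log-normal spread.
#' @param acc_ref,acc_slope,acc_subject_sd Single-task answer accuracy at
#'   MMSE 30, its drop per point below 30, and between-subject noise.
#' @param answer_time_ref,answer_time_slope,answer_time_subject_sd
#'   Single-task mean answer time at MMSE 30 (s), its increase per point
#'   below 30, and between-subject noise.
#' @param answer_time_cv Log-normal coefficient of variation of individual
#'   response times.
#' @param cost_jitter,cost_accuracy,cost_answer_time,cost_amplitude
#'   Dual-task cost per point of `(30 - mmse)` (fractional).
#' @param learn_gain,learn_plateau,learn_gate_mmse Learning-curve gain
#'   (rad/trial), plateau trial, and the MMSE gate for the learning effect.
#' @param position_noise_m Gaussian sensor noise added to each joint
#'   coordinate (m).
#' @param calc A [calc_config()].
#' @param seed Mandatory master seed (functions accept an override).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L, trials_per_subject = 20L,
                          mmse_mean = 24.6, mmse_sd = 5.24,
                          p_male = 32 / 90, age_mean_male = 81.5,
                          age_mean_female = 82.6, age_sd = 6,
                          cognitive_s = 30, physical_s = 20, dual_s = 30,
                          frame_rate_hz = 30,
                          extended_angle = 2.95,
                          amp_ref = 0.45, amp_slope = 0.02,
                          amp_subject_sd = 0.05, amp_cycle_sd = 0.05,
                          amp_min = 0.08, raise_halfwidth_s = 0.35,
                          step_interval_mean = 0.55,
                          step_interval_subject_sd = 0.04,
                          step_jitter = 0.03, step_jitter_subject_sdlog = 0.2,
                          acc_ref = 0.95, acc_slope = 0.015,
                          acc_subject_sd = 0.03,
                          answer_time_ref = 1.5, answer_time_slope = 0.05,
                          answer_time_subject_sd = 0.15, answer_time_cv = 0.25,
                          cost_jitter = 0.10, cost_accuracy = 0.005,
                          cost_answer_time = 0.01, cost_amplitude = 0.008,
                          learn_gain = 0.004, learn_plateau = 40L,
                          learn_gate_mmse = 24,
                          position_noise_m = 0.002,
                          calc = calc_config(), seed = 20171L) {
  cfg <- as.list(environment())
  noise <- c("mmse_sd", "amp_subject_sd", "amp_cycle_sd",
             "step_interval_subject_sd", "step_jitter_subject_sdlog",
             "acc_subject_sd", "answer_time_subject_sd", "answer_time_cv",
             "position_noise_m")
  for (nm in noise)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop_dualgait(sprintf("noise scale '%s' must be >= 0", nm),
                    "dualgait_config_error")
  slopes <- c("amp_slope", "cost_jitter", "cost_accuracy",
              "cost_answer_time", "cost_amplitude", "learn_gain")
  for (nm in slopes)
    if (!is.finite(cfg[[nm]]))
      stop_dualgait(sprintf("slope '%s' must be finite", nm),
                    "dualgait_config_error")
  if (is.null(cfg$seed)) stop_dualgait("seed is mandatory",
                                       "dualgait_config_error")
  if (cfg$n_subjects < 2) stop_dualgait("n_subjects must be >= 2",
                                        "dualgait_config_error")
  if (cfg$extended_angle <= 0 || cfg$extended_angle > pi)
    stop_dualgait("extended_angle must lie in (0, pi]", "dualgait_config_error")
  structure(cfg, class = "cohort_config")
}

rnorm0 <- function(n, sd) if (sd == 0) rep(0, n) else rnorm(n, 0, sd)

#' Sample subject profiles
#'
#' Draws MMSE from a rounded, clipped normal; genders and ages to match the
#' configured marginals; and the latent behaviour parameters as the
#' configured functions of MMSE plus subject-level noise. With all noise
#' scales zero the latent parameters are exact deterministic functions of
#' MMSE.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with one row per subject: `subject_id`, `age`, `gender`,
#'   `mmse`, and the latent columns `amp_base`, `step_interval`,
#'   `step_jitter`, `acc`, `answer_time`, `learn_on`.
#' @export
sample_subjects <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  mmse <- pmin(30, pmax(0, round(rnorm(n, config$mmse_mean, config$mmse_sd))))
  male <- runif(n) < config$p_male
  age <- ifelse(male,
                rnorm(n, config$age_mean_male, config$age_sd),
                rnorm(n, config$age_mean_female, config$age_sd))
  d30 <- 30 - mmse
  tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(age, 1),
    gender = ifelse(male, "male", "female"),
    mmse = as.integer(mmse),
    amp_base = pmin(1.2, pmax(config$amp_min + 0.02,
      config$amp_ref + config$amp_slope * (mmse - 24) +
        rnorm0(n, config$amp_subject_sd))),
    step_interval = pmin(1.0, pmax(0.3,
      config$step_interval_mean + rnorm0(n, config$step_interval_subject_sd))),
    step_jitter = config$step_jitter *
      exp(rnorm0(n, config$step_jitter_subject_sdlog)),
    acc = pmin(1, pmax(0.5,
      config$acc_ref - config$acc_slope * d30 + rnorm0(n, config$acc_subject_sd))),
    answer_time = pmax(0.5,
      config$answer_time_ref + config$answer_time_slope * d30 +
        rnorm0(n, config$answer_time_subject_sd)),
    learn_on = mmse >= config$learn_gate_mmse
  )
}

# one stepping-in-place stream: floor contacts alternate feet; each contact
# is preceded by a flexion bump of the contacting leg's knee angle
simulate_step_phase <- function(duration_s, amp_eff, interval_s, jitter_s,
                                config) {
  h <- config$raise_halfwidth_s
  contacts <- numeric(); t <- 0
  repeat {
    step <- max(0.25 * interval_s, interval_s + rnorm0(1L, jitter_s))
    t <- t + step
    if (t > duration_s - 1e-9) break
    contacts <- c(contacts, t)
  }
  feet <- rep(c("left", "right"), length.out = length(contacts))
  raise <- contacts >= 2 * h
  amps <- pmax(config$amp_min,
               amp_eff + rnorm0(sum(raise), config$amp_cycle_sd))
  raises <- tibble(foot = feet[raise], center_t = contacts[raise] - h,
                   amplitude = amps)
  tf <- seq(0, duration_s, by = 1 / config$frame_rate_hz)
  trace <- function(foot) {
    th <- rep(config$extended_angle, length(tf))
    rs <- raises[raises$foot == foot, ]
    for (i in seq_len(nrow(rs))) {
      u <- (tf - rs$center_t[i]) / h
      inb <- abs(u) < 1
      th[inb] <- th[inb] - rs$amplitude[i] * cos(pi * u[inb] / 2)^2
    }
    th
  }
  th_l <- trace("left"); th_r <- trace("right")
  frames <- leg_geometry(tf, th_l, th_r, config)
  list(
    frames = frames,
    steps = tibble(t = contacts, foot = feet),
    ground_truth = list(
      angle = list(left = tibble(t = tf, angle = th_l),
                   right = tibble(t = tf, angle = th_r)),
      raises = raises,
      amp_effective = amp_eff, interval_s = interval_s, jitter_s = jitter_s
    )
  )
}

# synthesize 3-D joint positions whose interior knee angle reproduces the
# target traces exactly (before sensor noise): hip center fixed, thigh and
# shank directions parameterized in a per-leg plane
leg_geometry <- function(tf, theta_left, theta_right, config) {
  hip <- c(0, 0.95, 2.6)
  thigh <- 0.40; shank <- 0.42
  one_leg <- function(theta, lateral) {
    a <- c(lateral, -1, 0); a <- a / sqrt(sum(a^2))  # down direction in plane
    b <- c(0, 0, 1)                                  # forward, orthogonal to a
    phi <- 0.12 + 0.5 * (config$extended_angle - theta)  # thigh swing
    chi <- phi - pi + theta                              # shank direction
    knee <- cbind(hip[1] + thigh * (cos(phi) * a[1] + sin(phi) * b[1]),
                  hip[2] + thigh * (cos(phi) * a[2] + sin(phi) * b[2]),
                  hip[3] + thigh * (cos(phi) * a[3] + sin(phi) * b[3]))
    ankle <- knee + cbind(shank * (cos(chi) * a[1] + sin(chi) * b[1]),
                          shank * (cos(chi) * a[2] + sin(chi) * b[2]),
                          shank * (cos(chi) * a[3] + sin(chi) * b[3]))
    list(knee = knee, ankle = ankle)
  }
  L <- one_leg(theta_left, -0.09)
  R <- one_leg(theta_right, +0.09)
  n <- length(tf)
  noise <- function(m) m + matrix(rnorm0(3L * n, config$position_noise_m),
                                  ncol = 3L)
  hipm <- noise(matrix(hip, nrow = n, ncol = 3L, byrow = TRUE))
  Lk <- noise(L$knee); La <- noise(L$ankle)
  Rk <- noise(R$knee); Ra <- noise(R$ankle)
  tibble(
    t = tf,
    hip_center_x = hipm[, 1], hip_center_y = hipm[, 2], hip_center_z = hipm[, 3],
    left_knee_x = Lk[, 1], left_knee_y = Lk[, 2], left_knee_z = Lk[, 3],
    right_knee_x = Rk[, 1], right_knee_y = Rk[, 2], right_knee_z = Rk[, 3],
    left_ankle_x = La[, 1], left_ankle_y = La[, 2], left_ankle_z = La[, 3],
    right_ankle_x = Ra[, 1], right_ankle_y = Ra[, 2], right_ankle_z = Ra[, 3]
  )
}

# one calculation stream: sequential display/answer windows, responses drawn
# from the subject's accuracy and (log-normal) answer-time distribution
simulate_calc_phase <- function(duration_s, acc, time_mean_s, config) {
  cc <- config$calc
  cv <- config$answer_time_cv
  qs <- list(); t <- 0; i <- 0L
  display_on <- response_time <- numeric()
  chosen_side <- character(); is_correct <- logical()
  while (t + cc$display_s <= duration_s) {
    window <- min(cc$answer_window_s, duration_s - (t + cc$display_s))
    if (window <= 0) break
    i <- i + 1L
    q <- gen_question(cc)
    qs[[i]] <- q
    rt <- if (cv == 0) time_mean_s else
      rlnorm(1L, meanlog = log(time_mean_s) - cv^2 / 2, sdlog = cv)
    display_off <- t + cc$display_s
    display_on[i] <- t
    if (rt <= window) {
      correct <- runif(1L) < acc
      response_time[i] <- rt
      chosen_side[i] <- if (correct) q$correct_side else
        setdiff(c("left", "right"), q$correct_side)
      is_correct[i] <- correct
      t <- display_off + rt
    } else {
      response_time[i] <- NA_real_
      chosen_side[i] <- NA_character_
      is_correct[i] <- NA
      t <- display_off + window
    }
  }
  tibble(
    operand_a = vapply(qs, `[[`, 0L, "operand_a"),
    operand_b = vapply(qs, `[[`, 0L, "operand_b"),
    operator = vapply(qs, `[[`, "", "operator"),
    correct_answer = vapply(qs, `[[`, 0L, "correct_answer"),
    distractor = vapply(qs, `[[`, 0L, "distractor"),
    distractor_rule = vapply(qs, `[[`, "", "distractor_rule"),
    correct_side = vapply(qs, `[[`, "", "correct_side"),
    display_on = display_on, response_time = response_time,
    chosen_side = chosen_side, is_correct = is_correct
  )
}

#' Simulate one dual-task trial session
#'
#' Produces the three phases: the single cognitive phase (calculation
#' responses), the single physical phase (skeleton frames plus alternating
#' floor contacts phase-locked to the knee flexion waveform), and the dual
#' phase, where the configured dual-task cost multipliers apply — step
#' jitter inflated, accuracy reduced, answer time lengthened, knee amplitude
#' reduced — with cost magnitude growing as MMSE decreases. The effective
#' knee amplitude includes the learning term
#' `learn_gain * min(trial_index, learn_plateau)` when the subject's
#' learning gate is on. Ground-truth angle traces, scheduled raises and the
#' effective parameters are exposed under each gait phase's `ground_truth`.
#'
#' @param subject One row of [sample_subjects()] (tibble or list).
#' @param trial_index Positive integer.
#' @param config A [cohort_config()].
#' @return A `trial_session` object.
#' @export
simulate_trial <- function(subject, trial_index, config = cohort_config()) {
  if (trial_index < 1) stop_dualgait("trial_index must be >= 1",
                                     "dualgait_validation_error")
  s <- as.list(subject)
  d30 <- 30 - s$mmse
  amp_eff <- s$amp_base +
    (if (isTRUE(s$learn_on)) config$learn_gain * min(trial_index, config$learn_plateau) else 0)
  jitter_dual <- s$step_jitter * (1 + config$cost_jitter * d30)
  acc_dual <- min(1, max(0.05, s$acc * (1 - config$cost_accuracy * d30)))
  time_dual <- s$answer_time * (1 + config$cost_answer_time * d30)
  amp_dual <- max(config$amp_min, amp_eff * (1 - config$cost_amplitude * d30))

  cognitive <- list(kind = "cognitive", duration_s = config$cognitive_s,
                    responses = simulate_calc_phase(
                      config$cognitive_s, s$acc, s$answer_time, config))
  phys <- simulate_step_phase(config$physical_s, amp_eff, s$step_interval,
                              s$step_jitter, config)
  physical <- c(list(kind = "physical", duration_s = config$physical_s), phys)
  dual_gait <- simulate_step_phase(config$dual_s, amp_dual, s$step_interval,
                                   jitter_dual, config)
  dual <- c(list(kind = "dual", duration_s = config$dual_s), dual_gait,
            list(responses = simulate_calc_phase(
              config$dual_s, acc_dual, time_dual, config)))

  structure(
    list(schema_version = "1.0",
         subject_id = s$subject_id,
         trial_index = as.integer(trial_index),
         mmse = as.numeric(s$mmse),
         phases = list(cognitive = cognitive, physical = physical,
                       dual = dual)),
    class = "trial_session"
  )
}

trials_for <- function(config, n) {
  tp <- config$trials_per_subject
  if (is.function(tp)) as.integer(tp(n)) else rep(as.integer(tp), n)
}

#' Simulate a full cohort
#'
#' Samples the subjects and all their trial sessions. Each (subject, trial)
#' pair uses a random substream derived from the master seed and the subject
#' identifier, so the result is reproducible and independent of iteration
#' order.
#'
#' @inheritParams sample_subjects
#' @return A list of class `dualgait_cohort` with elements `subjects`
#'   (tibble) and `sessions` (list of `trial_session`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  subjects <- sample_subjects(config, seed)
  counts <- {
    set.seed(derive_seed(seed, "trial-counts"))
    trials_for(config, nrow(subjects))
  }
  sessions <- list(); k <- 0L
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    for (j in seq_len(counts[i])) {
      set.seed(derive_seed(seed, paste0(subj$subject_id, ":", j)))
      k <- k + 1L
      sessions[[k]] <- simulate_trial(subj, j, config)
    }
  }
  structure(list(subjects = subjects, sessions = sessions),
            class = "dualgait_cohort")
}

#' Simulate straight to a feature table
#'
#' Streams the cohort: each session is simulated, features are extracted,
#' and the raw frames are discarded, keeping memory flat for large cohorts.
#'
#' @inheritParams sample_subjects
#' @param params An [extract_params()].
#' @param trial_indices Optional vector of trial indices to simulate for
#'   every subject (default `1:trials_per_subject`); useful for sparse
#'   designs such as "first trial plus experienced trials".
#' @return Feature tibble as from [extract_feature_table()].
#' @export
simulate_feature_table <- function(config = cohort_config(),
                                   seed = config$seed,
                                   params = extract_params(),
                                   trial_indices = NULL) {
  subjects <- sample_subjects(config, seed)
  counts <- {
    set.seed(derive_seed(seed, "trial-counts"))
    trials_for(config, nrow(subjects))
  }
  rows <- list(); k <- 0L; dropped <- 0L
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    idx <- if (is.null(trial_indices)) seq_len(counts[i]) else trial_indices
    for (j in idx) {
      set.seed(derive_seed(seed, paste0(subj$subject_id, ":", j)))
      sess <- simulate_trial(subj, j, config)
      row <- tryCatch(extract_features(sess, params),
                      dualgait_incomplete_trial = function(e) {
                        dropped <<- dropped + 1L; NULL
                      })
      if (!is.null(row)) { k <- k + 1L; rows[[k]] <- row }
    }
  }
  if (dropped > 0L) message(sprintf("dropped %d incomplete trial(s)", dropped))
  bind_rows(rows)
}
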