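# Gait feature extraction: knee angles from skeleton joints, raise-cycle
# segmentation (peaks and valleys of the knee-angle trace), step-interval
# statistics from floor-contact events, and assembly of the 12-dimensional
# feature vector.

#' Parameters of the feature extractor
#'
#' @param smooth_window_s Width in seconds of the centered moving average
#'   applied to the knee-angle trace before extremum search. Smoothing is
#'   used only to *locate* peaks and valleys; their values are re-read from
#'   the raw trace so amplitudes are not attenuated.
#' @param min_prominence Minimum peak-to-valley angle difference in radians
#'   for a raise cycle to count.
#' @param min_separation_s Minimum time between successive flexion valleys.
#'   Defaults sized to adult stepping-in-place cadence.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   standard deviation for all dispersion features.
#' @return A list of class `extract_params`.
#' @export
extract_params <- function(smooth_window_s = 0.3, min_prominence = 0.05,
                           min_separation_s = 0.4,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (smooth_window_s < 0 || min_prominence <= 0 || min_separation_s <= 0)
    stop_dualgait("extraction parameters must be positive",
                  "dualgait_config_error")
  structure(list(smooth_window_s = smooth_window_s,
                 min_prominence = min_prominence,
                 min_separation_s = min_separation_s,
                 sd_type = sd_type),
            class = "extract_params")
}

#' Knee angle from three joints
#'
#' The knee angle is the interior angle at the knee between the knee-to-hip
#' and knee-to-ankle segments (hip center, knee, ankle), in radians. A fully
#' extended leg gives pi; flexion during a knee raise lowers the angle.
#'
#' @param hip,knee,ankle Numeric length-3 vectors: 3-D joint positions in
#'   meters (sensor coordinates).
#' @return Angle in radians, in `(0, pi]`.
#' @export
#' @examples
#' knee_angle(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)) # straight leg: pi
#' knee_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # right angle: pi/2
knee_angle <- function(hip, knee, ankle) {
  u <- hip - knee; v <- ankle - knee
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu < 1e-9 || nv < 1e-9)
    stop_dualgait("degenerate geometry: knee coincides with hip or ankle",
                  "dualgait_geometry_error")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

# vectorized interior angle at the knee over frame matrices (n x 3 each)
knee_angle_vec <- function(hip, knee, ankle) {
  u <- hip - knee; v <- ankle - knee
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  ang <- acos(pmax(-1, pmin(1, cosang)))
  ang[nu < 1e-9 | nv < 1e-9] <- NA_real_
  ang
}

joint_matrix <- function(frames, joint) {
  cols <- paste0(joint, c("_x", "_y", "_z"))
  if (!all(cols %in% names(frames)))
    stop_dualgait(sprintf("frames lack columns for joint '%s'", joint),
                  "dualgait_validation_error")
  as.matrix(frames[cols])
}

#' Knee-angle time series for one leg
#'
#' Computes the per-frame knee angle for the chosen side from skeleton
#' frames. Frames with degenerate geometry (zero-length segments or
#' non-finite coordinates) are dropped; their count is attached as the
#' `n_dropped` attribute.
#'
#' @param frames Tibble of skeleton frames with columns `t` and
#'   `<joint>_{x,y,z}` for `hip_center`, `left_knee`, `right_knee`,
#'   `left_ankle`, `right_ankle`.
#' @param side `"left"` or `"right"`.
#' @return Tibble with columns `t` (seconds) and `angle` (radians), with
#'   attributes `side` and `n_dropped`.
#' @export
knee_angle_series <- function(frames, side = c("left", "right")) {
  side <- match.arg(side)
  if (nrow(frames) < 2L)
    stop_dualgait("need at least 2 frames for an angle series",
                  "dualgait_validation_error")
  if (is.unsorted(frames$t))
    stop_dualgait("frame timestamps must be non-decreasing",
                  "dualgait_validation_error")
  ang <- knee_angle_vec(joint_matrix(frames, "hip_center"),
                        joint_matrix(frames, paste0(side, "_knee")),
                        joint_matrix(frames, paste0(side, "_ankle")))
  keep <- is.finite(ang)
  if (!any(keep))
    stop_dualgait("all frames degenerate: no angle series",
                  "dualgait_validation_error")
  out <- tibble(t = frames$t[keep], angle = ang[keep])
  attr(out, "side") <- side
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# local minima of a numeric vector, robust to flat plateaus: a minimum is the
# midpoint of a run where the sign of the difference changes from - to +
local_minima <- function(x) {
  dx <- diff(x)
  nz <- which(dx != 0)
  if (length(nz) < 2L) return(integer())
  s <- sign(dx[nz])
  ch <- which(s[-length(s)] < 0 & s[-1] > 0)
  if (length(ch) == 0L) return(integer())
  # valley spans from end of the fall to start of the rise; take the midpoint
  lo <- nz[ch] + 1L
  hi <- nz[ch + 1L]
  as.integer(floor((lo + hi) / 2))
}

#' Segment knee-raise cycles from an angle series
#'
#' Smooths the knee-angle trace with a centered moving average, locates
#' flexion valleys (local minima of the smoothed angle), enforces a minimum
#' separation between valleys (keeping the deeper one on conflict), and
#' pairs each valley with its preceding extension peak (the maximum of the
#' raw trace since the previous valley). Peak and valley values are read
#' from the raw series near the detected locations. Cycles whose amplitude
#' falls below the prominence threshold are discarded, so a motionless
#' subject yields an empty result rather than an error.
#'
#' @param series Tibble from [knee_angle_series()] (columns `t`, `angle`).
#' @param params An [extract_params()].
#' @return Tibble of raise cycles with columns `peak_t`, `valley_t`,
#'   `peak_angle`, `valley_angle`, `amplitude` (radians, `>= 0`), ordered in
#'   time.
#' @export
detect_raise_cycles <- function(series, params = extract_params()) {
  if (nrow(series) == 0L)
    stop_dualgait("empty angle series", "dualgait_validation_error")
  dur <- diff(range(series$t))
  if (dur <= params$min_separation_s)
    stop_dualgait("series shorter than the minimum cycle separation",
                  "dualgait_validation_error")
  x <- series$angle; t <- series$t; n <- length(x)
  dt <- stats::median(diff(t))
  k <- max(1L, round(params$smooth_window_s / max(dt, 1e-6)))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- if (k > 1L && n > k) {
    f <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    ifelse(is.na(f), x, f)
  } else x
  cand <- local_minima(sm)
  empty <- tibble(peak_t = double(), valley_t = double(),
                  peak_angle = double(), valley_angle = double(),
                  amplitude = double())
  if (length(cand) == 0L) return(empty)
  # gate candidates on their depth in the *smoothed* trace: raw-noise
  # wiggles on flat segments must not masquerade as raise cycles. The 0.6
  # factor tolerates the attenuation of a genuine flexion bump by the
  # moving average.
  depth <- vapply(cand, function(i) {
    win <- which(t >= t[i] - params$min_separation_s &
                   t <= t[i] + params$min_separation_s)
    max(sm[win]) - sm[i]
  }, 0)
  cand <- cand[depth >= 0.6 * params$min_prominence]
  if (length(cand) == 0L) return(empty)
  # enforce minimum separation greedily, deepest valleys first
  ord <- cand[order(sm[cand])]
  keep <- integer()
  for (i in ord) {
    if (all(abs(t[i] - t[keep]) >= params$min_separation_s)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  half <- max(1L, floor(k / 2))
  prev_end <- 1L
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    # refine valley on the raw trace near the smoothed minimum
    vlo <- max(1L, i - half); vhi <- min(n, i + half)
    vi <- vlo + which.min(x[vlo:vhi]) - 1L
    # preceding extension peak: raw maximum since the previous valley
    seg <- prev_end:max(prev_end, vlo)
    pi_ <- seg[which.max(x[seg])]
    out[[j]] <- c(peak_t = t[pi_], valley_t = t[vi],
                  peak_angle = x[pi_], valley_angle = x[vi])
    prev_end <- vhi
  }
  cyc <- as_tibble(do.call(rbind, out))
  cyc$amplitude <- cyc$peak_angle - cyc$valley_angle
  cyc <- cyc[cyc$amplitude >= params$min_prominence, , drop = FALSE]
  as_tibble(cyc)
}

#' Mean and dispersion of knee-raise amplitudes
#'
#' Summarises per-cycle amplitudes (both legs pooled into one sample). With
#' a single cycle the standard deviation is defined as 0; with none, a
#' missing-feature condition is signalled.
#'
#' @param cycles Tibble of raise cycles (needs an `amplitude` column);
#'   typically the row-bound cycles of both legs.
#' @param sd_type Dispersion convention, see [extract_params()].
#' @return Named list with `mean` and `sd` in radians.
#' @export
knee_amplitude_stats <- function(cycles, sd_type = "population") {
  a <- cycles$amplitude
  if (length(a) == 0L)
    signal_missing_feature("knee_amplitude", "no raise cycles detected")
  list(mean = mean(a), sd = pop_sd(a, sd_type))
}

#' Step-interval statistics from floor-contact events
#'
#' Walking (stepping) speed is represented as the time between two
#' consecutive steps of the left and right foot; intervals are successive
#' differences of event times restricted to alternating-foot pairs. Two
#' consecutive same-foot contacts are skipped (their count is attached as
#' attribute `n_skipped`).
#'
#' @param events Tibble with columns `t` (strictly increasing seconds) and
#'   `foot` (`"left"`/`"right"`).
#' @param sd_type Dispersion convention, see [extract_params()].
#' @return Named list with `mean` and `sd` in seconds.
#' @export
step_interval_stats <- function(events, sd_type = "population") {
  if (nrow(events) < 2L)
    signal_missing_feature("step_interval", "fewer than 2 step events")
  if (any(diff(events$t) <= 0))
    stop_dualgait("step event times must be strictly increasing",
                  "dualgait_validation_error")
  alt <- events$foot[-1] != events$foot[-nrow(events)]
  ivl <- diff(events$t)[alt]
  if (length(ivl) == 0L)
    signal_missing_feature("step_interval", "no alternating-foot pairs")
  out <- list(mean = mean(ivl), sd = pop_sd(ivl, sd_type))
  attr(out, "n_skipped") <- sum(!alt)
  out
}

#' Answer accuracy and speed
#'
#' Rate of correct answers and mean response time over the *answered*
#' questions of a phase. Response time runs from the moment the two answer
#' candidates appear to the button press.
#'
#' @param responses Tibble with columns `is_correct` (logical) and
#'   `response_time` (seconds); unanswered questions carry `NA` in both.
#' @return Named list with `rate` (fraction in `[0, 1]`) and `mean_time`
#'   (seconds).
#' @export
answer_stats <- function(responses) {
  answered <- !is.na(responses$is_correct)
  if (!any(answered))
    signal_missing_feature("answer", "no answered questions")
  list(rate = mean(responses$is_correct[answered]),
       mean_time = mean(responses$response_time[answered]))
}

# features of the gait stream of one phase (4 values)
phase_gait_features <- function(phase, params) {
  cycles <- bind_rows(
    detect_raise_cycles(knee_angle_series(phase$frames, "left"), params),
    detect_raise_cycles(knee_angle_series(phase$frames, "right"), params)
  )
  amp <- knee_amplitude_stats(cycles, params$sd_type)
  stp <- step_interval_stats(phase$steps, params$sd_type)
  list(step_interval_mean = stp$mean, step_interval_sd = stp$sd,
       knee_amplitude_mean = amp$mean, knee_amplitude_sd = amp$sd)
}

#' Extract the 12-dimensional feature vector of one trial
#'
#' Maps the three phases onto the canonical feature vector: gait features of
#' the `single` context come from the single physical phase, calculation
#' features of the `single` context from the single cognitive phase, and all
#' six `dual` features from the dual phase. Any missing-feature signal
#' (e.g. no raise cycles, no answered questions) is escalated to an
#' incomplete-trial error naming the feature, so callers can drop the trial.
#'
#' @param session A `trial_session` (see [simulate_trial()] /
#'   [read_sessions()]).
#' @param params An [extract_params()].
#' @return One-row tibble: `subject_id`, `trial_index`, `mmse`, then the 12
#'   features named as in [feature_names()].
#' @export
extract_features <- function(session, params = extract_params()) {
  validate_session(session)
  handler <- function(e) {
    abort(sprintf("incomplete trial (subject %s, trial %d): %s",
                  session$subject_id, session$trial_index, conditionMessage(e)),
          class = c("dualgait_incomplete_trial", "dualgait_error"),
          feature = e$feature)
  }
  withCallingHandlers(
    {
      g1 <- phase_gait_features(session$phases$physical, params)
      g2 <- phase_gait_features(session$phases$dual, params)
      c1 <- answer_stats(session$phases$cognitive$responses)
      c2 <- answer_stats(session$phases$dual$responses)
      out <- tibble(
        subject_id = session$subject_id,
        trial_index = as.integer(session$trial_index),
        mmse = if (is.null(session$mmse)) NA_real_ else as.numeric(session$mmse),
        step_interval_mean_single = g1$step_interval_mean,
        step_interval_sd_single = g1$step_interval_sd,
        knee_amplitude_mean_single = g1$knee_amplitude_mean,
        knee_amplitude_sd_single = g1$knee_amplitude_sd,
        answer_rate_single = c1$rate,
        answer_time_mean_single = c1$mean_time,
        step_interval_mean_dual = g2$step_interval_mean,
        step_interval_sd_dual = g2$step_interval_sd,
        knee_amplitude_mean_dual = g2$knee_amplitude_mean,
        knee_amplitude_sd_dual = g2$knee_amplitude_sd,
        answer_rate_dual = c2$rate,
        answer_time_mean_dual = c2$mean_time
      )
      stopifnot(all(is.finite(as.numeric(out[feature_names()]))))
      out
    },
    dualgait_missing_feature = handler
  )
}

#' Extract the feature table of many sessions
#'
#' Complete-case policy: trials where any feature is undefined are dropped
#' with a message (`on_incomplete = "drop"`, the default) or abort the
#' extraction (`"error"`).
#'
#' @param sessions List of `trial_session` objects.
#' @param params An [extract_params()].
#' @param on_incomplete `"drop"` or `"error"`.
#' @return Tibble with one row per retained trial (15 columns).
#' @export
extract_feature_table <- function(sessions, params = extract_params(),
                                  on_incomplete = c("drop", "error")) {
  on_incomplete <- match.arg(on_incomplete)
  rows <- vector("list", length(sessions))
  dropped <- 0L
  for (i in seq_along(sessions)) {
    rows[[i]] <- tryCatch(
      extract_features(sessions[[i]], params),
      dualgait_incomplete_trial = function(e) {
        if (on_incomplete == "error") stop(e)
        dropped <<- dropped + 1L
        NULL
      }
    )
  }
  if (dropped > 0L)
    message(sprintf("dropped %d incomplete trial(s)", dropped))
  bind_rows(rows)
}
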