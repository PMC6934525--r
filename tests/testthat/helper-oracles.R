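# Independent oracle implementations used to cross-check the package's
# computations. These deliberately use different formulas / code paths than
# the implementation under test.

# interior angle via the law of cosines on the three pairwise distances
oracle_knee_angle <- function(hip, knee, ankle) {
  a <- sqrt(sum((hip - knee)^2))
  b <- sqrt(sum((ankle - knee)^2))
  cc <- sqrt(sum((hip - ankle)^2))
  acos(max(-1, min(1, (a^2 + b^2 - cc^2) / (2 * a * b))))
}

# digit-array arithmetic: split into units/tens digit vectors and operate
# digit by digit, without carry/borrow propagation where the mistake rule
# says so. Returns NULL where the rule is inapplicable (would reproduce the
# correct answer); for unit_place returns the set of admissible values.
oracle_distractor <- function(a, b, operator, rule) {
  digits <- function(x) c(x %% 10L, x %/% 10L)  # units, tens
  da <- digits(a); db <- digits(b)
  correct <- if (operator == "addition") a + b else a - b
  if (rule == "carry_borrow") {
    if (operator == "addition") {
      if (da[1] + db[1] < 10L) return(NULL)      # no carry to forget
      units <- (da[1] + db[1]) %% 10L
      tens <- (da[2] + db[2]) %% 10L             # carry dropped
      return(tens * 10L + units)
    }
    if (da[1] >= db[1]) return(NULL)             # no borrow to forget
    units <- da[1] + 10L - db[1]
    tens <- da[2] - db[2]                        # borrow not propagated
    return(tens * 10L + units)
  }
  if (rule == "unit_place") {
    u <- correct %% 10L; t10 <- correct %/% 10L
    return(c(t10 * 10L + (u + 1L) %% 10L, t10 * 10L + (u - 1L) %% 10L))
  }
  if (rule == "operator_swap") {
    v <- if (operator == "addition") abs(a - b) else a + b
    if (v == correct) return(NULL)
    return(v)
  }
  stop("unknown rule")
}

# direct-formula recomputation of the 12 features from the raw streams of a
# session, written as plain loops; knee amplitudes are measured at the
# generator's scheduled raise locations instead of by extremum detection
oracle_features <- function(session) {
  step_stats <- function(steps) {
    ivl <- c()
    for (i in 2:nrow(steps)) {
      if (steps$foot[i] != steps$foot[i - 1])
        ivl <- c(ivl, steps$t[i] - steps$t[i - 1])
    }
    c(mean = sum(ivl) / length(ivl),
      sd = sqrt(sum((ivl - mean(ivl))^2) / length(ivl)))
  }
  answer_stats_direct <- function(resp) {
    ok <- which(!is.na(resp$is_correct))
    c(rate = sum(resp$is_correct[ok]) / length(ok),
      mean_time = sum(resp$response_time[ok]) / length(ok))
  }
  knee_stats <- function(phase) {
    amps <- c()
    for (side in c("left", "right")) {
      ser <- knee_angle_series(phase$frames, side)
      raises <- phase$ground_truth$raises
      raises <- raises[raises$foot == side, ]
      prev <- min(ser$t)
      for (i in seq_len(nrow(raises))) {
        ctr <- raises$center_t[i]
        half <- 0.15
        near <- ser$t >= ctr - half & ser$t <= ctr + half
        if (!any(near)) next
        valley <- min(ser$angle[near])
        before <- ser$t >= prev & ser$t < ctr - half
        if (!any(before)) before <- ser$t < ctr
        peak <- max(ser$angle[before])
        amps <- c(amps, peak - valley)
        prev <- ctr + half
      }
    }
    c(mean = mean(amps), sd = sqrt(mean((amps - mean(amps))^2)))
  }
  g1 <- knee_stats(session$phases$physical)
  g2 <- knee_stats(session$phases$dual)
  s1 <- step_stats(session$phases$physical$steps)
  s2 <- step_stats(session$phases$dual$steps)
  a1 <- answer_stats_direct(session$phases$cognitive$responses)
  a2 <- answer_stats_direct(session$phases$dual$responses)
  c(step_interval_mean_single = unname(s1["mean"]),
    step_interval_sd_single = unname(s1["sd"]),
    knee_amplitude_mean_single = unname(g1["mean"]),
    knee_amplitude_sd_single = unname(g1["sd"]),
    answer_rate_single = unname(a1["rate"]),
    answer_time_mean_single = unname(a1["mean_time"]),
    step_interval_mean_dual = unname(s2["mean"]),
    step_interval_sd_dual = unname(s2["sd"]),
    knee_amplitude_mean_dual = unname(g2["mean"]),
    knee_amplitude_sd_dual = unname(g2["sd"]),
    answer_rate_dual = unname(a2["rate"]),
    answer_time_mean_dual = unname(a2["mean_time"]))
}

# random proper rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
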