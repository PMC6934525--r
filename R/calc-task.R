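# Two-alternative arithmetic task: question generation and the error model
# used to produce plausible wrong answers (distractors).

#' Calculation task settings
#'
#' Settings for the two-number addition/subtraction task. Operands default to
#' 1--49 for addition (sums stay two-digit) and a minuend up to 99 for
#' subtraction, so that every mistake rule of the distractor model is
#' well-defined on two-digit arithmetic. Questions are shown briefly and then
#' replaced by two answer candidates; `display_s` and `answer_window_s` set
#' those two windows.
#'
#' @param operand_min,operand_max Inclusive operand range for addition (and
#'   the subtrahend); integers in `[0, 99]`.
#' @param subtraction_max Upper bound for the minuend.
#' @param operators Operators to draw from, subset of
#'   `c("addition", "subtraction")`.
#' @param rules Distractor rules to draw from, subset of
#'   `c("carry_borrow", "unit_place", "operator_swap")`.
#' @param display_s Seconds the question is displayed before the candidates
#'   replace it.
#' @param answer_window_s Maximum seconds allowed to answer once the
#'   candidates are shown.
#' @return A list of class `calc_config`.
#' @export
calc_config <- function(operand_min = 1L, operand_max = 49L,
                        subtraction_max = 99L,
                        operators = c("addition", "subtraction"),
                        rules = c("carry_borrow", "unit_place", "operator_swap"),
                        display_s = 3, answer_window_s = 5) {
  operators <- match.arg(operators, several.ok = TRUE)
  rules <- match.arg(rules, several.ok = TRUE)
  if (operand_min < 0 || operand_max > 99 || operand_min > operand_max)
    stop_dualgait("operand range must satisfy 0 <= min <= max <= 99",
                  "dualgait_config_error")
  if (operand_max == operand_min && operand_min == 0 &&
      identical(operators, "addition"))
    stop_dualgait("degenerate operand range [0,0]: no valid distractor exists",
                  "dualgait_config_error")
  if (display_s <= 0 || answer_window_s <= 0)
    stop_dualgait("display_s and answer_window_s must be positive",
                  "dualgait_config_error")
  structure(
    list(operand_min = as.integer(operand_min),
         operand_max = as.integer(operand_max),
         subtraction_max = as.integer(subtraction_max),
         operators = operators, rules = rules,
         display_s = display_s, answer_window_s = answer_window_s),
    class = "calc_config"
  )
}

#' Generate a distractor for an arithmetic question
#'
#' Produces the wrong answer candidate by simulating a common calculation
#' mistake:
#' * `carry_borrow` — digitwise addition/subtraction with the carry (borrow)
#'   into the tens place dropped, e.g. 27 + 15 -> 32 (units 7+5 = 12, the
#'   carry is forgotten) or 42 - 15 -> 37 (the borrow is not propagated).
#' * `unit_place` — the units digit of the correct answer is perturbed by
#'   plus or minus one, wrapping within 0--9; the tens digit is unchanged.
#' * `operator_swap` — the opposite operator is applied: `a + b` for a
#'   subtraction question, `|a - b|` for an addition question.
#'
#' A rule that would reproduce the correct answer (for instance
#' `carry_borrow` on a sum with no carry) is *inapplicable* and signals a
#' condition of class `dualgait_rule_inapplicable`, so the caller can resample
#' another rule.
#'
#' @param operand_a,operand_b Non-negative integer operands (for subtraction,
#'   `operand_a >= operand_b`).
#' @param operator `"addition"` or `"subtraction"`.
#' @param rule One of `"carry_borrow"`, `"unit_place"`, `"operator_swap"`.
#' @return The integer distractor, guaranteed to differ from the correct
#'   answer.
#' @export
generate_distractor <- function(operand_a, operand_b, operator, rule) {
  a <- as.integer(operand_a); b <- as.integer(operand_b)
  if (a < 0 || b < 0) stop_dualgait("operands must be non-negative",
                                    "dualgait_validation_error")
  if (operator == "subtraction" && a < b)
    stop_dualgait("subtraction requires operand_a >= operand_b",
                  "dualgait_validation_error")
  correct <- if (operator == "addition") a + b else a - b
  inapplicable <- function() abort(
    sprintf("rule '%s' is inapplicable for %d %s %d", rule, a, operator, b),
    class = c("dualgait_rule_inapplicable", "dualgait_error")
  )
  val <- switch(
    rule,
    carry_borrow = {
      au <- a %% 10L; bu <- b %% 10L
      at <- a %/% 10L; bt <- b %/% 10L
      if (operator == "addition") {
        if (au + bu < 10L) inapplicable()
        ((at + bt) %% 10L) * 10L + (au + bu) %% 10L
      } else {
        if (au >= bu) inapplicable()
        (at - bt) * 10L + (au - bu) %% 10L
      }
    },
    unit_place = {
      delta <- sample(c(-1L, 1L), 1L)
      (correct %/% 10L) * 10L + (correct %% 10L + delta) %% 10L
    },
    operator_swap = {
      swapped <- if (operator == "addition") abs(a - b) else a + b
      if (swapped == correct) inapplicable()
      swapped
    },
    stop_dualgait(sprintf("unknown distractor rule '%s'", rule),
                  "dualgait_config_error")
  )
  if (val == correct) inapplicable()
  as.integer(val)
}

#' Generate a two-alternative calculation question
#'
#' Draws an addition or subtraction of two numbers (operator uniform over the
#' configured set), orders subtraction operands so the result is
#' non-negative, attaches a distractor produced by [generate_distractor()]
#' (rule drawn uniformly, resampling among the remaining rules when one is
#' inapplicable), and assigns the correct answer to the left or right button
#' uniformly at random. Fully deterministic given the R random seed.
#'
#' @param config A [calc_config()].
#' @return A one-row tibble with columns `operand_a`, `operand_b`,
#'   `operator`, `correct_answer`, `distractor`, `distractor_rule`,
#'   `correct_side`.
#' @export
generate_question <- function(config = calc_config()) {
  as_tibble(gen_question(config))
}

# list-returning core of generate_question; avoids per-question tibble
# overhead inside the simulator's inner loop
gen_question <- function(config) {
  stopifnot(inherits(config, "calc_config"))
  for (attempt in seq_len(100L)) {
    operator <- if (length(config$operators) == 1L) config$operators else
      sample(config$operators, 1L)
    if (operator == "addition") {
      a <- sample(config$operand_min:config$operand_max, 1L)
      b <- sample(config$operand_min:config$operand_max, 1L)
    } else {
      a <- sample(config$operand_min:config$subtraction_max, 1L)
      b <- sample(config$operand_min:a, 1L)
    }
    rules <- if (length(config$rules) == 1L) config$rules else
      sample(config$rules)
    for (rule in rules) {
      d <- tryCatch(generate_distractor(a, b, operator, rule),
                    dualgait_rule_inapplicable = function(e) NULL)
      if (!is.null(d)) {
        correct <- if (operator == "addition") a + b else a - b
        return(list(
          operand_a = as.integer(a), operand_b = as.integer(b),
          operator = operator, correct_answer = as.integer(correct),
          distractor = d, distractor_rule = rule,
          correct_side = sample(c("left", "right"), 1L)
        ))
      }
    }
    # every configured rule inapplicable for these operands: redraw
  }
  stop_dualgait("no valid distractor found for the configured operand range",
                "dualgait_config_error")
}

#' Schedule question display/answer windows within a phase
#'
#' Questions run back-to-back: each is displayed for `display_s` seconds and
#' then replaced by the two answer candidates; the next question appears as
#' soon as the subject answers (or the answer window closes). A question is
#' scheduled only if its display fits inside the phase; its answer window is
#' truncated at the phase end. How many questions fit therefore depends on
#' how quickly each is answered.
#'
#' @param phase_duration_s Phase length in seconds (> 0).
#' @param response_times Optional vector of response times (seconds) consumed
#'   in order; recycled if shorter than the number of scheduled questions.
#'   `NULL` means every answer uses the full window.
#' @param config A [calc_config()].
#' @return Tibble with columns `question`, `display_on`, `display_off`,
#'   `answer_deadline`, `answered_at` (NA when the window lapses), all in
#'   seconds from phase start.
#' @export
question_schedule <- function(phase_duration_s, response_times = NULL,
                              config = calc_config()) {
  if (!is.numeric(phase_duration_s) || phase_duration_s <= 0)
    stop_dualgait("phase_duration_s must be positive", "dualgait_config_error")
  if (config$display_s > phase_duration_s)
    stop_dualgait("display window longer than the phase",
                  "dualgait_config_error")
  rows <- list(); t <- 0; i <- 0L
  while (t + config$display_s <= phase_duration_s) {
    window <- min(config$answer_window_s,
                  phase_duration_s - (t + config$display_s))
    if (window <= 0) break
    i <- i + 1L
    rt <- if (is.null(response_times)) window else
      response_times[(i - 1L) %% length(response_times) + 1L]
    answered <- rt <= window
    display_off <- t + config$display_s
    rows[[i]] <- tibble(
      question = i, display_on = t, display_off = display_off,
      answer_deadline = display_off + window,
      answered_at = if (answered) display_off + rt else NA_real_
    )
    t <- display_off + if (answered) rt else window
  }
  if (length(rows) == 0L)
    return(tibble(question = integer(), display_on = double(),
                  display_off = double(), answer_deadline = double(),
                  answered_at = double()))
  bind_rows(rows)
}
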