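# On-disk formats: trial sessions as JSON-Lines (one trial per line,
# streamable and append-friendly for a continuously running kiosk), feature
# tables as RFC-4180 CSV, run configuration as YAML. Writers and readers
# share one validator, so both reject the same invariant violations.

KNOWN_SCHEMA_VERSIONS <- "1.0"

FRAME_JOINTS <- c("hip_center", "left_knee", "right_knee",
                  "left_ankle", "right_ankle")

frame_template <- local({
  nm <- c("t", paste0(rep(FRAME_JOINTS, each = 3), c("_x", "_y", "_z")))
  setNames(rep("double", length(nm)), nm)
})
steps_template <- c(t = "double", foot = "character")
responses_template <- c(
  operand_a = "integer", operand_b = "integer", operator = "character",
  correct_answer = "integer", distractor = "integer",
  distractor_rule = "character", correct_side = "character",
  display_on = "double", response_time = "double",
  chosen_side = "character", is_correct = "logical"
)
angle_template <- c(t = "double", angle = "double")
raises_template <- c(foot = "character", center_t = "double",
                     amplitude = "double")

cast_column <- function(x, type) {
  x <- unlist(x, use.names = FALSE)
  if (is.null(x)) x <- logical(0)
  switch(type,
         double = as.double(x),
         integer = as.integer(x),
         character = as.character(x),
         logical = as.logical(x))
}

cast_tibble <- function(cols, template) {
  as_tibble(lapply(names(template), function(nm) {
    cast_column(cols[[nm]], template[[nm]])
  }) %>% setNames(names(template)))
}

#' Validate a trial session
#'
#' Checks the session invariants enforced by both the writer and the reader:
#' a known `schema_version`, a non-empty `subject_id`, `trial_index >= 1`,
#' exactly the three phases `cognitive`, `physical`, `dual`; finite skeleton
#' coordinates with non-decreasing timestamps; strictly increasing step
#' events with valid foot labels; positive response times; and answered
#' responses whose `is_correct` agrees with the chosen side.
#'
#' @param session A `trial_session`.
#' @return The session, invisibly; aborts with a validation error naming the
#'   offending field otherwise.
#' @export
validate_session <- function(session) {
  fail <- function(field, msg)
    stop_dualgait(sprintf("invalid session field '%s': %s", field, msg),
                  "dualgait_validation_error")
  if (is.null(session$schema_version) ||
      !session$schema_version %in% KNOWN_SCHEMA_VERSIONS)
    abort(sprintf("unknown schema_version '%s'", session$schema_version),
          class = c("dualgait_version_error", "dualgait_error"))
  if (is.null(session$subject_id) || !nzchar(session$subject_id))
    fail("subject_id", "must be a non-empty identifier")
  if (is.null(session$trial_index) || session$trial_index < 1)
    fail("trial_index", "must be >= 1")
  ph <- session$phases
  if (!setequal(names(ph), c("cognitive", "physical", "dual")) ||
      length(ph) != 3L)
    fail("phases", "must contain exactly cognitive, physical and dual")
  for (nm in c("physical", "dual")) {
    fr <- ph[[nm]]$frames
    if (is.null(fr) || nrow(fr) == 0L)
      fail(paste0(nm, ".frames"), "missing skeleton frames")
    coords <- as.matrix(fr[setdiff(names(frame_template), "t")])
    if (!all(is.finite(coords)))
      fail(paste0(nm, ".frames"), "non-finite joint coordinates")
    if (is.unsorted(fr$t))
      fail(paste0(nm, ".frames"), "timestamps must be non-decreasing")
    st <- ph[[nm]]$steps
    if (!is.null(st) && nrow(st) > 1L && any(diff(st$t) <= 0))
      fail(paste0(nm, ".steps"), "event times must be strictly increasing")
    if (!is.null(st) && !all(st$foot %in% c("left", "right")))
      fail(paste0(nm, ".steps"), "foot must be left or right")
  }
  for (nm in c("cognitive", "dual")) {
    rs <- ph[[nm]]$responses
    if (is.null(rs))
      fail(paste0(nm, ".responses"), "missing calculation responses")
    answered <- !is.na(rs$is_correct)
    if (any(rs$response_time[answered] <= 0))
      fail(paste0(nm, ".responses"), "response_time must be positive")
    agree <- rs$is_correct[answered] ==
      (rs$chosen_side[answered] == rs$correct_side[answered])
    if (!all(agree))
      fail(paste0(nm, ".responses"),
           "is_correct must match chosen_side == correct_side")
  }
  invisible(session)
}

session_to_json <- function(session) {
  jsonlite::toJSON(unclass(session), dataframe = "columns",
                   auto_unbox = TRUE, digits = NA, na = "null",
                   null = "null")
}

rebuild_phase <- function(p) {
  out <- list(kind = p$kind, duration_s = as.double(p$duration_s))
  if (!is.null(p$frames)) {
    out$frames <- cast_tibble(p$frames, frame_template)
    out$steps <- cast_tibble(p$steps, steps_template)
    if (!is.null(p$ground_truth)) {
      gt <- p$ground_truth
      out$ground_truth <- list(
        angle = list(left = cast_tibble(gt$angle$left, angle_template),
                     right = cast_tibble(gt$angle$right, angle_template)),
        raises = cast_tibble(gt$raises, raises_template),
        amp_effective = as.double(gt$amp_effective),
        interval_s = as.double(gt$interval_s),
        jitter_s = as.double(gt$jitter_s)
      )
    }
  }
  if (!is.null(p$responses))
    out$responses <- cast_tibble(p$responses, responses_template)
  out
}

session_from_list <- function(x) {
  structure(
    list(schema_version = x$schema_version,
         subject_id = x$subject_id,
         trial_index = as.integer(x$trial_index),
         mmse = if (is.null(x$mmse)) NA_real_ else as.double(x$mmse),
         phases = lapply(x$phases, rebuild_phase)),
    class = "trial_session"
  )
}

#' Write trial sessions as JSON-Lines
#'
#' One JSON object per line, UTF-8, deterministic field order, numeric
#' fields at full (round-trip) precision. Every session is validated before
#' anything is written.
#'
#' @param sessions Non-empty list of `trial_session` objects.
#' @param path Output file path.
#' @export
write_sessions <- function(sessions, path) {
  if (length(sessions) == 0L)
    stop_dualgait("sessions must be non-empty", "dualgait_validation_error")
  walk(sessions, validate_session)
  lines <- vapply(sessions, function(s) as.character(session_to_json(s)), "")
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read trial sessions from JSON-Lines
#'
#' Records are returned in file order; every invariant is re-validated on
#' load, so a reader rejects exactly what the writer would have rejected.
#' An empty file yields an empty list; a malformed line raises a parse error
#' carrying its line number; an unknown `schema_version` raises a version
#' error.
#'
#' @param path Path to a JSON-Lines session file.
#' @return List of `trial_session` objects.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path))
    stop_dualgait(sprintf("no such file: %s", path), "dualgait_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                         simplifyDataFrame = FALSE),
      error = function(e) abort(
        sprintf("parse error at line %d: %s", i, conditionMessage(e)),
        class = c("dualgait_parse_error", "dualgait_error"))
    )
    sess <- session_from_list(parsed)
    withCallingHandlers(
      validate_session(sess),
      dualgait_error = function(e) {
        abort(sprintf("line %d: %s", i, conditionMessage(e)),
              class = class(e))
      }
    )
    out[[i]] <- sess
  }
  out
}

#' Write / read the feature table CSV
#'
#' Fixed 15-column layout: `subject_id`, `trial_index`, `mmse`, then the 12
#' feature columns of [feature_names()]; header mandatory, decimal point
#' locale-independent, values at full round-trip precision. Non-finite
#' features are rejected.
#'
#' @param features Feature tibble (as from [extract_feature_table()]).
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  need <- c("subject_id", "trial_index", "mmse", feature_names())
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L)
    stop_dualgait(paste("feature table lacks columns:",
                        paste(missing, collapse = ", ")),
                  "dualgait_validation_error")
  vals <- as.matrix(features[feature_names()])
  if (!all(is.finite(vals)))
    stop_dualgait("non-finite feature values", "dualgait_validation_error")
  out <- features[need]
  # 17 significant digits guarantee bit-exact double round-trips
  for (nm in c("mmse", feature_names()))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table()` returns the feature tibble.
#' @export
read_feature_table <- function(path) {
  spec <- readr::cols(
    subject_id = readr::col_character(),
    trial_index = readr::col_integer(),
    .default = readr::col_character()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  # parse doubles via strtod (correctly rounded), keeping round-trips exact
  for (nm in intersect(c("mmse", feature_names()), names(out)))
    out[[nm]] <- as.numeric(out[[nm]])
  missing <- setdiff(c("subject_id", "trial_index", "mmse", feature_names()),
                     names(out))
  if (length(missing) > 0L)
    stop_dualgait(paste("feature table lacks columns:",
                        paste(missing, collapse = ", ")),
                  "dualgait_validation_error")
  if (!all(is.finite(as.matrix(out[feature_names()]))))
    stop_dualgait("non-finite feature values", "dualgait_validation_error")
  out
}

#' Run configuration in YAML
#'
#' A run configuration has four sections — `simulate`, `extract`,
#' `estimate`, `analyze` — whose keys override the corresponding function
#' defaults ([cohort_config()] and its nested `calc` block,
#' [extract_params()], [regressor_spec()]).
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sections <- c("simulate", "extract", "estimate", "analyze")
  unknown <- setdiff(names(raw), sections)
  if (length(unknown) > 0L)
    stop_dualgait(paste("unknown config sections:",
                        paste(unknown, collapse = ", ")),
                  "dualgait_config_error")
  out <- lapply(setNames(sections, sections), function(s) raw[[s]] %||% list())
  structure(out, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list of sections).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
as_cohort_config <- function(config) {
  sim <- config$simulate
  calc_args <- sim$calc
  sim$calc <- NULL
  args <- sim
  if (length(calc_args) > 0L)
    args$calc <- do.call(calc_config, calc_args)
  do.call(cohort_config, args)
}

#' @rdname read_run_config
#' @export
as_extract_params <- function(config) {
  do.call(extract_params, config$extract)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
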