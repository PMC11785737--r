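#' Mimicry session configuration
#'
#' Parameters of the closed-loop feedback protocol: a 5 s mimicry window,
#' a 3 s cooldown between expressions, at most 3 attempts per expression,
#' and feedback thresholds at 80% ("Great Job!") and 50% ("Good Job!").
#' Time is frame-driven: the window length in frames is
#' `round(window_seconds * frame_rate_hz)` (16 at the defaults, matching the
#' system's observed ~3.2 Hz recognition rate), which keeps session replays
#' deterministic.
#'
#' @param window_seconds Mimicry window length in seconds.
#' @param cooldown_seconds Idle period between expressions (recorded in the
#'   log; no computational effect in the frame-driven engine).
#' @param max_attempts Attempt cap per expression.
#' @param great_threshold,good_threshold Mean-accuracy cutoffs in (0, 1].
#' @param expression_sequence Ordered seven-class names presented by the
#'   avatar.
#' @param frame_rate_hz Recognition rate used to convert seconds to frames.
#' @return A `session_config` list.
#' @export
session_config <- function(window_seconds = 5, cooldown_seconds = 3,
                           max_attempts = 3L, great_threshold = 0.80,
                           good_threshold = 0.50,
                           expression_sequence = label_scheme()$seven_classes,
                           frame_rate_hz = 3.2) {
  if (!(good_threshold > 0 && good_threshold < great_threshold &&
        great_threshold <= 1)) {
    stop_fm("config", "thresholds must satisfy 0 < good < great <= 1")
  }
  if (max_attempts < 1) stop_fm("config", "max_attempts must be >= 1")
  if (window_seconds <= 0 || frame_rate_hz <= 0) {
    stop_fm("config", "window_seconds and frame_rate_hz must be positive")
  }
  structure(list(window_seconds = window_seconds,
                 cooldown_seconds = cooldown_seconds,
                 max_attempts = as.integer(max_attempts),
                 great_threshold = great_threshold,
                 good_threshold = good_threshold,
                 expression_sequence = expression_sequence,
                 frame_rate_hz = frame_rate_hz),
            class = "session_config")
}

#' Frames per mimicry window
#' @param config A [session_config()].
#' @return Integer number of frames classified per attempt.
#' @export
window_frames <- function(config) {
  max(1L, as.integer(round(config$window_seconds * config$frame_rate_hz)))
}

#' Feedback string for a mean window accuracy
#'
#' `"Great Job!"` at or above the great threshold (default 80%),
#' `"Good Job!"` from the good threshold (default 50%, inclusive) up to it,
#' `"Try Again!"` below.
#'
#' @param mean_accuracy Value in \[0, 1\].
#' @param config A [session_config()].
#' @return One of `"Great Job!"`, `"Good Job!"`, `"Try Again!"`.
#' @export
feedback_for <- function(mean_accuracy, config = session_config()) {
  if (!is.finite(mean_accuracy) || mean_accuracy < 0 || mean_accuracy > 1) {
    stop_fm("range", "mean accuracy must lie in [0, 1]")
  }
  if (mean_accuracy >= config$great_threshold) "Great Job!"
  else if (mean_accuracy >= config$good_threshold) "Good Job!"
  else "Try Again!"
}

# classify a window of frames: returns binary labels, one per valid frame.
# `model` is either a trained_model or a function(frames, expression) that
# returns binary labels directly (used for stubbed/oracle classifiers).
classify_window <- function(frames, reference, expression, model, table,
                            scheme) {
  if (is.function(model)) return(model(frames, expression))
  feats <- extract_feature_frame(frames, reference, table)
  predict_model(model, as.matrix(feats))$labels
}

#' Run one mimicry attempt over a window of frames
#'
#' Each frame is feature-extracted against the neutral reference and
#' classified; the attempt's mean accuracy is the fraction of frame
#' predictions matching the binary image of the avatar's expression, and the
#' feedback string follows [feedback_for()]. Frames failing face validity
#' (all-zero or non-finite landmark clouds) are skipped and excluded from
#' the denominator; if every frame fails, a face-not-recognized error is
#' raised for the attempt.
#'
#' @param frames List of `landmark_frame`s supplying the window.
#' @param reference Neutral `landmark_frame`.
#' @param expression Seven-class name the avatar displayed.
#' @param model A `trained_model`, or a function `(frames, expression)`
#'   returning binary labels (stub classifiers for testing).
#' @param config A [session_config()].
#' @param table The `feature_table` in use.
#' @param attempt_number Attempt index within \[1, max_attempts\].
#' @return An `attempt_result` with the per-frame predictions, mean accuracy,
#'   feedback, and skipped-frame count.
#' @export
run_attempt <- function(frames, reference, expression, model,
                        config = session_config(),
                        table = default_feature_table(),
                        attempt_number = 1L) {
  scheme <- if (is.function(model)) label_scheme() else model$label_scheme
  if (!expression %in% scheme$seven_classes) {
    stop_fm("label", sprintf("unknown expression: %s", expression))
  }
  valid <- vapply(frames, frame_valid, logical(1))
  n_skipped <- sum(!valid)
  if (!any(valid)) {
    stop_fm("face_not_recognized",
            sprintf("no valid face frames in the %s attempt window", expression))
  }
  preds <- classify_window(frames[valid], reference, expression, model,
                           table, scheme)
  target <- map_to_binary(expression, scheme)
  mean_acc <- mean(preds == target)
  structure(list(expression = expression,
                 attempt_number = as.integer(attempt_number),
                 frame_predictions = preds,
                 skipped_frames = n_skipped,
                 mean_accuracy = mean_acc,
                 feedback = feedback_for(mean_acc, config)),
            class = "attempt_result")
}

#' @export
print.attempt_result <- function(x, ...) {
  cat(sprintf("<attempt_result> %s, attempt %d: accuracy %.3f -> %s\n",
              x$expression, x$attempt_number, x$mean_accuracy, x$feedback))
  invisible(x)
}

#' Run a full mimicry session with retry queueing
#'
#' Presents the configured expression sequence in order. After a
#' `"Try Again!"` attempt the failed expression is re-enqueued at the end of
#' the current lineup, up to `max_attempts` total attempts per expression.
#' Feedback is logged for every attempt, including a final failed one.
#'
#' @param stream_provider Function `(expression, attempt_number)` returning
#'   the window's list of `landmark_frame`s (frame-driven time).
#' @param model Classifier as in [run_attempt()].
#' @param reference Neutral `landmark_frame`.
#' @param config A [session_config()].
#' @param table The `feature_table` in use.
#' @param subject_id Logged subject identifier.
#' @return A `session_log`: attempts in presentation order, per-expression
#'   attempt counts, and the configuration used.
#' @export
run_session <- function(stream_provider, model, reference,
                        config = session_config(),
                        table = default_feature_table(),
                        subject_id = "s00") {
  if (!length(config$expression_sequence)) {
    stop_fm("config", "expression_sequence must be non-empty")
  }
  queue <- config$expression_sequence
  attempts_done <- stats::setNames(integer(length(unique(queue))), unique(queue))
  log <- list()
  frame_clock <- 0L
  while (length(queue)) {
    expr <- queue[1]
    queue <- queue[-1]
    k <- attempts_done[[expr]] + 1L
    frames <- stream_provider(expr, k)
    res <- run_attempt(frames, reference, expr, model, config, table,
                       attempt_number = k)
    res$frame_start <- frame_clock
    frame_clock <- frame_clock + length(frames)
    attempts_done[[expr]] <- k
    log[[length(log) + 1L]] <- res
    if (res$feedback == "Try Again!" && k < config$max_attempts) {
      queue <- c(queue, expr)
    }
  }
  structure(list(subject_id = subject_id,
                 attempts = log,
                 attempt_counts = attempts_done,
                 config = config),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> subject %s: %d attempts over %d expressions\n",
              x$subject_id, length(x$attempts), length(x$attempt_counts)))
  invisible(x)
}

#' Per-expression counts of "Try Again!" feedback
#'
#' Counts feedback events, not expressions: a final failed attempt is
#' counted, matching the study's reporting convention.
#'
#' @param log A `session_log`, or a list of them (counts are summed).
#' @param scheme A [label_scheme()] fixing the class order of the output.
#' @return Named integer vector over the seven class names.
#' @export
try_again_counts <- function(log, scheme = label_scheme()) {
  logs <- if (inherits(log, "session_log")) list(log) else log
  counts <- stats::setNames(integer(length(scheme$seven_classes)),
                            scheme$seven_classes)
  for (l in logs) {
    for (a in l$attempts) {
      if (a$feedback == "Try Again!") {
        counts[[a$expression]] <- counts[[a$expression]] + 1L
      }
    }
  }
  counts
}

#' Write / read a session log as JSON lines
#'
#' One attempt per line; a `meta` first line records subject and config.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @export
write_session_jsonl <- function(log, path) {
  meta <- jsonlite::toJSON(list(type = "meta", subject_id = log$subject_id,
                                config = unclass(log$config)),
                           auto_unbox = TRUE, digits = NA)
  lines <- vapply(log$attempts, function(a) {
    jsonlite::toJSON(list(type = "attempt", expression = a$expression,
                          attempt_number = a$attempt_number,
                          frame_predictions = a$frame_predictions,
                          skipped_frames = a$skipped_frames,
                          mean_accuracy = a$mean_accuracy,
                          feedback = a$feedback,
                          frame_start = a$frame_start),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(meta, lines), path)
  invisible(path)
}

#' @rdname write_session_jsonl
#' @export
read_session_jsonl <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON)
  meta <- objs[[1]]
  attempts <- lapply(objs[-1], function(o) {
    structure(list(expression = o$expression,
                   attempt_number = o$attempt_number,
                   frame_predictions = o$frame_predictions,
                   skipped_frames = o$skipped_frames,
                   mean_accuracy = o$mean_accuracy,
                   feedback = o$feedback,
                   frame_start = o$frame_start),
              class = "attempt_result")
  })
  counts_tab <- table(vapply(attempts, `[[`, character(1), "expression"))
  cfg <- meta$config
  config <- session_config(cfg$window_seconds, cfg$cooldown_seconds,
                           cfg$max_attempts, cfg$great_threshold,
                           cfg$good_threshold, cfg$expression_sequence,
                           cfg$frame_rate_hz)
  counts <- stats::setNames(as.integer(counts_tab), names(counts_tab))
  structure(list(subject_id = meta$subject_id, attempts = attempts,
                 attempt_counts = counts, config = config),
            class = "session_log")
}

#' Summarize a session log as a data frame
#'
#' One row per attempt: expression, attempt number, mean accuracy, feedback.
#'
#' @param log A `session_log`.
#' @return Data frame summary (also the CSV log format).
#' @export
session_summary <- function(log) {
  data.frame(
    subject_id = log$subject_id,
    expression = vapply(log$attempts, `[[`, character(1), "expression"),
    attempt_number = vapply(log$attempts, `[[`, integer(1), "attempt_number"),
    mean_accuracy = vapply(log$attempts, `[[`, numeric(1), "mean_accuracy"),
    skipped_frames = vapply(log$attempts, `[[`, numeric(1), "skipped_frames"),
    feedback = vapply(log$attempts, `[[`, character(1), "feedback"))
}
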