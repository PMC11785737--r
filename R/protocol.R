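#' Command grammar of the two-process handshake
#'
#' The interface process (avatar GUI) and the recognition process exchange
#' one-line text commands. Verbs are matched case-sensitively; a payload, if
#' any, is the space-separated suffix: `Initialize` carries a user ID and
#' `Start ER` carries the avatar's pre-set seven-class emotion.
#'
#' @param verb One of the protocol verbs.
#' @param payload Optional payload string.
#' @return A `protocol_command`.
#' @export
protocol_command <- function(verb, payload = NULL) {
  verbs <- c("Initialize", "initialization complete", "Ready01", "Capture",
             "Ready02", "Start ER", "Wait", "Ready", "Stop",
             "Terminating code", "FaceNotRecognized", "Next")
  if (!verb %in% verbs) {
    stop_fm("protocol", sprintf("unknown protocol verb: %s", verb))
  }
  needs_payload <- verb %in% c("Initialize", "Start ER")
  if (needs_payload && is.null(payload)) {
    stop_fm("protocol", sprintf("verb '%s' requires a payload", verb))
  }
  if (!needs_payload && !is.null(payload)) {
    stop_fm("protocol", sprintf("verb '%s' carries no payload", verb))
  }
  if (verb == "Start ER" && !payload %in% label_scheme()$seven_classes) {
    stop_fm("protocol", sprintf("Start ER payload must be a seven-class name, got '%s'",
                                payload))
  }
  structure(list(verb = verb, payload = payload), class = "protocol_command")
}

#' Parse / format one command line
#'
#' @param line A single command line, e.g. `"Start ER happiness"`.
#' @return `parse_command` returns a `protocol_command`; `format_command`
#'   its one-line text form.
#' @export
parse_command <- function(line) {
  line <- trimws(line)
  # multi-word verbs first so "Start ER happiness" parses as verb + payload
  for (v in c("initialization complete", "Terminating code", "Start ER",
              "Initialize", "FaceNotRecognized", "Ready01", "Ready02",
              "Capture", "Ready", "Wait", "Stop", "Next")) {
    if (line == v) return(protocol_command(v))
    if (startsWith(line, paste0(v, " "))) {
      return(protocol_command(v, substring(line, nchar(v) + 2)))
    }
  }
  stop_fm("protocol", sprintf("unparseable command line: '%s'", line))
}

#' @rdname parse_command
#' @export
format_command <- function(cmd) {
  if (is.null(cmd$payload)) cmd$verb else paste(cmd$verb, cmd$payload)
}

#' Fresh protocol state
#'
#' Phases: `idle` -> (`Initialize`) -> `awaiting_capture` -> (`Capture`) ->
#' `captured` -> (`Start ER`) -> `recognizing` -> (`Wait`/`Ready` cooldown)
#' -> `cooldown` -> (`Next`) back to `captured`, until `Stop` enters the
#' absorbing `terminated` phase.
#'
#' @return A `protocol_state`.
#' @export
protocol_state <- function() {
  structure(list(phase = "idle", user_id = NULL, active_expression = NULL),
            class = "protocol_state")
}

#' Advance the handshake state machine by one incoming command
#'
#' Pure function of `(state, command)`. Legal transitions emit the protocol's
#' replies: `Initialize` answers `initialization complete` then `Ready01`;
#' `Capture` answers `Ready02`; `Start ER` starts recognition; `Wait` during
#' the post-recognition cooldown answers `Ready`; `Stop` answers
#' `Terminating code` and terminates.
#'
#' @param state A `protocol_state`.
#' @param command A `protocol_command` (or a command line string).
#' @return List with the new `state` and `replies` (list of commands).
#' @export
protocol_step <- function(state, command) {
  if (is.character(command)) command <- parse_command(command)
  phase <- state$phase
  violate <- function() {
    stop_fm("protocol", sprintf(
      "command '%s' is illegal in phase '%s'", command$verb, phase),
      phase = phase, verb = command$verb)
  }
  replies <- list()
  if (phase == "terminated") violate()
  if (command$verb == "Stop") {
    if (phase == "idle") violate()
    state$phase <- "terminated"
    state$active_expression <- NULL
    return(list(state = state,
                replies = list(protocol_command("Terminating code"))))
  }
  switch(command$verb,
    "Initialize" = {
      if (phase != "idle") violate()
      state$user_id <- command$payload
      state$phase <- "awaiting_capture"
      replies <- list(protocol_command("initialization complete"),
                      protocol_command("Ready01"))
    },
    "Capture" = {
      if (phase != "awaiting_capture") violate()
      state$phase <- "captured"
      replies <- list(protocol_command("Ready02"))
    },
    "Start ER" = {
      if (!phase %in% c("captured", "cooldown")) violate()
      state$phase <- "recognizing"
      state$active_expression <- command$payload
    },
    "Wait" = {
      if (phase != "recognizing") violate()
      state$phase <- "cooldown"
      state$active_expression <- NULL
      replies <- list(protocol_command("Ready"))
    },
    "FaceNotRecognized" = {
      if (phase != "recognizing") violate()
      replies <- list(protocol_command("FaceNotRecognized"))
    },
    "Next" = {
      if (phase != "cooldown") violate()
      state$phase <- "captured"
    },
    violate())
  list(state = state, replies = replies)
}

#' Replay and validate a recorded command exchange
#'
#' Feeds the interface-side command lines through [protocol_step()] and
#' checks the recorded replies against the emitted ones.
#'
#' @param trace Character vector of lines: incoming commands, each optionally
#'   followed by lines of the form `"> <reply>"` recording the replies.
#' @return List with `valid`, `position` of the first violation (`NA` if
#'   valid), `reason`, and the annotated trace data frame.
#' @export
protocol_transcribe <- function(trace) {
  if (!length(trace)) stop_fm("protocol", "empty trace")
  state <- protocol_state()
  rows <- list()
  i <- 1L
  while (i <= length(trace)) {
    line <- trace[i]
    if (startsWith(line, ">")) {
      return(list(valid = FALSE, position = i,
                  reason = "reply line with no preceding command",
                  trace = do.call(rbind, rows)))
    }
    step_res <- tryCatch(protocol_step(state, line), fm_error = function(e) e)
    if (inherits(step_res, "fm_error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = i, line = line, phase = state$phase, ok = FALSE)
      return(list(valid = FALSE, position = i,
                  reason = conditionMessage(step_res),
                  trace = do.call(rbind, rows)))
    }
    expected <- vapply(step_res$replies, format_command, character(1))
    j <- i + 1L
    got <- character(0)
    while (j <= length(trace) && startsWith(trace[j], ">")) {
      got <- c(got, trimws(substring(trace[j], 2)))
      j <- j + 1L
    }
    if (!identical(got, expected)) {
      return(list(valid = FALSE, position = i,
                  reason = sprintf("expected replies [%s], recorded [%s]",
                                   paste(expected, collapse = "; "),
                                   paste(got, collapse = "; ")),
                  trace = do.call(rbind, rows)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      position = i, line = line, phase = step_res$state$phase, ok = TRUE)
    state <- step_res$state
    i <- j
  }
  list(valid = TRUE, position = NA_integer_, reason = "",
       trace = do.call(rbind, rows))
}

# ---- transports -------------------------------------------------------------

#' In-memory and file-based command transports
#'
#' A transport carries one-line commands between the interface and the
#' recognition process. The in-memory transport is a pair of queues; the
#' file transport is the deployed mechanism: two append-only UTF-8 text
#' files (interface -> engine and engine -> interface), one command per
#' line, polled for appended lines.
#'
#' @param dir Directory in which the file transport keeps its two files.
#' @return A transport object with `send(channel, line)` and
#'   `receive(channel)` functions; channels are `"to_engine"` and
#'   `"to_interface"`.
#' @export
transport_memory <- function() {
  env <- new.env(parent = emptyenv())
  env$to_engine <- character(0)
  env$to_interface <- character(0)
  env$cursor <- c(to_engine = 0L, to_interface = 0L)
  list(
    send = function(channel, line) {
      env[[channel]] <- c(env[[channel]], line)
      invisible(NULL)
    },
    receive = function(channel) {
      pos <- env$cursor[[channel]]
      new <- env[[channel]][seq_len(length(env[[channel]]) - pos) + pos]
      env$cursor[[channel]] <- length(env[[channel]])
      new
    })
}

#' @rdname transport_memory
#' @export
transport_file <- function(dir = tempfile("protocol")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(to_engine = file.path(dir, "interface_to_engine.txt"),
             to_interface = file.path(dir, "engine_to_interface.txt"))
  for (p in paths) if (!file.exists(p)) file.create(p)
  env <- new.env(parent = emptyenv())
  env$cursor <- c(to_engine = 0L, to_interface = 0L)
  list(
    send = function(channel, line) {
      con <- file(paths[[channel]], open = "a", encoding = "UTF-8")
      on.exit(close(con))
      writeLines(line, con)
      invisible(NULL)
    },
    receive = function(channel) {
      all_lines <- readLines(paths[[channel]], encoding = "UTF-8")
      pos <- env$cursor[[channel]]
      new <- all_lines[seq_len(length(all_lines) - pos) + pos]
      env$cursor[[channel]] <- length(all_lines)
      new
    })
}

#' Drive the recognition-side state machine over a transport
#'
#' Sends each interface command over the transport, lets the engine poll,
#' step its state machine and post replies, and collects the full annotated
#' exchange. Identical inputs produce identical traces on the in-memory and
#' file transports.
#'
#' @param commands Character vector of interface-side command lines.
#' @param transport A transport from [transport_memory()] or
#'   [transport_file()].
#' @return Character vector trace: each command line followed by its replies
#'   prefixed with `"> "` (the format [protocol_transcribe()] reads).
#' @export
protocol_exchange <- function(commands, transport = transport_memory()) {
  state <- protocol_state()
  trace <- character(0)
  for (cmd in commands) {
    transport$send("to_engine", cmd)
    incoming <- transport$receive("to_engine")
    for (line in incoming) {
      res <- protocol_step(state, line)
      state <- res$state
      for (r in res$replies) transport$send("to_interface", format_command(r))
      replies <- transport$receive("to_interface")
      trace <- c(trace, line,
                 if (length(replies)) paste(">", replies))
    }
  }
  trace
}
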