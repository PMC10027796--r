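# ExperimentSession: the top-level container for one experimental run —
# participant metadata, global config, the trial list, validation results —
# with run flow and single-file JSON serialization.

#' Create an experiment session
#'
#' @param metadata Participant metadata (\code{\link{param_set}} or named
#'   list): participant code, demographics, etc.
#' @param config Global session configuration. The flag
#'   \code{continue_on_error} (default \code{FALSE}) controls whether an
#'   uncaught task failure aborts the run or continues with the next trial.
#' @param trials Optional list of \code{\link{trial_record}} objects.
#' @return An object of class \code{"vr_session"}.
#' @export
experiment_session <- function(metadata = param_set(), config = param_set(),
                               trials = list()) {
  s <- new.env(parent = emptyenv())
  s$metadata <- as_param_set(metadata)
  s$config <- as_param_set(config)
  s$trials <- trials
  s$validations <- list()
  s$start_time <- NA_real_
  s$end_time <- NA_real_
  class(s) <- "vr_session"
  s
}

#' @export
print.vr_session <- function(x, ...) {
  statuses <- vapply(x$trials, function(t) t$status, character(1))
  cat(sprintf("<session> %d trials (%s), %d validation(s)\n",
              length(x$trials),
              paste(sprintf("%d %s", table(statuses),
                            names(table(statuses))), collapse = ", "),
              length(x$validations)))
  invisible(x)
}

#' Add trials to a session
#' @param session A \code{\link{experiment_session}}.
#' @param trials List of \code{\link{trial_record}} objects. Creation
#'   indices must be unique within the session.
#' @export
add_trials <- function(session, trials) {
  all_trials <- c(session$trials, trials)
  idx <- vapply(all_trials, function(t) t$index, integer(1))
  if (anyDuplicated(idx)) stop("trial indices must be unique")
  session$trials <- all_trials
  invisible(session)
}

#' Run all trials of a session
#'
#' Iterates over the session's trials in list order. For each trial the
#' status is set to \code{running}, the optional \code{pre_task}, the
#' \code{main_task} and the optional \code{post_task} are called in that
#' order (each receives the trial, the session and the clock), and the
#' status becomes \code{done}. Presentation numbers 1..N are assigned in
#' run order. An uncaught error in any task marks that trial
#' \code{status = "error"}; the run then continues with the next trial when
#' \code{config$continue_on_error} is \code{TRUE} and aborts otherwise
#' (remaining trials stay \code{pending}).
#'
#' @param session A \code{\link{experiment_session}} with at least one trial.
#' @param main_task \code{function(trial, session, clock)}.
#' @param pre_task,post_task Optional task functions with the same signature.
#' @param clock A \code{\link{frame_clock}} (passed through to the tasks).
#' @return The session, invisibly.
#' @export
run_experiment <- function(session, main_task, pre_task = NULL,
                           post_task = NULL, clock = frame_clock()) {
  if (length(session$trials) == 0)
    stop("run error: session has no trials", call. = FALSE)
  continue_on_error <- isTRUE(session$config$continue_on_error)
  if (is.na(session$start_time)) session$start_time <- clock$time
  number <- 0L
  for (trial in session$trials) {
    number <- number + 1L
    trial$number <- number
    set_trial_status(trial, "running")
    ok <- tryCatch({
      if (!is.null(pre_task)) pre_task(trial, session, clock)
      main_task(trial, session, clock)
      if (!is.null(post_task)) post_task(trial, session, clock)
      TRUE
    }, error = function(e) {
      trial$results <- as_param_set(c(unclass(trial$results),
                                      list(error_message = conditionMessage(e))))
      FALSE
    })
    set_trial_status(trial, if (ok) "done" else "error")
    if (!ok && !continue_on_error) break
  }
  session$end_time <- clock$time
  invisible(session)
}

# --- serialization ----------------------------------------------------------

trial_to_list <- function(trial) {
  list(
    index = trial$index,
    number = if (is.na(trial$number)) NULL else trial$number,
    block = trial$block,
    status = trial$status,
    params = ps_to_list(trial$params),
    results = ps_to_list(trial$results),
    events = lapply(trial$events, function(ev) {
      out <- list(time = ev$time, frame = ev$frame, label = ev$label)
      if (!is.null(ev$payload)) out$payload <- ps_to_list(ev$payload)
      out
    }),
    samples = if (is.null(trial$samples)) NULL
              else samples_to_columns(trial$samples)
  )
}

trial_from_list <- function(x) {
  tr <- trial_record(as_param_set(x$params), index = x$index,
                     block = if (is.null(x$block)) 0L else x$block)
  tr$number <- if (is.null(x$number)) NA_integer_ else as.integer(x$number)
  tr$status <- x$status
  tr$results <- as_param_set(x$results)
  tr$events <- lapply(x$events, function(ev) {
    list(time = ev$time, frame = as.integer(ev$frame), label = ev$label,
         payload = if (is.null(ev$payload)) NULL
                   else as_param_set(ev$payload))
  })
  if (!is.null(x$samples)) tr$samples <- samples_from_columns(x$samples)
  tr
}

# samples data.frame <-> columnar list (compact in JSON)
samples_to_columns <- function(df) {
  lapply(as.list(df), function(col) {
    if (is.character(col)) lapply(col, function(v) if (is.na(v)) NULL else v)
    else lapply(col, function(v) if (is.na(v)) NULL else v)
  })
}

samples_from_columns <- function(cols) {
  out <- lapply(cols, function(col) {
    vals <- lapply(col, function(v) if (is.null(v)) NA else v)
    if (all(vapply(vals, function(v) is.na(v) || is.numeric(v), logical(1))))
      vapply(vals, function(v) if (is.na(v)) NA_real_ else as.numeric(v),
             numeric(1))
    else
      vapply(vals, function(v) if (is.na(v)) NA_character_
                               else as.character(v), character(1))
  })
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

session_to_list <- function(session) {
  list(
    metadata = ps_to_list(session$metadata),
    config = ps_to_list(session$config),
    start_time = if (is.na(session$start_time)) NULL else session$start_time,
    end_time = if (is.na(session$end_time)) NULL else session$end_time,
    validations = lapply(session$validations, validation_to_list),
    trials = lapply(session$trials, trial_to_list)
  )
}

#' Save / load a session as a single JSON file
#'
#' The entire session — metadata, config, validation results, and every
#' trial with its params, results, events and continuous samples — is
#' written as one JSON document. \code{load_session_json(save_session_json(s))}
#' reproduces all persisted fields exactly.
#'
#' @param session A \code{\link{experiment_session}}.
#' @param path Output file path.
#' @return \code{load_session_json} returns the reconstructed session;
#'   \code{save_session_json} returns \code{path} invisibly.
#' @export
save_session_json <- function(session, path) {
  doc <- session_to_list(session)
  check_serializable(doc, "session")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

check_serializable <- function(x, path) {
  if (is.null(x) || is.function(x)) {
    if (is.function(x))
      stop("serialization error: unserializable value at ", path,
           call. = FALSE)
    return(invisible())
  }
  if (is.environment(x))
    stop("serialization error: unserializable value at ", path, call. = FALSE)
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
      check_serializable(x[[i]], paste(path, key, sep = "."))
    }
  } else if (!is.atomic(x)) {
    stop("serialization error: unserializable value at ", path, call. = FALSE)
  }
  invisible()
}

#' @rdname save_session_json
#' @export
load_session_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  s <- experiment_session(metadata = as_param_set(doc$metadata),
                          config = as_param_set(doc$config))
  s$start_time <- if (is.null(doc$start_time)) NA_real_ else doc$start_time
  s$end_time <- if (is.null(doc$end_time)) NA_real_ else doc$end_time
  s$validations <- lapply(doc$validations, validation_from_list)
  s$trials <- lapply(doc$trials, trial_from_list)
  s
}

#' Write the per-trial results table
#'
#' One CSV row per trial: identifier columns (\code{number}, \code{index},
#' \code{block}, \code{status}), then all param keys, then all result keys
#' (the union across trials, in first-seen order); values missing for a
#' trial are written as empty cells.
#'
#' @param session A session, or a list of trials.
#' @param path Output CSV path.
#' @param append If \code{TRUE}, append rows without rewriting the header
#'   (incremental per-trial writing; the header is created when the file
#'   does not yet exist).
#' @export
save_trials_csv <- function(session, path, append = FALSE) {
  trials <- if (inherits(session, "vr_session")) session$trials else session
  pkeys <- character(0)
  rkeys <- character(0)
  for (t in trials) {
    pkeys <- union(pkeys, names(ps_flatten(t$params)))
    rkeys <- union(rkeys, names(ps_flatten(t$results)))
  }
  header <- c("number", "index", "block", "status",
              pkeys, paste0("result.", rkeys))
  rows <- vapply(trials, function(t) {
    fp <- ps_flatten(t$params)
    fr <- ps_flatten(t$results)
    cells <- c(if (is.na(t$number)) "" else as.character(t$number),
               as.character(t$index), as.character(t$block), t$status,
               vapply(pkeys, function(k)
                 if (k %in% names(fp)) format_scalar(fp[[k]]) else "",
                 character(1)),
               vapply(rkeys, function(k)
                 if (k %in% names(fr)) format_scalar(fr[[k]]) else "",
                 character(1)))
    paste(vapply(cells, csv_quote, character(1)), collapse = ",")
  }, character(1))
  if (append && file.exists(path)) {
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(rows, con)
  } else {
    writeLines(c(paste(vapply(header, csv_quote, character(1)),
                       collapse = ","), rows), path)
  }
  invisible(path)
}

csv_quote <- function(s) {
  if (grepl('[",\n]', s)) paste0('"', gsub('"', '""', s), '"') else s
}

#' Read a per-trial results table back
#'
#' Inverse of \code{\link{save_trials_csv}}: reconstructs trial records with
#' params and results (type-inferred).
#'
#' @param path CSV path written by \code{save_trials_csv}.
#' @return List of \code{\link{trial_record}} objects.
#' @export
load_trials_results_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  id_cols <- c("number", "index", "block", "status")
  res_cols <- grep("^result\\.", names(raw), value = TRUE)
  par_cols <- setdiff(names(raw), c(id_cols, res_cols))
  lapply(seq_len(nrow(raw)), function(i) {
    params <- list()
    for (k in par_cols) {
      v <- infer_scalar(raw[[k]][i])
      if (!is.null(v)) params[[k]] <- v
    }
    tr <- trial_record(ps_unflatten(as_param_set(params)),
                       index = as.integer(raw$index[i]),
                       block = as.integer(raw$block[i]))
    tr$number <- suppressWarnings(as.integer(raw$number[i]))
    tr$status <- raw$status[i]
    results <- list()
    for (k in res_cols) {
      v <- infer_scalar(raw[[k]][i])
      if (!is.null(v)) results[[sub("^result\\.", "", k)]] <- v
    }
    tr$results <- as_param_set(results)
    tr
  })
}
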