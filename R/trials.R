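# Trial records, factorial design generation, CSV import/export and
# block-aware randomization.

TRIAL_STATUSES <- c("pending", "running", "done", "error")

#' Create a trial record
#'
#' A trial is an environment-backed object holding its creation index
#' (0-based), presentation number (1-based, assigned when run), block,
#' status, stimulus parameters and (initially empty) results, plus optional
#' attached continuous samples and event logs.
#'
#' @param params A \code{\link{param_set}} (or named list) of trial
#'   parameters.
#' @param index 0-based creation index.
#' @param block Integer block number (>= 0), default 0.
#' @return An object of class \code{"vr_trial"}.
#' @export
trial_record <- function(params = param_set(), index = 0L, block = 0L) {
  if (block < 0) stop("block must be >= 0")
  tr <- new.env(parent = emptyenv())
  tr$index <- as.integer(index)
  tr$number <- NA_integer_
  tr$block <- as.integer(block)
  tr$status <- "pending"
  tr$params <- as_param_set(params)
  tr$results <- param_set()
  tr$samples <- NULL      # data.frame of per-frame samples, or NULL
  tr$events <- list()     # list of list(time, frame, label, payload)
  class(tr) <- "vr_trial"
  tr
}

#' @export
print.vr_trial <- function(x, ...) {
  cat(sprintf("<trial> index %d, number %s, block %d, status %s, %d params, %d results\n",
              x$index, ifelse(is.na(x$number), "-", x$number), x$block,
              x$status, length(x$params), length(x$results)))
  invisible(x)
}

#' Advance a trial's status
#'
#' Enforces the life cycle \code{pending -> running -> done|error}.
#' Results may be written only once the trial has started.
#'
#' @param trial A \code{\link{trial_record}}.
#' @param status New status.
#' @export
set_trial_status <- function(trial, status) {
  status <- match.arg(status, TRIAL_STATUSES)
  ok <- switch(trial$status,
    pending = status == "running",
    running = status %in% c("done", "error"),
    FALSE)
  if (!ok)
    stop("invalid trial status transition: ", trial$status, " -> ", status,
         call. = FALSE)
  trial$status <- status
  invisible(trial)
}

#' Store a result value on a trial
#'
#' @param trial A \code{\link{trial_record}}; must have started
#'   (status \code{running} or later).
#' @param key Result name.
#' @param value Scalar result value.
#' @export
set_trial_result <- function(trial, key, value) {
  if (trial$status == "pending")
    stop("results are writable only once the trial is running", call. = FALSE)
  res <- unclass(trial$results)
  res[[key]] <- value
  trial$results <- as_param_set(res)
  invisible(trial)
}

#' Specify a full-factorial design
#'
#' @param factors Named list: factor name -> vector of levels (each factor
#'   must have at least one level).
#' @param repetitions Number of repetitions of the full crossing (>= 1).
#' @param block_factor Optional name of a factor whose level index is used
#'   as the trial's block number.
#' @return An object of class \code{"design_spec"}.
#' @export
design_spec <- function(factors, repetitions = 1L, block_factor = NULL) {
  if (length(factors) == 0) stop("design error: no factors given")
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("design error: factors must be named")
  if (any(vapply(factors, length, integer(1)) == 0))
    stop("design error: every factor needs at least one level")
  if (repetitions < 1) stop("design error: repetitions must be >= 1")
  if (!is.null(block_factor) && !block_factor %in% names(factors))
    stop("design error: unknown block factor '", block_factor, "'")
  structure(list(factors = factors, repetitions = as.integer(repetitions),
                 block_factor = block_factor),
            class = "design_spec")
}

#' Generate trials for a full-factorial design
#'
#' Produces \code{prod(levels) * repetitions} trials. The last factor varies
#' fastest within a repetition and repetitions are the outermost loop; each
#' trial's params hold one factor-level combination plus a 1-based
#' \code{repetition} key.
#'
#' @param spec A \code{\link{design_spec}} (or a bare named list of factors).
#' @param repetitions Used when \code{spec} is a bare factor list.
#' @return A list of \code{\link{trial_record}} objects.
#' @examples
#' trials <- make_factorial_design(design_spec(
#'   list(pos = c("L", "R"), cue = c("pro", "anti")), repetitions = 2))
#' length(trials)  # 8
#' @export
make_factorial_design <- function(spec, repetitions = 1L) {
  if (!inherits(spec, "design_spec"))
    spec <- design_spec(spec, repetitions)
  fnames <- names(spec$factors)
  # last factor varies fastest -> build grid with expand.grid on reversed
  # factors, then reorder columns
  grid <- expand.grid(rev(spec$factors), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(fnames)), drop = FALSE]
  names(grid) <- fnames
  trials <- vector("list", nrow(grid) * spec$repetitions)
  idx <- 0L
  for (rep_i in seq_len(spec$repetitions)) {
    for (row_i in seq_len(nrow(grid))) {
      params <- as.list(grid[row_i, , drop = FALSE])
      params <- lapply(params, function(v) v[[1]])
      params$repetition <- rep_i
      block <- 0L
      if (!is.null(spec$block_factor)) {
        block <- match(params[[spec$block_factor]],
                       spec$factors[[spec$block_factor]])
      }
      trials[[idx + 1L]] <- trial_record(params, index = idx, block = block)
      idx <- idx + 1L
    }
  }
  trials
}

#' Load trials from a CSV design file
#'
#' One row per trial; columns become trial parameters with type inference
#' (integer, then float, then the boolean literals \code{true}/\code{false},
#' else text).
#'
#' @param path CSV file with a mandatory header row.
#' @param block_column Optional name of a column holding integer block
#'   numbers; it populates each trial's \code{block} field and is not
#'   duplicated into the params.
#' @return A list of \code{\link{trial_record}} objects.
#' @export
load_trials_csv <- function(path, block_column = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(names(raw)))
    stop("format error: duplicate header names in ", path, call. = FALSE)
  if (!is.null(block_column) && !block_column %in% names(raw))
    stop("format error: block column '", block_column, "' not found in ",
         path, call. = FALSE)
  param_cols <- setdiff(names(raw), block_column)
  lapply(seq_len(nrow(raw)), function(i) {
    params <- list()
    for (k in param_cols) params[k] <- list(infer_scalar(raw[[k]][i]))
    block <- 0L
    if (!is.null(block_column)) {
      block <- suppressWarnings(as.integer(raw[[block_column]][i]))
      if (is.na(block))
        stop("format error: non-integer block value in row ", i,
             ", column '", block_column, "'", call. = FALSE)
    }
    trial_record(ps_unflatten(as_param_set(params)),
                 index = i - 1L, block = block)
  })
}

#' Randomize trial order
#'
#' Returns a permutation of \code{trials}. With \code{within_blocks = TRUE},
#' trials are first grouped by ascending block number and shuffled only
#' within each block, so the block sequence is preserved. The permutation is
#' deterministic given \code{seed}; the caller's RNG state is untouched.
#'
#' @param trials List of \code{\link{trial_record}} objects.
#' @param seed Integer seed.
#' @param within_blocks Shuffle only within blocks?
#' @return The permuted list of trials (same objects).
#' @export
randomize_trials <- function(trials, seed, within_blocks = FALSE) {
  n <- length(trials)
  if (n == 0) return(trials)
  perm <- with_local_seed(seed, {
    if (within_blocks) {
      blocks <- vapply(trials, function(t) t$block, integer(1))
      out <- integer(0)
      for (b in sort(unique(blocks))) {
        members <- which(blocks == b)
        out <- c(out, if (length(members) == 1) members
                      else sample(members))
      }
      out
    } else {
      sample.int(n)
    }
  })
  trials[perm]
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
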