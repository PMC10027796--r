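# ParamSet: an ordered key -> scalar mapping used for session config, trial
# parameters and trial results, with lossless JSON and single-row-CSV
# round trips. One level of nesting is allowed; nested maps are flattened
# to "parent.child" keys for CSV.

#' Create a parameter set
#'
#' An ordered mapping of string keys to scalar values (number, text, boolean
#' or NULL). Nested parameter sets are allowed one level deep; they serialize
#' as nested JSON objects and as flattened \code{parent.child} CSV columns.
#'
#' @param ... Named scalar values (or one-level-deep named lists).
#' @return An object of class \code{"param_set"} (a named list).
#' @examples
#' p <- param_set(subject = "S01", age = 29, lefthanded = FALSE)
#' p$age
#' @export
param_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.null(names(entries)) &&
      is.list(entries[[1]])) {
    entries <- entries[[1]]
  }
  as_param_set(entries)
}

#' Coerce a named list to a parameter set
#' @param x A named list of scalars (one nesting level allowed).
#' @export
as_param_set <- function(x) {
  if (inherits(x, "param_set")) return(x)
  x <- as.list(x)
  if (length(x) > 0) {
    nm <- names(x)
    if (is.null(nm) || any(nm == "")) stop("param_set keys must be named")
    if (anyDuplicated(nm)) stop("param_set keys must be unique")
    for (k in nm) {
      v <- x[[k]]
      if (is.list(v)) {
        if (any(vapply(v, is.list, logical(1))))
          stop("param_set allows only one level of nesting (key '", k, "')")
        x[[k]] <- as_param_set(v)
      } else if (!is.null(v) && (length(v) != 1 || !is.atomic(v))) {
        stop("param_set values must be scalars (key '", k, "')")
      }
    }
  }
  structure(x, class = c("param_set", "list"))
}

#' @export
print.param_set <- function(x, ...) {
  if (length(x) == 0) {
    cat("<param_set> (empty)\n")
    return(invisible(x))
  }
  cat("<param_set>\n")
  flat <- ps_flatten(x)
  for (k in names(flat)) {
    v <- flat[[k]]
    cat(sprintf("  %s: %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Flatten / unflatten one level of nesting
#'
#' \code{ps_flatten} turns \code{list(a = list(b = 1))} into a flat set with
#' key \code{"a.b"}; \code{ps_unflatten} reverses this.
#'
#' @param x A \code{\link{param_set}}.
#' @return A \code{param_set}.
#' @export
ps_flatten <- function(x) {
  out <- list()
  for (k in names(x)) {
    v <- x[[k]]
    if (inherits(v, "param_set") || (is.list(v) && !is.null(names(v)))) {
      for (k2 in names(v)) out[[paste(k, k2, sep = ".")]] <- v[[k2]]
    } else {
      out[k] <- list(v)  # preserves NULL values
    }
  }
  structure(out, class = c("param_set", "list"))
}

#' @rdname ps_flatten
#' @export
ps_unflatten <- function(x) {
  out <- list()
  for (k in names(x)) {
    if (grepl(".", k, fixed = TRUE)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("at most one nesting level: '", k, "'")
      if (is.null(out[[parts[1]]])) out[[parts[1]]] <- list()
      out[[parts[1]]][[parts[2]]] <- x[[k]]
    } else {
      out[k] <- list(x[[k]])
    }
  }
  as_param_set(out)
}

# Parse a character scalar using the package's CSV type-inference rule:
# integer, then float, then boolean literals true/false, else text.
infer_scalar <- function(s) {
  if (is.na(s) || identical(s, "")) return(NULL)
  if (grepl("^-?[0-9]+$", s)) {
    v <- suppressWarnings(as.integer(s))
    if (!is.na(v)) return(v)
    return(as.numeric(s))  # integer overflow -> float
  }
  if (grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s))
    return(as.numeric(s))
  if (s %in% c("true", "false")) return(s == "true")
  s
}

# Format a scalar for CSV output so that infer_scalar() inverts it.
format_scalar <- function(v) {
  if (is.null(v) || (length(v) == 1 && is.na(v))) return("")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, digits = 17, scientific = FALSE,
                                   trim = TRUE))
  as.character(v)
}

#' Read / write a parameter set as JSON
#'
#' @param x A \code{\link{param_set}}.
#' @param path File path.
#' @return \code{ps_from_json} returns a \code{param_set};
#'   \code{ps_to_json} returns \code{path} invisibly.
#' @export
ps_to_json <- function(x, path) {
  jsonlite::write_json(ps_to_list(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname ps_to_json
#' @export
ps_from_json <- function(path) {
  as_param_set(jsonlite::read_json(path, simplifyVector = FALSE))
}

# plain-list view (for embedding in session JSON)
ps_to_list <- function(x) {
  out <- lapply(unclass(x), function(v) {
    if (inherits(v, "param_set")) ps_to_list(v) else v
  })
  out
}

#' Read / write a parameter set as a single-row CSV
#'
#' Column names are the (flattened) keys; booleans are written as
#' \code{true}/\code{false}; \code{NULL} values as empty cells.
#'
#' @inheritParams ps_to_json
#' @export
ps_to_csv <- function(x, path) {
  flat <- ps_flatten(x)
  vals <- vapply(names(flat), function(k) format_scalar(flat[[k]]),
                 character(1))
  df <- as.data.frame(as.list(vals), optional = TRUE,
                      stringsAsFactors = FALSE)
  names(df) <- names(flat)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ps_to_csv
#' @export
ps_from_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != 1) stop("expected a single-row CSV for a param_set")
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  out <- list()
  for (k in names(df)) out[k] <- list(infer_scalar(df[[k]][1]))
  ps_unflatten(structure(out, class = c("param_set", "list")))
}
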