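# Eye-tracker validation: fixation-target layouts and angular data-quality
# metrics (accuracy = mean angular error, precision = SD of angular errors,
# RMSE of angular errors), per target and averaged.

#' Five-target cross validation layout
#'
#' The standard layout: one central target straight ahead plus four
#' peripheral targets displaced by \code{eccentricity_deg} along the
#' horizontal and vertical great circles, all on a sphere of radius
#' \code{depth_m} around the cyclopean origin. Positions are expressed
#' relative to the cyclopean origin with straight-ahead = +Z; add the head
#' position to place them in the world.
#'
#' @param eccentricity_deg Peripheral eccentricity in degrees, in (0, 45].
#' @param depth_m Viewing distance in meters (> 0).
#' @return A data frame with one row per target: \code{name},
#'   \code{h_offset_deg}, \code{v_offset_deg}, \code{depth_m},
#'   \code{x, y, z} (origin-relative position).
#' @examples
#' make_cross_layout(5, 0.5)
#' @export
make_cross_layout <- function(eccentricity_deg = 5, depth_m = 0.5) {
  if (!(eccentricity_deg > 0 && eccentricity_deg <= 45))
    stop("eccentricity must be in (0, 45] degrees", call. = FALSE)
  if (depth_m <= 0) stop("depth must be positive", call. = FALSE)
  e <- eccentricity_deg
  offs <- rbind(c(0, 0), c(-e, 0), c(e, 0), c(0, -e), c(0, e))
  names <- c("center", "left", "right", "down", "up")
  dirs <- t(apply(offs, 1, function(hv) offset_direction(hv[1], hv[2])))
  pos <- dirs * depth_m
  data.frame(name = names,
             h_offset_deg = offs[, 1], v_offset_deg = offs[, 2],
             depth_m = depth_m,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# Unit direction for angular offsets (h along the horizontal great circle,
# v along the vertical one) from straight-ahead +Z. For a pure horizontal or
# vertical offset the recomputed eccentricity is exact; for combined offsets
# it equals sqrt(h^2 + v^2) to small-angle accuracy.
offset_direction <- function(h_deg, v_deg) {
  if (h_deg == 0 && v_deg == 0) return(c(0, 0, 1))
  ecc <- sqrt(h_deg^2 + v_deg^2) * DEG2RAD
  # in-plane direction within the fronto-parallel (x, y) tangent plane
  u <- c(h_deg, v_deg) / sqrt(h_deg^2 + v_deg^2)
  c(sin(ecc) * u[1], sin(ecc) * u[2], cos(ecc))
}

new_validation_result <- function(per_target, timestamp = NA_real_) {
  structure(list(per_target = per_target, timestamp = timestamp),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  print(x$per_target, row.names = FALSE)
  s <- summarize_validation(x)
  cat(sprintf("  mean accuracy %.3f deg, SD %.3f deg, RMSE %.3f deg\n",
              s$mean_accuracy_deg, s$mean_sd_deg, s$mean_rmse_deg))
  invisible(x)
}

# metrics from a vector of angular errors (degrees)
angular_metrics <- function(errors) {
  n <- length(errors)
  c(accuracy_deg = mean(errors),
    sd_deg = if (n > 1) stats::sd(errors) else 0,
    rmse_deg = sqrt(mean(errors^2)),
    n_samples = n)
}

#' Run a gaze validation sequence
#'
#' Presents each target in order, records gaze for
#' \code{fixation_window_s} seconds at the recorder's clock rate, discards
#' the first \code{settle_s} seconds (saccade settling), and computes the
#' angular error of every remaining sample as the angle between the
#' recorded world gaze direction and the direction from the gaze origin to
#' the target. Per-target accuracy (mean error), precision (sample SD of
#' errors) and RMSE are stored, and the result is appended to
#' \code{session$validations}.
#'
#' @param session A \code{\link{experiment_session}}.
#' @param recorder A \code{\link{sample_recorder}} with a registered eye
#'   tracker.
#' @param targets Layout data frame from \code{\link{make_cross_layout}}
#'   (origin-relative positions).
#' @param origin World position of the cyclopean origin (head position).
#' @param fixate Optional callback \code{function(world_pos)} invoked before
#'   each target's window — used to point a simulated gaze source at the
#'   target; with real hardware the participant fixates instead.
#' @param fixation_window_s Recording window per target (s), default 1.
#' @param settle_s Initial portion discarded per target (s), default 0.2.
#' @return The \code{validation_result}, invisibly.
#' @export
run_validation <- function(session, recorder, targets,
                           origin = vec3(0, 0, 0), fixate = NULL,
                           fixation_window_s = 1.0, settle_s = 0.2) {
  if (is.null(recorder$eye_tracker))
    stop("no eye tracker registered", call. = FALSE)
  clock <- recorder$clock
  n_frames <- round(fixation_window_s * clock$rate)
  n_skip <- round(settle_s * clock$rate)
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    world_pos <- origin + c(targets$x[i], targets$y[i], targets$z[i])
    if (!is.null(fixate)) fixate(world_pos)
    errors <- numeric(0)
    for (f in seq_len(n_frames)) {
      clock$tick()
      record_frame(recorder)
      if (f <= n_skip) next
      g <- recorder$last_gaze
      # only gaze computed on this very frame counts (a source dropout must
      # not let stale data through)
      if (is.null(g) || !identical(recorder$last_gaze_frame, clock$frame))
        next
      to_target <- world_pos - g$ray$origin
      errors <- c(errors, angular_distance(g$ray$direction, to_target))
    }
    if (length(errors) == 0) {
      rows[[i]] <- data.frame(name = targets$name[i],
                              accuracy_deg = NA_real_, sd_deg = NA_real_,
                              rmse_deg = NA_real_, n_samples = 0L,
                              flagged = TRUE, stringsAsFactors = FALSE)
    } else {
      m <- angular_metrics(errors)
      rows[[i]] <- data.frame(name = targets$name[i],
                              accuracy_deg = m[["accuracy_deg"]],
                              sd_deg = m[["sd_deg"]],
                              rmse_deg = m[["rmse_deg"]],
                              n_samples = as.integer(m[["n_samples"]]),
                              flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  result <- new_validation_result(do.call(rbind, rows),
                                  timestamp = clock$time)
  session$validations[[length(session$validations) + 1L]] <- result
  invisible(result)
}

#' Summarize a validation result
#'
#' Unweighted means of per-target accuracy, precision SD and RMSE across
#' unflagged targets, plus the worst (largest-accuracy-error) target.
#'
#' @param result A \code{validation_result}.
#' @return A \code{\link{param_set}} with \code{mean_accuracy_deg},
#'   \code{mean_sd_deg}, \code{mean_rmse_deg}, \code{n_targets},
#'   \code{worst_target}, \code{worst_accuracy_deg}.
#' @export
summarize_validation <- function(result) {
  pt <- result$per_target[!result$per_target$flagged, , drop = FALSE]
  if (nrow(pt) == 0) stop("all validation targets flagged", call. = FALSE)
  worst <- which.max(pt$accuracy_deg)
  param_set(mean_accuracy_deg = mean(pt$accuracy_deg),
            mean_sd_deg = mean(pt$sd_deg),
            mean_rmse_deg = mean(pt$rmse_deg),
            n_targets = nrow(pt),
            worst_target = pt$name[worst],
            worst_accuracy_deg = pt$accuracy_deg[worst])
}

validation_to_list <- function(v) {
  list(timestamp = v$timestamp,
       per_target = lapply(seq_len(nrow(v$per_target)), function(i)
         as.list(v$per_target[i, , drop = FALSE])))
}

validation_from_list <- function(x) {
  rows <- lapply(x$per_target, function(r)
    data.frame(name = r$name,
               accuracy_deg = if (is.null(r$accuracy_deg)) NA_real_
                              else r$accuracy_deg,
               sd_deg = if (is.null(r$sd_deg)) NA_real_ else r$sd_deg,
               rmse_deg = if (is.null(r$rmse_deg)) NA_real_ else r$rmse_deg,
               n_samples = as.integer(r$n_samples),
               flagged = isTRUE(r$flagged), stringsAsFactors = FALSE))
  new_validation_result(do.call(rbind, rows),
                        timestamp = if (is.null(x$timestamp)) NA_real_
                                    else x$timestamp)
}

#' Write a validation report CSV (one row per target)
#' @param result A \code{validation_result}.
#' @param path Output CSV path.
#' @export
validation_report_csv <- function(result, path) {
  utils::write.csv(result$per_target, path, row.names = FALSE)
  invisible(path)
}
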