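# Frame clock, scene-object registry, and the frame-locked sample recorder:
# per-frame polling of tracked nodes and the eye tracker, world-space gaze
# computation, raycasting against pickable scene objects, event logging and
# sample CSV export.

#' Simulated display frame clock
#'
#' Drives all sampling: one tick per display refresh. Time is defined as
#' \code{frame / rate} seconds since session start, so the simulated clock
#' is exactly frame-locked and monotone.
#'
#' @param rate Refresh rate in Hz (default 90, a typical VR headset).
#' @return An object of class \code{"frame_clock"} with fields \code{rate},
#'   \code{frame} (0-based index) and \code{time} (s), and a method
#'   \code{$tick()} advancing one frame.
#' @export
frame_clock <- function(rate = 90) {
  stopifnot(rate > 0)
  clk <- new.env(parent = emptyenv())
  clk$rate <- rate
  clk$frame <- 0L
  clk$time <- 0
  clk$tick <- function() {
    clk$frame <- clk$frame + 1L
    clk$time <- clk$frame / clk$rate
    invisible(clk)
  }
  class(clk) <- "frame_clock"
  clk
}

#' Create a scene (object registry)
#'
#' Holds \code{\link{scene_primitives}} in registration order. Registration
#' order is the tie-break order for raycasts.
#'
#' @return An object of class \code{"vr_scene"}.
#' @export
scene <- function() {
  sc <- new.env(parent = emptyenv())
  sc$objects <- list()
  class(sc) <- "vr_scene"
  sc
}

#' Add an object to a scene
#' @param scene A \code{\link{scene}}.
#' @param prim A \code{\link{scene_primitives}} object with a unique id.
#' @export
scene_add <- function(scene, prim) {
  if (prim$id %in% names(scene$objects))
    stop("object id '", prim$id, "' already registered", call. = FALSE)
  scene$objects[[prim$id]] <- prim
  invisible(scene)
}

#' Get a scene object by id
#' @inheritParams scene_add
#' @param id Object id.
#' @export
scene_get <- function(scene, id) {
  if (!id %in% names(scene$objects))
    stop("unknown object id '", id, "'", call. = FALSE)
  scene$objects[[id]]
}

#' Change state of one or several scene objects at once
#'
#' Applies the given properties to every listed object, mirroring grouped
#' stimulus handling ("show/hide these objects"). Visibility and
#' pickability are independent: hiding an object does not remove it from
#' gaze raycasts unless \code{pickable = FALSE} is also set.
#'
#' @param scene A \code{\link{scene}}.
#' @param ids Character vector of object ids.
#' @param visible,pickable Optional logical flags.
#' @param pose Optional \code{\link{pose}}: sets the object center (and, for
#'   boxes, orientation).
#' @param scale Optional positive factor multiplying radius / half extents /
#'   plane extents.
#' @export
set_object_group_state <- function(scene, ids, visible = NULL,
                                   pickable = NULL, pose = NULL,
                                   scale = NULL) {
  for (id in ids) {
    obj <- scene_get(scene, id)
    if (!is.null(visible)) obj$visible <- visible
    if (!is.null(pickable)) obj$pickable <- pickable
    if (!is.null(pose)) {
      obj$center <- pose$position
      if (obj$shape == "box") obj$orientation <- pose$orientation
    }
    if (!is.null(scale)) {
      stopifnot(scale > 0)
      if (obj$shape == "sphere") obj$radius <- obj$radius * scale
      if (obj$shape == "box") obj$half_extents <- obj$half_extents * scale
      if (obj$shape == "rect_plane") {
        obj$width <- obj$width * scale
        obj$height <- obj$height * scale
      }
    }
    scene$objects[[id]] <- obj
  }
  invisible(scene)
}

# --- sample recorder --------------------------------------------------------

#' Create a frame-locked sample recorder
#'
#' Records one \emph{sample} per clock tick: the pose of every registered
#' tracked node plus, when an eye tracker is registered, the local gaze ray,
#' its world-space transform (using the head node's pose), and the result of
#' a raycast against all pickable scene objects (hit object id and 3D hit
#' point).
#'
#' @param scene A \code{\link{scene}} raycast against each frame.
#' @param clock A \code{\link{frame_clock}} supplying time and frame index.
#' @param head_node Id of the node whose pose maps tracker-local gaze to
#'   world space (default \code{"head"}).
#' @return An object of class \code{"sample_recorder"}.
#' @export
sample_recorder <- function(scene, clock, head_node = "head") {
  rec <- new.env(parent = emptyenv())
  rec$scene <- scene
  rec$clock <- clock
  rec$head_node <- head_node
  rec$nodes <- list()          # id -> function(time, frame) -> vr_pose
  rec$eye_tracker <- NULL      # function(time, frame) -> list(origin, direction)
  rec$buffer <- list()
  rec$nbuf <- 0L
  rec$trial_number <- NA_integer_
  rec$events <- list()
  rec$last_gaze <- NULL
  rec$last_gaze_frame <- NA_integer_
  class(rec) <- "sample_recorder"
  rec
}

#' Register a tracked node or the eye tracker
#'
#' A node source is a function \code{function(time, frame)} returning a
#' \code{\link{pose}}; the eye tracker source returns
#' \code{list(origin =, direction =)} in the head-tracker local frame. Every
#' registered node appears in all subsequent samples. Without an eye
#' tracker, recording still works and all gaze fields are marked invalid.
#'
#' @param recorder A \code{\link{sample_recorder}}.
#' @param id Unique node id (e.g. \code{"head"}, \code{"controller"}).
#' @param source Poll function (see above).
#' @export
register_node <- function(recorder, id, source) {
  if (id %in% names(recorder$nodes))
    stop("node id '", id, "' already registered", call. = FALSE)
  recorder$nodes[[id]] <- source
  invisible(recorder)
}

#' @rdname register_node
#' @export
register_eye_tracker <- function(recorder, source) {
  recorder$eye_tracker <- source
  invisible(recorder)
}

# column schema for the current node set (samples are stored as one numeric
# vector per frame under this layout, plus the hit-object id)
sample_schema <- function(recorder) {
  cols <- c("time", "frame", "trial")
  for (id in names(recorder$nodes)) {
    cols <- c(cols, paste0(id, c("_pos_x", "_pos_y", "_pos_z",
                                 "_yaw", "_pitch", "_roll")))
  }
  c(cols,
    paste0("gaze_local_origin_", c("x", "y", "z")),
    paste0("gaze_local_dir_", c("x", "y", "z")),
    paste0("gaze_world_origin_", c("x", "y", "z")),
    paste0("gaze_world_dir_", c("x", "y", "z")),
    paste0("gaze_hit_", c("x", "y", "z")))
}

#' Record one frame
#'
#' Polls every registered source exactly once at the clock's current time,
#' computes the world-space gaze ray and its closest scene intersection, and
#' appends the sample to the recorder's buffer. A failing source marks that
#' node's fields invalid for this frame; recording never aborts mid-trial.
#'
#' @param recorder A \code{\link{sample_recorder}}.
#' @return The recorded sample as a named list (invisibly).
#' @export
record_frame <- function(recorder) {
  time <- recorder$clock$time
  frame <- recorder$clock$frame
  num <- c(time, frame,
           if (is.na(recorder$trial_number)) NA_real_
           else recorder$trial_number)
  head_pose <- NULL
  for (id in names(recorder$nodes)) {
    p <- tryCatch(recorder$nodes[[id]](time, frame), error = function(e) NULL)
    if (is.null(p)) {
      num <- c(num, rep(NA_real_, 6))
    } else {
      if (id == recorder$head_node) head_pose <- p
      num <- c(num, p$position, quat_to_euler(p$orientation))
    }
  }
  gaze <- rep(NA_real_, 15)
  hit_id <- NA_character_
  if (!is.null(recorder$eye_tracker) && !is.null(head_pose)) {
    g <- tryCatch(recorder$eye_tracker(time, frame),
                  error = function(e) NULL)
    if (!is.null(g)) {
      wo <- transform_point(head_pose, g$origin)
      wd <- transform_direction(head_pose, g$direction)
      gaze[1:12] <- c(g$origin, g$direction, wo, wd)
      hit <- closest_intersection(ray(wo, wd), recorder$scene$objects)
      if (!is.null(hit)) {
        gaze[13:15] <- hit$point
        hit_id <- hit$id
      }
      recorder$last_gaze <- list(ray = ray(wo, wd),
                                 hit_object = if (is.na(hit_id)) NULL
                                              else hit_id,
                                 hit_point = if (is.null(hit)) NULL
                                             else hit$point)
      recorder$last_gaze_frame <- frame
    }
  }
  recorder$nbuf <- recorder$nbuf + 1L
  recorder$buffer[[recorder$nbuf]] <- list(num = unname(c(num, gaze)),
                                           hit = hit_id)
  invisible(recorder$buffer[[recorder$nbuf]])
}

#' Most recent gaze state
#'
#' Returns the last computed world gaze ray, hit object and hit point
#' without re-polling the eye tracker — for immediate fixation checks
#' between frames.
#'
#' @param recorder A \code{\link{sample_recorder}} with at least one
#'   recorded frame containing gaze data.
#' @return \code{list(ray, hit_object, hit_point)}; \code{hit_object} /
#'   \code{hit_point} are \code{NULL} when nothing was hit.
#' @export
current_gaze <- function(recorder) {
  if (is.null(recorder$last_gaze))
    stop("no gaze recorded yet", call. = FALSE)
  recorder$last_gaze
}

#' Start / finish a trial's sample buffer
#'
#' \code{recorder_start_trial} clears the buffer and tags subsequent samples
#' with the trial's presentation number; \code{recorder_collect} returns the
#' buffered samples as a data frame (one row per frame) and clears the
#' buffer.
#'
#' @param recorder A \code{\link{sample_recorder}}.
#' @param trial_number 1-based presentation number.
#' @export
recorder_start_trial <- function(recorder, trial_number) {
  recorder$buffer <- list()
  recorder$nbuf <- 0L
  recorder$events <- list()
  recorder$trial_number <- as.integer(trial_number)
  invisible(recorder)
}

#' @rdname recorder_start_trial
#' @export
recorder_collect <- function(recorder) {
  cols <- sample_schema(recorder)
  n <- recorder$nbuf
  mat <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  hits <- character(n)
  for (i in seq_len(n)) {
    mat[i, ] <- recorder$buffer[[i]]$num
    hits[i] <- recorder$buffer[[i]]$hit
  }
  df <- as.data.frame(mat)
  df$gaze_hit_object <- hits
  recorder$buffer <- list()
  recorder$nbuf <- 0L
  df
}

#' Log a timestamped event
#'
#' Events mark stimulus onsets/offsets and other discrete occurrences; they
#' are stamped with the clock's current time and frame and attached to the
#' current trial by the task code.
#'
#' @param recorder A \code{\link{sample_recorder}}.
#' @param label Event label string.
#' @param payload Optional \code{\link{param_set}} with event details.
#' @export
log_event <- function(recorder, label, payload = NULL) {
  ev <- list(time = recorder$clock$time, frame = recorder$clock$frame,
             label = label,
             payload = if (is.null(payload)) NULL else as_param_set(payload))
  recorder$events[[length(recorder$events) + 1L]] <- ev
  invisible(ev)
}

#' Export continuous samples to CSV
#'
#' One row per recorded sample. Columns, in fixed order: \code{time},
#' \code{frame}, \code{trial}, then per registered node
#' \code{<id>_pos_x/y/z} and \code{<id>_yaw/_pitch/_roll} (degrees), then
#' the gaze block (\code{gaze_local_origin_*}, \code{gaze_local_dir_*},
#' \code{gaze_world_origin_*}, \code{gaze_world_dir_*}, \code{gaze_hit_*},
#' \code{gaze_hit_object}). Invalid fields are written as empty cells.
#'
#' @param x A samples data frame (from \code{\link{recorder_collect}} or a
#'   trial's \code{$samples}), a \code{\link{trial_record}}, or a session
#'   (all trials' samples concatenated).
#' @param path Output CSV path.
#' @export
export_samples_csv <- function(x, path) {
  df <- if (is.data.frame(x)) x
        else if (inherits(x, "vr_trial")) x$samples
        else if (inherits(x, "vr_session")) {
          parts <- Filter(Negate(is.null),
                          lapply(x$trials, function(t) t$samples))
          if (length(parts) == 0) NULL else do.call(rbind, parts)
        } else stop("cannot export samples from this object")
  if (is.null(df) || nrow(df) == 0) stop("no samples to export")
  out <- df
  for (k in names(out)) {
    if (is.numeric(out[[k]]))
      out[[k]] <- ifelse(is.na(out[[k]]), "",
                         format(out[[k]], digits = 17,
                                scientific = FALSE, trim = TRUE))
    else out[[k]] <- ifelse(is.na(out[[k]]), "", out[[k]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample CSV back into a data frame
#' @param path CSV written by \code{\link{export_samples_csv}}.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (k in names(df)) {
    if (k == "gaze_hit_object") {
      df[[k]] <- as.character(df[[k]])
      df[[k]][df[[k]] == ""] <- NA_character_
    } else if (!is.numeric(df[[k]])) {
      v <- suppressWarnings(as.numeric(df[[k]]))
      df[[k]] <- v
    }
  }
  df
}
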