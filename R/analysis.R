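# Kinematic analysis pipeline: controller velocity, velocity-criterion
# movement onset, per-trial dependent variables (latency, duration,
# horizontal endpoint error, correct-hemifield response), 3-SD outlier
# filtering, per-condition aggregation, and gaze-on-plane extraction.

#' Controller velocity by finite differences
#'
#' Backward difference \code{(p[i] - p[i-1]) / (t[i] - t[i-1])}, assigned
#' to the later sample; the first sample's velocity is undefined
#' (\code{NA}). No smoothing is applied by default; an optional centered
#' moving average can be requested.
#'
#' @param samples A samples data frame containing \code{time} and
#'   \code{<node>_pos_x/y/z} columns.
#' @param node Node id, default \code{"controller"}.
#' @param smooth_window Odd integer width of an optional centered moving
#'   average over the velocity (1 = none).
#' @return Data frame \code{time}, \code{vx}, \code{vy}, \code{vz} (m/s).
#' @export
controller_velocity <- function(samples, node = "controller",
                                smooth_window = 1L) {
  t <- samples$time
  if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("non-monotone timestamps in sample data", call. = FALSE)
  pos <- as.matrix(samples[paste0(node, "_pos_", c("x", "y", "z"))])
  dt <- diff(t)
  v <- rbind(c(NA_real_, NA_real_, NA_real_), diff(pos) / dt)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    for (j in 1:3) {
      ok <- !is.na(v[, j])
      v[ok, j] <- stats::filter(v[ok, j], k, sides = 2)
    }
  }
  data.frame(time = t, vx = v[, 1], vy = v[, 2], vz = v[, 3])
}

#' Velocity-criterion movement onset
#'
#' Time of the first sample whose positive depth (Z) velocity — away from
#' the participant — exceeds \code{threshold_mps}. The whole trial is
#' searched, so movements starting before the go cue are found (yielding
#' negative latencies downstream).
#'
#' @param samples Samples data frame (see
#'   \code{\link{controller_velocity}}).
#' @param threshold_mps Velocity threshold in m/s (default 0.05).
#' @param node Node id.
#' @return Onset time in seconds, or \code{NA} if the threshold is never
#'   exceeded.
#' @export
detect_movement_onset <- function(samples, threshold_mps = 0.05,
                                  node = "controller") {
  v <- controller_velocity(samples, node = node)
  hit <- which(!is.na(v$vz) & v$vz > threshold_mps)
  if (length(hit) == 0) return(NA_real_)
  v$time[hit[1]]
}

#' Time of the first event with a given label
#' @param trial A \code{\link{trial_record}}.
#' @param label Event label.
#' @return Event time in seconds, or \code{NA} if absent.
#' @export
event_time <- function(trial, label) {
  for (ev in trial$events) if (ev$label == label) return(ev$time)
  NA_real_
}

#' Per-trial kinematic measures
#'
#' Computes the dependent variables of one trial from its samples and
#' events: \describe{
#'   \item{latency}{movement onset minus go-cue time (s); negative for
#'     movements started before the go cue.}
#'   \item{duration}{threshold-crossing time minus onset (s).}
#'   \item{endpoint_error_target}{absolute lateral (X) distance between the
#'     controller at the first frame at/beyond the depth threshold and the
#'     trial's \emph{target} position (the literal definition; for
#'     anti-reach trials this includes the full target-goal separation).}
#'   \item{endpoint_error_goal}{same error relative to the mirrored motor
#'     goal — usually the quantity of interest for anti trials.}
#'   \item{correct_hemifield}{whether the controller crossed in the
#'     hemifield of the motor goal.}
#' }
#' Missing events or samples yield \code{NA} measures rather than errors.
#'
#' @param trial A completed \code{\link{trial_record}} with samples and
#'   \code{go_cue} / \code{threshold_crossed} events.
#' @param threshold_mps Onset velocity threshold (m/s).
#' @return One-row data frame of measures.
#' @export
compute_trial_measures <- function(trial, threshold_mps = 0.05) {
  p <- trial$params
  out <- data.frame(
    number = trial$number, status = trial$status,
    target_side = p$target_side %||% NA_character_,
    cue = p$cue %||% NA_character_,
    feedback = p$feedback %||% NA_character_,
    target_x = p$target_x %||% NA_real_,
    goal_x = p$goal_x %||% NA_real_,
    latency = NA_real_, duration = NA_real_,
    endpoint_error_target = NA_real_, endpoint_error_goal = NA_real_,
    correct_hemifield = NA, stringsAsFactors = FALSE)
  go <- event_time(trial, "go_cue")
  crossed <- event_time(trial, "threshold_crossed")
  if (is.na(go) || is.na(crossed) || is.null(trial$samples) ||
      nrow(trial$samples) < 2)
    return(out)
  onset <- detect_movement_onset(trial$samples, threshold_mps)
  if (!is.na(onset)) {
    out$latency <- onset - go
    out$duration <- crossed - onset
  }
  # controller at the first frame at/beyond the crossing event
  si <- which(trial$samples$time >= crossed)[1]
  if (!is.na(si)) {
    end_x <- trial$samples$controller_pos_x[si]
    if (!is.na(end_x) && !is.na(out$target_x)) {
      out$endpoint_error_target <- abs(end_x - out$target_x)
      out$endpoint_error_goal <- abs(end_x - out$goal_x)
      out$correct_hemifield <- sign(end_x) == sign(out$goal_x)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trial measures for a whole session
#'
#' @param session A completed session (or a list of trials).
#' @param threshold_mps Onset velocity threshold (m/s).
#' @param participant Optional participant label added as a column
#'   (defaults to the session metadata's \code{participant}).
#' @return Data frame with one row per trial with status \code{done}.
#' @export
session_measures <- function(session, threshold_mps = 0.05,
                             participant = NULL) {
  trials <- if (inherits(session, "vr_session")) session$trials else session
  if (is.null(participant) && inherits(session, "vr_session"))
    participant <- session$metadata$participant %||% "unknown"
  trials <- Filter(function(t) t$status == "done", trials)
  rows <- lapply(trials, compute_trial_measures,
                 threshold_mps = threshold_mps)
  df <- do.call(rbind, rows)
  if (!is.null(df) && nrow(df) > 0)
    df <- cbind(participant = participant, df, stringsAsFactors = FALSE)
  df
}

#' Flag outlier trials (3-SD rule)
#'
#' Per participant and per measure (latency and duration), trials farther
#' than \code{k} standard deviations from that participant's mean are
#' flagged as outliers; a trial flagged on either measure is excluded from
#' aggregates. Statistics are computed in a single pass over defined values
#' (no re-computation after exclusion), pooled across conditions.
#'
#' @param measures Data frame from \code{\link{session_measures}} (may span
#'   several participants).
#' @param k SD multiplier, default 3.
#' @return The input with logical \code{outlier} and character
#'   \code{outlier_reason} columns added.
#' @export
filter_outliers <- function(measures, k = 3) {
  measures$outlier <- FALSE
  measures$outlier_reason <- NA_character_
  for (p in unique(measures$participant)) {
    rows <- which(measures$participant == p)
    for (m in c("latency", "duration")) {
      vals <- measures[[m]][rows]
      ok <- !is.na(vals)
      if (sum(ok) < 2) next
      mu <- mean(vals[ok])
      sd_ <- stats::sd(vals[ok])
      bad <- ok & (vals < mu - k * sd_ | vals > mu + k * sd_)
      if (any(bad)) {
        idx <- rows[bad]
        measures$outlier[idx] <- TRUE
        measures$outlier_reason[idx] <-
          ifelse(is.na(measures$outlier_reason[idx]), m,
                 paste(measures$outlier_reason[idx], m, sep = "+"))
      }
    }
  }
  measures
}

#' Aggregate measures by condition
#'
#' For each target-side x cue cell: per-participant means of each dependent
#' variable over non-outlier trials, then the across-participant mean and
#' standard error (SD / sqrt(N participants)). The correct-response rate is
#' the proportion of non-outlier trials whose reach crossed in the correct
#' hemifield.
#'
#' @param measures Data frame from \code{\link{filter_outliers}} (an
#'   \code{outlier} column is added as all-\code{FALSE} if absent).
#' @return Data frame with one row per condition cell; empty cells are
#'   reported with \code{NA} (missing), never zero.
#' @export
aggregate_by_condition <- function(measures) {
  if (!"outlier" %in% names(measures)) measures$outlier <- FALSE
  keep <- measures[!measures$outlier & measures$status == "done", ,
                   drop = FALSE]
  cells <- expand.grid(target_side = c("left", "right"),
                       cue = c("pro", "anti"), stringsAsFactors = FALSE)
  dvs <- c("latency", "duration", "endpoint_error_target",
           "endpoint_error_goal")
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- keep[keep$target_side == cells$target_side[i] &
                keep$cue == cells$cue[i], , drop = FALSE]
    row <- cells[i, , drop = FALSE]
    row$n_trials <- nrow(sub)
    if (nrow(sub) == 0) {
      for (m in dvs) { row[[paste0(m, "_mean")]] <- NA_real_
                       row[[paste0(m, "_se")]] <- NA_real_ }
      row$correct_rate <- NA_real_
    } else {
      for (m in dvs) {
        pm <- tapply(sub[[m]], sub$participant,
                     function(v) mean(v, na.rm = TRUE))
        pm <- pm[!is.na(pm)]
        row[[paste0(m, "_mean")]] <- mean(pm)
        row[[paste0(m, "_se")]] <-
          if (length(pm) > 1) stats::sd(pm) / sqrt(length(pm)) else NA_real_
      }
      row$correct_rate <- mean(sub$correct_hemifield, na.rm = TRUE)
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Gaze position on the recording plane over a trial
#'
#' Extracts the per-frame 3D gaze intersection with the fronto-parallel
#' recording plane as horizontal/vertical coordinates relative to the plane
#' center, time-aligned to the go cue. Frames where gaze missed the plane
#' (or hit another object) are \code{NA} gaps.
#'
#' @param trial A completed \code{\link{trial_record}}.
#' @param plane_center World position of the plane center (defaults to
#'   straight ahead of the midline at the trial's target depth, i.e.
#'   \code{(0, eye height, stimulus depth)} as recorded in the samples'
#'   world gaze; pass explicitly for other layouts).
#' @param plane_id Scene id of the recording plane.
#' @return Data frame \code{time} (s, relative to go cue; negative before
#'   it), \code{x}, \code{y} (m, relative to plane center).
#' @export
gaze_on_plane <- function(trial, plane_center = NULL,
                          plane_id = "gaze_plane") {
  s <- trial$samples
  if (is.null(s) || nrow(s) == 0)
    return(data.frame(time = numeric(0), x = numeric(0), y = numeric(0)))
  go <- event_time(trial, "go_cue")
  if (is.na(go)) go <- 0
  on_plane <- !is.na(s$gaze_hit_object) & s$gaze_hit_object == plane_id
  if (is.null(plane_center)) {
    # infer: median hit point of on-plane frames defines the depth; center
    # x at the midline (0) and y at the head height recorded in the samples
    ey <- stats::median(s$head_pos_y, na.rm = TRUE)
    plane_center <- c(0, if (is.na(ey)) 0 else ey, NA)
  }
  data.frame(time = s$time - go,
             x = ifelse(on_plane, s$gaze_hit_x - plane_center[1], NA_real_),
             y = ifelse(on_plane, s$gaze_hit_y - plane_center[2], NA_real_))
}

#' Analyze a set of saved sessions
#'
#' Loads one or more session JSON files, computes per-trial measures, flags
#' outliers and aggregates by condition — the standard post-hoc pipeline
#' for saved data.
#'
#' @param paths Character vector of session JSON paths.
#' @param threshold_mps Onset velocity threshold (m/s).
#' @param k Outlier SD multiplier.
#' @return \code{list(measures =, aggregates =, meta =)} where \code{meta}
#'   records the analysis parameters.
#' @export
analyze_sessions <- function(paths, threshold_mps = 0.05, k = 3) {
  parts <- lapply(paths, function(p) {
    s <- load_session_json(p)
    session_measures(s, threshold_mps = threshold_mps)
  })
  measures <- do.call(rbind, parts)
  if (is.null(measures) || nrow(measures) == 0)
    stop("no completed trials found in the given sessions", call. = FALSE)
  measures <- filter_outliers(measures, k = k)
  list(measures = measures,
       aggregates = aggregate_by_condition(measures),
       meta = list(threshold_mps = threshold_mps, k = k,
                   n_sessions = length(paths)))
}
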