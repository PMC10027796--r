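# The example paradigm: a 2 (target side) x 2 (pro/anti cue) x 2 (visual
# feedback) reaching task. Each trial: fixate a central sphere for 1 s; the
# sphere recolors to cue reach direction (blue = pro, red = anti) while a
# target cube appears 30 cm left or right for 1 s; both disappear (go cue);
# the participant reaches and the trial ends when the controller crosses a
# depth threshold of 45 cm.

#' Task configuration for the pro-/anti-reach paradigm
#'
#' All geometry in meters, durations in seconds. Defaults follow the
#' published paradigm: 5 cm fixation sphere at 50 cm depth, targets 30 cm
#' left/right of the body midline at the same depth, 1 s fixation hold,
#' 1 s target presentation, trial end at 45 cm controller depth, 10
#' repetitions per condition (80 trials).
#'
#' @param ... Overrides for any default field.
#' @return An object of class \code{"proanti_config"}.
#' @export
proanti_config <- function(...) {
  cfg <- list(
    fixation_diameter = 0.05,
    stimulus_depth = 0.5,
    target_lateral_offset = 0.30,
    target_size = 0.05,
    proximity_threshold_z = 0.45,
    fixation_hold = 1.0,
    target_duration = 1.0,
    fixation_timeout = 10.0,
    response_timeout = 5.0,
    cue_colors = list(pro = "blue", anti = "red", neutral = "white"),
    repetitions = 10L,
    eye_height = 1.2,
    hand_height = 1.0,
    hand_start_z = 0.05,
    frame_rate = 90,
    gaze_plane_size = 2.0
  )
  over <- list(...)
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown config field '", k, "'")
    cfg[[k]] <- over[[k]]
  }
  stopifnot(cfg$fixation_diameter > 0, cfg$stimulus_depth > 0,
            cfg$target_lateral_offset > 0, cfg$proximity_threshold_z > 0,
            cfg$fixation_hold > 0, cfg$target_duration > 0,
            cfg$repetitions >= 1)
  structure(cfg, class = "proanti_config")
}

#' Build the randomized pro-/anti-reach trial list
#'
#' Full factorial crossing of \code{target_side} (left/right), \code{cue}
#' (pro/anti) and \code{feedback} (visible/hidden controller), repeated
#' \code{config$repetitions} times and shuffled with \code{seed}. Each
#' trial additionally carries the derived parameters \code{target_x}
#' (signed lateral target position) and \code{goal_x} (the motor goal:
#' equal to \code{target_x} for pro cues, mirrored for anti cues).
#'
#' @param config A \code{\link{proanti_config}}.
#' @param seed Integer randomization seed.
#' @return List of \code{\link{trial_record}} objects.
#' @export
build_proanti_design <- function(config = proanti_config(), seed = 1L) {
  spec <- design_spec(list(target_side = c("left", "right"),
                           cue = c("pro", "anti"),
                           feedback = c("visible", "hidden")),
                      repetitions = config$repetitions)
  trials <- make_factorial_design(spec)
  off <- config$target_lateral_offset
  for (t in trials) {
    p <- unclass(t$params)
    p$target_x <- if (p$target_side == "left") -off else off
    p$goal_x <- if (p$cue == "pro") p$target_x else -p$target_x
    t$params <- as_param_set(p)
  }
  randomize_trials(trials, seed = seed)
}

#' Build the task scene
#'
#' Fixation sphere and target cube at eye height and stimulus depth (both
#' hidden and non-pickable initially), plus the invisible fronto-parallel
#' gaze-recording plane at target depth. Only the plane is pickable during
#' the response phase, so logged 3D gaze points always lie on it.
#'
#' @param config A \code{\link{proanti_config}}.
#' @return A \code{\link{scene}}.
#' @export
build_proanti_scene <- function(config = proanti_config()) {
  sc <- scene()
  ey <- config$eye_height
  d <- config$stimulus_depth
  scene_add(sc, sphere("fixation", vec3(0, ey, d),
                       radius = config$fixation_diameter / 2,
                       visible = FALSE, pickable = FALSE))
  scene_add(sc, box("target", vec3(0, ey, d),
                    half_extents = rep(config$target_size / 2, 3),
                    visible = FALSE, pickable = FALSE))
  scene_add(sc, rect_plane("gaze_plane", vec3(0, ey, d),
                           normal = vec3(0, 0, -1),
                           width = config$gaze_plane_size,
                           height = config$gaze_plane_size,
                           visible = FALSE, pickable = TRUE))
  sc
}

#' Run one pro-/anti-reach trial
#'
#' Executes the trial state machine at the recorder's frame clock:
#' \enumerate{
#'   \item \emph{fixation}: the white fixation sphere is shown; the
#'     participant must keep gaze on it for every frame of a sliding window
#'     of \code{fixation_hold} seconds (a single miss resets the window).
#'   \item \emph{cue and target}: the sphere recolors (pro/anti) and the
#'     target cube appears at \code{target_x} for
#'     \code{target_duration} seconds.
#'   \item \emph{go}: both stimuli disappear (the go cue); controller
#'     visibility is set from the feedback factor.
#'   \item \emph{response}: the trial ends at the first frame with
#'     controller depth \code{z >= proximity_threshold_z}.
#' }
#' Every stimulus on/offset and the threshold crossing are logged as
#' events; results store the end time, end controller position, cue and
#' target/goal coordinates. Failure to attain fixation within
#' \code{fixation_timeout} raises an error (the run flow marks the trial
#' \code{status = "error"}).
#'
#' @param trial A \code{\link{trial_record}} from
#'   \code{\link{build_proanti_design}}.
#' @param devices A \code{\link{simulate_participant}} bundle (or any object
#'   with the same hook/source fields).
#' @param recorder A \code{\link{sample_recorder}} with registered head,
#'   controller and eye tracker.
#' @param config A \code{\link{proanti_config}}.
#' @return The trial, invisibly (samples and events attached).
#' @export
run_proanti_trial <- function(trial, devices, recorder,
                              config = proanti_config()) {
  sc <- recorder$scene
  clock <- recorder$clock
  fps <- clock$rate
  ey <- config$eye_height
  d <- config$stimulus_depth
  devices$begin_trial(trial)
  recorder_start_trial(recorder, trial$number)
  log_trial_event <- function(label, payload = NULL) {
    ev <- log_event(recorder, label, payload)
    devices$on_event(label, ev$time, trial)
    ev
  }
  log_trial_event("trial_start_confirmed")

  # --- phase 1: fixation ----------------------------------------------------
  set_object_group_state(sc, "fixation", visible = TRUE, pickable = TRUE,
                         pose = pose(vec3(0, ey, d)))
  set_object_group_state(sc, c("target", "gaze_plane"),
                         visible = FALSE, pickable = FALSE)
  log_trial_event("fixation_on", param_set(color = "white"))
  hold_frames <- round(config$fixation_hold * fps)
  consecutive <- 0L
  deadline <- clock$time + config$fixation_timeout
  repeat {
    clock$tick()
    record_frame(recorder)
    g <- recorder$last_gaze
    on_sphere <- !is.null(g) &&
      identical(recorder$last_gaze_frame, clock$frame) &&
      identical(g$hit_object, "fixation")
    consecutive <- if (on_sphere) consecutive + 1L else 0L
    if (consecutive >= hold_frames) break
    if (clock$time > deadline)
      stop("fixation not attained within timeout", call. = FALSE)
  }
  log_trial_event("fixation_acquired")

  # --- phase 2: cue + target ------------------------------------------------
  cue <- trial$params$cue
  target_x <- trial$params$target_x
  set_object_group_state(sc, "target", visible = TRUE,
                         pose = pose(vec3(target_x, ey, d)))
  log_trial_event("cue_on", param_set(color = config$cue_colors[[cue]]))
  log_trial_event("target_on", param_set(x = target_x))
  target_frames <- round(config$target_duration * fps)
  for (i in seq_len(target_frames)) {
    clock$tick()
    record_frame(recorder)
  }

  # --- phase 3: go cue ------------------------------------------------------
  set_object_group_state(sc, c("fixation", "target"),
                         visible = FALSE, pickable = FALSE)
  set_object_group_state(sc, "gaze_plane", pickable = TRUE)
  feedback_visible <- identical(trial$params$feedback, "visible")
  log_trial_event("fixation_off")
  log_trial_event("target_off")
  log_trial_event("go_cue",
                  param_set(controller_visible = feedback_visible))

  # --- phase 4: response ----------------------------------------------------
  schema <- sample_schema(recorder)
  pos_idx <- match(paste0("controller_pos_", c("x", "y", "z")), schema)
  deadline <- clock$time + config$response_timeout
  end_pos <- NULL
  repeat {
    clock$tick()
    s <- record_frame(recorder)
    z <- s$num[pos_idx[3]]
    if (!is.na(z) && z >= config$proximity_threshold_z) {
      end_pos <- s$num[pos_idx]
      break
    }
    if (clock$time > deadline)
      stop("no threshold crossing within response timeout", call. = FALSE)
  }
  log_trial_event("threshold_crossed",
                  param_set(x = end_pos[1], y = end_pos[2], z = end_pos[3]))

  trial$samples <- recorder_collect(recorder)
  trial$events <- recorder$events
  set_trial_result(trial, "end_time", clock$time)
  set_trial_result(trial, "end_x", end_pos[1])
  set_trial_result(trial, "end_y", end_pos[2])
  set_trial_result(trial, "end_z", end_pos[3])
  set_trial_result(trial, "cue", cue)
  set_trial_result(trial, "target_x", target_x)
  set_trial_result(trial, "goal_x", trial$params$goal_x)
  set_trial_result(trial, "controller_visible", feedback_visible)
  invisible(trial)
}

#' Simulate a complete pro-/anti-reach session
#'
#' Builds the randomized design, the scene, the simulated devices and the
#' recorder, optionally runs a gaze validation, and runs all trials through
#' \code{\link{run_experiment}}. The seed drives the design randomization,
#' all device noise and the per-trial behavior draws; it is recorded in the
#' session metadata.
#'
#' @param participant Participant code stored in the metadata.
#' @param profile A \code{\link{participant_profile}}.
#' @param config A \code{\link{proanti_config}}.
#' @param seed Integer session seed.
#' @param validate Run the five-target validation before the trials?
#' @param continue_on_error Continue the run when a trial errors?
#' @return The completed \code{\link{experiment_session}}.
#' @export
simulate_proanti_session <- function(participant = "sim01",
                                     profile = participant_profile(),
                                     config = proanti_config(),
                                     seed = 1L, validate = TRUE,
                                     continue_on_error = TRUE) {
  clock <- frame_clock(config$frame_rate)
  trials <- build_proanti_design(config, seed = seed)
  session <- experiment_session(
    metadata = param_set(participant = participant, seed = seed,
                         profile = profile$type),
    config = param_set(continue_on_error = continue_on_error,
                       frame_rate = config$frame_rate,
                       onset_note = "simulated session"),
    trials = trials)
  sc <- build_proanti_scene(config)
  devices <- simulate_participant(profile, config, length(trials),
                                  seed = seed, clock = clock)
  recorder <- sample_recorder(sc, clock)
  register_node(recorder, "head", devices$head_source)
  register_node(recorder, "controller", devices$controller_source)
  register_eye_tracker(recorder, devices$gaze_source)

  if (validate) {
    targets <- make_cross_layout(5, config$stimulus_depth)
    origin <- vec3(0, config$eye_height, 0)
    run_validation(session, recorder, targets, origin = origin,
                   fixate = devices$set_fixation)
    devices$set_fixation(vec3(0, config$eye_height, config$stimulus_depth))
  }

  run_experiment(session,
                 main_task = function(trial, session, clk)
                   run_proanti_trial(trial, devices, recorder, config),
                 clock = clock)
  session
}
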