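# Seeded device simulators: head-mounted display, reaching hand controller
# (minimum-jerk kinematics), and eye tracker with configurable angular bias
# and noise — everything needed to run the example task headlessly.

#' Minimum-jerk position along a straight reach
#'
#' Straight-line point-to-point movement with displacement fraction
#' \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5},
#' \eqn{\tau = t / duration} clamped to [0, 1] — the standard smooth-reach
#' model with a bell-shaped speed profile peaking at
#' \eqn{1.875\,|goal - start| / duration} at \eqn{\tau = 0.5}.
#'
#' @param start,goal \code{\link{vec3}} endpoints.
#' @param t_since_onset Time since movement onset (s); values outside
#'   [0, duration] clamp to the endpoints.
#' @param duration Movement duration (s), > 0.
#' @return Position \code{vec3}.
#' @export
minimum_jerk_position <- function(start, goal, t_since_onset, duration) {
  stopifnot(duration > 0)
  tau <- t_since_onset / duration
  if (tau <= 0) return(start)
  if (tau >= 1) return(goal)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  start + s * (goal - start)
}

#' Define a simulated participant behavior profile
#'
#' Controls how the simulated participant behaves across the trials of a
#' session, including the scripted "mistake" modes used to illustrate data
#' errors: \code{"early_start"} begins reaches before the go cue (negative
#' movement latency) and \code{"gaze_to_target"} breaks central fixation by
#' looking at the target when it appears.
#'
#' @param type One of \code{"compliant"}, \code{"early_start"},
#'   \code{"gaze_to_target"}.
#' @param latency_mean,latency_sd Reach onset latency after the go cue (s);
#'   drawn per trial from a normal distribution truncated at 0 (compliant /
#'   gaze-to-target) or centered 0.2 s \emph{before} the go cue
#'   (early start).
#' @param duration_mean,duration_sd Movement duration (s), truncated at 0.
#' @param gaze_noise_deg Isotropic gaze noise SD per angular axis
#'   (degrees/frame).
#' @param gaze_bias_deg Constant angular gaze bias magnitude (degrees);
#'   \code{NULL} draws one value per participant in [0.2, 0.7] degrees, the
#'   typical accuracy range of consumer VR eye trackers.
#' @param head_jitter_m Positional head jitter SD (m/axis), default 0.
#' @param hold_jitter_m Controller hold jitter SD at the start position
#'   (m/axis), default 0.
#' @return An object of class \code{"participant_profile"}.
#' @export
participant_profile <- function(type = c("compliant", "early_start",
                                         "gaze_to_target"),
                                latency_mean = NULL, latency_sd = 0.08,
                                duration_mean = 0.5, duration_sd = 0.1,
                                gaze_noise_deg = 0.3, gaze_bias_deg = NULL,
                                head_jitter_m = 0, hold_jitter_m = 0) {
  type <- match.arg(type)
  if (is.null(latency_mean))
    latency_mean <- if (type == "early_start") -0.2 else 0.45
  if (type == "early_start") latency_sd <- min(latency_sd, 0.05)
  structure(list(type = type,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 gaze_noise_deg = gaze_noise_deg,
                 gaze_bias_deg = gaze_bias_deg,
                 head_jitter_m = head_jitter_m,
                 hold_jitter_m = hold_jitter_m),
            class = "participant_profile")
}

#' A noiseless, perfectly compliant profile (for parameter-recovery checks)
#' @param latency,duration Fixed reach latency and duration (s) used on
#'   every trial.
#' @export
noiseless_profile <- function(latency = 0.45, duration = 0.5) {
  participant_profile("compliant",
                      latency_mean = latency, latency_sd = 0,
                      duration_mean = duration, duration_sd = 0,
                      gaze_noise_deg = 0, gaze_bias_deg = 0)
}

# truncated-normal draw (resample below `lower`)
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Build simulated devices for one participant session
#'
#' Returns a bundle of pollable sources (head pose, controller pose, local
#' gaze) driven by the frame clock, plus the event hooks the task uses to
#' cue behavior. All randomness (per-trial latencies and durations, gaze
#' bias direction, per-frame noise) flows from \code{seed}, so the same
#' seed reproduces byte-identical sample streams.
#'
#' Behavior per trial: the controller rests at the start position (with
#' optional hold jitter); when the cue/target appears the reach is
#' scheduled at the expected go time (cue onset + target duration) plus the
#' trial's latency (which is negative for the early-start profile), then
#' follows a straight minimum-jerk path to a point whose lateral coordinate
#' is the trial's motor goal and whose depth is the trial-ending proximity
#' plane. Gaze fixates the fixation sphere; the gaze-to-target profile
#' instead shifts fixation to the target when it appears.
#'
#' @param profile A \code{\link{participant_profile}}.
#' @param config A \code{\link{proanti_config}} (supplies geometry/timing).
#' @param n_trials Number of trials the session will run.
#' @param seed Integer seed.
#' @param clock The session \code{\link{frame_clock}}.
#' @return An object of class \code{"device_bundle"}: sources
#'   \code{$head_source}, \code{$controller_source}, \code{$gaze_source};
#'   hooks \code{$begin_trial(trial)}, \code{$on_event(label, time, trial)},
#'   \code{$set_fixation(world_pos)}; and the drawn per-trial parameters in
#'   \code{$trial_params} (data frame with \code{latency}, \code{duration}).
#' @export
simulate_participant <- function(profile, config, n_trials, seed,
                                 clock = frame_clock()) {
  dev <- new.env(parent = emptyenv())
  dev$profile <- profile
  dev$config <- config
  dev$clock <- clock

  draws <- with_local_seed(seed, {
    lat <- if (profile$type == "early_start")
      stats::rnorm(n_trials, profile$latency_mean, profile$latency_sd)
    else
      rnorm_trunc(n_trials, profile$latency_mean, profile$latency_sd,
                  lower = 0)
    dur <- rnorm_trunc(n_trials, profile$duration_mean, profile$duration_sd,
                       lower = 0.05)
    bias_mag <- if (is.null(profile$gaze_bias_deg))
      stats::runif(1, 0.2, 0.7) else profile$gaze_bias_deg
    bias_dir <- stats::runif(1, 0, 2 * pi)
    list(lat = lat, dur = dur,
         bias = bias_mag * c(cos(bias_dir), sin(bias_dir)))
  })
  dev$trial_params <- data.frame(latency = draws$lat, duration = draws$dur)
  dev$gaze_bias <- draws$bias  # (horizontal, vertical) degrees

  # per-frame noise uses a dedicated RNG stream so trial draws stay stable
  dev$noise_rng <- new_rng_stream(seed + 1L)

  eye_height <- config$eye_height
  dev$head_base <- pose(vec3(0, eye_height, 0))
  dev$hand_start <- vec3(0, config$hand_height, config$hand_start_z)
  dev$fixation_point <- vec3(0, eye_height, config$stimulus_depth)
  dev$trial_i <- 0L
  dev$reach_onset <- NA_real_
  dev$reach_goal <- dev$hand_start

  dev$begin_trial <- function(trial) {
    dev$trial_i <- dev$trial_i + 1L
    dev$reach_onset <- NA_real_
    goal_x <- trial$params$goal_x
    dev$reach_goal <- vec3(goal_x, config$hand_height,
                           config$proximity_threshold_z)
    dev$fixation_point <- vec3(0, eye_height, config$stimulus_depth)
    invisible(dev)
  }

  dev$on_event <- function(label, time, trial) {
    if (label == "cue_on") {
      # participant anticipates the go cue at cue onset + target duration
      expected_go <- time + config$target_duration
      dev$reach_onset <- expected_go + dev$trial_params$latency[dev$trial_i]
    } else if (label == "target_on" && profile$type == "gaze_to_target") {
      dev$fixation_point <- vec3(trial$params$target_x, eye_height,
                                 config$stimulus_depth)
    }
    invisible(dev)
  }

  dev$set_fixation <- function(world_pos) {
    dev$fixation_point <- world_pos
    invisible(dev)
  }

  dev$head_source <- function(time, frame) {
    p <- dev$head_base$position
    if (profile$head_jitter_m > 0)
      p <- p + dev$noise_rng$norm(3) * profile$head_jitter_m
    pose(p, dev$head_base$orientation)
  }

  dev$controller_source <- function(time, frame) {
    if (is.na(dev$reach_onset) || time < dev$reach_onset) {
      p <- dev$hand_start
      if (profile$hold_jitter_m > 0)
        p <- p + dev$noise_rng$norm(3) * profile$hold_jitter_m
    } else {
      p <- minimum_jerk_position(dev$hand_start, dev$reach_goal,
                                 time - dev$reach_onset,
                                 dev$trial_params$duration[dev$trial_i])
    }
    pose(p)
  }

  # local gaze in the head frame: ray from the cyclopean origin (head
  # position) toward the fixation point, perturbed by bias then noise in
  # horizontal/vertical angular coordinates
  dev$gaze_source <- function(time, frame) {
    head <- dev$head_base
    local_dir <- inverse_transform_direction(head, dev$fixation_point -
                                                     head$position)
    h <- dev$gaze_bias[1]
    v <- dev$gaze_bias[2]
    if (profile$gaze_noise_deg > 0) {
      n <- dev$noise_rng$norm(2) * profile$gaze_noise_deg
      h <- h + n[1]
      v <- v + n[2]
    }
    if (h != 0 || v != 0) local_dir <- perturb_direction(local_dir, h, v)
    list(origin = vec3(0, 0, 0), direction = local_dir)
  }

  class(dev) <- "device_bundle"
  dev
}

# small independent RNG stream (so per-frame noise does not disturb or
# depend on the caller's RNG state)
new_rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- with_local_seed(seed, {
    stats::runif(1)
    get(".Random.seed", envir = globalenv())
  })
  env$norm <- function(n) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::rnorm(n)
    env$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
  env
}

# Rotate a direction by angular offsets about axes orthogonal to it:
# h degrees along the horizontal (rightward positive), v degrees along the
# vertical (upward positive). Single-axis offsets displace the direction by
# exactly the given angle regardless of where it points.
perturb_direction <- function(dir, h_deg, v_deg) {
  up <- if (abs(dir[2]) > 1 - 1e-9) c(0, 0, 1) else c(0, 1, 0)
  right <- vec3_normalize(vec3_cross(up, dir))
  local_up <- vec3_cross(dir, right)
  q <- quat_multiply(quat_from_axis_angle(local_up, h_deg),
                     quat_from_axis_angle(right, -v_deg))
  vec3_normalize(quat_rotate(q, dir))
}
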