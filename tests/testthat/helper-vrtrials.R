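# Shared test helpers: numeric normalization for serialization comparisons
# and small builders for recorder/device fixtures.

# Recursively coerce integers to doubles so that JSON round trips (which
# may turn 1.0 into integer 1) compare structurally equal.
normalize_numeric <- function(x) {
  if (is.integer(x)) return(as.double(x))
  if (is.data.frame(x)) {
    for (k in names(x)) if (is.integer(x[[k]])) x[[k]] <- as.double(x[[k]])
    return(x)
  }
  if (is.list(x)) return(lapply(x, normalize_numeric))
  x
}

session_snapshot <- function(s) normalize_numeric(vrtrials:::session_to_list(s))

# a recorder with a static head at `head_pose` and a gaze source always
# aiming at `fixation_env$point` (world), for direct recorder tests
make_static_rig <- function(sc, clock, head_pose = pose(vec3(0, 0, 0)),
                            fixation = vec3(0, 0, 1)) {
  env <- new.env()
  env$point <- fixation
  env$head <- head_pose
  rec <- sample_recorder(sc, clock)
  register_node(rec, "head", function(time, frame) env$head)
  register_eye_tracker(rec, function(time, frame) {
    list(origin = vec3(0, 0, 0),
         direction = inverse_transform_direction(env$head,
                                                 env$point -
                                                   env$head$position))
  })
  list(recorder = rec, env = env)
}

# independent rotation-matrix form of a quaternion (for oracle checks)
quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# minimum-jerk displacement fraction (closed form, test-side oracle)
mj_fraction <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}
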