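make_samples <- function(z, rate = 90, x = 0, y = 0) {
  n <- length(z)
  data.frame(time = (seq_len(n) - 1) / rate, frame = seq_len(n) - 1,
             trial = 1,
             controller_pos_x = rep(x, n)[seq_len(n)],
             controller_pos_y = rep(y, n)[seq_len(n)],
             controller_pos_z = z)
}

test_that("backward-difference velocity matches hand-computed values", {
  s <- make_samples(c(0, 0, 0, 0.01, 0.03, 0.06))
  v <- controller_velocity(s)
  expect_true(is.na(v$vz[1]))
  expect_equal(v$vz[-1], c(0, 0, 0.9, 1.8, 2.7), tolerance = 1e-9)

  # constant position -> zeros; uniform motion -> constant velocity
  expect_true(all(controller_velocity(make_samples(rep(0.2, 10)))$vz[-1] == 0))
  lin <- make_samples(seq(0, 1, length.out = 91))
  vv <- controller_velocity(lin)$vz[-1]
  expect_equal(vv, rep(1, 90), tolerance = 1e-9)

  bad <- make_samples(c(0, 1, 2))
  bad$time <- c(0, 0.1, 0.1)
  expect_error(controller_velocity(bad), "non-monotone")
  expect_error(controller_velocity(make_samples(0)), "2 samples")
})

test_that("movement onset is the first sample with v_z above threshold", {
  s <- make_samples(c(0, 0, 0, 0.01, 0.03, 0.06))
  expect_equal(detect_movement_onset(s, threshold_mps = 0.5), 3 / 90)
  expect_true(is.na(detect_movement_onset(s, threshold_mps = 10)))
})

# build a synthetic completed trial from scratch (no task machinery)
make_synthetic_trial <- function(go = 0.5, onset = 0.95, duration = 0.5,
                                 target_x = 0.3, goal_x = 0.3,
                                 rate = 90, start_z = 0.05, end_z = 0.45,
                                 cue = "pro") {
  n <- ceiling((onset + duration + 0.2) * rate)
  t <- (seq_len(n) - 1) / rate
  frac <- mj_fraction((t - onset) / duration)
  z <- start_z + frac * (end_z - start_z)
  x <- frac * goal_x
  tr <- trial_record(param_set(target_side = if (target_x < 0) "left"
                                             else "right",
                               cue = cue, feedback = "visible",
                               target_x = target_x, goal_x = goal_x),
                     index = 0L)
  tr$number <- 1L
  set_trial_status(tr, "running")
  tr$samples <- data.frame(time = t, frame = seq_len(n) - 1, trial = 1,
                           controller_pos_x = x, controller_pos_y = 1,
                           controller_pos_z = z)
  cross_i <- which(z >= end_z - 1e-12)[1]
  tr$events <- list(list(time = go, frame = as.integer(go * rate),
                         label = "go_cue", payload = NULL),
                    list(time = t[cross_i], frame = cross_i - 1L,
                         label = "threshold_crossed", payload = NULL))
  set_trial_status(tr, "done")
  tr
}

test_that("trial measures: latency, duration, endpoint errors, hemifield", {
  tr <- make_synthetic_trial()
  m <- compute_trial_measures(tr, threshold_mps = 0.05)
  # onset detected shortly after the scripted 0.45 s latency (velocity
  # rise lag), never before it
  expect_gte(m$latency, 0.45)
  expect_lt(m$latency, 0.45 + 0.05)
  expect_gt(m$duration, 0)
  expect_equal(m$endpoint_error_target, 0, tolerance = 1e-9)
  expect_equal(m$endpoint_error_goal, 0, tolerance = 1e-9)
  expect_true(m$correct_hemifield)

  # anti-reach: endpoint at -0.3 with target at +0.3 -> correct hemifield,
  # 0.6 m error relative to the target, 0 relative to the goal
  anti <- make_synthetic_trial(target_x = 0.3, goal_x = -0.3, cue = "anti")
  ma <- compute_trial_measures(anti)
  expect_true(ma$correct_hemifield)
  expect_equal(ma$endpoint_error_target, 0.6, tolerance = 1e-9)
  expect_equal(ma$endpoint_error_goal, 0, tolerance = 1e-9)

  # early start: onset before the go cue -> negative latency
  early <- make_synthetic_trial(go = 1.2, onset = 0.95)
  expect_lt(compute_trial_measures(early)$latency, 0)

  # missing events -> undefined measures, no error
  noev <- make_synthetic_trial()
  noev$events <- list()
  mn <- compute_trial_measures(noev)
  expect_true(is.na(mn$latency))
  expect_true(is.na(mn$endpoint_error_target))
})

test_that("3-SD outlier filter flags extremes, single pass, per participant", {
  base <- data.frame(participant = "p1", number = 1:100, status = "done",
                     latency = c(rep(0.4, 99), 10),
                     duration = rep(0.5, 100), stringsAsFactors = FALSE)
  f <- filter_outliers(base, k = 3)
  expect_equal(which(f$outlier), 100)
  expect_equal(f$outlier_reason[100], "latency")

  # all values equal: SD 0, band degenerates to the mean, nothing flagged
  same <- base
  same$latency <- 0.4
  expect_false(any(filter_outliers(same)$outlier))

  # k -> large: no flags
  expect_false(any(filter_outliers(base, k = 1e6)$outlier))

  # per-participant statistics: an extreme participant does not drag the
  # other's mean
  two <- rbind(base,
               transform(base, participant = "p2", latency = 0.4))
  f2 <- filter_outliers(two, k = 3)
  expect_equal(sum(f2$outlier[f2$participant == "p2"]), 0)
  expect_equal(sum(f2$outlier[f2$participant == "p1"]), 1)

  # idempotent single pass: re-running on the same table flags no new trials
  f3 <- filter_outliers(f2[, setdiff(names(f2),
                                     c("outlier", "outlier_reason"))], k = 3)
  expect_equal(f3$outlier, f2$outlier)
})

test_that("condition aggregation: participant means, SE = SD/sqrt(N), rates", {
  grid <- expand.grid(participant = c("a", "b", "c"),
                      target_side = c("left", "right"),
                      cue = c("pro", "anti"), stringsAsFactors = FALSE)
  lat <- c(a = 0.40, b = 0.50, c = 0.60)
  df <- data.frame(grid, number = seq_len(nrow(grid)), status = "done",
                   latency = lat[grid$participant],
                   duration = 0.5, endpoint_error_target = 0.02,
                   endpoint_error_goal = 0.02, correct_hemifield = TRUE,
                   outlier = FALSE, stringsAsFactors = FALSE)
  agg <- aggregate_by_condition(df)
  expect_equal(nrow(agg), 4)
  expect_equal(agg$latency_mean, rep(0.5, 4))
  expect_equal(agg$latency_se, rep(sd(c(0.4, 0.5, 0.6)) / sqrt(3), 4))
  expect_equal(agg$correct_rate, rep(1, 4))

  # left/right symmetry of symmetric input
  expect_equal(agg$latency_mean[agg$target_side == "left"],
               agg$latency_mean[agg$target_side == "right"])

  # empty cell reported as missing, not zero
  sub <- df[df$cue == "pro", ]
  agg2 <- aggregate_by_condition(sub)
  expect_true(all(is.na(agg2$latency_mean[agg2$cue == "anti"])))
  expect_equal(agg2$n_trials[agg2$cue == "anti"], c(0, 0))
})

test_that("gaze-on-plane extraction aligns to the go cue with NA gaps", {
  tr <- make_synthetic_trial(go = 0.5)
  n <- nrow(tr$samples)
  tr$samples$gaze_hit_object <- c(rep("gaze_plane", n - 5),
                                  rep(NA_character_, 5))
  tr$samples$gaze_hit_x <- c(rep(0.01, n - 5), rep(NA_real_, 5))
  tr$samples$gaze_hit_y <- c(rep(1.2, n - 5), rep(NA_real_, 5))
  tr$samples$head_pos_y <- 1.2
  g <- gaze_on_plane(tr)
  expect_equal(nrow(g), n)
  expect_equal(g$time[1], -0.5)
  expect_equal(g$x[1], 0.01)
  expect_equal(g$y[1], 0, tolerance = 1e-12)   # relative to head height
  expect_true(all(is.na(g$x[(n - 4):n])))

  # plane never hit -> no usable points
  tr$samples$gaze_hit_object <- NA_character_
  g2 <- gaze_on_plane(tr)
  expect_true(all(is.na(g2$x)))

  empty <- trial_record()
  expect_equal(nrow(gaze_on_plane(empty)), 0)
})

test_that("session pipeline recovers scripted parameters end to end", {
  cfg <- proanti_config(repetitions = 1L)
  s <- simulate_proanti_session("p1", noiseless_profile(), cfg,
                                seed = 8, validate = FALSE)
  m <- session_measures(s)
  expect_equal(nrow(m), 8)
  frame <- 1 / cfg$frame_rate
  # scripted latency 0.45 s and duration 0.5 s: the velocity criterion
  # detects onset within the analytic rise lag + one frame
  rise_lag <- uniroot(function(tau)
    30 * tau^2 * (1 - tau)^2 * 0.4 / 0.5 - 0.05, c(1e-6, 0.5))$root * 0.5
  expect_true(all(abs(m$latency - (0.45 + rise_lag)) <= 2 * frame))
  expect_true(all(abs(m$duration - (0.5 - rise_lag)) <= 2 * frame))
  expect_true(all(m$endpoint_error_goal < 1e-9))
  expect_true(all(m$correct_hemifield))
})
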