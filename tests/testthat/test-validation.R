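# A minimal validation rig: static head at a given origin, gaze source that
# fixates a settable point with optional angular bias/noise applied in
# horizontal/vertical coordinates.
make_validation_rig <- function(bias = c(0, 0), noise_sd = 0,
                                origin = vec3(0, 0, 0)) {
  sc <- scene()
  clk <- frame_clock(90)
  env <- new.env()
  env$point <- vec3(0, 0, 0.5)
  head <- pose(origin)
  rec <- sample_recorder(sc, clk)
  register_node(rec, "head", function(t, f) head)
  register_eye_tracker(rec, function(t, f) {
    dir <- inverse_transform_direction(head, env$point - head$position)
    h <- bias[1] + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    v <- bias[2] + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    if (h != 0 || v != 0) dir <- vrtrials:::perturb_direction(dir, h, v)
    list(origin = vec3(0, 0, 0), direction = dir)
  })
  list(recorder = rec, clock = clk, origin = origin,
       fixate = function(p) env$point <- p)
}

test_that("cross layout geometry: eccentricity survives the 3D round trip", {
  lay <- make_cross_layout(5, 0.5)
  expect_equal(nrow(lay), 5)
  center_dir <- c(0, 0, 1)
  for (i in 2:5) {
    p <- c(lay$x[i], lay$y[i], lay$z[i])
    expect_equal(sqrt(sum(p^2)), 0.5, tolerance = 1e-12)   # on the sphere
    expect_equal(angular_distance(p, center_dir), 5, tolerance = 1e-9)
  }
  # depth rescales positions, not angles
  lay2 <- make_cross_layout(5, 1.5)
  expect_equal(as.matrix(lay2[c("x", "y", "z")]),
               3 * as.matrix(lay[c("x", "y", "z")]), ignore_attr = TRUE)
  for (i in 2:5)
    expect_equal(angular_distance(c(lay2$x[i], lay2$y[i], lay2$z[i]),
                                  center_dir), 5, tolerance = 1e-9)
  expect_error(make_cross_layout(0, 0.5), "eccentricity")
  expect_error(make_cross_layout(5, -1), "depth")
})

test_that("zero-noise gaze gives zero error; constant bias is recovered", {
  targets <- make_cross_layout(5, 0.5)
  rig <- make_validation_rig()
  s <- experiment_session()
  res <- run_validation(s, rig$recorder, targets, origin = rig$origin,
                        fixate = rig$fixate)
  expect_true(all(res$per_target$accuracy_deg < 1e-9))
  expect_true(all(res$per_target$sd_deg < 1e-9))
  expect_true(all(res$per_target$rmse_deg < 1e-9))
  expect_length(s$validations, 1)

  # constant 1 deg horizontal bias: accuracy 1, sd 0, rmse 1
  rig2 <- make_validation_rig(bias = c(1, 0))
  res2 <- run_validation(s, rig2$recorder, targets, origin = rig2$origin,
                         fixate = rig2$fixate)
  expect_equal(res2$per_target$accuracy_deg, rep(1, 5), tolerance = 1e-3)
  expect_true(all(res2$per_target$sd_deg < 1e-9))
  expect_equal(res2$per_target$rmse_deg, rep(1, 5), tolerance = 1e-3)
  expect_length(s$validations, 2)
})

test_that("bias magnitudes 0.25/1/2 deg are recovered as accuracy", {
  # zero noise makes the recovery deterministic; tolerance covers only the
  # second-order error of composing two small rotations
  for (delta in c(0.25, 1, 2)) {
    phi <- 0.7
    rig <- make_validation_rig(bias = delta * c(cos(phi), sin(phi)))
    s <- experiment_session()
    res <- run_validation(s, rig$recorder, make_cross_layout(5, 0.5),
                          origin = rig$origin, fixate = rig$fixate)
    expect_equal(mean(res$per_target$accuracy_deg), delta,
                 tolerance = 2e-3)
  }
})

test_that("isotropic noise: accuracy matches the Rayleigh mean, sd recovers sigma", {
  sigma <- 0.5
  set.seed(31)
  rig <- make_validation_rig(noise_sd = sigma)
  s <- experiment_session()
  # a single long window giving n = 900 retained samples
  res <- run_validation(s, rig$recorder,
                        make_cross_layout(5, 0.5)[1, , drop = FALSE],
                        origin = rig$origin, fixate = rig$fixate,
                        fixation_window_s = 12, settle_s = 2)
  n <- res$per_target$n_samples[1]
  expect_equal(n, 900)
  acc <- res$per_target$accuracy_deg[1]
  sd_ <- res$per_target$sd_deg[1]

  # mean of a Rayleigh(sigma) is sigma * sqrt(pi / 2)
  rayleigh_mean <- sigma * sqrt(pi / 2)
  rayleigh_sd <- sigma * sqrt((4 - pi) / 2)
  expect_lt(abs(acc - rayleigh_mean), 3 * rayleigh_sd / sqrt(n))

  # sd of the angular errors estimates sigma via the Rayleigh relation;
  # SE(sd) from the asymptotic variance (mu4 - sd^4) / (4 sd^2 n) with the
  # exact Rayleigh fourth central moment
  mu4 <- sigma^4 * (32 - 3 * pi^2) / 4
  se_sd <- sqrt((mu4 - rayleigh_sd^4) / (4 * rayleigh_sd^2 * n))
  sigma_hat <- sd_ / sqrt((4 - pi) / 2)
  expect_lt(abs(sigma_hat - sigma), 3 * se_sd / sqrt((4 - pi) / 2))
})

test_that("rmse^2 = accuracy^2 + ((n-1)/n) sd^2 on every computed result", {
  set.seed(32)
  for (i in 1:5) {
    rig <- make_validation_rig(bias = runif(2, -1, 1),
                               noise_sd = runif(1, 0.1, 0.8))
    s <- experiment_session()
    res <- run_validation(s, rig$recorder, make_cross_layout(5, 0.5),
                          origin = rig$origin, fixate = rig$fixate)
    with(res$per_target, {
      lhs <- rmse_deg^2
      rhs <- accuracy_deg^2 + ((n_samples - 1) / n_samples) * sd_deg^2
      expect_equal(lhs, rhs, tolerance = 1e-12)
    })
  }
})

vec3_normalize_test <- function(v) v / sqrt(sum(v^2))

test_that("targets with no valid samples are flagged and excluded", {
  sc <- scene()
  clk <- frame_clock(90)
  env <- new.env(); env$point <- vec3(0, 0, 0.5); env$broken <- FALSE
  head <- pose(vec3(0, 0, 0))
  rec <- sample_recorder(sc, clk)
  register_node(rec, "head", function(t, f) head)
  register_eye_tracker(rec, function(t, f) {
    if (env$broken) stop("tracker dropout")
    list(origin = vec3(0, 0, 0),
         direction = vec3_normalize_test(env$point))
  })
  s <- experiment_session()
  targets <- make_cross_layout(5, 0.5)
  res <- run_validation(s, rec, targets, fixate = function(p) {
    env$broken <- abs(p[1]) > 1e-6 && p[1] < 0  # drop out on "left" only
    env$point <- p
  })
  expect_equal(res$per_target$flagged,
               c(FALSE, TRUE, FALSE, FALSE, FALSE))
  sm <- summarize_validation(res)
  expect_equal(sm$n_targets, 4)
  expect_lt(sm$mean_accuracy_deg, 1e-9)
})

test_that("summary averages per-target metrics and reports the worst", {
  pt <- data.frame(name = c("c", "l", "r", "d", "u"),
                   accuracy_deg = c(0.4, 0.5, 0.5, 0.55, 0.6),
                   sd_deg = rep(0.2, 5), rmse_deg = rep(0.5, 5),
                   n_samples = rep(72L, 5), flagged = FALSE,
                   stringsAsFactors = FALSE)
  res <- vrtrials:::new_validation_result(pt)
  sm <- summarize_validation(res)
  expect_equal(sm$mean_accuracy_deg, 0.51)
  expect_equal(sm$worst_target, "u")
  expect_equal(sm$worst_accuracy_deg, 0.6)

  pt$flagged <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  sm2 <- summarize_validation(vrtrials:::new_validation_result(pt))
  expect_equal(sm2$n_targets, 4)
  expect_equal(sm2$mean_accuracy_deg, mean(c(0.4, 0.5, 0.5, 0.55)))
  pt$flagged <- TRUE
  expect_error(summarize_validation(vrtrials:::new_validation_result(pt)),
               "all validation targets flagged")
})
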