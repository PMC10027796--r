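test_that("full factorial generation yields the complete crossing", {
  # the example task's design: 3 two-level factors x 10 reps = 80 trials
  trials <- make_factorial_design(design_spec(
    list(pos = c("L", "R"), cue = c("pro", "anti"),
         feedback = c("on", "off")), repetitions = 10))
  expect_length(trials, 80)
  combos <- vapply(trials, function(t)
    paste(t$params$pos, t$params$cue, t$params$feedback), character(1))
  expect_length(unique(combos), 8)
  expect_true(all(table(combos) == 10))

  # degenerate single-cell design
  one <- make_factorial_design(design_spec(list(a = 1), repetitions = 1))
  expect_length(one, 1)
  expect_equal(one[[1]]$params$a, 1)
  expect_equal(one[[1]]$params$repetition, 1)

  # 3 levels x 2 reps, checked against a hand-enumerated cross product
  six <- make_factorial_design(design_spec(list(a = c(1, 2, 3)),
                                           repetitions = 2))
  expect_length(six, 6)
  lv <- vapply(six, function(t) t$params$a, numeric(1))
  expect_equal(lv, c(1, 2, 3, 1, 2, 3))
  expect_true(all(table(lv) == 2))

  expect_error(design_spec(list()), "design error")
  expect_error(design_spec(list(a = character(0))), "design error")
})

test_that("last factor varies fastest, repetitions outermost", {
  trials <- make_factorial_design(design_spec(
    list(first = c("A", "B"), last = c(1, 2)), repetitions = 2))
  lasts <- vapply(trials, function(t) t$params$last, numeric(1))
  firsts <- vapply(trials, function(t) t$params$first, character(1))
  reps <- vapply(trials, function(t) t$params$repetition, numeric(1))
  expect_equal(lasts, c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_equal(firsts, rep(c("A", "A", "B", "B"), 2))
  expect_equal(reps, rep(1:2, each = 4))
})

test_that("trial CSV import infers types and blocks; round trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("target_x,cue,block", "0.3,pro,1", "-0.3,anti,1",
               "0.3,anti,2", "-0.3,pro,2"), path)
  trials <- load_trials_csv(path, block_column = "block")
  expect_length(trials, 4)
  expect_identical(trials[[1]]$params$target_x, 0.3)
  expect_identical(trials[[1]]$params$cue, "pro")
  expect_equal(vapply(trials, function(t) t$block, integer(1)),
               c(1L, 1L, 2L, 2L))

  # save and reload reproduces params
  out <- withr::local_tempfile(fileext = ".csv")
  save_trials_csv(trials, out)
  back <- load_trials_results_csv(out)
  for (i in seq_along(trials))
    expect_equal(vrtrials:::ps_to_list(back[[i]]$params),
                 vrtrials:::ps_to_list(trials[[i]]$params))

  writeLines(c("a,a", "1,2"), path)
  expect_error(load_trials_csv(path), "duplicate")
  writeLines(c("a,b", "1,2"), path)
  expect_error(load_trials_csv(path, block_column = "blk"), "block column")
})

test_that("randomization is a seeded bijection; blocks stay in place", {
  trials <- make_factorial_design(design_spec(
    list(pos = c("L", "R"), cue = c("pro", "anti"),
         feedback = c("on", "off")), repetitions = 10))
  shuffled <- randomize_trials(trials, seed = 42)
  idx <- sort(vapply(shuffled, function(t) t$index, integer(1)))
  expect_equal(idx, 0:79)
  combos <- vapply(shuffled, function(t)
    paste(t$params$pos, t$params$cue, t$params$feedback), character(1))
  expect_true(all(table(combos) == 10))

  again <- randomize_trials(trials, seed = 42)
  expect_equal(vapply(again, function(t) t$index, integer(1)),
               vapply(shuffled, function(t) t$index, integer(1)))
  other <- randomize_trials(trials, seed = 43)
  expect_false(identical(vapply(other, function(t) t$index, integer(1)),
                         vapply(shuffled, function(t) t$index, integer(1))))

  # within-block shuffle: block sequence exactly preserved
  blocked <- lapply(0:7, function(i)
    trial_record(param_set(v = i), index = i, block = i %/% 2))
  ws <- randomize_trials(blocked, seed = 5, within_blocks = TRUE)
  expect_equal(vapply(ws, function(t) t$block, integer(1)),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  for (b in 0:3) {
    members <- sort(vapply(Filter(function(t) t$block == b, ws),
                           function(t) t$index, integer(1)))
    expect_equal(members, c(2L * b, 2L * b + 1L))
  }
})

test_that("randomization does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(randomize_trials(make_factorial_design(list(a = 1:3)), seed = 1))
  expect_identical(runif(1), before)
})

test_that("run_experiment calls pre/main/post in order and numbers trials", {
  trials <- lapply(0:2, function(i) trial_record(param_set(i = i), index = i))
  s <- experiment_session(trials = trials)
  calls <- character(0)
  rec_task <- function(tag) function(trial, session, clock)
    calls <<- c(calls, paste0(tag, trial$number))
  run_experiment(s, main_task = rec_task("main"),
                 pre_task = rec_task("pre"), post_task = rec_task("post"))
  expect_equal(calls, c("pre1", "main1", "post1", "pre2", "main2", "post2",
                        "pre3", "main3", "post3"))
  expect_equal(vapply(s$trials, function(t) t$status, character(1)),
               rep("done", 3))
  expect_equal(vapply(s$trials, function(t) t$number, integer(1)), 1:3)
})

test_that("task failures follow the configured error policy", {
  fail_on_2 <- function(trial, session, clock)
    if (trial$number == 2) stop("boom")

  s <- experiment_session(config = param_set(continue_on_error = TRUE),
                          trials = lapply(0:2, function(i)
                            trial_record(index = i)))
  run_experiment(s, main_task = fail_on_2)
  expect_equal(vapply(s$trials, function(t) t$status, character(1)),
               c("done", "error", "done"))
  expect_match(s$trials[[2]]$results$error_message, "boom")

  # default: abort, remaining trials stay pending
  s2 <- experiment_session(trials = lapply(0:2, function(i)
    trial_record(index = i)))
  run_experiment(s2, main_task = fail_on_2)
  expect_equal(vapply(s2$trials, function(t) t$status, character(1)),
               c("done", "error", "pending"))

  expect_error(run_experiment(experiment_session(), function(...) NULL),
               "run error")
})

test_that("trial status transitions and result writes are guarded", {
  tr <- trial_record()
  expect_error(set_trial_status(tr, "done"), "transition")
  expect_error(set_trial_result(tr, "rt", 0.5), "running")
  set_trial_status(tr, "running")
  set_trial_result(tr, "rt", 0.5)
  expect_equal(tr$results$rt, 0.5)
  set_trial_status(tr, "done")
  expect_error(set_trial_status(tr, "running"), "transition")
})

test_that("session JSON round trip is the identity on persisted fields", {
  trials <- make_factorial_design(design_spec(list(a = 1:2), repetitions = 1))
  s <- experiment_session(metadata = param_set(participant = "p01", seed = 7),
                          config = param_set(continue_on_error = FALSE),
                          trials = trials)
  # attach samples and events to one trial
  set_trial_status(trials[[1]], "running")
  trials[[1]]$samples <- data.frame(
    time = c(0, 1 / 90), frame = c(0, 1), trial = c(1, 1),
    head_pos_x = c(0, 0.1), gaze_hit_x = c(NA, 0.5),
    gaze_hit_object = c(NA, "plane"), stringsAsFactors = FALSE)
  trials[[1]]$events <- list(list(time = 0, frame = 0L, label = "go_cue",
                                  payload = NULL))
  set_trial_status(trials[[1]], "done")

  path <- withr::local_tempfile(fileext = ".json")
  save_session_json(s, path)
  s2 <- load_session_json(path)
  expect_equal(session_snapshot(s2), session_snapshot(s))
  expect_equal(nrow(s2$trials[[1]]$samples), 2)
  expect_identical(s2$trials[[1]]$samples$gaze_hit_object[1], NA_character_)

  # empty session round trip
  e <- experiment_session()
  save_session_json(e, path)
  expect_equal(session_snapshot(load_session_json(path)),
               session_snapshot(e))
})

test_that("unserializable session content names the offending key path", {
  s <- experiment_session(trials = list(trial_record(index = 0L)))
  s$trials[[1]]$results <- structure(list(cb = function() NULL),
                                     class = c("param_set", "list"))
  expect_error(save_session_json(s, tempfile()),
               "serialization error.*results\\.cb")
})

test_that("per-trial CSV uses the key union and supports incremental rows", {
  t1 <- trial_record(param_set(a = 1), index = 0L)
  t2 <- trial_record(param_set(a = 2), index = 1L)
  for (t in list(t1, t2)) set_trial_status(t, "running")
  set_trial_result(t1, "rt", 0.5)
  set_trial_result(t2, "rt", 0.6)
  set_trial_result(t2, "err", 1)
  path <- withr::local_tempfile(fileext = ".csv")
  save_trials_csv(list(t1, t2), path)
  raw <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(raw), 2)
  expect_true(all(c("result.rt", "result.err") %in% names(raw)))
  expect_true(is.na(raw$result.err[1]))
  expect_equal(raw$result.err[2], 1)

  # incremental mode: file grows one row per trial
  inc <- withr::local_tempfile(fileext = ".csv")
  save_trials_csv(list(t1), inc)
  expect_length(readLines(inc), 2)  # header + 1
  save_trials_csv(list(t2), inc, append = TRUE)
  expect_length(readLines(inc), 3)
})
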