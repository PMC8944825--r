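test_that("sessions have the configured block structure and no test feedback", {
  env <- toy2_env()
  q <- toy2_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  log <- simulate_participant(participant_spec("optimal", seed = 4), env,
                              q, cfg)
  expect_equal(sum(log$block == "training"), 10)
  expect_equal(sum(log$block == "test"), 20)
  expect_true(all(vapply(log$feedback[log$block == "test"], is.null,
                         logical(1))))
  expect_true(all(!vapply(log$feedback[log$block == "training"], is.null,
                          logical(1))))
  # clicks strictly precede the move: terminate is always last
  for (comps in log$computations) {
    expect_identical(comps[length(comps)], "terminate")
    expect_false("terminate" %in% comps[-length(comps)])
  }
})

test_that("sessions are deterministic and lapse_rate = 0 reduces to optimal", {
  env <- reduced_env()
  q <- reduced_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  a <- simulate_participant(participant_spec("optimal", seed = 7), env, q,
                            cfg, n_train = 4, n_test = 6)
  b <- simulate_participant(participant_spec("optimal", seed = 7), env, q,
                            cfg, n_train = 4, n_test = 6)
  expect_identical(a$computations, b$computations)
  expect_identical(a$raw_score, b$raw_score)
  lap0 <- simulate_participant(
    participant_spec("backward_lapse", lapse_rate = 0, seed = 7), env, q,
    cfg, n_train = 4, n_test = 6, id = "optimal_7")
  expect_identical(lap0$computations, a$computations)
  expect_identical(lap0$path, a$path)
  lap <- simulate_participant(
    participant_spec("backward_lapse", lapse_rate = 0.8, seed = 7), env, q,
    cfg, n_train = 4, n_test = 6)
  expect_false(identical(lap$computations, a$computations))
})

test_that("non-planners wait the full no-planning delay in training", {
  env <- reduced_env()
  q <- reduced_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  log <- simulate_participant(participant_spec("non_planner", seed = 2),
                              env, q, cfg, n_train = 5, n_test = 5)
  expect_true(all(log$n_clicks == 0))
  train_fb <- log$feedback[log$block == "training"]
  delays <- vapply(train_fb, function(fb) fb$delay[1], numeric(1))
  expect_equal(delays, rep(42, 5))
})

test_that("the forward satisficer is a myopic depth-1 strategy", {
  env <- reduced_env()
  log <- simulate_participant(
    participant_spec("forward_satisficer", satisficing_threshold = 0,
                     seed = 3),
    env, q = NULL, cfg = feedback_config("none"), n_train = 0, n_test = 12)
  for (i in seq_len(nrow(log))) {
    comps <- log$computations[[i]]
    clicks <- comps[comps != "terminate"]
    expect_true(all(grepl("^d1_", clicks)))
    # moves toward the first nonnegative first-step value seen, else best
    vals <- log$values[[i]][seq_along(clicks)]
    target <- if (any(vals >= 0)) clicks[which(vals >= 0)[1]] else
      clicks[which.max(vals)]
    expect_identical(log$path[[i]][1], target)
  }
  expect_false(any(is_backward_planning(log, env)))
})

test_that("feedback mode changes delays but never money scores", {
  env <- reduced_env()
  q <- reduced_q()
  modes <- list(
    calibrate_scaling(env, q, feedback_config("metacognitive_full")),
    calibrate_scaling(env, q, feedback_config("action")),
    feedback_config("none"))
  scores <- lapply(modes, function(cfg) {
    simulate_participant(participant_spec("backward_lapse", seed = 5), env,
                         q, cfg, n_train = 4, n_test = 4)$raw_score
  })
  expect_identical(scores[[1]], scores[[2]])
  expect_identical(scores[[1]], scores[[3]])
})

test_that("trial logs round-trip through JSONL and replay cleanly", {
  env <- reduced_env()
  q <- reduced_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  log <- simulate_participant(participant_spec("backward_lapse", seed = 9),
                              env, q, cfg, n_train = 3, n_test = 3)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_trials_jsonl(log, f)
  back <- read_trials_jsonl(f)
  expect_identical(back$computations, log$computations)
  expect_identical(back$values, log$values)
  expect_identical(back$path, log$path)
  expect_identical(back$raw_score, log$raw_score)
  replayed <- replay_feedback(back, env, q, cfg)
  for (i in which(log$block == "training")) {
    expect_equal(replayed$feedback[[i]]$delay, log$feedback[[i]]$delay)
    expect_equal(replayed$feedback[[i]]$message_key,
                 log$feedback[[i]]$message_key)
  }
  corrupt <- back
  corrupt$computations[[1]] <- c("d1_1", "d1_1", "terminate")
  corrupt$values[[1]] <- c(-4, -4, NA_real_)
  expect_error(replay_feedback(corrupt, env, q, cfg), "illegal")
})

test_that("the fixture suite is complete, deterministic and readable", {
  env <- reduced_env()
  q <- reduced_q()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixture_suite(d1, seed = 42, env = env, q = q,
                           n_train = 3, n_test = 4)
  m2 <- make_fixture_suite(d2, seed = 42, env = env, q = q,
                           n_train = 3, n_test = 4)
  sessions <- grep("^sessions/", m1$files$path, value = TRUE)
  expect_gte(length(sessions), 12)
  expect_identical(m1$files$path, m2$files$path)
  expect_identical(m1$files$md5, m2$files$md5)   # byte-identical reruns
  log <- read_trials_jsonl(file.path(d1, sessions[1]))
  expect_gt(nrow(log), 0)
  expect_true(all(c("computations", "raw_score") %in% names(log)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_silent(read_meta_q(file.path(d1, "toy2_q.json")))
})
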