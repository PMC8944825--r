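test_that("calibration makes the no-planning delay hit the target exactly", {
  toy <- toy2_env()
  q <- toy2_q()
  cfg <- calibrate_scaling(toy, q, feedback_config("metacognitive_full"))
  expect_equal(cfg$scaling_a, (42 - 2) / 0.25)  # = 160 from the toy2 table
  ev <- metacognitive_feedback(q, empty_belief(), "terminate", cfg)
  expect_identical(ev$delay, 42)
  # the unstructured environment is calibrated to the same 42-s target
  cfg_c <- calibrate_scaling(constant_env(), constant_q(),
                             feedback_config("metacognitive_full"))
  ev_c <- metacognitive_feedback(constant_q(), empty_belief(), "terminate",
                                 cfg_c)
  expect_equal(ev_c$delay, 42, tolerance = 1e-12)
})

test_that("calibration fails when planning is worthless", {
  # with a prohibitive click cost the empty-belief loss of terminating is 0
  env <- make_env(2, list(uniform_spec(-1, 1)), click_cost = 10)
  q <- solve_meta(env)
  expect_error(calibrate_scaling(env, q, feedback_config("metacognitive_full")),
               "worthless")
})

test_that("full metacognitive feedback penalizes and instructs", {
  env <- training_env()
  q <- training_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  finals <- env$graph$nodes$id[env$graph$nodes$depth == 3]
  # myopic first click: suboptimal, so delayed, with final nodes highlighted
  ev <- metacognitive_feedback(q, empty_belief(), "d1_1", cfg)
  expect_gt(ev$loss, 0)
  expect_gt(ev$delay, cfg$base_delay)
  expect_true(all(ev$highlighted[[1]] %in% finals))
  expect_gt(length(ev$highlighted[[1]]), 0)
  expect_identical(ev$message_key, "should_have_inspected")
  expect_match(ev$message, "inspected one of the highlighted nodes")
  # clicking on after uncovering the best possible final reward
  b48 <- setNames(48, finals[1])
  ev2 <- metacognitive_feedback(q, b48, "d1_1", cfg)
  expect_identical(ev2$message_key, "should_not_have_inspected")
  expect_match(ev2$message, "shouldn't have inspected")
  expect_length(ev2$highlighted[[1]], 0)
  # an optimal operation: no delay, no highlighting, praise
  opt <- optimal_computations(q)[1]
  ev3 <- metacognitive_feedback(q, empty_belief(), opt, cfg)
  expect_identical(ev3$delay, 0)
  expect_identical(ev3$loss, 0)
  expect_identical(ev3$message, "Good job!")
  expect_length(ev3$highlighted[[1]], 0)
})

test_that("delay decreases with Q and vanishes exactly on the argmax", {
  env <- reduced_env()
  q <- reduced_q()
  cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
  set.seed(13)
  for (i in 1:8) {
    b <- random_belief(env, sample(0:4, 1))
    qv <- q_values(q, b)
    delays <- vapply(qv$computation, function(comp) {
      metacognitive_feedback(q, b, comp, cfg)$delay
    }, numeric(1))
    ord <- order(qv$q)
    expect_true(all(diff(delays[ord]) <= 1e-9))
    on_max <- qv$q >= max(qv$q) - 1e-9
    expect_true(all(delays[on_max] == 0))
    expect_true(all(delays[!on_max] >= cfg$base_delay))
    # highlighting only ever points at unobserved nodes
    for (comp in qv$computation) {
      hl <- metacognitive_feedback(q, b, comp, cfg)$highlighted[[1]]
      expect_length(intersect(hl, names(b)), 0)
    }
  }
})

test_that("component-analysis variants decompose the feedback", {
  env <- reduced_env()
  q <- reduced_q()
  bad <- "d1_1"  # suboptimal first click in the increasing-variance web
  base <- feedback_config("metacognitive_full",
                          unconditional_click_delay = 1,
                          posttrial_delay = 11)
  full <- calibrate_scaling(env, q, base)
  ev_full <- metacognitive_feedback(q, empty_belief(), bad, full)
  # unconditional 1 s + penalty, additive
  expect_equal(ev_full$delay,
               1 + 2 + full$scaling_a * ev_full$loss)
  delay_only <- calibrate_scaling(env, q,
    feedback_config("metacognitive_delay_only",
                    unconditional_click_delay = 1, posttrial_delay = 11))
  ev_d <- metacognitive_feedback(q, empty_belief(), bad, delay_only)
  expect_gt(ev_d$delay, 1)
  expect_length(ev_d$highlighted[[1]], 0)
  expect_identical(ev_d$message_key, "none")
  info_only <- feedback_config("metacognitive_info_only",
                               unconditional_click_delay = 1,
                               posttrial_delay = 1)
  ev_i <- metacognitive_feedback(q, empty_belief(), bad, info_only)
  expect_identical(ev_i$delay, 1)  # info shown for at least 1 s, no penalty
  expect_gt(length(ev_i$highlighted[[1]]), 0)
  none <- feedback_config("none", unconditional_click_delay = 1)
  ev_n <- feedback_for_mode(none, computation = bad)
  expect_identical(ev_n$delay, 1)
  expect_identical(ev_n$message, "")
  # optimal click under the unconditional-delay regime still waits 1 s
  opt <- optimal_computations(q)[1]
  ev_opt <- metacognitive_feedback(q, empty_belief(), opt, full)
  expect_identical(ev_opt$delay, 1)
  expect_identical(ev_opt$message, "Good job!")
})

test_that("action feedback scores the first move against full information", {
  toy <- toy2_env()
  q <- toy2_q()
  cfg <- calibrate_scaling(toy, q, feedback_config("action"))
  truth <- c(d1_1 = 1, d1_2 = -1)
  ev <- action_feedback(toy, truth, "d1_2", cfg)
  expect_equal(ev$loss, 2)  # 1 - (-1) by path enumeration
  expect_equal(ev$delay, 2 + cfg$scaling_a * 2)
  expect_identical(ev$message_key, "should_have_moved")
  expect_match(ev$message, "You should have moved left")
  ev_ok <- action_feedback(toy, truth, "d1_1", cfg)
  expect_identical(ev_ok$loss, 0)
  expect_identical(ev_ok$delay, 0)
  expect_error(action_feedback(toy, truth, "d3_1", cfg), "first move")
  # three-branch environment uses left/up/right labels
  env <- training_env()
  tt <- sample_ground_truth(env, 4)
  paths <- enumerate_paths(env)
  totals <- vapply(paths, function(p) sum(tt[p]), numeric(1))
  best_first <- paths[[which.max(totals)]][1]
  wrong <- setdiff(c("d1_1", "d1_2", "d1_3"), best_first)[1]
  cfg_t <- calibrate_scaling(env, training_q(), feedback_config("action"))
  ev_t <- action_feedback(env, tt, wrong, cfg_t)
  lab <- c(d1_1 = "left", d1_2 = "up", d1_3 = "right")[best_first]
  expect_match(ev_t$message, lab)
})
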