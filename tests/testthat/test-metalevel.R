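test_that("legal computations are the unobserved nodes plus terminate", {
  toy <- toy2_env()
  expect_setequal(legal_computations(toy, empty_belief()),
                  c("d1_1", "d1_2", "terminate"))
  full <- belief(d1_1 = 1, d1_2 = -1)
  expect_identical(legal_computations(toy, full), "terminate")
  expect_length(legal_computations(training_env(), empty_belief()), 13)
})

test_that("belief updates are single, legal and non-destructive", {
  b0 <- empty_belief()
  b1 <- update_belief(b0, "d1_1", 1)
  expect_length(b0, 0)
  expect_equal(b1, c(d1_1 = 1))
  expect_error(update_belief(b1, "d1_1", -1), "already observed")
  expect_error(update_belief(b1, "terminate", 0))
  expect_error(update_belief(b1, "d1_2", 99, env = toy2_env()),
               "support")
  expect_length(update_belief(b1, "d1_2", -1), 2)
})

test_that("termination value is the best expected path under the belief", {
  toy <- toy2_env()
  expect_equal(termination_value(toy, empty_belief()), 0)
  expect_equal(termination_value(toy, belief(d1_1 = 1)), 1)
  expect_equal(termination_value(toy, belief(d1_1 = -1)), 0)
  env <- training_env()
  expect_equal(termination_value(env, belief(d3_1 = 48)), 48)
  # independent check by direct path enumeration on a random belief
  set.seed(42)
  b <- random_belief(env, 5)
  mu <- c(0, 0, 0)
  ev <- vapply(enumerate_paths(env), function(p) {
    sum(ifelse(p %in% names(b), b[p], 0))
  }, numeric(1))
  expect_equal(termination_value(env, b), max(ev))
})

test_that("toy2 solution matches the closed form", {
  q <- toy2_q()
  qv <- q_values(q)
  expect_equal(qv$q[qv$computation == "d1_1"], 0.25, tolerance = 1e-12)
  expect_equal(qv$q[qv$computation == "d1_2"], 0.25, tolerance = 1e-12)
  expect_equal(qv$q[qv$computation == "terminate"], 0, tolerance = 1e-12)
  expect_equal(q$root_value, 0.25, tolerance = 1e-12)
  expect_equal(compute_loss(q, empty_belief(), "terminate"), 0.25,
               tolerance = 1e-12)
  expect_equal(compute_loss(q, empty_belief(), "d1_1"), 0)
  expect_setequal(optimal_computations(q), c("d1_1", "d1_2"))
  # after a bad first observation, stopping is optimal: the second click
  # is worth E[max(-1, X)] - 0.25 = -0.25 < 0
  b <- belief(d1_1 = -1)
  expect_identical(optimal_computations(q, b), "terminate")
  expect_equal(q_values(q, b)$q, c(-0.25, 0), tolerance = 1e-12)
})

test_that("gaussian environments are rejected by the exact solver", {
  expect_error(solve_meta(preset_env("transfer_5step")),
               "goal-setting")
})

test_that("solver agrees with the brute-force oracle on toy environments", {
  t0 <- Sys.time()
  for (env in list(toy2_env(), two_step_env(), reduced_env())) {
    q <- solve_meta(env)
    o <- brute_force_oracle(env)
    expect_equal(q$root_value, o$root_value, tolerance = 1e-9)
    set.seed(7)
    for (i in 1:60) {
      b <- random_belief(env)
      qa <- q_values(q, b)
      qb <- q_values(o, b)
      expect_identical(qa$computation, qb$computation)
      expect_lt(max(abs(qa$q - qb$q)), 1e-9)
    }
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
})

test_that("the oracle refuses large environments", {
  expect_error(brute_force_oracle(training_env()), "refuses")
})

test_that("Q table invariants hold on randomly sampled beliefs", {
  env <- reduced_env()
  q <- reduced_q()
  set.seed(99)
  for (i in 1:40) {
    b <- random_belief(env)
    qv <- q_values(q, b)
    v <- max(qv$q)
    qterm <- qv$q[qv$computation == "terminate"]
    # value of information: V(b) >= Q(b, terminate), which equals the
    # termination value exactly
    expect_gte(v, qterm)
    expect_equal(qterm, termination_value(env, b), tolerance = 1e-9)
    opt <- optimal_computations(q, b)
    expect_gt(length(opt), 0)
    for (comp in opt) expect_equal(compute_loss(q, b, comp), 0)
    sub <- setdiff(qv$computation, opt)
    for (comp in head(sub, 3)) expect_gt(compute_loss(q, b, comp), 1e-9)
  }
})

test_that("values are invariant under branch permutations", {
  env <- reduced_env()
  q <- reduced_q()
  # swap the two branches of a belief: d*_1 <-> d*_2, leaves 1,2 <-> 3,4
  swap <- c(d1_1 = "d1_2", d1_2 = "d1_1", d2_1 = "d2_2", d2_2 = "d2_1",
            d3_1 = "d3_3", d3_2 = "d3_4", d3_3 = "d3_1", d3_4 = "d3_2")
  set.seed(3)
  for (i in 1:20) {
    b <- random_belief(env)
    pb <- setNames(as.numeric(b), unname(swap[names(b)]))
    expect_equal(max(q_values(q, b)$q), max(q_values(q, pb)$q),
                 tolerance = 1e-9)
    expect_identical(canonicalize(env, b), canonicalize(env, pb))
  }
})

test_that("canonical keys separate beliefs that differ in observed values", {
  toy <- toy2_env()
  expect_identical(canonicalize(toy, belief(d1_1 = 1)),
                   canonicalize(toy, belief(d1_2 = 1)))
  expect_false(identical(canonicalize(toy, belief(d1_1 = 1)),
                         canonicalize(toy, belief(d1_1 = -1))))
  expect_false(identical(canonicalize(toy, belief(d1_1 = 1)),
                         canonicalize(toy, empty_belief())))
})

test_that("illegal or malformed queries raise errors", {
  q <- toy2_q()
  expect_error(compute_loss(q, belief(d1_1 = 1), "d1_1"), "not legal")
  expect_error(q_values(q, belief(bogus = 1)), "unknown")
  expect_error(q_values(q, belief(d1_1 = 3)), "support")
})

test_that("the discovered strategy starts at the final step", {
  # in the increasing-variance web every optimal first computation
  # inspects a final-step node, and uncovering the best possible final
  # reward makes immediate termination the unique optimal computation
  for (pair in list(list(reduced_env(), reduced_q()),
                    list(training_env(), training_q()))) {
    env <- pair[[1]]
    q <- pair[[2]]
    finals <- env$graph$nodes$id[env$graph$nodes$depth == 3]
    opt <- optimal_computations(q)
    expect_gt(length(opt), 0)
    expect_true(all(opt %in% finals))
    b48 <- setNames(48, finals[1])
    expect_identical(optimal_computations(q, b48), "terminate")
  }
})

test_that("small Q tables serialize and round-trip through JSON", {
  toy <- toy2_env()
  q <- toy2_q()
  f <- withr::local_tempfile(fileext = ".json")
  write_meta_q(q, f)
  back <- read_meta_q(f)
  expect_equal(back$root_value, q$root_value)
  expect_equal(back$env, "toy2")
  # the empty-belief entry reproduces the solved Q values
  key0 <- canonicalize(toy, empty_belief())
  e0 <- back$table[back$table$key == key0, ]
  expect_equal(sort(e0$q), sort(q_values(q)$q), tolerance = 1e-12)
  expect_error(write_meta_q(training_q(), withr::local_tempfile()),
               "<= 6")
})
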