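# Shared fixtures. Solved Q tables are cached across test files because the
# full training solve takes a few seconds.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

uniform_spec <- function(...) reward_spec("discrete", support = c(...))

toy2_env <- function() cached("toy2_env", function() preset_env("toy2"))
toy2_q <- function() cached("toy2_q", function() solve_meta(toy2_env()))

two_step_env <- function() cached("two_step_env", function() {
  make_env(c(2, 1), list(uniform_spec(-4, -2, 2, 4),
                         uniform_spec(-48, -24, 24, 48)),
           click_cost = 1, name = "two_step")
})

reduced_env <- function() cached("reduced_env", function() {
  preset_env("training_3step", branching = c(2, 1, 2))
})
reduced_q <- function() cached("reduced_q", function() solve_meta(reduced_env()))

training_env <- function() cached("training_env",
                                  function() preset_env("training_3step"))
training_q <- function() cached("training_q",
                                function() solve_meta(training_env()))

constant_env <- function() cached("constant_env",
                                  function() preset_env("constant_3step"))
constant_q <- function() cached("constant_q",
                                function() solve_meta(constant_env()))

# random valid belief for a discrete environment, drawn with the ambient RNG
random_belief <- function(env, n_obs = NULL) {
  ids <- env$graph$nodes$id[env$graph$nodes$depth > 0]
  n_obs <- n_obs %||% sample(0:length(ids), 1)
  if (n_obs == 0) return(empty_belief())
  obs <- sample(ids, n_obs)
  setNames(vapply(obs, function(id) {
    d <- env$graph$nodes$depth[match(id, env$graph$nodes$id)]
    sample(env$reward_by_depth[[d]]$support, 1)
  }, numeric(1)), obs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

derive_seed_test <- function(...) metatutor:::derive_seed(...)

# light rollout wrapper reporting click count and chosen leaf only
rollout_ends <- function(pol, env, truth, seed) {
  r <- rollout(pol, env, truth, seed = seed)
  path <- r$path[[1]]
  list(n_clicks = r$n_clicks, leaf = path[length(path)])
}

# first final-step node the goal-setting policy checks under a fixed
# check-order seed (reproduces the policy's own order draw)
with_order_first <- function(env, seed) {
  nodes <- env$graph$nodes
  finals <- nodes$id[nodes$depth == max(nodes$depth)]
  withr::with_seed(seed, sample(finals))[1]
}
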