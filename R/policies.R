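#' Planning policies
#'
#' A policy decides, in each belief state, which computation to perform
#' next (a click or `"terminate"`), and optionally how to choose the path
#' after terminating. Policies are executed with [rollout()] and evaluated
#' with [evaluate_policy()].
#'
#' * `optimal_policy(q)` follows the exactly solved metalevel policy,
#'   breaking ties deterministically (terminate preferred, then the first
#'   unobserved node in depth/index order).
#' * `random_baseline()` performs no planning: it terminates immediately
#'   and picks a path uniformly at random — the chance anchor of the
#'   relative score.
#' * `goal_setting_policy(params)` checks final-step nodes in random order
#'   until one exceeds the threshold, then commits to the path through it;
#'   if none does, it commits to the best final value seen. This
#'   approximates the strategy taught by the tutor and anchors the optimal
#'   score in environments too large to solve exactly.
#'
#' @param q A solved `meta_q` from [solve_meta()].
#' @return A policy object.
#' @name policies
NULL

#' @rdname policies
#' @export
optimal_policy <- function(q) {
  structure(list(kind = "optimal", q = q), class = c("optimal_policy",
                                                     "policy"))
}

#' @rdname policies
#' @export
random_baseline <- function() {
  structure(list(kind = "random"), class = c("random_policy", "policy"))
}

#' Parameters of the goal-setting strategy
#'
#' @param threshold Reward value; final-step nodes are checked until one is
#'   revealed *strictly above* this threshold. Must lie within the range of
#'   the final-step support (discrete) or within 4 standard deviations of
#'   the mean (gaussian) of the environment it is used in; checked at
#'   rollout time.
#' @param check_order_seed Optional integer; if supplied, the random check
#'   order of final-step nodes is fixed across rollouts. By default the
#'   order is drawn from the rollout's own random stream.
#' @return A `goal_setting_params` object.
#' @export
goal_setting_params <- function(threshold, check_order_seed = NULL) {
  structure(list(threshold = as.numeric(threshold),
                 check_order_seed = check_order_seed),
            class = "goal_setting_params")
}

#' @rdname policies
#' @param params A [goal_setting_params()] object (or a bare threshold).
#' @export
goal_setting_policy <- function(params) {
  if (is.numeric(params)) params <- goal_setting_params(params)
  structure(list(kind = "goal_setting", params = params),
            class = c("goal_setting_policy", "policy"))
}

#' @export
print.policy <- function(x, ...) {
  cat("<policy>", x$kind, "\n")
  invisible(x)
}

# ----------------------------------------------------------- policy protocol

policy_init <- function(policy, env) UseMethod("policy_init")
policy_step <- function(policy, env, belief, state) UseMethod("policy_step")
policy_path <- function(policy, env, belief, state, paths) {
  UseMethod("policy_path")
}

#' @export
policy_init.policy <- function(policy, env) list()
#' @export
policy_path.policy <- function(policy, env, belief, state, paths) NULL

#' @export
policy_step.optimal_policy <- function(policy, env, belief, state) {
  list(computation = optimal_computation(policy$q, belief), state = state)
}

#' @export
policy_step.random_policy <- function(policy, env, belief, state) {
  list(computation = TERMINATE, state = state)
}
#' @export
policy_path.random_policy <- function(policy, env, belief, state, paths) {
  paths[[sample.int(length(paths), 1)]]
}

final_nodes <- function(env) {
  env$graph$nodes$id[env$graph$nodes$depth == max_depth(env)]
}

check_threshold <- function(env, threshold) {
  spec <- env$reward_by_depth[[max_depth(env)]]
  ok <- if (spec$kind == "discrete") {
    threshold >= min(spec$support) && threshold <= max(spec$support)
  } else {
    abs(threshold - spec$mean) <= 4 * spec$sd
  }
  if (!ok) abort("goal-setting threshold outside the final-step reward range")
}

#' @export
policy_init.goal_setting_policy <- function(policy, env) {
  check_threshold(env, policy$params$threshold)
  finals <- final_nodes(env)
  seed <- policy$params$check_order_seed
  order <- if (is.null(seed)) sample(finals) else
    with_private_seed(seed, sample(finals))
  list(order = order, i = 1L, target = NULL)
}

#' @export
policy_step.goal_setting_policy <- function(policy, env, belief, state) {
  th <- policy$params$threshold
  checked <- state$order[seq_len(state$i - 1L)]
  vals <- belief[checked]
  hit <- checked[which(vals > th)]
  if (length(hit) > 0) {
    state$target <- hit[1]
    return(list(computation = TERMINATE, state = state))
  }
  if (state$i > length(state$order)) {
    state$target <- checked[which.max(vals)]  # first encountered maximum
    return(list(computation = TERMINATE, state = state))
  }
  node <- state$order[state$i]
  state$i <- state$i + 1L
  list(computation = node, state = state)
}

#' @export
policy_path.goal_setting_policy <- function(policy, env, belief, state,
                                            paths) {
  through <- purrr::keep(paths, function(p) state$target %in% p)
  best_expected_path(env, belief, through)
}

# expected-value-maximizing path; ties broken by listing order
best_expected_path <- function(env, belief, paths) {
  mu <- vapply(env$reward_by_depth, spec_mean, numeric(1))
  depths <- setNames(env$graph$nodes$depth, env$graph$nodes$id)
  ev <- vapply(paths, function(p) {
    obs <- p %in% names(belief)
    sum(ifelse(obs, belief[p], mu[depths[p]]))
  }, numeric(1))
  paths[[which.max(ev)]]
}

# ---------------------------------------------------------------- rollouts

# lean internal rollout returning a plain list
rollout_raw <- function(policy, env, truth, seed = NULL) {
  if (!is.null(seed)) return(with_private_seed(seed, {
    rollout_raw(policy, env, truth)
  }))
  paths <- enumerate_paths(env)
  b <- empty_belief()
  comps <- character(0)
  vals <- numeric(0)
  state <- policy_init(policy, env)
  n_max <- n_reward_nodes(env) + 1L
  repeat {
    res <- policy_step(policy, env, b, state)
    comp <- res$computation
    state <- res$state
    comps <- c(comps, comp)
    if (identical(comp, TERMINATE)) {
      vals <- c(vals, NA_real_)
      break
    }
    if (comp %in% names(b) || !comp %in% reward_nodes(env)) {
      abort(paste0("policy emitted an illegal computation: ", comp))
    }
    v <- truth[[comp]]
    vals <- c(vals, v)
    b <- update_belief(b, comp, v)
    if (length(comps) >= n_max) abort("policy failed to terminate")
  }
  path <- policy_path(policy, env, b, state, paths) %||%
    best_expected_path(env, b, paths)
  n_clicks <- length(comps) - 1L
  list(env = env$name, computations = comps, values = vals, path = path,
       n_clicks = n_clicks,
       raw_score = sum(truth[path]) - env$click_cost * n_clicks)
}

#' Execute one trial of a policy against a ground truth
#'
#' The policy's computations are applied in sequence, revealing
#' ground-truth values on clicks, until it terminates; the chosen path then
#' maximizes expected return under the final belief (ties broken by path
#' order) unless the policy prescribes its own path rule.
#'
#' @param policy A policy (see [policies]).
#' @param env An `env_config`.
#' @param truth Ground truth from [sample_ground_truth()].
#' @param seed Optional integer; if given, the rollout's randomness is
#'   drawn from a private stream seeded with it.
#' @return A one-row tibble (a trial record) with list columns
#'   `computations`, `values`, `path`, `feedback` and scalar columns `env`,
#'   `n_clicks`, `raw_score`.
#' @export
rollout <- function(policy, env, truth, seed = NULL) {
  r <- rollout_raw(policy, env, truth, seed)
  tibble::tibble(env = r$env, computations = list(r$computations),
                 values = list(r$values), path = list(r$path),
                 n_clicks = r$n_clicks, raw_score = r$raw_score,
                 feedback = list(NULL))
}

#' Optimize the goal-setting threshold by Monte-Carlo search
#'
#' Each candidate threshold is evaluated by the mean raw score of the
#' goal-setting strategy over a common set of seeded ground truths (common
#' random numbers across candidates); the argmax is returned, with ties
#' going to the smallest threshold.
#'
#' @param env An `env_config`.
#' @param candidates Candidate thresholds. Defaults to the final-step
#'   support values plus their midpoints (discrete) or 17 evenly spaced
#'   quantiles of the final-step distribution (gaussian).
#' @param n_sim Simulations per candidate.
#' @param seed Integer seed; the selection is deterministic given it.
#' @return A `threshold_opt` object: the chosen [goal_setting_params()]
#'   plus a per-candidate evaluation table.
#' @export
optimize_threshold <- function(env, candidates = NULL, n_sim = 1000,
                               seed = 1) {
  if (n_sim < 1) abort("n_sim must be >= 1")
  spec <- env$reward_by_depth[[max_depth(env)]]
  if (is.null(candidates)) {
    candidates <- if (spec$kind == "discrete") {
      s <- sort(spec$support)
      sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
    } else {
      spec$mean + spec$sd * stats::qnorm(seq_len(17) / 18)
    }
  }
  if (length(candidates) == 0) abort("candidates must be nonempty")
  candidates <- sort(as.numeric(candidates))
  truth_seeds <- with_private_seed(derive_seed(seed, "truths"),
                                   sample.int(2147483646L, n_sim))
  truths <- lapply(truth_seeds, function(s) sample_ground_truth(env, s))
  evals <- lapply(candidates, function(th) {
    pol <- goal_setting_policy(goal_setting_params(th))
    scores <- vapply(seq_len(n_sim), function(i) {
      rollout_raw(pol, env, truths[[i]],
                  seed = derive_seed(seed, "order", i))$raw_score
    }, numeric(1))
    c(mean(scores), stats::sd(scores) / sqrt(n_sim))
  })
  means <- vapply(evals, `[`, numeric(1), 1)
  best <- candidates[which.max(means)]  # which.max: first (smallest) at ties
  structure(list(params = goal_setting_params(best),
                 evaluations = tibble::tibble(
                   threshold = candidates, mean_raw_score = means,
                   se = vapply(evals, `[`, numeric(1), 2)),
                 n_sim = n_sim, seed = seed),
            class = "threshold_opt")
}

#' @export
print.threshold_opt <- function(x, ...) {
  cat("<threshold_opt> chosen threshold:", x$params$threshold,
      sprintf("(%d candidates x %d simulations)\n",
              nrow(x$evaluations), x$n_sim))
  invisible(x)
}

#' Monte-Carlo evaluation of a policy's expected raw score
#'
#' Runs `n` independent seeded rollouts on freshly sampled ground truths
#' and summarizes the mean raw score with its standard error and a
#' percentile bootstrap confidence interval (1,000 resamples, seeded).
#'
#' @inheritParams rollout
#' @param n Number of rollouts (at least 2).
#' @param seed Integer seed controlling ground truths, rollout randomness
#'   and the bootstrap.
#' @param n_boot Bootstrap resamples.
#' @return A `policy_eval` object with fields `mean`, `se`, `ci_lo`,
#'   `ci_hi`, `n` and the raw `scores`.
#' @export
evaluate_policy <- function(policy, env, n = 1000, seed = 1, n_boot = 1000) {
  if (n < 2) abort("n must be >= 2")
  truth_seeds <- with_private_seed(derive_seed(seed, "truths"),
                                   sample.int(2147483646L, n))
  scores <- vapply(seq_len(n), function(i) {
    truth <- sample_ground_truth(env, truth_seeds[i])
    rollout_raw(policy, env, truth, seed = derive_seed(seed, "roll", i))$raw_score
  }, numeric(1))
  boot <- with_private_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(i) {
      mean(scores[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(mean = mean(scores), se = stats::sd(scores) / sqrt(n),
                 ci_lo = ci[1], ci_hi = ci[2], n = n, scores = scores,
                 policy = policy$kind, env = env$name),
            class = "policy_eval")
}

#' @export
print.policy_eval <- function(x, ...) {
  cat(sprintf("<policy_eval> %s on %s: mean %.4g (SE %.3g, 95%% CI [%.4g, %.4g], n = %d)\n",
              x$policy, x$env, x$mean, x$se, x$ci_lo, x$ci_hi, x$n))
  invisible(x)
}
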