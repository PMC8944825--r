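#' Chance and optimal anchors for the relative score
#'
#' The relative score normalizes raw money scores so that 0 is the
#' expected score of choosing a path uniformly at random with no clicks
#' (chance) and 100 is (approximately) optimal performance. In exactly
#' solvable environments the optimal anchor is the solver's value of the
#' empty belief and the chance anchor is computed in closed form (the mean
#' over paths of the prior depth means). In environments too large to
#' solve exactly, the optimal anchor is approximated by the optimized
#' goal-setting strategy and the chance anchor by Monte-Carlo.
#'
#' @param env An `env_config`.
#' @param mode `"exact"` (discrete, solvable environments) or
#'   `"goal_setting_approx"`.
#' @param n_sim Simulations for the approximate mode.
#' @param seed Integer seed for the approximate mode.
#' @param q Optional pre-solved `meta_q` (exact mode), to avoid re-solving.
#' @param candidates Optional threshold candidates passed to
#'   [optimize_threshold()].
#' @return A `score_norm` object with fields `s_opt`, `s_rand`, `method`,
#'   `env`.
#' @export
score_norm <- function(env, mode = c("exact", "goal_setting_approx"),
                       n_sim = 1000, seed = 1, q = NULL, candidates = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (!is_discrete_env(env)) {
      abort("exact score_norm requires a discrete (solvable) environment")
    }
    q <- q %||% solve_meta(env)
    s_opt <- q$root_value
    mu <- vapply(env$reward_by_depth, spec_mean, numeric(1))
    depths <- setNames(env$graph$nodes$depth, env$graph$nodes$id)
    s_rand <- mean(vapply(enumerate_paths(env),
                          function(p) sum(mu[depths[p]]), numeric(1)))
  } else {
    opt <- optimize_threshold(env, candidates = candidates, n_sim = n_sim,
                              seed = seed)
    ev <- evaluate_policy(goal_setting_policy(opt$params), env, n = n_sim,
                          seed = derive_seed(seed, "opt"))
    s_opt <- ev$mean
    s_rand <- evaluate_policy(random_baseline(), env, n = n_sim,
                              seed = derive_seed(seed, "rand"))$mean
  }
  if (s_opt <= s_rand) {
    abort("normalization undefined: optimal anchor does not exceed chance")
  }
  structure(list(s_opt = s_opt, s_rand = s_rand, method = mode,
                 env = env$name), class = "score_norm")
}

#' @export
print.score_norm <- function(x, ...) {
  cat(sprintf("<score_norm> %s (%s): s_opt = %.4g, s_rand = %.4g\n",
              x$env, x$method, x$s_opt, x$s_rand))
  invisible(x)
}

#' Relative score: 0 is chance, 100 is optimal
#'
#' `100 * (s - s_rand) / (s_opt - s_rand)`. Affine and strictly increasing
#' in `s`; individual trials may score below 0 or above 100.
#'
#' @param s Raw money score(s); vectorized.
#' @param norm A [score_norm()] object.
#' @return Relative score(s) in points.
#' @export
relative_score <- function(s, norm) {
  if (norm$s_opt <= norm$s_rand) abort("normalization undefined")
  100 * (s - norm$s_rand) / (norm$s_opt - norm$s_rand)
}

#' Did a trial start with backward planning?
#'
#' Backward planning is operationalized as the first click landing on a
#' final-step node (a node reached after the last move). Trials with zero
#' clicks count as not planning backward.
#'
#' @param trials A tibble of trial records (from [rollout()] or
#'   [simulate_participant()]).
#' @param env The `env_config` the trials were generated in.
#' @return Logical vector, one entry per trial.
#' @export
is_backward_planning <- function(trials, env) {
  finals <- final_nodes(env)
  vapply(trials$computations, function(comps) {
    comps[1] %in% finals
  }, logical(1))
}

#' Summarize trials on the relative-score scale
#'
#' Averages first within participant (relative score and backward-planning
#' rate over that participant's trials), then across participants, with
#' percentile bootstrap confidence intervals from participant-level
#' resampling (1,000 resamples, seeded). If a `condition` column is
#' present, summaries are computed per condition.
#'
#' @param trials A tibble of trial records; optional `participant` and
#'   `condition` columns.
#' @param norm A [score_norm()] for the trials' environment.
#' @param env The `env_config` (for the backward-planning classifier).
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return A `session_summary`: list with `participants` (per-participant
#'   means) and `overall` (per-condition means with CIs).
#' @export
summarize_trials <- function(trials, norm, env, n_boot = 1000, seed = 1) {
  if (nrow(trials) == 0) abort("no trials to summarize")
  df <- tibble::as_tibble(trials)
  if (!"participant" %in% names(df)) df$participant <- "p1"
  if (!"condition" %in% names(df)) df$condition <- "all"
  df$relative <- relative_score(df$raw_score, norm)
  df$backward <- is_backward_planning(df, env)
  participants <- df |>
    dplyr::group_by(.data$condition, .data$participant) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_relative_score = mean(.data$relative),
                     backward_rate = mean(.data$backward),
                     .groups = "drop")
  boot_ci <- function(x, stream) {
    if (length(x) == 1) return(c(x, x))
    with_private_seed(derive_seed(seed, stream), {
      b <- vapply(seq_len(n_boot), function(i) {
        mean(x[sample.int(length(x), length(x), replace = TRUE)])
      }, numeric(1))
      unname(quantile(b, c(0.025, 0.975)))
    })
  }
  overall <- participants |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(g, key) {
      ci_s <- boot_ci(g$mean_relative_score, paste0(key$condition, "_score"))
      ci_b <- boot_ci(g$backward_rate, paste0(key$condition, "_back"))
      tibble::tibble(n = nrow(g),
                     mean_relative_score = mean(g$mean_relative_score),
                     ci_lo = ci_s[1], ci_hi = ci_s[2],
                     backward_rate = mean(g$backward_rate),
                     backward_ci_lo = ci_b[1], backward_ci_hi = ci_b[2])
    }) |>
    dplyr::ungroup()
  structure(list(participants = participants, overall = overall,
                 env = norm$env, method = norm$method),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>", x$env, "\n")
  print(x$overall)
  invisible(x)
}

#' Write a session summary as CSV or JSON
#'
#' The CSV has one row per condition: `condition, n, mean_relative_score,
#' ci_lo, ci_hi, backward_rate, backward_ci_lo, backward_ci_hi`.
#'
#' @param summary A `session_summary` from [summarize_trials()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  write.csv(summary$overall, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(list(env = summary$env, method = summary$method,
                            overall = summary$overall,
                            participants = summary$participants),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
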