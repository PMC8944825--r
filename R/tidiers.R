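#' Tidy a solved metalevel Q table at a belief
#'
#' @param x A `meta_q`.
#' @param belief Belief state to query (default empty).
#' @param ... Unused.
#' @return A tibble with one row per legal computation: `computation`,
#'   `q`, `loss`, `optimal`.
#' @export
tidy.meta_q <- function(x, belief = empty_belief(), ...) {
  qv <- q_values(x, belief)
  qv$loss <- max(qv$q) - qv$q
  qv$optimal <- qv$loss <= 1e-9
  qv
}

#' @rdname tidy.meta_q
#' @export
glance.meta_q <- function(x, ...) {
  tibble::tibble(env = x$env$name, solver = x$solver,
                 n_reward_nodes = n_reward_nodes(x$env),
                 n_states = x$n_states, root_value = x$root_value)
}

#' @export
tidy.policy_eval <- function(x, ...) {
  tibble::tibble(policy = x$policy, env = x$env, mean = x$mean, se = x$se,
                 ci_lo = x$ci_lo, ci_hi = x$ci_hi, n = x$n)
}

#' @export
glance.policy_eval <- function(x, ...) tidy.policy_eval(x)

#' @export
tidy.threshold_opt <- function(x, ...) x$evaluations

#' @export
glance.threshold_opt <- function(x, ...) {
  tibble::tibble(threshold = x$params$threshold, n_sim = x$n_sim,
                 n_candidates = nrow(x$evaluations))
}

#' @export
tidy.score_norm <- function(x, ...) {
  tibble::tibble(env = x$env, method = x$method, s_opt = x$s_opt,
                 s_rand = x$s_rand)
}

#' @export
glance.score_norm <- function(x, ...) tidy.score_norm(x)

#' @export
tidy.session_summary <- function(x, ...) x$participants

#' @export
glance.session_summary <- function(x, ...) x$overall

# --------------------------------------------------------------------- plots

#' Plot Q values of the legal computations at a belief
#'
#' @param object A `meta_q`.
#' @param belief Belief state (default empty).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_q <- function(object, belief = empty_belief(), ...) {
  df <- tidy.meta_q(object, belief)
  df$computation <- factor(df$computation, levels = df$computation)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$computation, y = .data$q,
                                   fill = .data$optimal)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey65")) +
    ggplot2::labs(x = "computation", y = "Q(b, c)",
                  title = paste0("Metalevel Q values (", object$env$name,
                                 ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the goal-setting threshold search
#'
#' @param object A `threshold_opt` from [optimize_threshold()].
#' @param ... Unused.
#' @return A ggplot of mean raw score against candidate threshold; the
#'   chosen threshold is marked.
#' @export
autoplot.threshold_opt <- function(object, ...) {
  df <- object$evaluations
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$mean_raw_score)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$params$threshold,
                        linetype = "dashed", color = "#d95f02") +
    ggplot2::labs(x = "candidate threshold", y = "mean raw score",
                  title = "Goal-setting threshold optimization") +
    ggplot2::theme_minimal()
}

#' Plot condition summaries of simulated sessions
#'
#' @param object A `session_summary` from [summarize_trials()].
#' @param ... Unused.
#' @return A ggplot of mean relative score per condition with bootstrap
#'   CIs.
#' @export
autoplot.session_summary <- function(object, ...) {
  df <- object$overall
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_relative_score)) +
    ggplot2::geom_col(fill = "#2c7fb8", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::labs(x = NULL, y = "relative score (0 = chance, 100 = optimal)",
                  title = paste0("Test performance by condition (",
                                 object$env, ")")) +
    ggplot2::theme_minimal()
}
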