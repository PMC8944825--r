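#' Tutor feedback configuration
#'
#' Controls how the regret (loss) of each planning operation is translated
#' into delay penalties, highlighting and messages.
#'
#' Modes:
#' * `metacognitive_full` — delay penalty `base_delay + a * loss` plus
#'   instruction (highlighted optimal clicks / messages); the tutor used in
#'   the main training condition.
#' * `metacognitive_delay_only` — the delay penalty without instruction.
#' * `metacognitive_info_only` — instruction shown for at least 1 s, no
#'   loss-proportional delay.
#' * `action` — feedback on the first move only, using the task-level
#'   (full-information) loss.
#' * `none` — no feedback beyond the unconditional click delay.
#'
#' @param mode Feedback mode (see above).
#' @param base_delay Seconds added to every nonzero penalty (default 2).
#' @param scaling_a Seconds of delay per money unit of loss; set by
#'   [calibrate_scaling()] so that terminating at the empty belief (acting
#'   without any planning) costs `target_no_planning_delay` seconds.
#' @param target_no_planning_delay Calibration target in seconds
#'   (default 42).
#' @param unconditional_click_delay Seconds of delay after every click
#'   regardless of quality (default 0; the component-analysis variants
#'   use 1).
#' @param posttrial_delay Seconds of delay after each training trial
#'   (default 0; 11 in delay-bearing component-analysis conditions,
#'   1 otherwise).
#' @param min_planning_time Minimum seconds of planning time enforced by
#'   the interface (default 7); recorded as configuration only — the
#'   package never sleeps.
#' @return A `feedback_config` object.
#' @export
feedback_config <- function(mode = c("metacognitive_full",
                                     "metacognitive_delay_only",
                                     "metacognitive_info_only",
                                     "action", "none"),
                            base_delay = 2, scaling_a = NULL,
                            target_no_planning_delay = 42,
                            unconditional_click_delay = 0,
                            posttrial_delay = 0, min_planning_time = 7) {
  mode <- match.arg(mode)
  delays <- c(base_delay, target_no_planning_delay,
              unconditional_click_delay, posttrial_delay, min_planning_time)
  if (any(delays < 0)) abort("all delays must be nonnegative")
  if (!is.null(scaling_a) && scaling_a <= 0) {
    abort("scaling_a must be positive")
  }
  structure(list(mode = mode, base_delay = base_delay,
                 scaling_a = scaling_a,
                 target_no_planning_delay = target_no_planning_delay,
                 unconditional_click_delay = unconditional_click_delay,
                 posttrial_delay = posttrial_delay,
                 min_planning_time = min_planning_time),
            class = "feedback_config")
}

#' @export
print.feedback_config <- function(x, ...) {
  cat("<feedback_config>", x$mode, "\n")
  cat("  delay = ", x$base_delay, " + a * loss, a =",
      x$scaling_a %||% "(uncalibrated)", "\n")
  invisible(x)
}

feedback_messages <- c(
  good_job = "Good job!",
  should_have_inspected = "You should have inspected one of the highlighted nodes.",
  should_not_have_inspected = "You shouldn't have inspected any more nodes.",
  should_have_moved = "You should have moved %s.",
  none = ""
)

feedback_event <- function(computation, loss, delay, highlighted = character(0),
                           message_key = "none", message_args = NULL) {
  msg <- feedback_messages[[message_key]]
  if (message_key == "should_have_moved") {
    msg <- sprintf(msg, paste(message_args, collapse = "/"))
  }
  tibble::tibble(computation = computation, loss = loss, delay = delay,
                 highlighted = list(highlighted), message_key = message_key,
                 message = msg)
}

#' Calibrate the delay scaling factor of the tutor
#'
#' Sets `scaling_a` so that the delay for terminating at the empty belief —
#' acting without any planning, the worst possible planning decision in
#' environments where planning pays — equals the configured target
#' (42 s by default): `a = (target - base_delay) / loss(empty, terminate)`.
#'
#' @param env An `env_config` (used for validation only).
#' @param q The solved `meta_q` for `env`.
#' @param cfg A [feedback_config()].
#' @return `cfg` with `scaling_a` filled in.
#' @export
calibrate_scaling <- function(env, q, cfg) {
  loss0 <- compute_loss(q, empty_belief(), TERMINATE)
  if (loss0 <= 1e-12) {
    abort("planning is worthless at the empty belief; cannot calibrate")
  }
  cfg$scaling_a <- (cfg$target_no_planning_delay - cfg$base_delay) / loss0
  cfg
}

#' Metacognitive feedback for one planning operation
#'
#' Evaluates the inferred planning operation by its loss
#' `max_c' Q(b, c') - Q(b, c)` and translates it into a delay penalty and,
#' in information-bearing modes, instruction: the click targets of the
#' optimal computation set are highlighted and a message says what should
#' have been done instead.
#'
#' @param q A solved `meta_q`.
#' @param belief The belief state in which the operation was performed.
#' @param computation The operation: a node id or `"terminate"`.
#' @param cfg A [feedback_config()] in a metacognitive mode; delay-bearing
#'   modes require a calibrated `scaling_a`.
#' @param tol Loss tolerance below which the operation counts as optimal.
#' @return A one-row tibble (a feedback event) with columns `computation`,
#'   `loss`, `delay`, `highlighted` (list), `message_key`, `message`.
#' @export
metacognitive_feedback <- function(q, belief, computation, cfg, tol = 1e-9) {
  if (!startsWith(cfg$mode, "metacognitive")) {
    abort("cfg$mode must be a metacognitive variant")
  }
  delay_bearing <- cfg$mode %in% c("metacognitive_full",
                                   "metacognitive_delay_only")
  info_bearing <- cfg$mode %in% c("metacognitive_full",
                                  "metacognitive_info_only")
  loss <- compute_loss(q, belief, computation)
  if (loss <= tol) {
    return(feedback_event(computation, loss = loss,
                          delay = cfg$unconditional_click_delay,
                          message_key = if (info_bearing) "good_job" else "none"))
  }
  delay <- if (delay_bearing) {
    if (is.null(cfg$scaling_a)) {
      abort("delay-bearing feedback requires a calibrated scaling_a")
    }
    cfg$unconditional_click_delay + cfg$base_delay + cfg$scaling_a * loss
  } else {
    max(cfg$unconditional_click_delay, 1)
  }
  highlighted <- character(0)
  key <- "none"
  if (info_bearing) {
    opt <- optimal_computations(q, belief, tol)
    clicks <- setdiff(opt, TERMINATE)
    if (length(clicks) > 0) {
      highlighted <- clicks
      key <- "should_have_inspected"
    } else {
      key <- "should_not_have_inspected"
    }
  }
  feedback_event(computation, loss = loss, delay = delay,
                 highlighted = highlighted, message_key = key)
}

default_direction_labels <- function(b) {
  if (b <= 3) c("left", "up", "right")[seq_len(b)] else
    paste0("path ", seq_len(b))
}

#' Action feedback on the first move (task-level loss)
#'
#' The conventional control: feedback on *what* was decided rather than on
#' how. The loss is task level — the best full-information path total
#' overall minus the best total among paths starting with the chosen first
#' move — and the delay uses the same `base_delay + a * loss` rule. It
#' depends only on the ground truth and the first move, never on clicks.
#'
#' @param env An `env_config`.
#' @param truth The trial's ground truth.
#' @param first_move A child of the root (a depth-1 node id).
#' @param cfg A [feedback_config()] with a calibrated `scaling_a`.
#' @param direction_labels Optional labels for the root's children in index
#'   order; defaults to left/up/right for three first moves.
#' @return A feedback event (see [metacognitive_feedback()]); `loss` holds
#'   the task-level loss.
#' @export
action_feedback <- function(env, truth, first_move, cfg,
                            direction_labels = NULL) {
  firsts <- env$graph$children[["root"]]
  if (!first_move %in% firsts) {
    abort(paste0(first_move, " is not a first move of this environment"))
  }
  paths <- enumerate_paths(env)
  totals <- vapply(paths, function(p) sum(truth[p]), numeric(1))
  best_overall <- max(totals)
  starts <- vapply(paths, function(p) p[1], character(1))
  task_loss <- best_overall - max(totals[starts == first_move])
  if (task_loss <= 1e-9) {
    return(feedback_event(first_move, loss = 0, delay = 0))
  }
  if (is.null(cfg$scaling_a)) {
    abort("action feedback requires a calibrated scaling_a")
  }
  labels <- direction_labels %||% default_direction_labels(length(firsts))
  best_firsts <- unique(starts[totals >= best_overall - 1e-9])
  feedback_event(first_move, loss = task_loss,
                 delay = cfg$base_delay + cfg$scaling_a * task_loss,
                 message_key = "should_have_moved",
                 message_args = labels[match(best_firsts, firsts)])
}

#' Dispatch feedback according to the configured mode
#'
#' Routes one inferred operation to the matching feedback rule: the
#' metacognitive variants (full, delay-only, info-only), action feedback on
#' the first move, or none (unconditional click delay only).
#'
#' @param cfg A [feedback_config()]; `cfg$mode` selects the cell.
#' @param q Solved `meta_q` (metacognitive modes).
#' @param belief Belief state at the operation (metacognitive modes).
#' @param computation The operation performed (metacognitive and none
#'   modes).
#' @param env,truth,first_move Inputs for action mode.
#' @inheritParams metacognitive_feedback
#' @return A feedback event.
#' @export
feedback_for_mode <- function(cfg, q = NULL, belief = NULL,
                              computation = NULL, env = NULL, truth = NULL,
                              first_move = NULL, tol = 1e-9) {
  switch(cfg$mode,
    none = feedback_event(
      computation, loss = NA_real_,
      delay = if (identical(computation, TERMINATE)) 0 else
        cfg$unconditional_click_delay),
    action = action_feedback(env, truth, first_move, cfg),
    metacognitive_feedback(q, belief, computation, cfg, tol)
  )
}
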