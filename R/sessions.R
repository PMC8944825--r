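#' Scripted participant specifications
#'
#' Synthetic stand-ins for the behavioral variety seen in planning
#' experiments, used to exercise the tutor and scoring pipeline end to end
#' without human data. None of them is a model of real participants.
#'
#' * `optimal` — follows the solved metalevel policy exactly.
#' * `backward_lapse` — follows the optimal policy but, with probability
#'   `lapse_rate` per operation, performs a uniformly random legal
#'   computation instead.
#' * `forward_satisficer` — a myopic foil: clicks first-step nodes in
#'   order and moves toward the first value at or above
#'   `satisficing_threshold` (falling back to the best value seen).
#' * `non_planner` — makes no clicks and picks a path at random.
#'
#' @param strategy One of the four strategies above.
#' @param lapse_rate Per-operation lapse probability (backward_lapse).
#' @param satisficing_threshold Reward value (forward_satisficer).
#' @param seed Integer seed; all of the participant's randomness derives
#'   from it.
#' @return A `participant_spec` object.
#' @export
participant_spec <- function(strategy = c("optimal", "backward_lapse",
                                          "forward_satisficer",
                                          "non_planner"),
                             lapse_rate = 0.1, satisficing_threshold = 0,
                             seed = 1) {
  strategy <- match.arg(strategy)
  if (lapse_rate < 0 || lapse_rate > 1) abort("lapse_rate must be in [0, 1]")
  structure(list(strategy = strategy, lapse_rate = lapse_rate,
                 satisficing_threshold = satisficing_threshold,
                 seed = as.integer(seed)),
            class = "participant_spec")
}

# ---------------------------------------------------- strategy policy objects

lapse_policy <- function(q, lapse_rate) {
  structure(list(kind = "backward_lapse", q = q, lapse_rate = lapse_rate),
            class = c("lapse_policy", "policy"))
}

#' @export
policy_step.lapse_policy <- function(policy, env, belief, state) {
  comp <- if (stats::runif(1) < policy$lapse_rate) {
    legal <- legal_computations(env, belief)
    legal[sample.int(length(legal), 1)]
  } else {
    optimal_computation(policy$q, belief)
  }
  list(computation = comp, state = state)
}

satisficer_policy <- function(threshold) {
  structure(list(kind = "forward_satisficer", threshold = threshold),
            class = c("satisficer_policy", "policy"))
}

#' @export
policy_init.satisficer_policy <- function(policy, env) {
  list(order = env$graph$children[["root"]], i = 1L, target = NULL)
}

#' @export
policy_step.satisficer_policy <- function(policy, env, belief, state) {
  checked <- state$order[seq_len(state$i - 1L)]
  vals <- belief[checked]
  hit <- checked[which(vals >= policy$threshold)]
  if (length(hit) > 0 || state$i > length(state$order)) {
    state$target <- if (length(hit) > 0) hit[1] else
      checked[which.max(vals)]
    return(list(computation = TERMINATE, state = state))
  }
  node <- state$order[state$i]
  state$i <- state$i + 1L
  list(computation = node, state = state)
}

#' @export
policy_path.satisficer_policy <- function(policy, env, belief, state, paths) {
  through <- purrr::keep(paths, function(p) state$target %in% p)
  best_expected_path(env, belief, through)
}

spec_policy <- function(spec, q) {
  needs_q <- spec$strategy %in% c("optimal", "backward_lapse")
  if (needs_q && is.null(q)) {
    abort(paste0("strategy '", spec$strategy, "' requires a solved meta_q"))
  }
  switch(spec$strategy,
    optimal = optimal_policy(q),
    backward_lapse = lapse_policy(q, spec$lapse_rate),
    forward_satisficer = satisficer_policy(spec$satisficing_threshold),
    non_planner = random_baseline()
  )
}

# ------------------------------------------------------------------ feedback

# annotate one trial record (list form) with feedback events per cfg
trial_feedback <- function(rec, env, truth, q, cfg) {
  if (cfg$mode == "action") {
    return(feedback_for_mode(cfg, env = env, truth = truth,
                             first_move = rec$path[1]))
  }
  b <- empty_belief()
  events <- vector("list", length(rec$computations))
  for (i in seq_along(rec$computations)) {
    comp <- rec$computations[i]
    events[[i]] <- feedback_for_mode(cfg, q = q, belief = b,
                                     computation = comp)
    if (!identical(comp, TERMINATE)) {
      b <- update_belief(b, comp, rec$values[i], env = env)
    }
  }
  dplyr::bind_rows(events)
}

#' Simulate one participant's full session
#'
#' Runs a scripted participant through a training block (with feedback per
#' `cfg`) and a test block (no feedback). Clicks always strictly precede
#' the first move, and everything is deterministic given the spec's seed.
#'
#' @param spec A [participant_spec()].
#' @param env An `env_config`.
#' @param q Solved `meta_q`; required for the optimal/backward_lapse
#'   strategies and for metacognitive feedback conditions.
#' @param cfg A [feedback_config()]; delay-bearing modes must be
#'   calibrated.
#' @param n_train,n_test Block sizes (defaults 10 training and 20 test
#'   trials).
#' @param id Participant identifier; defaults to the strategy name plus
#'   seed.
#' @return A `session_log`: a tibble with one row per trial (columns
#'   `participant`, `condition`, `block`, `trial`, `env`, `truth_seed`,
#'   `computations`, `values`, `path`, `n_clicks`, `raw_score`,
#'   `feedback`).
#' @export
simulate_participant <- function(spec, env, q = NULL, cfg, n_train = 10,
                                 n_test = 20, id = NULL) {
  if (startsWith(cfg$mode, "metacognitive") && is.null(q)) {
    abort("metacognitive feedback conditions require a solved meta_q")
  }
  policy <- spec_policy(spec, q)
  id <- id %||% paste0(spec$strategy, "_", spec$seed)
  n_total <- n_train + n_test
  rows <- vector("list", n_total)
  for (t in seq_len(n_total)) {
    truth_seed <- derive_seed(spec$seed, "truth", t)
    truth <- sample_ground_truth(env, truth_seed)
    rec <- rollout_raw(policy, env, truth,
                       seed = derive_seed(spec$seed, "roll", t))
    training <- t <= n_train
    fb <- if (training && cfg$mode != "none") {
      trial_feedback(rec, env, truth, q, cfg)
    } else NULL
    rows[[t]] <- tibble::tibble(
      participant = id, condition = cfg$mode,
      block = if (training) "training" else "test", trial = t,
      env = env$name, truth_seed = truth_seed,
      computations = list(rec$computations), values = list(rec$values),
      path = list(rec$path), n_clicks = rec$n_clicks,
      raw_score = rec$raw_score, feedback = list(fb))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("session_log", class(out))
  out
}

#' Replay logged trials through the feedback engine
#'
#' Re-derives belief states from each trial's click sequence, checking
#' every computation for legality, and recomputes feedback events. Used to
#' validate externally supplied or deserialized logs.
#'
#' @param trials A tibble of trial records.
#' @param env The `env_config` the trials belong to.
#' @param q Solved `meta_q` (metacognitive modes).
#' @param cfg A [feedback_config()].
#' @return `trials` with the `feedback` column replaced by freshly
#'   computed events.
#' @export
replay_feedback <- function(trials, env, q = NULL, cfg) {
  ids <- reward_nodes(env)
  events <- vector("list", nrow(trials))
  for (r in seq_len(nrow(trials))) {
    comps <- trials$computations[[r]]
    vals <- trials$values[[r]]
    if (comps[length(comps)] != TERMINATE) {
      abort("trial does not end with terminate")
    }
    b <- empty_belief()
    for (i in seq_along(comps)) {
      if (!comps[i] %in% c(legal_computations(env, b))) {
        abort(paste0("illegal computation in trial ", r, ": ", comps[i]))
      }
      if (comps[i] != TERMINATE) b <- update_belief(b, comps[i], vals[i], env)
    }
    if (cfg$mode != "none") {
      rec <- list(computations = comps, values = vals,
                  path = trials$path[[r]])
      truth <- if (cfg$mode == "action") {
        sample_ground_truth(env, trials$truth_seed[r])
      }
      events[[r]] <- trial_feedback(rec, env, truth, q, cfg)
    }
  }
  trials$feedback <- events
  trials
}

# ------------------------------------------------------------------- JSONL

#' Read and write trial logs as JSON lines
#'
#' One trial per line:
#' `{participant, condition, block, trial, env, truth_seed,
#' computations: [{node | "terminate", value?}], path, n_clicks, raw_score,
#' feedback?}`. Values round-trip exactly.
#'
#' @param trials A tibble of trial records.
#' @param path File path.
#' @return `read_trials_jsonl()` returns the tibble of trials;
#'   `write_trials_jsonl()` returns `path` invisibly.
#' @export
write_trials_jsonl <- function(trials, path) {
  lines <- vapply(seq_len(nrow(trials)), function(r) {
    comps <- trials$computations[[r]]
    vals <- trials$values[[r]]
    doc <- list(
      participant = trials$participant[r] %||% NULL,
      condition = trials$condition[r] %||% NULL,
      block = trials$block[r] %||% NULL,
      trial = trials$trial[r] %||% NULL,
      env = trials$env[r],
      truth_seed = trials$truth_seed[r] %||% NULL,
      computations = lapply(seq_along(comps), function(i) {
        if (comps[i] == TERMINATE) list(node = TERMINATE) else
          list(node = comps[i], value = vals[i])
      }),
      path = as.list(trials$path[[r]]),
      n_clicks = trials$n_clicks[r],
      raw_score = trials$raw_score[r])
    fb <- trials$feedback[[r]]
    if (!is.null(fb)) {
      doc$feedback <- lapply(seq_len(nrow(fb)), function(i) {
        list(computation = fb$computation[i], loss = fb$loss[i],
             delay = fb$delay[i], highlighted = as.list(fb$highlighted[[i]]),
             message_key = fb$message_key[i], message = fb$message[i])
      })
    }
    doc <- doc[!vapply(doc, is.null, logical(1))]
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trials_jsonl
#' @export
read_trials_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(line) {
    doc <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    comps <- vapply(doc$computations, function(c) c$node, character(1))
    vals <- vapply(doc$computations, function(c) {
      if (is.null(c$value)) NA_real_ else as.numeric(c$value)
    }, numeric(1))
    fb <- NULL
    if (!is.null(doc$feedback)) {
      fb <- dplyr::bind_rows(lapply(doc$feedback, function(e) {
        tibble::tibble(computation = e$computation,
                       loss = if (is.null(e$loss)) NA_real_ else
                         as.numeric(e$loss),
                       delay = as.numeric(e$delay),
                       highlighted = list(unlist(e$highlighted) %||%
                                            character(0)),
                       message_key = e$message_key, message = e$message)
      }))
    }
    tibble::tibble(
      participant = doc$participant %||% NA_character_,
      condition = doc$condition %||% NA_character_,
      block = doc$block %||% NA_character_,
      trial = as.integer(doc$trial %||% NA_integer_),
      env = doc$env,
      truth_seed = as.integer(doc$truth_seed %||% NA_integer_),
      computations = list(comps), values = list(vals),
      path = list(vapply(doc$path, identity, character(1))),
      n_clicks = as.integer(doc$n_clicks),
      raw_score = as.numeric(doc$raw_score),
      feedback = list(fb))
  })
  dplyr::bind_rows(rows)
}

# ------------------------------------------------------------- fixture suite

#' Generate a deterministic fixture suite on disk
#'
#' Writes the preset environment configurations, a solved toy Q table, and
#' one session log for each feedback condition (metacognitive_full,
#' action, none) crossed with each scripted participant strategy, plus a
#' manifest with content hashes. Re-running with the same seed reproduces
#' byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param env Training environment for the session logs (default
#'   `training_3step`).
#' @param q Optional pre-solved `meta_q` for `env`.
#' @param n_train,n_test Block sizes.
#' @return The manifest: a list with the seed and a tibble of files and
#'   their MD5 hashes (also written to `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1, env = NULL, q = NULL,
                               n_train = 10, n_test = 20) {
  env <- env %||% preset_env("training_3step")
  dir.create(file.path(out_dir, "envs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "sessions"), showWarnings = FALSE)
  files <- character(0)
  for (nm in c("training_3step", "constant_3step", "transfer_5step",
               "toy2")) {
    f <- file.path(out_dir, "envs", paste0(nm, ".json"))
    write_env_json(preset_env(nm), f)
    files <- c(files, f)
  }
  toy <- preset_env("toy2")
  f <- file.path(out_dir, "toy2_q.json")
  write_meta_q(solve_meta(toy), f)
  files <- c(files, f)

  q <- q %||% solve_meta(env)
  conditions <- c("metacognitive_full", "action", "none")
  strategies <- c("optimal", "backward_lapse", "forward_satisficer",
                  "non_planner")
  for (cond in conditions) {
    cfg <- feedback_config(mode = cond)
    if (cond %in% c("metacognitive_full", "action")) {
      cfg <- calibrate_scaling(env, q, cfg)
    }
    for (strat in strategies) {
      spec <- participant_spec(strat, seed = derive_seed(seed, cond, strat))
      log <- simulate_participant(spec, env, q = q, cfg = cfg,
                                  n_train = n_train, n_test = n_test,
                                  id = strat)
      f <- file.path(out_dir, "sessions", paste0(cond, "_", strat,
                                                 ".jsonl"))
      write_trials_jsonl(log, f)
      files <- c(files, f)
    }
  }
  manifest <- list(
    seed = seed, env = env$name,
    files = tibble::tibble(
      path = sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                                  out_dir), "/?"), "", files),
      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
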