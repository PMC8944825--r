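#' Belief states and computations
#'
#' A belief state records which node rewards have been observed so far: a
#' named numeric vector mapping inspected node ids to their revealed values.
#' All other reward-bearing nodes implicitly carry their prior distribution.
#' A *computation* is either a click (encoded as the node id to inspect) or
#' the string `"terminate"`, which ends deliberation and commits to the
#' path with the highest expected return under the current belief.
#'
#' @param ... Named observed values, e.g. `belief(d3_1 = 48)`.
#' @return Named numeric vector of class-free observations (possibly empty).
#' @examples
#' empty_belief()
#' belief(d1_1 = 4, d3_2 = -24)
#' @export
belief <- function(...) {
  obs <- c(...)
  if (length(obs) == 0) return(empty_belief())
  if (is.null(names(obs)) || any(names(obs) == "")) {
    abort("all observations must be named by node id")
  }
  obs
}

#' @rdname belief
#' @export
empty_belief <- function() setNames(numeric(0), character(0))

validate_belief <- function(env, belief) {
  if (length(belief) == 0) return(invisible(belief))
  ids <- names(belief)
  if (anyDuplicated(ids)) abort("belief observes a node twice")
  unknown <- setdiff(ids, reward_nodes(env))
  if (length(unknown) > 0) {
    abort(paste0("belief observes unknown or unclickable node(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (i in seq_along(belief)) {
    spec <- env$reward_by_depth[[node_depth(env, ids[i])]]
    if (spec$kind == "discrete" &&
        min(abs(spec$support - belief[[i]])) > 1e-9) {
      abort(paste0("observed value ", belief[[i]], " not in the support of ",
                   ids[i]))
    }
  }
  invisible(belief)
}

#' Legal computations in a belief state
#'
#' One click per still-unobserved reward-bearing node, plus `"terminate"`.
#' Re-clicking an observed node is excluded (it pays the cost and reveals
#' nothing).
#'
#' @param env An `env_config`.
#' @param belief A belief state (see [belief()]).
#' @return Character vector of computations.
#' @export
legal_computations <- function(env, belief) {
  validate_belief(env, belief)
  c(setdiff(reward_nodes(env), names(belief)), TERMINATE)
}

#' Apply a click outcome to a belief
#'
#' @param belief Current belief.
#' @param node Node id that was clicked; must be unobserved.
#' @param value Observed reward value.
#' @param env Optional `env_config`; if supplied, the click is checked for
#'   full legality (clickable node, value in support).
#' @return The belief with one additional observation; the input is
#'   unchanged.
#' @export
update_belief <- function(belief, node, value, env = NULL) {
  if (identical(node, TERMINATE)) abort("terminate does not update the belief")
  if (node %in% names(belief)) {
    abort(paste0("node ", node, " is already observed"))
  }
  out <- c(belief, setNames(as.numeric(value), node))
  if (!is.null(env)) validate_belief(env, out)
  out
}

#' Expected return of terminating deliberation in a belief state
#'
#' The maximum over root-to-leaf paths of the expected path sum: observed
#' values where present, prior depth means where not.
#'
#' @inheritParams legal_computations
#' @return Money value (numeric scalar).
#' @export
termination_value <- function(env, belief) {
  validate_belief(env, belief)
  mu <- vapply(env$reward_by_depth, spec_mean, numeric(1))
  best <- -Inf
  for (path in enumerate_paths(env)) {
    ev <- 0
    for (id in path) {
      ev <- ev + if (id %in% names(belief)) belief[[id]] else
        mu[node_depth(env, id)]
    }
    if (ev > best) best <- ev
  }
  best
}

# -------------------------------------------------------------- fork layout

# Is the tree of the form [b, 1, ..., 1, k]: root fan-out, single-successor
# spine, final fork? All presets and their reduced variants are.
fork_layout <- function(env) {
  br <- env$branching
  len <- length(br)
  if (len >= 3 && any(br[2:(len - 1)] != 1)) return(NULL)
  b <- br[1]
  k <- if (len == 1) 1L else br[len]
  D <- if (len == 1) 1L else len
  if (b > 4) return(NULL)
  list(b = b, k = k, D = D, nspine = D - 1L)
}

# map a belief to the canonical fork state matrix (b x (nspine + 2))
fork_state <- function(env, lay, belief) {
  state <- matrix(0L, nrow = lay$b, ncol = lay$nspine + 2L)
  if (length(belief) == 0) return(state)
  ids <- names(belief)
  depths <- node_depth(env, ids)
  idx <- env$graph$nodes$index[match(ids, env$graph$nodes$id)]
  for (i in seq_along(ids)) {
    d <- depths[i]
    spec <- env$reward_by_depth[[d]]
    v <- match_support(spec$support, belief[[i]])
    if (d < lay$D) {                       # spine node: branch = index
      state[idx[i], d] <- v
    } else {                               # leaf node
      j <- (idx[i] - 1L) %/% lay$k + 1L
      state[j, lay$nspine + 1L] <- state[j, lay$nspine + 1L] + 1L
      state[j, lay$nspine + 2L] <- max(state[j, lay$nspine + 2L], v)
    }
  }
  state
}

match_support <- function(support, value) {
  i <- match(value, support)
  if (is.na(i)) i <- which(abs(support - value) <= 1e-9)[1]
  if (is.na(i)) abort("observed value not in support")
  as.integer(i)
}

# ------------------------------------------------------------------- solver

#' Solve the metalevel MDP of a discrete environment exactly
#'
#' Backward induction over belief states computes `Q(b, c)` for every
#' reachable belief `b` and computation `c`:
#' `Q(b, click n) = -cost + sum_v P(v) V(b + {n: v})`,
#' `Q(b, terminate) = termination_value(b)`, `V(b) = max_c Q(b, c)`.
#' The compiled core memoizes over canonical states (exchangeable sibling
#' branches are interchangeable, and of the observed final-step values in a
#' branch only the count and maximum can influence any later decision), so
#' the three-step training environment solves in seconds.
#'
#' Gaussian environments have continuous (uncountable) belief spaces and
#' are rejected; use the goal-setting approximation in [score_norm()] /
#' [goal_setting_policy()] for those.
#'
#' @param env A discrete `env_config` whose tree has the fork layout
#'   `[b, 1, ..., 1, k]` (all presets do).
#' @return An object of class `meta_q` with fields `env`, `root_value`
#'   (the value `V` of the empty belief) and a handle to the solved table.
#' @seealso [q_values()], [compute_loss()], [optimal_computations()],
#'   [brute_force_oracle()].
#' @export
solve_meta <- function(env) {
  if (!is_discrete_env(env)) {
    abort(paste("gaussian environments cannot be solved exactly;",
                "use the goal-setting approximation (see score_norm)"))
  }
  lay <- fork_layout(env)
  if (is.null(lay)) {
    abort(paste("solve_meta supports trees with layout [b, 1, ..., 1, k]",
                "and at most 4 branches; use brute_force_oracle for small",
                "arbitrary trees"))
  }
  sup <- lapply(env$reward_by_depth, function(s) s$support)
  pr <- lapply(env$reward_by_depth, function(s) s$probs)
  sol <- fork_solve_cpp(lay$b, lay$k, sup, pr, env$click_cost)
  structure(list(env = env, solver = "fork", layout = lay, ptr = sol$ptr,
                 root_value = sol$root_value, n_states = sol$n_states),
            class = "meta_q")
}

#' Brute-force metalevel solver for tiny environments (independent oracle)
#'
#' Direct recursion over concrete beliefs with a dense memo table and no
#' symmetry reduction — an independent code path used to verify
#' [solve_meta()] on small fixtures.
#'
#' @param env A discrete `env_config` with at most 9 reward-bearing nodes.
#' @return A `meta_q` (same query surface as [solve_meta()]).
#' @export
brute_force_oracle <- function(env) {
  if (!is_discrete_env(env)) abort("oracle requires discrete rewards")
  if (n_reward_nodes(env) > 9) {
    abort("brute-force oracle refuses environments with > 9 reward nodes")
  }
  ids <- reward_nodes(env)
  depths <- node_depth(env, ids)
  sup <- lapply(depths, function(d) env$reward_by_depth[[d]]$support)
  pr <- lapply(depths, function(d) env$reward_by_depth[[d]]$probs)
  paths <- lapply(enumerate_paths(env), function(p) match(p, ids))
  sol <- brute_solve_cpp(sup, pr, paths, env$click_cost)
  structure(list(env = env, solver = "brute", node_ids = ids, ptr = sol$ptr,
                 root_value = sol$root_value, n_states = sol$n_states),
            class = "meta_q")
}

#' @export
print.meta_q <- function(x, ...) {
  cat("<meta_q>", x$env$name, sprintf("(%s solver)\n", x$solver))
  cat("  V(empty belief):", format(x$root_value, digits = 10), "\n")
  cat("  states solved:", format(x$n_states, big.mark = ","), "\n")
  invisible(x)
}

# raw Q query: list(term, V, q = named vector over unobserved nodes)
meta_q_raw <- function(q, belief) {
  env <- q$env
  if (q$solver == "fork") {
    lay <- q$layout
    res <- fork_q_cpp(q$ptr, fork_state(env, lay, belief))
    ids <- setdiff(reward_nodes(env), names(belief))
    if (length(ids) == 0) {
      return(list(term = res$term, V = res$V,
                  q = setNames(numeric(0), character(0))))
    }
    depths <- node_depth(env, ids)
    idx <- env$graph$nodes$index[match(ids, env$graph$nodes$id)]
    vals <- vapply(seq_along(ids), function(i) {
      if (depths[i] < lay$D) res$qspine[idx[i], depths[i]]
      else res$qleaf[(idx[i] - 1L) %/% lay$k + 1L]
    }, numeric(1))
    list(term = res$term, V = res$V, q = setNames(vals, ids))
  } else {
    digits <- integer(length(q$node_ids))
    if (length(belief) > 0) {
      pos <- match(names(belief), q$node_ids)
      digits[pos] <- vapply(seq_along(belief), function(i) {
        spec <- env$reward_by_depth[[node_depth(env, names(belief)[i])]]
        match_support(spec$support, belief[[i]])
      }, integer(1))
    }
    res <- brute_q_cpp(q$ptr, digits)
    keep <- is.na(match(q$node_ids, names(belief)))
    list(term = res$term, V = res$V,
         q = setNames(res$qclick[keep], q$node_ids[keep]))
  }
}

#' State-action values of all legal computations in a belief
#'
#' @param q A solved `meta_q`.
#' @param belief A belief state.
#' @return A tibble with columns `computation` and `q`, one row per legal
#'   computation (clicks in node order, then `"terminate"`).
#' @export
q_values <- function(q, belief = empty_belief()) {
  validate_belief(q$env, belief)
  raw <- meta_q_raw(q, belief)
  tibble::tibble(computation = c(names(raw$q), TERMINATE),
                 q = c(unname(raw$q), raw$term))
}

#' Loss (regret) of a computation under the optimal metalevel policy
#'
#' `loss(b, c) = max_c' Q(b, c') - Q(b, c)`: how much worse computation `c`
#' is than the best available computation in belief `b`. Nonnegative, and
#' zero exactly when `c` attains the maximum.
#'
#' @inheritParams q_values
#' @param computation A node id (click) or `"terminate"`.
#' @return Nonnegative money value.
#' @export
compute_loss <- function(q, belief, computation) {
  validate_belief(q$env, belief)
  raw <- meta_q_raw(q, belief)
  if (!computation %in% c(names(raw$q), TERMINATE)) {
    abort(paste0("computation ", computation, " is not legal in this belief"))
  }
  qc <- if (identical(computation, TERMINATE)) raw$term
        else raw$q[[computation]]
  max(raw$V - qc, 0)
}

#' The optimal computation set in a belief state
#'
#' All computations whose Q value is within the tie tolerance (1e-9) of the
#' maximum; always nonempty.
#'
#' @inheritParams q_values
#' @param tol Tie tolerance.
#' @return Character vector of computations.
#' @export
optimal_computations <- function(q, belief = empty_belief(), tol = 1e-9) {
  qv <- q_values(q, belief)
  qv$computation[qv$q >= max(qv$q) - tol]
}

# deterministic single choice: prefer terminate at ties, then the first
# unobserved node in natural (depth, index) order; lean (no tibbles)
optimal_computation <- function(q, belief, tol = 1e-9) {
  raw <- meta_q_raw(q, belief)
  if (raw$term >= raw$V - tol) return(TERMINATE)
  names(raw$q)[which(raw$q >= raw$V - tol)[1]]
}

#' Canonical key of a belief state
#'
#' Beliefs that differ only by a permutation of exchangeable sibling
#' subtrees (identical topology and reward distributions) share a key, and
#' share the same value `V`; beliefs differing in any observed value get
#' different keys.
#'
#' @inheritParams legal_computations
#' @return A string key.
#' @export
canonicalize <- function(env, belief) {
  validate_belief(env, belief)
  ser <- function(id) {
    obs <- if (id %in% names(belief)) format(belief[[id]], digits = 15) else "?"
    ch <- env$graph$children[[id]]
    inner <- if (length(ch) == 0) "" else
      paste0("(", paste(sort(vapply(ch, ser, character(1))), collapse = ","),
             ")")
    paste0(obs, inner)
  }
  ser("root")
}

# ------------------------------------------------------------- serialization

env_content_hash <- function(env) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_env_json(env, tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a solved Q table for a small environment
#'
#' Writes the full table as JSON, one entry per canonical belief key,
#' mapping each legal computation of a representative belief to its Q
#' value, together with the environment name and a content hash. Only
#' environments with at most 6 reward-bearing nodes are serialized (larger
#' tables should be re-solved, which is fast, rather than shipped).
#'
#' @param q A solved `meta_q`.
#' @param path Output file.
#' @return `path`, invisibly. `read_meta_q()` returns a list with the
#'   environment name, hash, and a tibble (`key`, `computation`, `q`).
#' @export
write_meta_q <- function(q, path) {
  env <- q$env
  if (n_reward_nodes(env) > 6) {
    abort("meta_q serialization is limited to environments with <= 6 nodes")
  }
  ids <- reward_nodes(env)
  sup <- lapply(ids, function(i) env$reward_by_depth[[node_depth(env, i)]]$support)
  grid <- expand.grid(lapply(sup, function(s) 0:length(s)))
  entries <- list()
  for (r in seq_len(nrow(grid))) {
    digits <- as.integer(grid[r, ])
    obs <- digits > 0
    b <- setNames(vapply(which(obs), function(i) sup[[i]][digits[i]],
                         numeric(1)), ids[obs])
    key <- canonicalize(env, b)
    if (!is.null(entries[[key]])) next
    qv <- q_values(q, b)
    entries[[key]] <- as.list(setNames(qv$q, qv$computation))
  }
  doc <- list(env = env$name, env_hash = env_content_hash(env),
              root_value = q$root_value, entries = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_meta_q
#' @export
read_meta_q <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- purrr::imap_dfr(doc$entries, function(e, key) {
    tibble::tibble(key = key, computation = names(e),
                   q = unlist(e, use.names = FALSE))
  })
  list(env = doc$env, env_hash = doc$env_hash,
       root_value = doc$root_value, table = entries)
}
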