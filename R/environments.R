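#' Reward distribution for one depth of a planning environment
#'
#' Each depth of a Mouselab-MDP reward tree draws its node rewards i.i.d.
#' from a single distribution: either a discrete distribution over a small
#' support (money units) or a zero-mean-style Gaussian.
#'
#' @param kind `"discrete"` or `"gaussian"`.
#' @param support Numeric vector of possible reward values (discrete only).
#' @param probs Probabilities for `support`; defaults to uniform.
#' @param mean,sd Gaussian parameters (gaussian only); `sd` must be positive.
#' @return An object of class `reward_spec`.
#' @examples
#' reward_spec("discrete", support = c(-4, -2, 2, 4))
#' reward_spec("gaussian", mean = 0, sd = 32)
#' @export
reward_spec <- function(kind = c("discrete", "gaussian"), support = NULL,
                        probs = NULL, mean = 0, sd = NULL) {
  kind <- match.arg(kind)
  if (kind == "discrete") {
    if (is.null(support) || length(support) == 0) {
      abort("discrete reward_spec needs a nonempty support")
    }
    probs <- probs %||% rep(1 / length(support), length(support))
    if (length(probs) != length(support)) {
      abort("probs must match support length")
    }
    if (abs(sum(probs) - 1) > 1e-12) abort("probabilities must sum to 1")
    spec <- list(kind = kind, support = as.numeric(support),
                 probs = as.numeric(probs))
  } else {
    if (is.null(sd) || sd <= 0) abort("gaussian reward_spec needs sd > 0")
    spec <- list(kind = kind, mean = as.numeric(mean), sd = as.numeric(sd))
  }
  structure(spec, class = "reward_spec")
}

spec_mean <- function(spec) {
  if (spec$kind == "discrete") sum(spec$support * spec$probs) else spec$mean
}

#' @export
print.reward_spec <- function(x, ...) {
  if (x$kind == "discrete") {
    cat("<reward_spec> discrete {", paste(x$support, collapse = ", "), "}\n")
  } else {
    cat("<reward_spec> gaussian mean", x$mean, "sd", x$sd, "\n")
  }
  invisible(x)
}

# Build the rooted reward tree for a branching profile. branching[d] is the
# fan-out of every node at depth d-1; depth-0 is the (rewardless) root.
# Node ids are "d{depth}_{index}" with indices 1-based within a depth.
build_graph <- function(branching) {
  branching <- as.integer(branching)
  if (length(branching) < 1 || any(branching < 1)) {
    abort("branching must be a vector of positive fan-outs")
  }
  ids <- "root"
  depth <- 0L
  index <- 1L
  parent <- NA_character_
  prev_ids <- "root"
  for (d in seq_along(branching)) {
    b <- branching[d]
    n_prev <- length(prev_ids)
    idx <- seq_len(n_prev * b)
    cur <- sprintf("d%d_%d", d, idx)
    ids <- c(ids, cur)
    depth <- c(depth, rep(d, length(cur)))
    index <- c(index, idx)
    parent <- c(parent, rep(prev_ids, each = b))
    prev_ids <- cur
  }
  nodes <- tibble::tibble(id = ids, depth = as.integer(depth),
                          index = as.integer(index), parent = parent)
  children <- lapply(setNames(ids, ids), function(i) {
    nodes$id[!is.na(nodes$parent) & nodes$parent == i]
  })
  list(nodes = nodes, children = children, branching = branching)
}

#' Construct a Mouselab-MDP environment configuration
#'
#' An environment is a rooted reward tree (every root-to-leaf move sequence
#' is a candidate path), a reward distribution per depth, and a fixed money
#' cost per information-gathering click. The root carries no reward and is
#' never clickable.
#'
#' @param branching Integer vector; `branching[d]` is the fan-out of each
#'   node at depth `d - 1`. E.g. `c(3, 1, 2)` is the three-step web: three
#'   first moves, one successor each, forking into two final states.
#' @param reward_by_depth List of [reward_spec()] objects, one per depth.
#' @param click_cost Money units charged per click; must be nonnegative.
#' @param name Identifier for the configuration.
#' @return An object of class `env_config`.
#' @seealso [preset_env()] for the environments used in the experiments.
#' @export
make_env <- function(branching, reward_by_depth, click_cost, name = "custom") {
  graph <- build_graph(branching)
  d_max <- max(graph$nodes$depth)
  if (length(reward_by_depth) != d_max) {
    abort("need one reward_spec per depth 1..max_depth")
  }
  if (!all(vapply(reward_by_depth, inherits, logical(1), "reward_spec"))) {
    abort("reward_by_depth must be a list of reward_spec objects")
  }
  if (click_cost < 0) abort("click_cost must be nonnegative")
  env <- structure(list(name = name, branching = graph$branching,
                        graph = graph, reward_by_depth = reward_by_depth,
                        click_cost = as.numeric(click_cost)),
                   class = "env_config")
  env$paths <- enumerate_paths(env$graph)  # cached; trees are immutable
  env
}

#' @export
print.env_config <- function(x, ...) {
  cat("<env_config>", x$name, "\n")
  cat("  branching:", paste(x$branching, collapse = "-"),
      " (", n_reward_nodes(x), "reward nodes )\n")
  cat("  click cost:", x$click_cost, "\n")
  for (d in seq_along(x$reward_by_depth)) {
    s <- x$reward_by_depth[[d]]
    cat("  depth", d, ":",
        if (s$kind == "discrete") {
          paste0("{", paste(s$support, collapse = ", "), "}")
        } else sprintf("N(%g, %g^2)", s$mean, s$sd), "\n")
  }
  invisible(x)
}

reward_nodes <- function(env) {
  env$graph$nodes$id[env$graph$nodes$depth > 0]
}

n_reward_nodes <- function(env) sum(env$graph$nodes$depth > 0)

max_depth <- function(env) max(env$graph$nodes$depth)

node_depth <- function(env, id) {
  env$graph$nodes$depth[match(id, env$graph$nodes$id)]
}

is_discrete_env <- function(env) {
  all(vapply(env$reward_by_depth, function(s) s$kind == "discrete", logical(1)))
}

#' Preset environments from the planning-tutor experiments
#'
#' @param name One of:
#' \describe{
#'   \item{`training_3step`}{Three-step web with reward variance increasing
#'     with depth: uniform supports \{-4,-2,+2,+4\}, \{-8,-4,+4,+8\},
#'     \{-48,-24,+24,+48\} and a $1 click cost. The default topology is
#'     branching 3-1-2 (12 reward nodes).}
#'   \item{`constant_3step`}{Same tree, but all depths share the uniform
#'     support \{-10,-5,+5,+10\} ($1 click cost); the "unstructured"
#'     environment.}
#'   \item{`transfer_5step`}{Five-step tree (branching 3-1-1-1-2) with
#'     zero-mean Gaussian rewards, sd `2^(i-1)` at depths 1-4 and `2^5 = 32`
#'     at depth 5; $3 click cost. Too large to solve exactly; used with the
#'     goal-setting approximation.}
#'   \item{`toy2`}{Two-leaf one-step tree, uniform \{-1,+1\}, click cost
#'     0.25. A fixture whose metalevel MDP is solvable by hand.}
#' }
#' @param branching Optional topology override (the experiments' exact webs
#'   are rendered figures; the defaults are the package's interpretation).
#' @return An `env_config`.
#' @examples
#' preset_env("training_3step")
#' @export
preset_env <- function(name = c("training_3step", "constant_3step",
                                "transfer_5step", "toy2"),
                       branching = NULL) {
  name <- match.arg(name)
  u <- function(...) reward_spec("discrete", support = c(...))
  switch(name,
    training_3step = make_env(
      branching %||% c(3, 1, 2),
      list(u(-4, -2, 2, 4), u(-8, -4, 4, 8), u(-48, -24, 24, 48)),
      click_cost = 1, name = name),
    constant_3step = make_env(
      branching %||% c(3, 1, 2),
      list(u(-10, -5, 5, 10), u(-10, -5, 5, 10), u(-10, -5, 5, 10)),
      click_cost = 1, name = name),
    transfer_5step = make_env(
      branching %||% c(3, 1, 1, 1, 2),
      c(lapply(1:4, function(i) reward_spec("gaussian", mean = 0,
                                            sd = 2^(i - 1))),
        list(reward_spec("gaussian", mean = 0, sd = 2^5))),
      click_cost = 3, name = name),
    toy2 = make_env(branching %||% 2, list(u(-1, 1)),
                    click_cost = 0.25, name = name)
  )
}

#' Sample concealed ground-truth rewards for every reward-bearing node
#'
#' Each node's reward is drawn independently from its depth's distribution.
#' Draws are seeded per node (a sub-seed derived from `seed` and the node
#' id), so the value a node receives does not depend on the order in which
#' nodes are processed, and the same seed always reproduces the same truth.
#'
#' @param env An `env_config`.
#' @param seed Integer seed.
#' @return Named numeric vector: node id -> realized reward.
#' @export
sample_ground_truth <- function(env, seed) {
  nodes <- env$graph$nodes[env$graph$nodes$depth > 0, ]
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  vals <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    spec <- env$reward_by_depth[[nodes$depth[i]]]
    # per-node sub-seed: the draw a node receives is independent of the
    # order in which nodes are processed
    set.seed((abs(seed) * 48271 + nodes$depth[i] * 131071 +
                nodes$index[i] * 7919) %% 2147483629)
    vals[i] <- if (spec$kind == "discrete") {
      spec$support[sample.int(length(spec$support), 1, prob = spec$probs)]
    } else {
      rnorm(1, spec$mean, spec$sd)
    }
  }
  setNames(vals, nodes$id)
}

#' Enumerate all root-to-leaf paths of an environment
#'
#' @param env An `env_config` (or a graph as built internally).
#' @return List of character vectors, each the reward-bearing nodes of one
#'   path in move order; paths are listed in the natural node-index order.
#' @export
enumerate_paths <- function(env) {
  if (inherits(env, "env_config") && !is.null(env$paths)) return(env$paths)
  graph <- if (inherits(env, "env_config")) env$graph else env
  walk <- function(id) {
    ch <- graph$children[[id]]
    if (length(ch) == 0) return(list(character(0)))
    out <- list()
    for (c_id in ch) {
      for (tail in walk(c_id)) out <- c(out, list(c(c_id, tail)))
    }
    out
  }
  walk("root")
}

#' Raw money score of one trial
#'
#' The sum of the ground-truth rewards along the chosen path, minus the
#' click cost times the number of clicks. Endowments and bonus conversion
#' are not included.
#'
#' @param env An `env_config`.
#' @param truth Ground truth from [sample_ground_truth()].
#' @param path Character vector of reward-node ids in move order; must be a
#'   root-to-leaf path of the environment.
#' @param n_clicks Number of clicks made before moving (nonnegative).
#' @return Money score (numeric scalar).
#' @export
trial_score <- function(env, truth, path, n_clicks) {
  if (n_clicks < 0) abort("n_clicks must be nonnegative")
  paths <- enumerate_paths(env)
  ok <- any(vapply(paths, function(p) identical(p, as.character(path)),
                   logical(1)))
  if (!ok) abort("path is not a root-to-leaf path of this environment")
  sum(truth[path]) - env$click_cost * n_clicks
}

# ------------------------------------------------------------- JSON round-trip

#' Read and write environment configurations as JSON
#'
#' The on-disk format is a plain JSON document
#' `{name, branching, rewards: [{depth, kind, support, probs | mean, sd}],
#' click_cost}`; reading it back reproduces the configuration exactly.
#'
#' @param env An `env_config`.
#' @param path File path.
#' @return `read_env_json()` returns an `env_config`; `write_env_json()`
#'   returns `path` invisibly.
#' @export
write_env_json <- function(env, path) {
  rewards <- lapply(seq_along(env$reward_by_depth), function(d) {
    s <- env$reward_by_depth[[d]]
    if (s$kind == "discrete") {
      list(depth = d, kind = s$kind, support = s$support, probs = s$probs)
    } else {
      list(depth = d, kind = s$kind, mean = s$mean, sd = s$sd)
    }
  })
  doc <- list(name = env$name, branching = env$branching, rewards = rewards,
              click_cost = env$click_cost)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_env_json
#' @export
read_env_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  need <- c("name", "branching", "rewards", "click_cost")
  if (!all(need %in% names(doc))) {
    abort("invalid environment config: missing fields")
  }
  specs <- vector("list", length(doc$rewards))
  for (r in doc$rewards) {
    specs[[r$depth]] <- if (r$kind == "discrete") {
      reward_spec("discrete", support = unlist(r$support),
                  probs = unlist(r$probs))
    } else {
      reward_spec("gaussian", mean = r$mean, sd = r$sd)
    }
  }
  make_env(unlist(doc$branching), specs, doc$click_cost, name = doc$name)
}

#' @rdname write_env_json
#' @param truth Named numeric vector of node rewards.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(as.list(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_env_json
#' @export
read_ground_truth_json <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
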