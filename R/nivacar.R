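#' Cell-specific network inference via causal reasoning (NIVaCaR)
#'
#' Given a signed, directed prior-knowledge network (PKN), a set of
#' perturbed input nodes with known direction, and discretized per-gene
#' measurements c_j in \{-1, 0, +1\} for one cell type, the inference
#' problem is to pick node states x_j in \{-1, 0, +1\} minimizing
#'
#'   sum_j alpha * |x_j - c_j|  +  sum_j beta * (x_j^+ + x_j^-)
#'
#' subject to sign-consistency: writing x_j = x_j^+ - x_j^- with
#' x_j^+, x_j^- binary and mutually exclusive, every nonzero non-input node
#' must have at least one incoming edge (s -> j, sign sigma) whose source
#' state supports it (sigma * x_s = x_j), i.e. a state needs a cause. Input
#' nodes need no cause but may only take state 0 or their assigned
#' perturbation sign. The alpha term penalizes mismatch with the
#' measurements; the beta term penalizes every node included in the solution,
#' so among explanations of equal fit the smallest subnetwork wins.
#'
#' The program is an integer linear program in the x^+/x^- node variables
#' and per-edge transmission variables; [build_ilp()] assembles it and
#' [solve_network_inference()] solves it exactly by depth-first branch and
#' bound over node states (feasibility of the edge variables is decided
#' locally once node states are fixed, so branching on nodes is complete).
#' [brute_force_oracle()] is an independent full-enumeration check for small
#' instances.
#'
#' @name nivacar
NULL

#' Configuration for the causal-reasoning program
#'
#' @param alpha mismatch penalty (> 0).
#' @param beta node-inclusion penalty (>= 0). A warning is issued when
#'   beta/alpha falls outside the recommended 0.03-0.5 band.
#' @param time_limit solver wall-clock limit in seconds.
#' @param gap accepted relative optimality gap when the limit is hit.
#' @return A list of class `ilp_config`.
#' @export
ilp_config <- function(alpha = 1, beta = 0.1, time_limit = 60, gap = 0) {
  stopifnot(alpha > 0, beta >= 0)
  ratio <- beta / alpha
  if (beta > 0 && (ratio < 0.03 || ratio > 0.5)) {
    warning(sprintf("beta/alpha = %.3g outside the recommended 0.03-0.5 band",
                    ratio))
  }
  structure(list(alpha = alpha, beta = beta, time_limit = time_limit,
                 gap = gap), class = "ilp_config")
}

#' Assemble the causal-reasoning integer program
#'
#' Builds the model object solved by [solve_network_inference()]. Variables:
#' binary x_j^+ and x_j^- per node (state decomposition, x_j^+ + x_j^- <= 1)
#' and binary e_u^+ / e_u^- per edge (the edge transmits up- or
#' down-regulation). Constraints: a nonzero non-input node needs at least
#' one incoming transmitting edge of matching direction; an edge can
#' transmit only a signal its source state produces under its sign; input
#' nodes are fixed to \{0, assigned sign\}. Mismatch terms |x_j - c_j| are
#' linearized via auxiliary variables in the ILP view; cyclic networks are
#' accepted (no loop-breaking constraints), so a cycle may sustain itself.
#'
#' @param pkn a [signed_network()].
#' @param inputs named vector over a subset of nodes with values in
#'   \{-1, +1\}: the perturbed input nodes and their direction.
#' @param measurement named vector with values in \{-1, 0, +1\} over a
#'   subset of nodes (see [discretize_measurements()]).
#' @param config an [ilp_config()].
#' @return A list of class `nivacar_model`.
#' @export
build_ilp <- function(pkn, inputs = numeric(), measurement = numeric(),
                      config = ilp_config()) {
  stopifnot(inherits(pkn, "signed_network"), inherits(config, "ilp_config"))
  if (length(inputs)) {
    if (is.null(names(inputs)) || !all(names(inputs) %in% pkn$nodes)) {
      stop("input node(s) absent from the network")
    }
    if (!all(inputs %in% c(-1, 1))) stop("input states must be -1 or +1")
  }
  cell_type <- attr(measurement, "cell_type")
  if (length(measurement)) {
    if (!all(measurement %in% c(-1, 0, 1))) {
      stop("measurements must be in {-1, 0, +1}")
    }
    measurement <- measurement[names(measurement) %in% pkn$nodes]
  }
  nodes <- pkn$nodes
  n <- length(nodes)
  c_j <- stats::setNames(numeric(n), nodes)
  meas_mask <- stats::setNames(logical(n), nodes)
  if (length(measurement)) {
    c_j[names(measurement)] <- measurement
    meas_mask[names(measurement)] <- TRUE
  }
  # incoming edge list per node: (source index, sign)
  e <- pkn$edges
  src_idx <- match(e$from, nodes)
  tgt_idx <- match(e$to, nodes)
  incoming <- lapply(seq_len(n), function(i) {
    sel <- tgt_idx == i
    list(src = src_idx[sel], sign = e$sign[sel])
  })
  structure(list(
    network = pkn, nodes = nodes, incoming = incoming, cell_type = cell_type,
    inputs = inputs, c_j = c_j, measured = meas_mask, config = config,
    n_variables = 2L * n + 2L * nrow(e) + sum(meas_mask),
    n_constraints = n + 2L * n + 2L * nrow(e)
  ), class = "nivacar_model")
}

#' @export
print.nivacar_model <- function(x, ...) {
  cat(sprintf(paste0(
    "causal-reasoning ILP: %d nodes, %d edges, %d inputs, %d measured\n",
    "  %d binary variables, %d constraints; alpha = %g, beta = %g\n"),
    length(x$nodes), nrow(x$network$edges), length(x$inputs),
    sum(x$measured), x$n_variables, x$n_constraints,
    x$config$alpha, x$config$beta))
  invisible(x)
}

# states each node may take: inputs {0, sign}; others {-1,0,+1}
allowed_states <- function(model) {
  lapply(model$nodes, function(nd) {
    if (nd %in% names(model$inputs)) c(0, model$inputs[[nd]]) else c(-1, 0, 1)
  })
}

# node cost given its state
node_cost <- function(state, c_j, measured, alpha, beta) {
  unname(beta * (state != 0) + if (measured) alpha * abs(state - c_j) else 0)
}

# TRUE when state x_j of node i is causally supported by assignment x
supported <- function(model, x, i) {
  if (x[i] == 0 || model$nodes[i] %in% names(model$inputs)) return(TRUE)
  inc <- model$incoming[[i]]
  if (!length(inc$src)) return(FALSE)
  any(inc$sign * x[inc$src] == x[i])
}

feasible_assignment <- function(model, x) {
  all(vapply(seq_along(x), function(i) supported(model, x, i), logical(1)))
}

assignment_objective <- function(model, x) {
  a <- model$config$alpha; b <- model$config$beta
  sum(b * (x != 0)) +
    sum(a * abs(x[model$measured] - model$c_j[model$measured]))
}

# used edges: sign-consistent transmissions between nonzero nodes that feed
# a nonzero target in its observed direction
used_edges <- function(model, x) {
  e <- model$network$edges
  if (!nrow(e)) return(e)
  xs <- x[match(e$from, model$nodes)]
  xt <- x[match(e$to, model$nodes)]
  e[xs != 0 & xt != 0 & e$sign * xs == xt, , drop = FALSE]
}

#' Solve the causal-reasoning program exactly
#'
#' Depth-first branch and bound over node states. Nodes are expanded in an
#' order that places a node after its in-neighbors where possible, so causal
#' support can be checked as early as the last parent is assigned; partial
#' assignments are pruned against the incumbent using a per-node lower bound
#' on the remaining cost. The all-zero assignment (always feasible) seeds
#' the incumbent. On hitting the time limit the best incumbent is returned
#' with `gap_flag = TRUE`.
#'
#' @param model a `nivacar_model` from [build_ilp()].
#' @param config optional [ilp_config()] overriding the model's.
#' @return A list of class `activated_subnetwork`: `cell_type`,
#'   `node_states` (named vector in \{-1,0,1\}), `used_edges` (data frame),
#'   `objective`, `optimal` (FALSE when the time limit truncated the
#'   search), `nodes_expanded`.
#' @export
solve_network_inference <- function(model, config = NULL) {
  stopifnot(inherits(model, "nivacar_model"))
  if (!is.null(config)) model$config <- config
  alpha <- model$config$alpha; beta <- model$config$beta
  n <- length(model$nodes)
  states <- allowed_states(model)

  # expansion order: approximate topological (by BFS distance from inputs),
  # so parents tend to precede children
  ord <- order_by_input_distance(model)
  # position in ord after which all parents of node i are assigned
  pos_of <- integer(n); pos_of[ord] <- seq_len(n)
  last_parent_pos <- vapply(seq_len(n), function(i) {
    inc <- model$incoming[[i]]
    if (!length(inc$src)) 0L else max(pos_of[inc$src])
  }, integer(1))
  # check node i once max(own position, last parent position) is reached
  check_at <- pmax(pos_of, last_parent_pos)
  checks <- split(seq_len(n), factor(check_at, levels = seq_len(n)))

  # lower bound on each node's eventual cost, ignoring feasibility
  lb <- vapply(seq_len(n), function(i) {
    min(vapply(states[[i]], node_cost, numeric(1),
               c_j = model$c_j[i], measured = model$measured[i],
               alpha = alpha, beta = beta))
  }, numeric(1))
  lb_suffix <- rev(cumsum(rev(c(lb[ord], 0))))  # lb_suffix[d] = bound from depth d

  x0 <- numeric(n)
  best <- list(x = x0, obj = assignment_objective(model, x0))
  deadline <- Sys.time() + model$config$time_limit
  expanded <- 0L
  timed_out <- FALSE
  x <- numeric(n)

  recurse <- function(depth, cost) {
    if (timed_out) return()
    expanded <<- expanded + 1L
    if (expanded %% 4096L == 0L && Sys.time() > deadline) {
      timed_out <<- TRUE
      return()
    }
    if (depth > n) {
      if (cost < best$obj - 1e-12) best <<- list(x = x, obj = cost)
      return()
    }
    i <- ord[depth]
    for (s in states[[i]]) {
      new_cost <- cost + node_cost(s, model$c_j[i], model$measured[i],
                                   alpha, beta)
      if (new_cost + lb_suffix[depth + 1L] >= best$obj - 1e-12) next
      x[i] <<- s
      ok <- TRUE
      for (j in checks[[depth]]) {
        if (!supported(model, x, j)) { ok <- FALSE; break }
      }
      if (ok) recurse(depth + 1L, new_cost)
    }
    x[i] <<- 0
  }
  recurse(1L, 0)

  xb <- stats::setNames(best$x, model$nodes)
  structure(list(
    cell_type = model$cell_type,
    node_states = xb,
    used_edges = used_edges(model, best$x),
    objective = best$obj,
    optimal = !timed_out,
    nodes_expanded = expanded
  ), class = "activated_subnetwork")
}

# BFS distance from input nodes (unreached nodes last), stable by node order
order_by_input_distance <- function(model) {
  n <- length(model$nodes)
  if (!length(model$inputs)) return(seq_len(n))
  g <- as_igraph_signed(model$network)
  d <- suppressWarnings(igraph::distances(
    g, v = names(model$inputs), to = model$nodes, mode = "out"))
  dmin <- apply(d, 2, min)
  dmin[!is.finite(dmin)] <- n + 1
  order(dmin[model$nodes], seq_len(n))
}

#' @export
print.activated_subnetwork <- function(x, ...) {
  on <- x$node_states[x$node_states != 0]
  cat(sprintf("activated subnetwork%s: objective %.4g%s\n",
              if (!is.null(x$cell_type)) paste0(" [", x$cell_type, "]") else "",
              x$objective, if (x$optimal) "" else " (time limit, incumbent)"))
  cat(sprintf("  %d active nodes, %d used edges\n", length(on),
              nrow(x$used_edges)))
  invisible(x)
}

#' Exhaustive enumeration oracle for small instances
#'
#' Enumerates every assignment of node states, keeps the causally feasible
#' ones, and returns the exact optimum together with all optimal
#' assignments. Independent of the branch-and-bound path: intended for
#' verifying [solve_network_inference()] on small networks.
#'
#' @inheritParams build_ilp
#' @param max_free maximum number of non-input nodes (default 12).
#' @return A list with `objective` and `optima` (list of named state
#'   vectors).
#' @export
brute_force_oracle <- function(pkn, inputs = numeric(),
                               measurement = numeric(),
                               config = ilp_config(), max_free = 12) {
  model <- build_ilp(pkn, inputs, measurement, config)
  n_free <- length(model$nodes) - length(model$inputs)
  if (n_free > max_free) {
    stop(sprintf("too many non-input nodes for enumeration (%d > %d)",
                 n_free, max_free))
  }
  grids <- allowed_states(model)
  if (!length(grids)) {
    return(list(objective = 0,
                optima = list(stats::setNames(numeric(), character()))))
  }
  combos <- as.matrix(do.call(expand.grid, grids))
  best_obj <- Inf
  optima <- list()
  for (r in seq_len(nrow(combos))) {
    x <- combos[r, ]
    if (!feasible_assignment(model, x)) next
    obj <- assignment_objective(model, x)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      optima <- list(stats::setNames(x, model$nodes))
    } else if (abs(obj - best_obj) <= 1e-12) {
      optima[[length(optima) + 1L]] <- stats::setNames(x, model$nodes)
    }
  }
  list(objective = best_obj, optima = optima)
}

#' Shared subnetwork across activated subnetworks
#'
#' Intersection of the used-edge sets and of the node states: a node is
#' kept when it carries the same nonzero state in every result, an edge when
#' it is used in every result. This extracts the regulation core common to
#' a group of cell types (e.g. all excitatory neurons).
#'
#' @param results non-empty list of `activated_subnetwork` objects.
#' @return A [signed_network()] with attribute `node_states` (named vector
#'   over its nodes).
#' @export
shared_subnetwork <- function(results) {
  stopifnot(length(results) >= 1)
  states <- results[[1]]$node_states
  keep <- names(states)[states != 0]
  for (r in results[-1]) {
    s <- r$node_states
    keep <- keep[keep %in% names(s) & states[keep] == s[keep]]
  }
  keys <- Reduce(intersect, lapply(results, function(r) edge_key(r$used_edges)))
  e0 <- results[[1]]$used_edges
  edges <- e0[edge_key(e0) %in% keys, , drop = FALSE]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  net <- suppressWarnings(signed_network(nodes = keep, edges = edges))
  attr(net, "node_states") <- states[net$nodes]
  net
}
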