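#' Probabilistic logic contextualization (ProComReN)
#'
#' The signed network is turned into a probabilistic logic model in the
#' dynamic-Bayesian-network family: each node carries a semi-quantitative
#' activity X(i) in [0,1] (the probability of the molecule being in its
#' active form) and each edge a weight k_j(i) in [0,1] quantifying the
#' relative influence of parent j on node i. Weights obey the law of total
#' probability: activating weights into a node sum to exactly 1, inhibiting
#' weights sum to at most 1. Node activities propagate by the mean-field
#' update
#'
#'   X_t(i) = ( sum_j+ k_j+(i) X_{t-1}(j+) ) * ( 1 - sum_j- k_j-(i) X_{t-1}(j-) )
#'
#' i.e. expected activation damped by expected inhibition; a node with
#' inhibitors but no activators uses a basal first factor of 1, and a node
#' with no parents keeps its current value. Edge weights are fitted to
#' observed per-condition node values by multi-start constrained
#' least squares on the quasi-steady state.
#'
#' @name procomren
NULL

#' Attach edge weights to a signed network
#'
#' @param network a [signed_network()].
#' @param weights numeric vector in [0,1], one per row of `network$edges`
#'   (in the network's canonical edge order), or a named vector with names
#'   `"from|to"`.
#' @param check enforce the total-probability invariants (activating fan-in
#'   sums to 1 within `tol`, inhibiting fan-in sums to at most 1).
#' @param tol tolerance on the activating-sum constraint.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(network, weights, check = TRUE, tol = 1e-9) {
  stopifnot(inherits(network, "signed_network"))
  e <- network$edges
  if (!is.null(names(weights))) {
    key <- paste(e$from, e$to, sep = "|")
    idx <- match(key, names(weights))
    if (anyNA(idx)) stop("missing weight for edge(s): ",
                         paste(key[is.na(idx)], collapse = ", "))
    weights <- unname(weights[idx])
  }
  if (length(weights) != nrow(e)) {
    stop("need exactly one weight per edge")
  }
  if (any(weights < -tol | weights > 1 + tol)) {
    stop("weights must lie in [0,1]")
  }
  weights <- pmin(pmax(weights, 0), 1)
  wn <- structure(list(network = network, weights = weights),
                  class = "weighted_network")
  if (check) check_weight_invariants(wn, tol = max(tol, 1e-9))
  wn
}

check_weight_invariants <- function(wn, tol = 1e-9) {
  e <- wn$network$edges
  for (nd in unique(e$to)) {
    act <- wn$weights[e$to == nd & e$sign == 1L]
    inh <- wn$weights[e$to == nd & e$sign == -1L]
    if (length(act) && abs(sum(act) - 1) > tol) {
      stop(sprintf("activating weights into '%s' sum to %.6g, expected 1",
                   nd, sum(act)))
    }
    if (length(inh) && sum(inh) > 1 + tol) {
      stop(sprintf("inhibiting weights into '%s' sum to %.6g > 1",
                   nd, sum(inh)))
    }
  }
  invisible(wn)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network with", nrow(x$network$edges), "weighted edges\n")
  e <- x$network$edges
  e$weight <- round(x$weights, 4)
  print(e)
  invisible(x)
}

#' Look up the weight of one edge
#'
#' @param wn a [weighted_network()].
#' @param from,to edge endpoints.
#' @return The weight (error when the edge is absent).
#' @export
edge_weight <- function(wn, from, to) {
  e <- wn$network$edges
  i <- which(e$from == from & e$to == to)
  if (!length(i)) stop(sprintf("no edge %s -> %s", from, to))
  wn$weights[i[1]]
}

#' Write / read a weighted network as 4-column SIF (+ weight)
#'
#' @param wn a [weighted_network()].
#' @param file path.
#' @return `read_weighted_sif` returns a [weighted_network()].
#' @export
write_weighted_sif <- function(wn, file) {
  e <- wn$network$edges
  writeLines(paste(e$from, e$sign, e$to, format(wn$weights, digits = 10),
                   sep = "\t"), file)
  invisible(file)
}

#' @rdname write_weighted_sif
#' @export
read_weighted_sif <- function(file) {
  tab <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  net <- signed_network(edges = data.frame(
    from = tab$V1, to = tab$V3, sign = as.integer(tab$V2)))
  key <- paste(tab$V1, tab$V3, sep = "|")
  weighted_network(net, stats::setNames(as.numeric(tab$V4), key))
}

# per-node parent bookkeeping reused by the update loop and the fitter
parent_index <- function(network) {
  e <- network$edges
  lapply(stats::setNames(network$nodes, network$nodes), function(nd) {
    sel <- e$to == nd
    list(act = which(sel & e$sign == 1L), inh = which(sel & e$sign == -1L),
         act_src = e$from[sel & e$sign == 1L],
         inh_src = e$from[sel & e$sign == -1L])
  })
}

#' One mean-field update of a single node
#'
#' @param parents named numeric vector of current node activities (must
#'   cover the node's parents).
#' @param wn a [weighted_network()].
#' @param node the node to update.
#' @param current the node's current value, returned unchanged when it has
#'   no parents.
#' @return The updated activity in [0,1].
#' @export
dbn_update <- function(parents, wn, node, current = NA_real_) {
  pi <- parent_index(wn$network)[[node]]
  if (is.null(pi)) stop("unknown node: ", node)
  if (!length(pi$act) && !length(pi$inh)) return(current)
  act <- if (length(pi$act)) {
    sum(wn$weights[pi$act] * parents[pi$act_src])
  } else 1
  inh <- if (length(pi$inh)) {
    sum(wn$weights[pi$inh] * parents[pi$inh_src])
  } else 0
  act * (1 - inh)
}

# synchronous update of every non-clamped node; pidx from parent_index()
update_all <- function(x, wn, pidx, clamped) {
  out <- x
  for (nd in names(pidx)) {
    if (nd %in% clamped) next
    pi <- pidx[[nd]]
    if (!length(pi$act) && !length(pi$inh)) next
    act <- if (length(pi$act)) sum(wn$weights[pi$act] * x[pi$act_src]) else 1
    inh <- if (length(pi$inh)) sum(wn$weights[pi$inh] * x[pi$inh_src]) else 0
    out[nd] <- act * (1 - inh)
  }
  out
}

#' Quasi-steady state of the probabilistic logic model
#'
#' Iterates the synchronous mean-field update over all non-clamped nodes
#' until the largest per-node change falls below `tol`. On an acyclic
#' network this converges exactly within the longest-path number of
#' iterations; cyclic networks may oscillate, in which case the last state
#' is returned flagged as non-converged.
#'
#' @param wn a [weighted_network()].
#' @param clamp named numeric vector of input-node values held fixed.
#' @param init initial value for non-clamped nodes: a single number, a named
#'   vector, or `NULL` for 0.5.
#' @param tol convergence tolerance on max |change| (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return Named numeric vector of node activities with attributes
#'   `iterations` and `converged`.
#' @export
steady_state <- function(wn, clamp = numeric(), init = NULL, tol = 1e-6,
                         max_iter = 1000) {
  stopifnot(inherits(wn, "weighted_network"))
  nodes <- wn$network$nodes
  if (length(clamp) && !all(names(clamp) %in% nodes)) {
    stop("clamped node(s) absent from the network")
  }
  x <- stats::setNames(rep(0.5, length(nodes)), nodes)
  if (is.numeric(init) && is.null(names(init)) && length(init) == 1) {
    x[] <- init
  } else if (!is.null(init)) {
    x[names(init)] <- init
  }
  x[names(clamp)] <- clamp
  pidx <- parent_index(wn$network)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x_new <- update_all(x, wn, pidx, names(clamp))
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  attr(x, "iterations") <- it
  attr(x, "converged") <- converged
  x
}

#' Map per-condition mean expression onto [0,1] node targets
#'
#' For each gene, the mean log-normalized expression is computed per
#' condition within the given cell type and min-max scaled across the two
#' conditions, so the lower condition maps to 0 and the higher to 1; equal
#' means map both to 0.5. This puts observed expression on the activity
#' scale of the logic model.
#'
#' @param mat a log-normalized [expression_matrix()].
#' @param cell_type cell type to use.
#' @param genes genes to map; those absent from the matrix are omitted with
#'   a warning.
#' @param control_label,case_label the two condition labels.
#' @return A list with named numeric vectors `control` and `case`.
#' @export
normalize_to_unit_interval <- function(mat, cell_type, genes = NULL,
                                       control_label = "CTL",
                                       case_label = "ASD") {
  stopifnot(inherits(mat, "expression_matrix"))
  if (is.null(genes)) genes <- rownames(mat$values)
  missing <- setdiff(genes, rownames(mat$values))
  if (length(missing)) {
    warning("gene(s) absent from the matrix, omitted: ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  sel <- mat$cell_type == cell_type
  m0 <- rowMeans(mat$values[genes, sel & mat$condition == control_label,
                            drop = FALSE])
  m1 <- rowMeans(mat$values[genes, sel & mat$condition == case_label,
                            drop = FALSE])
  lo <- pmin(m0, m1); hi <- pmax(m0, m1)
  span <- hi - lo
  scale1 <- function(m) ifelse(span > 0, (m - lo) / span, 0.5)
  list(control = stats::setNames(scale1(m0), genes),
       case = stats::setNames(scale1(m1), genes))
}

#' Build the two-condition observations for weight fitting
#'
#' @param targets named numeric vector in [0,1]: the measured node values
#'   for this condition.
#' @param clamp named numeric vector: input nodes held fixed.
#' @param condition condition label.
#' @return A list of class `condition_observation`.
#' @export
condition_observation <- function(targets, clamp, condition = "") {
  stopifnot(all(targets >= 0 & targets <= 1), all(clamp >= 0 & clamp <= 1))
  structure(list(condition = condition, targets = targets, clamp = clamp),
            class = "condition_observation")
}

# --- constrained parameterization -----------------------------------------
# Activating weights per node: softmax over the node's activators (sum 1 by
# construction; a single activator is pinned at 1 and contributes no free
# parameter). Inhibiting weights per node: softmax over the inhibitors plus
# one slack term, so each weight is in (0,1) and the sum stays below 1.
weight_parameterization <- function(network) {
  e <- network$edges
  free <- list()
  for (nd in unique(e$to)) {
    act <- which(e$to == nd & e$sign == 1L)
    inh <- which(e$to == nd & e$sign == -1L)
    if (length(act) > 1) free[[length(free) + 1L]] <- list(edges = act, kind = "act")
    if (length(inh) >= 1) free[[length(free) + 1L]] <- list(edges = inh, kind = "inh")
  }
  n_par <- sum(vapply(free, function(g) length(g$edges), integer(1)))
  list(groups = free, n_par = n_par)
}

params_to_weights <- function(theta, network, param) {
  w <- rep(1, nrow(network$edges))  # single activators default to 1
  pos <- 0L
  for (g in param$groups) {
    k <- length(g$edges)
    z <- theta[pos + seq_len(k)]
    pos <- pos + k
    ez <- exp(z - max(z, 0))
    if (g$kind == "act") {
      w[g$edges] <- ez / sum(ez)
    } else {
      w[g$edges] <- ez / (sum(ez) + exp(-max(z, 0)))  # slack keeps sum < 1
    }
  }
  w
}

#' Fit edge weights to two-condition observations
#'
#' Minimizes the mean squared error between the model's quasi-steady-state
#' node activities and the observed targets across all conditions, subject
#' to the total-probability weight constraints. The constraints hold by
#' construction through a softmax parameterization (activating fan-ins sum
#' to 1; inhibiting fan-ins get a slack term keeping their sum below 1), so
#' an unconstrained quasi-Newton optimizer (L-BFGS-B with numeric
#' gradients) can be used. The fit is restarted from `n_restarts` random
#' parameter draws with reproducible per-restart seeds; non-clamped node
#' values are initialized from N(0.5, 0.1) truncated to [0,1], redrawn per
#' restart.
#'
#' @param network a [signed_network()].
#' @param observations list of [condition_observation()]s (>= 1); every
#'   target node must be in the network.
#' @param n_restarts number of random restarts (default 20).
#' @param seed master seed from which per-restart seeds are derived.
#' @param max_iter optimizer iteration cap per restart (default 2000).
#' @param reltol relative objective tolerance (default 1e-8).
#' @param ss_tol,ss_max_iter steady-state tolerance and iteration cap.
#' @return A list of class `fit_result`: `weighted` (the fitted
#'   [weighted_network()]), `mse`, `n_restarts`, `best_seed`, `converged`,
#'   `iterations`, `predictions` (per observation).
#' @export
fit_weights <- function(network, observations, n_restarts = 20, seed = 1,
                        max_iter = 2000, reltol = 1e-8,
                        ss_tol = 1e-6, ss_max_iter = 1000) {
  stopifnot(inherits(network, "signed_network"), length(observations) >= 1)
  for (ob in observations) {
    if (!length(ob$targets)) stop("observation with zero measured nodes")
    if (!all(names(ob$targets) %in% network$nodes)) {
      stop("measured node(s) absent from the network")
    }
  }
  param <- weight_parameterization(network)
  pidx <- parent_index(network)

  objective <- function(theta, init_vec) {
    w <- params_to_weights(theta, network, param)
    wn <- structure(list(network = network, weights = w),
                    class = "weighted_network")
    err <- 0; n <- 0L
    for (ob in observations) {
      ss <- steady_state(wn, clamp = ob$clamp, init = init_vec,
                         tol = ss_tol, max_iter = ss_max_iter)
      err <- err + sum((ss[names(ob$targets)] - ob$targets)^2)
      n <- n + length(ob$targets)
    }
    err / n
  }

  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    theta0 <- stats::rnorm(param$n_par, 0, 1)
    init_vec <- pmin(pmax(stats::rnorm(length(network$nodes), 0.5, 0.1), 0), 1)
    names(init_vec) <- network$nodes
    fit <- if (param$n_par > 0) {
      stats::optim(theta0, objective, init_vec = init_vec,
                   method = "L-BFGS-B",
                   control = list(maxit = max_iter, factr = reltol / 1e-15))
    } else {
      list(par = numeric(), value = objective(numeric(), init_vec),
           convergence = 0, counts = c(1, 0))
    }
    if (is.null(best) || fit$value < best$fit$value) {
      best <- list(fit = fit, seed = restart_seeds[r], restart = r,
                   init_vec = init_vec)
    }
  }
  w <- params_to_weights(best$fit$par, network, param)
  wn <- weighted_network(network, w, check = TRUE, tol = 1e-6)
  preds <- lapply(observations, function(ob) {
    steady_state(wn, clamp = ob$clamp, init = best$init_vec,
                 tol = ss_tol, max_iter = ss_max_iter)
  })
  structure(list(
    weighted = wn,
    mse = best$fit$value,
    n_restarts = n_restarts,
    best_seed = best$seed,
    best_restart = best$restart,
    converged = best$fit$convergence == 0,
    iterations = unname(best$fit$counts[1]),
    predictions = preds
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: mse %.6g after %d restarts (best restart %d%s)\n",
              x$mse, x$n_restarts, x$best_restart,
              if (x$converged) ", converged" else ", not converged"))
  invisible(x)
}

#' Contextualize a network against two-condition expression
#'
#' Pipeline wrapper around [fit_weights()]: control and case are treated as
#' two clamped steady-state problems sharing one weight set. Input genes are
#' clamped at their observed unit-interval values (from
#' [normalize_to_unit_interval()]) per condition; all other network genes
#' present in the matrix become fit targets.
#'
#' @param network a [signed_network()] whose nodes are gene symbols.
#' @param mat a log-normalized [expression_matrix()].
#' @param cell_type cell type to contextualize.
#' @param input_nodes genes clamped as inputs (must be network nodes).
#' @param control_label,case_label condition labels.
#' @param ... passed to [fit_weights()] (`n_restarts`, `seed`, ...).
#' @return A `fit_result` (see [fit_weights()]).
#' @export
contextualize_network <- function(network, mat, cell_type, input_nodes,
                                  control_label = "CTL", case_label = "ASD",
                                  ...) {
  stopifnot(all(input_nodes %in% network$nodes))
  genes <- intersect(network$nodes, rownames(mat$values))
  u <- normalize_to_unit_interval(mat, cell_type, genes,
                                  control_label, case_label)
  targets <- setdiff(genes, input_nodes)
  if (!length(targets)) stop("no non-input network genes in the matrix")
  obs <- list(
    condition_observation(u$control[targets], u$control[input_nodes],
                          control_label),
    condition_observation(u$case[targets], u$case[input_nodes], case_label))
  fit_weights(network, obs, ...)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  e <- fit$weighted$network$edges
  jsonlite::write_json(list(
    edges = data.frame(from = e$from, to = e$to, sign = e$sign,
                       weight = fit$weighted$weights),
    mse = fit$mse, n_restarts = fit$n_restarts, best_seed = fit$best_seed,
    converged = fit$converged
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
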