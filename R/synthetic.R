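#' Fixtures and synthetic data generation
#'
#' Everything in the pipeline is testable offline: the packaged
#' translation-control core network and its protein-interaction evidence
#' table, random signed prior-knowledge networks for solver verification,
#' and two-condition expression matrices simulated from a known weighted
#' logic network so that inference and weight fitting can be checked against
#' ground truth.
#'
#' @name synthetic
NULL

#' The translation-control core network
#'
#' Six nodes (MAPK1, MKNK1, RPS6KA5, MTOR, EIF4EBP1, EIF4E) and seven
#' edges: MAPK1 activates MKNK1 and RPS6KA5, MKNK1 activates EIF4E, and
#' RPS6KA5, MAPK1 and MTOR each inhibit EIF4EBP1, which in turn inhibits
#' EIF4E. This is the first neighborhood of the EIF4EBP1-EIF4E regulation
#' pair, the module through which the four canonical sub-pathway patterns
#' run (see [core_patterns()]). A copy is shipped as
#' `inst/extdata/core_network.sif`.
#'
#' @return A [signed_network()].
#' @export
core_network_fixture <- function() {
  signed_network(edges = data.frame(
    from = c("MAPK1", "MKNK1", "MAPK1", "RPS6KA5", "EIF4EBP1", "MAPK1", "MTOR"),
    to = c("MKNK1", "EIF4E", "RPS6KA5", "EIF4EBP1", "EIF4E", "EIF4EBP1",
           "EIF4EBP1"),
    sign = c(1L, 1L, 1L, -1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE))
}

#' Evidence-channel scores for the core-network gene pairs
#'
#' The packaged per-channel protein-interaction score table covering all 13
#' undirected pairs among the six core-network genes (7 network edges plus
#' 6 pairs without a network edge), read from
#' `inst/extdata/string_scores_core.tsv`.
#'
#' @return A data frame (see [read_string_scores()]).
#' @export
core_string_scores <- function() {
  read_string_scores(system.file("extdata", "string_scores_core.tsv",
                                 package = "sirenet", mustWork = TRUE))
}

#' Generate a random signed directed network
#'
#' Uniformly samples `n_edges` distinct ordered node pairs (no self-loops)
#' and assigns `round(inhibitory_fraction * n_edges)` of them sign -1.
#' Reproducible given the seed.
#'
#' @param n_nodes,n_edges network size; `n_edges` at most
#'   `n_nodes * (n_nodes - 1)`.
#' @param inhibitory_fraction fraction of inhibiting edges in [0,1].
#' @param seed integer seed.
#' @return A [signed_network()] with nodes `N1..Nk`.
#' @export
generate_random_pkn <- function(n_nodes, n_edges, inhibitory_fraction = 0.3,
                                seed = 1) {
  stopifnot(n_nodes >= 2, inhibitory_fraction >= 0, inhibitory_fraction <= 1)
  if (n_edges > n_nodes * (n_nodes - 1)) {
    stop("more edges requested than ordered node pairs available")
  }
  set.seed(seed)
  nodes <- sprintf("N%d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  n_inh <- round(inhibitory_fraction * n_edges)
  sgn <- rep(1L, n_edges)
  if (n_inh > 0) sgn[sample.int(n_edges, n_inh)] <- -1L
  pick$sign <- sgn
  suppressWarnings(signed_network(nodes = nodes, edges = pick))
}

#' Configuration for expression simulation
#'
#' @param n_genes total genes in the simulated matrix (network genes plus
#'   off-network filler drawn identically in both conditions).
#' @param n_cells_per_condition cells per condition per cell type.
#' @param cell_types character vector of cell-type labels.
#' @param noise_sd Gaussian noise standard deviation on the log-normalized
#'   activity scale.
#' @param clamp_control,clamp_case named vectors of clamped input-node
#'   values per condition.
#' @param control_label,case_label condition labels.
#' @param seed master seed; per-component child seeds are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100, n_cells_per_condition = 50,
                              cell_types = "sim", noise_sd = 0.05,
                              clamp_control = numeric(),
                              clamp_case = numeric(),
                              control_label = "CTL", case_label = "ASD",
                              seed = 1) {
  stopifnot(n_genes > 0, n_cells_per_condition > 0, noise_sd >= 0)
  structure(list(n_genes = n_genes,
                 n_cells_per_condition = n_cells_per_condition,
                 cell_types = cell_types, noise_sd = noise_sd,
                 clamp_control = clamp_control, clamp_case = clamp_case,
                 control_label = control_label, case_label = case_label,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a two-condition expression matrix from a weighted logic network
#'
#' Per condition, the network genes' mean expression is the quasi-steady
#' state of the generating [weighted_network()] under that condition's
#' clamps; per cell, values are the means plus Gaussian noise truncated at
#' zero. Filler genes (`G1`, `G2`, ...) are drawn identically in both
#' conditions (uniform means), so any filler DEG call is a false positive.
#' The values are on the log-normalized activity scale in [0,1] plus noise,
#' ready for [differential_expression()] (use `log_base = 2` to read mean
#' differences directly as log2 fold changes) and for weight-fitting
#' targets.
#'
#' @param truth the generating [weighted_network()].
#' @param config a [simulation_config()]; clamped nodes must be network
#'   nodes.
#' @return A list: `matrix` (an [expression_matrix()]), `truth` (list with
#'   the generating weights and per-condition steady-state means).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "weighted_network"),
            inherits(config, "simulation_config"))
  nodes <- truth$network$nodes
  clamps <- list(control = config$clamp_control, case = config$clamp_case)
  for (cl in clamps) {
    if (length(cl) && !all(names(cl) %in% nodes)) {
      stop("clamped node(s) absent from the network")
    }
  }
  means <- lapply(clamps, function(cl) {
    ss <- steady_state(truth, clamp = cl)
    if (!attr(ss, "converged")) {
      stop("generating network did not reach a steady state (cycle?)")
    }
    ss
  })
  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1L,
                      2L + length(config$cell_types))
  n_fill <- max(0L, config$n_genes - length(nodes))
  set.seed(child[1])
  filler_means <- stats::setNames(stats::runif(n_fill, 0.1, 0.9),
                                  if (n_fill) sprintf("G%d", seq_len(n_fill))
                                  else character())
  genes <- c(nodes, names(filler_means))
  nc <- config$n_cells_per_condition
  cols <- list(); cond <- character(); ctype <- character()
  for (k in seq_along(config$cell_types)) {
    set.seed(child[2L + k])
    for (cnd in c("control", "case")) {
      mu <- c(means[[cnd]][nodes], filler_means)
      block <- matrix(stats::rnorm(length(genes) * nc, mean = mu,
                                   sd = config$noise_sd),
                      nrow = length(genes))
      block <- pmax(block, 0)
      cols[[length(cols) + 1L]] <- block
      lab <- if (cnd == "control") config$control_label else config$case_label
      cond <- c(cond, rep(lab, nc))
      ctype <- c(ctype, rep(config$cell_types[k], nc))
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  colnames(values) <- sprintf("cell%d", seq_len(ncol(values)))
  list(
    matrix = expression_matrix(values, cond, ctype),
    truth = list(weights = truth$weights,
                 edges = truth$network$edges,
                 means_control = means$control,
                 means_case = means$case,
                 filler_means = filler_means)
  )
}
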