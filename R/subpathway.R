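#' Sub-pathway extraction and scoring
#'
#' The regulation pair EIF4EBP1 -| EIF4E and its first-neighborhood subgraph
#' (adding MAPK1, MKNK1, RPS6KA5 and MTOR) form the translation-control core
#' network; four canonical routes ("patterns") lead from MAPK1 or MTOR to
#' the endpoint EIF4E. Fitted edge weights quantify each route: the strength
#' of the sub-pathway (SSP) is the product of the on-path edge weights,
#' expressed as a percent, and the abnormality index (AISP) additionally
#' scales each on-path weight by the log2 fold change of the upstream node,
#' so a route only scores highly when both strongly wired and fed by
#' dysregulated genes.
#'
#' @name subpathway
NULL

#' Declare a sub-pathway on a host network
#'
#' @param nodes ordered character vector from the input node to the
#'   endpoint; consecutive nodes must be joined by an edge of `network`.
#' @param network the host [signed_network()].
#' @param pattern optional pattern id (`"I"`-`"IV"` or `"custom"`).
#' @return A list of class `sub_pathway` with `nodes`, `edges`, `pattern`.
#' @export
sub_pathway <- function(nodes, network, pattern = "custom") {
  stopifnot(length(nodes) >= 2, inherits(network, "signed_network"))
  e <- network$edges
  steps <- lapply(seq_len(length(nodes) - 1L), function(i) {
    hit <- e[e$from == nodes[i] & e$to == nodes[i + 1L], , drop = FALSE]
    if (!nrow(hit)) {
      stop(sprintf("no edge %s -> %s in the host network",
                   nodes[i], nodes[i + 1L]))
    }
    hit[1, ]
  })
  structure(list(nodes = nodes, edges = do.call(rbind, steps),
                 pattern = pattern),
            class = "sub_pathway")
}

#' The four canonical core-network sub-pathway patterns
#'
#' Routes to EIF4E: I = MAPK1-MKNK1-EIF4E; II = MAPK1-RPS6KA5-EIF4EBP1-EIF4E;
#' III = MAPK1-EIF4EBP1-EIF4E; IV = MTOR-EIF4EBP1-EIF4E.
#'
#' @param network host network containing the core edges (default the
#'   packaged core network, [core_network_fixture()]).
#' @return Named list of [sub_pathway()]s `I`, `II`, `III`, `IV`.
#' @export
core_patterns <- function(network = core_network_fixture()) {
  list(
    I = sub_pathway(c("MAPK1", "MKNK1", "EIF4E"), network, "I"),
    II = sub_pathway(c("MAPK1", "RPS6KA5", "EIF4EBP1", "EIF4E"), network, "II"),
    III = sub_pathway(c("MAPK1", "EIF4EBP1", "EIF4E"), network, "III"),
    IV = sub_pathway(c("MTOR", "EIF4EBP1", "EIF4E"), network, "IV")
  )
}

#' Extract the core network around a module
#'
#' Induced subgraph on the module nodes together with their 1-hop in- and
#' out-neighbors.
#'
#' @param net a [signed_network()].
#' @param module character set of module nodes (must all be in the network).
#' @return A [signed_network()].
#' @export
extract_core_network <- function(net, module) {
  stopifnot(inherits(net, "signed_network"))
  missing <- setdiff(module, net$nodes)
  if (length(missing)) {
    stop("module node(s) absent from the network: ",
         paste(missing, collapse = ", "))
  }
  e <- net$edges
  nbrs <- c(e$from[e$to %in% module], e$to[e$from %in% module])
  induced_subnetwork(net, union(module, nbrs))
}

path_weights <- function(path, wn) {
  vapply(seq_len(nrow(path$edges)), function(i) {
    edge_weight(wn, path$edges$from[i], path$edges$to[i])
  }, numeric(1))
}

#' Strength of a sub-pathway (SSP)
#'
#' SSP = 100 x the product, over the path nodes after the input, of the
#' on-path incoming edge weight. All weights lie in [0,1], so SSP is a
#' percent in [0,100]; with full fan-in sums enabled (`fan_in = TRUE`) the
#' per-node factor is instead the node's total activating-weight sum, which
#' is 1 by construction whenever the node has activators.
#'
#' @param path a [sub_pathway()].
#' @param wn a [weighted_network()] carrying every path edge.
#' @param fan_in use the full activating fan-in sum per node instead of the
#'   single on-path weight (default `FALSE`).
#' @return SSP as a percent, with attribute `factors` (per-node breakdown).
#' @export
compute_ssp <- function(path, wn, fan_in = FALSE) {
  stopifnot(inherits(path, "sub_pathway"), inherits(wn, "weighted_network"))
  factors <- if (fan_in) {
    e <- wn$network$edges
    vapply(path$nodes[-1], function(nd) {
      idx <- which(e$to == nd & e$sign == 1L)
      if (length(idx)) sum(wn$weights[idx]) else {
        path_weights(path, wn)[match(nd, path$nodes) - 1L]
      }
    }, numeric(1))
  } else {
    stats::setNames(path_weights(path, wn), path$nodes[-1])
  }
  structure(100 * prod(factors), factors = factors)
}

#' Abnormality index of a sub-pathway (AISP)
#'
#' AISP = 100 x the product, over the path nodes after the input, of
#' (on-path edge weight x f(log2FC of the upstream node)), where f is the
#' absolute value by default (`absolute = FALSE` propagates signs instead).
#' Genes missing from the DEG table contribute log2FC = 0, zeroing the
#' index.
#'
#' @param path a [sub_pathway()].
#' @param wn a [weighted_network()].
#' @param degs a `deg_table` (see [differential_expression()]) supplying
#'   per-gene `log2fc`.
#' @param absolute use |log2FC| (default) rather than the signed value.
#' @return AISP (percent scale), with attribute `factors`.
#' @export
compute_aisp <- function(path, wn, degs, absolute = TRUE) {
  w <- path_weights(path, wn)
  fc <- stats::setNames(degs$log2fc, degs$gene)
  upstream <- path$nodes[-length(path$nodes)]
  lfc <- fc[upstream]
  if (anyNA(lfc)) {
    warning("no log2FC for node(s): ",
            paste(upstream[is.na(lfc)], collapse = ", "), "; using 0")
    lfc[is.na(lfc)] <- 0
  }
  if (absolute) lfc <- abs(lfc)
  factors <- stats::setNames(w * as.numeric(lfc), path$nodes[-1])
  structure(100 * prod(factors), factors = factors)
}

#' Classify which sub-pathway patterns are active
#'
#' A pattern counts as active when every edge on its route carries a fitted
#' weight strictly above the threshold (default 0.2, the wiring-intensity
#' cutoff used when drawing activation diagrams).
#'
#' @param wn a [weighted_network()] over (at least) the core network.
#' @param threshold weight threshold (default 0.2).
#' @param patterns list of [sub_pathway()]s (default [core_patterns()] on
#'   the weighted network's own graph).
#' @return Character vector of active pattern ids.
#' @export
classify_activation_patterns <- function(wn, threshold = 0.2,
                                         patterns = core_patterns(wn$network)) {
  active <- vapply(patterns, function(p) {
    all(path_weights(p, wn) > threshold)
  }, logical(1))
  names(patterns)[active]
}

#' Score all patterns for one cell type as a table row
#'
#' @param wn fitted [weighted_network()].
#' @param degs `deg_table` for the cell type.
#' @param cell_type label for the output row.
#' @param patterns list of [sub_pathway()]s.
#' @param threshold pattern-activation weight threshold.
#' @return One-row data frame with SSP and AISP per pattern and the pattern
#'   call.
#' @export
score_subpathways <- function(wn, degs, cell_type = "",
                              patterns = core_patterns(wn$network),
                              threshold = 0.2) {
  row <- data.frame(cell_type = cell_type, stringsAsFactors = FALSE)
  for (id in names(patterns)) {
    row[[paste0("SSP_", id)]] <- as.numeric(compute_ssp(patterns[[id]], wn))
    row[[paste0("AISP_", id)]] <-
      as.numeric(suppressWarnings(compute_aisp(patterns[[id]], wn, degs)))
  }
  row$pattern <- paste(
    classify_activation_patterns(wn, threshold, patterns), collapse = ",")
  row
}
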