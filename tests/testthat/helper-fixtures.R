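# shared fixtures and independent oracles, built in code

# small expression matrix with explicit values
make_expr <- function(values, condition, cell_type = "sim") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  expression_matrix(values, condition, cell_type)
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
# (independent of stats::wilcox.test); feasible for small n only
rank_sum_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# the identifiable 4-node fan-in topology used for weight-recovery checks:
# inputs A and B; C <- 0.7 A + 0.3 B; D <- C * (1 - 0.4 B)
fanin_network <- function() {
  signed_network(edges = data.frame(
    from = c("A", "B", "C", "B"), to = c("C", "C", "D", "D"),
    sign = c(1L, 1L, 1L, -1L)))
}
fanin_truth <- function() {
  weighted_network(fanin_network(),
                   c("A|C" = 0.7, "B|C" = 0.3, "C|D" = 1, "B|D" = 0.4))
}
fanin_clamps <- function() {
  list(control = c(A = 0.9, B = 0.2), case = c(A = 0.3, B = 0.8))
}

# random causal-reasoning instance for solver-vs-oracle equivalence
random_ilp_instance <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(4:8, 1)
  n_edges <- sample(3:min(12, n_nodes * (n_nodes - 1)), 1)
  pkn <- generate_random_pkn(n_nodes, n_edges,
                             inhibitory_fraction = stats::runif(1, 0, 0.6),
                             seed = seed + 10000L)
  set.seed(seed + 20000L)
  inputs <- stats::setNames(sample(c(-1, 1), 2, replace = TRUE),
                            sample(pkn$nodes, 2))
  n_meas <- sample(1:n_nodes, 1)
  meas <- stats::setNames(sample(c(-1, 0, 1), n_meas, replace = TRUE),
                          sample(pkn$nodes, n_meas))
  cfg <- suppressWarnings(
    ilp_config(alpha = 1, beta = stats::runif(1, 0.03, 0.5)))
  list(pkn = pkn, inputs = inputs, measurement = meas, config = cfg)
}
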