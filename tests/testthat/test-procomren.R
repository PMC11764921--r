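test_that("weighted_network enforces total-probability invariants", {
  net <- fanin_network()
  expect_s3_class(fanin_truth(), "weighted_network")
  # activating weights into C must sum to 1
  expect_error(weighted_network(net, c("A|C" = 0.7, "B|C" = 0.5, "C|D" = 1,
                                       "B|D" = 0.4)),
               "sum to")
  # inhibiting sum above 1 rejected
  two_inh <- signed_network(edges = data.frame(
    from = c("A", "B"), to = c("C", "C"), sign = c(-1L, -1L)))
  expect_error(weighted_network(two_inh, c(0.7, 0.6)), "> 1")
  expect_error(weighted_network(net, c(1, 1, 1)), "one weight per edge")
  expect_error(weighted_network(net, c("A|C" = 0.7, "B|C" = 0.3, "C|D" = 1,
                                       "B|D" = 1.4)),
               "\\[0,1\\]")
})

test_that("dbn_update implements expected activation damped by inhibition", {
  # one activator k=1, parent 0.5
  n1 <- signed_network(edges = data.frame(from = "P", to = "X", sign = 1))
  w1 <- weighted_network(n1, 1)
  expect_equal(dbn_update(c(P = 0.5), w1, "X"), 0.5)

  # full activation fully inhibited -> 0
  n2 <- signed_network(edges = data.frame(
    from = c("P", "Q"), to = "X", sign = c(1L, -1L)))
  w2 <- weighted_network(n2, c(1, 1))
  expect_equal(dbn_update(c(P = 1, Q = 1), w2, "X"), 0)

  # mixed fan-in: 0.3*1 + 0.7*0 damped by 0.5*0.5 -> 0.3 * 0.75
  n3 <- signed_network(edges = data.frame(
    from = c("P", "Q", "R"), to = "X", sign = c(1L, 1L, -1L)))
  w3 <- weighted_network(n3, c("P|X" = 0.3, "Q|X" = 0.7, "R|X" = 0.5))
  expect_equal(dbn_update(c(P = 1, Q = 0, R = 0.5), w3, "X"), 0.225)

  # no parents: current value is kept
  iso <- signed_network(nodes = c("L", "P"),
                        edges = data.frame(from = "P", to = "L", sign = 1))
  wi <- weighted_network(iso, 1)
  expect_equal(dbn_update(c(L = 0.7), wi, "P", current = 0.42), 0.42)
})

test_that("steady_state reaches the expected fixed points", {
  # activating chain propagates the clamped value
  chain <- signed_network(edges = data.frame(
    from = c("A", "B"), to = c("B", "C"), sign = 1L))
  wc <- weighted_network(chain, c(1, 1))
  ss <- steady_state(wc, clamp = c(A = 0.8))
  expect_equal(unname(ss[c("B", "C")]), c(0.8, 0.8), tolerance = 1e-9)
  expect_true(attr(ss, "converged"))
  # acyclic: convergence within longest-path iterations (2 updates + check)
  expect_lte(attr(ss, "iterations"), 3)

  # inhibitor-only node uses basal activation 1
  inh <- signed_network(edges = data.frame(from = "A", to = "B", sign = -1))
  wi <- weighted_network(inh, 0.4)
  ssi <- steady_state(wi, clamp = c(A = 1))
  expect_equal(unname(ssi[["B"]]), 0.6, tolerance = 1e-9)

  # symmetric weight-1 positive 2-cycle keeps its initial value
  cyc <- signed_network(edges = data.frame(
    from = c("A", "B"), to = c("B", "A"), sign = 1L))
  wcy <- weighted_network(cyc, c(1, 1))
  ssc <- steady_state(wcy, init = 0.5)
  expect_true(attr(ssc, "converged"))
  expect_equal(as.numeric(ssc), c(0.5, 0.5))

  expect_error(steady_state(wc, clamp = c(Z = 1)), "absent")
})

test_that("dbn updates never leave [0,1] for valid weights (closure)", {
  set.seed(314)
  for (rep in 1:50) {
    m <- sample(0:3, 1); l <- sample(0:3, 1)
    if (m + l == 0) next
    ka <- if (m) { z <- stats::runif(m); z / sum(z) } else numeric()
    ki <- if (l) { z <- stats::runif(l); z * stats::runif(1) / sum(z) } else numeric()
    pa <- stats::runif(m); pi_ <- stats::runif(l)
    act <- if (m) sum(ka * pa) else 1
    x <- act * (1 - sum(ki * pi_))
    expect_gte(x, 0); expect_lte(x, 1)
  }
})

test_that("normalize_to_unit_interval min-max scales condition means", {
  v <- matrix(c(2, 1, 5,   2, 1, 5,   4, 1, 3,   4, 1, 3), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), sprintf("c%d", 1:4)))
  mat <- make_expr(v, c("CTL", "CTL", "ASD", "ASD"))
  u <- normalize_to_unit_interval(mat, "sim")
  expect_equal(unname(u$control[c("gA", "gB", "gC")]), c(0, 0.5, 1))
  expect_equal(unname(u$case[c("gA", "gB", "gC")]), c(1, 0.5, 0))
  expect_warning(normalize_to_unit_interval(mat, "sim", genes = c("gA", "gZ")),
                 "omitted")
})

test_that("fit_weights recovers generating weights from noiseless data", {
  truth <- fanin_truth()
  cl <- fanin_clamps()
  ss1 <- steady_state(truth, clamp = cl$control)
  ss2 <- steady_state(truth, clamp = cl$case)
  obs <- list(
    condition_observation(ss1[c("C", "D")], cl$control, "CTL"),
    condition_observation(ss2[c("C", "D")], cl$case, "ASD"))
  fit <- fit_weights(fanin_network(), obs, n_restarts = 5, seed = 42)
  expect_lte(fit$mse, 1e-6)
  expect_equal(unname(fit$weighted$weights), c(0.7, 0.3, 0.4, 1),
               tolerance = 0.02)
  check_ok <- tryCatch({
    sirenet:::check_weight_invariants(fit$weighted, tol = 1e-6); TRUE
  }, error = function(e) FALSE)
  expect_true(check_ok)
})

test_that("a forced single edge fits weight 1 with zero error", {
  e1 <- signed_network(edges = data.frame(from = "A", to = "B", sign = 1))
  fit <- fit_weights(e1, list(condition_observation(c(B = 0.8), c(A = 0.8))),
                     n_restarts = 2, seed = 1)
  expect_equal(unname(fit$weighted$weights), 1)
  expect_equal(fit$mse, 0)
})

test_that("best-of-restarts mse is nonincreasing in the restart count", {
  truth <- fanin_truth()
  cl <- fanin_clamps()
  set.seed(8)
  noisy <- function(ss) pmin(pmax(ss + stats::rnorm(length(ss), 0, 0.05), 0), 1)
  obs <- list(
    condition_observation(noisy(steady_state(truth, clamp = cl$control)[c("C", "D")]),
                          cl$control),
    condition_observation(noisy(steady_state(truth, clamp = cl$case)[c("C", "D")]),
                          cl$case))
  mses <- vapply(c(1, 3, 6), function(k) {
    fit_weights(fanin_network(), obs, n_restarts = k, seed = 77)$mse
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-12))
})

test_that("fit_weights validates its inputs", {
  net <- fanin_network()
  expect_error(fit_weights(net, list()), "length")
  expect_error(
    fit_weights(net, list(condition_observation(c(Z = 0.5), c(A = 1)))),
    "absent")
  expect_error(condition_observation(c(B = 1.2), c(A = 0.5)), "not TRUE")
})

test_that("weighted networks round-trip through 4-column SIF", {
  truth <- fanin_truth()
  f <- withr::local_tempfile(fileext = ".sif")
  write_weighted_sif(truth, f)
  back <- read_weighted_sif(f)
  expect_true(networks_equal(back$network, truth$network))
  expect_equal(back$weights, truth$weights, tolerance = 1e-9)
})

test_that("contextualize_network fits from an expression matrix end to end", {
  truth <- fanin_truth()
  cl <- fanin_clamps()
  sim <- simulate_expression(truth, simulation_config(
    n_genes = 6, n_cells_per_condition = 40, noise_sd = 0.02,
    clamp_control = cl$control, clamp_case = cl$case, seed = 5))
  fit <- contextualize_network(fanin_network(), sim$matrix, "sim",
                               input_nodes = c("A", "B"),
                               n_restarts = 5, seed = 9)
  expect_lt(fit$mse, 0.05)
  expect_s3_class(fit$weighted, "weighted_network")
})
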