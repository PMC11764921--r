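# weights used across scoring tests: the pattern-II worked values plus
# fill-ins for the remaining core edges (subnetwork view, so no fan-in check)
core_weights_example <- function() {
  weighted_network(core_network_fixture(), c(
    "MAPK1|MKNK1" = 0.5, "MKNK1|EIF4E" = 0.9, "MAPK1|RPS6KA5" = 0.73,
    "RPS6KA5|EIF4EBP1" = 0.64, "EIF4EBP1|EIF4E" = 0.70,
    "MAPK1|EIF4EBP1" = 0.15, "MTOR|EIF4EBP1" = 0.1), check = FALSE)
}

test_that("sub_pathway requires consecutive host edges", {
  net <- core_network_fixture()
  p <- sub_pathway(c("MAPK1", "RPS6KA5", "EIF4EBP1", "EIF4E"), net, "II")
  expect_equal(nrow(p$edges), 3)
  expect_equal(p$edges$sign, c(1L, -1L, -1L))
  expect_error(sub_pathway(c("MTOR", "EIF4E"), net), "no edge")
})

test_that("extract_core_network takes the module plus 1-hop neighbors", {
  fix <- core_network_fixture()
  core <- extract_core_network(fix, c("EIF4EBP1", "EIF4E"))
  expect_equal(length(core$nodes), 6)
  expect_true(networks_equal(core, fix))

  expect_true(networks_equal(extract_core_network(fix, fix$nodes), fix))

  with_iso <- signed_network(nodes = "LONER",
                             edges = fix$edges)
  lone <- extract_core_network(with_iso, "LONER")
  expect_equal(lone$nodes, "LONER")
  expect_equal(nrow(lone$edges), 0)

  expect_error(extract_core_network(fix, "GHOST"), "GHOST")
})

test_that("compute_ssp is the percent product of on-path weights", {
  wn <- core_weights_example()
  pats <- core_patterns()
  expect_equal(as.numeric(compute_ssp(pats$II, wn)), 32.7, tolerance = 0.005)

  single <- sub_pathway(c("MTOR", "EIF4EBP1"), core_network_fixture())
  expect_equal(as.numeric(compute_ssp(single, wn)), 10)  # 100 * 0.1

  ones <- weighted_network(core_network_fixture(), rep(1, 7), check = FALSE)
  expect_equal(as.numeric(compute_ssp(pats$II, ones)), 100)

  # scaling one weight by c scales SSP by c
  w2 <- core_weights_example()
  i <- which(w2$network$edges$from == "RPS6KA5")
  w2$weights[i] <- w2$weights[i] * 0.5
  expect_equal(as.numeric(compute_ssp(pats$II, w2)),
               as.numeric(compute_ssp(pats$II, wn)) * 0.5)
  expect_error(compute_ssp(pats$II, weighted_network(
    signed_network(edges = data.frame(from = "A", to = "B", sign = 1)), 1)),
    "no edge")
})

test_that("compute_aisp scales each step by the upstream log2FC", {
  wn <- core_weights_example()
  pats <- core_patterns()
  degs <- data.frame(gene = core_network_fixture()$nodes, cell_type = "t",
                     log2fc = 1, p = 0.01, direction = 1L)

  # all |log2FC| = 1 reduces AISP to SSP
  expect_equal(as.numeric(compute_aisp(pats$II, wn, degs)),
               as.numeric(compute_ssp(pats$II, wn)))

  # single edge, k = 0.5, upstream log2FC = 2 -> 100
  half <- weighted_network(core_network_fixture(),
                           c("MAPK1|MKNK1" = 0.5, "MKNK1|EIF4E" = 1,
                             "MAPK1|RPS6KA5" = 1, "RPS6KA5|EIF4EBP1" = 1,
                             "EIF4EBP1|EIF4E" = 1, "MAPK1|EIF4EBP1" = 1,
                             "MTOR|EIF4EBP1" = 1), check = FALSE)
  degs2 <- transform(degs, log2fc = ifelse(gene == "MAPK1", 2, 1))
  p1 <- sub_pathway(c("MAPK1", "MKNK1"), core_network_fixture())
  expect_equal(as.numeric(compute_aisp(p1, half, degs2)), 100)

  # direct product with per-node fold changes (recomputed by hand)
  degs3 <- transform(degs, log2fc = c(MAPK1 = 1.2, RPS6KA5 = 0.9,
                                      EIF4EBP1 = 1.0, EIF4E = 0.5,
                                      MKNK1 = 1, MTOR = 1)[gene])
  expect_equal(as.numeric(compute_aisp(pats$II, wn, degs3)),
               100 * (0.73 * 1.2) * (0.64 * 0.9) * (0.70 * 1.0),
               tolerance = 1e-9)
  expect_equal(as.numeric(compute_aisp(pats$II, wn, degs3)), 35.3,
               tolerance = 0.05)

  # a zero on-path log2FC annihilates the index
  degs4 <- transform(degs, log2fc = ifelse(gene == "RPS6KA5", 0, 1))
  expect_equal(as.numeric(compute_aisp(pats$II, wn, degs4)), 0)

  # signed mode propagates signs
  degs5 <- transform(degs, log2fc = ifelse(gene == "MAPK1", -1, 1))
  expect_lt(as.numeric(compute_aisp(pats$II, wn, degs5, absolute = FALSE)), 0)

  # missing fold changes default to zero with a warning
  expect_warning(a <- compute_aisp(pats$II, wn, degs[degs$gene != "MAPK1", ]),
                 "MAPK1")
  expect_equal(as.numeric(a), 0)
})

test_that("classify_activation_patterns applies the per-route weight rule", {
  all_on <- weighted_network(core_network_fixture(), rep(1, 7), check = FALSE)
  expect_setequal(classify_activation_patterns(all_on),
                  c("I", "II", "III", "IV"))

  all_off <- weighted_network(core_network_fixture(), rep(0.1, 7),
                              check = FALSE)
  expect_equal(length(classify_activation_patterns(all_off)), 0)

  only_I <- weighted_network(core_network_fixture(), c(
    "MAPK1|MKNK1" = 0.9, "MKNK1|EIF4E" = 0.8, "MAPK1|RPS6KA5" = 0.15,
    "RPS6KA5|EIF4EBP1" = 0.15, "EIF4EBP1|EIF4E" = 0.15,
    "MAPK1|EIF4EBP1" = 0.15, "MTOR|EIF4EBP1" = 0.15), check = FALSE)
  expect_equal(classify_activation_patterns(only_I), "I")

  # monotone in the threshold: raising it never adds a pattern
  wn <- core_weights_example()
  thr <- c(0.05, 0.2, 0.5, 0.8)
  calls <- lapply(thr, function(t) classify_activation_patterns(wn, t))
  for (i in seq_along(thr)[-1]) {
    expect_true(all(calls[[i]] %in% calls[[i - 1]]))
  }
})

test_that("score_subpathways produces one labelled row per cell type", {
  wn <- core_weights_example()
  degs <- data.frame(gene = core_network_fixture()$nodes, cell_type = "L23",
                     log2fc = 1, p = 0.01, direction = 1L)
  row <- score_subpathways(wn, degs, cell_type = "L23")
  expect_equal(row$cell_type, "L23")
  expect_named(row, c("cell_type", "SSP_I", "AISP_I", "SSP_II", "AISP_II",
                      "SSP_III", "AISP_III", "SSP_IV", "AISP_IV", "pattern"))
  expect_equal(row$SSP_II, 32.704, tolerance = 1e-9)
  expect_true(all(vapply(row[grepl("^SSP", names(row))], function(x)
    x >= 0 && x <= 100, logical(1))))
})
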