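test_that("qc_filter enforces gene-count and flagged-fraction bounds", {
  # 600 genes; cell1 expresses 499, cell2 exactly 500
  v <- matrix(0, nrow = 600, ncol = 2)
  v[1:499, 1] <- 1
  v[1:500, 2] <- 1
  mat <- make_expr(v, condition = "CTL")
  out <- qc_filter(mat, min_genes = 500)
  expect_equal(ncol(out$values), 1)
  expect_equal(colnames(out$values), "c2")

  # flagged fraction exactly 0.06 removed, 0.04 kept (strict < 0.05)
  v2 <- matrix(c(6, 94, 4, 96), nrow = 2,
               dimnames = list(c("MT-1", "g2"), c("c1", "c2")))
  out2 <- qc_filter(make_expr(v2, "CTL"), min_genes = 0,
                    flagged_genes = "MT-1")
  expect_equal(colnames(out2$values), "c2")

  # permissive thresholds are the identity
  out3 <- qc_filter(mat, min_genes = 0, max_flagged_fraction = 1.0)
  expect_equal(dim(out3$values), dim(mat$values))

  expect_warning(qc_filter(mat, min_genes = 1000), "all cells removed")
  expect_error(qc_filter(mat, flagged_genes = "nope"), "absent")
})

test_that("normalize_log rescales by cell total and log-transforms", {
  v <- matrix(9, 1, 1, dimnames = list("g", "c"))
  out <- normalize_log(make_expr(v, "CTL"), scale = 9)  # scale = cell total
  expect_equal(out$values[1, 1], log(10))

  # all-zero cell stays zero
  vz <- matrix(c(0, 0, 5, 5), 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  outz <- normalize_log(make_expr(vz, "CTL"))
  expect_equal(unname(outz$values[, "c1"]), c(0, 0))

  # proportional cells normalize to identical profiles
  vp <- matrix(c(2, 4, 6, 20, 40, 60), nrow = 3)
  outp <- normalize_log(make_expr(vp, "CTL"))
  expect_equal(outp$values[, 1], outp$values[, 2])
})

test_that("differential_expression computes Welch t-tests per gene", {
  set.seed(11)
  # identical groups give log2fc 0
  v <- matrix(rep(stats::runif(5), 6), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  mat <- make_expr(v, rep(c("CTL", "ASD"), each = 3))
  d0 <- differential_expression(mat, "sim")
  expect_equal(d0$log2fc, rep(0, 5))

  # constant shifted groups: epsilon guard keeps the statistic finite
  v1 <- matrix(rep(c(1, 1, 1, 1, 2, 2, 2, 2), each = 1), nrow = 1,
               dimnames = list("g1", sprintf("c%d", 1:8)))
  m1 <- make_expr(v1, rep(c("CTL", "ASD"), each = 4))
  d1 <- differential_expression(m1, "sim", log_base = 2)
  expect_equal(d1$log2fc, 1)
  expect_lt(d1$p, 1e-6)

  # agreement with stats::t.test on noisy data
  set.seed(42)
  v2 <- matrix(stats::rnorm(10 * 20, mean = 1.5, sd = 0.4), nrow = 10)
  v2 <- pmax(v2, 0)
  rownames(v2) <- sprintf("g%d", 1:10); colnames(v2) <- sprintf("c%d", 1:20)
  m2 <- make_expr(v2, rep(c("CTL", "ASD"), each = 10))
  d2 <- differential_expression(m2, "sim", log_base = 2)
  for (i in 1:10) {
    ref <- stats::t.test(v2[i, 11:20], v2[i, 1:10])
    expect_equal(d2$p[i], ref$p.value, tolerance = 1e-6)
    expect_equal(d2$log2fc[i], unname(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-10)
  }

  # insufficient replication is an error naming the cell type
  m3 <- make_expr(v2[, 1:3, drop = FALSE], c("CTL", "ASD", "ASD"))
  expect_error(differential_expression(m3, "sim"), "sim")
})

test_that("null data give an approximately uniform p-value distribution", {
  set.seed(7)
  v <- matrix(abs(stats::rnorm(1000 * 40, 1, 0.3)), nrow = 1000,
              dimnames = list(sprintf("g%d", 1:1000), sprintf("c%d", 1:40)))
  mat <- make_expr(v, rep(c("CTL", "ASD"), each = 20))
  d <- differential_expression(mat, "sim")
  expect_gt(mean(d$p < 0.5), 0.45)
  expect_lt(mean(d$p < 0.5), 0.55)
})

test_that("call_degs applies strict thresholds and is monotone", {
  rec <- data.frame(gene = c("a", "b", "c"), cell_type = "t",
                    log2fc = c(0.5, 0.30, -0.4), p = c(0.01, 0.01, 0.2),
                    direction = 0L)
  out <- call_degs(rec)
  expect_equal(out$direction, c(1, 0, 0))

  # monotone: loosening thresholds never removes a DEG
  set.seed(5)
  rnd <- data.frame(gene = sprintf("g%d", 1:200), cell_type = "t",
                    log2fc = stats::rnorm(200, 0, 0.5),
                    p = stats::runif(200), direction = 0L)
  tight <- call_degs(rnd, fc_threshold = 0.4, p_threshold = 0.01)
  loose <- call_degs(rnd, fc_threshold = 0.2, p_threshold = 0.1)
  expect_true(all(loose$direction[tight$direction != 0] ==
                    tight$direction[tight$direction != 0]))
})

test_that("discretize_measurements maps DEG directions onto network nodes", {
  core <- core_network_fixture()
  degs <- data.frame(gene = c("EIF4E", "NOTINNET"), cell_type = "L23",
                     log2fc = c(1, 2), p = 0.001, direction = c(1L, 1L))
  m <- discretize_measurements(degs, core$nodes)
  expect_equal(m[["EIF4E"]], 1)
  expect_equal(sum(m != 0), 1)
  expect_true(all(m %in% c(-1, 0, 1)))
  expect_equal(attr(m, "cell_type"), "L23")

  m0 <- discretize_measurements(degs[0, ], core$nodes)
  expect_true(all(m0 == 0))
})

test_that("wilcoxon_two_group matches exact rank-sum enumeration", {
  expect_equal(wilcoxon_two_group(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_two_group(rep(2, 5), rep(2, 4)), 1)

  p_sep <- wilcoxon_two_group(1:10, 11:20)
  expect_lt(p_sep, 0.01)
  expect_equal(p_sep, rank_sum_enum_p(1:10, 11:20), tolerance = 1e-9)

  # single swap from identical groups: p near 1, equal to enumeration
  a <- c(1, 2, 3, 4, 5); b <- c(1, 2, 3, 4, 6)
  expect_gt(wilcoxon_two_group(a, b), 0.5)

  a2 <- c(1.3, 2.1, 3.2, 4.9); b2 <- c(1.8, 2.4, 3.9, 4.1)
  expect_equal(wilcoxon_two_group(a2, b2), rank_sum_enum_p(a2, b2),
               tolerance = 1e-9)
  expect_error(wilcoxon_two_group(numeric(), 1:3), "non-empty")
})

test_that("expression matrices round-trip through TSV and MTX with annotations", {
  set.seed(2)
  v <- matrix(stats::rpois(12, 5), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), sprintf("c%d", 1:4)))
  td <- withr::local_tempdir()
  expr_f <- file.path(td, "expr.tsv")
  ann_f <- file.path(td, "cells.tsv")
  utils::write.table(data.frame(gene = rownames(v), v), expr_f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = colnames(v), condition = c("CTL", "CTL", "ASD", "ASD"),
               cell_type = "sim"),
    ann_f, sep = "\t", quote = FALSE, row.names = FALSE)
  mat <- read_expression_tsv(expr_f, ann_f)
  expect_equal(mat$values, v)
  expect_equal(mat$condition, c("CTL", "CTL", "ASD", "ASD"))

  mtx_f <- file.path(td, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), mtx_f)
  writeLines(rownames(v), file.path(td, "genes.txt"))
  writeLines(colnames(v), file.path(td, "cells.txt"))
  mat2 <- read_expression_mtx(mtx_f, file.path(td, "genes.txt"),
                              file.path(td, "cells.txt"), ann_f)
  expect_equal(unname(mat2$values), unname(v))
})
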