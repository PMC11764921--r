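#' Gene-by-cell expression matrices with condition and cell-type labels
#'
#' @param values numeric gene x cell matrix (UMI counts or log-normalized
#'   values) with gene symbols as row names and cell ids as column names.
#' @param condition condition label per cell (e.g. `"CTL"` vs `"ASD"`);
#'   recycled if length 1.
#' @param cell_type cell-type label per cell; recycled if length 1.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, cell_type) {
  values <- as.matrix(values)
  if ((nrow(values) && is.null(rownames(values))) ||
      (ncol(values) && is.null(colnames(values)))) {
    stop("values must carry gene row names and cell column names")
  }
  if (any(values < 0)) stop("expression values must be nonnegative")
  condition <- rep_len(as.character(condition), ncol(values))
  cell_type <- rep_len(as.character(cell_type), ncol(values))
  structure(list(values = values, condition = condition,
                 cell_type = cell_type),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  cat("  conditions:", paste(names(table(x$condition)), table(x$condition),
                             sep = "=", collapse = ", "), "\n")
  cat("  cell types:", paste(unique(x$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

subset_cells <- function(mat, keep) {
  expression_matrix(mat$values[, keep, drop = FALSE],
                    mat$condition[keep], mat$cell_type[keep])
}

#' Read an expression matrix with cell annotations
#'
#' `read_expression_tsv` reads a genes-x-cells TSV (first column = gene
#' symbol, remaining columns = cells). `read_expression_mtx` reads a
#' MatrixMarket triplet file plus one-symbol-per-line row (gene) and column
#' (cell) name files. Both attach an annotation TSV with header columns
#' `cell`, `condition`, `cell_type` covering every cell.
#'
#' @param file expression TSV path (genes x cells).
#' @param annotations path to the cell annotation TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(file, annotations) {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  attach_annotations(values, annotations)
}

#' @rdname read_expression_tsv
#' @param mtx,genes,cells MatrixMarket file and row/column name files.
#' @export
read_expression_mtx <- function(mtx, genes, cells, annotations) {
  values <- as.matrix(Matrix::readMM(mtx))
  rownames(values) <- readLines(genes)
  colnames(values) <- readLines(cells)
  attach_annotations(values, annotations)
}

attach_annotations <- function(values, annotations) {
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  if (!all(c("cell", "condition", "cell_type") %in% names(ann))) {
    stop("annotation table needs columns 'cell', 'condition', 'cell_type'")
  }
  idx <- match(colnames(values), ann$cell)
  if (anyNA(idx)) {
    stop("cells missing from the annotation table: ",
         paste(utils::head(colnames(values)[is.na(idx)]), collapse = ", "))
  }
  expression_matrix(values, ann$condition[idx], ann$cell_type[idx])
}

#' Quality-control filtering of nuclei/cells
#'
#' Retains cells expressing at least `min_genes` genes (value > 0) and whose
#' summed expression over `flagged_genes` (typically mitochondrial and
#' ribosomal genes) is strictly below `max_flagged_fraction` of the cell
#' total. Defaults follow common snRNA-seq practice: at least 500 genes and
#' under 5% mitochondrial/ribosomal content.
#'
#' @param mat an [expression_matrix()] of raw counts.
#' @param min_genes minimum number of expressed genes per cell.
#' @param max_flagged_fraction maximum flagged-gene fraction of total UMIs.
#' @param flagged_genes character set of flagged gene symbols.
#' @return The filtered [expression_matrix()] (warning when no cell
#'   survives).
#' @export
qc_filter <- function(mat, min_genes = 500, max_flagged_fraction = 0.05,
                      flagged_genes = character()) {
  stopifnot(inherits(mat, "expression_matrix"))
  bad <- setdiff(flagged_genes, rownames(mat$values))
  if (length(bad)) stop("flagged genes absent from the matrix: ",
                        paste(bad, collapse = ", "))
  n_genes <- colSums(mat$values > 0)
  totals <- colSums(mat$values)
  flagged <- if (length(flagged_genes)) {
    colSums(mat$values[flagged_genes, , drop = FALSE])
  } else rep(0, ncol(mat$values))
  frac <- ifelse(totals > 0, flagged / totals, 0)
  keep <- n_genes >= min_genes & frac < max_flagged_fraction
  if (!any(keep)) warning("all cells removed by QC filtering")
  subset_cells(mat, keep)
}

#' Depth-normalize and log-transform counts
#'
#' Per cell: `value' = log(1 + scale * value / cell_total)` (natural log by
#' default, the usual log1p normalization). Cells with zero total stay all
#' zero.
#'
#' @param mat an [expression_matrix()] of raw counts.
#' @param scale library-size scale factor (default 1e4).
#' @param base logarithm base (default natural).
#' @return The normalized [expression_matrix()].
#' @export
normalize_log <- function(mat, scale = 1e4, base = exp(1)) {
  stopifnot(inherits(mat, "expression_matrix"))
  totals <- colSums(mat$values)
  denom <- ifelse(totals > 0, totals, 1)
  v <- log1p(sweep(mat$values, 2, scale / denom, `*`)) / log(base)
  expression_matrix(v, mat$condition, mat$cell_type)
}

#' Per-cell-type differential expression between two conditions
#'
#' For every gene, the effect size is the difference in mean log-normalized
#' expression (case minus control), converted to log2 units, and the p-value
#' comes from a two-sided Welch t-test on the per-cell values. A small
#' epsilon (1e-9) is added to the squared standard error so genes with zero
#' variance in both groups yield a finite statistic.
#'
#' @param mat a log-normalized [expression_matrix()].
#' @param cell_type the cell type to test.
#' @param control_label,case_label condition labels (defaults `"CTL"`,
#'   `"ASD"`).
#' @param log_base base of the logarithm the matrix values are on; effect
#'   sizes are rescaled to log2. Default natural log, matching
#'   [normalize_log()].
#' @return A data frame of class `deg_table`: columns `gene`, `cell_type`,
#'   `log2fc`, `p`, and `direction` (all 0 until [call_degs()] is applied).
#' @export
differential_expression <- function(mat, cell_type,
                                    control_label = "CTL",
                                    case_label = "ASD",
                                    log_base = exp(1)) {
  stopifnot(inherits(mat, "expression_matrix"))
  sel <- mat$cell_type == cell_type
  ctl <- mat$values[, sel & mat$condition == control_label, drop = FALSE]
  cas <- mat$values[, sel & mat$condition == case_label, drop = FALSE]
  if (ncol(ctl) < 2 || ncol(cas) < 2) {
    stop(sprintf("cell type '%s': need >= 2 cells per condition (%d control, %d case)",
                 cell_type, ncol(ctl), ncol(cas)))
  }
  n1 <- ncol(cas); n0 <- ncol(ctl)
  m1 <- rowMeans(cas); m0 <- rowMeans(ctl)
  v1 <- apply(cas, 1, stats::var); v0 <- apply(ctl, 1, stats::var)
  se2 <- v1 / n1 + v0 / n0 + 1e-9
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)) + 1e-300)
  df <- pmin(pmax(df, 1), n1 + n0 - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  log2fc <- (m1 - m0) / log(2, base = log_base)
  structure(data.frame(gene = rownames(mat$values),
                       cell_type = cell_type,
                       log2fc = log2fc, p = p, direction = 0L,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"))
}

#' Call differentially expressed genes at fold-change and p-value thresholds
#'
#' A gene is a DEG when `|log2fc| > fc_threshold` and `p < p_threshold`
#' (both strict); its `direction` is then the sign of `log2fc`, otherwise 0.
#' An optional Benjamini-Hochberg correction is available but off by
#' default: the pipeline filters on raw p-values.
#'
#' @param records a `deg_table` from [differential_expression()].
#' @param fc_threshold absolute log2 fold-change threshold (default 0.3).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg to `p` before thresholding.
#' @return The `deg_table` with `direction` filled in.
#' @export
call_degs <- function(records, fc_threshold = 0.3, p_threshold = 0.05,
                      adjust = FALSE) {
  p <- if (adjust) stats::p.adjust(records$p, method = "BH") else records$p
  hit <- abs(records$log2fc) > fc_threshold & p < p_threshold
  records$direction <- ifelse(hit, sign(records$log2fc), 0L)
  records
}

#' Discretize DEG calls into a node measurement for causal reasoning
#'
#' Maps DEG directions onto the nodes of a network: +1/-1 for network genes
#' called up-/down-regulated, 0 for everything else (including genes absent
#' from the DEG table). DEGs for genes outside the network are ignored.
#'
#' @param degs a `deg_table` with `direction` filled in (see [call_degs()]).
#' @param nodes character set of network node symbols.
#' @return A named integer vector over `nodes` with values in \{-1, 0, 1\},
#'   carrying the cell type as attribute `cell_type` when unique.
#' @export
discretize_measurements <- function(degs, nodes) {
  m <- stats::setNames(integer(length(nodes)), nodes)
  hits <- degs[degs$direction != 0 & degs$gene %in% nodes, , drop = FALSE]
  m[hits$gene] <- as.integer(hits$direction)
  ct <- unique(degs$cell_type)
  if (length(ct) == 1) attr(m, "cell_type") <- ct
  m
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mid-ranks for ties; the exact distribution for small untied samples and
#' the normal approximation (with continuity correction) otherwise, as in
#' [stats::wilcox.test()]. Degenerate input where every value in both groups
#' is identical returns p = 1.
#'
#' @param a,b non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
wilcoxon_two_group <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}

#' Write / read a DEG table as TSV
#'
#' @param degs a `deg_table`.
#' @param file output path.
#' @return `read_deg_table` returns a `deg_table`.
#' @export
write_deg_table <- function(degs, file) {
  utils::write.table(degs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  structure(d, class = c("deg_table", "data.frame"))
}
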