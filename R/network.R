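#' Signed directed networks
#'
#' A `signed_network` is the basic container used throughout sirenet: a
#' directed graph whose edges carry a sign, +1 for activation and -1 for
#' inhibition. It represents both prior-knowledge networks (PKNs) of signed
#' regulatory interactions and the mRNA signaling-regulatory networks
#' (mSiReNs) derived from them.
#'
#' @param nodes character vector of node identifiers (HGNC-style gene or
#'   protein symbols). Nodes referenced by `edges` are added automatically.
#' @param edges a data frame with columns `from`, `to` and `sign`
#'   (each sign exactly +1 or -1), or `NULL` for an edgeless network.
#'
#' @return An object of class `signed_network`: a list with elements
#'   `nodes` (sorted character vector) and `edges` (data frame with columns
#'   `from`, `to`, `sign`, sorted by from/to/sign, no duplicate rows).
#'
#' @details Self-loops are permitted; duplicate `(from, to, sign)` triples
#'   are collapsed. A pair of nodes connected by both an activating and an
#'   inhibiting edge is legal (curated networks occasionally record
#'   context-dependent dual regulation) but triggers a warning.
#'
#' @examples
#' net <- signed_network(
#'   edges = data.frame(from = "MAPK1", to = "MKNK1", sign = 1)
#' )
#' network_stats(net)
#' @export
signed_network <- function(nodes = character(), edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("from", "to", "sign")
  if (!all(required %in% names(edges))) {
    stop("edges must have columns 'from', 'to' and 'sign'")
  }
  edges <- edges[required]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be exactly +1 or -1")
  }
  edges <- unique(edges)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (nrow(edges)) {
    edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
    pair <- paste(edges$from, edges$to, sep = "\r")
    dual <- unique(pair[duplicated(pair)])
    if (length(dual)) {
      warning("dual-sign edge pair(s): ",
              paste(gsub("\r", " -> ", dual), collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "signed_network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
    s$n_nodes, s$n_edges, s$n_activating, s$n_inhibiting))
  invisible(x)
}

# canonical "from|to|sign" key, used for set operations on edges
edge_key <- function(edges) {
  paste(edges$from, edges$to, edges$sign, sep = "\r")
}

#' Test two signed networks for equality
#'
#' Equality of node sets and edge sets, ignoring order.
#'
#' @param a,b `signed_network` objects.
#' @return `TRUE` or `FALSE`.
#' @export
networks_equal <- function(a, b) {
  setequal(a$nodes, b$nodes) && setequal(edge_key(a$edges), edge_key(b$edges))
}

#' Parse a signed-network SIF document
#'
#' Reads the 3-column signed SIF dialect used by CARNIVAL/CellNOptR-style
#' tools: each non-empty, non-comment line is `source  relation  target`,
#' whitespace- or tab-separated, with relation one of `1`, `-1`,
#' `activates`, `inhibits`. Isolated nodes may be listed one per line after
#' a `#nodes:` marker (the dialect [write_sif()] emits).
#'
#' @param text a character vector of lines, a single string with embedded
#'   newlines, or a connection/file path via `file`.
#' @param file path to a SIF file; used when `text` is missing.
#' @return A [signed_network()].
#' @export
parse_sif <- function(text, file = NULL) {
  if (missing(text)) {
    if (is.null(file)) stop("either 'text' or 'file' must be given")
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  iso <- character()
  edges <- list()
  in_nodes <- FALSE
  for (i in seq_along(text)) {
    line <- trimws(text[[i]])
    if (!nzchar(line)) next
    if (grepl("^#nodes:", line)) { in_nodes <- TRUE; next }
    if (startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (in_nodes) {
      if (length(fields) != 1) {
        stop(sprintf("line %d: expected a single node id in the #nodes: section", i))
      }
      iso <- c(iso, fields)
      next
    }
    if (length(fields) != 3) {
      stop(sprintf("line %d: expected 3 fields, found %d", i, length(fields)))
    }
    sgn <- switch(fields[2],
                  "1" = 1L, "+1" = 1L, "activates" = 1L,
                  "-1" = -1L, "inhibits" = -1L,
                  stop(sprintf("line %d: unknown relation token '%s'", i, fields[2])))
    edges[[length(edges) + 1L]] <- data.frame(
      from = fields[1], to = fields[3], sign = sgn, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  signed_network(nodes = iso, edges = edges)
}

#' Serialize a signed network to SIF text
#'
#' Writes the dialect accepted by [parse_sif()]: one `source  sign  target`
#' line per edge (tab-separated, signs as `1`/`-1`), edges in sorted order.
#' Because plain SIF cannot express isolated nodes, any node without an
#' incident edge is appended under a trailing `#nodes:` comment block so
#' that the round trip is lossless.
#'
#' @param network a [signed_network()].
#' @param file optional path; when given the text is also written there.
#' @return The SIF document as a single string (invisibly when `file` is
#'   given).
#' @export
write_sif <- function(network, file = NULL) {
  stopifnot(inherits(network, "signed_network"))
  e <- network$edges
  lines <- if (nrow(e)) paste(e$from, e$sign, e$to, sep = "\t") else character()
  iso <- setdiff(network$nodes, c(e$from, e$to))
  if (length(iso)) lines <- c(lines, "#nodes:", sort(iso))
  text <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", text), file)
    return(invisible(text))
  }
  text
}

#' Summary counts for a signed network
#'
#' @param network a [signed_network()].
#' @return A list of class `network_stats` with `n_nodes`, `n_edges`,
#'   `n_activating` and `n_inhibiting` (`n_edges = n_activating +
#'   n_inhibiting`).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  structure(list(
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    n_activating = sum(network$edges$sign == 1L),
    n_inhibiting = sum(network$edges$sign == -1L)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d  (+): %d  (-): %d\n",
              x$n_nodes, x$n_edges, x$n_activating, x$n_inhibiting))
  invisible(x)
}

# igraph view of a signed network (edge attribute "sign")
as_igraph_signed <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = TRUE, vertices = network$nodes)
}

#' Induced subgraph of a signed network
#'
#' Keeps the given nodes and every edge whose two endpoints both survive.
#'
#' @param network a [signed_network()].
#' @param keep character vector of node ids to retain.
#' @return A [signed_network()].
#' @export
induced_subnetwork <- function(network, keep) {
  keep <- intersect(network$nodes, keep)
  e <- network$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  suppressWarnings(signed_network(nodes = keep, edges = e))
}
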