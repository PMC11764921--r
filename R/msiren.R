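#' Building an mRNA signaling-regulatory network (mSiReN)
#'
#' A curated protein signal-transduction network speaks in terms of proteins,
#' complexes and protein families, while transcriptomic data quantify mRNAs.
#' The functions in this file translate the protein network to the gene level
#' in three offline steps, each driven by a user-supplied table snapshot
#' (no live database access): (1) expand protein/complex/family nodes to the
#' genes encoding their members; (2) keep only genes annotated to the
#' signaling pathways of interest; (3) restrict to gene-gene interactions
#' documented in an RNA-interaction table, pruned to nodes that lie on a
#' directed path from an input node to a terminal node.
#'
#' @name msiren
NULL

default_initial_nodes <- function() {
  c("BDNF", "IGF1", "HRAS", "NRAS", "KRAS", "PIK3CA", "PIK3CG", "CAMK2A")
}
default_final_nodes <- function() "EIF4E"

#' Describe the protein/complex nodes of a signal network
#'
#' @param label character vector of node labels as used in the network.
#' @param kind one of `"protein"`, `"complex"`, `"family"` per node
#'   (recycled). A `protein` node must map to exactly one gene.
#' @return A data frame of class `protein_nodes`.
#' @export
protein_nodes <- function(label, kind = "protein") {
  kind <- rep_len(kind, length(label))
  if (!all(kind %in% c("protein", "complex", "family"))) {
    stop("kind must be 'protein', 'complex' or 'family'")
  }
  structure(data.frame(label = as.character(label), kind = kind,
                       stringsAsFactors = FALSE),
            class = c("protein_nodes", "data.frame"))
}

#' Read a protein-to-gene mapping table
#'
#' TSV with header columns `label`, `gene` and optionally `source_db`;
#' one row per (protein label, member gene) pair.
#'
#' @param file path to the TSV file.
#' @return A data frame with columns `label`, `gene`, `source_db`.
#' @export
read_mapping_table <- function(file) {
  m <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("label", "gene") %in% names(m))) {
    stop("mapping table needs columns 'label' and 'gene'")
  }
  if (is.null(m$source_db)) m$source_db <- NA_character_
  if (anyDuplicated(m[c("label", "gene")])) {
    stop("mapping table contains duplicate (label, gene) pairs")
  }
  m
}

#' Read a gene-to-pathway annotation table
#'
#' TSV with header columns `gene` and `pathway`.
#'
#' @param file path to the TSV file.
#' @return A data frame with columns `gene`, `pathway`.
#' @export
read_annotation_table <- function(file) {
  a <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(a))) {
    stop("annotation table needs columns 'gene' and 'pathway'")
  }
  if (any(!nzchar(a$pathway))) stop("empty pathway names in annotation table")
  a
}

#' Read a signed RNA/gene interaction table
#'
#' TSV with header columns `source`, `target`, `sign` (+1/-1) and optionally
#' `source_db`.
#'
#' @param file path to the TSV file.
#' @return A data frame with columns `source`, `target`, `sign`, `source_db`.
#' @export
read_interaction_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(x))) {
    stop("interaction table needs columns 'source', 'target' and 'sign'")
  }
  x$sign <- as.integer(x$sign)
  if (!all(x$sign %in% c(-1L, 1L))) stop("interaction signs must be +1 or -1")
  if (is.null(x$source_db)) x$source_db <- NA_character_
  x
}

#' Expand protein/complex nodes to gene-level nodes
#'
#' Each node of the protein network is replaced by the gene(s) the mapping
#' table assigns to its label; every incident edge is inherited, with its
#' original sign, by every mapped gene. A complex or family with no mapped
#' member is dropped together with its incident edges (the treatment a
#' non-matching complex such as TSC1/2 receives), whereas an unmapped
#' `protein` node is an error unless listed in `droppable`.
#'
#' @param signal_net a [signed_network()] over protein-node labels.
#' @param nodes a [protein_nodes()] table covering every network node.
#' @param mapping a mapping table as from [read_mapping_table()].
#' @param droppable labels that may be silently dropped when unmapped even
#'   if declared `protein`.
#' @return A [signed_network()] over gene symbols.
#' @export
expand_protein_nodes <- function(signal_net, nodes, mapping,
                                 droppable = character()) {
  stopifnot(inherits(signal_net, "signed_network"))
  missing_decl <- setdiff(signal_net$nodes, nodes$label)
  if (length(missing_decl)) {
    stop("network node(s) absent from the node table: ",
         paste(missing_decl, collapse = ", "))
  }
  genes_of <- split(mapping$gene, mapping$label)
  kind_of <- stats::setNames(nodes$kind, nodes$label)
  unmapped <- signal_net$nodes[!signal_net$nodes %in% names(genes_of)]
  hard <- unmapped[kind_of[unmapped] == "protein" & !unmapped %in% droppable]
  if (length(hard)) {
    stop("unmapped protein node(s): ", paste(hard, collapse = ", "))
  }
  expand <- function(lab) genes_of[[lab]] # NULL when dropped
  e <- signal_net$edges
  out <- list()
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      src <- expand(e$from[i]); tgt <- expand(e$to[i])
      if (is.null(src) || is.null(tgt)) next
      out[[length(out) + 1L]] <- expand.grid(
        from = src, to = tgt, stringsAsFactors = FALSE)
      out[[length(out)]]$sign <- e$sign[i]
    }
  }
  kept_nodes <- unlist(genes_of[intersect(signal_net$nodes, names(genes_of))],
                       use.names = FALSE)
  edges <- if (length(out)) unique(do.call(rbind, out)) else NULL
  signed_network(nodes = kept_nodes, edges = edges)
}

#' Filter a gene network by pathway annotation
#'
#' Keeps nodes annotated to at least one selected pathway, plus an explicit
#' whitelist (typically the designated input and terminal nodes), and the
#' edges whose both endpoints survive.
#'
#' @param net a [signed_network()] over gene symbols.
#' @param annot annotation table as from [read_annotation_table()].
#' @param pathways non-empty character vector of pathway names to keep.
#' @param whitelist nodes kept regardless of annotation.
#' @return A [signed_network()].
#' @export
filter_by_pathway_annotation <- function(net, annot, pathways,
                                         whitelist = character()) {
  stopifnot(inherits(net, "signed_network"))
  if (!length(pathways)) stop("selected pathway set must be non-empty")
  annotated <- unique(annot$gene[annot$pathway %in% pathways])
  induced_subnetwork(net, union(annotated, whitelist))
}

#' Assemble gene-level edges from an interaction table, pruned to
#' input-to-terminal paths
#'
#' Retains interaction rows with both endpoints in `genes`, then prunes to
#' the nodes lying on at least one directed path from an initial node to a
#' final node (the intersection of the set reachable from the initial nodes
#' with the set that can reach the final nodes). Initial and final nodes
#' themselves are retained only when they lie on such a path (an initial
#' node that is also final always does).
#'
#' @param genes character set of gene nodes.
#' @param interactions interaction table as from [read_interaction_table()].
#' @param initial,final character subsets of `genes`; defaults follow the
#'   postsynaptic translation-control convention (growth-factor/RAS/PI3K/
#'   CAMK2 inputs, EIF4E terminal).
#' @return A [signed_network()]; empty (with a warning) when no
#'   initial-to-final path exists.
#' @export
infer_rna_edges <- function(genes, interactions,
                            initial = default_initial_nodes(),
                            final = default_final_nodes()) {
  initial <- intersect(initial, genes)
  final <- intersect(final, genes)
  if (!length(initial) || !length(final)) {
    warning("no initial/final nodes present in the gene set")
    return(signed_network())
  }
  rows <- interactions[interactions$source %in% genes &
                         interactions$target %in% genes, , drop = FALSE]
  net <- signed_network(
    nodes = genes,
    edges = if (nrow(rows)) {
      data.frame(from = rows$source, to = rows$target, sign = rows$sign,
                 stringsAsFactors = FALSE)
    } else NULL)
  g <- as_igraph_signed(net)
  fwd <- unique(unlist(lapply(initial, function(v)
    names(igraph::subcomponent(g, v, mode = "out")))))
  bwd <- unique(unlist(lapply(final, function(v)
    names(igraph::subcomponent(g, v, mode = "in")))))
  on_path <- intersect(fwd, bwd)
  if (!length(on_path)) {
    warning("no directed path from any initial node to any final node")
    return(signed_network())
  }
  suppressWarnings(induced_subnetwork(net, on_path))
}

#' Run the full protein-to-mRNA network construction pipeline
#'
#' Convenience wrapper chaining [expand_protein_nodes()],
#' [filter_by_pathway_annotation()] and [infer_rna_edges()]. Pathway
#' filtering is applied before interaction matching, following the order of
#' the three construction steps.
#'
#' @inheritParams expand_protein_nodes
#' @inheritParams filter_by_pathway_annotation
#' @inheritParams infer_rna_edges
#' @param annot,pathways passed to [filter_by_pathway_annotation()];
#'   `pathways = NULL` skips the annotation filter.
#' @param interactions passed to [infer_rna_edges()].
#' @return A [signed_network()] over gene symbols: the mSiReN.
#' @export
build_msiren <- function(signal_net, nodes, mapping, interactions,
                         annot = NULL, pathways = NULL,
                         initial = default_initial_nodes(),
                         final = default_final_nodes(),
                         droppable = character()) {
  gene_net <- expand_protein_nodes(signal_net, nodes, mapping, droppable)
  if (!is.null(pathways)) {
    gene_net <- filter_by_pathway_annotation(
      gene_net, annot, pathways, whitelist = union(initial, final))
  }
  infer_rna_edges(gene_net$nodes, interactions, initial = initial,
                  final = final)
}
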