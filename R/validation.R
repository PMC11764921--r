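#' Edge-reliability validation against protein-interaction evidence
#'
#' Network edges derived from RNA-level reasoning can be cross-checked
#' against protein-protein interaction evidence of the STRING kind: per gene
#' pair, independent evidence channels (coexpression, experiments, curated
#' databases, text mining) each give a score in [0,1), which are combined
#' into a single confidence after removing the prior probability of a random
#' pair interacting.
#'
#' @name validation
NULL

#' Combine STRING-style evidence-channel scores
#'
#' Each nonzero channel score s is first corrected for the prior p:
#' s' = max(0, (s - p) / (1 - p)). The corrected channels are combined as
#' independent evidence (noisy-OR): c' = 1 - prod(1 - s'). The prior is then
#' restored, c = c' + p (1 - c'), and the result capped at `cap`.
#' Homology-corrected channels are not supported: a nonzero homology score
#' requires using the published combined score directly.
#'
#' @param channels named numeric vector in [0,1) with any of the names
#'   `homology`, `coexpression`, `experimental`, `database`, `textmining`
#'   (missing channels count as 0).
#' @param prior prior probability of interaction (default 0.041).
#' @param cap upper cap on the combined score (default 0.999).
#' @param digits rounding applied to the reported score (default 3; use
#'   `NA` for no rounding).
#' @return The combined score.
#' @examples
#' string_combined_score(c(coexpression = 0.063, textmining = 0.406))
#' @export
string_combined_score <- function(channels, prior = 0.041, cap = 0.999,
                                  digits = 3) {
  known <- c("homology", "coexpression", "experimental", "database",
             "textmining")
  if (length(channels) && is.null(names(channels))) {
    stop("channels must be a named vector")
  }
  bad <- setdiff(names(channels), known)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (any(channels < 0 | channels >= 1)) {
    stop("channel scores must lie in [0, 1)")
  }
  if (!is.na(channels["homology"]) && channels[["homology"]] > 0) {
    stop("nonzero homology channel is unsupported; use the printed combined score")
  }
  s <- channels[setdiff(names(channels), "homology")]
  s <- s[s > 0]
  corrected <- pmax(0, (s - prior) / (1 - prior))
  combined <- 1 - prod(1 - corrected)
  out <- min(cap, combined + prior * (1 - combined))
  if (!is.na(digits)) out <- round(out, digits) else out
}

#' Read a STRING-style per-channel score table
#'
#' TSV with header columns `node1`, `node2`, `homology`, `coexpression`,
#' `experimental`, `database`, `textmining`, `combined` (the packaged core
#' table uses these names).
#'
#' @param file path to the TSV.
#' @return A data frame.
#' @export
read_string_scores <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("node1", "node2", "combined")
  if (!all(need %in% names(x))) {
    stop("score table needs at least columns 'node1', 'node2', 'combined'")
  }
  x
}

undirected_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Validate network edges against interaction evidence
#'
#' Matches each network edge to a score row by undirected, sign-blind gene
#' pair (reliability concerns the existence of an interaction, not its
#' direction). For rows carrying channel columns and zero homology the
#' combined score is recomputed with [string_combined_score()]; otherwise
#' the printed `combined` value is used. Edges with score at or above the
#' threshold pass.
#'
#' @param net a [signed_network()].
#' @param scores a score table (see [read_string_scores()]); channel
#'   columns are optional.
#' @param threshold pass threshold on the combined score (default 0.9).
#' @param recompute recompute combined scores from channels where possible
#'   (default `TRUE`).
#' @param prior,cap passed to [string_combined_score()].
#' @return A list of class `reliability_report`: `edges` (data frame with
#'   `from`, `to`, `sign`, `combined`, `source` = recomputed/printed,
#'   `pass`), `unmatched_edges` (network edges with no score row),
#'   `unmatched_interactions` (score rows with no network edge),
#'   `threshold`, `n_pass`.
#' @export
validate_edge_reliability <- function(net, scores, threshold = 0.9,
                                      recompute = TRUE, prior = 0.041,
                                      cap = 0.999) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  has_channels <- all(c("coexpression", "experimental", "database",
                        "textmining") %in% names(scores))
  score_key <- undirected_key(scores$node1, scores$node2)
  combined_of <- function(i) {
    if (recompute && has_channels &&
        (is.null(scores$homology) || scores$homology[i] == 0)) {
      ch <- c(coexpression = scores$coexpression[i],
              experimental = scores$experimental[i],
              database = scores$database[i],
              textmining = scores$textmining[i])
      c(string_combined_score(ch, prior = prior, cap = cap), "recomputed")
    } else {
      c(scores$combined[i], "printed")
    }
  }
  if (nrow(e)) {
    ekey <- undirected_key(e$from, e$to)
    idx <- match(ekey, score_key)
    got <- !is.na(idx)
    comb <- rep(NA_real_, nrow(e)); src <- rep(NA_character_, nrow(e))
    for (i in which(got)) {
      cs <- combined_of(idx[i])
      comb[i] <- as.numeric(cs[1]); src[i] <- cs[2]
    }
    edges <- data.frame(e, combined = comb, source = src,
                        pass = !is.na(comb) & comb >= threshold,
                        stringsAsFactors = FALSE)
    unmatched_edges <- e[!got, , drop = FALSE]
    matched_rows <- unique(idx[got])
  } else {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), combined = numeric(),
                        source = character(), pass = logical())
    unmatched_edges <- e
    matched_rows <- integer()
  }
  unmatched_interactions <-
    scores[setdiff(seq_len(nrow(scores)), matched_rows), , drop = FALSE]
  structure(list(edges = edges, unmatched_edges = unmatched_edges,
                 unmatched_interactions = unmatched_interactions,
                 threshold = threshold, n_pass = sum(edges$pass)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("reliability_report: %d/%d edges pass at threshold %.2f\n",
              x$n_pass, nrow(x$edges), x$threshold))
  if (nrow(x$unmatched_edges)) {
    cat("  edges without evidence:", nrow(x$unmatched_edges), "\n")
  }
  if (nrow(x$unmatched_interactions)) {
    cat("  interactions outside the network:",
        nrow(x$unmatched_interactions), "\n")
  }
  invisible(x)
}
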