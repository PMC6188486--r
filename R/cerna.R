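#' Build the dysregulated circRNA-related ceRNA network (DCCN)
#'
#' Scores every circRNA-mRNA pair of the tripartite network that shares at
#' least one miRNA (pairs with no shared miRNA have tail probability 1 by
#' construction and are not enumerated) with the hypergeometric shared-miRNA
#' test ([hypergeomPValue()]): with a universe of `m` miRNAs, `t` miRNAs
#' predicted to target the mRNA, `n` the circRNA, and `r` shared, the pair is
#' a competing pair when `P(X >= r) < alpha` (strict). Pairs passing the
#' cutoff form the bipartite DCCN; the full score table, including a
#' Benjamini-Hochberg FDR column computed across all tested pairs (reported
#' for reference, not used for the default cutoff), is retained.
#'
#' The universe size defaults to the number of distinct miRNAs in the
#' unfiltered interaction set when one is supplied, falls back to the miRNA
#' count of the tripartite network itself, and can be overridden with an
#' explicit integer (e.g. a genome-wide miRNA count).
#'
#' @param network a [TripleNetwork-class].
#' @param universe `NULL` (auto, as above) or an explicit integer universe
#'   size.
#' @param interactions optional unfiltered interaction data.frame used to
#'   derive the default universe.
#' @param alpha significance cutoff on the raw p-value (default 0.05, strict).
#' @return a [CeRNANetwork-class].
#' @export
buildDCCN <- function(network, universe = NULL, interactions = NULL,
                      alpha = 0.05) {
  stopifnot(is(network, "TripleNetwork"))
  ed <- edgeTable(network)
  nd <- nodeTable(network)

  if (is.null(universe)) {
    m <- if (!is.null(interactions)) length(unique(interactions$mirna_id))
         else length(unique(ed$mirna_id))
  } else {
    m <- as.integer(universe)
    if (length(m) != 1L || is.na(m) || m < 1L)
      stop("universe must be a single positive integer")
  }

  emptyPairs <- data.frame(
    circ_id = character(), mrna_id = character(), m = integer(),
    t = integer(), n = integer(), r = integer(), p_value = numeric(),
    fdr = numeric(), shared_ids = character(), significant = logical(),
    stringsAsFactors = FALSE
  )
  if (!nrow(ed)) {
    return(new("CeRNANetwork", pairs = emptyPairs, nodes = emptyNodes(),
               alpha = alpha, universeSize = as.integer(m)))
  }

  mirByMrna <- split(ed$mirna_id[ed$target_class == "mRNA"],
                     ed$target_id[ed$target_class == "mRNA"])
  mirByCirc <- split(ed$mirna_id[ed$target_class == "circRNA"],
                     ed$target_id[ed$target_class == "circRNA"])

  # enumerate only pairs with r >= 1, via the miRNAs they share
  circOfMir <- split(ed$target_id[ed$target_class == "circRNA"],
                     ed$mirna_id[ed$target_class == "circRNA"])
  mrnaOfMir <- split(ed$target_id[ed$target_class == "mRNA"],
                     ed$mirna_id[ed$target_class == "mRNA"])
  pairKeys <- unique(do.call(rbind, lapply(names(circOfMir), function(mir) {
    expand.grid(circ_id = circOfMir[[mir]], mrna_id = mrnaOfMir[[mir]],
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })))
  if (is.null(pairKeys) || !nrow(pairKeys)) {
    return(new("CeRNANetwork", pairs = emptyPairs, nodes = emptyNodes(),
               alpha = alpha, universeSize = as.integer(m)))
  }
  pairKeys <- pairKeys[order(pairKeys$circ_id, pairKeys$mrna_id), ,
                       drop = FALSE]

  sharedList <- Map(function(c, g) intersect(mirByCirc[[c]], mirByMrna[[g]]),
                    pairKeys$circ_id, pairKeys$mrna_id)
  t <- lengths(mirByMrna[pairKeys$mrna_id])
  n <- lengths(mirByCirc[pairKeys$circ_id])
  r <- lengths(sharedList)
  if (any(t > m) || any(n > m)) {
    off <- which(t > m | n > m)[1]
    stop("universe (m = ", m, ") smaller than the interaction count of pair ",
         pairKeys$circ_id[off], " - ", pairKeys$mrna_id[off])
  }
  p <- hypergeomPValue(m, t, n, r)
  pairs <- data.frame(
    circ_id = pairKeys$circ_id, mrna_id = pairKeys$mrna_id,
    m = as.integer(m), t = as.integer(t), n = as.integer(n),
    r = as.integer(r), p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    shared_ids = vapply(sharedList, function(s) paste(sort(s), collapse = ";"),
                        character(1)),
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL

  sigIds <- unique(c(pairs$circ_id[pairs$significant],
                     pairs$mrna_id[pairs$significant]))
  nodes <- nd[nd$node_id %in% sigIds, , drop = FALSE]
  rownames(nodes) <- NULL
  new("CeRNANetwork", pairs = pairs, nodes = nodes, alpha = alpha,
      universeSize = as.integer(m))
}

#' @describeIn asIgraph bipartite graph of the significant competing pairs.
#' @export
setMethod("asIgraph", "CeRNANetwork", function(x) {
  sig <- x@pairs[x@pairs$significant, , drop = FALSE]
  if (!nrow(sig)) return(igraph::make_empty_graph(0, directed = FALSE))
  nd <- x@nodes
  igraph::graph_from_data_frame(
    sig[c("circ_id", "mrna_id")], directed = FALSE,
    vertices = data.frame(name = nd$node_id, class = nd$node_class,
                          status = nd$status, stringsAsFactors = FALSE)
  )
})

#' @rdname writeSIF
#' @export
setMethod("writeSIF", "CeRNANetwork", function(x, path) {
  sig <- x@pairs[x@pairs$significant, , drop = FALSE]
  out <- data.frame(a = sig$circ_id,
                    rel = rep("circRNA-mRNA", nrow(sig)), b = sig$mrna_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
})

#' Write the full competing-pair score table as TSV
#'
#' @param x a [CeRNANetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(x, path) {
  stopifnot(is(x, "CeRNANetwork"))
  utils::write.table(x@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
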