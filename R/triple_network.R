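#' Construct a TripleNetwork from edge and node tables
#'
#' Low-level constructor (used when deserializing); [buildTripleNetwork()] is
#' the standard entry point. Validity enforces the both-classes rule: every
#' miRNA node must retain at least one circRNA edge and one mRNA edge.
#'
#' @param edges data.frame `mirna_id`, `target_id`, `target_class`.
#' @param nodes data.frame `node_id`, `node_class`, `status`.
#' @return a [TripleNetwork-class].
#' @export
tripleNetwork <- function(edges, nodes) {
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  new("TripleNetwork", edges = edges, nodes = nodes)
}

emptyTripleEdges <- function() {
  data.frame(mirna_id = character(), target_id = character(),
             target_class = character(), stringsAsFactors = FALSE)
}

emptyNodes <- function() {
  data.frame(node_id = character(), node_class = character(),
             status = character(), stringsAsFactors = FALSE)
}

#' Build the DE circRNA-miRNA-mRNA tripartite network
#'
#' Restricts the interaction set to differentially expressed features, then
#' keeps only miRNAs predicted to pair with at least one DE circRNA *and* at
#' least one DE mRNA (the ceRNA prerequisite: a miRNA can only mediate
#' competition if it touches both classes), and finally drops targets orphaned
#' by that pruning. Dropping a miRNA can only orphan targets, and orphan
#' removal cannot take away a surviving miRNA's last partner of either class,
#' so a single pass of each step reaches the fixed point.
#'
#' @param deRecords annotated DE table from [filterDE()] (or an equivalent
#'   data.frame with `feature_id`, `feature_class`, `status`).
#' @param interactions filtered interaction data.frame
#'   (see [loadInteractions()]).
#' @return a [TripleNetwork-class]; empty (with a warning) if no interaction
#'   survives the DE restriction.
#' @export
buildTripleNetwork <- function(deRecords, interactions) {
  stopifnot(all(c("feature_id", "feature_class", "status") %in%
                  names(deRecords)))
  sig <- deRecords[deRecords$status %in% c("UP", "DOWN"), , drop = FALSE]
  deBy <- split(sig$feature_id, sig$feature_class)
  status <- stats::setNames(sig$status, sig$feature_id)

  ed <- interactions
  ed <- ed[ed$mirna_id %in% deBy$miRNA, , drop = FALSE]
  keepTarget <- (ed$target_class == "mRNA" & ed$target_id %in% deBy$mRNA) |
    (ed$target_class == "circRNA" & ed$target_id %in% deBy$circRNA)
  ed <- ed[keepTarget, , drop = FALSE]

  if (nrow(ed)) {
    byMir <- split(ed$target_class, ed$mirna_id)
    both <- names(byMir)[vapply(byMir, function(cl)
      all(c("mRNA", "circRNA") %in% cl), logical(1))]
    ed <- ed[ed$mirna_id %in% both, , drop = FALSE]
  }
  if (!nrow(ed)) {
    warning("no interactions connect the DE sets; returning an empty network")
    return(tripleNetwork(emptyTripleEdges(), emptyNodes()))
  }
  ed <- ed[c("mirna_id", "target_id", "target_class")]
  nodeIds <- c(unique(ed$mirna_id), unique(ed$target_id))
  nodeCls <- c(rep("miRNA", length(unique(ed$mirna_id))),
               ed$target_class[match(unique(ed$target_id), ed$target_id)])
  nodes <- data.frame(node_id = nodeIds, node_class = nodeCls,
                      status = unname(status[nodeIds]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node_class, nodes$node_id), ]
  ed <- ed[order(ed$mirna_id, ed$target_id), ]
  tripleNetwork(ed, nodes)
}

#' Extract the subnetwork anchored on a set of mRNAs
#'
#' Two-hop expansion: the given mRNAs, every miRNA linked to them, and every
#' circRNA linked to those miRNAs; the both-classes rule is then re-enforced
#' (a miRNA with no remaining circRNA partner is dropped along with targets it
#' alone supported).
#'
#' @param network a [TripleNetwork-class].
#' @param mrnaSubset mRNA node ids to anchor on; unknown ids are ignored with
#'   a warning.
#' @return the induced [TripleNetwork-class] (possibly empty).
#' @export
extractClassSubnetwork <- function(network, mrnaSubset) {
  stopifnot(is(network, "TripleNetwork"))
  nd <- nodeTable(network)
  ed <- edgeTable(network)
  known <- mrnaSubset %in% nd$node_id[nd$node_class == "mRNA"]
  if (any(!known))
    warning("ignoring unknown mRNA id(s): ",
            paste(mrnaSubset[!known], collapse = ", "))
  mrnas <- mrnaSubset[known]
  if (!length(mrnas)) {
    return(tripleNetwork(emptyTripleEdges(), emptyNodes()))
  }
  mirs <- unique(ed$mirna_id[ed$target_class == "mRNA" &
                               ed$target_id %in% mrnas])
  keep <- (ed$mirna_id %in% mirs) &
    (ed$target_class == "circRNA" | ed$target_id %in% mrnas)
  sub <- ed[keep, , drop = FALSE]
  if (nrow(sub)) {
    byMir <- split(sub$target_class, sub$mirna_id)
    both <- names(byMir)[vapply(byMir, function(cl)
      all(c("mRNA", "circRNA") %in% cl), logical(1))]
    sub <- sub[sub$mirna_id %in% both, , drop = FALSE]
  }
  if (!nrow(sub)) {
    return(tripleNetwork(emptyTripleEdges(), emptyNodes()))
  }
  ids <- unique(c(sub$mirna_id, sub$target_id))
  tripleNetwork(sub, nd[nd$node_id %in% ids, , drop = FALSE])
}

#' @describeIn asIgraph undirected graph with miRNA-target edges.
#' @export
setMethod("asIgraph", "TripleNetwork", function(x) {
  nd <- x@nodes
  if (!nrow(nd)) return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    x@edges[c("mirna_id", "target_id")], directed = FALSE,
    vertices = data.frame(name = nd$node_id, class = nd$node_class,
                          status = nd$status, stringsAsFactors = FALSE)
  )
})

#' @rdname writeSIF
#' @export
setMethod("writeSIF", "TripleNetwork", function(x, path) {
  ed <- x@edges
  out <- data.frame(a = ed$mirna_id,
                    rel = sprintf("miRNA-%s", ed$target_class),
                    b = ed$target_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
})

#' Write a network in GraphML format
#'
#' Node attributes `class` and `status` are carried over; the file loads into
#' Cytoscape or igraph.
#'
#' @param x a network object convertible with [asIgraph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(x, path) {
  g <- if (inherits(x, "igraph")) x else asIgraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
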