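#' Accessors for ceRNAnet objects
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x a ceRNAnet S4 object.
#' @return `nodeTable()` and `edgeTable()` return data.frames;
#'   `pairTable()` the full competing-pair score table; `hubIds()`,
#'   `moduleGenes()`, `plantedHub()` character vectors; `deFeatures()` and
#'   `plantedPairs()` data.frames; `asIgraph()` an [igraph::graph] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("hubIds", function(x) standardGeneric("hubIds"))

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setGeneric("deFeatures", function(x) standardGeneric("deFeatures"))

#' @rdname accessors
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname accessors
#' @export
setGeneric("plantedHub", function(x) standardGeneric("plantedHub"))

#' Convert a network object to an igraph graph
#'
#' Builds the simple undirected graph used for topology analysis. Node
#' attributes `class` (and `status` where known) are carried over.
#'
#' @param x a [TripleNetwork-class] or [CeRNANetwork-class] object.
#' @return an undirected [igraph::graph].
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Write a network in SIF format
#'
#' Simple interaction format (`node TAB relation TAB node`), loadable by
#' Cytoscape. Relations are `miRNA-circRNA` / `miRNA-mRNA` for a
#' [TripleNetwork-class] and `circRNA-mRNA` for a [CeRNANetwork-class] or
#' [HubModule-class].
#'
#' @param x a network object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
setGeneric("writeSIF", function(x, path) standardGeneric("writeSIF"))
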