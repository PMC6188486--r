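#' @rdname accessors
#' @export
setMethod("nodeTable", "TripleNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "TripleNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nodeTable", "CeRNANetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "CeRNANetwork",
          function(x) x@pairs[x@pairs$significant, , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("pairTable", "CeRNANetwork", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("hubIds", "HubModule", function(x) x@hubIds)

#' @rdname accessors
#' @export
setMethod("moduleGenes", "HubModule", function(x) x@mrnaIds)

#' @rdname accessors
#' @export
setMethod("nodeTable", "HubModule", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "HubModule", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("deFeatures", "GroundTruth", function(x) x@deFeatures)

#' @rdname accessors
#' @export
setMethod("plantedPairs", "GroundTruth", function(x) {
  cbind(x@plantedPairs,
        shared_mirnas = vapply(x@sharedMirnas, paste, character(1),
                               collapse = ";"))
})

#' @rdname accessors
#' @export
setMethod("plantedHub", "GroundTruth", function(x) x@hubCirc)

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:",
      object@nMrna, "mRNA /", object@nMirna, "miRNA /",
      object@nCirc, "circRNA;",
      object@nSamplesPerGroup, "vs", object@nSamplesPerGroup, "samples\n")
  cat(sprintf("  NB mean [%g, %g], dispersion %g; planted |log2FC| %g\n",
              object@nbMeanRange[1], object@nbMeanRange[2],
              object@nbDispersion, object@deLog2FC))
  cat(sprintf(
    "  %d planted pairs sharing %d miRNAs (hub carries %d); bg share p %g; seed %d\n",
    object@nPlantedPairs, object@sharedMirnasPerPair, object@hubPairs,
    object@backgroundShareProb, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@deFeatures$feature_class)
  cat("GroundTruth:", paste(tab, names(tab), collapse = ", "),
      "planted DE features;", nrow(object@plantedPairs),
      "planted pairs; hub", object@hubCirc, "\n")
})

setMethod("show", "TripleNetwork", function(object) {
  tab <- table(object@nodes$node_class)
  cat("TripleNetwork:",
      sum(object@nodes$node_class == "miRNA"), "miRNAs,",
      sum(object@nodes$node_class == "circRNA"), "circRNAs,",
      sum(object@nodes$node_class == "mRNA"), "mRNAs,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "CeRNANetwork", function(object) {
  sig <- object@pairs[object@pairs$significant, , drop = FALSE]
  cat("CeRNANetwork (DCCN):", nrow(sig), "edges between",
      length(unique(sig$mrna_id)), "mRNAs and",
      length(unique(sig$circ_id)), "circRNAs",
      sprintf("(tested %d pairs, m = %d, alpha = %g)\n",
              nrow(object@pairs), object@universeSize, object@alpha))
})

setMethod("show", "HubModule", function(object) {
  cat("HubModule:", length(object@hubIds), "hubs;",
      nrow(object@nodes), "nodes /", nrow(object@edges), "edges;",
      length(object@mrnaIds), "module mRNAs\n")
})
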