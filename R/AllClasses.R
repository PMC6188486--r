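#' @import methods
NULL

#' Configuration for the synthetic ceRNA study generator
#'
#' Bundles every tunable of the synthetic-data generator: dimensions of the
#' three RNA classes, the two-group design, the negative-binomial noise model,
#' the planted differential-expression signal and the planted competing-pair
#' structure. All randomness downstream of a `SynthConfig` is controlled by
#' its `seed`, so an identical configuration reproduces identical data.
#'
#' @slot nMrna,nMirna,nCirc number of features simulated per RNA class.
#' @slot nSamplesPerGroup samples per group (two groups: case, control).
#' @slot nbMeanRange length-2 numeric; baseline negative-binomial means are
#'   drawn log-uniformly between these bounds.
#' @slot nbDispersion negative-binomial dispersion; variance is
#'   `mu + mu^2 * dispersion`.
#' @slot fracDE named numeric of length 3 (`mRNA`, `miRNA`, `circRNA`):
#'   fraction of features per class with a planted expression shift.
#' @slot deLog2FC planted absolute log2 fold change (case over control);
#'   direction is split evenly up/down.
#' @slot nPlantedPairs number of planted competing circRNA-mRNA pairs.
#' @slot sharedMirnasPerPair exact number of miRNAs each planted pair shares.
#' @slot backgroundShareProb per-(miRNA, target) probability of a background
#'   interaction edge outside the planted structure.
#' @slot decoyFraction fraction of additional interaction records emitted with
#'   binding energy above -20 kcal/mol, exercising the energy filter.
#' @slot hubPairs number of planted pairs routed through a single hub circRNA.
#' @slot seed integer seed controlling all generator randomness.
#'
#' @seealso [synthConfig()] for the user-facing constructor with the default
#'   study conditions, [generateCounts()], [generateInteractions()],
#'   [generateGeneSets()].
#' @export
setClass("SynthConfig",
  representation(
    nMrna = "integer", nMirna = "integer", nCirc = "integer",
    nSamplesPerGroup = "integer",
    nbMeanRange = "numeric", nbDispersion = "numeric",
    fracDE = "numeric", deLog2FC = "numeric",
    nPlantedPairs = "integer", sharedMirnasPerPair = "integer",
    backgroundShareProb = "numeric", decoyFraction = "numeric",
    hubPairs = "integer", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  cnt <- c(
    nMrna = object@nMrna, nMirna = object@nMirna, nCirc = object@nCirc,
    nSamplesPerGroup = object@nSamplesPerGroup,
    nPlantedPairs = object@nPlantedPairs,
    sharedMirnasPerPair = object@sharedMirnasPerPair
  )
  if (any(cnt <= 0L)) {
    msg <- c(msg, paste0("counts must be positive: ",
                         paste(names(cnt)[cnt <= 0L], collapse = ", ")))
  }
  if (length(object@nbMeanRange) != 2L || any(object@nbMeanRange <= 0) ||
      object@nbMeanRange[1] > object@nbMeanRange[2])
    msg <- c(msg, "nbMeanRange must be two positive values (low, high)")
  if (object@nbDispersion <= 0)
    msg <- c(msg, "nbDispersion must be positive")
  if (!identical(sort(names(object@fracDE)),
                 sort(c("mRNA", "miRNA", "circRNA"))))
    msg <- c(msg, "fracDE must be named mRNA, miRNA, circRNA")
  if (any(object@fracDE < 0 | object@fracDE > 1))
    msg <- c(msg, "fracDE values must lie in [0, 1]")
  if (object@deLog2FC <= 0)
    msg <- c(msg, "deLog2FC must be positive")
  if (object@backgroundShareProb < 0 || object@backgroundShareProb > 1)
    msg <- c(msg, "backgroundShareProb must be a probability")
  if (object@decoyFraction < 0 || object@decoyFraction > 1)
    msg <- c(msg, "decoyFraction must be a probability")
  if (object@sharedMirnasPerPair > object@nMirna)
    msg <- c(msg, "sharedMirnasPerPair cannot exceed nMirna")
  if (object@hubPairs > object@nPlantedPairs)
    msg <- c(msg, "hubPairs cannot exceed nPlantedPairs")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic run
#'
#' Records what the generator planted so recovery can be scored: the
#' differentially expressed features per class with their direction, the
#' planted competing circRNA-mRNA pairs with their shared miRNA sets, and the
#' identity of the planted hub circRNA.
#'
#' @slot deFeatures data.frame with columns `feature_id`, `feature_class`,
#'   `direction` (`"UP"` or `"DOWN"`).
#' @slot plantedPairs data.frame with columns `circ_id`, `mrna_id`.
#' @slot sharedMirnas list of character vectors, parallel to `plantedPairs`
#'   rows: the miRNA ids each pair shares.
#' @slot hubCirc id of the circRNA carrying multiple planted pairs.
#'
#' @seealso [generateCounts()], [plantedPairs()], [deFeatures()],
#'   [plantedHub()]
#' @export
setClass("GroundTruth",
  representation(
    deFeatures = "data.frame",
    plantedPairs = "data.frame",
    sharedMirnas = "list",
    hubCirc = "character"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@plantedPairs) != length(object@sharedMirnas))
    msg <- c(msg, "sharedMirnas must be parallel to plantedPairs rows")
  de <- object@deFeatures
  circOK <- object@plantedPairs$circ_id %in%
    de$feature_id[de$feature_class == "circRNA"]
  mrnaOK <- object@plantedPairs$mrna_id %in%
    de$feature_id[de$feature_class == "mRNA"]
  if (!all(circOK) || !all(mrnaOK))
    msg <- c(msg, "planted pairs must reference planted-DE circRNAs and mRNAs")
  if (length(msg)) msg else TRUE
})

#' Tripartite circRNA-miRNA-mRNA regulatory network
#'
#' The network of predicted miRNA-target interactions restricted to
#' differentially expressed features, after pruning miRNAs that do not pair
#' with at least one DE circRNA *and* one DE mRNA (and the targets those
#' prunings orphan). Edges connect a miRNA to a circRNA or mRNA; there are no
#' circRNA-mRNA edges at this stage.
#'
#' @slot edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_class` (`"mRNA"` or `"circRNA"`).
#' @slot nodes data.frame with columns `node_id`, `node_class`
#'   (`"miRNA"`, `"mRNA"`, `"circRNA"`), `status` (`"UP"`/`"DOWN"`).
#'
#' @seealso [buildTripleNetwork()], [extractClassSubnetwork()], [buildDCCN()],
#'   [asIgraph()], [writeSIF()]
#' @export
setClass("TripleNetwork",
  representation(edges = "data.frame", nodes = "data.frame")
)

setValidity("TripleNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  nd <- object@nodes
  if (!all(c("mirna_id", "target_id", "target_class") %in% names(ed)))
    msg <- c(msg, "edges need mirna_id, target_id, target_class")
  if (!all(c("node_id", "node_class", "status") %in% names(nd)))
    msg <- c(msg, "nodes need node_id, node_class, status")
  if (length(msg)) return(msg)
  if (anyDuplicated(nd$node_id))
    msg <- c(msg, "duplicate node ids")
  if (!all(ed$mirna_id %in% nd$node_id[nd$node_class == "miRNA"]) ||
      !all(ed$target_id %in% nd$node_id[nd$node_class != "miRNA"]))
    msg <- c(msg, "edge endpoints must exist in the node table")
  if (nrow(ed)) {
    byMir <- split(ed$target_class, ed$mirna_id)
    both <- vapply(byMir, function(cl) all(c("mRNA", "circRNA") %in% cl),
                   logical(1))
    if (!all(both))
      msg <- c(msg, "every miRNA must have >=1 circRNA and >=1 mRNA edge")
  }
  if (length(msg)) msg else TRUE
})

#' Dysregulated circRNA-related ceRNA network (DCCN)
#'
#' The bipartite network of circRNA-mRNA competing pairs. Every circRNA-mRNA
#' pair sharing at least one miRNA is scored with the hypergeometric
#' shared-miRNA test; pairs below the significance cutoff form the edges.
#' The full score table (all tested pairs, including non-significant ones, a
#' Benjamini-Hochberg FDR column and the shared miRNA ids) is retained.
#'
#' @slot pairs data.frame with columns `circ_id`, `mrna_id`, `m`, `t`, `n`,
#'   `r`, `p_value`, `fdr`, `shared_ids` (semicolon-joined), `significant`.
#' @slot nodes data.frame of the circRNA/mRNA nodes appearing in significant
#'   pairs, with `node_id`, `node_class`, `status`.
#' @slot alpha significance cutoff applied to the raw p-value (strict `<`).
#' @slot universeSize the miRNA universe size `m` used by the test.
#'
#' @seealso [buildDCCN()], [hypergeomPValue()], [computeCentralities()],
#'   [pairTable()], [edgeTable()]
#' @export
setClass("CeRNANetwork",
  representation(
    pairs = "data.frame", nodes = "data.frame",
    alpha = "numeric", universeSize = "integer"
  )
)

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("circ_id", "mrna_id", "m", "t", "n", "r", "p_value", "fdr",
            "shared_ids", "significant")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("pairs table needs columns:",
                        paste(setdiff(need, names(p)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(p)) {
    if (any(p$r > pmin(p$t, p$n)) || any(p$t > p$m) || any(p$n > p$m))
      msg <- c(msg, "count constraints violated: need r <= min(t, n) <= m")
    if (any(p$p_value < 0 | p$p_value > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(p$significant & p$p_value >= object@alpha))
      msg <- c(msg, "significant pairs must have p < alpha")
  }
  if (length(msg)) msg else TRUE
})

#' Hub set and its neighborhood module
#'
#' The hubs are the nodes ranked in the top k simultaneously by degree,
#' betweenness and closeness; the module is the subgraph induced on the hubs
#' and all of their neighbors. The module's mRNA members are the gene list
#' used for functional enrichment.
#'
#' @slot hubIds ordered hub node ids (degree descending).
#' @slot nodes data.frame of module nodes (`node_id`, `node_class`).
#' @slot edges data.frame of module edges (`from`, `to`).
#' @slot mrnaIds mRNA ids contained in the module.
#'
#' @seealso [selectHubs()], [extractModule()], [enrichGeneSets()]
#' @export
setClass("HubModule",
  representation(
    hubIds = "character", nodes = "data.frame",
    edges = "data.frame", mrnaIds = "character"
  )
)

setValidity("HubModule", function(object) {
  msg <- character()
  if (!all(object@hubIds %in% object@nodes$node_id))
    msg <- c(msg, "hubs must be module nodes")
  if (nrow(object@edges)) {
    inNodes <- c(object@edges$from, object@edges$to) %in% object@nodes$node_id
    if (!all(inNodes)) msg <- c(msg, "module edges must join module nodes")
  }
  if (length(msg)) msg else TRUE
})
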