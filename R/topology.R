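asGraph <- function(x) {
  if (inherits(x, "igraph")) x else asIgraph(x)
}

#' Node centralities: degree, betweenness, closeness
#'
#' Computes the three indices used for hub ranking on the simple undirected
#' graph. Degree is the incident edge count. Betweenness is the shortest-path
#' pair-dependency sum with fractional credit across equal-length paths,
#' normalized by `(N-1)(N-2)/2` with `N` the node count of the whole graph, so
#' values lie in \[0, 1\]. Closeness follows the within-component convention,
#' `(reachable - 1) / sum(distances to reachable)`; isolated nodes get
#' closeness (and betweenness) 0. These are the conventions of Cytoscape's
#' NetworkAnalyzer.
#'
#' @param x a [TripleNetwork-class], [CeRNANetwork-class] or igraph graph.
#' @return data.frame with `node_id`, `node_class` (if known), `degree`,
#'   `betweenness`, `closeness`; zero rows for an empty graph.
#' @export
computeCentralities <- function(x) {
  g <- asGraph(x)
  nv <- igraph::vcount(g)
  if (nv == 0L) {
    return(data.frame(node_id = character(), node_class = character(),
                      degree = integer(), betweenness = numeric(),
                      closeness = numeric(), stringsAsFactors = FALSE))
  }
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  btw <- if (nv < 3L) rep(0, nv)
         else igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  cls <- suppressWarnings(igraph::closeness(g, mode = "all",
                                            normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  nodeClass <- if ("class" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$class else NA_character_
  data.frame(
    node_id = igraph::V(g)$name %||% as.character(seq_len(nv)),
    node_class = nodeClass,
    degree = as.integer(deg), betweenness = unname(btw),
    closeness = unname(cls), stringsAsFactors = FALSE, row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a power law to a degree distribution
#'
#' Builds the empirical degree distribution `P(k)` over distinct degrees
#' `k >= 1` with non-zero count and fits ordinary least squares of
#' `log10 P(k)` on `log10 k`; the slope and R-squared characterize how
#' scale-free the network is. A distribution can also be supplied directly via
#' `k` and `pk` (normalization does not affect slope or R-squared). A
#' maximum-likelihood exponent (continuous approximation,
#' `1 + n / sum(log(k / (kmin - 0.5)))`) is reported alongside as `alpha_mle`.
#'
#' @param degrees integer vector of node degrees (used when `k` is `NULL`).
#' @param k,pk optional: distinct degree values and their (possibly
#'   unnormalized) probabilities.
#' @return list of class `PowerLawFit`: `slope`, `r_squared`, `n_points`,
#'   `alpha_mle` (`NA` when only the distribution form was supplied).
#' @examples
#' fitPowerLaw(rep(c(1, 2, 4, 8), c(64, 16, 4, 1)))  # slope -2, R^2 = 1
#' @export
fitPowerLaw <- function(degrees = NULL, k = NULL, pk = NULL) {
  if (is.null(k)) {
    if (is.null(degrees)) stop("supply degrees or (k, pk)")
    degrees <- degrees[degrees >= 1]
    tab <- table(degrees)
    k <- as.numeric(names(tab))
    pk <- as.numeric(tab) / sum(tab)
  } else {
    stopifnot(length(k) == length(pk), all(pk > 0), all(k > 0))
  }
  if (length(unique(k)) < 2L)
    stop("power-law fit undefined: need >= 2 distinct positive degrees")
  fit <- stats::lm(log10(pk) ~ log10(k))
  rsq <- suppressWarnings(summary(fit)$r.squared)
  alphaMLE <- NA_real_
  if (!is.null(degrees)) {
    degAll <- degrees[degrees >= 1]
    kmin <- min(degAll)
    alphaMLE <- 1 + length(degAll) / sum(log(degAll / (kmin - 0.5)))
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         r_squared = rsq,
         n_points = length(k),
         alpha_mle = alphaMLE),
    class = "PowerLawFit"
  )
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf("Power-law fit: slope %.3f, R-squared %.3f (%d degree points)\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of a topological property between groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, e.g. circRNA vs mRNA degree.
#' The p-value is exact (full permutation null) when there are no ties and the
#' permutation space is modest; otherwise the normal approximation with tie
#' and continuity correction is used.
#'
#' @param valuesA,valuesB numeric samples, both non-empty.
#' @param metric label carried into the result.
#' @return list: `metric`, `mean_a`, `mean_b`, `statistic` (Mann-Whitney W for
#'   the first sample), `p_value`, `exact`.
#' @export
wilcoxonRankSum <- function(valuesA, valuesB, metric = "") {
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0L
  exact <- !ties &&
    choose(length(valuesA) + length(valuesB), length(valuesA)) <= 1e5
  wt <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, exact = exact, correct = TRUE)
  )
  list(metric = metric, mean_a = mean(valuesA), mean_b = mean(valuesB),
       statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

topWithTies <- function(ids, values, k) {
  if (length(ids) <= k) return(ids)
  thr <- sort(values, decreasing = TRUE)[k]
  ids[values >= thr]
}

#' Select hub nodes by top-k intersection of three centralities
#'
#' A node is a hub when it appears in the top `k` simultaneously by degree,
#' by betweenness and by closeness. Each top-k set includes every node tied
#' with the k-th value, making the result independent of input ordering. Hubs
#' are returned ordered by degree descending, ties broken by betweenness then
#' by id.
#'
#' @param topology data.frame from [computeCentralities()].
#' @param k rank cutoff per index (default 10).
#' @param restrictClass optional node class (e.g. `"circRNA"`) to rank within;
#'   `NULL` ranks all nodes together.
#' @return character vector of hub node ids (possibly empty).
#' @export
selectHubs <- function(topology, k = 10L, restrictClass = NULL) {
  if (k < 1L) stop("k must be >= 1")
  tp <- topology
  if (!is.null(restrictClass))
    tp <- tp[tp$node_class %in% restrictClass, , drop = FALSE]
  if (!nrow(tp)) return(character())
  hubs <- Reduce(intersect, list(
    topWithTies(tp$node_id, tp$degree, k),
    topWithTies(tp$node_id, tp$betweenness, k),
    topWithTies(tp$node_id, tp$closeness, k)
  ))
  sel <- tp[match(hubs, tp$node_id), , drop = FALSE]
  sel <- sel[order(-sel$degree, -sel$betweenness, sel$node_id), , drop = FALSE]
  sel$node_id
}

#' Extract the key module around a hub set
#'
#' Induces the subgraph on the hubs and all of their neighbors. The module's
#' mRNA members are reported as the gene list for functional enrichment.
#'
#' @param x a network ([CeRNANetwork-class], [TripleNetwork-class] or igraph).
#' @param hubIds hub node ids; must exist in the network.
#' @return a [HubModule-class].
#' @export
extractModule <- function(x, hubIds) {
  g <- asGraph(x)
  names <- igraph::V(g)$name
  unknown <- setdiff(hubIds, names)
  if (length(unknown))
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  nbrs <- unique(unlist(lapply(hubIds, function(h)
    names(igraph::neighbors(g, h)))))
  keep <- union(hubIds, nbrs)
  sub <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(sub)
  cls <- if ("class" %in% igraph::vertex_attr_names(sub))
    igraph::V(sub)$class else rep(NA_character_, igraph::vcount(sub))
  nodes <- data.frame(node_id = igraph::V(sub)$name, node_class = cls,
                      stringsAsFactors = FALSE)
  new("HubModule",
      hubIds = hubIds,
      nodes = nodes,
      edges = data.frame(from = el[, 1], to = el[, 2],
                         stringsAsFactors = FALSE),
      mrnaIds = nodes$node_id[!is.na(nodes$node_class) &
                                nodes$node_class == "mRNA"])
}

#' @rdname writeSIF
#' @export
setMethod("writeSIF", "HubModule", function(x, path) {
  ed <- x@edges
  out <- data.frame(a = ed$from, rel = rep("circRNA-mRNA", nrow(ed)),
                    b = ed$to)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
})

#' Write a topology table as TSV
#'
#' @param topology data.frame from [computeCentralities()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTopology <- function(topology, path) {
  utils::write.table(topology, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
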