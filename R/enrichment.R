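#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: term id, description, then member gene ids. Reading
#' goes through the standard `fgsea` parser; empty sets are rejected.
#'
#' @param path GMT file.
#' @return `readGMT()`: named list of gene id vectors; `writeGMT()`: `path`,
#'   invisibly.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s) in GMT: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets
}

#' @rdname readGMT
#' @param sets named list of gene id vectors.
#' @param descriptions optional term descriptions (recycled `"na"`).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation analysis
#'
#' For each gene set, tests whether the query list hits it more often than
#' expected under random draws from the background: with `N` background genes,
#' `K` of them in the term, a list of `n` genes and `k` hits, the p-value is
#' the hypergeometric upper tail `P(X >= k)` from the same kernel as the
#' competing-pair test ([hypergeomPValue()]). Benjamini-Hochberg FDR is
#' computed across all tested terms.
#'
#' Query genes absent from the background are dropped (with a message); term
#' members outside the background are ignored. Terms smaller than
#' `minTermSize` (after background restriction) are not tested.
#'
#' @param geneList character vector of query gene ids.
#' @param sets named list of gene id vectors (e.g. from [readGMT()]).
#' @param background gene universe; `NULL` uses the union of all sets.
#' @param minTermSize smallest term tested (default 2).
#' @return data.frame sorted by p ascending: `term_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `hit_ids` (semicolon-joined).
#' @seealso [filterSignificant()]
#' @export
enrichGeneSets <- function(geneList, sets, background = NULL,
                           minTermSize = 2L) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.null(background)) background <- unique(unlist(sets))
  background <- unique(background)
  qry <- unique(geneList)
  dropped <- sum(!qry %in% background)
  if (dropped > 0) {
    message(dropped, " query gene(s) not in the background were dropped")
    qry <- qry[qry %in% background]
  }
  if (!length(qry)) stop("no query genes remain after background restriction")
  N <- length(background)
  n <- length(qry)
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  sets <- sets[lengths(sets) >= minTermSize]
  if (!length(sets)) stop("no gene set passes minTermSize")
  K <- lengths(sets)
  hits <- lapply(sets, intersect, qry)
  k <- lengths(hits)
  p <- hypergeomPValue(N, K, n, k)
  out <- data.frame(
    term_id = names(sets), k = as.integer(k), K = as.integer(K),
    n = as.integer(n), N = as.integer(N), p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    hit_ids = vapply(hits, function(h) paste(sort(h), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Filter enrichment results on FDR and p-value
#'
#' Keeps terms with `fdr < maxFDR` *and* `p_value < maxP`, both strict;
#' input order is preserved.
#'
#' @param results data.frame from [enrichGeneSets()].
#' @param maxFDR FDR cutoff (default 0.05).
#' @param maxP p-value cutoff (default 0.01).
#' @return the filtered data.frame.
#' @export
filterSignificant <- function(results, maxFDR = 0.05, maxP = 0.01) {
  stopifnot(all(c("p_value", "fdr") %in% names(results)))
  results[results$fdr < maxFDR & results$p_value < maxP, , drop = FALSE]
}
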