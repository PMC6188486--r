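#' Assemble an expression SummarizedExperiment
#'
#' Convenience constructor bundling a count (or normalized) matrix with the
#' per-feature RNA class and per-sample group labels the pipeline needs.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param featureClass character vector (`"mRNA"`, `"miRNA"`, `"circRNA"`),
#'   one per row; a single value is recycled.
#' @param group character vector (`"case"`/`"control"`), one per column.
#' @param unit `"counts"`, `"CPM"` or `"TPM"`.
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
expressionMatrix <- function(values, featureClass, group, unit = "counts") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  unit <- match.arg(unit, c("counts", "CPM", "TPM"))
  featureClass <- rep_len(featureClass, nrow(values))
  if (!all(featureClass %in% c("mRNA", "miRNA", "circRNA")))
    stop("featureClass must be mRNA, miRNA or circRNA")
  if (length(group) != ncol(values))
    stop("one group label per sample required")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), if (unit == "counts") "counts"
                             else unit),
    rowData = S4Vectors::DataFrame(featureClass = featureClass,
                                   row.names = rownames(values)),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(values)),
    metadata = list(unit = unit)
  )
}

#' Read a counts table and sample sheet into a SummarizedExperiment
#'
#' @param countsPath TSV with a header; first column feature ids, remaining
#'   columns one per sample.
#' @param sampleSheetPath TSV with columns `sample_id`, `group`.
#' @param featureClass RNA class of the features in this table.
#' @return a counts [SummarizedExperiment::SummarizedExperiment].
#' @export
readCounts <- function(countsPath, sampleSheetPath, featureClass) {
  df <- utils::read.delim(countsPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sheet <- utils::read.delim(sampleSheetPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, group")
  miss <- setdiff(colnames(m), sheet$sample_id)
  if (length(miss))
    stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  grp <- sheet$group[match(colnames(m), sheet$sample_id)]
  expressionMatrix(m, featureClass, grp, unit = "counts")
}

exprUnit <- function(se) {
  u <- S4Vectors::metadata(se)$unit
  if (is.null(u)) "counts" else u
}

#' Library-size normalization (CPM or TPM)
#'
#' CPM scales each sample so its column sums to one million. TPM first divides
#' each count by its feature length (per-kilobase rate), then scales each
#' column of rates to one million, so longer features are not over-weighted.
#'
#' @param se a counts [SummarizedExperiment::SummarizedExperiment].
#' @param mode `"CPM"` or `"TPM"`.
#' @param lengths positive per-feature lengths (bp), required for TPM; a named
#'   vector is matched to the features by name.
#' @return a SummarizedExperiment in the requested unit.
#' @examples
#' se <- expressionMatrix(matrix(c(1, 3), 2, 1,
#'                               dimnames = list(c("a", "b"), "s1")),
#'                        "mRNA", "case")
#' SummarizedExperiment::assay(normalizeExpression(se, "TPM",
#'                                                 lengths = c(100, 100)))
#' @export
normalizeExpression <- function(se, mode = c("CPM", "TPM"), lengths = NULL) {
  mode <- match.arg(mode)
  if (exprUnit(se) != "counts")
    stop("normalization requires raw counts; unit is ", exprUnit(se))
  m <- SummarizedExperiment::assay(se)
  if (mode == "TPM") {
    if (is.null(lengths))
      stop("TPM normalization requires per-feature lengths")
    if (!is.null(names(lengths))) lengths <- lengths[rownames(m)]
    lengths <- rep_len(as.numeric(lengths), nrow(m))
    if (any(!is.finite(lengths) | lengths <= 0))
      stop("all feature lengths must be positive")
    m <- m / lengths
  }
  libs <- colSums(m)
  if (any(libs == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[libs == 0], collapse = ", "))
  norm <- sweep(m, 2, libs, "/") * 1e6
  out <- se
  SummarizedExperiment::assay(out, withDimnames = FALSE) <- norm
  S4Vectors::metadata(out)$unit <- mode
  names(SummarizedExperiment::assays(out)) <- mode
  out
}

#' Remove features with uniformly low counts
#'
#' A feature is retained if and only if at least one sample has a count of
#' `minCount` or more; features below `minCount` in every sample are removed.
#' Removed ids are recorded in `metadata(se)$removedLowCount`.
#'
#' @param se a counts SummarizedExperiment.
#' @param minCount retention threshold (default 2).
#' @return the filtered SummarizedExperiment.
#' @export
filterLowCounts <- function(se, minCount = 2L) {
  if (minCount < 0) stop("minCount must be non-negative")
  if (exprUnit(se) != "counts")
    stop("low-count filtering applies to raw counts")
  m <- SummarizedExperiment::assay(se)
  keep <- apply(m, 1, function(x) any(x >= minCount))
  out <- se[keep, ]
  S4Vectors::metadata(out)$removedLowCount <- rownames(m)[!keep]
  out
}

#' Two-group differential-expression screen
#'
#' Computes per-feature log2 fold changes on the CPM scale,
#' `log2((mean case CPM + c) / (mean control CPM + c))` with pseudo-count
#' `c` (default 1 CPM, keeping zero rows finite), and p-values from a Welch
#' t-test on `log2(CPM + 1)`. This is a simple built-in screen for synthetic
#' and exploratory use; differential-expression results computed elsewhere
#' (e.g. by a count-model package) can be supplied directly via
#' [readDETable()] and passed to [filterDE()] unchanged.
#'
#' @param se a counts SummarizedExperiment with `group` column data containing
#'   at least two `"case"` and two `"control"` samples.
#' @param pseudoCount CPM pseudo-count for the fold change.
#' @return data.frame with `feature_id`, `feature_class`, `log2fc`,
#'   `p_value`, `status` (all `"NS"`; see [filterDE()]).
#' @export
testDifferentialExpression <- function(se, pseudoCount = 1) {
  grp <- SummarizedExperiment::colData(se)$group
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
    stop("the built-in test needs >= 2 samples per group; ",
         "load a precomputed DE table instead (readDETable)")
  cpm <- SummarizedExperiment::assay(
    normalizeExpression(se, "CPM"))
  caseM <- rowMeans(cpm[, grp == "case", drop = FALSE])
  ctrlM <- rowMeans(cpm[, grp == "control", drop = FALSE])
  log2fc <- log2((caseM + pseudoCount) / (ctrlM + pseudoCount))
  lg <- log2(cpm + 1)
  pv <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, grp == "case"]
    b <- lg[i, grp == "control"]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(
    feature_id = rownames(se),
    feature_class = as.character(
      SummarizedExperiment::rowData(se)$featureClass),
    log2fc = unname(log2fc), p_value = unname(pv), status = "NS",
    stringsAsFactors = FALSE
  )
}

#' Threshold differential-expression records
#'
#' Applies the fold-change and p-value cutoffs: a feature is `UP` if
#' `log2fc > minAbsLog2FC` (strictly, so a fold change of exactly 2 does not
#' pass the default), `DOWN` if `log2fc < -minAbsLog2FC`, and `NS` otherwise
#' or when the p-value fails. The p comparison is inclusive (`<=`) by default,
#' with `pInclusive = FALSE` switching to strict `<`.
#'
#' @param records data.frame with `log2fc` and `p_value` columns (e.g. from
#'   [testDifferentialExpression()] or [readDETable()]).
#' @param minAbsLog2FC absolute log2 fold-change threshold (default 1,
#'   i.e. fold change > 2).
#' @param maxP p-value threshold (default 0.05).
#' @param pInclusive if `TRUE` (default) pass when `p <= maxP`, else `p < maxP`.
#' @return the records with `status` set to `UP`/`DOWN`/`NS`. Idempotent.
#' @seealso [deSets()] to extract the significant id sets per class.
#' @export
filterDE <- function(records, minAbsLog2FC = 1, maxP = 0.05,
                     pInclusive = TRUE) {
  stopifnot(all(c("log2fc", "p_value") %in% names(records)))
  if (minAbsLog2FC <= 0 || maxP <= 0 || maxP >= 1)
    stop("thresholds must satisfy minAbsLog2FC > 0 and 0 < maxP < 1")
  if (any(!is.finite(records$log2fc)) ||
      any(records$p_value < 0 | records$p_value > 1))
    stop("records must carry finite log2fc and p in [0, 1]")
  pOK <- if (pInclusive) records$p_value <= maxP else records$p_value < maxP
  records$status <- ifelse(
    pOK & records$log2fc > minAbsLog2FC, "UP",
    ifelse(pOK & records$log2fc < -minAbsLog2FC, "DOWN", "NS")
  )
  records
}

#' Extract significant feature-id sets from annotated DE records
#'
#' @param records output of [filterDE()].
#' @return named list: for every feature class present, a list with `up`,
#'   `down` and `all` (union) id vectors.
#' @export
deSets <- function(records) {
  stopifnot("status" %in% names(records))
  cls <- if ("feature_class" %in% names(records)) records$feature_class
         else "feature"
  out <- lapply(split(records, cls), function(d) {
    list(up = d$feature_id[d$status == "UP"],
         down = d$feature_id[d$status == "DOWN"],
         all = d$feature_id[d$status != "NS"])
  })
  out
}

#' Read / write differential-expression tables
#'
#' TSV with columns `feature_id`, `feature_class`, `log2fc`, `p_value` and
#' optionally `status`.
#'
#' @param path file path.
#' @return `readDETable()`: a data.frame (with `status = "NS"` added if
#'   absent); `writeDETable()`: `path`, invisibly.
#' @export
readDETable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "feature_class", "log2fc", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "))
  if (!"status" %in% names(df)) df$status <- "NS"
  df
}

#' @rdname readDETable
#' @param records annotated DE data.frame.
#' @export
writeDETable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
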