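#' Assemble a pipeline configuration
#'
#' Exactly one of the two input modes is active: synthetic mode (a
#' [SynthConfig-class] drives the generators) or file mode (paths to counts or
#' a precomputed DE table, an interaction table, and optionally a GMT file).
#' All thresholds applied anywhere in the run are recorded here and echoed
#' into the run manifest.
#'
#' @param synth a [SynthConfig-class], or `NULL` for file mode.
#' @param deSource synthetic mode only: `"builtin"` screens the simulated
#'   counts with [testDifferentialExpression()]; `"truth"` feeds the planted
#'   DE structure through the precomputed-table path
#'   ([groundTruthDETable()]), isolating the network stages from
#'   expression-screen noise.
#' @param countsPaths named list of count TSV paths per class
#'   (`mRNA`, `miRNA`, `circRNA`); requires `sampleSheetPath`.
#' @param sampleSheetPath sample sheet TSV (`sample_id`, `group`).
#' @param deTablePath precomputed DE table TSV (preferred over counts when
#'   both are given).
#' @param interactionsPath interaction table TSV.
#' @param gmtPath optional GMT file for enrichment.
#' @param minAbsLog2FC,maxP,pInclusive DE thresholds (see [filterDE()]).
#' @param energyCutoff binding-energy filter, kcal/mol.
#' @param alpha competing-pair significance cutoff.
#' @param universe explicit miRNA universe size or `NULL` (auto).
#' @param hubK top-k cutoff for hub selection.
#' @param enrichMaxFDR,enrichMaxP enrichment significance thresholds.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the run.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synth = NULL, deSource = c("builtin", "truth"),
                           countsPaths = NULL,
                           sampleSheetPath = NULL, deTablePath = NULL,
                           interactionsPath = NULL, gmtPath = NULL,
                           minAbsLog2FC = 1, maxP = 0.05, pInclusive = TRUE,
                           energyCutoff = -20, alpha = 0.05, universe = NULL,
                           hubK = 10L, enrichMaxFDR = 0.05, enrichMaxP = 0.01,
                           outDir = tempfile("cernanet_run_"), seed = 1L) {
  deSource <- match.arg(deSource)
  synthetic <- !is.null(synth)
  if (synthetic && (!is.null(countsPaths) || !is.null(deTablePath)))
    stop("choose either synthetic mode or file inputs, not both")
  if (!synthetic) {
    if (is.null(interactionsPath) ||
        (is.null(countsPaths) && is.null(deTablePath)))
      stop("file mode needs an interaction table and counts or a DE table")
    paths <- c(unlist(countsPaths), sampleSheetPath, deTablePath,
               interactionsPath, gmtPath)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(
    synth = synth, deSource = deSource, countsPaths = countsPaths,
    sampleSheetPath = sampleSheetPath, deTablePath = deTablePath,
    interactionsPath = interactionsPath, gmtPath = gmtPath,
    minAbsLog2FC = minAbsLog2FC, maxP = maxP, pInclusive = pInclusive,
    energyCutoff = energyCutoff, alpha = alpha, universe = universe,
    hubK = as.integer(hubK), enrichMaxFDR = enrichMaxFDR,
    enrichMaxP = enrichMaxP, outDir = outDir, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a `synth:`
#' section (keys mirroring [synthConfig()] arguments) switches on synthetic
#' mode.
#'
#' @param path YAML file.
#' @param outDir overrides the configured output directory when non-`NULL`.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) do.call(synthConfig, y$synth) else NULL
  args <- y[setdiff(names(y), "synth")]
  args$synth <- synth
  if (!is.null(outDir)) args$outDir <- outDir
  do.call(pipelineConfig, args)
}

runSeed <- function(config) {
  if (!is.null(config$synth)) config$synth@seed else config$seed
}

#' Run the full ceRNA network pipeline
#'
#' Sequences all stages: input generation or loading, differential-expression
#' thresholding, interaction filtering, tripartite network assembly, competing
#' -pair scoring (DCCN), topology analysis with hub selection and key-module
#' extraction, and gene-set enrichment of the module mRNAs. Every stage writes
#' its artifact under `outDir` and a `manifest.json` records the applied
#' thresholds, per-stage counts, file checksums and an overall run hash:
#' identical configuration and seed reproduce an identical hash. Empty
#' intermediate results degrade gracefully (downstream stages emit empty
#' outputs and the run completes with warnings).
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, a run report list: `counts` (per-stage sizes), `de`,
#'   `tripleNetwork`, `dccn`, `topology`, `powerLaw`, `degreeComparison`,
#'   `hubs`, `module`, `enrichment`, `truth` (synthetic mode), `files`,
#'   `manifestHash`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  files <- character()
  report <- list(counts = list())
  synthetic <- !is.null(config$synth)

  # --- inputs: generate or load -------------------------------------------
  if (synthetic) {
    sim <- generateCounts(config$synth)
    truth <- sim$truth
    rawInteractions <- generateInteractions(config$synth, truth)
    geneSets <- generateGeneSets(config$synth, truth)
    for (cl in names(sim$matrices)) {
      f <- out(sprintf("counts_%s.tsv", cl))
      writeCounts(sim$matrices[[cl]], f); files <- c(files, f)
    }
    f <- out("ground_truth.json"); writeGroundTruth(truth, f)
    files <- c(files, f)
    f <- out("gene_sets.gmt"); writeGMT(geneSets$sets, f)
    files <- c(files, f)
    report$truth <- truth
    if (config$deSource == "truth") {
      deRecords <- groundTruthDETable(config$synth, truth)
    } else {
      deRecords <- do.call(rbind, lapply(sim$matrices, function(se) {
        testDifferentialExpression(filterLowCounts(se, 2L))
      }))
      rownames(deRecords) <- NULL
    }
    sets <- geneSets$sets
    background <- geneSets$background
  } else {
    rawInteractions <- utils::read.delim(config$interactionsPath,
                                         stringsAsFactors = FALSE)
    if (!is.null(config$deTablePath)) {
      deRecords <- readDETable(config$deTablePath)
    } else {
      deRecords <- do.call(rbind, lapply(names(config$countsPaths),
        function(cl) {
          se <- readCounts(config$countsPaths[[cl]],
                           config$sampleSheetPath, cl)
          testDifferentialExpression(filterLowCounts(se, 2L))
        }))
      rownames(deRecords) <- NULL
    }
    if (!is.null(config$gmtPath)) {
      sets <- readGMT(config$gmtPath)
      background <- unique(unlist(sets))
    } else {
      sets <- NULL
      background <- NULL
    }
  }

  # --- differential expression --------------------------------------------
  deRecords <- filterDE(deRecords, config$minAbsLog2FC, config$maxP,
                        config$pInclusive)
  f <- out("de_table.tsv"); writeDETable(deRecords, f); files <- c(files, f)
  report$de <- deRecords
  sig <- deRecords[deRecords$status != "NS", , drop = FALSE]
  report$counts$de <- as.list(table(sig$feature_class))

  # --- interactions --------------------------------------------------------
  interactions <- filterInteractions(rawInteractions, config$energyCutoff)
  f <- out("interactions_filtered.tsv"); writeInteractions(interactions, f)
  files <- c(files, f)
  report$counts$interactions <- nrow(interactions)

  # --- triple network ------------------------------------------------------
  net <- withCallingHandlers(
    buildTripleNetwork(deRecords, interactions),
    warning = function(w) {
      warning(w); invokeRestart("muffleWarning")
    })
  nd <- nodeTable(net)
  report$tripleNetwork <- net
  report$counts$triple <- list(
    miRNA = sum(nd$node_class == "miRNA"),
    circRNA = sum(nd$node_class == "circRNA"),
    mRNA = sum(nd$node_class == "mRNA"),
    edges = nrow(edgeTable(net))
  )
  f <- out("triple_network.sif"); writeSIF(net, f); files <- c(files, f)
  f <- out("triple_network.graphml"); writeGraphML(net, f)
  files <- c(files, f)

  # --- DCCN ----------------------------------------------------------------
  dccn <- buildDCCN(net, universe = config$universe,
                    interactions = rawInteractions, alpha = config$alpha)
  report$dccn <- dccn
  edges <- edgeTable(dccn)
  report$counts$dccn <- list(
    edges = nrow(edges),
    circRNA = length(unique(edges$circ_id)),
    mRNA = length(unique(edges$mrna_id)),
    tested = nrow(pairTable(dccn))
  )
  f <- out("dccn_pairs.tsv"); writePairTable(dccn, f); files <- c(files, f)
  f <- out("dccn.sif"); writeSIF(dccn, f); files <- c(files, f)
  f <- out("dccn.graphml"); writeGraphML(dccn, f); files <- c(files, f)

  # --- topology, hubs, module ---------------------------------------------
  topo <- computeCentralities(dccn)
  f <- out("topology.tsv"); writeTopology(topo, f); files <- c(files, f)
  report$topology <- topo
  report$powerLaw <- NULL
  degs <- topo$degree
  if (length(unique(degs[degs >= 1])) >= 2L)
    report$powerLaw <- fitPowerLaw(degs)
  circDeg <- topo$degree[topo$node_class == "circRNA"]
  mrnaDeg <- topo$degree[topo$node_class == "mRNA"]
  report$degreeComparison <- if (length(circDeg) && length(mrnaDeg))
    wilcoxonRankSum(circDeg, mrnaDeg, metric = "degree") else NULL

  hubs <- if (nrow(topo)) selectHubs(topo, k = config$hubK) else character()
  report$hubs <- hubs
  f <- out("hubs.txt"); writeLines(hubs, f); files <- c(files, f)

  if (length(hubs)) {
    module <- extractModule(dccn, hubs)
    report$module <- module
    f <- out("module.sif"); writeSIF(module, f); files <- c(files, f)
    f <- out("module_genes.txt"); writeLines(moduleGenes(module), f)
    files <- c(files, f)
    moduleGeneIds <- moduleGenes(module)
  } else {
    warning("no hubs selected; skipping module extraction")
    report$module <- NULL
    moduleGeneIds <- character()
    f <- out("module_genes.txt"); writeLines(character(), f)
    files <- c(files, f)
  }
  report$counts$module <- list(genes = length(moduleGeneIds),
                               hubs = length(hubs))

  # --- enrichment ----------------------------------------------------------
  report$enrichment <- NULL
  if (!is.null(sets) && length(moduleGeneIds)) {
    inBg <- moduleGeneIds[moduleGeneIds %in% background]
    if (length(inBg)) {
      enr <- suppressMessages(
        enrichGeneSets(moduleGeneIds, sets, background = background))
      report$enrichment <- enr
      report$enrichmentSignificant <-
        filterSignificant(enr, config$enrichMaxFDR, config$enrichMaxP)
      f <- out("enrichment.tsv")
      utils::write.table(enr, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    } else {
      warning("no module gene is in the enrichment background; skipped")
    }
  }

  # --- manifest ------------------------------------------------------------
  cfgRecord <- config[setdiff(names(config), "synth")]
  if (synthetic) {
    s <- config$synth
    cfgRecord$synth <- list(
      nMrna = s@nMrna, nMirna = s@nMirna, nCirc = s@nCirc,
      nSamplesPerGroup = s@nSamplesPerGroup,
      nbMeanRange = s@nbMeanRange, nbDispersion = s@nbDispersion,
      fracDE = as.list(s@fracDE), deLog2FC = s@deLog2FC,
      nPlantedPairs = s@nPlantedPairs,
      sharedMirnasPerPair = s@sharedMirnasPerPair,
      backgroundShareProb = s@backgroundShareProb,
      decoyFraction = s@decoyFraction, hubPairs = s@hubPairs, seed = s@seed
    )
  }
  checksums <- as.list(tools::md5sum(sort(files)))
  names(checksums) <- basename(sort(files))
  manifest <- list(
    package = "ceRNAnet",
    seed = runSeed(config),
    config = cfgRecord,
    stage_counts = report$counts,
    files = checksums
  )
  tmp <- tempfile()
  writeLines(unlist(checksums), tmp)
  manifestHash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest$manifest_hash <- manifestHash
  f <- out("manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, f)
  report$files <- files
  report$manifestHash <- manifestHash
  invisible(report)
}
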