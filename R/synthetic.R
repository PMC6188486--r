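#' Construct a synthetic study configuration
#'
#' Defaults emulate a two-group (case vs control) design with three biological
#' replicates per group, negative-binomial counts for the three RNA classes,
#' planted four-fold differential expression in both directions, and a planted
#' competing-pair structure: `nPlantedPairs` circRNA-mRNA pairs that each
#' share exactly `sharedMirnasPerPair` miRNAs against a sparse Bernoulli
#' background, with one circRNA acting as a hub carrying `hubPairs` of those
#' pairs. Dispersion 0.05 and baseline means in \[50, 1000\] reflect bulk
#' RNA-seq from genetically homogeneous laboratory animals.
#'
#' @param nMrna,nMirna,nCirc features per RNA class.
#' @param nSamplesPerGroup biological replicates per group.
#' @param nbMeanRange baseline negative-binomial mean range (log-uniform draw).
#' @param nbDispersion NB dispersion; variance is `mu + mu^2 * dispersion`.
#' @param fracDE named fractions of DE features per class.
#' @param deLog2FC planted absolute log2 fold change.
#' @param nPlantedPairs planted competing circRNA-mRNA pairs.
#' @param sharedMirnasPerPair miRNAs shared by each planted pair (exact).
#' @param backgroundShareProb background interaction edge probability.
#' @param decoyFraction fraction of extra weak-binding (> -20 kcal/mol) decoy
#'   interaction records, exercising the energy filter.
#' @param hubPairs planted pairs routed through the single hub circRNA.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 7)
#' cfg
#' @export
synthConfig <- function(nMrna = 200L, nMirna = 30L, nCirc = 50L,
                        nSamplesPerGroup = 3L,
                        nbMeanRange = c(50, 1000), nbDispersion = 0.05,
                        fracDE = c(mRNA = 0.30, miRNA = 0.50, circRNA = 0.40),
                        deLog2FC = 2.0,
                        nPlantedPairs = 20L, sharedMirnasPerPair = 5L,
                        backgroundShareProb = 0.01, decoyFraction = 0.15,
                        hubPairs = 8L, seed = 1L) {
  new("SynthConfig",
    nMrna = as.integer(nMrna), nMirna = as.integer(nMirna),
    nCirc = as.integer(nCirc),
    nSamplesPerGroup = as.integer(nSamplesPerGroup),
    nbMeanRange = as.numeric(nbMeanRange),
    nbDispersion = as.numeric(nbDispersion),
    fracDE = fracDE, deLog2FC = as.numeric(deLog2FC),
    nPlantedPairs = as.integer(nPlantedPairs),
    sharedMirnasPerPair = as.integer(sharedMirnasPerPair),
    backgroundShareProb = as.numeric(backgroundShareProb),
    decoyFraction = as.numeric(decoyFraction),
    hubPairs = as.integer(hubPairs), seed = as.integer(seed)
  )
}

featureIds <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

classPrefix <- c(mRNA = "gene", miRNA = "miR", circRNA = "circ")

simulateClassCounts <- function(n, cfg, cls) {
  nn <- cfg@nSamplesPerGroup
  ids <- featureIds(classPrefix[[cls]], n)
  baseMu <- exp(stats::runif(n, log(cfg@nbMeanRange[1]),
                             log(cfg@nbMeanRange[2])))
  nDE <- round(cfg@fracDE[[cls]] * n)
  deIdx <- if (nDE > 0) sort(sample.int(n, nDE)) else integer()
  # 50/50 up/down split of the planted direction
  dirs <- rep_len(c(1, -1), length(deIdx))
  dirs <- dirs[sample.int(length(deIdx))]
  caseMu <- baseMu
  caseMu[deIdx] <- baseMu[deIdx] * 2^(dirs * cfg@deLog2FC)
  size <- 1 / cfg@nbDispersion
  drawGroup <- function(mu) {
    matrix(stats::rnbinom(n * nn, mu = rep(mu, nn), size = size), nrow = n)
  }
  counts <- cbind(drawGroup(caseMu), drawGroup(baseMu))
  dimnames(counts) <- list(ids, c(sprintf("case_%d", seq_len(nn)),
                                  sprintf("ctrl_%d", seq_len(nn))))
  de <- data.frame(
    feature_id = ids[deIdx], feature_class = rep(cls, length(deIdx)),
    direction = ifelse(dirs > 0, "UP", "DOWN"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, de = de)
}

#' Generate synthetic count matrices with planted differential expression
#'
#' Draws negative-binomial counts for each RNA class under a two-group design.
#' Planted DE features have their case-group mean multiplied by
#' `2^deLog2FC` (half up, half down), so the expected group-mean ratio equals
#' the configured fold change. Also decides the planted competing-pair
#' structure (which DE circRNAs pair with which DE mRNAs through which DE
#' miRNAs), recorded in the returned ground truth for use by
#' [generateInteractions()] and recovery tests.
#'
#' @param config a [SynthConfig-class].
#' @return a list with elements
#'   \describe{
#'     \item{matrices}{named list (`mRNA`, `miRNA`, `circRNA`) of
#'       [SummarizedExperiment::SummarizedExperiment] objects with a
#'       `counts` assay, `featureClass` row data and `group` column data.}
#'     \item{truth}{a [GroundTruth-class] object.}
#'   }
#' @examples
#' sim <- generateCounts(synthConfig(seed = 42))
#' dim(SummarizedExperiment::assay(sim$matrices$mRNA))
#' @export
generateCounts <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  set.seed(config@seed)
  classes <- c("mRNA", "miRNA", "circRNA")
  ns <- c(mRNA = config@nMrna, miRNA = config@nMirna, circRNA = config@nCirc)
  sims <- lapply(classes, function(cl) simulateClassCounts(ns[[cl]], config, cl))
  names(sims) <- classes
  de <- do.call(rbind, lapply(sims, `[[`, "de"))
  rownames(de) <- NULL

  deCirc <- de$feature_id[de$feature_class == "circRNA"]
  deMrna <- de$feature_id[de$feature_class == "mRNA"]
  deMir <- de$feature_id[de$feature_class == "miRNA"]
  nPairs <- config@nPlantedPairs
  nonHub <- nPairs - config@hubPairs
  if (length(deCirc) < nonHub + 1L || length(deMrna) < nPairs)
    stop("not enough planted-DE circRNAs/mRNAs for the requested pairs; ",
         "raise fracDE or lower nPlantedPairs")
  if (length(deMir) < config@sharedMirnasPerPair)
    stop("not enough planted-DE miRNAs for the requested shared set size")

  circPool <- sample(deCirc, nonHub + 1L)
  hub <- circPool[1L]
  pairCirc <- c(rep(hub, config@hubPairs), circPool[-1L])
  pairMrna <- sample(deMrna, nPairs)
  shared <- lapply(seq_len(nPairs), function(i)
    sample(deMir, config@sharedMirnasPerPair))

  truth <- new("GroundTruth",
    deFeatures = de,
    plantedPairs = data.frame(circ_id = pairCirc, mrna_id = pairMrna,
                              stringsAsFactors = FALSE),
    sharedMirnas = shared,
    hubCirc = hub
  )

  group <- rep(c("case", "control"), each = config@nSamplesPerGroup)
  mats <- lapply(classes, function(cl) {
    cnt <- sims[[cl]]$counts
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cnt),
      rowData = S4Vectors::DataFrame(
        featureClass = rep(cl, nrow(cnt)), row.names = rownames(cnt)),
      colData = S4Vectors::DataFrame(group = group,
                                     row.names = colnames(cnt)),
      metadata = list(unit = "counts")
    )
  })
  names(mats) <- classes
  list(matrices = mats, truth = truth)
}

#' Generate a synthetic miRNA-target interaction set
#'
#' Emits the parsed-prediction table the pipeline consumes. Each planted pair
#' `(circRNA, mRNA)` shares exactly its configured miRNA set: both the
#' miRNA-circRNA and miRNA-mRNA records are emitted for every shared miRNA.
#' All other miRNA-target edges arise independently with probability
#' `backgroundShareProb`; background edges that would accidentally push a
#' planted pair's overlap above the configured size are dropped
#' deterministically. Real records carry binding free energies drawn uniformly
#' in \[-35, -20\] kcal/mol so all survive the -20 kcal/mol filter, plus a
#' configurable fraction of weak decoy records (energy > -20) that the filter
#' must remove.
#'
#' @param config the [SynthConfig-class] used for [generateCounts()].
#' @param truth the matching [GroundTruth-class].
#' @return data.frame with columns `mirna_id`, `target_id`, `target_class`,
#'   `score`, `energy_kcal_mol`.
#' @export
generateInteractions <- function(config, truth) {
  stopifnot(is(config, "SynthConfig"), is(truth, "GroundTruth"))
  pp <- truth@plantedPairs
  if (nrow(pp) != config@nPlantedPairs ||
      any(lengths(truth@sharedMirnas) != config@sharedMirnasPerPair))
    stop("ground truth does not match the configuration it was built from")
  set.seed(config@seed + 1L)

  mirIds <- featureIds(classPrefix[["miRNA"]], config@nMirna)
  targets <- data.frame(
    target_id = c(featureIds(classPrefix[["mRNA"]], config@nMrna),
                  featureIds(classPrefix[["circRNA"]], config@nCirc)),
    target_class = rep(c("mRNA", "circRNA"), c(config@nMrna, config@nCirc)),
    stringsAsFactors = FALSE
  )

  planted <- do.call(rbind, lapply(seq_len(nrow(pp)), function(i) {
    mirs <- truth@sharedMirnas[[i]]
    data.frame(
      mirna_id = rep(mirs, 2L),
      target_id = rep(c(pp$circ_id[i], pp$mrna_id[i]), each = length(mirs)),
      target_class = rep(c("circRNA", "mRNA"), each = length(mirs)),
      stringsAsFactors = FALSE
    )
  }))

  grid <- expand.grid(mirna_id = mirIds, target_id = targets$target_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < config@backgroundShareProb
  bg <- grid[keep, , drop = FALSE]
  bg$target_class <- targets$target_class[match(bg$target_id,
                                                targets$target_id)]

  rec <- rbind(planted, bg)
  rec <- rec[!duplicated(rec[c("mirna_id", "target_id")]), , drop = FALSE]

  # keep planted overlaps exact: drop background mRNA-side edges that add
  # an unplanned shared miRNA to a planted pair
  mirByTarget <- split(rec$mirna_id, rec$target_id)
  drop <- logical(nrow(rec))
  for (i in seq_len(nrow(pp))) {
    extra <- setdiff(
      intersect(mirByTarget[[pp$circ_id[i]]], mirByTarget[[pp$mrna_id[i]]]),
      truth@sharedMirnas[[i]]
    )
    if (length(extra))
      drop <- drop | (rec$target_id == pp$mrna_id[i] &
                        rec$mirna_id %in% extra)
  }
  rec <- rec[!drop, , drop = FALSE]

  rec$score <- round(stats::runif(nrow(rec), 140, 180), 1)
  rec$energy_kcal_mol <- round(stats::runif(nrow(rec), -35, -20), 2)

  nDecoy <- round(config@decoyFraction * nrow(rec))
  if (nDecoy > 0) {
    haveKey <- paste(rec$mirna_id, rec$target_id)
    pool <- grid[!(paste(grid$mirna_id, grid$target_id) %in% haveKey), ,
                 drop = FALSE]
    dec <- pool[sample.int(nrow(pool), min(nDecoy, nrow(pool))), ,
                drop = FALSE]
    dec$target_class <- targets$target_class[match(dec$target_id,
                                                   targets$target_id)]
    dec$score <- round(stats::runif(nrow(dec), 140, 180), 1)
    dec$energy_kcal_mol <- round(stats::runif(nrow(dec), -19.9, -5), 2)
    rec <- rbind(rec, dec)
  }
  rownames(rec) <- NULL
  rec[order(rec$mirna_id, rec$target_id), , drop = FALSE]
}

#' Generate synthetic gene sets with one planted enriched term
#'
#' Produces a GMT-serializable collection over the mRNA background: one
#' planted term drawn predominantly (80%) from the planted-DE mRNAs, and
#' `nRandomTerms` terms drawn uniformly from the background, against which
#' enrichment of a DE gene list can be scored.
#'
#' @param config the [SynthConfig-class].
#' @param truth the matching [GroundTruth-class]; must contain DE mRNAs.
#' @param plantedSize size of the planted term.
#' @param plantedDEFrac fraction of the planted term drawn from DE mRNAs.
#' @param nRandomTerms number of uniformly drawn terms.
#' @return list with `sets` (named list of gene id vectors; the planted term
#'   is named `"TERM_PLANTED"`) and `background` (all mRNA ids).
#' @export
generateGeneSets <- function(config, truth, plantedSize = 30L,
                             plantedDEFrac = 0.8, nRandomTerms = 10L) {
  stopifnot(is(config, "SynthConfig"), is(truth, "GroundTruth"))
  de <- truth@deFeatures
  deMrna <- de$feature_id[de$feature_class == "mRNA"]
  if (length(deMrna) == 0L)
    stop("no planted-DE mRNAs in the ground truth; cannot plant an enriched term")
  set.seed(config@seed + 2L)
  background <- featureIds(classPrefix[["mRNA"]], config@nMrna)
  nFromDE <- min(round(plantedDEFrac * plantedSize), length(deMrna))
  nonDE <- setdiff(background, deMrna)
  plantedTerm <- c(sample(deMrna, nFromDE),
                   sample(nonDE, plantedSize - nFromDE))
  sets <- c(
    list(TERM_PLANTED = plantedTerm),
    stats::setNames(
      lapply(seq_len(nRandomTerms), function(i)
        sample(background, sample(10:40, 1L))),
      sprintf("TERM_RANDOM_%02d", seq_len(nRandomTerms))
    )
  )
  list(sets = sets, background = background)
}

#' Ground-truth differential-expression table
#'
#' Renders the planted DE structure as a precomputed DE table (the pipeline's
#' canonical input form): planted features carry the configured log2 fold
#' change with p-value 0 and their planted status; all other features are
#' null (log2fc 0, p 1, `NS`). Feeding this through [filterDE()] and
#' [buildTripleNetwork()] isolates the network/statistic stages from the
#' noise of any expression-level DE screen.
#'
#' @param config the [SynthConfig-class].
#' @param truth the matching [GroundTruth-class].
#' @return an annotated DE data.frame (same shape as [filterDE()] output).
#' @export
groundTruthDETable <- function(config, truth) {
  stopifnot(is(config, "SynthConfig"), is(truth, "GroundTruth"))
  all <- data.frame(
    feature_id = c(featureIds(classPrefix[["mRNA"]], config@nMrna),
                   featureIds(classPrefix[["miRNA"]], config@nMirna),
                   featureIds(classPrefix[["circRNA"]], config@nCirc)),
    feature_class = rep(c("mRNA", "miRNA", "circRNA"),
                        c(config@nMrna, config@nMirna, config@nCirc)),
    stringsAsFactors = FALSE
  )
  de <- truth@deFeatures
  i <- match(all$feature_id, de$feature_id)
  planted <- !is.na(i)
  all$log2fc <- ifelse(planted,
                       ifelse(de$direction[i] == "UP", 1, -1) * config@deLog2FC,
                       0)
  all$p_value <- ifelse(planted, 0, 1)
  all$status <- ifelse(planted, de$direction[i], "NS")
  all
}

#' Write a counts SummarizedExperiment as TSV
#'
#' First column `feature_id`, one column per sample.
#'
#' @param se a SummarizedExperiment with a `counts` (or sole) assay.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(se, path) {
  m <- SummarizedExperiment::assay(se)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(
    de_features = truth@deFeatures,
    planted_pairs = cbind(
      truth@plantedPairs,
      shared_mirnas = vapply(truth@sharedMirnas, paste, character(1),
                             collapse = ";")
    ),
    hub_circ = truth@hubCirc
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
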