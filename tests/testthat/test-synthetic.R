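test_that("identical configuration and seed reproduce identical data", {
  cfg <- synthConfig(seed = 99L)
  a <- generateCounts(cfg)
  b <- generateCounts(cfg)
  for (cl in names(a$matrices)) {
    expect_identical(SummarizedExperiment::assay(a$matrices[[cl]]),
                     SummarizedExperiment::assay(b$matrices[[cl]]))
  }
  expect_identical(plantedPairs(a$truth), plantedPairs(b$truth))
  expect_identical(generateInteractions(cfg, a$truth),
                   generateInteractions(cfg, b$truth))
})

test_that("count matrices have the configured dimensions and class labels", {
  cfg <- synthConfig(nMrna = 100L, nSamplesPerGroup = 3L, seed = 5L)
  sim <- generateCounts(cfg)
  m <- SummarizedExperiment::assay(sim$matrices$mRNA)
  expect_equal(dim(m), c(100L, 6L))
  expect_equal(dim(SummarizedExperiment::assay(sim$matrices$circRNA)),
               c(50L, 6L))
  expect_true(all(m >= 0 & m == floor(m)))
  expect_equal(
    as.character(SummarizedExperiment::colData(sim$matrices$miRNA)$group),
    rep(c("case", "control"), each = 3))
})

test_that("planted fold change is calibrated: mean empirical log2 ratio near target", {
  # many planted features so the Monte-Carlo mean is tight
  cfg <- synthConfig(nMrna = 10000L, fracDE = c(mRNA = 1, miRNA = 0.5,
                                                circRNA = 0.4),
                     nPlantedPairs = 5L, hubPairs = 2L, seed = 13L)
  sim <- generateCounts(cfg)
  cnt <- SummarizedExperiment::assay(sim$matrices$mRNA)
  de <- deFeatures(sim$truth)
  de <- de[de$feature_class == "mRNA", ]
  caseM <- rowMeans(cnt[de$feature_id, 1:3]) + 0.5
  ctrlM <- rowMeans(cnt[de$feature_id, 4:6]) + 0.5
  lfc <- log2(caseM / ctrlM) * ifelse(de$direction == "UP", 1, -1)
  expect_equal(mean(lfc), 2.0, tolerance = 0.05)
  expect_lt(abs(mean(lfc) - 2.0), 0.1)
})

test_that("planted pairs share exactly the configured number of miRNAs", {
  cfg <- synthConfig(seed = 21L)
  sim <- generateCounts(cfg)
  ints <- generateInteractions(cfg, sim$truth)
  mirByTarget <- split(ints$mirna_id[ints$energy_kcal_mol <= -20],
                       ints$target_id[ints$energy_kcal_mol <= -20])
  pp <- sim$truth@plantedPairs
  for (i in seq_len(nrow(pp))) {
    shared <- intersect(mirByTarget[[pp$circ_id[i]]],
                        mirByTarget[[pp$mrna_id[i]]])
    expect_length(shared, 5L)
    expect_setequal(shared, sim$truth@sharedMirnas[[i]])
  }
})

test_that("zero background share probability: only planted endpoints carry edges", {
  cfg <- synthConfig(backgroundShareProb = 0, decoyFraction = 0, seed = 3L)
  sim <- generateCounts(cfg)
  ints <- generateInteractions(cfg, sim$truth)
  pp <- sim$truth@plantedPairs
  # every interaction belongs to some planted pair's shared set
  expect_true(all(ints$target_id %in% c(pp$circ_id, pp$mrna_id)))
  expect_true(all(ints$mirna_id %in% unlist(sim$truth@sharedMirnas)))
  # a pair with at least one unplanted endpoint shares nothing
  # (planted endpoints of different pairs can still share, because the
  # 20 x 5 shared sets are drawn from the same DE miRNA pool)
  mirByTarget <- split(ints$mirna_id, ints$target_id)
  offCirc <- setdiff(sprintf("circ_%04d", 1:50), pp$circ_id)
  offMrna <- setdiff(sprintf("gene_%04d", 1:200), pp$mrna_id)
  expect_false(any(offCirc %in% ints$target_id))
  expect_false(any(offMrna %in% ints$target_id))
})

test_that("planted pairs score far better than random non-planted pairs", {
  cfg <- synthConfig(seed = 7L)
  sim <- generateCounts(cfg)
  ints <- generateInteractions(cfg, sim$truth)
  ints <- filterInteractions(ints)
  m <- length(unique(ints$mirna_id))
  mirByTarget <- split(ints$mirna_id, ints$target_id)
  pairP <- function(cc, gg) {
    tt <- length(mirByTarget[[gg]])
    nn <- length(mirByTarget[[cc]])
    rr <- length(intersect(mirByTarget[[cc]], mirByTarget[[gg]]))
    if (tt == 0 || nn == 0) return(1)
    hypergeomPValue(m, tt, nn, rr)
  }
  pp <- sim$truth@plantedPairs
  pPlanted <- mapply(pairP, pp$circ_id, pp$mrna_id)
  set.seed(1)
  circs <- sprintf("circ_%04d", sample.int(50, 100, replace = TRUE))
  genes <- sprintf("gene_%04d", sample.int(200, 100, replace = TRUE))
  keep <- !paste(circs, genes) %in% paste(pp$circ_id, pp$mrna_id)
  pRandom <- mapply(pairP, circs[keep], genes[keep])
  expect_lt(median(pPlanted), median(pRandom))
  expect_lt(max(pPlanted), 0.05)
})

test_that("decoy records exceed the energy cutoff and are removed by the filter", {
  cfg <- synthConfig(seed = 17L)
  sim <- generateCounts(cfg)
  ints <- generateInteractions(cfg, sim$truth)
  expect_gt(sum(ints$energy_kcal_mol > -20), 0)
  kept <- filterInteractions(ints)
  expect_true(all(kept$energy_kcal_mol <= -20))
})

test_that("gene sets include a planted term and respect preconditions", {
  cfg <- synthConfig(seed = 31L)
  sim <- generateCounts(cfg)
  gs <- generateGeneSets(cfg, sim$truth)
  expect_true("TERM_PLANTED" %in% names(gs$sets))
  expect_length(gs$sets$TERM_PLANTED, 30L)
  deMrna <- deFeatures(sim$truth)
  deMrna <- deMrna$feature_id[deMrna$feature_class == "mRNA"]
  expect_gte(sum(gs$sets$TERM_PLANTED %in% deMrna), 20L)
  emptyTruth <- sim$truth
  emptyTruth@deFeatures <-
    emptyTruth@deFeatures[emptyTruth@deFeatures$feature_class != "mRNA", ]
  emptyTruth@plantedPairs <- emptyTruth@plantedPairs[0, ]
  emptyTruth@sharedMirnas <- list()
  expect_error(generateGeneSets(cfg, emptyTruth), "cannot plant")
})

test_that("configuration invariants are enforced", {
  expect_error(synthConfig(nMrna = 0L), "positive")
  expect_error(synthConfig(nbDispersion = -1), "positive")
  expect_error(synthConfig(fracDE = c(mRNA = 1.2, miRNA = 0.5,
                                      circRNA = 0.4)), "0, 1")
  expect_error(synthConfig(sharedMirnasPerPair = 31L, nMirna = 30L),
               "exceed")
  cfg <- synthConfig(seed = 2L)
  other <- synthConfig(nPlantedPairs = 10L, hubPairs = 5L, seed = 2L)
  truth <- generateCounts(cfg)$truth
  expect_error(generateInteractions(other, truth), "does not match")
})
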