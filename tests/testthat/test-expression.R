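toySE <- function(values, group = c("case", "case", "control", "control"),
                  cls = "mRNA") {
  m <- matrix(values, nrow = length(values) / length(group), byrow = TRUE)
  dimnames(m) <- list(sprintf("f%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  expressionMatrix(m, cls, group)
}

test_that("CPM columns sum to one million and TPM matches the hand computation", {
  set.seed(1)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:6)))
  se <- expressionMatrix(m, "mRNA", rep(c("case", "control"), each = 3))
  cpm <- SummarizedExperiment::assay(normalizeExpression(se, "CPM"))
  expect_equal(unname(colSums(cpm)), rep(1e6, 6), tolerance = 1e-9)

  se2 <- expressionMatrix(
    matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1")),
    "mRNA", "case")
  tpm <- SummarizedExperiment::assay(
    normalizeExpression(se2, "TPM", lengths = c(100, 100)))
  expect_equal(unname(tpm[, 1]), c(250000, 750000))
  # unequal lengths reweight: same counts, length 100 vs 300
  tpm2 <- SummarizedExperiment::assay(
    normalizeExpression(se2, "TPM", lengths = c(100, 300)))
  expect_equal(unname(tpm2[, 1]), c(0.01, 0.01) / 0.02 * 1e6)

  # single feature degenerates to 1e6 whatever the count
  se1 <- expressionMatrix(matrix(7, 1, 1, dimnames = list("x", "s")),
                          "miRNA", "case")
  expect_equal(unname(SummarizedExperiment::assay(
    normalizeExpression(se1, "CPM"))[1, 1]), 1e6)

  expect_error(normalizeExpression(se2, "TPM"), "lengths")
  seZero <- expressionMatrix(
    matrix(c(1, 0), 1, 2, dimnames = list("x", c("ok", "empty"))),
    "mRNA", c("case", "control"))
  expect_error(normalizeExpression(seZero, "CPM"), "empty")
})

test_that("low-count filter removes only features below the threshold everywhere", {
  se <- toySE(c(1, 1, 1, 1,
                0, 0, 0, 5,
                2, 0, 0, 0,
                0, 1, 1, 0))
  kept <- filterLowCounts(se, 2L)
  expect_setequal(rownames(kept), c("f2", "f3"))
  expect_setequal(S4Vectors::metadata(kept)$removedLowCount, c("f1", "f4"))
  expect_equal(nrow(filterLowCounts(se, 0L)), 4L)
  expect_error(filterLowCounts(se, -1L), "non-negative")
})

test_that("built-in DE screen handles no-signal and degenerate rows", {
  # filler row keeps library sizes equal so CPM ratios track the counts
  se <- toySE(c(10, 12, 10, 12,
                0, 0, 0, 0,
                100, 90, 10, 9,
                90, 98, 180, 179))
  de <- testDifferentialExpression(se)
  expect_equal(de$log2fc[2], 0)
  expect_equal(de$p_value[2], 1)
  expect_gt(de$log2fc[3], 1)
  # identical case/control values: no signal
  seSame <- toySE(c(5, 8, 5, 8))
  deSame <- testDifferentialExpression(seSame)
  expect_equal(deSame$log2fc[1], 0)
  expect_gte(deSame$p_value[1], 0.99)
  seOne <- toySE(c(1, 2), group = c("case", "control"))
  expect_error(testDifferentialExpression(seOne), "precomputed")
})

test_that("planted features are recovered near their fold change by the screen", {
  cfg <- synthConfig(nMrna = 500L, seed = 8L)
  sim <- generateCounts(cfg)
  de <- testDifferentialExpression(sim$matrices$mRNA)
  truthDE <- deFeatures(sim$truth)
  planted <- truthDE$feature_id[truthDE$feature_class == "mRNA"]
  expect_equal(median(abs(de$log2fc[de$feature_id %in% planted])), 2.0,
               tolerance = 0.15)
  expect_lt(abs(median(abs(de$log2fc[de$feature_id %in% planted])) - 2), 0.3)
})

test_that("DE thresholding matches the fold-change and p rules exactly", {
  toy <- data.frame(
    feature_id = letters[1:5], feature_class = "mRNA",
    log2fc = c(2.5, -3, -1.5, 0.2, 1.2),
    p_value = c(0.01, 0.2, 0.04, 0.001, 0.05),
    status = "NS", stringsAsFactors = FALSE
  )
  ann <- filterDE(toy)
  expect_equal(ann$status, c("UP", "NS", "DOWN", "NS", "UP"))
  # p = 0.05 passes the inclusive default; boundary log2fc does not
  strict <- filterDE(toy, pInclusive = FALSE)
  expect_equal(strict$status, c("UP", "NS", "DOWN", "NS", "NS"))
  boundary <- filterDE(data.frame(log2fc = 1.0, p_value = 0.01,
                                  feature_id = "x", feature_class = "mRNA"))
  expect_equal(boundary$status, "NS")
  # printed example: strong upregulation passes
  expect_equal(filterDE(data.frame(log2fc = 4.485, p_value = 1.45e-07,
                                   feature_id = "y",
                                   feature_class = "miRNA"))$status, "UP")
  # idempotence
  expect_identical(filterDE(ann), ann)
})

test_that("fold changes are invariant to library-size rescaling of raw counts", {
  set.seed(4)
  m <- matrix(rpois(120, 50), 20, 6,
              dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:6)))
  grp <- rep(c("case", "control"), each = 3)
  scaled <- sweep(m, 2, c(1, 3, 5, 2, 4, 10), "*")
  de1 <- testDifferentialExpression(expressionMatrix(m, "mRNA", grp))
  de2 <- testDifferentialExpression(expressionMatrix(scaled, "mRNA", grp))
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-12)
})

test_that("under the global null the screen is conservative-to-nominal", {
  nullMatrix <- function(nFeat, nPerGroup, seed) {
    set.seed(seed)
    mu <- exp(runif(nFeat, log(50), log(1000)))
    ns <- 2 * nPerGroup
    m <- matrix(rnbinom(nFeat * ns, mu = rep(mu, ns), size = 1 / 0.05),
                nFeat, ns,
                dimnames = list(sprintf("f%d", seq_len(nFeat)),
                                sprintf("s%d", seq_len(ns))))
    expressionMatrix(m, "mRNA", rep(c("case", "control"), each = nPerGroup))
  }
  # 3 vs 3: the Welch screen at n = 3 never exceeds the nominal level
  de3 <- testDifferentialExpression(nullMatrix(2000, 3, 12))
  frac3 <- mean(de3$p_value <= 0.05)
  expect_lt(frac3, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(frac3, 0.02)  # conservative, but not degenerate
  # 10 vs 10: the test is calibrated, rate within binomial 99% bounds
  de10 <- testDifferentialExpression(nullMatrix(2000, 10, 12))
  frac10 <- mean(de10$p_value <= 0.05)
  expect_lt(abs(frac10 - 0.05), 2.58 * sqrt(0.05 * 0.95 / 2000) + 1e-9)
})

test_that("DE tables round-trip through TSV", {
  toy <- data.frame(feature_id = c("a", "b"), feature_class = "mRNA",
                    log2fc = c(1.5, -2), p_value = c(0.01, 0.3),
                    status = c("UP", "NS"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeDETable(toy, f)
  back <- readDETable(f)
  expect_equal(back, toy)
  f2 <- tempfile()
  writeLines(c("a\tb", "1\t2"), f2)
  expect_error(readDETable(f2), "missing columns")
})
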