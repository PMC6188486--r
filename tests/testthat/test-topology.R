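igraphFrom <- function(edges, n) {
  igraph::make_graph(t(edges), n = n, directed = FALSE)
}

test_that("closed forms hold on star, path and 4-cycle", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  tp <- computeCentralities(star)
  expect_equal(tp$degree, c(3L, 1L, 1L, 1L))
  expect_equal(tp$betweenness, c(1, 0, 0, 0))
  expect_equal(tp$closeness, c(1, 0.6, 0.6, 0.6))

  path <- igraph::make_graph(~ a - b, b - c)
  tpp <- computeCentralities(path)
  expect_equal(tpp$betweenness[tpp$node_id == "b"], 1)
  expect_equal(tpp$closeness[tpp$node_id == "a"], 2 / 3)

  cyc <- igraph::make_ring(4)
  tpc <- computeCentralities(cyc)
  expect_equal(tpc$betweenness, rep(1 / 6, 4))
  expect_equal(tpc$closeness, rep(3 / 4, 4))
})

test_that("centralities match the brute-force oracle on random graphs", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    edges <- randomGraphEdges(n, runif(1, 0.25, 0.7))
    oracle <- bruteCentralities(n, edges)
    tp <- computeCentralities(igraphFrom(edges, n))
    ord <- order(as.integer(tp$node_id))
    expect_equal(tp$degree[ord], unname(oracle$degree), tolerance = 1e-9)
    expect_equal(tp$betweenness[ord], oracle$betweenness, tolerance = 1e-9)
    expect_equal(tp$closeness[ord], oracle$closeness, tolerance = 1e-9)
  }
})

test_that("raw betweenness sums to the count of intermediate incidences", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    edges <- randomGraphEdges(n, 0.5)
    oracle <- bruteCentralities(n, edges)
    tp <- computeCentralities(igraphFrom(edges, n))
    norm <- (n - 1) * (n - 2) / 2
    expect_equal(sum(tp$betweenness) * norm, sum(oracle$betweennessRaw),
                 tolerance = 1e-9)
  }
})

test_that("isolated nodes get zero closeness and betweenness", {
  g <- igraph::make_graph(~ a - b) + igraph::vertex("iso")
  tp <- computeCentralities(g)
  expect_equal(tp$closeness[tp$node_id == "iso"], 0)
  expect_equal(tp$betweenness[tp$node_id == "iso"], 0)
  expect_equal(nrow(computeCentralities(igraph::make_empty_graph(0))), 0L)
})

test_that("power-law fit recovers exact log-linear data", {
  # integer counts proportional to k^-2
  fit <- fitPowerLaw(rep(c(1, 2, 4, 8), c(64, 16, 4, 1)))
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)
  # property: exact recovery for random exponents via the distribution form
  set.seed(5)
  for (i in 1:20) {
    s <- runif(1, 1, 3)
    k <- sort(sample(1:50, 8))
    fit <- fitPowerLaw(k = k, pk = k^(-s))
    expect_equal(fit$slope, -s, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  expect_error(fitPowerLaw(rep(3, 10)), "distinct")
})

test_that("preferential-attachment degree sequences fit a heavy-tailed slope", {
  set.seed(31)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  fit <- fitPowerLaw(igraph::degree(g))
  expect_gt(fit$slope, -3.5)
  expect_lt(fit$slope, -1.5)
  expect_gt(fit$r_squared, 0.6)
})

test_that("rank-sum test matches full permutation enumeration when exact", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:25) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    vals <- sample(seq_len(50), na + nb)  # no ties
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    res <- wilcoxonRankSum(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, enumRankSumP(a, b), tolerance = 1e-12)
  }
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("hub selection intersects the three top-k sets with boundary ties", {
  tp <- data.frame(
    node_id = c("hub", "b", "c", "d", "e", "f"),
    node_class = "circRNA",
    degree = c(9L, 5L, 5L, 2L, 2L, 1L),
    betweenness = c(0.9, 0.5, 0.4, 0.1, 0.05, 0),
    closeness = c(0.95, 0.6, 0.5, 0.4, 0.3, 0.2),
    stringsAsFactors = FALSE
  )
  expect_equal(selectHubs(tp, k = 1), "hub")
  # k=2: degree top-2 includes the tie at 5 -> {hub,b,c}; others {hub,b}
  expect_equal(selectHubs(tp, k = 2), c("hub", "b"))
  expect_setequal(selectHubs(tp, k = 10), tp$node_id)
  # invariant to input ordering
  set.seed(3)
  expect_equal(selectHubs(tp[sample(6), ], k = 2), c("hub", "b"))
  expect_error(selectHubs(tp, k = 0), ">= 1")
})

test_that("module extraction induces the hub-neighborhood subgraph", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:4))
  mod <- extractModule(star, "center")
  expect_setequal(nodeTable(mod)$node_id, igraph::V(star)$name)
  expect_equal(nrow(edgeTable(mod)), 4L)

  twoTri <- igraph::make_graph(~ a - b, b - c, c - a, x - y, y - z, z - x)
  modA <- extractModule(twoTri, "a")
  expect_setequal(nodeTable(modA)$node_id, c("a", "b", "c"))
  expect_equal(nrow(edgeTable(modA)), 3L)
  expect_error(extractModule(twoTri, "nope"), "unknown hub")
})

test_that("module mRNAs are reported for enrichment on a DCCN", {
  cfg <- synthConfig(seed = 7L)
  sim <- generateCounts(cfg)
  ints <- filterInteractions(generateInteractions(cfg, sim$truth))
  net <- buildTripleNetwork(groundTruthDETable(cfg, sim$truth), ints)
  dccn <- buildDCCN(net, interactions = ints)
  topo <- computeCentralities(dccn)
  hubs <- selectHubs(topo, k = 10)
  expect_true(plantedHub(sim$truth) %in% hubs)
  mod <- extractModule(dccn, hubs)
  expect_true(all(hubIds(mod) %in% nodeTable(mod)$node_id))
  expect_true(all(grepl("^gene", moduleGenes(mod))))
  expect_gt(length(moduleGenes(mod)), 0L)
})
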