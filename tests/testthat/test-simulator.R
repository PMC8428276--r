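test_that("topologies validate structure and count leaves/edges", {
  single <- makeTopology(data.frame(from = "root", to = "A"), root = "root")
  expect_length(single@branches, 1L)
  expect_equal(topologyLeaves(single), "A")
  # the seven-leaf comparison shape has 13 branch segments
  fig5 <- makeTopology(data.frame(
    from = c("0", "1", "2", "3", "4", "5", "1", "2", "3", "4", "5", "6", "6"),
    to = as.character(1:13)), root = "0")
  expect_length(fig5@branches, 13L)
  expect_length(topologyLeaves(fig5), 7L)
  # recursive bifurcation to 7 leaves: edges = 2 * leaves - 1
  withr::with_seed(81, {
    edges <- data.frame(from = "r", to = "n1")
    tips <- "n1"; nxt <- 2
    while (length(tips) < 7) {
      pick <- sample(tips, 1)
      kids <- paste0("n", nxt + 0:1); nxt <- nxt + 2
      edges <- rbind(edges, data.frame(from = pick, to = kids))
      tips <- c(setdiff(tips, pick), kids)
    }
  })
  topo <- makeTopology(edges, root = "r")
  expect_equal(length(topologyLeaves(topo)), 7L)
  expect_equal(length(topo@branches), 2L * 7L - 1L)
})

test_that("cycles and multiple roots are structural errors", {
  expect_error(makeTopology(data.frame(from = c("r", "a", "b"),
                                       to = c("a", "b", "a")), root = "r"),
               "multiple parents")
  expect_error(makeTopology(data.frame(from = c("r", "q"),
                                       to = c("a", "b")), root = "r"),
               "multiple roots|structural")
  expect_error(makeTopology(data.frame(from = c("r", "r"),
                                       to = c("a", "b")), root = "r"),
               "exactly one branch")
})

test_that("cell bookkeeping matches the requested design", {
  topo <- makeTopology(data.frame(from = c("0", "1", "1"),
                                  to = c("1", "2", "3")), root = "0")
  sim <- simulateLineage(topo, c(`1` = 40L, `2` = 25L, `3` = 35L),
                         nGenes = 60, seed = 4)
  expect_equal(nrow(simCounts(sim)), 100L)
  expect_equal(as.integer(table(simCellInfo(sim)$type)[c("1", "2", "3")]),
               c(40L, 25L, 35L))
  expect_true(all(simCounts(sim) >= 0))
  expect_true(all(simCellInfo(sim)$library_factor > 0))
  # pseudotime lies within each branch's global interval
  info <- simCellInfo(sim)
  expect_true(all(info$pseudotime[info$branch == "1"] <= 40))
  expect_true(all(info$pseudotime[info$branch == "2"] >= 40))
})

test_that("constant programs with Poisson emission match their means", {
  topo <- makeTopology(data.frame(from = "0", to = "1", length = 10),
                       root = "0")
  sim <- simulateLineage(topo, c(`1` = 2000L), nGenes = 100,
                         programWalkSd = 0, dispersion = Inf,
                         libsizeSigma = 0, totalCounts = 500, seed = 5)
  cnt <- simCounts(sim)
  # constant programs + no library noise -> a single mean vector; each
  # per-gene sample mean within 3 standard errors of the empirical mean
  mu <- colMeans(cnt)
  se <- sqrt(mu / nrow(cnt))      # Poisson variance equals the mean
  varObs <- apply(cnt, 2, var)
  # Poisson: variance matches mean within sampling error for most genes
  ratio <- varObs[mu > 1] / mu[mu > 1]
  expect_lt(abs(median(ratio) - 1), 0.15)
  expect_equal(sum(mu), 500, tolerance = 0.05 * 500)
  expect_true(all(is.finite(se)))
})

test_that("library factors follow the requested log-normal scale", {
  topo <- makeTopology(data.frame(from = "0", to = "1"), root = "0")
  sim <- simulateLineage(topo, c(`1` = 1200L), nGenes = 50,
                         libsizeSigma = 0.7, seed = 6)
  lf <- simCellInfo(sim)$library_factor
  expect_lt(abs(sd(log(lf)) - 0.7) / 0.7, 0.05)
})

test_that("the rare-lineage preset reproduces the published design", {
  sim <- lineagePreset("rare_lineage", seed = 1)
  tab <- table(simCellInfo(sim)$type)
  expect_equal(sum(tab), 1915L)
  expect_equal(as.integer(tab["E"]), 15L)
  expect_equal(as.integer(tab[c("A", "B", "C", "D")]), rep(300L, 4))
  expect_equal(as.integer(tab[c("F", "G")]), rep(350L, 2))
  expect_equal(round(100 * tab[["E"]] / sum(tab), 2), 0.78)
})

test_that("the six-bifurcation preset has the published dimensions", {
  sim <- lineagePreset("six_bifurcations", seed = 1)
  expect_equal(dim(simCounts(sim)), c(1300L, 500L))
  topo <- simTopology(sim)
  expect_length(topo@branches, 13L)
  expect_length(topologyLeaves(topo), 7L)
})

test_that("simulation is reproducible per seed and names its presets", {
  a <- lineagePreset("rare_lineage", seed = 9)
  b <- lineagePreset("rare_lineage", seed = 9)
  expect_identical(simCounts(a), simCounts(b))
  c <- lineagePreset("rare_lineage", seed = 10)
  expect_false(identical(simCounts(a), simCounts(c)))
  expect_error(lineagePreset("nope"), "rare_lineage")
})

test_that("a smaller k yields at least as many clusters on the rare preset", {
  counts <- vapply(1:2, function(seed) {
    sim <- lineagePreset("rare_lineage", seed = seed)
    em <- ExpressionMatrix(simCounts(sim), layer = "counts")
    scaled <- scaleFeatures(filterAndNormalize(em))
    coords <- selectedCoords(runPCA(scaled, nComponents = 10))
    vapply(c(4L, 12L), function(k) {
      nClusters(clusterCommunities(buildKnnGraph(coords, k), coords,
                                   seed = seed))
    }, integer(1))
  }, integer(2))
  # median over seeds: k = 4 gives at least as many clusters as k = 12,
  # the granularity that lets rare terminal types separate
  expect_gte(median(counts[1, ]), median(counts[2, ]))
})

test_that("simulated datasets round-trip through the standard formats", {
  topo <- makeTopology(data.frame(from = c("0", "1", "1"),
                                  to = c("1", "2", "3")), root = "0")
  sim <- simulateLineage(topo, c(`1` = 15L, `2` = 10L, `3` = 5L),
                         nGenes = 30, seed = 7)
  dir <- tempfile()
  writeSimDataset(sim, dir)
  back <- loadMatrix(file.path(dir, "counts.mtx"))
  expect_equal(unname(exprValues(back)), unname(simCounts(sim)))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 30L)
  ph <- ape::read.tree(file.path(dir, "topology.nwk"))
  expect_equal(sort(ph$tip.label), c("2", "3"))
})
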