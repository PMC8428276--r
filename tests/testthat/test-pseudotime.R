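# a hand-built path tree over clusters 1-2-3 with centroids on a line
pathTree <- function(lens = c(1, 1)) {
  new("TrajectoryTree", nodes = 1:3,
      edges = data.frame(parent = c(1, 2), child = c(2, 3), length = lens),
      root = 1L,
      leafFlags = stats::setNames(c(FALSE, FALSE, TRUE), as.character(1:3)),
      provenance = stats::setNames(rep("backbone", 3), as.character(1:3)),
      validation = character(0))
}

clusteringFor <- function(labels, coords, centroids = NULL) {
  if (is.null(centroids))
    centroids <- trajtree:::.centroidsOf(coords, as.integer(labels))
  new("Clustering", labels = stats::setNames(as.integer(labels),
                                             paste0("cell", seq_along(labels))),
      centroids = centroids,
      algorithm = "leiden", kUsed = 1L, seed = 0L)
}

test_that("centroid and midpoint cells get the forced edge and offset", {
  # clusters with fixed centroids at x = 0, 1, 2
  coords <- cbind(c(-0.1, 0.1, 0.9, 1.1, 1.9, 2.1, 1.5), 0)
  labels <- c(1, 1, 2, 2, 3, 3, 3)
  cents <- cbind(c(0, 1, 2), 0)
  rownames(cents) <- 1:3
  cl <- clusteringFor(labels, coords, centroids = cents)
  tree <- pathTree()
  a <- assignmentTable(mapCells(tree, cl, coords))
  # cell 7 is in cluster 3 at the midpoint of the 2 -> 3 centroid segment
  expect_equal(a$edgeParent[7], 2)
  expect_equal(a$edgeChild[7], 3)
  expect_equal(a$offset[7], 0.5, tolerance = 1e-9)
  expect_equal(a$pseudotime[7], 1 + 0.5 * 1, tolerance = 1e-9)
  # a leaf-cluster cell at the leaf centroid has offset 1 and full depth
  coords2 <- coords; coords2[6, ] <- c(2, 0)
  a2 <- assignmentTable(mapCells(tree,
                                 clusteringFor(labels, coords2,
                                               centroids = cents),
                                 coords2))
  expect_equal(a2$offset[6], 1)
  expect_equal(a2$pseudotime[6], 2)
  # offsets clamp into [0, 1] and pseudotime is nonnegative
  expect_true(all(a$offset >= 0 & a$offset <= 1))
  expect_true(all(a$pseudotime >= 0))
})

test_that("a root cell at the root centroid has pseudotime zero", {
  coords <- cbind(c(0, 0.2, 1, 2), 0)
  cl <- clusteringFor(c(1, 1, 2, 3), coords)
  a <- assignmentTable(mapCells(pathTree(), cl, coords))
  expect_equal(a$pseudotime[1], 0)
})

test_that("missing clusters are named in the error", {
  coords <- cbind(c(0, 1, 5), 0)
  cl <- clusteringFor(c(1, 2, 3), coords)
  twoNode <- new("TrajectoryTree", nodes = 1:2,
                 edges = data.frame(parent = 1, child = 2, length = 1),
                 root = 1L,
                 leafFlags = stats::setNames(c(FALSE, TRUE), c("1", "2")),
                 provenance = stats::setNames(rep("backbone", 2), c("1", "2")),
                 validation = character(0))
  expect_error(mapCells(twoNode, cl, coords), "3")
})

test_that("assigned pseudotime tracks generative time on a linear lineage", {
  rhos <- vapply(1:5, function(seed) {
    topo <- makeTopology(data.frame(from = c("0", "1", "2"),
                                    to = c("1", "2", "3")), root = "0")
    sim <- simulateLineage(topo, c(`1` = 70L, `2` = 70L, `3` = 60L),
                           nGenes = 200, seed = seed)
    em <- ExpressionMatrix(simCounts(sim), layer = "counts")
    sc <- scaleFeatures(filterAndNormalize(em))
    coords <- selectedCoords(runPCA(sc, nComponents = 5))
    g <- buildKnnGraph(coords, 8)
    cl <- clusterCommunities(g, coords, seed = seed)
    g <- bridgeComponents(g, coords)
    info <- simCellInfo(sim)
    lab <- clusterLabels(cl)
    ord <- order(info$pseudotime)
    rootCl <- as.integer(names(which.max(table(lab[head(ord, 30)]))))
    leafCl <- as.integer(names(which.max(table(lab[tail(ord, 30)]))))
    if (rootCl == leafCl) return(NA_real_)
    cg <- clusterDistances(g, cl)
    tree <- spanningTree(cg, rootCl, list(LeafGroup(leafCl)),
                         centroids = clusterCentroids(cl))
    pt <- pseudotime(mapCells(tree, cl, coords))
    cor(pt, info$pseudotime, method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos, na.rm = TRUE), 0.9)
})

test_that("branch membership equals a brute-force path test", {
  # bifurcating tree: 1 -> 2 -> {3, 4}
  tree <- new("TrajectoryTree", nodes = 1:4,
              edges = data.frame(parent = c(1, 2, 2), child = c(2, 3, 4),
                                 length = c(1, 1, 1)),
              root = 1L,
              leafFlags = stats::setNames(c(FALSE, FALSE, TRUE, TRUE),
                                          as.character(1:4)),
              provenance = stats::setNames(rep("backbone", 4),
                                           as.character(1:4)),
              validation = character(0))
  withr::with_seed(61, {
    centers <- rbind(c(0, 0), c(2, 0), c(4, 1), c(4, -1))
    labels <- sample(1:4, 80, replace = TRUE)
    coords <- centers[labels, ] + matrix(rnorm(160, 0, 0.2), 80, 2)
  })
  cl <- clusteringFor(labels, coords)
  assign <- mapCells(tree, cl, coords)
  a <- assignmentTable(assign)
  for (leaf in c(3L, 4L)) {
    got <- branchCells(assign, tree, leaf)
    pathEdges <- paste(c(1, 2), c(2, leaf))
    oracle <- which(paste(a$edgeParent, a$edgeChild) %in% pathEdges)
    expect_setequal(got, oracle)
    expect_false(is.unsorted(a$pseudotime[got]))
  }
  # a cell on the sibling branch is excluded
  sib <- which(a$edgeChild == 4)[1]
  expect_false(sib %in% branchCells(assign, tree, 3L))
  expect_error(branchCells(assign, tree, 2L), "not a leaf")
})

test_that("pseudotime is nondecreasing along every root-to-leaf centroid walk", {
  tree <- pathTree(lens = c(2, 3))
  coords <- cbind(c(0, 0.5, 2, 2.5, 5, 4.5), 0)
  cl <- clusteringFor(c(1, 1, 2, 2, 3, 3), coords)
  depths <- treeDepths(tree)
  path <- treePath(tree, 3)
  expect_false(is.unsorted(depths[as.character(path)]))
})

test_that("pseudotime CSV has normalised column and provenance header", {
  coords <- cbind(c(0, 1, 2), 0)
  cl <- clusteringFor(c(1, 2, 3), coords)
  assign <- mapCells(pathTree(), cl, coords)
  p <- tempfile(fileext = ".csv")
  writePseudotimeCSV(assign, p, header = "test-run")
  expect_match(readLines(p, n = 1), "^# test-run")
  tab <- read.csv(p, comment.char = "#")
  expect_equal(max(tab$pseudotime_norm), 1)
  expect_named(tab, c("cell_id", "pseudotime", "pseudotime_norm", "branch",
                      "edge_parent", "edge_child", "offset"))
})
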