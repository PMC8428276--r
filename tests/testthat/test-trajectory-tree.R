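# cell graph with labelled clusters, from explicit inter-cluster edges
cellGraphWithClusters <- function(labels, edges, weights) {
  e <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                  j = pmax(edges[, 1], edges[, 2]), weight = weights)
  e <- e[order(e$i, e$j), ]; rownames(e) <- NULL
  n <- length(labels)
  g <- new("CellGraph", nCells = as.integer(n), edges = e, kUsed = 1L,
           cellIds = paste0("cell", seq_len(n)))
  coords <- cbind(seq_len(n), 0)
  cl <- new("Clustering",
            labels = stats::setNames(as.integer(labels), g@cellIds),
            centroids = trajtree:::.centroidsOf(coords, as.integer(labels)),
            algorithm = "leiden", kUsed = 1L, seed = 0L)
  list(graph = g, clustering = cl)
}

test_that("neighbour distances are edge means; missing pairs are NA", {
  x <- cellGraphWithClusters(c(1, 1, 2, 2),
                             rbind(c(1, 3), c(2, 4), c(1, 2), c(3, 4)),
                             c(1, 3, 0.5, 0.5))
  cg <- clusterDistances(x$graph, x$clustering)
  expect_equal(neighborDist(cg)["1", "2"], 2)           # mean of 1 and 3
  expect_equal(neighborDist(cg)["1", "1"], 0)
})

test_that("graph distances chain through intermediate clusters", {
  # clusters A-B-C with no direct A-C edge
  x <- cellGraphWithClusters(c(1, 2, 2, 3),
                             rbind(c(1, 2), c(3, 4)), c(2, 5))
  cg <- clusterDistances(x$graph, x$clustering)
  expect_true(is.na(neighborDist(cg)["1", "3"]))
  expect_equal(graphDist(cg)["1", "3"], 2 + 5)
})

test_that("graph distances equal Floyd-Warshall on random instances", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      labels <- sample(1:5, 40, replace = TRUE)
      coords <- matrix(rnorm(80), 40, 2)
    })
    g <- buildKnnGraph(coords, 4)
    cl <- new("Clustering",
              labels = stats::setNames(as.integer(labels), cellIds(g)),
              centroids = trajtree:::.centroidsOf(coords, labels),
              algorithm = "leiden", kUsed = 4L, seed = 0L)
    cg <- clusterDistances(g, cl)
    expect_equal(unname(graphDist(cg)),
                 unname(floydWarshall(neighborDist(cg))), tolerance = 1e-10)
  }
})

test_that("backbone connects at k = 3 on a line and grows k when needed", {
  cents <- cbind(c(0, 1, 2, 3), 0)
  cg <- geometricClusterGraph(cents, reach = 1.5)
  bb <- buildBackbone(cg, root = 1, leafClusters = integer(0))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = bb$edges$a, to = bb$edges$b), directed = FALSE,
    vertices = data.frame(name = bb$nodes))
  expect_equal(igraph::components(ig)$no, 1L)
  expect_equal(bb$kUsed, 3L)
  # two separated pairs: with k pinned at 3 of 5 clusters the pairs stay
  # apart until k covers the far side
  cents2 <- cbind(c(0, 1, 2, 50, 51, 52), 0)
  cg2 <- geometricClusterGraph(cents2, reach = 100)
  bb2 <- buildBackbone(cg2, root = 1, leafClusters = integer(0))
  ig2 <- igraph::graph_from_data_frame(
    data.frame(from = bb2$edges$a, to = bb2$edges$b), directed = FALSE,
    vertices = data.frame(name = bb2$nodes))
  expect_equal(igraph::components(ig2)$no, 1L)
  # degenerate backbone over the root alone
  bb3 <- buildBackbone(geometricClusterGraph(cbind(0:2, 0), 5), root = 1,
                       leafClusters = c(2, 3))
  expect_equal(bb3$nodes, 1)
  expect_equal(nrow(bb3$edges), 0L)
})

test_that("leaf groups attach by structure", {
  # backbone cluster 1 at origin; members 2,3,4 along a line
  cents <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(0, 3))
  cg <- geometricClusterGraph(cents, reach = 3.5)
  bb <- buildBackbone(cg, root = 1, leafClusters = 2:4)
  single <- attachLeafGroups(bb, cg, list(LeafGroup(2, "mst")))
  expect_true(any(single$edges$a == 1 & single$edges$b == 2))
  lin <- attachLeafGroups(bb, cg, list(LeafGroup(c(4, 2, 3), "linear")))
  e <- lin$edges
  hasEdge <- function(a, b) any((e$a == a & e$b == b) | (e$a == b & e$b == a))
  expect_true(hasEdge(1, 2) && hasEdge(2, 3) && hasEdge(3, 4))
  expect_equal(lin$groups[[1]]@connector, 2L)
})

test_that("mst groups reproduce the exhaustive minimum spanning tree", {
  withr::with_seed(31, cents <- rbind(c(0, 0), matrix(rnorm(10, 4, 1.4), 5, 2)))
  cg <- geometricClusterGraph(cents, reach = 100)
  bb <- buildBackbone(cg, root = 1, leafClusters = 2:6)
  got <- attachLeafGroups(bb, cg, list(LeafGroup(2:6, "mst")))
  internal <- got$edges[got$edges$a %in% 2:6 & got$edges$b %in% 2:6, ]
  d <- graphDist(cg)[as.character(2:6), as.character(2:6)]
  expect_equal(sum(internal$weight), exhaustiveMSTWeight(d), tolerance = 1e-10)
})

test_that("forced chain gives root -> mid -> leaf with a degree-1 leaf", {
  cents <- cbind(c(0, 1, 2), 0)
  cg <- geometricClusterGraph(cents, reach = 1.5)
  tree <- spanningTree(cg, root = 1, groups = list(LeafGroup(3)))
  expect_equal(treeEdges(tree)$parent, c(2, 1))
  expect_equal(treeEdges(tree)$child, c(3, 2))
  expect_equal(unname(treeDegrees(tree)["3"]), 1L)
  expect_equal(treeRoot(tree), 1L)
})

test_that("a structured-leaf tree keeps declared leaves terminal and embeds the MST group", {
  # backbone arc of clusters plus a 5-member group and singleton leaves,
  # shaped after the constrained-tree use case with one MST leaf group
  withr::with_seed(32, {
    backboneC <- cbind(0:5 * 2, 0)
    groupC <- sweep(matrix(rnorm(10, 0, 0.8), 5, 2), 2, c(12, 2), "+")
    singlesC <- rbind(c(2, 3), c(6, 3), c(10, -3))
    cents <- rbind(backboneC, groupC, singlesC)
  })
  cg <- geometricClusterGraph(cents, reach = 4.5)
  groups <- c(list(LeafGroup(7:11, "mst")),
              lapply(12:14, function(m) LeafGroup(m)))
  tree <- spanningTree(cg, root = 1, groups = groups)
  deg <- treeDegrees(tree)
  expect_true(validObject(tree))
  expect_equal(length(treeEdges(tree)$parent), length(treeNodes(tree)) - 1L)
  # singleton leaves are terminal
  expect_true(all(deg[as.character(12:14)] == 1L))
  # the group's internal edges form a tree over the 5 members
  e <- treeEdges(tree)
  internal <- e[e$parent %in% 7:11 & e$child %in% 7:11, ]
  expect_equal(nrow(internal), 4L)
})

test_that("root-to-leaf path lengths are Dijkstra-minimal over the routing graph", {
  for (seed in 1:3) {
    withr::with_seed(seed + 40,
      cents <- matrix(rnorm(16, 0, 3), 8, 2))
    cg <- geometricClusterGraph(cents, reach = 100)
    leaves <- c(6, 7, 8)
    tree <- spanningTree(cg, root = 1, groups = lapply(leaves, LeafGroup))
    bb <- buildBackbone(cg, 1, leaves)
    gd <- graphDist(cg)
    routing <- bb$edges
    for (lf in leaves) {
      dl <- gd[as.character(lf), as.character(bb$nodes)]
      routing <- rbind(routing, data.frame(
        a = bb$nodes[which.min(dl)], b = lf, weight = min(dl)))
    }
    oracle <- dijkstraRef(c(bb$nodes, leaves), routing, 1)
    depths <- treeDepths(tree)
    for (lf in leaves)
      expect_equal(unname(depths[as.character(lf)]),
                   unname(oracle[as.character(lf)]), tolerance = 1e-9)
  }
})

test_that("unreachable leaves and bad roots raise informative errors", {
  cents <- rbind(c(0, 0), c(1, 0), c(50, 50))
  rownames(cents) <- 1:3
  cg <- geometricClusterGraph(cents, reach = 2)
  expect_error(spanningTree(cg, root = 1, groups = list(LeafGroup(1))),
               "root must not be")
  expect_warning(
    tr <- spanningTree(cg, root = 1, groups = list(LeafGroup(3)),
                       centroids = cents), "centroid")
  expect_true(3 %in% treeNodes(tr))
})

test_that("exploratory MST matches exhaustive enumeration", {
  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  cg3 <- new("ClusterGraph", clusters = 1:3, neighborDist = d3,
             graphDist = d3)
  m <- exploratoryMST(cg3)
  expect_equal(nrow(m), 2L)
  expect_equal(sum(m$weight), 3)         # edges {1-2, 1-3}
  for (seed in 1:3) {
    withr::with_seed(seed + 50, cents <- matrix(rnorm(14, 0, 2), 7, 2))
    cg <- geometricClusterGraph(cents, reach = 100)
    m <- exploratoryMST(cg)
    expect_equal(nrow(m), 6L)
    expect_equal(sum(m$weight), exhaustiveMSTWeight(graphDist(cg)),
                 tolerance = 1e-10)
  }
  # idempotence: feeding a tree metric back returns the same total weight
  cgT <- geometricClusterGraph(cbind(0:4, 0), reach = 1.5)
  mt <- exploratoryMST(cgT)
  expect_equal(sum(mt$weight), 4)
})

test_that("tree exports round-trip and parse", {
  cents <- cbind(0:3, 0)
  cg <- geometricClusterGraph(cents, reach = 1.5)
  tree <- spanningTree(cg, root = 1, groups = list(LeafGroup(4)))
  p <- tempfile(fileext = ".json")
  exportTree(tree, p, "json")
  back <- readTreeJSON(p)
  expect_equal(treeEdges(back), treeEdges(tree))
  expect_equal(treeRoot(back), treeRoot(tree))
  nwk <- treeToNewick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ph$tip.label, "c4")
  expect_equal(sum(ph$edge.length), sum(treeEdges(tree)$length),
               tolerance = 1e-6)
  pg <- tempfile(fileext = ".graphml")
  exportTree(tree, pg, "graphml")
  gg <- igraph::read_graph(pg, format = "graphml")
  expect_equal(igraph::gorder(gg), length(treeNodes(tree)))
})

test_that("bifurcation and branch counts follow the rooted conventions", {
  # root with two children, one child chain to a leaf:
  # 1 -> 2 -> 4, 1 -> 3 ; root has 2 children -> one bifurcation
  tr <- new("TrajectoryTree", nodes = 1:4,
            edges = data.frame(parent = c(1, 2, 1), child = c(2, 4, 3),
                               length = c(1, 1, 1)),
            root = 1L,
            leafFlags = stats::setNames(c(FALSE, FALSE, TRUE, TRUE),
                                        as.character(1:4)),
            provenance = stats::setNames(rep("backbone", 4),
                                         as.character(1:4)),
            validation = character(0))
  expect_equal(countBifurcations(tr), 1L)
  expect_equal(countBranches(tr), 2L)    # chain node 2 collapses
  # pure path keeps its single branch and no bifurcations
  path <- new("TrajectoryTree", nodes = 1:3,
              edges = data.frame(parent = c(1, 2), child = c(2, 3),
                                 length = c(1, 1)),
              root = 1L,
              leafFlags = stats::setNames(c(FALSE, FALSE, TRUE),
                                          as.character(1:3)),
              provenance = stats::setNames(rep("backbone", 3),
                                           as.character(1:3)),
              validation = character(0))
  expect_equal(countBifurcations(path), 0L)
  expect_equal(countBranches(path), 1L)
})
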