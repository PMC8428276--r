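#' Build a kNN graph over cells in PC space
#'
#' The directed k-nearest-neighbour relation (Euclidean distance, ties
#' broken by lower cell index) is symmetrised by union: an edge is kept if
#' either endpoint lists the other among its k nearest. Union rather than
#' mutual symmetrisation keeps rare cells connected to the graph.
#'
#' @param coords cells x dims coordinate matrix (e.g. [selectedCoords]).
#' @param k neighbourhood size, `1 <= k < n_cells`.
#' @return A [CellGraph-class] weighted by Euclidean distance.
#' @export
buildKnnGraph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n_cells")
  d <- as.matrix(stats::dist(coords))
  ii <- integer(0); jj <- integer(0)
  for (v in seq_len(n)) {
    ord <- order(d[v, ], seq_len(n))      # ties by lower cell index
    ord <- ord[ord != v][seq_len(k)]
    ii <- c(ii, rep.int(v, k)); jj <- c(jj, ord)
  }
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  edges <- data.frame(i = a, j = b, weight = d[cbind(a, b)])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- if (!is.null(rownames(coords))) rownames(coords)
         else paste0("cell", seq_len(n))
  new("CellGraph", nCells = as.integer(n), edges = edges,
      kUsed = as.integer(k), cellIds = ids)
}

# igraph view of a CellGraph (weighted unless weighted = FALSE)
.asIgraph <- function(graph, weighted = TRUE) {
  g <- igraph::make_empty_graph(n = graph@nCells, directed = FALSE)
  if (nrow(graph@edges)) {
    g <- igraph::add_edges(g, rbind(graph@edges$i, graph@edges$j))
    if (weighted) igraph::E(g)$weight <- graph@edges$weight
  }
  g
}

#' Cluster cells by community detection on the kNN graph
#'
#' Runs Leiden (default; modularity objective) or Louvain community
#' detection on the unweighted graph topology. Cluster ids are relabelled
#' `1..C` by decreasing size; centroids are computed from the same
#' coordinates used to build the graph.
#'
#' @param graph a [CellGraph-class].
#' @param coords the cells x dims coordinates the graph was built from.
#' @param algorithm `"leiden"` or `"louvain"`.
#' @param resolution resolution parameter (default 1).
#' @param seed RNG seed; fixed seed gives identical labels.
#' @return A [Clustering-class].
#' @export
clusterCommunities <- function(graph, coords, algorithm = c("leiden", "louvain"),
                               resolution = 1, seed = 0L) {
  stopifnot(is(graph, "CellGraph"))
  algorithm <- match.arg(algorithm)
  coords <- as.matrix(coords)
  if (nrow(coords) != graph@nCells)
    stop("coords rows must match graph nCells")
  g <- .asIgraph(graph, weighted = FALSE)
  memb <- withr::with_seed(seed, {
    if (algorithm == "leiden") {
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity",
        resolution = resolution, n_iterations = 5))
    } else {
      igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
    }
  })
  labels <- .relabelBySize(as.integer(memb))
  centroids <- .centroidsOf(coords, labels)
  names(labels) <- graph@cellIds
  new("Clustering", labels = labels, centroids = centroids,
      algorithm = algorithm, kUsed = graph@kUsed, seed = as.integer(seed))
}

.relabelBySize <- function(labels) {
  tab <- table(labels)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- integer(length(tab))
  map[as.integer(names(tab))[ord]] <- seq_along(ord)
  map[labels]
}

.centroidsOf <- function(coords, labels) {
  cl <- sort(unique(labels))
  cent <- t(vapply(cl, function(c)
    colMeans(coords[labels == c, , drop = FALSE]), numeric(ncol(coords))))
  rownames(cent) <- cl
  cent
}

#' Sweep the kNN neighbourhood size
#'
#' Clusters the cells once per k in `kValues` (default 4..20) and reports
#' the resulting cluster counts; the number of clusters tends to fall as k
#' grows, and a smaller k helps isolate rare cell types. The caller picks
#' the clustering to carry forward.
#'
#' @param coords cells x dims coordinate matrix.
#' @param kValues integer vector of neighbourhood sizes.
#' @inheritParams clusterCommunities
#' @return A list with `clusterings` (one [Clustering-class] per k) and
#'   `summary` (data.frame of k and n_clusters).
#' @export
sweepK <- function(coords, kValues = 4:20, algorithm = c("leiden", "louvain"),
                   resolution = 1, seed = 0L) {
  if (!length(kValues)) stop("kValues must be nonempty")
  algorithm <- match.arg(algorithm)
  coords <- as.matrix(coords)
  clusterings <- lapply(kValues, function(k) {
    g <- buildKnnGraph(coords, k)
    clusterCommunities(g, coords, algorithm = algorithm,
                       resolution = resolution, seed = seed)
  })
  names(clusterings) <- paste0("k", kValues)
  summary <- data.frame(
    k = as.integer(kValues),
    n_clusters = vapply(clusterings, nClusters, integer(1)))
  rownames(summary) <- NULL
  list(clusterings = clusterings, summary = summary)
}
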