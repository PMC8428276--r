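#' Find per-cluster graph hubs to use as embedding landmarks
#'
#' Within each cluster, the hub cells are those with the most kNN-graph
#' connections to other members of the same cluster (ties broken by lower
#' cell index). Hubs anchor the landmark-ISOMAP embedding. If the total
#' number of landmarks falls below `minLandmarks`, `hubsPerCluster` is
#' raised automatically until the floor is met (or clusters are exhausted).
#'
#' @param graph a [CellGraph-class].
#' @param clustering a [Clustering-class] over the same cells.
#' @param hubsPerCluster number of hubs requested per cluster (default 1).
#' @param minLandmarks landmark floor; default `max(10, n_clusters)`,
#'   never below 5 so the 3-D triangulation is well-posed.
#' @return A [LandmarkSet-class].
#' @export
findHubs <- function(graph, clustering, hubsPerCluster = 1L,
                     minLandmarks = NULL) {
  stopifnot(is(graph, "CellGraph"), is(clustering, "Clustering"))
  if (hubsPerCluster < 1L) stop("hubsPerCluster must be >= 1")
  labels <- clustering@labels
  if (length(labels) != graph@nCells)
    stop("clustering must cover all graph nodes")
  cl <- sort(unique(labels))
  if (is.null(minLandmarks)) minLandmarks <- max(10L, length(cl))
  minLandmarks <- max(5L, minLandmarks)
  # intra-cluster degree per cell
  e <- graph@edges
  sameCluster <- labels[e$i] == labels[e$j]
  deg <- integer(graph@nCells)
  if (any(sameCluster)) {
    t1 <- table(e$i[sameCluster]); t2 <- table(e$j[sameCluster])
    deg[as.integer(names(t1))] <- deg[as.integer(names(t1))] + as.integer(t1)
    deg[as.integer(names(t2))] <- deg[as.integer(names(t2))] + as.integer(t2)
  }
  maxSize <- max(table(labels))
  repeat {
    lm <- integer(0); src <- integer(0); hd <- integer(0)
    for (c in cl) {
      members <- which(labels == c)
      if (length(members) == 1L)
        warning("cluster ", c, " is a singleton; its only cell is its hub")
      ord <- members[order(-deg[members], members)]
      take <- ord[seq_len(min(hubsPerCluster, length(ord)))]
      lm <- c(lm, take)
      src <- c(src, rep.int(c, length(take)))
      hd <- c(hd, deg[take])
    }
    if (length(lm) >= minLandmarks || hubsPerCluster >= maxSize) break
    hubsPerCluster <- hubsPerCluster + 1L
  }
  new("LandmarkSet", landmarkCells = as.integer(lm),
      sourceCluster = as.integer(src), hubDegree = as.integer(hd))
}

#' Geodesic distances from landmarks to all cells
#'
#' Runs one single-source weighted shortest-path search per landmark over
#' the kNN graph (landmark-first ordering; the searches are independent).
#' Disconnected graphs are first bridged by repeatedly adding the shortest
#' Euclidean inter-component edge until one component remains, so all
#' entries are finite.
#'
#' @param graph a [CellGraph-class].
#' @param landmarks a [LandmarkSet-class] or integer vector of landmark
#'   cell indices.
#' @param coords optional cells x dims coordinates; required to bridge a
#'   disconnected graph.
#' @return landmarks x cells matrix of geodesic distances.
#' @export
geodesicsFromLandmarks <- function(graph, landmarks, coords = NULL) {
  stopifnot(is(graph, "CellGraph"))
  lm <- if (is(landmarks, "LandmarkSet")) landmarks@landmarkCells
        else as.integer(landmarks)
  graph <- bridgeComponents(graph, coords)
  g <- .asIgraph(graph)
  D <- igraph::distances(g, v = lm, algorithm = "dijkstra")
  rownames(D) <- lm
  D
}

#' Bridge disconnected components of a cell graph
#'
#' Adds the single shortest inter-component Euclidean edge, iterating until
#' the graph is connected. Returns the graph unchanged when already
#' connected.
#'
#' @inheritParams geodesicsFromLandmarks
#' @return A connected [CellGraph-class].
#' @export
bridgeComponents <- function(graph, coords = NULL) {
  g <- .asIgraph(graph)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(graph)
  if (is.null(coords))
    stop("graph is disconnected (", comp$no,
         " components); coords needed to bridge")
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  edges <- graph@edges
  memb <- comp$membership
  while (length(unique(memb)) > 1L) {
    dd <- d
    same <- outer(memb, memb, "==")
    dd[same] <- Inf
    idx <- arrayInd(which.min(dd), dim(dd))
    a <- min(idx); b <- max(idx)
    edges <- rbind(edges, data.frame(i = a, j = b, weight = d[a, b]))
    memb[memb == memb[idx[2]]] <- memb[idx[1]]
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("CellGraph", nCells = graph@nCells, edges = edges,
      kUsed = graph@kUsed, cellIds = graph@cellIds)
}

#' Landmark classical-MDS embedding (L-ISOMAP)
#'
#' Classical metric MDS on the squared landmark-landmark geodesic
#' submatrix (double centering, top-`dim` eigenpairs), followed by the
#' standard landmark triangulation: each remaining cell is placed from its
#' squared-distance vector to the landmarks via the pseudo-inverse
#' projection against the landmark column means. Axes are ordered by
#' eigenvalue and sign-fixed (largest-magnitude coordinate positive).
#' Negative eigenvalues arising from non-Euclidean geodesics are truncated
#' at zero; if fewer than `dim` positive eigenvalues exist the remaining
#' axes are zero-padded with a warning.
#'
#' @param D landmarks x cells geodesic distance matrix
#'   (from [geodesicsFromLandmarks]); rownames identify the landmark
#'   columns.
#' @param landmarks landmark cell indices (defaults to `rownames(D)`).
#' @param dim embedding dimension (default 3).
#' @return An [Embedding3D-class].
#' @export
landmarkMDSEmbed <- function(D, landmarks = NULL, dim = 3L) {
  if (is.null(landmarks)) landmarks <- as.integer(rownames(D))
  m <- length(landmarks)
  if (m != nrow(D)) stop("one landmark per row of D required")
  if (m < dim + 2L) stop("need >= dim + 2 landmarks")
  Dll2 <- D[, landmarks, drop = FALSE]^2
  J <- diag(m) - 1 / m
  B <- -0.5 * J %*% Dll2 %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values) * 1e-12 & eg$values > 0)
  kUse <- min(dim, length(pos))
  if (kUse < dim)
    warning("only ", kUse, " positive eigenvalues; padding ",
            dim - kUse, " zero axes")
  lam <- eg$values[seq_len(kUse)]
  V <- eg$vectors[, seq_len(kUse), drop = FALSE]
  L <- V %*% diag(sqrt(lam), kUse)               # landmark coordinates
  # triangulation: x_i = -1/2 * Lpinv %*% (delta_i - delta_mean)
  Lpinv <- diag(1 / sqrt(lam), kUse) %*% t(V)    # kUse x m
  deltaMean <- rowMeans(Dll2)                    # mean over landmark columns
  X <- -0.5 * t(Lpinv %*% (D^2 - deltaMean))     # cells x kUse
  X[landmarks, ] <- L                            # exact by construction
  if (kUse < dim)
    X <- cbind(X, matrix(0, nrow(X), dim - kUse))
  for (k in seq_len(dim)) {
    i <- which.max(abs(X[, k]))
    if (X[i, k] < 0) X[, k] <- -X[, k]
  }
  colnames(X) <- paste0("LIso", seq_len(dim))
  embD <- .crossDist(X[landmarks, , drop = FALSE], X)
  stress <- sqrt(sum((embD - D)^2) / sum(D^2))
  new("Embedding3D", coords = X, stress = stress,
      landmarkCoords = X[landmarks, , drop = FALSE],
      landmarkCells = as.integer(landmarks))
}

# Euclidean distances between rows of A and rows of B
.crossDist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Run the full landmark-ISOMAP embedding
#'
#' Convenience wrapper: find per-cluster hubs, compute landmark geodesics
#' (bridging disconnected components using `coords`), and embed.
#'
#' @inheritParams findHubs
#' @param coords cells x dims PC coordinates (used for bridging).
#' @param dim embedding dimension.
#' @return An [Embedding3D-class].
#' @export
runLISOMAP <- function(graph, clustering, coords, hubsPerCluster = 1L,
                       dim = 3L) {
  lm <- findHubs(graph, clustering, hubsPerCluster = hubsPerCluster)
  D <- geodesicsFromLandmarks(graph, lm, coords = coords)
  landmarkMDSEmbed(D, landmarks = lm@landmarkCells, dim = dim)
}
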