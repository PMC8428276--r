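# Independent oracles used across the suite. These are deliberately naive
# (dense loops, exhaustive enumeration) and never call the code paths they
# check.

# all-pairs shortest paths, dense triple loop; w: symmetric matrix with NA
# or Inf for absent edges
floydWarshall <- function(w) {
  n <- nrow(w)
  d <- w
  d[is.na(d)] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# single-source Dijkstra over an edge data.frame (a, b, weight)
dijkstraRef <- function(nodes, edges, source) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[as.character(source)] <- 0
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  repeat {
    cand <- names(dist)[!done & is.finite(dist)]
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    inc <- edges[edges$a == as.integer(u) | edges$b == as.integer(u), ,
                 drop = FALSE]
    for (r in seq_len(nrow(inc))) {
      v <- as.character(if (inc$a[r] == as.integer(u)) inc$b[r] else inc$a[r])
      if (dist[u] + inc$weight[r] < dist[v]) dist[v] <- dist[u] + inc$weight[r]
    }
  }
  dist
}

# minimum spanning tree weight by exhaustive enumeration over all labelled
# trees (Prufer sequences); d: full symmetric distance matrix, n <= 7
exhaustiveMSTWeight <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 7)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    prufer <- seqs[r, ]
    degree <- rep(1L, n)
    for (x in prufer) degree[x] <- degree[x] + 1L
    w <- 0
    deg <- degree
    for (x in prufer) {
      leaf <- which(deg == 1L)[1]
      w <- w + d[leaf, x]
      deg[leaf] <- 0L
      deg[x] <- deg[x] - 1L
    }
    last <- which(deg == 1L)
    w <- w + d[last[1], last[2]]
    if (w < best) best <- w
  }
  best
}

# orthogonal Procrustes residual after centering and optimal
# rotation/reflection of Y onto X (no scaling)
procrustesResidual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(sum((Yc %*% R - Xc)^2) / sum(Xc^2))
}

# isotropic Gaussian blobs
makeBlobs <- function(centers, nPer, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      sweep(matrix(rnorm(nPer * ncol(centers), 0, sd), nPer), 2,
            centers[i, ], "+")))
    list(coords = x, labels = rep(seq_len(nrow(centers)), each = nPer))
  })
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(a, maxv) {
    i <- length(a) + 1
    if (i > n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (v in seq_len(maxv + 1)) rec(c(a, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# a small ClusterGraph built from centroid geometry: clusters within
# `reach` of each other are "directly connected" with their Euclidean
# distance; used to exercise tree construction without a cell graph
geometricClusterGraph <- function(centroids, reach) {
  C <- nrow(centroids)
  nd <- matrix(NA_real_, C, C)
  d <- as.matrix(dist(centroids))
  nd[d <= reach] <- d[d <= reach]
  diag(nd) <- 0
  gd <- floydWarshall(nd)
  ids <- seq_len(C)
  dimnames(nd) <- dimnames(gd) <- list(ids, ids)
  new("ClusterGraph", clusters = as.integer(ids), neighborDist = nd,
      graphDist = gd)
}
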