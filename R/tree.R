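#' Cluster-level neighbour and geodesic distance matrices
#'
#' For each pair of clusters joined by at least one cell-level kNN edge,
#' the neighbour distance is the mean weight of the joining edges; pairs
#' with no joining edge are NA. The graph distance matrix is the all-pairs
#' shortest-path closure of the cluster-level graph whose edge weights are
#' the neighbour distances (NA treated as absent, i.e. infinite).
#'
#' @param graph a [CellGraph-class].
#' @param clustering a [Clustering-class] covering all graph nodes.
#' @return A [ClusterGraph-class].
#' @export
clusterDistances <- function(graph, clustering) {
  stopifnot(is(graph, "CellGraph"), is(clustering, "Clustering"))
  labels <- clustering@labels
  if (length(labels) != graph@nCells)
    stop("clustering must cover all graph nodes")
  cl <- sort(unique(labels))
  C <- length(cl)
  nd <- matrix(NA_real_, C, C, dimnames = list(cl, cl))
  diag(nd) <- 0
  e <- graph@edges
  a <- labels[e$i]; b <- labels[e$j]
  cross <- a != b
  if (any(cross)) {
    key <- paste(pmin(a, b)[cross], pmax(a, b)[cross])
    means <- tapply(e$weight[cross], key, mean)
    for (k in names(means)) {
      ij <- as.integer(strsplit(k, " ")[[1]])
      i <- match(ij[1], cl); j <- match(ij[2], cl)
      nd[i, j] <- nd[j, i] <- means[[k]]
    }
  }
  gd <- .shortestPathClosure(nd)
  dimnames(gd) <- dimnames(nd)
  new("ClusterGraph", clusters = as.integer(cl), neighborDist = nd,
      graphDist = gd)
}

# all-pairs shortest paths over a symmetric matrix with NA = no edge
.shortestPathClosure <- function(nd) {
  C <- nrow(nd)
  el <- which(upper.tri(nd) & !is.na(nd), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = C, directed = FALSE)
  if (nrow(el)) {
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- nd[el]
  }
  gd <- igraph::distances(g, algorithm = "dijkstra")
  diag(gd) <- 0
  gd
}

#' Build the backbone kNN graph over non-leaf clusters
#'
#' A kNN graph over the non-leaf clusters using the geodesic cluster
#' distances as the metric. The neighbour size starts at 3 and is
#' incremented until the graph is connected (capped at one less than the
#' number of non-leaf clusters; reaching the cap while disconnected is an
#' error naming the components).
#'
#' @param cg a [ClusterGraph-class].
#' @param root root cluster id (must not be a leaf cluster).
#' @param leafClusters integer ids of all user-declared leaf clusters.
#' @return A list with `nodes` (non-leaf cluster ids), `edges`
#'   (data.frame `a`, `b`, `weight`) and `kUsed`.
#' @export
buildBackbone <- function(cg, root, leafClusters = integer(0)) {
  stopifnot(is(cg, "ClusterGraph"))
  root <- as.integer(root)
  if (root %in% leafClusters) stop("root must not be in any leaf group")
  if (!root %in% cg@clusters) stop("root cluster ", root, " not found")
  nonLeaf <- setdiff(cg@clusters, as.integer(leafClusters))
  n <- length(nonLeaf)
  if (n < 2L)
    return(list(nodes = root, edges = data.frame(
      a = integer(0), b = integer(0), weight = numeric(0)), kUsed = 0L))
  idx <- match(nonLeaf, cg@clusters)
  d <- cg@graphDist[idx, idx, drop = FALSE]
  for (k in 3:max(3, n - 1)) {
    kk <- min(k, n - 1)
    ii <- integer(0); jj <- integer(0)
    for (v in seq_len(n)) {
      ord <- order(d[v, ], seq_len(n))
      ord <- ord[ord != v]
      ord <- ord[is.finite(d[v, ord])]
      ord <- ord[seq_len(min(kk, length(ord)))]
      ii <- c(ii, rep.int(v, length(ord))); jj <- c(jj, ord)
    }
    a <- pmin(ii, jj); b <- pmax(ii, jj)
    keep <- !duplicated(cbind(a, b))
    a <- a[keep]; b <- b[keep]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(a, b))
    comp <- igraph::components(g)
    if (comp$no == 1L) {
      edges <- data.frame(a = nonLeaf[a], b = nonLeaf[b],
                          weight = d[cbind(a, b)])
      edges <- edges[order(edges$a, edges$b), , drop = FALSE]
      rownames(edges) <- NULL
      return(list(nodes = nonLeaf, edges = edges, kUsed = as.integer(kk)))
    }
    if (kk >= n - 1)
      stop("backbone never connects: components {",
           paste(tapply(nonLeaf, comp$membership, paste, collapse = ","),
                 collapse = "} {"), "}")
  }
}

#' Attach structured leaf groups to the backbone
#'
#' Each group's connector is the member with minimal geodesic cluster
#' distance to any non-leaf cluster; the connector is linked to that
#' nearest non-leaf cluster. The group's internal structure is then added:
#' `parallel` links every member independently to the attachment cluster,
#' `linear` chains members by increasing distance from the attachment
#' (connector first), `mst` builds a minimum spanning tree over the
#' member-to-member distances and attaches it via the connector. Members
#' unreachable in geodesic distance fall back to centroid Euclidean
#' distance with a warning.
#'
#' @param backbone result of [buildBackbone].
#' @param cg a [ClusterGraph-class].
#' @param groups list of [LeafGroup-class] objects.
#' @param centroids optional cluster centroid matrix (rownames = cluster
#'   ids) for the unreachable-member fallback.
#' @return A list with `edges` (augmented edge data.frame `a`, `b`,
#'   `weight`) and `groups` (connectors filled in).
#' @export
attachLeafGroups <- function(backbone, cg, groups, centroids = NULL) {
  stopifnot(is(cg, "ClusterGraph"))
  edges <- backbone$edges
  nonLeaf <- backbone$nodes
  allMembers <- unlist(lapply(groups, function(g) g@members))
  if (anyDuplicated(allMembers))
    stop("leaf-group members must be disjoint across groups")
  gd <- cg@graphDist
  cid <- as.character(cg@clusters)
  dist2 <- function(a, b) {
    d <- gd[match(a, cg@clusters), match(b, cg@clusters)]
    if (!is.finite(d)) {
      if (is.null(centroids))
        stop("clusters ", a, " and ", b,
             " are unreachable and no centroids were given")
      warning("clusters ", a, " and ", b,
              " unreachable by graph distance; using centroid distance")
      d <- sqrt(sum((centroids[as.character(a), ] -
                     centroids[as.character(b), ])^2))
    }
    d
  }
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    members <- grp@members
    # connector: member closest to any non-leaf cluster
    best <- t(vapply(members, function(m) {
      dd <- vapply(nonLeaf, function(nl) dist2(m, nl), numeric(1))
      c(min(dd), nonLeaf[which.min(dd)])
    }, numeric(2)))
    ci <- which.min(best[, 1])
    connector <- members[ci]
    attachment <- as.integer(best[ci, 2])
    grp@connector <- as.integer(connector)
    groups[[gi]] <- grp
    add <- switch(grp@structure,
      parallel = data.frame(
        a = rep.int(attachment, length(members)), b = members,
        weight = vapply(members, function(m) dist2(attachment, m), numeric(1))),
      linear = {
        dFromAtt <- vapply(members, function(m) dist2(attachment, m), numeric(1))
        chain <- members[order(dFromAtt, members)]
        from <- c(attachment, chain[-length(chain)])
        data.frame(a = from, b = chain,
                   weight = mapply(dist2, from, chain))
      },
      mst = {
        internal <- .mstEdges(members, function(a, b) dist2(a, b))
        rbind(data.frame(a = attachment, b = connector,
                         weight = dist2(attachment, connector)),
              internal)
      })
    edges <- rbind(edges, add)
  }
  a <- pmin(edges$a, edges$b); b <- pmax(edges$a, edges$b)
  edges <- data.frame(a = a, b = b, weight = edges$weight)
  edges <- edges[!duplicated(edges[c("a", "b")]), , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, groups = groups)
}

# Prim MST over an id vector with a distance callback
.mstEdges <- function(ids, distFun) {
  n <- length(ids)
  if (n < 2) return(data.frame(a = integer(0), b = integer(0),
                               weight = numeric(0)))
  inTree <- c(TRUE, rep(FALSE, n - 1))
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  while (!all(inTree)) {
    best <- c(Inf, NA, NA)
    for (u in which(inTree)) for (v in which(!inTree)) {
      d <- distFun(ids[u], ids[v])
      if (d < best[1] ||
          (is.finite(best[1]) && d == best[1] && (ids[u] < ids[best[2]] ||
            (ids[u] == ids[best[2]] && ids[v] < ids[best[3]])))) {
        best <- c(d, u, v)
      }
    }
    ea <- c(ea, ids[best[2]]); eb <- c(eb, ids[best[3]]); ew <- c(ew, best[1])
    inTree[best[3]] <- TRUE
  }
  data.frame(a = ea, b = eb, weight = ew)
}

# Dijkstra over an edge data.frame; nodes are arbitrary integer ids.
# Equal-cost ties prefer the deepest predecessor (largest dist[u]), then the
# lexicographically smallest id. Because the cluster graph distances form a
# metric closure, a direct edge and the chain through intermediate clusters
# often cost exactly the same; preferring the deepest predecessor routes
# paths through every intermediate cluster instead of star-collapsing the
# tree onto hub nodes.
.dijkstraLex <- function(nodes, edges, source, sinks = integer(0)) {
  n <- length(nodes)
  adj <- stats::setNames(vector("list", n), as.character(nodes))
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges$a[r]); b <- as.character(edges$b[r])
    w <- edges$weight[r]
    adj[[a]] <- rbind(adj[[a]], c(edges$b[r], w))
    adj[[b]] <- rbind(adj[[b]], c(edges$a[r], w))
  }
  dist <- stats::setNames(rep(Inf, n), as.character(nodes))
  pred <- stats::setNames(rep(NA_integer_, n), as.character(nodes))
  done <- stats::setNames(rep(FALSE, n), as.character(nodes))
  dist[as.character(source)] <- 0
  repeat {
    cand <- names(dist)[!done & is.finite(dist)]
    if (!length(cand)) break
    u <- cand[order(dist[cand], as.integer(cand))][1]
    done[u] <- TRUE
    if (as.integer(u) %in% sinks) next   # paths never pass through sinks
    nb <- adj[[u]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      v <- as.character(as.integer(nb[r, 1])); w <- nb[r, 2]
      nd <- dist[u] + w
      if (!is.finite(dist[v])) {
        dist[v] <- nd
        pred[v] <- as.integer(u)
        next
      }
      eps <- 1e-9 * (1 + abs(dist[v]))
      better <- nd < dist[v] - eps
      tie <- !better && abs(nd - dist[v]) <= eps
      if (tie && !is.na(pred[v])) {
        dp <- dist[as.character(pred[v])]
        tie <- dist[u] > dp + eps ||
          (abs(dist[u] - dp) <= eps && as.integer(u) < pred[v])
      }
      if (better || tie) {
        dist[v] <- min(dist[v], nd)
        pred[v] <- as.integer(u)
      }
    }
  }
  list(dist = dist, pred = pred)
}

#' Build the rooted spanning tree with specified root and leaf groups
#'
#' The core constrained tree construction: (1) build the backbone kNN graph
#' over non-leaf clusters ([buildBackbone]); (2) connect each leaf group's
#' connector (its member nearest to the backbone) to the backbone through
#' the connector's direct neighbour edges, treating leaf clusters as path
#' sinks; (3) trace the shortest path from the root to every leaf
#' connector and take the union of those paths — the path itself selects
#' each group's attachment cluster from the root side, and equal-cost ties
#' prefer the deepest predecessor so chains of intermediate clusters stay
#' on the paths. Multi-member groups are then expanded behind their
#' connector (`parallel` / `linear` / `mst`, see [attachLeafGroups] for
#' the same semantics on a free-standing graph). Non-leaf clusters on no
#' path are merged in afterwards by linking each to its nearest on-tree
#' non-leaf cluster (provenance `attached_isolated`). The validation
#' report lists any non-leaf node of degree 1 and any declared leaf
#' cluster that ends up interior (possible inside `linear`/`mst` groups).
#'
#' @param cg a [ClusterGraph-class].
#' @param root root cluster id.
#' @param groups list of [LeafGroup-class] objects.
#' @param centroids optional centroid matrix for unreachable-member
#'   fallback.
#' @return A [TrajectoryTree-class].
#' @export
spanningTree <- function(cg, root, groups, centroids = NULL,
                         attachMode = c("nearest", "path")) {
  attachMode <- match.arg(attachMode)
  stopifnot(is(cg, "ClusterGraph"))
  root <- as.integer(root)
  groups <- lapply(groups, function(g) {
    if (is(g, "LeafGroup")) g else LeafGroup(g)
  })
  leafClusters <- unlist(lapply(groups, function(g) g@members))
  backbone <- buildBackbone(cg, root, leafClusters)
  nonLeaf <- backbone$nodes
  gd <- cg@graphDist
  gdAt <- function(a, b) gd[match(a, cg@clusters), match(b, cg@clusters)]
  # connector of each group: member nearest (graph distance) to the backbone
  connectors <- vapply(groups, function(grp) {
    dmin <- vapply(grp@members, function(m)
      min(gdAt(m, nonLeaf)), numeric(1))
    grp@members[which.min(dmin)]
  }, integer(1))
  # routing graph: backbone edges plus, per group, the connector's direct
  # neighbour edges to non-leaf clusters (falling back to its single
  # nearest non-leaf by graph distance when no direct edge exists);
  # connectors are path sinks, so the root-to-leaf shortest path itself
  # chooses each group's attachment cluster
  routeEdges <- backbone$edges
  for (ci in connectors) {
    ndRow <- cg@neighborDist[match(ci, cg@clusters), match(nonLeaf, cg@clusters)]
    direct <- which(!is.na(ndRow) & nonLeaf != ci)
    if (attachMode == "nearest") {
      dAll <- gdAt(ci, nonLeaf)
      if (all(!is.finite(dAll))) direct <- integer(0)   # centroid fallback below
      else {
        routeEdges <- rbind(routeEdges, data.frame(
          a = nonLeaf[which.min(dAll)], b = ci, weight = min(dAll, na.rm = TRUE)))
        next
      }
    }
    if (length(direct)) {
      add <- data.frame(a = nonLeaf[direct], b = ci, weight = ndRow[direct])
    } else {
      dAll <- gdAt(ci, nonLeaf)
      if (all(!is.finite(dAll))) {
        if (is.null(centroids))
          stop("leaf cluster ", ci, " unreachable and no centroids given")
        warning("leaf cluster ", ci,
                " unreachable by graph distance; using centroid distance")
        dAll <- sqrt(colSums((t(centroids[as.character(nonLeaf), , drop = FALSE]) -
                              centroids[as.character(ci), ])^2))
      }
      add <- data.frame(a = nonLeaf[which.min(dAll)], b = ci,
                        weight = min(dAll, na.rm = TRUE))
    }
    routeEdges <- rbind(routeEdges, add)
  }
  nodesAll <- sort(unique(c(nonLeaf, connectors)))
  sp <- .dijkstraLex(nodesAll, routeEdges, root, sinks = connectors)
  if (any(!is.finite(sp$dist[as.character(connectors)]))) {
    bad <- connectors[!is.finite(sp$dist[as.character(connectors)])]
    stop("leaf cluster(s) ", paste(bad, collapse = ", "),
         " unreachable from root ", root)
  }
  # union of root -> connector paths via predecessor pointers
  edgeKey <- character(0)
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  addEdge <- function(p, v, w) {
    key <- paste(p, v)
    if (!(key %in% edgeKey)) {
      edgeKey <<- c(edgeKey, key)
      parent <<- c(parent, p); child <<- c(child, v); len <<- c(len, w)
    }
  }
  addPath <- function(leaf) {
    v <- leaf
    while (v != root) {
      p <- sp$pred[[as.character(v)]]
      addEdge(p, v, sp$dist[[as.character(v)]] - sp$dist[[as.character(p)]])
      v <- p
    }
  }
  for (ci in connectors) addPath(ci)
  # expand multi-member groups behind their connector
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    ci <- connectors[gi]
    rest <- setdiff(grp@members, ci)
    if (!length(rest)) next
    attachment <- sp$pred[[as.character(ci)]]
    if (grp@structure == "parallel") {
      for (m in rest) addEdge(attachment, m, gdAt(attachment, m))
    } else if (grp@structure == "linear") {
      dFromAtt <- gdAt(attachment, grp@members)
      chain <- grp@members[order(dFromAtt, grp@members)]
      from <- c(attachment, chain[-length(chain)])
      for (r in seq_along(chain))
        if (chain[r] != ci || from[r] != attachment)
          addEdge(from[r], chain[r], gdAt(from[r], chain[r]))
    } else {
      internal <- .mstEdges(grp@members, function(a, b) gdAt(a, b))
      # orient internal MST edges away from the connector
      adjI <- stats::setNames(vector("list", length(grp@members)),
                              as.character(grp@members))
      for (r in seq_len(nrow(internal))) {
        adjI[[as.character(internal$a[r])]] <-
          rbind(adjI[[as.character(internal$a[r])]],
                c(internal$b[r], internal$weight[r]))
        adjI[[as.character(internal$b[r])]] <-
          rbind(adjI[[as.character(internal$b[r])]],
                c(internal$a[r], internal$weight[r]))
      }
      queue <- ci; seen <- ci
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        nb <- adjI[[as.character(u)]]
        if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
          v <- as.integer(nb[r, 1])
          if (!(v %in% seen)) {
            addEdge(u, v, nb[r, 2])
            seen <- c(seen, v); queue <- c(queue, v)
          }
        }
      }
    }
  }
  onTree <- unique(c(root, parent, child))
  provenance <- stats::setNames(
    ifelse(onTree %in% leafClusters, "leaf", "backbone"),
    as.character(onTree))
  # merge isolated non-leaf clusters: nearest on-tree NON-LEAF cluster by
  # graph dist (attaching to a declared leaf would break its degree-1 rule)
  isolated <- setdiff(backbone$nodes, onTree)
  validation <- character(0)
  while (length(isolated)) {
    attachable <- setdiff(onTree, leafClusters)
    dSub <- cg@graphDist[match(isolated, cg@clusters),
                         match(attachable, cg@clusters), drop = FALSE]
    dSub[!is.finite(dSub)] <- NA
    if (all(is.na(dSub))) stop("isolated non-leaf clusters unreachable: ",
                               paste(isolated, collapse = ", "))
    idx <- arrayInd(which.min(dSub), dim(dSub))
    iso <- isolated[idx[1]]; near <- attachable[idx[2]]
    parent <- c(parent, near); child <- c(child, iso)
    len <- c(len, dSub[idx])
    onTree <- c(onTree, iso)
    provenance[as.character(iso)] <- "attached_isolated"
    isolated <- setdiff(isolated, iso)
  }
  edges <- data.frame(parent = parent, child = child, length = len)
  nodes <- sort(unique(c(root, edges$parent, edges$child)))
  deg <- stats::setNames(integer(length(nodes)), as.character(nodes))
  for (v in c(edges$parent, edges$child))
    deg[as.character(v)] <- deg[as.character(v)] + 1L
  leafFlags <- stats::setNames(
    nodes %in% leafClusters & deg[as.character(nodes)] == 1L,
    as.character(nodes))
  interiorDeclared <- leafClusters[deg[as.character(leafClusters)] > 1L]
  if (length(interiorDeclared))
    validation <- c(validation, paste0(
      "declared leaf cluster(s) interior to the tree (degree > 1): ",
      paste(interiorDeclared, collapse = ", ")))
  pendantNonLeaf <- nodes[!(nodes %in% leafClusters) & nodes != root &
                          deg[as.character(nodes)] == 1L]
  if (length(pendantNonLeaf))
    validation <- c(validation, paste0(
      "non-leaf cluster(s) of degree 1: ",
      paste(pendantNonLeaf, collapse = ", ")))
  new("TrajectoryTree", nodes = as.integer(nodes), edges = edges,
      root = root, leafFlags = leafFlags, provenance = provenance,
      validation = validation)
}

#' Exploratory minimum spanning tree over clusters
#'
#' An unrooted MST over the geodesic cluster distances, for exploratory
#' analysis when no root/leaf knowledge is available. A disconnected
#' cluster graph yields a per-component spanning forest with a warning.
#'
#' @param cg a [ClusterGraph-class].
#' @return data.frame of MST edges (`a`, `b`, `weight`).
#' @export
exploratoryMST <- function(cg) {
  stopifnot(is(cg, "ClusterGraph"))
  C <- length(cg@clusters)
  el <- which(upper.tri(cg@graphDist) & is.finite(cg@graphDist),
              arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = C, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- cg@graphDist[el]
  if (igraph::components(g)$no > 1L)
    warning("cluster graph disconnected; returning a spanning forest")
  m <- igraph::mst(g)
  em <- igraph::as_edgelist(m)
  edges <- data.frame(a = cg@clusters[pmin(em[, 1], em[, 2])],
                      b = cg@clusters[pmax(em[, 1], em[, 2])],
                      weight = igraph::E(m)$weight)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export a trajectory tree
#'
#' Writes the tree as JSON (nodes, edges, lengths, provenance), Newick
#' (cluster ids as labels, edge lengths as branch lengths) or GraphML.
#'
#' @param tree a [TrajectoryTree-class].
#' @param path output file.
#' @param format `"json"`, `"newick"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportTree <- function(tree, path, format = c("json", "newick", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      root = tree@root,
      nodes = tree@nodes,
      provenance = as.list(tree@provenance),
      leaf_flags = as.list(tree@leafFlags),
      edges = tree@edges,
      validation = tree@validation)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "newick") {
    writeLines(treeToNewick(tree), path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(tree@edges$parent),
                 to = as.character(tree@edges$child),
                 weight = tree@edges$length),
      directed = TRUE,
      vertices = data.frame(name = as.character(tree@nodes),
                            provenance = tree@provenance[as.character(tree@nodes)]))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Newick string for a trajectory tree
#'
#' Cluster ids become labels and edge lengths branch lengths; the result
#' is readable by standard Newick parsers (e.g. `ape::read.tree`).
#' @param tree a [TrajectoryTree-class]
#' @export
treeToNewick <- function(tree) {
  e <- tree@edges
  rec <- function(v) {
    ch <- e$child[e$parent == v]
    lab <- paste0("c", v)
    if (!length(ch)) return(lab)
    lens <- e$length[match(ch, e$child)]
    paste0("(", paste0(vapply(ch, rec, character(1)), ":",
                       format(lens, trim = TRUE), collapse = ","),
           ")", lab)
  }
  paste0(rec(tree@root), ";")
}
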