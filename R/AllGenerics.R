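# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname ExpressionMatrix-class
#' @param object an object
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellIds", "ExpressionMatrix", function(object) object@cellIds)
#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellIds", "CellGraph", function(object) object@cellIds)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname ExpressionMatrix-class
#' @export
setMethod("featureIds", "ExpressionMatrix", function(object) object@featureIds)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("layerTag", function(object) standardGeneric("layerTag"))
#' @rdname ExpressionMatrix-class
#' @export
setMethod("layerTag", "ExpressionMatrix", function(object) object@layer)

#' @rdname PCSpace-class
#' @param object an object
#' @export
setGeneric("pcCoords", function(object) standardGeneric("pcCoords"))
#' @rdname PCSpace-class
#' @export
setMethod("pcCoords", "PCSpace", function(object) object@coords)

#' Selected-PC coordinates
#'
#' Returns the cells x `nSelected` submatrix of the PC scores.
#' @param object a [PCSpace-class]
#' @export
selectedCoords <- function(object) {
  stopifnot(is(object, "PCSpace"))
  object@coords[, seq_len(object@nSelected), drop = FALSE]
}

#' @rdname PCSpace-class
#' @export
setGeneric("pcRotation", function(object) standardGeneric("pcRotation"))
#' @rdname PCSpace-class
#' @export
setMethod("pcRotation", "PCSpace", function(object) object@rotation)

#' @rdname PCSpace-class
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname PCSpace-class
#' @export
setMethod("explainedVariance", "PCSpace", function(object) object@explainedVariance)

#' @rdname CellGraph-class
#' @param object an object
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname CellGraph-class
#' @export
setMethod("graphEdges", "CellGraph", function(object) object@edges)

#' @rdname Clustering-class
#' @param object an object
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname Clustering-class
#' @export
setMethod("clusterLabels", "Clustering", function(object) object@labels)

#' @rdname Clustering-class
#' @export
setGeneric("clusterCentroids", function(object) standardGeneric("clusterCentroids"))
#' @rdname Clustering-class
#' @export
setMethod("clusterCentroids", "Clustering", function(object) object@centroids)

#' @rdname Embedding3D-class
#' @param object an object
#' @export
setGeneric("embeddingCoords", function(object) standardGeneric("embeddingCoords"))
#' @rdname Embedding3D-class
#' @export
setMethod("embeddingCoords", "Embedding3D", function(object) object@coords)

#' @rdname ClusterGraph-class
#' @param object an object
#' @export
setGeneric("neighborDist", function(object) standardGeneric("neighborDist"))
#' @rdname ClusterGraph-class
#' @export
setMethod("neighborDist", "ClusterGraph", function(object) object@neighborDist)

#' @rdname ClusterGraph-class
#' @export
setGeneric("graphDist", function(object) standardGeneric("graphDist"))
#' @rdname ClusterGraph-class
#' @export
setMethod("graphDist", "ClusterGraph", function(object) object@graphDist)

#' @rdname TrajectoryTree-class
#' @param object an object
#' @export
setGeneric("treeEdges", function(object) standardGeneric("treeEdges"))
#' @rdname TrajectoryTree-class
#' @export
setMethod("treeEdges", "TrajectoryTree", function(object) object@edges)

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeRoot", function(object) standardGeneric("treeRoot"))
#' @rdname TrajectoryTree-class
#' @export
setMethod("treeRoot", "TrajectoryTree", function(object) object@root)

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))
#' @rdname TrajectoryTree-class
#' @export
setMethod("treeNodes", "TrajectoryTree", function(object) object@nodes)

#' Node degrees of a trajectory tree
#' @param tree a [TrajectoryTree-class]
#' @return named integer vector of degrees (undirected).
#' @export
treeDegrees <- function(tree) .treeDegree(tree)

#' Leaves of a trajectory tree
#'
#' Degree-1 nodes other than the root.
#' @param tree a [TrajectoryTree-class]
#' @export
treeLeaves <- function(tree) {
  deg <- .treeDegree(tree)
  nodes <- as.integer(names(deg)[deg == 1L])
  setdiff(nodes, tree@root)
}

#' Cumulative root-to-node path lengths
#' @param tree a [TrajectoryTree-class]
#' @return named numeric vector of depths (root depth 0).
#' @export
treeDepths <- function(tree) {
  depth <- stats::setNames(rep(NA_real_, length(tree@nodes)),
                           as.character(tree@nodes))
  depth[as.character(tree@root)] <- 0
  e <- tree@edges
  queue <- tree@root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    ch <- e[e$parent == u, , drop = FALSE]
    for (r in seq_len(nrow(ch))) {
      depth[as.character(ch$child[r])] <- depth[as.character(u)] + ch$length[r]
      queue <- c(queue, ch$child[r])
    }
  }
  depth
}

# drop subtrees hanging off attached_isolated nodes: those clusters are
# merged in so the tree spans every cluster, but they are not part of the
# root-to-leaf trajectory system
.trajectoryEdges <- function(tree) {
  e <- tree@edges
  iso <- as.integer(names(tree@provenance)[tree@provenance ==
                                           "attached_isolated"])
  if (!length(iso)) return(e)
  drop <- iso
  repeat {
    more <- e$child[e$parent %in% drop & !(e$child %in% drop)]
    if (!length(more)) break
    drop <- c(drop, more)
  }
  e[!(e$child %in% drop), , drop = FALSE]
}

#' Count bifurcation nodes of a rooted trajectory tree
#'
#' A bifurcation is a node where the trajectory splits: a node with at
#' least two children in the rooted tree. This counts the root when it has
#' two or more children (the root is a split point even though its
#' undirected degree is only 2), matching how split points are counted on
#' trajectory figures. With `trajectoryOnly = TRUE`, clusters merged in
#' as `attached_isolated` — spanning bookkeeping, not part of any
#' root-to-leaf path — are excluded first; by default every node the tree
#' shows is counted.
#' @param tree a [TrajectoryTree-class]
#' @param trajectoryOnly drop `attached_isolated` side nodes before
#'   counting.
#' @export
countBifurcations <- function(tree, trajectoryOnly = FALSE) {
  e <- if (trajectoryOnly) .trajectoryEdges(tree) else tree@edges
  if (!nrow(e)) return(0L)
  kids <- table(e$parent)
  sum(kids >= 2L)
}

#' Count branches after collapsing chain nodes
#'
#' Contracts every non-root node with exactly one parent and one child
#' (an undirected degree-2 chain node) and returns the number of
#' remaining edges — the number of biological branch segments between the
#' root, the bifurcation points and the leaves. The root is never
#' collapsed: a two-child root is a genuine split point. With
#' `trajectoryOnly = TRUE`, `attached_isolated` side nodes are excluded
#' before collapsing, as in [countBifurcations].
#' @param tree a [TrajectoryTree-class]
#' @param trajectoryOnly drop `attached_isolated` side nodes first.
#' @export
countBranches <- function(tree, trajectoryOnly = FALSE) {
  sub <- tree
  if (trajectoryOnly) {
    e <- .trajectoryEdges(tree)
    nodes <- sort(unique(c(tree@root, e$parent, e$child)))
    sub <- new("TrajectoryTree", nodes = as.integer(nodes), edges = e,
               root = tree@root,
               leafFlags = tree@leafFlags[as.character(nodes)],
               provenance = tree@provenance[as.character(nodes)],
               validation = character(0))
  }
  tree <- sub
  deg <- .treeDegree(tree)
  if (length(tree@nodes) <= 1L) return(0L)
  collapse <- deg == 2L
  collapse[as.character(tree@root)] <- FALSE
  keep <- as.integer(names(deg)[!collapse])
  # walk from each kept node along each incident edge until the next kept node
  adj <- .treeAdjacency(tree)
  nBranch <- 0L
  visited <- character()
  for (v in keep) {
    for (w in adj[[as.character(v)]]) {
      key <- paste(sort(c(v, w)), collapse = "-")
      if (key %in% visited) next
      prev <- v; cur <- w
      while (collapse[as.character(cur)]) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        visited <- c(visited, paste(sort(c(prev, cur)), collapse = "-"))
        prev <- cur; cur <- nxt
      }
      visited <- c(visited, paste(sort(c(prev, cur)), collapse = "-"),
                   paste(sort(c(v, w)), collapse = "-"))
      nBranch <- nBranch + 1L
    }
  }
  nBranch
}

.treeAdjacency <- function(tree) {
  adj <- stats::setNames(vector("list", length(tree@nodes)),
                         as.character(tree@nodes))
  for (r in seq_len(nrow(tree@edges))) {
    p <- tree@edges$parent[r]; c <- tree@edges$child[r]
    adj[[as.character(p)]] <- c(adj[[as.character(p)]], c)
    adj[[as.character(c)]] <- c(adj[[as.character(c)]], p)
  }
  adj
}

#' Root-to-node path in a trajectory tree
#' @param tree a [TrajectoryTree-class]
#' @param node target node id
#' @return integer vector of nodes from root to `node` inclusive.
#' @export
treePath <- function(tree, node) {
  stopifnot(node %in% tree@nodes)
  par <- stats::setNames(tree@edges$parent, as.character(tree@edges$child))
  path <- node
  while (path[1] != tree@root) {
    path <- c(par[[as.character(path[1])]], path)
  }
  path
}

#' @rdname PseudotimeAssignment-class
#' @param object an object
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))
#' @rdname PseudotimeAssignment-class
#' @export
setMethod("pseudotime", "PseudotimeAssignment", function(object) {
  stats::setNames(object@assignment$pseudotime, object@assignment$cellId)
})

#' @rdname PseudotimeAssignment-class
#' @export
setGeneric("assignmentTable", function(object) standardGeneric("assignmentTable"))
#' @rdname PseudotimeAssignment-class
#' @export
setMethod("assignmentTable", "PseudotimeAssignment", function(object) object@assignment)

#' @rdname SimDataset-class
#' @param object an object
#' @export
setGeneric("simCounts", function(object) standardGeneric("simCounts"))
#' @rdname SimDataset-class
#' @export
setMethod("simCounts", "SimDataset", function(object) object@counts)

#' @rdname SimDataset-class
#' @export
setGeneric("simCellInfo", function(object) standardGeneric("simCellInfo"))
#' @rdname SimDataset-class
#' @export
setMethod("simCellInfo", "SimDataset", function(object) object@cellInfo)

#' @rdname SimDataset-class
#' @export
setGeneric("simTopology", function(object) standardGeneric("simTopology"))
#' @rdname SimDataset-class
#' @export
setMethod("simTopology", "SimDataset", function(object) object@topology)

#' @rdname TrendResult-class
#' @param object an object
#' @export
setGeneric("trendRanks", function(object) standardGeneric("trendRanks"))
#' @rdname TrendResult-class
#' @export
setMethod("trendRanks", "TrendResult", function(object) object@ranks)
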