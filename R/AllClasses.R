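#' @import methods
NULL

.LAYERS <- c("counts", "lognorm", "scaled", "zscore")

#' ExpressionMatrix: cells x features expression values
#'
#' Container for a single-cell expression matrix in cells x features
#' orientation with a layer tag recording the transformation state of the
#' values (`counts`, `lognorm`, `scaled` or `zscore`).
#'
#' @slot values numeric matrix, cells in rows, features in columns.
#' @slot cellIds character vector of unique cell identifiers.
#' @slot featureIds character vector of unique feature identifiers.
#' @slot layer one of `"counts"`, `"lognorm"`, `"scaled"`, `"zscore"`.
#'
#' @examples
#' m <- ExpressionMatrix(matrix(0:5, 3, 2), layer = "counts")
#' dim(m)
#' @export
setClass("ExpressionMatrix",
  representation(
    values = "matrix",
    cellIds = "character",
    featureIds = "character",
    layer = "character"
  )
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@cellIds))
    msg <- c(msg, "number of rows of 'values' must equal length of 'cellIds'")
  if (ncol(object@values) != length(object@featureIds))
    msg <- c(msg, "number of columns of 'values' must equal length of 'featureIds'")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "duplicate cell ids")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "duplicate feature ids")
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of: %s", paste(.LAYERS, collapse = ", ")))
  if (identical(object@layer, "counts") && length(object@values) &&
      min(object@values, na.rm = TRUE) < 0)
    msg <- c(msg, "counts layer must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, cells x features. Row/column names are used
#'   as cell/feature ids when `cellIds`/`featureIds` are missing.
#' @param cellIds,featureIds identifier vectors; defaults are taken from
#'   dimnames or generated (`cell1..`, `gene1..`).
#' @param layer transformation state of `values`.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, cellIds = NULL, featureIds = NULL,
                             layer = c("counts", "lognorm", "scaled", "zscore")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(cellIds))
    cellIds <- if (!is.null(rownames(values))) rownames(values)
               else paste0("cell", seq_len(nrow(values)))
  if (is.null(featureIds))
    featureIds <- if (!is.null(colnames(values))) colnames(values)
                  else paste0("gene", seq_len(ncol(values)))
  dimnames(values) <- list(cellIds, featureIds)
  new("ExpressionMatrix", values = values, cellIds = as.character(cellIds),
      featureIds = as.character(featureIds), layer = layer)
}

#' @describeIn ExpressionMatrix-class dimensions (cells, features)
#' @param x an `ExpressionMatrix`
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d cells x %d features [layer: %s]\n",
              nrow(object@values), ncol(object@values), object@layer))
})

#' PCSpace: principal-component coordinates
#'
#' @slot coords cells x components score matrix.
#' @slot explainedVariance per-component fraction of total variance,
#'   nonincreasing.
#' @slot nSelected number of retained components (see [selectComponents]).
#' @slot rotation features x components loading matrix.
#' @export
setClass("PCSpace",
  representation(
    coords = "matrix",
    explainedVariance = "numeric",
    nSelected = "integer",
    rotation = "matrix"
  )
)

setValidity("PCSpace", function(object) {
  msg <- character()
  if (ncol(object@coords) != length(object@explainedVariance))
    msg <- c(msg, "one explainedVariance entry per component required")
  if (length(object@explainedVariance) > 1 &&
      any(diff(object@explainedVariance) > 1e-10))
    msg <- c(msg, "explainedVariance must be nonincreasing")
  if (object@nSelected < 1L || object@nSelected > ncol(object@coords))
    msg <- c(msg, "nSelected must lie in [1, n_components]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCSpace", function(object) {
  cat(sprintf("PCSpace: %d cells x %d components (%d selected, %.1f%% variance)\n",
              nrow(object@coords), ncol(object@coords), object@nSelected,
              100 * sum(object@explainedVariance[seq_len(object@nSelected)])))
})

#' CellGraph: undirected weighted kNN graph over cells
#'
#' Edges carry the Euclidean distance between the two cells in the selected
#' principal-component space. The directed kNN relation is symmetrised by
#' union, so each unordered pair appears at most once and there are no
#' self-loops.
#'
#' @slot nCells number of cells (graph vertices).
#' @slot edges data.frame with columns `i`, `j` (1-based cell indices,
#'   `i < j`) and `weight` (>= 0).
#' @slot kUsed neighbourhood size used to build the graph.
#' @slot cellIds cell identifiers, one per vertex.
#' @export
setClass("CellGraph",
  representation(
    nCells = "integer",
    edges = "data.frame",
    kUsed = "integer",
    cellIds = "character"
  )
)

setValidity("CellGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("i", "j", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns i, j, weight")
  else {
    if (nrow(e)) {
      if (any(e$i >= e$j)) msg <- c(msg, "edges must satisfy i < j (no self-loops, one row per pair)")
      if (any(e$weight < 0)) msg <- c(msg, "edge weights must be nonnegative")
      if (max(e$j) > object@nCells) msg <- c(msg, "edge endpoint exceeds nCells")
      if (anyDuplicated(e[c("i", "j")])) msg <- c(msg, "duplicate edges")
    }
  }
  if (length(object@cellIds) && length(object@cellIds) != object@nCells)
    msg <- c(msg, "cellIds length must equal nCells")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CellGraph", function(object) {
  cat(sprintf("CellGraph: %d cells, %d edges (k = %d)\n",
              object@nCells, nrow(object@edges), object@kUsed))
})

#' Clustering: cell labels with per-cluster centroids
#'
#' Cluster ids are integers `1..C`, relabelled by decreasing cluster size for
#' stable reporting.
#'
#' @slot labels integer vector, one label per cell, named by cell id.
#' @slot centroids clusters x dims matrix of mean member coordinates in the
#'   same PC space used to build the graph; rownames are cluster ids.
#' @slot algorithm `"leiden"` or `"louvain"`.
#' @slot kUsed neighbourhood size of the underlying graph.
#' @slot seed RNG seed used for community detection.
#' @export
setClass("Clustering",
  representation(
    labels = "integer",
    centroids = "matrix",
    algorithm = "character",
    kUsed = "integer",
    seed = "integer"
  )
)

setValidity("Clustering", function(object) {
  msg <- character()
  if (any(is.na(object@labels))) msg <- c(msg, "every cell must be labelled")
  cl <- sort(unique(object@labels))
  if (length(cl) && !identical(cl, seq_along(cl)))
    msg <- c(msg, "cluster labels must be 1..C")
  if (nrow(object@centroids) != length(cl))
    msg <- c(msg, "one centroid per cluster required")
  if (!object@algorithm %in% c("leiden", "louvain"))
    msg <- c(msg, "algorithm must be leiden or louvain")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Clustering", function(object) {
  tab <- table(object@labels)
  cat(sprintf("Clustering: %d cells in %d clusters (%s, k = %d, seed = %d)\n",
              length(object@labels), length(tab), object@algorithm,
              object@kUsed, object@seed))
})

#' @rdname Clustering-class
#' @param x a `Clustering`
#' @export
nClusters <- function(x) nrow(x@centroids)

#' LandmarkSet: per-cluster graph hubs used as embedding landmarks
#'
#' @slot landmarkCells integer indices of landmark cells.
#' @slot sourceCluster cluster id of each landmark.
#' @slot hubDegree intra-cluster kNN-graph degree of each landmark.
#' @export
setClass("LandmarkSet",
  representation(
    landmarkCells = "integer",
    sourceCluster = "integer",
    hubDegree = "integer"
  )
)

setValidity("LandmarkSet", function(object) {
  msg <- character()
  n <- length(object@landmarkCells)
  if (length(object@sourceCluster) != n || length(object@hubDegree) != n)
    msg <- c(msg, "sourceCluster and hubDegree must parallel landmarkCells")
  if (anyDuplicated(object@landmarkCells))
    msg <- c(msg, "duplicate landmark cells")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks over %d clusters\n",
              length(object@landmarkCells), length(unique(object@sourceCluster))))
})

#' Embedding3D: landmark-ISOMAP cell coordinates
#'
#' @slot coords cells x dim coordinate matrix (dim is 3 by default).
#' @slot stress residual relative distortion between geodesic and embedded
#'   landmark-cell distances.
#' @slot landmarkCoords landmark rows of `coords`.
#' @slot landmarkCells indices of the landmark cells.
#' @export
setClass("Embedding3D",
  representation(
    coords = "matrix",
    stress = "numeric",
    landmarkCoords = "matrix",
    landmarkCells = "integer"
  )
)

setValidity("Embedding3D", function(object) {
  msg <- character()
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(object@landmarkCells) != nrow(object@landmarkCoords))
    msg <- c(msg, "one landmarkCoords row per landmark")
  if (length(object@stress) != 1L || object@stress < 0)
    msg <- c(msg, "stress must be a nonnegative scalar")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Embedding3D", function(object) {
  cat(sprintf("Embedding3D: %d cells in %d-D (%d landmarks, stress %.4f)\n",
              nrow(object@coords), ncol(object@coords),
              length(object@landmarkCells), object@stress))
})

#' ClusterGraph: neighbour and geodesic distances between clusters
#'
#' `neighborDist[a, b]` is the mean length of cell-level kNN edges joining
#' clusters `a` and `b` (NA when no edge joins them); `graphDist` is the
#' all-pairs shortest-path closure of `neighborDist`.
#'
#' @slot clusters integer cluster ids.
#' @slot neighborDist C x C symmetric matrix with zero diagonal, NA where
#'   clusters share no edge.
#' @slot graphDist C x C shortest-path matrix (Inf across components).
#' @export
setClass("ClusterGraph",
  representation(
    clusters = "integer",
    neighborDist = "matrix",
    graphDist = "matrix"
  )
)

setValidity("ClusterGraph", function(object) {
  msg <- character()
  C <- length(object@clusters)
  for (nm in c("neighborDist", "graphDist")) {
    m <- slot(object, nm)
    if (!all(dim(m) == C)) msg <- c(msg, sprintf("%s must be %d x %d", nm, C, C))
    else {
      if (any(abs(diag(m)) > 1e-12, na.rm = TRUE))
        msg <- c(msg, sprintf("%s must have zero diagonal", nm))
      if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, sprintf("%s must be symmetric", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterGraph", function(object) {
  cat(sprintf("ClusterGraph: %d clusters, %d directly-connected pairs\n",
              length(object@clusters),
              sum(!is.na(object@neighborDist[upper.tri(object@neighborDist)]))))
})

#' LeafGroup: a structured set of terminal clusters
#'
#' A leaf group is attached to the backbone through its connector (the member
#' nearest to the non-leaf clusters) with one of three internal structures:
#' `linear` (chain ordered by distance from the attachment), `parallel`
#' (every member attached independently) or `mst` (internal minimum spanning
#' tree).
#'
#' @slot members integer cluster ids in the group.
#' @slot structure `"linear"`, `"parallel"` or `"mst"`.
#' @slot connector member cluster attaching the group to the backbone
#'   (`NA` until the tree is built).
#' @export
setClass("LeafGroup",
  representation(
    members = "integer",
    structure = "character",
    connector = "integer"
  )
)

setValidity("LeafGroup", function(object) {
  msg <- character()
  if (!length(object@members)) msg <- c(msg, "a leaf group needs >= 1 member")
  if (anyDuplicated(object@members)) msg <- c(msg, "duplicate members")
  if (!object@structure %in% c("linear", "parallel", "mst"))
    msg <- c(msg, "structure must be linear, parallel or mst")
  if (!is.na(object@connector) && !object@connector %in% object@members)
    msg <- c(msg, "connector must be a member")
  if (length(msg)) msg else TRUE
})

#' @rdname LeafGroup-class
#' @param members integer cluster ids.
#' @param structure internal structure of the group.
#' @return A `LeafGroup`.
#' @export
LeafGroup <- function(members, structure = c("parallel", "linear", "mst")) {
  structure <- match.arg(structure)
  new("LeafGroup", members = as.integer(members), structure = structure,
      connector = NA_integer_)
}

setMethod("show", "LeafGroup", function(object) {
  cat(sprintf("LeafGroup(%s): {%s}%s\n", object@structure,
              paste(object@members, collapse = ", "),
              if (is.na(object@connector)) ""
              else sprintf(" via connector %d", object@connector)))
})

#' TrajectoryTree: rooted tree over clusters
#'
#' @slot nodes integer cluster ids present in the tree.
#' @slot edges data.frame with columns `parent`, `child`, `length`; the
#'   parent is on the root side of every edge.
#' @slot root root cluster id.
#' @slot leafFlags named logical, TRUE for user-declared leaf clusters that
#'   are terminal (degree 1) in the tree.
#' @slot provenance named character: `backbone`, `leaf` or
#'   `attached_isolated` per node.
#' @slot validation character vector of validation-report messages (e.g.
#'   non-leaf nodes of degree 1).
#' @export
setClass("TrajectoryTree",
  representation(
    nodes = "integer",
    edges = "data.frame",
    root = "integer",
    leafFlags = "logical",
    provenance = "character",
    validation = "character"
  )
)

setValidity("TrajectoryTree", function(object) {
  msg <- character()
  n <- length(object@nodes)
  e <- object@edges
  if (!all(c("parent", "child", "length") %in% names(e)))
    return("edges must have columns parent, child, length")
  if (nrow(e) != n - 1L)
    msg <- c(msg, "a tree over n nodes must have n - 1 edges")
  if (!object@root %in% object@nodes) msg <- c(msg, "root must be a node")
  if (nrow(e)) {
    if (!all(c(e$parent, e$child) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (object@root %in% e$child) msg <- c(msg, "root must have no parent")
    if (anyDuplicated(e$child)) msg <- c(msg, "each node must have at most one parent")
    # connectivity: every non-root node reachable via parent pointers
    par <- stats::setNames(e$parent, e$child)
    for (v in setdiff(object@nodes, object@root)) {
      seen <- integer(); u <- v
      while (!is.na(u) && u != object@root && !(u %in% seen)) {
        seen <- c(seen, u)
        u <- if (as.character(u) %in% names(par)) par[[as.character(u)]] else NA_integer_
      }
      if (is.na(u) || u != object@root) {
        msg <- c(msg, "tree must be connected"); break
      }
    }
  }
  deg <- .treeDegree(object)
  declared <- names(object@leafFlags)[object@leafFlags]
  if (length(declared) && any(deg[declared] != 1L))
    msg <- c(msg, "every leaf-flagged node must have degree 1")
  if (length(msg)) msg else TRUE
})

.treeDegree <- function(tree) {
  deg <- stats::setNames(integer(length(tree@nodes)), as.character(tree@nodes))
  if (nrow(tree@edges)) {
    t1 <- table(as.character(tree@edges$parent))
    t2 <- table(as.character(tree@edges$child))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

setMethod("show", "TrajectoryTree", function(object) {
  deg <- .treeDegree(object)
  kids <- table(object@edges$parent)
  cat(sprintf("TrajectoryTree: %d clusters, root %d, %d leaves, %d bifurcations\n",
              length(object@nodes), object@root,
              sum(deg == 1L) - as.integer(deg[as.character(object@root)] == 1L),
              sum(kids >= 2L)))
  if (length(object@validation))
    cat("  validation:", paste(object@validation, collapse = "; "), "\n")
})

#' PseudotimeAssignment: per-cell edge placement and pseudotime
#'
#' @slot assignment data.frame with columns `cell` (index), `cellId`,
#'   `edgeParent`, `edgeChild`, `offset` (fraction in `[0, 1]` along the
#'   parent-to-child edge), `pseudotime` and `branch` (label of the branch
#'   leaf downstream of the assigned edge).
#' @export
setClass("PseudotimeAssignment",
  representation(assignment = "data.frame")
)

setValidity("PseudotimeAssignment", function(object) {
  a <- object@assignment
  need <- c("cell", "cellId", "edgeParent", "edgeChild", "offset",
            "pseudotime", "branch")
  if (!all(need %in% names(a)))
    return(sprintf("assignment must have columns: %s", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(a)) {
    if (any(a$offset < -1e-12 | a$offset > 1 + 1e-12))
      msg <- c(msg, "offset must lie in [0, 1]")
    if (any(a$pseudotime < -1e-12)) msg <- c(msg, "pseudotime must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PseudotimeAssignment", function(object) {
  cat(sprintf("PseudotimeAssignment: %d cells, pseudotime range [%.3f, %.3f]\n",
              nrow(object@assignment), min(object@assignment$pseudotime),
              max(object@assignment$pseudotime)))
})

#' BranchMatrix: neighbour-averaged expression along one branch
#'
#' Cells on a branch are grouped into contiguous equal-count pseudotime bins
#' and averaged per gene, reducing noise before trend extraction.
#'
#' @slot values genes x bins matrix of per-bin mean expression.
#' @slot binPseudotime per-bin mean pseudotime, strictly increasing.
#' @slot geneIds gene identifiers (rows of `values`).
#' @slot branch branch label.
#' @export
setClass("BranchMatrix",
  representation(
    values = "matrix",
    binPseudotime = "numeric",
    geneIds = "character",
    branch = "character"
  )
)

setValidity("BranchMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@binPseudotime))
    msg <- c(msg, "one binPseudotime per column required")
  if (nrow(object@values) != length(object@geneIds))
    msg <- c(msg, "one geneId per row required")
  if (length(object@binPseudotime) > 1 && any(diff(object@binPseudotime) <= 0))
    msg <- c(msg, "binPseudotime must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BranchMatrix", function(object) {
  cat(sprintf("BranchMatrix[%s]: %d genes x %d bins\n",
              object@branch, nrow(object@values), ncol(object@values)))
})

#' TrendResult: rank-1..r principal trends along a branch
#'
#' Each rank holds a magnitude `d`, a sparse per-gene score vector `scores`
#' (the gene's contribution to the trend), a unit-norm per-bin `trend`
#' curve, the share of variance explained and a convergence flag.
#'
#' @slot ranks list of per-rank lists with elements `d`, `scores`, `trend`,
#'   `varexp`, `converged`.
#' @slot branch branch label.
#' @slot binPseudotime pseudotime of the bins the trends are defined over.
#' @export
setClass("TrendResult",
  representation(
    ranks = "list",
    branch = "character",
    binPseudotime = "numeric"
  )
)

setValidity("TrendResult", function(object) {
  for (r in object@ranks) {
    if (!all(c("d", "scores", "trend", "varexp", "converged") %in% names(r)))
      return("each rank needs d, scores, trend, varexp, converged")
    if (r$d > 0 && abs(sqrt(sum(r$trend^2)) - 1) > 1e-6)
      return("each non-null trend must have unit norm")
  }
  TRUE
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf("TrendResult[%s]: %d ranks\n", object@branch, length(object@ranks)))
  for (i in seq_along(object@ranks)) {
    r <- object@ranks[[i]]
    cat(sprintf("  rank %d: d = %.3f, %d nonzero gene scores, varexp = %.3f\n",
                i, r$d, sum(r$scores != 0), r$varexp))
  }
})

#' SimTopology: ground-truth branching topology for simulation
#'
#' Nodes are branch segments; each non-root segment points at its parent
#' segment and carries a length in pseudotime steps.
#'
#' @slot branches character branch labels.
#' @slot parent named character, parent branch per branch (`NA` for root).
#' @slot length named numeric, steps per branch (>= 2).
#' @slot root root branch label.
#' @export
setClass("SimTopology",
  representation(
    branches = "character",
    parent = "character",
    length = "numeric",
    root = "character"
  )
)

setValidity("SimTopology", function(object) {
  msg <- character()
  b <- object@branches
  if (anyDuplicated(b)) msg <- c(msg, "duplicate branch labels")
  if (!object@root %in% b) msg <- c(msg, "root must be a branch")
  if (!all(names(object@parent) == b) || !all(names(object@length) == b))
    msg <- c(msg, "parent and length must be named by branches in order")
  if (sum(is.na(object@parent)) != 1L || !is.na(object@parent[object@root]))
    msg <- c(msg, "exactly the root may lack a parent")
  if (any(object@length < 2)) msg <- c(msg, "every branch length must be >= 2 steps")
  nonroot <- b[!is.na(object@parent)]
  if (length(nonroot) && !all(object@parent[nonroot] %in% b))
    msg <- c(msg, "parents must be branches")
  # acyclicity: walk to root from every branch
  for (v in b) {
    seen <- character(); u <- v
    while (!is.na(object@parent[u])) {
      if (u %in% seen) { msg <- c(msg, "topology must be acyclic"); break }
      seen <- c(seen, u); u <- object@parent[u]
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "SimTopology", function(object) {
  isLeaf <- !(object@branches %in% object@parent)
  cat(sprintf("SimTopology: %d branches, %d leaves, root '%s'\n",
              length(object@branches), sum(isLeaf), object@root))
})

#' SimDataset: simulated branching-lineage counts with ground truth
#'
#' @slot counts cells x genes integer count matrix.
#' @slot cellInfo data.frame with columns `cell_id`, `type`, `branch`,
#'   `pseudotime`, `library_factor`.
#' @slot topology the generating [SimTopology-class].
#' @slot seed RNG seed used.
#' @export
setClass("SimDataset",
  representation(
    counts = "matrix",
    cellInfo = "data.frame",
    topology = "SimTopology",
    seed = "integer"
  )
)

setValidity("SimDataset", function(object) {
  msg <- character()
  if (nrow(object@counts) != nrow(object@cellInfo))
    msg <- c(msg, "one cellInfo row per cell required")
  if (length(object@counts) && min(object@counts) < 0)
    msg <- c(msg, "counts must be nonnegative")
  if (nrow(object@cellInfo) && any(object@cellInfo$library_factor <= 0))
    msg <- c(msg, "library factors must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimDataset", function(object) {
  cat(sprintf("SimDataset: %d cells x %d genes, %d branches (seed %d)\n",
              nrow(object@counts), ncol(object@counts),
              length(object@topology@branches), object@seed))
})
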