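#' Map cells onto tree edges and compute pseudotime
#'
#' Each cell is assigned to one of the tree edges incident to its own
#' cluster: the cell is orthogonally projected (in the same PC space used
#' for clustering) onto the segment between the two endpoint-cluster
#' centroids, the along-edge offset is clamped to `[0, 1]`, and the
#' candidate edge with the smallest perpendicular residual wins.
#' Pseudotime is the accumulated tree-edge length from the root to the
#' projection point: `depth(parent) + offset * length(edge)`. Root-cluster
#' cells use the edges from the root to its children, so a root cell
#' projecting at offset 0 has pseudotime 0.
#'
#' @param tree a [TrajectoryTree-class].
#' @param clustering a [Clustering-class]; its clusters must all appear in
#'   the tree.
#' @param coords cells x dims PC coordinates (same space as the
#'   clustering).
#' @return A [PseudotimeAssignment-class].
#' @export
mapCells <- function(tree, clustering, coords) {
  stopifnot(is(tree, "TrajectoryTree"), is(clustering, "Clustering"))
  coords <- as.matrix(coords)
  labels <- clustering@labels
  cl <- sort(unique(labels))
  missing <- setdiff(cl, tree@nodes)
  if (length(missing))
    stop("cluster(s) absent from tree: ", paste(missing, collapse = ", "))
  cent <- clustering@centroids
  depth <- treeDepths(tree)
  e <- tree@edges
  e <- e[order(e$parent, e$child), , drop = FALSE]
  branchOf <- .edgeBranchLabels(tree)
  n <- length(labels)
  edgeParent <- integer(n); edgeChild <- integer(n)
  offset <- numeric(n); pt <- numeric(n); br <- character(n)
  for (i in seq_len(n)) {
    c0 <- labels[i]
    cand <- which(e$parent == c0 | e$child == c0)
    if (!length(cand))
      stop("cluster ", c0, " has no incident tree edge")
    best <- c(Inf, NA, NA)      # residual, edge row, offset
    for (r in cand) {
      p <- cent[as.character(e$parent[r]), ]
      q <- cent[as.character(e$child[r]), ]
      v <- q - p
      L2 <- sum(v^2)
      t <- if (L2 == 0) 0 else sum((coords[i, ] - p) * v) / L2
      t <- min(max(t, 0), 1)
      resid <- sqrt(sum((coords[i, ] - (p + t * v))^2))
      if (resid < best[1]) best <- c(resid, r, t)
    }
    r <- best[2]
    edgeParent[i] <- e$parent[r]; edgeChild[i] <- e$child[r]
    offset[i] <- best[3]
    pt[i] <- depth[as.character(e$parent[r])] + best[3] * e$length[r]
    br[i] <- branchOf[[r]]
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  new("PseudotimeAssignment", assignment = data.frame(
    cell = seq_len(n), cellId = ids, edgeParent = edgeParent,
    edgeChild = edgeChild, offset = offset, pseudotime = pt, branch = br,
    stringsAsFactors = FALSE))
}

# label each edge (in order(parent, child)) by the smallest-id leaf
# reachable through its child
.edgeBranchLabels <- function(tree) {
  e <- tree@edges
  e <- e[order(e$parent, e$child), , drop = FALSE]
  leaves <- treeLeaves(tree)
  downLeaf <- function(v) {
    ch <- e$child[e$parent == v]
    if (!length(ch)) return(v)
    min(vapply(ch, downLeaf, numeric(1)))
  }
  vapply(seq_len(nrow(e)), function(r) {
    lf <- downLeaf(e$child[r])
    paste0("branch_", lf)
  }, character(1))
}

#' Cells on a root-to-leaf branch, ordered by pseudotime
#'
#' Returns the cells whose assigned edge lies on the path from the root to
#' `leaf`, in ascending pseudotime (ties broken by cell index).
#'
#' @param assign a [PseudotimeAssignment-class].
#' @param tree the [TrajectoryTree-class] used for the assignment.
#' @param leaf a terminal (degree-1, non-root) tree node.
#' @return Integer vector of cell indices.
#' @export
branchCells <- function(assign, tree, leaf) {
  stopifnot(is(assign, "PseudotimeAssignment"), is(tree, "TrajectoryTree"))
  if (!leaf %in% treeLeaves(tree))
    stop("node ", leaf, " is not a leaf of the tree")
  path <- treePath(tree, leaf)
  onPath <- paste(path[-length(path)], path[-1])
  a <- assign@assignment
  key <- paste(a$edgeParent, a$edgeChild)
  sel <- which(key %in% onPath)
  sel[order(a$pseudotime[sel], a$cell[sel])]
}

#' Write the pseudotime table to CSV
#'
#' Columns: cell_id, pseudotime, pseudotime_norm (rescaled to `[0, 1]`),
#' branch, edge_parent, edge_child, offset.
#' @param assign a [PseudotimeAssignment-class]
#' @param path output CSV path
#' @param header optional comment lines (prefixed `#`) to prepend
#' @export
writePseudotimeCSV <- function(assign, path, header = NULL) {
  a <- assign@assignment
  maxpt <- max(a$pseudotime)
  out <- data.frame(
    cell_id = a$cellId, pseudotime = a$pseudotime,
    pseudotime_norm = if (maxpt > 0) a$pseudotime / maxpt else 0,
    branch = a$branch, edge_parent = a$edgeParent,
    edge_child = a$edgeChild, offset = a$offset)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
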