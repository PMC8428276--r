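# Static figure helpers (base graphics). The report stage collects these
# into a single PDF.

.clusterPalette <- function(n) {
  grDevices::hcl.colors(max(n, 3), "Dark 3")[seq_len(n)]
}

# layout tree nodes: x = depth from root, y = leaf-ordered spread
.treeLayout <- function(tree) {
  depth <- treeDepths(tree)
  leaves <- treeLeaves(tree)
  y <- stats::setNames(rep(NA_real_, length(tree@nodes)),
                       as.character(tree@nodes))
  y[as.character(leaves)] <- seq_along(leaves)
  fill <- function(v) {
    ch <- tree@edges$child[tree@edges$parent == v]
    if (!length(ch)) return(y[[as.character(v)]])
    vals <- vapply(ch, fill, numeric(1))
    y[as.character(v)] <<- mean(vals)
    y[[as.character(v)]]
  }
  fill(tree@root)
  cbind(x = depth[as.character(tree@nodes)],
        y = y[as.character(tree@nodes)])
}

#' Pie-tree plot of a trajectory
#'
#' Draws the cluster tree with one pie per cluster node showing its cell
#' composition (by `fill`, defaulting to cluster identity).
#'
#' @param tree a [TrajectoryTree-class].
#' @param clustering a [Clustering-class].
#' @param fill optional per-cell factor (e.g. cell-type annotation) to
#'   fill the pies with; default the cluster labels themselves.
#' @param main plot title.
#' @export
plotPieTree <- function(tree, clustering, fill = NULL, main = "Trajectory") {
  lay <- .treeLayout(tree)
  rownames(lay) <- as.character(tree@nodes)
  if (is.null(fill)) fill <- factor(clustering@labels)
  fill <- as.factor(fill)
  pal <- .clusterPalette(nlevels(fill))
  graphics::plot(lay[, "x"], lay[, "y"], type = "n", axes = FALSE,
                 xlab = "accumulated distance from root", ylab = "",
                 main = main,
                 xlim = range(lay[, "x"]) + c(-0.05, 0.05) * diff(range(lay[, "x"]) + 1e-9),
                 ylim = range(lay[, "y"]) + c(-0.6, 0.6))
  graphics::axis(1)
  for (r in seq_len(nrow(tree@edges))) {
    p <- as.character(tree@edges$parent[r]); c <- as.character(tree@edges$child[r])
    graphics::segments(lay[p, "x"], lay[p, "y"], lay[c, "x"], lay[c, "y"],
                       col = "grey50")
  }
  rad <- 0.035 * max(diff(range(lay[, "x"])), 1e-9)
  for (v in tree@nodes) {
    members <- clustering@labels == v
    prop <- table(fill[members])
    prop <- prop[prop > 0]
    .pieAt(lay[as.character(v), "x"], lay[as.character(v), "y"], rad,
           as.numeric(prop), pal[match(names(prop), levels(fill))])
    graphics::text(lay[as.character(v), "x"], lay[as.character(v), "y"] + 0.35,
                   labels = v, cex = 0.8)
  }
  invisible(lay)
}

.pieAt <- function(x, y, r, counts, cols) {
  asp <- diff(graphics::par("usr")[3:4]) / diff(graphics::par("usr")[1:2])
  frac <- counts / sum(counts)
  ang <- c(0, cumsum(frac)) * 2 * pi
  for (i in seq_along(frac)) {
    th <- seq(ang[i], ang[i + 1], length.out = 24)
    graphics::polygon(x + r * cos(th), y + r * sin(th) * asp,
                      col = cols[i], border = NA)
  }
}

#' Scatter plot of an embedding coloured by cluster
#'
#' For 3-D coordinates, draws the three axis pairs side by side.
#'
#' @param coords cells x 2 or cells x 3 coordinate matrix.
#' @param labels per-cell cluster labels (or any factor).
#' @param main title.
#' @export
plotEmbedding <- function(coords, labels, main = "Embedding") {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  pal <- .clusterPalette(nlevels(labels))
  if (ncol(coords) >= 3) {
    old <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(old))
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  } else pairs <- list(c(1, 2))
  for (p in pairs) {
    graphics::plot(coords[, p[1]], coords[, p[2]],
                   col = pal[as.integer(labels)], pch = 16, cex = 0.5,
                   xlab = colnames(coords)[p[1]] %||% paste0("dim", p[1]),
                   ylab = colnames(coords)[p[2]] %||% paste0("dim", p[2]),
                   main = main)
  }
  invisible(NULL)
}

#' Scatter plot coloured by pseudotime
#' @param coords cells x 2 coordinates
#' @param pt per-cell pseudotime
#' @param main title
#' @export
plotPseudotime <- function(coords, pt, main = "Pseudotime") {
  ramp <- grDevices::colorRamp(c("#2c7bb6", "#ffffbf", "#d7191c"))
  sc <- (pt - min(pt)) / max(max(pt) - min(pt), 1e-12)
  cols <- grDevices::rgb(ramp(sc), maxColorValue = 255)
  graphics::plot(coords[, 1], coords[, 2], col = cols, pch = 16, cex = 0.5,
                 xlab = "dim 1", ylab = "dim 2", main = main)
  invisible(NULL)
}

#' Trend curves along a branch
#' @param trends data.frame with `bin_pseudotime` and `rank*` columns
#'   (as written by the pta stage)
#' @param main title
#' @export
plotTrendCurves <- function(trends, main = "Principal trends") {
  rankCols <- grep("^rank", names(trends), value = TRUE)
  cols <- c("red", "blue", "darkgreen", "orange")[seq_along(rankCols)]
  ylim <- range(unlist(trends[rankCols]))
  graphics::plot(NA, xlim = range(trends$bin_pseudotime), ylim = ylim,
                 xlab = "pseudotime", ylab = "trend (d * v)", main = main)
  for (i in seq_along(rankCols))
    graphics::lines(trends$bin_pseudotime, trends[[rankCols[i]]],
                    col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = rankCols, col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

#' Heatmap of branch expression ordered by trend score
#'
#' Rows are the nonzero-score genes of the chosen rank, ordered from most
#' negative to most positive score; columns are pseudotime bins. Uses
#' `pheatmap` when available, otherwise a base `image`.
#'
#' @param bm a [BranchMatrix-class].
#' @param result the matching [TrendResult-class].
#' @param rank which trend's scores order the rows.
#' @param main title.
#' @export
plotTrendHeatmap <- function(bm, result, rank = 1L, main = NULL) {
  rg <- rankGenes(result, rank)
  if (!nrow(rg)) {
    warning("no nonzero scores at rank ", rank, "; heatmap skipped")
    return(invisible(NULL))
  }
  m <- bm@values[rg$gene, , drop = FALSE]
  if (is.null(main)) main <- sprintf("%s rank %d", bm@branch, rank)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = main, show_colnames = FALSE)
  } else {
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, main = main)
  }
  invisible(rg)
}
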