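#' Filter low-quality cells/features and library-size normalise
#'
#' Cells with fewer detected (nonzero) features than `minFeaturesPerCell`
#' are removed first; features detected in fewer remaining cells than
#' `minCellsPerFeature` are removed second. Surviving counts are scaled to
#' `scaleFactor` per cell and log1p-transformed, yielding the `lognorm`
#' layer.
#'
#' @param mat an [ExpressionMatrix-class] with `layer == "counts"`.
#' @param minFeaturesPerCell minimum detected features per retained cell.
#' @param minCellsPerFeature minimum supporting cells per retained feature.
#' @param scaleFactor per-cell library size after normalisation
#'   (default 1e4).
#' @return A `lognorm` [ExpressionMatrix-class].
#' @export
filterAndNormalize <- function(mat, minFeaturesPerCell = 0L,
                               minCellsPerFeature = 0L, scaleFactor = 1e4) {
  stopifnot(is(mat, "ExpressionMatrix"))
  if (mat@layer != "counts")
    stop("filterAndNormalize expects the counts layer, got ", mat@layer)
  stopifnot(scaleFactor > 0)
  x <- mat@values
  keepCells <- rowSums(x > 0) >= minFeaturesPerCell
  if (!any(keepCells)) stop("all cells removed by the cell filter")
  x <- x[keepCells, , drop = FALSE]
  keepFeatures <- colSums(x > 0) >= minCellsPerFeature
  x <- x[, keepFeatures, drop = FALSE]
  if (!ncol(x)) stop("all features removed by the feature filter")
  libsize <- rowSums(x)
  libsize[libsize == 0] <- 1          # empty cells map to all-zero rows
  norm <- log1p(x / libsize * scaleFactor)
  ExpressionMatrix(norm, cellIds = mat@cellIds[keepCells],
                   featureIds = mat@featureIds[keepFeatures],
                   layer = "lognorm")
}

#' Select highly variable features
#'
#' Ranks features by a variance-stabilised dispersion: the residual of
#' log-variance against a loess fit on log-mean, so that highly expressed
#' features do not dominate by mean-variance scaling alone. Deterministic
#' given the input.
#'
#' @param mat a `lognorm` [ExpressionMatrix-class].
#' @param nTop number of features to return (clamped to the feature count
#'   with a warning).
#' @return Character vector of `nTop` feature ids, most variable first.
#' @export
selectHVG <- function(mat, nTop = 2000L) {
  stopifnot(is(mat, "ExpressionMatrix"))
  if (mat@layer != "lognorm")
    stop("selectHVG expects the lognorm layer, got ", mat@layer)
  x <- mat@values
  if (nTop > ncol(x)) {
    warning("nTop exceeds feature count; returning all features ranked")
    nTop <- ncol(x)
  }
  m <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- rep(-Inf, ncol(x))           # zero-variance features rank last
  ok <- v > 0 & m > 0
  if (sum(ok) >= 4) {
    fit <- stats::lowess(log(m[ok]), log(v[ok]), f = 0.3)
    fitted <- stats::approx(fit$x, fit$y, xout = log(m[ok]), rule = 2)$y
    disp[ok] <- log(v[ok]) - fitted
  } else {
    disp[ok] <- v[ok]
  }
  ord <- order(disp, decreasing = TRUE)
  mat@featureIds[ord[seq_len(nTop)]]
}

#' Centre, scale and clip features
#'
#' Each feature is centred to mean 0 and unit sample variance, then clipped
#' to `[-clip, clip]`. Zero-variance features map to all-zero columns.
#'
#' @param mat a `lognorm` [ExpressionMatrix-class].
#' @param clip symmetric clipping bound (default 10).
#' @param features optional feature-id subset (e.g. from [selectHVG]) to
#'   keep before scaling.
#' @return A `scaled` [ExpressionMatrix-class].
#' @export
scaleFeatures <- function(mat, clip = 10, features = NULL) {
  stopifnot(is(mat, "ExpressionMatrix"))
  if (mat@layer != "lognorm")
    stop("scaleFeatures expects the lognorm layer, got ", mat@layer)
  stopifnot(clip > 0)
  x <- mat@values
  fid <- mat@featureIds
  if (!is.null(features)) {
    keep <- match(features, fid)
    if (anyNA(keep)) stop("unknown feature ids in 'features'")
    x <- x[, keep, drop = FALSE]
    fid <- fid[keep]
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  ExpressionMatrix(z, cellIds = mat@cellIds, featureIds = fid,
                   layer = "scaled")
}

#' Principal component analysis of a scaled matrix
#'
#' Projects cells onto the top right-singular directions of the
#' column-centred matrix. For reproducible embeddings the sign of each
#' component is fixed so the loading of largest magnitude is positive.
#' `zscore` matrices (e.g. accessibility deviations) feed in directly;
#' `scaled` matrices come from [scaleFeatures].
#'
#' @param mat a `scaled` or `zscore` [ExpressionMatrix-class].
#' @param nComponents number of components to retain
#'   (reduced to the matrix rank with a warning if it exceeds it).
#' @param seed unused by the deterministic solver; kept for interface
#'   stability.
#' @return A [PCSpace-class] with `nSelected` initialised to `nComponents`.
#' @export
runPCA <- function(mat, nComponents = 50L, seed = 0L) {
  stopifnot(is(mat, "ExpressionMatrix"))
  if (!mat@layer %in% c("scaled", "zscore"))
    stop("runPCA expects a scaled or zscore layer, got ", mat@layer)
  x <- mat@values
  if (nComponents > min(dim(x)))
    stop("nComponents must be <= min(cells, features)")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  rank <- sum(p$sdev > p$sdev[1] * 1e-12)
  if (nComponents > rank) {
    warning("requested ", nComponents, " components but rank is ", rank,
            "; reducing")
    nComponents <- rank
  }
  keep <- seq_len(nComponents)
  coords <- p$x[, keep, drop = FALSE]
  rot <- p$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in keep) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      coords[, k] <- -coords[, k]
      rot[, k] <- -rot[, k]
    }
  }
  rownames(coords) <- mat@cellIds
  rownames(rot) <- mat@featureIds
  new("PCSpace", coords = coords, explainedVariance = ev[keep],
      nSelected = as.integer(nComponents), rotation = rot)
}

#' Choose how many principal components to keep
#'
#' `elbow` picks the scree point with maximum perpendicular distance to the
#' chord joining the first and last scree values; `cumvar` picks the
#' smallest k whose cumulative explained-variance fraction reaches
#' `cumvarTarget`. The choice can always be overridden downstream.
#'
#' @param pcs a [PCSpace-class] with >= 2 components.
#' @param method `"elbow"` or `"cumvar"`.
#' @param cumvarTarget cumulative-fraction target for `cumvar` (of the
#'   variance captured by the computed components).
#' @return Integer number of components.
#' @export
selectComponents <- function(pcs, method = c("elbow", "cumvar"),
                             cumvarTarget = 0.9) {
  stopifnot(is(pcs, "PCSpace"))
  method <- match.arg(method)
  ev <- pcs@explainedVariance
  if (length(ev) < 2) stop("need >= 2 components to select from")
  if (method == "cumvar") {
    cs <- cumsum(ev) / sum(ev)
    return(as.integer(which(cs >= cumvarTarget)[1]))
  }
  n <- length(ev)
  # distance from each scree point to the chord (1, ev1) -- (n, evn)
  x1 <- 1; y1 <- ev[1]; x2 <- n; y2 <- ev[n]
  xs <- seq_len(n)
  d <- abs((y2 - y1) * xs - (x2 - x1) * ev + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  as.integer(which.max(d))
}

#' Update the selected-component count of a PCSpace
#' @param pcs a [PCSpace-class]
#' @param n number of components to mark selected
#' @export
setSelected <- function(pcs, n) {
  stopifnot(is(pcs, "PCSpace"))
  pcs@nSelected <- as.integer(n)
  validObject(pcs)
  pcs
}
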