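#' Bin a branch into neighbour-averaged pseudotime groups
#'
#' Cells (already ordered by pseudotime) are partitioned into `nBins`
#' contiguous equal-count groups, the remainder spread over the leading
#' bins, and expression is averaged per gene within each bin. Averaging
#' neighbouring cells reduces noise and running time before trend
#' extraction.
#'
#' @param cells integer cell indices ordered by pseudotime
#'   (e.g. from [branchCells]).
#' @param expr an [ExpressionMatrix-class] (typically `scaled`).
#' @param pseudotime per-cell pseudotime vector (full-length, indexed by
#'   cell).
#' @param nBins number of bins (>= 8; reduced to the cell count with a
#'   warning when cells are scarce).
#' @param branch branch label to record.
#' @return A [BranchMatrix-class] (genes x bins).
#' @export
binBranch <- function(cells, expr, pseudotime, nBins = NULL,
                      branch = "branch") {
  stopifnot(is(expr, "ExpressionMatrix"))
  ncell <- length(cells)
  if (is.null(nBins)) nBins <- min(100L, ncell)
  if (nBins > ncell) {
    warning("fewer cells than bins; reducing bins to ", ncell)
    nBins <- ncell
  }
  base <- ncell %/% nBins
  extra <- ncell %% nBins
  sizes <- rep(base, nBins)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  stopifnot(sum(sizes) == ncell)
  idx <- split(cells, rep(seq_len(nBins), sizes))
  x <- expr@values
  vals <- vapply(idx, function(ix)
    colMeans(x[ix, , drop = FALSE]), numeric(ncol(x)))
  binPt <- vapply(idx, function(ix) mean(pseudotime[ix]), numeric(1))
  if (any(diff(binPt) <= 0)) {
    # tied pseudotimes can collapse bin means; nudge to keep strict order
    binPt <- binPt + seq_along(binPt) * 1e-9 * max(1, abs(max(binPt)))
  }
  new("BranchMatrix", values = matrix(vals, ncol = nBins,
                                      dimnames = list(expr@featureIds, NULL)),
      binPseudotime = as.numeric(binPt), geneIds = expr@featureIds,
      branch = branch)
}

.softThreshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# second-difference penalty matrix D2' D2 for a length-n vector
.secondDiffPenalty <- function(n) {
  if (n < 3) return(matrix(0, n, n))
  D <- matrix(0, n - 2, n)
  for (r in seq_len(n - 2)) D[r, r:(r + 2)] <- c(1, -2, 1)
  crossprod(D)
}

# GCV choice of the smoothing penalty for the ridge smoother
# v = (I + lambda S)^-1 y
.gcvSmooth <- function(y, S, grid = 10^seq(-2, 3, length.out = 25)) {
  n <- length(y)
  eg <- eigen(S, symmetric = TRUE)
  yt <- crossprod(eg$vectors, y)
  best <- grid[1]; bestScore <- Inf
  for (lam in grid) {
    h <- 1 / (1 + lam * eg$values)
    resid2 <- sum(((1 - h) * yt)^2)
    df <- sum(h)
    score <- n * resid2 / (n - df)^2
    if (score < bestScore) { bestScore <- score; best <- lam }
  }
  best
}

#' Sparse-smooth rank-one trend extraction
#'
#' Alternating optimisation of `X ~ d u v'` where `u` (per-gene scores)
#' carries an L1 penalty (soft-thresholding, so most gene scores are
#' exactly zero) and `v` (the per-bin trend) a second-difference roughness
#' penalty. Updates: `u <- soft(X v, lambdaSparse)` renormalised;
#' `v <- solve(I + lambdaSmooth * D2'D2, X' u)` renormalised;
#' `d <- u' X v`; iterated from the leading singular pair until the
#' relative change in `d` drops below `tol`. The trend sign is fixed so
#' the endpoint difference is nonnegative (scores flip with it).
#'
#' @param X a [BranchMatrix-class] or genes x bins matrix.
#' @param lambdaSparse L1 penalty on the gene scores; `NULL` selects a
#'   Bonferroni-style threshold `sigma * qnorm(1 - 0.05 / (2 n_genes))`
#'   with `sigma` estimated by the MAD of the rank-one SVD residual, so
#'   that under Gaussian noise no pure-noise gene enters the support with
#'   probability about 0.95.
#' @param lambdaSmooth roughness penalty on the trend; `NULL` selects it by
#'   generalized cross-validation on the bin axis.
#' @param maxIter maximum alternations.
#' @param tol relative-change convergence tolerance on `d`.
#' @return list with `d`, `scores` (length genes), `trend` (unit-norm,
#'   length bins), `converged`, `lambdaSparse`, `lambdaSmooth`. A
#'   saturating sparsity penalty yields the null trend (`d = 0`, all-zero
#'   scores) with `converged = TRUE`.
#' @export
ptaRankOne <- function(X, lambdaSparse = NULL, lambdaSmooth = NULL,
                       maxIter = 200L, tol = 1e-7) {
  Xm <- if (is(X, "BranchMatrix")) X@values else as.matrix(X)
  if (any(!is.finite(Xm))) stop("X must be finite")
  g <- nrow(Xm); nb <- ncol(Xm)
  sv <- svd(Xm, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]; d <- sv$d[1]
  if (is.null(lambdaSparse)) {
    resid <- Xm - d * tcrossprod(u, v)
    sigma <- stats::mad(resid)
    lambdaSparse <- sigma * stats::qnorm(1 - 0.05 / (2 * max(g, 2)))
  }
  S <- .secondDiffPenalty(nb)
  if (is.null(lambdaSmooth))
    lambdaSmooth <- .gcvSmooth(crossprod(Xm, u)[, 1], S)
  A <- diag(nb) + lambdaSmooth * S
  cholA <- chol(A)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    uNew <- .softThreshold(Xm %*% v, lambdaSparse)[, 1]
    nu <- sqrt(sum(uNew^2))
    if (nu == 0) {
      return(list(d = 0, scores = numeric(g), trend = numeric(nb),
                  converged = TRUE, lambdaSparse = lambdaSparse,
                  lambdaSmooth = lambdaSmooth))
    }
    u <- uNew / nu
    vNew <- backsolve(cholA, forwardsolve(t(cholA), crossprod(Xm, u)[, 1]))
    v <- vNew / sqrt(sum(vNew^2))
    dNew <- as.numeric(crossprod(u, Xm %*% v))
    if (abs(dNew - d) <= tol * max(abs(d), 1e-12)) {
      d <- dNew; converged <- TRUE; break
    }
    d <- dNew
  }
  if (v[nb] - v[1] < 0) { v <- -v; u <- -u }
  list(d = d, scores = u, trend = v, converged = converged,
       lambdaSparse = lambdaSparse, lambdaSmooth = lambdaSmooth)
}

#' Principal trend analysis along a branch
#'
#' Sequentially extracts `nRanks` sparse-smooth rank-one trends
#' ([ptaRankOne]), deflating `X <- X - d u v'` between ranks. Three ranks
#' are commonly enough to capture the main expression patterns along a
#' branch. The variance explained by rank k is the drop in squared
#' residual Frobenius norm relative to the original matrix.
#'
#' @param X a [BranchMatrix-class].
#' @param nRanks number of trends to extract (default 3).
#' @param lambdaSparse,lambdaSmooth penalties, recycled across ranks;
#'   `NULL` selects them per rank as in [ptaRankOne].
#' @param maxIter,tol passed to [ptaRankOne].
#' @return A [TrendResult-class].
#' @export
pta <- function(X, nRanks = 3L, lambdaSparse = NULL, lambdaSmooth = NULL,
                maxIter = 200L, tol = 1e-7) {
  stopifnot(is(X, "BranchMatrix"), nRanks >= 1L)
  Xm <- X@values
  total <- sum(Xm^2)
  ranks <- vector("list", 0)
  res <- Xm
  prevShare <- 0
  for (k in seq_len(nRanks)) {
    fit <- ptaRankOne(res, lambdaSparse = lambdaSparse,
                      lambdaSmooth = lambdaSmooth, maxIter = maxIter,
                      tol = tol)
    if (fit$d == 0) {
      ranks[[k]] <- list(d = 0, scores = stats::setNames(fit$scores, X@geneIds),
                         trend = fit$trend, varexp = 0, converged = fit$converged)
      break
    }
    res <- res - fit$d * tcrossprod(fit$scores, fit$trend)
    share <- 1 - sum(res^2) / total
    ranks[[k]] <- list(d = fit$d,
                       scores = stats::setNames(fit$scores, X@geneIds),
                       trend = fit$trend,
                       varexp = share - prevShare,
                       converged = fit$converged)
    prevShare <- share
  }
  new("TrendResult", ranks = ranks, branch = X@branch,
      binPseudotime = X@binPseudotime)
}

#' Rank genes by trend score
#'
#' Genes with nonzero score for the given rank, ascending from most
#' negative to most positive score — the order used for trend heatmap
#' rows.
#'
#' @param result a [TrendResult-class].
#' @param rank which trend (1-based).
#' @return data.frame with columns `gene`, `score`, ascending by score.
#' @export
rankGenes <- function(result, rank = 1L) {
  stopifnot(is(result, "TrendResult"))
  if (rank > length(result@ranks)) stop("rank exceeds number of trends")
  s <- result@ranks[[rank]]$scores
  nz <- s[s != 0]
  nz <- nz[order(nz)]
  data.frame(gene = names(nz), score = as.numeric(nz),
             stringsAsFactors = FALSE)
}
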