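# planted sparse-smooth rank-one model: 5 active genes, sigmoid trend
plantedModel <- function(seed, nGenes = 50, nBins = 20, sdNoise = 0.1,
                         amp = 3) {
  withr::with_seed(seed, {
    v <- 1 / (1 + exp(-seq(-4, 4, length.out = nBins)))
    v <- v / sqrt(sum(v^2))
    u <- numeric(nGenes)
    active <- sample(nGenes, 5)
    u[active] <- 1 / sqrt(5)
    X <- amp * tcrossprod(u, v) + matrix(rnorm(nGenes * nBins, 0, sdNoise),
                                         nGenes, nBins)
    list(X = X, u = u, v = v, active = sort(active))
  })
}

asBranchMatrix <- function(X, branch = "b") {
  new("BranchMatrix", values = X, binPseudotime = seq_len(ncol(X)),
      geneIds = paste0("g", seq_len(nrow(X))), branch = branch)
}

test_that("binning splits cells into contiguous equal-count groups", {
  withr::with_seed(71, x <- matrix(rnorm(1000), 100, 10))
  em <- ExpressionMatrix(x, layer = "scaled")
  pt <- seq_len(100) / 10
  bm10 <- binBranch(1:10, em, pt, nBins = 5)
  expect_equal(ncol(bm10@values), 5L)
  expect_equal(bm10@values[, 1], colMeans(x[1:2, ]), ignore_attr = TRUE)
  # 97 cells over 10 bins: sizes 10x7 then 9x3, means match brute force
  cells <- 1:97
  bm <- binBranch(cells, em, pt, nBins = 10)
  sizes <- c(rep(10, 7), rep(9, 3))
  expect_equal(sum(sizes), 97)
  start <- cumsum(c(1, head(sizes, -1)))
  for (b in seq_along(sizes)) {
    ix <- cells[start[b]:(start[b] + sizes[b] - 1)]
    expect_equal(bm@values[, b], colMeans(x[ix, ]), ignore_attr = TRUE)
    expect_equal(bm@binPseudotime[b], mean(pt[ix]), tolerance = 1e-6)
  }
  # constant gene stays constant
  xc <- x; xc[, 1] <- 2
  bmc <- binBranch(1:40, ExpressionMatrix(xc, layer = "scaled"), pt, nBins = 8)
  expect_equal(unname(bmc@values[1, ]), rep(2, 8))
  expect_warning(binBranch(1:5, em, pt, nBins = 8), "fewer cells")
})

test_that("exact rank-one input is recovered without penalties", {
  withr::with_seed(72, {
    u <- rnorm(30); u <- u / sqrt(sum(u^2))
    v <- sort(rnorm(12)); v <- v / sqrt(sum(v^2))
  })
  X <- 5 * tcrossprod(u, v)
  fit <- ptaRankOne(X, lambdaSparse = 0, lambdaSmooth = 0)
  expect_true(fit$converged)
  expect_equal(fit$d, 5, tolerance = 1e-6)
  expect_lt(min(sum((fit$scores - u)^2), sum((fit$scores + u)^2)), 1e-10)
})

test_that("a saturating sparsity penalty yields the null trend", {
  withr::with_seed(73, X <- matrix(rnorm(100, 0, 0.1), 10, 10))
  fit <- ptaRankOne(X, lambdaSparse = 100, lambdaSmooth = 0)
  expect_equal(fit$d, 0)
  expect_true(all(fit$scores == 0))
})

test_that("planted support and trend are recovered across seeds", {
  cosines <- numeric(5)
  supportOK <- logical(5)
  for (s in 1:5) {
    pm <- plantedModel(s)
    fit <- ptaRankOne(pm$X)     # automatic penalty selection
    nz <- which(fit$scores != 0)
    supportOK[s] <- setequal(nz, pm$active)
    cosines[s] <- abs(sum(fit$trend * pm$v))
  }
  expect_true(all(supportOK))
  expect_true(all(cosines > 0.95))
})

test_that("smoothing reduces the trend's curvature energy", {
  pm <- plantedModel(9, sdNoise = 0.3)
  rough <- ptaRankOne(pm$X, lambdaSparse = 0, lambdaSmooth = 0)
  smooth <- ptaRankOne(pm$X, lambdaSparse = 0, lambdaSmooth = 50)
  energy <- function(v) sum(diff(diff(v))^2)
  expect_lt(energy(smooth$trend), energy(rough$trend))
})

test_that("trend sign convention gives nonnegative endpoint difference", {
  for (s in 1:3) {
    pm <- plantedModel(s + 20)
    fit <- ptaRankOne(-pm$X)
    expect_gte(fit$trend[length(fit$trend)] - fit$trend[1], 0)
  }
})

test_that("sequential deflation explains variance in decreasing residual", {
  pm <- plantedModel(74)
  res <- pta(asBranchMatrix(pm$X), nRanks = 3, lambdaSparse = 0.1,
             lambdaSmooth = 1)
  ranks <- trendRanks(res)
  expect_length(ranks, 3L)
  # reconstructed residual norms strictly decrease
  X <- pm$X
  norms <- numeric(3)
  for (k in 1:3) {
    X <- X - ranks[[k]]$d * tcrossprod(as.numeric(ranks[[k]]$scores),
                                       ranks[[k]]$trend)
    norms[k] <- sum(X^2)
  }
  expect_true(all(diff(c(sum(pm$X^2), norms)) < 0))
  expect_true(all(vapply(ranks, function(r) r$varexp, numeric(1)) >= 0))
})

test_that("rank-one data is exhausted by a single trend", {
  withr::with_seed(75, {
    u <- rnorm(20); v <- sort(rnorm(10))
  })
  X <- tcrossprod(u, v)
  res <- pta(asBranchMatrix(X), nRanks = 1, lambdaSparse = 0,
             lambdaSmooth = 0)
  expect_equal(trendRanks(res)[[1]]$varexp, 1, tolerance = 1e-6)
})

test_that("two orthogonal planted trends come out in magnitude order", {
  withr::with_seed(76, {
    n <- 40; nb <- 24
    u1 <- c(rep(1, 5), rep(0, 35)); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(rep(0, 35), rep(1, 5)); u2 <- u2 / sqrt(sum(u2^2))
    v1 <- sin(seq(0, pi, length.out = nb)); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- seq(-1, 1, length.out = nb); v2 <- v2 / sqrt(sum(v2^2))
    X <- 6 * tcrossprod(u1, v1) + 3 * tcrossprod(u2, v2) +
      matrix(rnorm(n * nb, 0, 0.05), n, nb)
  })
  res <- pta(asBranchMatrix(X), nRanks = 2)
  r <- trendRanks(res)
  expect_gt(r[[1]]$d, r[[2]]$d)
  expect_gt(abs(sum(r[[1]]$trend * v1)), 0.95)
  expect_gt(abs(sum(r[[2]]$trend * v2)), 0.95)
  expect_setequal(names(which(r[[1]]$scores != 0)), paste0("g", 1:5))
})

test_that("default analysis returns three ranks", {
  pm <- plantedModel(77)
  expect_length(trendRanks(pta(asBranchMatrix(pm$X))), 3L)
})

test_that("gene ranking orders nonzero scores ascending and drops zeros", {
  res <- new("TrendResult", branch = "b", binPseudotime = 1:3,
             ranks = list(list(d = 1,
                               scores = c(g1 = -0.2, g2 = 0, g3 = 0.1),
                               trend = c(0.6, 0.6, 0.52915026),
                               varexp = 0.5, converged = TRUE)))
  rg <- rankGenes(res, 1)
  expect_equal(rg$gene, c("g1", "g3"))
  expect_equal(rg$score, c(-0.2, 0.1))
  res0 <- new("TrendResult", branch = "b", binPseudotime = 1:3,
              ranks = list(list(d = 0, scores = c(g1 = 0, g2 = 0, g3 = 0),
                                trend = numeric(3), varexp = 0,
                                converged = TRUE)))
  expect_equal(nrow(rankGenes(res0, 1)), 0L)
  # planted model: the highest |score| genes are the active set
  pm <- plantedModel(78)
  fit <- pta(asBranchMatrix(pm$X), nRanks = 1)
  rg <- rankGenes(fit, 1)
  top <- rg$gene[order(-abs(rg$score))][1:5]
  expect_setequal(top, paste0("g", pm$active))
})
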