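#' Build a branching topology from a node-level edge list
#'
#' Each edge is one branch segment, labelled by its child node; the branch
#' of an edge out of the root node has no parent. The edge list must form
#' a tree rooted at `root` (a cycle or a second root is a structural
#' error).
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `length` (pseudotime steps per branch; default 40).
#' @param root root node label.
#' @param defaultLength branch length in steps when `edges$length` is
#'   absent (default 40).
#' @return A [SimTopology-class].
#' @export
makeTopology <- function(edges, root, defaultLength = 40) {
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$length)) edges$length <- defaultLength
  if (anyDuplicated(edges$to))
    stop("structural error: node(s) with multiple parents: ",
         paste(unique(edges$to[duplicated(edges$to)]), collapse = ", "))
  if (root %in% edges$to)
    stop("structural error: root node must have no incoming edge")
  rootBranches <- edges$to[edges$from == root]
  if (length(rootBranches) != 1L)
    stop("structural error: exactly one branch must leave the root node, found ",
         length(rootBranches))
  branches <- edges$to
  parent <- stats::setNames(edges$from, branches)
  parent[!(parent %in% branches)] <- NA_character_
  if (sum(is.na(parent)) != 1L)
    stop("structural error: multiple roots (edges from unknown nodes: ",
         paste(setdiff(edges$from, c(branches, root)), collapse = ", "), ")")
  topo <- new("SimTopology", branches = branches, parent = parent,
              length = stats::setNames(as.numeric(edges$length), branches),
              root = rootBranches)
  validObject(topo)
  topo
}

#' Leaf branches of a topology
#' @param topology a [SimTopology-class]
#' @export
topologyLeaves <- function(topology) {
  topology@branches[!(topology@branches %in% topology@parent)]
}

# branches in parent-before-child order
.topoOrder <- function(topology) {
  ord <- character(0)
  pending <- topology@branches
  while (length(pending)) {
    ready <- pending[is.na(topology@parent[pending]) |
                     topology@parent[pending] %in% ord]
    ord <- c(ord, ready)
    pending <- setdiff(pending, ready)
  }
  ord
}

# global start time of each branch
.branchStart <- function(topology) {
  start <- stats::setNames(numeric(length(topology@branches)),
                           topology@branches)
  for (b in .topoOrder(topology)) {
    p <- topology@parent[[b]]
    start[b] <- if (is.na(p)) 0 else start[p] + topology@length[[p]]
  }
  start
}

#' Simulate tree-structured single-cell counts
#'
#' A branching-process count generator: per-program activities follow a
#' Gaussian random walk along pseudotime
#' (`W[t+1] = a W[t] + N(0, programWalkSd)`, `a = exp(-1 / programTau)`,
#' pure diverging walk at the default `programTau = Inf`), each child
#' branch continuing from its parent's endpoint and then diverging
#' independently. The default per-step innovation keeps the accumulated
#' log-drift over the deepest paths within a realistic fold-change range
#' (roughly e^2 per program over seven branch lengths) so that no single
#' gene dominates a cell's library; a finite `programTau` adds mean
#' reversion that bounds the stationary spread for very deep trees.
#' Gene log-means are sparse nonnegative combinations of the program
#' activities (`mean_g = base_g * exp(sum_k H_gk W_k(t))`), renormalised
#' per cell so total depth is governed by the per-cell library factor
#' `~ LogNormal(0, libsizeSigma)`. Counts are negative binomial with the
#' given size parameter (`dispersion = Inf` gives Poisson). Cells are
#' placed uniformly along their type's branch. Fully reproducible per
#' seed.
#'
#' @param topology a [SimTopology-class].
#' @param cellsPerType named integer vector, cells per branch label.
#' @param nGenes number of genes.
#' @param nPrograms number of expression programs.
#' @param programWalkSd per-step innovation standard deviation of the
#'   program walk (log scale).
#' @param programTau mean-reversion timescale of the program walk, in
#'   pseudotime steps; `Inf` gives a pure random walk.
#' @param dispersion negative-binomial size parameter; variance is
#'   `mu + mu^2 / dispersion`. The default 10 makes variance about twice
#'   the mean at mean 10. `Inf` gives Poisson counts.
#' @param libsizeSigma log-normal scale of the per-cell library factor.
#' @param totalCounts expected total counts per cell at library factor 1.
#' @param seed RNG seed.
#' @return A [SimDataset-class].
#' @export
simulateLineage <- function(topology, cellsPerType, nGenes = 500L,
                            nPrograms = 20L, programWalkSd = 0.11,
                            programTau = Inf, dispersion = 10,
                            libsizeSigma = 0.7, totalCounts = 2000,
                            seed = 1L) {
  stopifnot(is(topology, "SimTopology"))
  cellsPerType <- cellsPerType[cellsPerType > 0]
  if (!all(names(cellsPerType) %in% topology@branches))
    stop("cellsPerType keys must be topology branches; unknown: ",
         paste(setdiff(names(cellsPerType), topology@branches), collapse = ", "))
  withr::with_seed(as.integer(seed), {
    # sparse nonnegative gene-program weights
    H <- matrix(0, nGenes, nPrograms)
    kPer <- sample(1:3, nGenes, replace = TRUE)
    for (g in seq_len(nGenes)) {
      ks <- sample.int(nPrograms, kPer[g])
      H[g, ks] <- stats::rgamma(kPer[g], shape = 2, rate = 2)
    }
    base <- stats::rlnorm(nGenes, 0, 1)
    # program walks per branch, continuous from the parent endpoint
    start <- .branchStart(topology)
    W <- list()   # per branch: (steps+1) x nPrograms
    for (b in .topoOrder(topology)) {
      p <- topology@parent[[b]]
      w0 <- if (is.na(p)) rep(0, nPrograms) else W[[p]][nrow(W[[p]]), ]
      steps <- topology@length[[b]]
      inc <- matrix(stats::rnorm(steps * nPrograms, 0, programWalkSd),
                    steps, nPrograms)
      a <- if (is.infinite(programTau)) 1 else exp(-1 / programTau)
      Wb <- matrix(0, steps + 1, nPrograms)
      Wb[1, ] <- w0
      for (s in seq_len(steps)) Wb[s + 1, ] <- a * Wb[s, ] + inc[s, ]
      W[[b]] <- Wb
    }
    # place cells
    types <- rep(names(cellsPerType), cellsPerType)
    n <- length(types)
    tLocal <- stats::runif(n) * topology@length[types]
    pt <- start[types] + tLocal
    lib <- stats::rlnorm(n, 0, libsizeSigma)
    counts <- matrix(0L, n, nGenes)
    for (i in seq_len(n)) {
      b <- types[i]
      steps <- topology@length[[b]]
      Wi <- vapply(seq_len(nPrograms), function(k)
        stats::approx(0:steps, W[[b]][, k], xout = tLocal[i])$y,
        numeric(1))
      rel <- base * exp(H %*% Wi)[, 1]
      mu <- lib[i] * totalCounts * rel / sum(rel)
      counts[i, ] <- if (is.infinite(dispersion)) stats::rpois(nGenes, mu)
                     else stats::rnbinom(nGenes, mu = mu, size = dispersion)
    }
    cellIds <- sprintf("cell%04d", seq_len(n))
    rownames(counts) <- cellIds
    colnames(counts) <- sprintf("gene%03d", seq_len(nGenes))
    info <- data.frame(cell_id = cellIds, type = types, branch = types,
                       pseudotime = as.numeric(pt),
                       library_factor = lib, stringsAsFactors = FALSE)
    new("SimDataset", counts = counts, cellInfo = info,
        topology = topology, seed = as.integer(seed))
  })
}

#' Evaluation presets for the simulator
#'
#' \describe{
#'   \item{`rare_lineage`}{seven cell types A-G on a three-bifurcation
#'     tree with a rare terminal population: 300 cells each in A-D, 350 in
#'     F and G, and 15 in the rare leaf E (0.78% of the 1,915 cells).}
#'   \item{`six_bifurcations`}{a caterpillar of six successive
#'     bifurcations: 13 branch segments, 7 leaves, 1,300 cells (100 per
#'     segment) by 500 genes, library factors log-normal with scale 0.7.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return A [SimDataset-class].
#' @export
lineagePreset <- function(name = c("rare_lineage", "six_bifurcations"),
                          seed = 1L) {
  if (!name[1] %in% c("rare_lineage", "six_bifurcations"))
    stop("unknown preset '", name[1],
         "'; available: rare_lineage, six_bifurcations")
  name <- match.arg(name)
  if (name == "rare_lineage") {
    topo <- makeTopology(data.frame(
      from = c("origin", "A", "A", "B", "B", "D", "D"),
      to = c("A", "B", "C", "D", "E", "F", "G")), root = "origin")
    cells <- c(A = 300L, B = 300L, C = 300L, D = 300L, E = 15L,
               F = 350L, G = 350L)
    simulateLineage(topo, cells, nGenes = 500L, seed = seed)
  } else {
    topo <- makeTopology(data.frame(
      from = c("0", "1", "2", "3", "4", "5", "1", "2", "3", "4", "5",
               "6", "6"),
      to = c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11",
             "12", "13")), root = "0")
    cells <- stats::setNames(rep(100L, 13), topo@branches)
    simulateLineage(topo, cells, nGenes = 500L, nPrograms = 20L,
                    seed = seed)
  }
}

#' Write a simulated dataset to disk
#'
#' Writes the counts (MTX triplet with sidecars), the ground truth CSV
#' (`cell_id`, `type`, `branch`, `pseudotime`, `library_factor`) and the
#' topology as JSON and Newick.
#'
#' @param sim a [SimDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimDataset <- function(sim, dir) {
  stopifnot(is(sim, "SimDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  em <- ExpressionMatrix(sim@counts, layer = "counts")
  saveMatrix(em, file.path(dir, "counts.mtx"), format = "mtx")
  utils::write.csv(sim@cellInfo, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  topo <- sim@topology
  jsonlite::write_json(
    list(root = topo@root, branches = topo@branches,
         parent = as.list(topo@parent), length = as.list(topo@length)),
    file.path(dir, "topology.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(.topologyNewick(topo), file.path(dir, "topology.nwk"))
  invisible(dir)
}

.topologyNewick <- function(topo) {
  rec <- function(b) {
    ch <- topo@branches[!is.na(topo@parent) & topo@parent == b]
    lab <- b
    if (!length(ch)) return(paste0(lab, ":", topo@length[[b]]))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           lab, ":", topo@length[[b]])
  }
  paste0(rec(topo@root), ";")
}
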