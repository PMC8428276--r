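.CONFIG_KEYS <- c(
  "input", "input_format", "layer", "min_features_per_cell",
  "min_cells_per_feature", "scale_factor", "n_hvg", "clip", "n_pcs",
  "k", "algorithm", "resolution", "seed", "root", "leaf_groups",
  "hubs_per_cluster", "pta_bins", "pta_ranks", "lambda_sparse",
  "lambda_smooth", "outdir", "simulate_preset")

.CONFIG_DEFAULTS <- list(
  input = NULL, input_format = "auto", layer = "counts",
  min_features_per_cell = 0L, min_cells_per_feature = 0L,
  scale_factor = 1e4, n_hvg = 0L, clip = 10, n_pcs = 10L, k = 12L,
  algorithm = "leiden", resolution = 1, seed = 1L, root = NULL,
  leaf_groups = list(), hubs_per_cluster = 1L, pta_bins = 0L,
  pta_ranks = 3L, lambda_sparse = NULL, lambda_smooth = NULL,
  outdir = "trajtree_out", simulate_preset = NULL)

#' Build and validate a run configuration
#'
#' The configuration names the input (a matrix file or a simulator
#' preset), preprocessing thresholds, the number of PCs, the kNN size,
#' clustering settings, the root cluster, leaf-group specifications
#' (lists with `members` and `structure`), embedding and trend settings,
#' and the output directory. Unknown keys are rejected.
#'
#' @param ... configuration keys (see `trajtree:::.CONFIG_DEFAULTS` for
#'   the full set and defaults).
#' @return A validated `RunConfig` (named list, class `RunConfig`).
#' @export
runConfig <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  cfg[names(user)] <- user
  if (is.null(cfg$root) && length(cfg$leaf_groups))
    stop("config must name the root cluster when leaf groups are given")
  if (is.null(cfg$input) && is.null(cfg$simulate_preset))
    stop("config must name an input file or a simulate_preset")
  for (g in cfg$leaf_groups)
    if (!all(c("members", "structure") %in% names(g)))
      stop("each leaf group needs 'members' and 'structure'")
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration (YAML)
#' @param path YAML file path
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param cfg a `RunConfig`
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

# polynomial rolling hash of the deparsed analysis settings (the output
# location does not change the analysis, so it is excluded)
configHash <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL
  bytes <- utf8ToInt(paste(deparse(x[order(names(x))]), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.artifact <- function(cfg, name) file.path(cfg$outdir, name)

.requireArtifact <- function(cfg, name, stage) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop("stage '", stage, "' requires missing artifact: ", p)
  p
}

.writeTableWithHash <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trajtree config %s", configHash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readArtifactCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Pipeline stages
#'
#' Each stage consumes the previous stage's on-disk artifacts from
#' `cfg$outdir` and writes its own, so staged execution is
#' artifact-equivalent to [runPipeline] for fixed seeds.
#'
#' @param cfg a `RunConfig` from [runConfig].
#' @return The stage's main in-memory object, invisibly.
#' @name stages
NULL

#' @rdname stages
#' @export
stageSimulate <- function(cfg) {
  if (is.null(cfg$simulate_preset)) stop("config has no simulate_preset")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- lineagePreset(cfg$simulate_preset, seed = cfg$seed)
  writeSimDataset(sim, file.path(cfg$outdir, "sim"))
  invisible(sim)
}

#' @rdname stages
#' @export
stagePreprocess <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$input)) {
    mat <- loadMatrix(cfg$input, format = cfg$input_format, layer = cfg$layer)
  } else {
    p <- .requireArtifact(cfg, "sim/counts.mtx", "preprocess")
    mat <- loadMatrix(p, format = "mtx", layer = "counts")
  }
  if (mat@layer == "counts") {
    mat <- filterAndNormalize(mat, cfg$min_features_per_cell,
                              cfg$min_cells_per_feature, cfg$scale_factor)
    hvg <- if (cfg$n_hvg > 0) selectHVG(mat, cfg$n_hvg) else NULL
    scaled <- scaleFeatures(mat, clip = cfg$clip, features = hvg)
  } else if (mat@layer == "zscore") {
    scaled <- mat            # accessibility z-scores feed PCA directly
  } else {
    stop("unsupported input layer: ", mat@layer)
  }
  pcs <- runPCA(scaled, nComponents = cfg$n_pcs, seed = cfg$seed)
  saveMatrix(scaled, .artifact(cfg, "scaled.csv"), format = "csv")
  df <- data.frame(cell_id = rownames(pcs@coords), pcs@coords,
                   check.names = FALSE)
  .writeTableWithHash(df, .artifact(cfg, "pca.csv"), cfg)
  invisible(pcs)
}

.readPCA <- function(cfg, stage) {
  df <- .readArtifactCSV(.requireArtifact(cfg, "pca.csv", stage))
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df[[1]]
  coords
}

#' @rdname stages
#' @export
stageCluster <- function(cfg) {
  coords <- .readPCA(cfg, "cluster")
  graph <- buildKnnGraph(coords, cfg$k)
  clust <- clusterCommunities(graph, coords, algorithm = cfg$algorithm,
                              resolution = cfg$resolution, seed = cfg$seed)
  .writeTableWithHash(
    data.frame(cell_id = names(clust@labels), cluster = clust@labels),
    .artifact(cfg, "clusters.csv"), cfg)
  utils::write.table(graph@edges, .artifact(cfg, "graph_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(clust)
}

.readClustering <- function(cfg, coords, stage) {
  df <- .readArtifactCSV(.requireArtifact(cfg, "clusters.csv", stage))
  labels <- stats::setNames(as.integer(df$cluster), df$cell_id)
  centroids <- .centroidsOf(coords, as.integer(labels))
  new("Clustering", labels = labels, centroids = centroids,
      algorithm = cfg$algorithm, kUsed = as.integer(cfg$k),
      seed = as.integer(cfg$seed))
}

#' @rdname stages
#' @export
stageEmbed <- function(cfg) {
  coords <- .readPCA(cfg, "embed")
  clust <- .readClustering(cfg, coords, "embed")
  graph <- buildKnnGraph(coords, cfg$k)
  emb <- runLISOMAP(graph, clust, coords,
                    hubsPerCluster = cfg$hubs_per_cluster)
  df <- data.frame(cell_id = rownames(coords), emb@coords,
                   check.names = FALSE)
  .writeTableWithHash(df, .artifact(cfg, "embedding.csv"), cfg)
  invisible(emb)
}

#' @rdname stages
#' @export
stageTree <- function(cfg) {
  if (is.null(cfg$root)) stop("config must name the root cluster")
  coords <- .readPCA(cfg, "tree")
  clust <- .readClustering(cfg, coords, "tree")
  graph <- bridgeComponents(buildKnnGraph(coords, cfg$k), coords)
  cg <- clusterDistances(graph, clust)
  groups <- lapply(cfg$leaf_groups, function(g)
    LeafGroup(g$members, g$structure))
  tree <- spanningTree(cg, cfg$root, groups,
                       centroids = clust@centroids)
  exportTree(tree, .artifact(cfg, "tree.json"), format = "json")
  exportTree(tree, .artifact(cfg, "tree.nwk"), format = "newick")
  invisible(tree)
}

#' Read a trajectory tree written by [exportTree]'s JSON format
#' @param path JSON path
#' @export
readTreeJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TrajectoryTree",
      nodes = as.integer(obj$nodes),
      edges = data.frame(parent = as.integer(obj$edges$parent),
                         child = as.integer(obj$edges$child),
                         length = as.numeric(obj$edges$length)),
      root = as.integer(obj$root),
      leafFlags = stats::setNames(unlist(obj$leaf_flags),
                                  names(obj$leaf_flags)),
      provenance = stats::setNames(unlist(obj$provenance),
                                   names(obj$provenance)),
      validation = as.character(obj$validation %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname stages
#' @export
stagePseudotime <- function(cfg) {
  coords <- .readPCA(cfg, "pseudotime")
  clust <- .readClustering(cfg, coords, "pseudotime")
  tree <- readTreeJSON(.requireArtifact(cfg, "tree.json", "pseudotime"))
  assign <- mapCells(tree, clust, coords)
  writePseudotimeCSV(assign, .artifact(cfg, "pseudotime.csv"),
                     header = sprintf("trajtree config %s", configHash(cfg)))
  invisible(assign)
}

#' @rdname stages
#' @export
stagePTA <- function(cfg) {
  scaled <- loadMatrix(.requireArtifact(cfg, "scaled.csv", "pta"),
                       format = "csv", layer = "scaled")
  coords <- .readPCA(cfg, "pta")
  clust <- .readClustering(cfg, coords, "pta")
  tree <- readTreeJSON(.requireArtifact(cfg, "tree.json", "pta"))
  pt <- .readArtifactCSV(.requireArtifact(cfg, "pseudotime.csv", "pta"))
  assign <- new("PseudotimeAssignment", assignment = data.frame(
    cell = seq_len(nrow(pt)), cellId = pt$cell_id,
    edgeParent = pt$edge_parent, edgeChild = pt$edge_child,
    offset = pt$offset, pseudotime = pt$pseudotime, branch = pt$branch))
  results <- list()
  for (leaf in treeLeaves(tree)) {
    cells <- branchCells(assign, tree, leaf)
    if (length(cells) < 8) {
      warning("branch to leaf ", leaf, " has too few cells; skipped")
      next
    }
    nBins <- if (cfg$pta_bins > 0) cfg$pta_bins else min(100L, length(cells))
    bm <- binBranch(cells, scaled, pt$pseudotime,
                    nBins = nBins, branch = paste0("branch_", leaf))
    tr <- pta(bm, nRanks = cfg$pta_ranks,
              lambdaSparse = cfg$lambda_sparse,
              lambdaSmooth = cfg$lambda_smooth)
    trends <- data.frame(bin_pseudotime = tr@binPseudotime)
    for (k in seq_along(tr@ranks))
      trends[[paste0("rank", k)]] <-
        tr@ranks[[k]]$d * tr@ranks[[k]]$trend
    .writeTableWithHash(trends,
      .artifact(cfg, sprintf("trends_branch_%s.csv", leaf)), cfg)
    scoreTab <- do.call(rbind, lapply(seq_along(tr@ranks), function(k) {
      rg <- rankGenes(tr, k)
      if (nrow(rg)) cbind(rank = k, rg) else NULL
    }))
    if (!is.null(scoreTab))
      .writeTableWithHash(scoreTab,
        .artifact(cfg, sprintf("scores_branch_%s.csv", leaf)), cfg)
    results[[paste0("branch_", leaf)]] <- tr
  }
  invisible(results)
}

#' @rdname stages
#' @export
stageReport <- function(cfg) {
  coords <- .readPCA(cfg, "report")
  clust <- .readClustering(cfg, coords, "report")
  tree <- readTreeJSON(.requireArtifact(cfg, "tree.json", "report"))
  grDevices::pdf(.artifact(cfg, "report.pdf"), width = 7, height = 7)
  on.exit(grDevices::dev.off())
  plotPieTree(tree, clust)
  embPath <- .artifact(cfg, "embedding.csv")
  if (file.exists(embPath)) {
    emb <- .readArtifactCSV(embPath)
    plotEmbedding(as.matrix(emb[, -1]), clust@labels,
                  main = "3D L-ISOMAP (axis pairs)")
  }
  ptPath <- .artifact(cfg, "pseudotime.csv")
  if (file.exists(ptPath)) {
    ptab <- .readArtifactCSV(ptPath)
    plotPseudotime(coords[, 1:2, drop = FALSE], ptab$pseudotime)
  }
  for (leaf in treeLeaves(tree)) {
    sp <- .artifact(cfg, sprintf("scores_branch_%s.csv", leaf))
    tp <- .artifact(cfg, sprintf("trends_branch_%s.csv", leaf))
    if (!file.exists(sp) || !file.exists(tp)) {
      warning("no trend artifacts for branch ", leaf, "; heatmap skipped")
      next
    }
    plotTrendCurves(.readArtifactCSV(tp),
                    main = sprintf("branch %s trends", leaf))
  }
  invisible(.artifact(cfg, "report.pdf"))
}

#' Run the whole trajectory pipeline
#'
#' Executes preprocess, PCA, kNN graph + clustering, 3-D landmark ISOMAP,
#' constrained spanning tree, pseudotime and per-branch principal trend
#' analysis, writing all artifacts plus a machine-readable run log to
#' `cfg$outdir`. Any stage error halts with the stage name; artifacts
#' already written are retained.
#'
#' @param cfg a `RunConfig` from [runConfig].
#' @return Named list of in-memory stage results, invisibly.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  stages <- list(
    simulate = function() if (!is.null(cfg$simulate_preset))
      stageSimulate(cfg) else NULL,
    preprocess = function() stagePreprocess(cfg),
    cluster = function() stageCluster(cfg),
    embed = function() stageEmbed(cfg),
    tree = function() stageTree(cfg),
    pseudotime = function() stagePseudotime(cfg),
    pta = function() stagePTA(cfg))
  for (nm in names(stages)) {
    out[[nm]] <- tryCatch(stages[[nm]](), error = function(e)
      stop("pipeline halted at stage '", nm, "': ", conditionMessage(e),
           call. = FALSE))
  }
  log <- list(
    package_version = as.character(utils::packageVersion("trajtree")),
    r_version = R.version.string,
    config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
    config_hash = configHash(cfg),
    n_clusters = if (!is.null(out$cluster)) nClusters(out$cluster),
    tree_validation = if (!is.null(out$tree)) out$tree@validation,
    n_bifurcations = if (!is.null(out$tree)) countBifurcations(out$tree),
    n_branches = if (!is.null(out$tree)) countBranches(out$tree))
  jsonlite::write_json(log, .artifact(cfg, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
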