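#' Load an expression matrix from disk
#'
#' Reads a cells x features [ExpressionMatrix-class] from one of three
#' on-disk formats:
#' \describe{
#'   \item{`csv`}{dense CSV/TSV: header row holds feature ids, first column
#'     holds cell ids.}
#'   \item{`mtx`}{MatrixMarket triplet in the conventional genes x cells
#'     orientation, transposed on load; `barcodes.tsv` (cells) and
#'     `features.tsv` (genes) sidecars must sit next to the `.mtx` file.}
#'   \item{`h5`}{HDF5 container with datasets `/X` (cells x genes),
#'     `/obs/ids` and `/var/ids`; requires the `rhdf5` package.}
#' }
#'
#' @param path file path (for `mtx`, the `.mtx` file).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`; default guessed from the
#'   file extension.
#' @param layer layer tag to attach (default `"counts"`).
#' @return An [ExpressionMatrix-class] in cells x features orientation.
#' @export
loadMatrix <- function(path, format = c("auto", "csv", "mtx", "h5"),
                       layer = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      mtx = "mtx", h5 = "h5", hdf5 = "h5", csv = "csv", tsv = "csv",
      txt = "csv",
      stop("cannot guess format from extension of ", path))
  }
  switch(format,
    csv = .loadCsv(path, layer),
    mtx = .loadMtx(path, layer),
    h5 = .loadH5(path, layer))
}

.loadCsv <- function(path, layer) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, comment.char = "#"),
    error = function(e) stop("malformed CSV ", path, ": ", conditionMessage(e)))
  ExpressionMatrix(as.matrix(df), layer = layer)
}

.loadMtx <- function(path, layer) {
  dir <- dirname(path)
  bpath <- file.path(dir, "barcodes.tsv")
  fpath <- file.path(dir, "features.tsv")
  if (!file.exists(bpath) || !file.exists(fpath))
    stop("MTX sidecar files barcodes.tsv and features.tsv must sit next to ", path)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed MTX ", path, ": ",
                                         conditionMessage(e)))
  barcodes <- readLines(bpath)
  features <- readLines(fpath)
  # first column of multi-column sidecars is the id
  barcodes <- vapply(strsplit(barcodes, "\t"), `[[`, character(1), 1L)
  features <- vapply(strsplit(features, "\t"), `[[`, character(1), 1L)
  if (nrow(m) != length(features))
    stop("MTX has ", nrow(m), " rows but features.tsv lists ", length(features))
  if (ncol(m) != length(barcodes))
    stop("MTX has ", ncol(m), " columns but barcodes.tsv lists ", length(barcodes))
  # on-disk convention is genes x cells; transpose to cells x features
  ExpressionMatrix(t(as.matrix(m)), cellIds = barcodes, featureIds = features,
                   layer = layer)
}

.loadH5 <- function(path, layer) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 requires the rhdf5 package")
  x <- rhdf5::h5read(path, "X")
  cells <- as.character(rhdf5::h5read(path, "obs/ids"))
  genes <- as.character(rhdf5::h5read(path, "var/ids"))
  # /X stored genes x cells (column-per-cell); transpose to cells x features
  if (nrow(x) == length(genes) && ncol(x) == length(cells)) x <- t(x)
  if (nrow(x) != length(cells) || ncol(x) != length(genes))
    stop("HDF5 /X dimensions do not match /obs/ids, /var/ids")
  ExpressionMatrix(as.matrix(x), cellIds = cells, featureIds = genes,
                   layer = layer)
}

#' Write an expression matrix to disk
#'
#' Inverse of [loadMatrix]; `mtx` writes genes x cells with `barcodes.tsv`
#' and `features.tsv` sidecars, `csv` writes cells x features with a header
#' row, `h5` writes `/X`, `/obs/ids`, `/var/ids`.
#'
#' @param mat an [ExpressionMatrix-class]
#' @param path output path (for `mtx`, the `.mtx` file)
#' @param format output format
#' @return `path`, invisibly.
#' @export
saveMatrix <- function(mat, path, format = c("auto", "csv", "mtx", "h5")) {
  stopifnot(is(mat, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      mtx = "mtx", h5 = "h5", hdf5 = "h5", csv = "csv", tsv = "csv",
      stop("cannot guess format from extension of ", path))
  }
  if (format == "csv") {
    df <- data.frame(cell_id = mat@cellIds, mat@values, check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else if (format == "mtx") {
    m <- Matrix::Matrix(t(mat@values), sparse = TRUE)
    Matrix::writeMM(m, path)
    writeLines(mat@cellIds, file.path(dirname(path), "barcodes.tsv"))
    writeLines(mat@featureIds, file.path(dirname(path), "features.tsv"))
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing HDF5 requires the rhdf5 package")
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t(mat@values), path, "X")
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(mat@cellIds, path, "obs/ids")
    rhdf5::h5write(mat@featureIds, path, "var/ids")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Coerce a SummarizedExperiment-like container to ExpressionMatrix
#'
#' Transposes the conventional features x cells assay into the cells x
#' features orientation used here.
#'
#' @param se a SummarizedExperiment (or SingleCellExperiment)
#' @param assay assay name or index to extract
#' @param layer layer tag for the extracted values
#' @return An [ExpressionMatrix-class].
#' @export
fromSummarizedExperiment <- function(se, assay = 1L, layer = "counts") {
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("fromSummarizedExperiment requires the SummarizedExperiment package")
  a <- SummarizedExperiment::assay(se, assay)
  ExpressionMatrix(t(as.matrix(a)), cellIds = colnames(a),
                   featureIds = rownames(a), layer = layer)
}
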