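#' Paired unspliced/spliced velocity dataset
#'
#' The universal container moved through every workflow stage: an
#' unspliced matrix `U` and a spliced matrix `S` (cells x genes, same
#' shape and orderings), cell and gene identifiers, optional cell-type
#' labels, and a processing-state flag. The state advances monotonically
#' `raw -> normalised -> imputed`; stages refuse out-of-order input.
#'
#' @param U,S cells x genes nonnegative numeric matrices.
#' @param cell_ids character vector of unique cell identifiers
#'   (default `cell_1..n`).
#' @param gene_ids character vector of unique gene identifiers
#'   (default `gene_1..G`).
#' @param cell_type optional factor/character of cell-type labels.
#' @param stage processing state, one of `"raw"`, `"normalised"`,
#'   `"imputed"`.
#' @return An object of class `velocity_dataset`.
#' @export
velocity_dataset <- function(U, S, cell_ids = NULL, gene_ids = NULL,
                             cell_type = NULL, stage = "raw") {
  U <- as.matrix(U); S <- as.matrix(S)
  if (!identical(dim(U), dim(S)))
    stop("U and S must have identical dimensions")
  if (any(U < 0) || any(S < 0))
    stop("U and S must be nonnegative")
  n <- nrow(U); G <- ncol(U)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(G))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(cell_ids) != n || length(gene_ids) != G)
    stop("id lengths do not match matrix dimensions")
  if (!is.null(cell_type) && length(cell_type) != n)
    stop("cell_type length must equal the number of cells")
  stage <- match.arg(stage, c("raw", "normalised", "imputed"))
  dimnames(U) <- dimnames(S) <- list(cell_ids, gene_ids)
  structure(list(U = U, S = S, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_type = cell_type, stage = stage),
            class = "velocity_dataset")
}

#' @export
print.velocity_dataset <- function(x, ...) {
  cat(sprintf("velocity_dataset: %d cells x %d genes [%s]\n",
              nrow(x$U), ncol(x$U), x$stage))
  if (!is.null(x$cell_type))
    cat("cell types:", paste(utils::head(unique(as.character(x$cell_type)), 6),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.velocity_dataset <- function(x) dim(x$U)

#' Subset a velocity dataset
#'
#' @param x a [velocity_dataset()].
#' @param cells,genes index vectors (integer, logical or character).
#' @return the subset dataset, preserving the processing stage.
#' @export
subset_dataset <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "velocity_dataset"))
  if (is.null(cells)) cells <- seq_len(nrow(x$U))
  if (is.null(genes)) genes <- seq_len(ncol(x$U))
  U <- x$U[cells, genes, drop = FALSE]
  S <- x$S[cells, genes, drop = FALSE]
  velocity_dataset(U, S,
                   cell_ids = rownames(U), gene_ids = colnames(U),
                   cell_type = if (is.null(x$cell_type)) NULL
                               else x$cell_type[cells],
                   stage = x$stage)
}

.stage_rank <- c(raw = 1L, normalised = 2L, imputed = 3L)

# internal: assert that a stage transition is monotone
.advance_stage <- function(data, required, new) {
  if (.stage_rank[[data$stage]] > .stage_rank[[required]])
    stop(sprintf("dataset is already '%s'; this step requires '%s' input",
                 data$stage, required))
  data$stage <- new
  data
}

#' Read a paired U/S dataset from an MTX + TSV directory
#'
#' Expects a directory containing `spliced.mtx`, `unspliced.mtx`,
#' `barcodes.tsv` (one cell id per line) and `features.tsv` (one gene id
#' per line), the standard plain-text interchange written by read-counting
#' pipelines. Matrices may be stored cells x genes or genes x cells;
#' orientation is auto-detected from the barcode/feature counts and
#' rejected with a clear message when ambiguous resolution fails.
#'
#' @param path directory containing the four files.
#' @return a [velocity_dataset()] with stage `"raw"`.
#' @export
read_dataset_mtx <- function(path) {
  need <- c("spliced.mtx", "unspliced.mtx", "barcodes.tsv", "features.tsv")
  files <- file.path(path, need)
  missing <- need[!file.exists(files)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  S <- as.matrix(Matrix::readMM(files[1]))
  U <- as.matrix(Matrix::readMM(files[2]))
  barcodes <- readLines(files[3])
  features <- readLines(files[4])
  orient <- function(M) {
    if (nrow(M) == length(barcodes) && ncol(M) == length(features)) M
    else if (nrow(M) == length(features) && ncol(M) == length(barcodes)) t(M)
    else stop(sprintf(
      "matrix is %d x %d but there are %d barcodes and %d features: cannot orient",
      nrow(M), ncol(M), length(barcodes), length(features)))
  }
  if (length(barcodes) == length(features))
    warning("equal barcode and feature counts: assuming cells x genes orientation")
  velocity_dataset(orient(U), orient(S),
                   cell_ids = barcodes, gene_ids = features)
}

#' Write a paired U/S dataset as an MTX + TSV directory
#'
#' Inverse of [read_dataset_mtx()]; the round trip is lossless up to
#' MatrixMarket numeric formatting.
#'
#' @param data a [velocity_dataset()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset_mtx <- function(data, path) {
  stopifnot(inherits(data, "velocity_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(data$S, sparse = TRUE),
                  file.path(path, "spliced.mtx"))
  Matrix::writeMM(Matrix::Matrix(data$U, sparse = TRUE),
                  file.path(path, "unspliced.mtx"))
  writeLines(data$cell_ids, file.path(path, "barcodes.tsv"))
  writeLines(data$gene_ids, file.path(path, "features.tsv"))
  invisible(path)
}
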