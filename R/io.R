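#' Read a dataset from MTX + TSV files
#'
#' Expects the MatrixMarket triplet layout common in single-cell pipelines:
#' `matrix.mtx` (features x cells or cells x features; orientation is
#' resolved against the id files), `features.tsv` (one feature id per line),
#' `barcodes.tsv` (one cell id per line) and optionally `labels.csv` with
#' columns `cell_id, cell_type`.
#'
#' @param dir directory containing the files, or explicit paths via the
#'   named arguments.
#' @param matrix_file,features_file,barcodes_file,labels_file file paths;
#'   defaults are resolved inside `dir`.
#' @param modality `"atac"` or `"rna"`.
#' @return A [raw_dataset()] (cells x features).
#' @export
read_mtx_dataset <- function(dir = NULL,
                             matrix_file = file.path(dir, "matrix.mtx"),
                             features_file = file.path(dir, "features.tsv"),
                             barcodes_file = file.path(dir, "barcodes.tsv"),
                             labels_file = file.path(dir, "labels.csv"),
                             modality = c("atac", "rna")) {
  modality <- match.arg(modality)
  for (f in c(matrix_file, features_file, barcodes_file)) {
    if (!file.exists(f)) stop("missing file: ", f)
  }
  x <- Matrix::readMM(matrix_file)
  # pattern matrices (written for binary data) come back without values
  x <- methods::as(methods::as(x, "dMatrix"), "CsparseMatrix")
  features <- readLines(features_file)
  barcodes <- readLines(barcodes_file)
  if (nrow(x) == length(features) && ncol(x) == length(barcodes)) {
    x <- Matrix::t(x)  # features x cells on disk
  } else if (!(nrow(x) == length(barcodes) && ncol(x) == length(features))) {
    stop("matrix dimensions ", nrow(x), "x", ncol(x),
         " match neither orientation of ", length(barcodes), " cells x ",
         length(features), " features")
  }
  labels <- NULL
  if (file.exists(labels_file)) {
    lab <- read.csv(labels_file, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "cell_type") %in% names(lab))) {
      stop("labels.csv needs columns cell_id, cell_type")
    }
    idx <- match(barcodes, lab$cell_id)
    if (any(is.na(idx))) {
      stop("labels.csv missing cell(s): ",
           paste(head(barcodes[is.na(idx)], 3L), collapse = ", "))
    }
    labels <- lab$cell_type[idx]
  }
  raw_dataset(methods::as(x, "CsparseMatrix"), features, barcodes, labels,
              modality)
}

#' Write a dataset as MTX + TSV files
#'
#' Inverse of [read_mtx_dataset()]: writes `matrix.mtx` (cells x features),
#' `features.tsv`, `barcodes.tsv` and, when labels are present, `labels.csv`.
#'
#' @param ds a [raw_dataset()] or [processed_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "raw_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- ds$matrix
  if (!is(m, "sparseMatrix")) m <- methods::as(Matrix::Matrix(m, sparse = TRUE),
                                               "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$feature_ids, file.path(dir, "features.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(ds$labels)) {
    write.csv(data.frame(cell_id = ds$cell_ids, cell_type = ds$labels),
              file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Write a selected-feature list, one id per line
#'
#' @param ds a [processed_dataset()].
#' @param path output text file.
#' @export
write_feature_list <- function(ds, path) {
  writeLines(ds$feature_ids, path)
  invisible(path)
}
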