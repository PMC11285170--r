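#' Cell-by-feature dataset containers
#'
#' `raw_dataset()` wraps a cells x features count matrix together with feature
#' identifiers, cell identifiers, an optional per-cell label vector and the
#' assay modality. `processed_dataset()` is the same container after
#' modality-specific preprocessing (binarization for ATAC, normalization for
#' RNA, highly variable feature selection) and carries a provenance record.
#'
#' Feature identifiers are genomic peak coordinates `"chrom:start-end"`
#' (0-based half-open) for ATAC, gene symbols for RNA.
#'
#' @param matrix numeric cells x features matrix (base matrix or a
#'   `Matrix` sparse matrix); all entries must be finite and non-negative.
#' @param feature_ids character vector, one id per column.
#' @param cell_ids character vector, one id per row.
#' @param labels optional character vector of per-cell type names (required
#'   for a labeled source dataset); non-empty strings, whitespace-trimmed.
#' @param modality `"atac"` or `"rna"`.
#' @param provenance list recording preprocessing parameters.
#' @return An object of class `raw_dataset` (resp. `processed_dataset`).
#' @export
raw_dataset <- function(matrix, feature_ids, cell_ids, labels = NULL,
                        modality = c("atac", "rna")) {
  modality <- match.arg(modality)
  stopifnot(length(dim(matrix)) == 2L)
  if (nrow(matrix) != length(cell_ids)) {
    stop("matrix has ", nrow(matrix), " rows but ", length(cell_ids), " cell_ids")
  }
  if (ncol(matrix) != length(feature_ids)) {
    stop("matrix has ", ncol(matrix), " columns but ", length(feature_ids),
         " feature_ids")
  }
  vals <- if (is(matrix, "sparseMatrix")) matrix@x else as.vector(as_dense(matrix))
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
    stop("matrix entries must be finite and >= 0")
  }
  if (!is.null(labels)) {
    labels <- trimws(as.character(labels))
    if (length(labels) != length(cell_ids)) {
      stop("labels length (", length(labels), ") != number of cells (",
           length(cell_ids), ")")
    }
    if (any(is.na(labels) | labels == "")) stop("labels must be non-empty strings")
  }
  structure(
    list(matrix = matrix, feature_ids = as.character(feature_ids),
         cell_ids = as.character(cell_ids), labels = labels,
         modality = modality),
    class = "raw_dataset"
  )
}

#' @rdname raw_dataset
#' @export
processed_dataset <- function(matrix, feature_ids, cell_ids, labels = NULL,
                              modality = c("atac", "rna"),
                              provenance = list()) {
  ds <- raw_dataset(matrix, feature_ids, cell_ids, labels, modality)
  if (ds$modality == "atac" && !is_binary_matrix(ds$matrix)) {
    stop("processed ATAC matrix must be binary (0/1)")
  }
  ds$provenance <- provenance
  class(ds) <- c("processed_dataset", "raw_dataset")
  ds
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d cells x %d features, modality %s%s\n",
              class(x)[1L], nrow(x$matrix), ncol(x$matrix), x$modality,
              if (is.null(x$labels)) "" else
                sprintf(", %d label(s)", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.raw_dataset <- function(x) dim(x$matrix)

# subset columns of a dataset by feature index, preserving class and metadata
subset_features <- function(ds, idx) {
  ds$matrix <- ds$matrix[, idx, drop = FALSE]
  ds$feature_ids <- ds$feature_ids[idx]
  ds
}
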