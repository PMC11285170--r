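#' Binarize an scATAC peak matrix and drop low-prevalence peaks
#'
#' Any positive count becomes 1, then only peaks with at least one read in at
#' least `min_cell_fraction` of cells are kept (at least
#' `max(1, ceiling(min_cell_fraction * N))` cells, so the filter stays
#' meaningful for tiny datasets). Feature order is preserved.
#'
#' @param raw an ATAC [raw_dataset()].
#' @param min_cell_fraction minimum fraction of cells with a nonzero entry
#'   (default 0.001, i.e. 0.1% of cells).
#' @return A binarized, filtered `raw_dataset`.
#' @export
binarize_and_filter <- function(raw, min_cell_fraction = 0.001) {
  stopifnot(inherits(raw, "raw_dataset"))
  if (raw$modality != "atac") stop("binarize_and_filter expects an ATAC dataset")
  if (!(min_cell_fraction >= 0 && min_cell_fraction < 1)) {
    stop("min_cell_fraction must be in [0, 1)")
  }
  n <- nrow(raw$matrix)
  if (n == 0L || ncol(raw$matrix) == 0L) stop("empty matrix")

  x <- raw$matrix
  if (is(x, "sparseMatrix")) {
    x <- methods::as(Matrix::drop0(x), "CsparseMatrix")
    x@x <- rep(1, length(x@x))
  } else {
    x <- (x > 0) * 1
  }
  threshold <- max(1L, ceiling(min_cell_fraction * n))
  prevalence <- Matrix::colSums(x)
  keep <- which(prevalence >= threshold)
  if (length(keep) == 0L) {
    stop("all ", ncol(x), " peaks fall below the prevalence threshold of ",
         threshold, " cells")
  }
  out <- raw
  out$matrix <- x[, keep, drop = FALSE]
  out$feature_ids <- raw$feature_ids[keep]
  out
}

#' Select highly variable features
#'
#' Ranks features by empirical (population) variance — for a binarized peak
#' matrix this is the accessible fraction p times (1 - p), maximal for peaks
#' open in half the cells — and keeps the top `n_features`. Ties are broken
#' toward the lower original column index, so selection is deterministic and
#' nested: the top-n set is a subset of the top-(n+1) set.
#'
#' @param ds a [raw_dataset()], already binarized+filtered (ATAC) or
#'   normalized (RNA).
#' @param n_features number of features to keep (20,000 peaks or 3,000 genes
#'   are the usual choices); if fewer are available, all are kept.
#' @param score optional alternative scoring function taking the matrix and
#'   returning one nonnegative score per column.
#' @return A [processed_dataset()] restricted to the selected features, in
#'   their original order.
#' @export
select_highly_variable <- function(ds, n_features, score = NULL) {
  stopifnot(inherits(ds, "raw_dataset"), n_features >= 1)
  x <- ds$matrix
  s <- if (is.null(score)) feature_variance(x) else score(x)
  stopifnot(length(s) == ncol(x))
  n_keep <- min(as.integer(n_features), ncol(x))
  top <- order(-s, seq_along(s))[seq_len(n_keep)]
  keep <- sort(top)  # original column order
  processed_dataset(x[, keep, drop = FALSE], ds$feature_ids[keep],
                    ds$cell_ids, ds$labels, ds$modality,
                    provenance = c(ds$provenance %||% list(),
                                   list(n_features = n_keep,
                                        score = if (is.null(score))
                                          "variance" else "custom")))
}

# population variance per column; equals p(1-p) for binary columns
feature_variance <- function(x) {
  m1 <- Matrix::colMeans(x)
  m2 <- Matrix::colMeans(x * x)
  as.numeric(m2 - m1^2)
}

#' Normalize an scRNA count matrix
#'
#' Scales each cell's counts so the cell total equals `size_factor`
#' (default 10,000), then applies `log(1 + x)`. Genes expressed in fewer than
#' 0.1% of cells are expected to have been removed beforehand (see
#' [prevalence_filter_rna()]).
#'
#' @param raw an RNA [raw_dataset()].
#' @param size_factor target per-cell total after scaling.
#' @return A `raw_dataset` of normalized log values.
#' @export
normalize_rna <- function(raw, size_factor = 1e4) {
  stopifnot(inherits(raw, "raw_dataset"))
  if (raw$modality != "rna") stop("normalize_rna expects an RNA dataset")
  totals <- Matrix::rowSums(raw$matrix)
  if (any(totals == 0)) {
    bad <- raw$cell_ids[which(totals == 0)]
    stop("cell(s) with zero total counts: ", paste(head(bad, 5L), collapse = ", "))
  }
  x <- as_dense(raw$matrix)
  x <- log1p(x * (size_factor / totals))
  out <- raw
  out$matrix <- x
  out
}

#' Drop genes expressed in fewer than a fraction of cells
#'
#' The RNA analogue of the ATAC prevalence filter: a gene is kept if it has a
#' nonzero count in at least `max(1, ceiling(min_cell_fraction * N))` cells.
#'
#' @inheritParams binarize_and_filter
#' @export
prevalence_filter_rna <- function(raw, min_cell_fraction = 0.001) {
  stopifnot(inherits(raw, "raw_dataset"), raw$modality == "rna")
  n <- nrow(raw$matrix)
  if (n == 0L || ncol(raw$matrix) == 0L) stop("empty matrix")
  threshold <- max(1L, ceiling(min_cell_fraction * n))
  prevalence <- Matrix::colSums(raw$matrix > 0)
  keep <- which(prevalence >= threshold)
  if (length(keep) == 0L) stop("all genes fall below the prevalence threshold")
  subset_features(raw, keep)
}

parse_peaks <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop("unparseable peak identifier: \"", ids[bad[1L]], "\"")
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.numeric(vapply(m, `[`, "", 3L))
  end <- as.numeric(vapply(m, `[`, "", 4L))
  # coordinates are 0-based half-open; IRanges is 1-based closed
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Remap a source peak matrix onto a target peak set
#'
#' When source and target were called against different peak sets, source
#' counts are transferred to the target peaks: each target peak receives the
#' sum of counts of every overlapping source peak (0-based half-open
#' intervals, overlap = nonempty intersection). Target peaks with no
#' overlapping source peak get zeros.
#'
#' @param source an ATAC [raw_dataset()] with `"chrom:start-end"` feature ids.
#' @param target_peaks character vector of target peak identifiers.
#' @return A `raw_dataset` over `target_peaks`.
#' @export
remap_source_to_target_peaks <- function(source, target_peaks) {
  stopifnot(inherits(source, "raw_dataset"), source$modality == "atac")
  src_gr <- parse_peaks(source$feature_ids)
  tgt_gr <- parse_peaks(target_peaks)
  hits <- GenomicRanges::findOverlaps(src_gr, tgt_gr)
  map <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(length(src_gr), length(tgt_gr)))
  remapped <- as_dense(source$matrix %*% map)
  out <- source
  out$matrix <- remapped
  out$feature_ids <- as.character(target_peaks)
  out
}

#' Restrict two processed datasets to their common features
#'
#' Both datasets are subset, in identical order (the source's selected
#' order), to the intersection of their feature identifiers.
#'
#' @param source,target [processed_dataset()]s.
#' @return A list with elements `source` and `target`.
#' @export
align_features <- function(source, target) {
  common <- intersect(source$feature_ids, target$feature_ids)
  if (length(common) == 0L) {
    stop("no common features between source (", length(source$feature_ids),
         ") and target (", length(target$feature_ids), ")")
  }
  list(source = subset_features(source, match(common, source$feature_ids)),
       target = subset_features(target, match(common, target$feature_ids)))
}

#' Full preprocessing pipeline for a source/target pair
#'
#' ATAC: optional remapping of source counts onto the target peak set (done
#' automatically when the peak sets differ), binarization + prevalence
#' filtering of each dataset, feature alignment, then highly variable peak
#' selection scored on the concatenation of source and target cells.
#' RNA: prevalence filter, per-cell normalization + log1p, alignment, highly
#' variable gene selection on the concatenation.
#'
#' @param source labeled [raw_dataset()].
#' @param target unlabeled [raw_dataset()] of the same modality.
#' @param n_features number of highly variable features to keep
#'   (default 20,000 for ATAC, 3,000 for RNA).
#' @param min_cell_fraction prevalence threshold (default 0.001).
#' @param size_factor RNA normalization size factor (default 10,000).
#' @param hv_on where to score variability: `"both"` (concatenated source and
#'   target, the default), `"source"`, or `"target"`.
#' @return A list with processed, feature-aligned `source` and `target`.
#' @export
preprocess_pair <- function(source, target, n_features = NULL,
                            min_cell_fraction = 0.001, size_factor = 1e4,
                            hv_on = c("both", "source", "target")) {
  hv_on <- match.arg(hv_on)
  stopifnot(inherits(source, "raw_dataset"), inherits(target, "raw_dataset"))
  if (source$modality != target$modality) stop("modalities differ")
  modality <- source$modality
  if (is.null(n_features)) n_features <- if (modality == "atac") 20000L else 3000L

  if (modality == "atac") {
    if (!identical(source$feature_ids, target$feature_ids)) {
      source <- remap_source_to_target_peaks(source, target$feature_ids)
    }
    src <- binarize_and_filter(source, min_cell_fraction)
    tgt <- binarize_and_filter(target, min_cell_fraction)
  } else {
    src <- normalize_rna(prevalence_filter_rna(source, min_cell_fraction),
                         size_factor)
    tgt <- normalize_rna(prevalence_filter_rna(target, min_cell_fraction),
                         size_factor)
  }
  common <- intersect(src$feature_ids, tgt$feature_ids)
  if (length(common) == 0L) stop("no features survive filtering in both datasets")
  src <- subset_features(src, match(common, src$feature_ids))
  tgt <- subset_features(tgt, match(common, tgt$feature_ids))

  score_mat <- switch(hv_on,
    both = rbind(as_dense(src$matrix), as_dense(tgt$matrix)),
    source = as_dense(src$matrix),
    target = as_dense(tgt$matrix))
  s <- feature_variance(score_mat)
  n_keep <- min(as.integer(n_features), length(s))
  keep <- sort(order(-s, seq_along(s))[seq_len(n_keep)])

  prov <- list(min_cell_fraction = min_cell_fraction, n_features = n_keep,
               modality = modality, hv_on = hv_on, score = "variance")
  list(
    source = processed_dataset(src$matrix[, keep, drop = FALSE],
                               src$feature_ids[keep], src$cell_ids,
                               src$labels, modality, prov),
    target = processed_dataset(tgt$matrix[, keep, drop = FALSE],
                               tgt$feature_ids[keep], tgt$cell_ids,
                               tgt$labels, modality, prov)
  )
}
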