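#' Annotate target cells with a trained model
#'
#' Deterministic inference: cells are embedded at the posterior mean (no
#' sampling), the closed-set classifier proposes the nearest known type, and
#' the corresponding one-vs-all head gates the call — a cell is labeled
#' `"unknown"` unless the gating probability exceeds the threshold. The
#' default threshold is the fixed 0.5 of the assignment rule; the learned
#' per-head boundary can be used instead via `gate_with_boundary`.
#'
#' Prediction never modifies the model or its boundary vector.
#'
#' @param object a trained `openanno_model` (or an `openanno_fit`).
#' @param target a [processed_dataset()] whose features match the model's
#'   feature list, or a bare cells x features matrix.
#' @param gate_with_boundary gate at the learned boundary vector instead of
#'   0.5.
#' @param ... unused.
#' @return An `openanno_prediction`: list with `cell_ids`, `labels` (known
#'   type or `"unknown"`), `closed_probs`, `open_probs`, and `embedding`
#'   (N x L posterior means).
#' @export
predict.openanno_model <- function(object, target, gate_with_boundary = FALSE,
                                   ...) {
  model <- object
  if (inherits(target, "raw_dataset")) {
    if (!is.null(model$feature_ids) &&
        !identical(target$feature_ids, model$feature_ids)) {
      missing <- setdiff(model$feature_ids, target$feature_ids)
      stop("target features do not match the model's feature list; ",
           length(missing), " missing, e.g. ",
           paste(head(missing, 3L), collapse = ", "))
    }
    x <- as_dense(target$matrix)
    ids <- target$cell_ids
  } else {
    x <- as_dense(target)
    ids <- rownames(x) %||% sprintf("cell_%d", seq_len(nrow(x)))
  }
  lat <- encode(x, model)
  closed <- closed_forward(lat$mu, model)
  open <- open_forward(lat$mu, model)
  jstar <- max.col(closed, ties.method = "first")
  gate <- open[cbind(seq_len(nrow(open)), jstar)]
  thr <- if (gate_with_boundary) model$boundary[jstar] else 0.5
  labels <- ifelse(gate > thr, model$config$labels[jstar], "unknown")
  structure(list(cell_ids = ids, labels = labels,
                 closed_probs = closed, open_probs = open,
                 embedding = lat$mu),
            class = "openanno_prediction")
}

#' @export
predict.openanno_fit <- function(object, target, ...) {
  predict(object$model, target, ...)
}

#' @export
print.openanno_prediction <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<openanno_prediction> %d cells: %s\n", length(x$labels),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export predictions and the latent embedding
#'
#' `write_predictions()` writes one row per cell with the predicted label,
#' the closed-set maximum probability and the gating open-set probability.
#' `write_embedding()` writes the N x L posterior-mean embedding with cell
#' ids and labels, for downstream analysis.
#'
#' @param pred an `openanno_prediction`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(pred, path) {
  jstar <- max.col(pred$closed_probs, ties.method = "first")
  df <- data.frame(
    cell_id = pred$cell_ids,
    predicted_label = pred$labels,
    closed_max_prob = pred$closed_probs[cbind(seq_along(jstar), jstar)],
    open_gate_prob = pred$open_probs[cbind(seq_along(jstar), jstar)]
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_embedding <- function(pred, path) {
  emb <- as.data.frame(pred$embedding)
  names(emb) <- sprintf("latent_%02d", seq_len(ncol(emb)))
  df <- cbind(data.frame(cell_id = pred$cell_ids, label = pred$labels), emb)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
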