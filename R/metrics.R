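#' Effective assignment scores for open-set annotation
#'
#' Let `N_k` be the truly-known cells (true label in `known_types`) and
#' `N_u` the truly-unknown cells. With `N_k^k` the known cells predicted as
#' any known type, `N_k^true` the known cells predicted as their own type,
#' and `N_u^k` the unknown cells predicted as a known type:
#'
#' `EAS = N_k^k / N_k - N_u^k / N_u`
#' `EAS_M = N_k^true / N_k - N_u^k / N_u`
#'
#' EAS_M is the stricter score (it demands the correct known type, not just
#' any known type) and never exceeds EAS. Both are 1 for a perfect open-set
#' classifier and 0 for one that predicts everything unknown.
#'
#' When a split has no unknown (or no known) cells the corresponding ratio is
#' undefined; the defined term is returned alone and the result carries a
#' `partial` flag naming the missing side.
#'
#' @param y_true character true labels (may include types outside
#'   `known_types`).
#' @param y_pred character predicted labels: a known type or `"unknown"`.
#' @param known_types character vector of the K known (source) types.
#' @return List with `eas`, `eas_m`, `counts` (N_k, N_u, N_k_k, N_k_true,
#'   N_u_k) and `partial` (NULL, `"no_unknown"` or `"no_known"`).
#' @export
effective_assignment <- function(y_true, y_pred, known_types) {
  stopifnot(length(y_true) == length(y_pred))
  true_known <- y_true %in% known_types
  pred_known <- y_pred %in% known_types
  counts <- list(
    N_k = sum(true_known),
    N_u = sum(!true_known),
    N_k_k = sum(true_known & pred_known),
    N_k_true = sum(true_known & y_pred == y_true),
    N_u_k = sum(!true_known & pred_known)
  )
  partial <- NULL
  if (counts$N_u == 0L && counts$N_k == 0L) stop("no cells")
  if (counts$N_u == 0L) {
    partial <- "no_unknown"
    eas <- counts$N_k_k / counts$N_k
    eas_m <- counts$N_k_true / counts$N_k
  } else if (counts$N_k == 0L) {
    partial <- "no_known"
    eas <- eas_m <- -counts$N_u_k / counts$N_u
  } else {
    eas <- counts$N_k_k / counts$N_k - counts$N_u_k / counts$N_u
    eas_m <- counts$N_k_true / counts$N_k - counts$N_u_k / counts$N_u
  }
  list(eas = eas, eas_m = eas_m, counts = counts, partial = partial)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors over the union of
#' their vocabularies: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement (confusion-matrix trace over total) and `p_e` the
#' expected agreement from the row/column marginals. In the degenerate case
#' `p_e == 1` (a single class on both sides), returns 1 if agreement is
#' perfect and 0 otherwise, with a `degenerate` attribute.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- union(y_true, y_pred)
  A <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  total <- sum(A)
  p_o <- sum(diag(A)) / total
  p_e <- sum(rowSums(A) * colSums(A)) / total^2
  if (abs(1 - p_e) < 1e-15) {
    out <- if (abs(p_o - 1) < 1e-15) 1 else 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Open-set evaluation of a prediction against ground truth
#'
#' Builds the (K+1) x (K+1) confusion matrix (rows true, columns predicted,
#' last class `"unknown"`), pooling every truly-unseen type into the single
#' unknown truth class — the scores only distinguish known from unknown, and
#' predictions cannot name unseen types. Computes EAS, EAS_M and Cohen's
#' kappa over the pooled (K+1)-class problem.
#'
#' @param pred an `openanno_prediction` (or a bare character vector of
#'   predicted labels).
#' @param truth_labels character true labels per cell.
#' @param known_types the K known types; defaults to the model vocabulary
#'   carried by `pred`.
#' @param cell_ids optional ids accompanying `truth_labels`, checked against
#'   `pred$cell_ids`.
#' @return An `open_set_eval`: list with `eas`, `eas_m`, `kappa`, `counts`,
#'   `confusion`, `known_types`, `partial`.
#' @export
evaluate_predictions <- function(pred, truth_labels, known_types = NULL,
                                 cell_ids = NULL) {
  if (inherits(pred, "openanno_prediction")) {
    if (!is.null(cell_ids)) {
      bad <- which(cell_ids != pred$cell_ids)
      if (length(bad)) {
        stop("cell id mismatch at position(s) ",
             paste(head(bad, 5L), collapse = ", "), ": ",
             paste(head(cell_ids[bad], 3L), collapse = ", "))
      }
    }
    y_pred <- pred$labels
  } else {
    y_pred <- as.character(pred)
  }
  stopifnot(length(y_pred) == length(truth_labels))
  if (is.null(known_types)) {
    known_types <- setdiff(unique(y_pred), "unknown")
  }
  ea <- effective_assignment(truth_labels, y_pred, known_types)
  pooled_true <- ifelse(truth_labels %in% known_types, truth_labels, "unknown")
  classes <- c(known_types, "unknown")
  confusion <- table(true = factor(pooled_true, levels = classes),
                     predicted = factor(y_pred, levels = classes))
  kappa <- cohens_kappa(pooled_true, y_pred)
  stopifnot(ea$eas_m <= ea$eas + 1e-12)
  structure(list(eas = ea$eas, eas_m = ea$eas_m, kappa = as.numeric(kappa),
                 counts = ea$counts, confusion = unclass(confusion),
                 known_types = known_types, partial = ea$partial),
            class = "open_set_eval")
}

#' @export
print.open_set_eval <- function(x, ...) {
  cat(sprintf("<open_set_eval> EAS %.4f, EAS_M %.4f, kappa %.4f (N_k=%d, N_u=%d)\n",
              x$eas, x$eas_m, x$kappa, x$counts$N_k, x$counts$N_u))
  invisible(x)
}
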