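#' Training objectives
#'
#' The model is trained with five terms: the KL divergence of the variational
#' posterior from the standard normal prior, a reconstruction loss (binary
#' cross-entropy for ATAC, mean squared error for RNA), cross-entropy of the
#' closed-set classifier on labeled source cells, a hard-example-weighted
#' one-vs-all loss on source cells ([open_source_loss()]), and an adversarial
#' boundary loss on target cells ([open_target_loss()]) applied through
#' gradient reversal.
#'
#' @name losses
NULL

#' KL divergence of the diagonal-Gaussian posterior from N(0, I)
#'
#' Mean over cells of `sum_l 0.5 * (-1 - log_var + mu^2 + exp(log_var))`.
#'
#' @param mu,log_var N x L matrices of posterior means and log-variances.
#' @return Nonnegative scalar; 0 iff mu = 0 and variance = 1 everywhere.
#' @export
kl_divergence <- function(mu, log_var) {
  mu <- as.matrix(mu); log_var <- as.matrix(log_var)
  stopifnot(identical(dim(mu), dim(log_var)))
  if (any(!is.finite(mu)) || any(!is.finite(log_var))) {
    stop("non-finite posterior parameters")
  }
  sum(0.5 * (-1 - log_var + mu^2 + exp(log_var))) / nrow(mu)
}

#' Reconstruction loss
#'
#' ATAC: mean binary cross-entropy between the observed binary matrix and the
#' decoder's Bernoulli probabilities. RNA: mean squared error.
#'
#' @param x_hat reconstruction (probabilities in (0,1) for ATAC).
#' @param x observed matrix (binary for ATAC).
#' @param modality `"atac"` or `"rna"`.
#' @return Nonnegative scalar (mean over all matrix entries).
#' @export
reconstruction_loss <- function(x_hat, x, modality = c("atac", "rna")) {
  modality <- match.arg(modality)
  x <- as_dense(x); x_hat <- as_dense(x_hat)
  stopifnot(identical(dim(x), dim(x_hat)))
  if (modality == "atac") {
    if (!all(x %in% c(0, 1))) stop("ATAC reconstruction target must be binary")
    p <- clamp_prob(x_hat)
    -mean(x * log(p) + (1 - x) * log(1 - p))
  } else {
    mean((x_hat - x)^2)
  }
}

#' Closed-set cross-entropy
#'
#' @param closed_probs N x K softmax probabilities.
#' @param labels integer class indices in 1..K.
#' @return Mean negative log probability of the true class.
#' @export
closed_loss <- function(closed_probs, labels) {
  n <- nrow(closed_probs)
  stopifnot(length(labels) == n)
  if (any(labels < 1L | labels > ncol(closed_probs))) {
    stop("label outside 1..K")
  }
  p <- clamp_prob(closed_probs[cbind(seq_len(n), labels)])
  -mean(log(p))
}

#' Class-imbalance weights for one one-vs-all head
#'
#' Head j sees the batch's cells of type j as positives and everything else
#' as negatives. Positives are up-weighted by the negative:positive count
#' ratio; negatives get weight 1. With no positives in the batch the ratio is
#' undefined: all-ones weights are returned with attribute
#' `skip_positive = TRUE` and the head's positive term is skipped for that
#' batch.
#'
#' @param labels integer class indices in 1..K.
#' @param j head index.
#' @return Numeric weight per cell.
#' @export
alpha_weights <- function(labels, j) {
  pos <- labels == j
  n_pos <- sum(pos)
  n_neg <- length(labels) - n_pos
  w <- rep(1, length(labels))
  if (n_pos == 0L) {
    attr(w, "skip_positive") <- TRUE
    return(w)
  }
  w[pos] <- n_neg / n_pos
  w
}

# p_hat: probability of the *wrong* side; 1-p for positives, p for negatives
open_phat <- function(open_probs, labels) {
  pos <- outer(labels, seq_len(ncol(open_probs)), `==`)
  ifelse(pos, 1 - open_probs, open_probs)
}

#' One-vs-all source loss with hard-example weighting
#'
#' For head j and cell i let `p_hat = 1 - p_j(x_i)` if the cell is a positive
#' for j and `p_hat = p_j(x_i)` otherwise (the probability mass on the wrong
#' side). The loss is `(1/N) * sum_j sum_i -alpha_ij * p_hat * log(1 - p_hat)`
#' — the `p_hat` factor focuses each head on its hard-to-separate cells, and
#' alpha corrects the one-vs-all class imbalance. Normalization is by the
#' number of cells N only (not N*K).
#'
#' @param open_probs N x K per-head probabilities.
#' @param labels integer class indices in 1..K.
#' @param plain_bce if `TRUE`, replace the weighted loss with standard
#'   per-head binary cross-entropy (the corresponding ablation), keeping the
#'   same 1/N normalization.
#' @return Nonnegative scalar.
#' @export
open_source_loss <- function(open_probs, labels, plain_bce = FALSE) {
  n <- nrow(open_probs); K <- ncol(open_probs)
  # labels beyond K are legal: such cells are negatives for every head
  stopifnot(length(labels) == n, all(labels >= 1L))
  p <- clamp_prob(open_probs)
  pos <- outer(labels, seq_len(K), `==`)
  if (plain_bce) {
    return(-sum(ifelse(pos, log(p), log(1 - p))) / n)
  }
  alpha <- vapply(seq_len(K), function(j) alpha_weights(labels, j),
                  numeric(n))
  skip <- vapply(seq_len(K), function(j)
    isTRUE(attr(alpha_weights(labels, j), "skip_positive")), logical(1L))
  phat <- ifelse(pos, 1 - p, p)
  phat_c <- pmin(phat, 1 - PROB_EPS)
  term <- -alpha * phat_c * log(1 - phat_c)
  if (any(skip)) term[pos & rep(skip, each = n)] <- 0
  sum(term) / n
}

#' Boundary-focused weights for the adversarial target loss
#'
#' Per cell and head, with probability p and boundary Pb (branches evaluated
#' in order, first match wins):
#' `1 - p` if `p > Pb`; `1 - Pb` if `1 - Pb < p <= Pb`; `p` otherwise.
#' Cells near the boundary get the largest weights; cells far from it (clear
#' negatives) are down-weighted, and the `1 - Pb` cap keeps the weight of
#' below-boundary cells from growing as Pb rises.
#'
#' @param open_probs_j probabilities for one head (numeric vector).
#' @param Pb_j that head's boundary value in `[0, 1]`.
#' @return Numeric weight per cell.
#' @export
beta_weights <- function(open_probs_j, Pb_j) {
  p <- open_probs_j
  w <- numeric(length(p))
  b1 <- p > Pb_j
  b2 <- !b1 & (1 - Pb_j < p & p <= Pb_j)
  b3 <- !b1 & !b2
  w[b1] <- 1 - p[b1]
  w[b2] <- 1 - Pb_j
  w[b3] <- p[b3]
  w
}

#' Adversarial target loss toward the per-head boundary
#'
#' `(1/(N*K)) * sum_j sum_i beta_ij * (-Pb_j * log p - (1 - Pb_j) * log(1-p))`
#' — the beta-weighted cross-entropy of each head's probability toward the
#' soft label Pb_j. The heads minimize it (pulling target probabilities to
#' the boundary); through the gradient-reversal layer the encoder maximizes
#' it, pushing target cells away from the boundary — known-type cells up,
#' unknown-type cells down. The beta weights are treated as constants
#' (stop-gradient) when differentiating.
#'
#' @param open_probs N x K per-head target probabilities.
#' @param Pb length-K boundary vector.
#' @param no_beta if `TRUE`, use unit weights (the corresponding ablation).
#' @return Nonnegative scalar.
#' @export
open_target_loss <- function(open_probs, Pb, no_beta = FALSE) {
  n <- nrow(open_probs); K <- ncol(open_probs)
  stopifnot(length(Pb) == K, all(Pb >= 0 & Pb <= 1))
  p <- clamp_prob(open_probs)
  beta <- if (no_beta) matrix(1, n, K) else
    vapply(seq_len(K), function(j) beta_weights(p[, j], Pb[j]), numeric(n))
  Pb_row <- rep(Pb, each = n)
  ce <- -(Pb_row * log(p) + (1 - Pb_row) * log(1 - p))
  sum(beta * ce) / (n * K)
}

#' Weighted total loss
#'
#' @param parts named list/vector with elements `kl`, `recon`, `sup_c`,
#'   `sup_o`, `sup_t`.
#' @param weights named coefficients, default 1 each; must be nonnegative.
#' @return Scalar weighted sum.
#' @export
total_loss <- function(parts, weights = NULL) {
  w <- c(kl = 1, recon = 1, sup_c = 1, sup_o = 1, sup_t = 1)
  if (!is.null(weights)) {
    if (any(unlist(weights) < 0)) stop("negative loss coefficient")
    w[names(weights)] <- unlist(weights)
  }
  sum(vapply(names(w), function(k) w[[k]] * (parts[[k]] %||% 0), 0))
}
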