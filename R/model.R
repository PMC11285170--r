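#' Model configuration
#'
#' Architecture of the annotation model: a fully connected variational
#' encoder (ReLU hidden layers, linear mean and log-variance outputs), a
#' linear sigmoid decoder (ATAC) or linear decoder (RNA), a linear softmax
#' closed-set classifier over the K known types, and K linear one-vs-all
#' sigmoid heads (the open-set classifier). Decoder and classifiers connect
#' directly to the embedding, without hidden layers.
#'
#' Default encoder widths are 3200-1600-800-400 for ATAC and 256-128-128 for
#' RNA; the embedding dimension defaults to 32. No batch normalization is
#' used, so per-cell outputs are independent of batch composition.
#'
#' @param input_dim number of input features m.
#' @param n_types number of known cell types K (>= 1).
#' @param modality `"atac"` or `"rna"`.
#' @param encoder_widths integer vector of hidden-layer widths; `NULL` picks
#'   the modality default.
#' @param embedding_dim latent dimension L (default 32).
#' @param grl_lambda gradient-reversal coefficient (default 1); gradients of
#'   the adversarial target loss are multiplied by `-grl_lambda` on their way
#'   into the encoder.
#' @param labels optional character vector naming the K known types.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim, n_types, modality = c("atac", "rna"),
                         encoder_widths = NULL, embedding_dim = 32L,
                         grl_lambda = 1, labels = NULL) {
  modality <- match.arg(modality)
  if (is.null(encoder_widths)) {
    encoder_widths <- if (modality == "atac") c(3200L, 1600L, 800L, 400L)
                      else c(256L, 128L, 128L)
  }
  stopifnot(input_dim >= 1, n_types >= 1, embedding_dim >= 1,
            all(encoder_widths >= 1), grl_lambda >= 0)
  if (!is.null(labels)) stopifnot(length(labels) == n_types)
  structure(list(input_dim = as.integer(input_dim),
                 n_types = as.integer(n_types), modality = modality,
                 encoder_widths = as.integer(encoder_widths),
                 embedding_dim = as.integer(embedding_dim),
                 grl_lambda = grl_lambda,
                 labels = labels %||% paste0("C", seq_len(n_types))),
            class = "model_config")
}

glorot <- function(fan_in, fan_out) {
  matrix(runif(fan_in * fan_out, -1, 1) * sqrt(6 / (fan_in + fan_out)),
         fan_in, fan_out)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases; deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return An `openanno_model`: list with `config`, `params` (named weight
#'   matrices/vectors), `boundary` (per-head decision boundary vector, all
#'   0.5 at initialization), and `feature_ids` (filled in by [fit_annotator()]).
#' @export
init_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    dims <- c(config$input_dim, config$encoder_widths)
    L <- config$embedding_dim
    K <- config$n_types
    last <- dims[length(dims)]
    params <- list(
      enc_W = lapply(seq_len(length(dims) - 1L),
                     function(i) glorot(dims[i], dims[i + 1L])),
      enc_b = lapply(dims[-1L], function(d) numeric(d)),
      W_mu = glorot(last, L), b_mu = numeric(L),
      W_lv = glorot(last, L), b_lv = numeric(L),
      W_dec = glorot(L, config$input_dim), b_dec = numeric(config$input_dim),
      W_cls = glorot(L, K), b_cls = numeric(K),
      W_open = glorot(L, K), b_open = numeric(K)
    )
    structure(list(config = config, params = params,
                   boundary = rep(0.5, K), feature_ids = NULL),
              class = "openanno_model")
  })
}

#' @export
print.openanno_model <- function(x, ...) {
  cat(sprintf("<openanno_model> %s, m=%d, encoder %s, L=%d, K=%d\n",
              x$config$modality, x$config$input_dim,
              paste(x$config$encoder_widths, collapse = "-"),
              x$config$embedding_dim, x$config$n_types))
  invisible(x)
}

# full encoder forward with caches for backprop:
# H[[1]] = input, H[[l+1]] = relu(H[[l]] W_l + b_l); mu/lv linear on last H
forward_encoder <- function(params, x) {
  H <- vector("list", length(params$enc_W) + 1L)
  A <- vector("list", length(params$enc_W))
  H[[1L]] <- x
  for (l in seq_along(params$enc_W)) {
    A[[l]] <- sweep_add(H[[l]] %*% params$enc_W[[l]], params$enc_b[[l]])
    H[[l + 1L]] <- relu(A[[l]])
  }
  last <- H[[length(H)]]
  mu <- sweep_add(last %*% params$W_mu, params$b_mu)
  lv <- sweep_add(last %*% params$W_lv, params$b_lv)
  list(H = H, A = A, mu = mu, log_var = lv)
}

# add a row vector b to every row of a matrix (no sweep() overhead)
sweep_add <- function(m, b) m + rep(b, each = nrow(m))

#' Encode cells to the latent posterior parameters
#'
#' @param x cells x features numeric matrix, columns matching the model's
#'   input dimension.
#' @param model an `openanno_model`.
#' @return A `latent_batch`: list with `mu` and `log_var` (N x L matrices);
#'   the posterior is N(mu, exp(log_var)).
#' @export
encode <- function(x, model) {
  x <- as_dense(x)
  if (ncol(x) != model$config$input_dim) {
    stop("input has ", ncol(x), " features; model expects ",
         model$config$input_dim)
  }
  fwd <- forward_encoder(model$params, x)
  structure(list(mu = fwd$mu, log_var = fwd$log_var), class = "latent_batch")
}

#' Sample the latent embedding by reparameterization
#'
#' `z = mu + exp(log_var / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param latent a `latent_batch` from [encode()].
#' @param seed optional seed for reproducible draws.
#' @return N x L matrix `z`.
#' @export
reparameterize <- function(latent, seed = NULL) {
  draw <- function() {
    eps <- matrix(rnorm(length(latent$mu)), nrow(latent$mu))
    latent$mu + exp(0.5 * latent$log_var) * eps
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Decode a latent batch to the input space
#'
#' ATAC: sigmoid outputs in (0,1), interpretable as the probability that each
#' region is open. RNA: unconstrained linear outputs (trained with MSE).
#'
#' @param z N x L latent matrix.
#' @param model an `openanno_model`.
#' @return N x m reconstruction matrix.
#' @export
decode <- function(z, model) {
  a <- sweep_add(z %*% model$params$W_dec, model$params$b_dec)
  if (model$config$modality == "atac") sigmoid(a) else a
}

#' Closed-set classifier probabilities
#'
#' @param z N x L latent matrix.
#' @param model an `openanno_model`.
#' @return N x K matrix of softmax probabilities over the known types.
#' @export
closed_forward <- function(z, model) {
  softmax_rows(sweep_add(z %*% model$params$W_cls, model$params$b_cls))
}

#' Open-set one-vs-all head probabilities
#'
#' K independent sigmoid heads; head j scores membership in known type j.
#' With `reverse = TRUE` the forward value is unchanged — the flag marks the
#' gradient-reversal path used during adversarial training, where gradients
#' flowing from these outputs back into the encoder are multiplied by
#' `-lambda` (see [train_step()]).
#'
#' @param z N x L latent matrix.
#' @param model an `openanno_model`.
#' @param reverse logical, gradient-reversal marker (forward-identical).
#' @param lambda reversal strength (defaults to the model's `grl_lambda`).
#' @return N x K matrix of per-head probabilities in (0,1).
#' @export
open_forward <- function(z, model, reverse = FALSE,
                         lambda = model$config$grl_lambda) {
  p <- sigmoid(sweep_add(z %*% model$params$W_open, model$params$b_open))
  attr(p, "grl") <- list(reverse = reverse, lambda = lambda)
  p
}

#' Save / load a model checkpoint
#'
#' One file holding parameters, configuration, the boundary vector and the
#' label vocabulary (RDS serialization).
#'
#' @param model an `openanno_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "openanno_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "openanno_model"))
  model
}
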