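#' Training configuration
#'
#' @param batch_size mini-batch size (default 64).
#' @param epochs training epochs (default 4000; the scaled-down synthetic
#'   benchmark uses 300).
#' @param learning_rate AdamW learning rate (default 2e-4).
#' @param weight_decay decoupled weight decay; default 5e-4 for ATAC and
#'   5e-5 for RNA (set automatically when `NULL`).
#' @param top_interval boundary quantile: each head's boundary is set to the
#'   value at the top `top_interval` of that head's ascending-sorted target
#'   probabilities (default 0.05, i.e. the 95th percentile).
#' @param seed integer RNG seed for parameter init, batching and sampling.
#' @param boundary_momentum EMA momentum for boundary updates; 0 (default)
#'   replaces the boundary with the batch quantile outright.
#' @param loss_weights named nonnegative coefficients for the five loss
#'   terms; default 1 each.
#' @param alpha_scope `"batch"` (default) computes the one-vs-all imbalance
#'   ratio per mini-batch; `"dataset"` uses whole-source class counts.
#' @param ablations character subset of `c("plain_bce_source",
#'   "fixed_boundary", "no_beta", "no_target_loss")`, each diverting exactly
#'   one ingredient of the objective.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, epochs = 4000L,
                         learning_rate = 2e-4, weight_decay = NULL,
                         top_interval = 0.05, seed = 0L,
                         boundary_momentum = 0, loss_weights = NULL,
                         alpha_scope = c("batch", "dataset"),
                         ablations = character()) {
  stopifnot(batch_size >= 2L, epochs >= 1L,
            top_interval >= 0, top_interval < 1)
  bad <- setdiff(ablations, c("plain_bce_source", "fixed_boundary",
                              "no_beta", "no_target_loss"))
  if (length(bad)) stop("unknown ablation(s): ", paste(bad, collapse = ", "))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 top_interval = top_interval, seed = as.integer(seed),
                 boundary_momentum = boundary_momentum,
                 loss_weights = loss_weights,
                 alpha_scope = match.arg(alpha_scope),
                 ablations = as.character(ablations)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# forward pass computing every loss term (used for training and for
# finite-difference gradient checks); eps_s/eps_t are the reparameterization
# noise draws so the computation is a deterministic function of the params.
forward_losses <- function(params, cfg, xs, ys, xt, Pb, eps_s, eps_t,
                           ablations = character(),
                           alpha_override = NULL) {
  atac <- cfg$modality == "atac"
  fs <- forward_encoder(params, xs)
  zs <- fs$mu + exp(0.5 * fs$log_var) * eps_s
  ft <- forward_encoder(params, xt)
  zt <- ft$mu + exp(0.5 * ft$log_var) * eps_t

  dec_s <- sweep_add(zs %*% params$W_dec, params$b_dec)
  dec_t <- sweep_add(zt %*% params$W_dec, params$b_dec)
  xhat_s <- if (atac) sigmoid(dec_s) else dec_s
  xhat_t <- if (atac) sigmoid(dec_t) else dec_t

  closed <- softmax_rows(sweep_add(zs %*% params$W_cls, params$b_cls))
  open_s <- sigmoid(sweep_add(zs %*% params$W_open, params$b_open))
  open_t <- sigmoid(sweep_add(zt %*% params$W_open, params$b_open))

  # objective uses per-element mean reductions: the KL term is averaged over
  # latent dimensions as well as cells, matching the per-entry reconstruction
  # mean, so neither term's scale depends on m or L (see methods vignette)
  L <- ncol(fs$mu)
  kl <- (kl_divergence(fs$mu, fs$log_var) + kl_divergence(ft$mu, ft$log_var)) / L
  recon <- reconstruction_loss(xhat_s, xs, cfg$modality) +
           reconstruction_loss(xhat_t, xt, cfg$modality)
  sup_c <- closed_loss(closed, ys)
  sup_o <- open_source_loss(open_s, ys,
                            plain_bce = "plain_bce_source" %in% ablations)
  sup_t <- if ("no_target_loss" %in% ablations) 0 else
    open_target_loss(open_t, Pb, no_beta = "no_beta" %in% ablations)

  list(kl = kl, recon = recon, sup_c = sup_c, sup_o = sup_o, sup_t = sup_t,
       caches = list(fs = fs, ft = ft, zs = zs, zt = zt,
                     xhat_s = xhat_s, xhat_t = xhat_t, dec_t = dec_t,
                     closed = closed, open_s = open_s, open_t = open_t))
}

zero_like <- function(params) rapply(params, function(m) m * 0, how = "replace")

# analytic gradients of the weighted total loss; the adversarial term's
# gradient is multiplied by -lambda on the encoder side (gradient reversal)
# while the open-set heads receive it unreversed.
backward_losses <- function(params, cfg, xs, ys, xt, Pb, eps_s, eps_t,
                            weights, lambda, ablations = character(),
                            alpha_override = NULL) {
  fl <- forward_losses(params, cfg, xs, ys, xt, Pb, eps_s, eps_t, ablations)
  ca <- fl$caches
  atac <- cfg$modality == "atac"
  m <- cfg$input_dim
  K <- cfg$n_types
  ns <- nrow(xs); nt <- nrow(xt)
  g <- zero_like(params)

  w <- c(kl = 1, recon = 1, sup_c = 1, sup_o = 1, sup_t = 1)
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)

  # --- decoder (both batches) ---
  dD_s <- if (atac) (ca$xhat_s - xs) / (ns * m) else 2 * (ca$xhat_s - xs) / (ns * m)
  dD_t <- if (atac) (ca$xhat_t - xt) / (nt * m) else 2 * (ca$xhat_t - xt) / (nt * m)
  dD_s <- dD_s * w["recon"]; dD_t <- dD_t * w["recon"]
  g$W_dec <- crossprod(ca$zs, dD_s) + crossprod(ca$zt, dD_t)
  g$b_dec <- colSums(dD_s) + colSums(dD_t)
  dz_s <- tcrossprod(dD_s, params$W_dec)
  dz_t <- tcrossprod(dD_t, params$W_dec)

  # --- closed-set classifier (source) ---
  Y <- matrix(0, ns, K); Y[cbind(seq_len(ns), ys)] <- 1
  dS <- (ca$closed - Y) / ns * w["sup_c"]
  g$W_cls <- crossprod(ca$zs, dS)
  g$b_cls <- colSums(dS)
  dz_s <- dz_s + tcrossprod(dS, params$W_cls)

  # --- one-vs-all source loss ---
  p <- clamp_prob(ca$open_s)
  pos <- outer(ys, seq_len(K), `==`)
  if ("plain_bce_source" %in% ablations) {
    dO_s <- (p - pos) / ns
  } else {
    alpha <- matrix(1, ns, K)
    skip <- logical(K)
    for (j in seq_len(K)) {
      aj <- if (is.null(alpha_override)) alpha_weights(ys, j) else {
        wj <- rep(1, ns); wj[ys == j] <- alpha_override[j]; wj
      }
      skip[j] <- isTRUE(attr(aj, "skip_positive"))
      alpha[, j] <- aj
    }
    # d/ds of -alpha*(1-p)*log(p) [positives] and -p*log(1-p) [negatives]
    dpos <- alpha * (p * (1 - p) * log(p) - (1 - p)^2)
    dneg <- -p * (1 - p) * log(1 - p) + p^2
    dO_s <- ifelse(pos, dpos, dneg) / ns
    if (any(skip)) dO_s[pos & rep(skip, each = ns)] <- 0
  }
  dO_s <- dO_s * w["sup_o"]
  g$W_open <- crossprod(ca$zs, dO_s)
  g$b_open <- colSums(dO_s)
  dz_s <- dz_s + tcrossprod(dO_s, params$W_open)

  # --- adversarial target loss through the gradient-reversal layer ---
  if (!("no_target_loss" %in% ablations) && w["sup_t"] > 0) {
    q <- clamp_prob(ca$open_t)
    beta <- if ("no_beta" %in% ablations) matrix(1, nt, K) else
      vapply(seq_len(K), function(j) beta_weights(q[, j], Pb[j]), numeric(nt))
    dO_t <- beta * (q - rep(Pb, each = nt)) / (nt * K) * w["sup_t"]
    g$W_open <- g$W_open + crossprod(ca$zt, dO_t)
    g$b_open <- g$b_open + colSums(dO_t)
    dz_t <- dz_t + (-lambda) * tcrossprod(dO_t, params$W_open)
  }

  # --- reparameterization + KL into the encoder, per batch ---
  backprop_encoder <- function(fwd, z, dz, n, gacc) {
    L <- ncol(fwd$mu)
    dmu <- dz + fwd$mu / (n * L) * w["kl"]
    dlv <- dz * (z - fwd$mu) * 0.5 +
      0.5 * (exp(fwd$log_var) - 1) / (n * L) * w["kl"]
    Hlast <- fwd$H[[length(fwd$H)]]
    gacc$W_mu <- gacc$W_mu + crossprod(Hlast, dmu)
    gacc$b_mu <- gacc$b_mu + colSums(dmu)
    gacc$W_lv <- gacc$W_lv + crossprod(Hlast, dlv)
    gacc$b_lv <- gacc$b_lv + colSums(dlv)
    dH <- tcrossprod(dmu, params$W_mu) + tcrossprod(dlv, params$W_lv)
    for (l in rev(seq_along(params$enc_W))) {
      dA <- dH * (fwd$A[[l]] > 0)
      gacc$enc_W[[l]] <- gacc$enc_W[[l]] + crossprod(fwd$H[[l]], dA)
      gacc$enc_b[[l]] <- gacc$enc_b[[l]] + colSums(dA)
      if (l > 1L) dH <- tcrossprod(dA, params$enc_W[[l]])
    }
    gacc
  }
  g <- backprop_encoder(ca$fs, ca$zs, dz_s, ns, g)
  g <- backprop_encoder(ca$ft, ca$zt, dz_t, nt, g)

  parts <- fl[c("kl", "recon", "sup_c", "sup_o", "sup_t")]
  parts$total <- total_loss(parts, weights)
  list(breakdown = parts, grads = g, caches = ca)
}

# ---------------------------------------------------------------------------
# AdamW (decoupled weight decay)
adamw_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, gr, m, v) {
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr * gr
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, gr, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, gr, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, gr, m, v)
  }
  out <- Map(walk, params, grads, opt$m, opt$v)
  list(params = lapply(out, function(o) o$p),
       opt = list(m = lapply(out, function(o) o$m),
                  v = lapply(out, function(o) o$v), t = opt$t))
}

# ---------------------------------------------------------------------------

#' Assign pseudo-labels from closed- and open-set probabilities
#'
#' Each cell's candidate type is the closed-set argmax (ties to the lowest
#' index); the cell is assigned that type if the corresponding one-vs-all
#' head's probability is strictly greater than 0.5, otherwise `"unknown"`.
#'
#' @param closed_probs,open_probs N x K matrices.
#' @param labels character vocabulary of the K known types.
#' @return Character vector of labels in `labels` or `"unknown"`.
#' @export
assign_pseudo_labels <- function(closed_probs, open_probs,
                                 labels = paste0("C", seq_len(ncol(closed_probs)))) {
  stopifnot(identical(dim(closed_probs), dim(open_probs)))
  jstar <- max.col(closed_probs, ties.method = "first")
  gate <- open_probs[cbind(seq_len(nrow(open_probs)), jstar)]
  ifelse(gate > 0.5, labels[jstar], "unknown")
}

#' Update the per-head boundary vector from a batch of target probabilities
#'
#' For each head, the batch's probabilities are sorted ascending and the
#' value at the top `top_interval` (nearest-rank index
#' `ceiling((1 - top_interval) * n)`) becomes the new boundary —
#' the 95th percentile for the default 5% interval; `top_interval = 0` gives
#' the batch maximum. With `momentum > 0` the new value is blended with the
#' current one.
#'
#' @param open_probs N x K target-batch probabilities.
#' @param top_interval upper-tail fraction (default 0.05).
#' @param current current length-K boundary vector.
#' @param momentum EMA momentum in `[0, 1)`; 0 replaces outright.
#' @return Updated length-K boundary vector.
#' @export
update_boundary <- function(open_probs, top_interval = 0.05, current = NULL,
                            momentum = 0) {
  n <- nrow(open_probs)
  stopifnot(n >= 1L)
  idx <- min(max(ceiling((1 - top_interval) * n), 1L), n)
  new <- apply(open_probs, 2L, function(p) sort(p)[idx])
  if (momentum > 0 && !is.null(current)) {
    new <- momentum * current + (1 - momentum) * new
  }
  new
}

#' One optimization step on paired source/target mini-batches
#'
#' Computes the joint loss (KL + reconstruction on both batches, closed-set
#' cross-entropy and the weighted one-vs-all loss on the source batch, the
#' adversarial boundary loss on the target batch through gradient reversal),
#' takes one AdamW step, then refreshes the batch's pseudo-labels and the
#' boundary vector from the updated model's probabilities.
#'
#' @param model an `openanno_model`.
#' @param opt AdamW state from `adamw_init`.
#' @param xs,ys source batch matrix and integer labels (1..K).
#' @param xt target batch matrix.
#' @param config a [train_config()].
#' @param alpha_override optional per-head dataset-level alpha ratios.
#' @return List with updated `model`, `opt`, the `breakdown` of loss terms,
#'   and the batch `pseudo_labels`.
#' @export
train_step <- function(model, opt, xs, ys, xt, config,
                       alpha_override = NULL) {
  cfg <- model$config
  eps_s <- matrix(rnorm(nrow(xs) * cfg$embedding_dim), nrow(xs))
  eps_t <- matrix(rnorm(nrow(xt) * cfg$embedding_dim), nrow(xt))
  weights <- config$loss_weights
  bw <- backward_losses(model$params, cfg, xs, ys, xt, model$boundary,
                        eps_s, eps_t, weights, cfg$grl_lambda,
                        config$ablations, alpha_override)
  for (nm in names(bw$breakdown)) {
    if (!is.finite(bw$breakdown[[nm]])) {
      stop("non-finite loss term: ", nm)
    }
  }
  wd <- config$weight_decay %||% (if (cfg$modality == "atac") 5e-4 else 5e-5)
  st <- adamw_step(model$params, bw$grads, opt, config$learning_rate, wd)
  model$params <- st$params

  # post-step bookkeeping on the target mini-batch (never touches params)
  lat <- forward_encoder(model$params, xt)
  closed <- softmax_rows(sweep_add(lat$mu %*% model$params$W_cls,
                                   model$params$b_cls))
  open <- sigmoid(sweep_add(lat$mu %*% model$params$W_open,
                            model$params$b_open))
  pseudo <- assign_pseudo_labels(closed, open, cfg$labels)
  if (!("fixed_boundary" %in% config$ablations)) {
    model$boundary <- update_boundary(open, config$top_interval,
                                      model$boundary,
                                      config$boundary_momentum)
  }
  list(model = model, opt = st$opt, breakdown = bw$breakdown,
       pseudo_labels = pseudo)
}

#' Fit the open-set annotation model
#'
#' Runs the full training loop: per epoch, the source cells are reshuffled
#' into mini-batches; target batches are drawn independently (reshuffled and
#' cycled as needed) and paired with each source batch for one [train_step()].
#' Boundaries start at 0.5 per head and pseudo-labels are refreshed per
#' batch; after the last epoch both are recomputed on the full target set
#' with the deterministic embedding (posterior means).
#'
#' @param source labeled [processed_dataset()].
#' @param target unlabeled [processed_dataset()], feature-aligned with
#'   `source`.
#' @param config a [train_config()].
#' @param model_cfg optional [model_config()]; defaults to the modality's
#'   standard architecture with K = number of distinct source labels.
#' @param engine `"cpp"` (default) runs the compiled step; `"r"` runs the
#'   pure-R reference implementation ([train_step()]). Both consume the same
#'   random stream and produce matching trajectories up to floating-point
#'   reassociation.
#' @param verbose print a progress line every 50 epochs.
#' @return An `openanno_fit`: list with the trained `model` (including the
#'   final boundary vector and feature list), `target_state`
#'   (pseudo-labels and boundary) and `history` (per-epoch mean of each loss
#'   term).
#' @export
fit_annotator <- function(source, target, config = train_config(),
                          model_cfg = NULL, engine = c("cpp", "r"),
                          verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(source, "raw_dataset"), inherits(target, "raw_dataset"))
  if (!identical(source$feature_ids, target$feature_ids)) {
    stop("source/target features not aligned; run preprocess_pair() or align_features()")
  }
  if (is.null(source$labels)) stop("source labels required")
  if (nrow(target$matrix) == 0L) stop("empty target dataset")

  vocab <- sort(unique(source$labels))
  K <- length(vocab)
  if (K < 2L) warning("only ", K, " known cell type in the source")
  ys_all <- match(source$labels, vocab)

  if (is.null(model_cfg)) {
    model_cfg <- model_config(ncol(source$matrix), K,
                              modality = source$modality, labels = vocab)
  }
  xs_all <- as_dense(source$matrix)
  xt_all <- as_dense(target$matrix)
  storage.mode(xs_all) <- "double"
  storage.mode(xt_all) <- "double"
  ns <- nrow(xs_all); nt <- nrow(xt_all)
  bs <- config$batch_size

  alpha_override <- NULL
  if (config$alpha_scope == "dataset") {
    alpha_override <- vapply(seq_len(K), function(j) {
      np <- sum(ys_all == j); if (np == 0) 1 else (ns - np) / np
    }, 0)
  }

  wd <- config$weight_decay %||%
    (if (model_cfg$modality == "atac") 5e-4 else 5e-5)
  lw <- c(kl = 1, recon = 1, sup_c = 1, sup_o = 1, sup_t = 1)
  if (!is.null(config$loss_weights)) {
    lw[names(config$loss_weights)] <- unlist(config$loss_weights)
  }
  cpp_cfg <- list(
    atac = model_cfg$modality == "atac", lambda = model_cfg$grl_lambda,
    lr = config$learning_rate, wd = wd,
    plain_bce_source = "plain_bce_source" %in% config$ablations,
    no_beta = "no_beta" %in% config$ablations,
    no_target_loss = "no_target_loss" %in% config$ablations,
    weights = unname(lw[c("kl", "recon", "sup_c", "sup_o", "sup_t")]),
    alpha_override = alpha_override %||% numeric())

  with_seed(config$seed, {
    model <- init_model(model_cfg, seed = sample.int(2^30, 1L))
    model$feature_ids <- source$feature_ids
    opt <- adamw_init(model$params)
    pseudo <- rep("unknown", nt)
    history <- vector("list", config$epochs)
    L <- model_cfg$embedding_dim
    t_step <- 0L

    n_steps <- ceiling(ns / bs)
    for (epoch in seq_len(config$epochs)) {
      src_perm <- sample.int(ns)
      n_cycles <- ceiling(n_steps * bs / nt)
      tgt_perm <- unlist(lapply(seq_len(n_cycles),
                                function(i) sample.int(nt)))
      acc <- NULL
      for (s in seq_len(n_steps)) {
        si <- src_perm[(((s - 1L) * bs + 1L):min(s * bs, ns))]
        ti <- tgt_perm[((s - 1L) * bs + 1L):(s * bs)]
        if (engine == "cpp") {
          eps_s <- matrix(rnorm(length(si) * L), length(si))
          eps_t <- matrix(rnorm(length(ti) * L), length(ti))
          t_step <- t_step + 1L
          res <- .cpp_train_step(model$params, opt$m, opt$v, t_step,
                                 xs_all[si, , drop = FALSE], ys_all[si],
                                 xt_all[ti, , drop = FALSE], model$boundary,
                                 eps_s, eps_t, cpp_cfg)
          pseudo[ti] <- assign_pseudo_labels(res$closed_t, res$open_t,
                                             model_cfg$labels)
          if (!("fixed_boundary" %in% config$ablations)) {
            model$boundary <- update_boundary(res$open_t,
                                              config$top_interval,
                                              model$boundary,
                                              config$boundary_momentum)
          }
          bd <- res$breakdown
        } else {
          step <- train_step(model, opt, xs_all[si, , drop = FALSE],
                             ys_all[si], xt_all[ti, , drop = FALSE], config,
                             alpha_override)
          model <- step$model; opt <- step$opt
          pseudo[ti] <- step$pseudo_labels
          bd <- unlist(step$breakdown)
        }
        acc <- if (is.null(acc)) bd else acc + bd
      }
      history[[epoch]] <- acc / n_steps
      if (verbose && epoch %% 50L == 0L) {
        message(sprintf("epoch %d: total %.4f", epoch,
                        history[[epoch]]["total"]))
      }
    }

    # final full-target refresh with the deterministic embedding
    lat <- forward_encoder(model$params, xt_all)
    closed <- softmax_rows(sweep_add(lat$mu %*% model$params$W_cls,
                                     model$params$b_cls))
    open <- sigmoid(sweep_add(lat$mu %*% model$params$W_open,
                              model$params$b_open))
    pseudo <- assign_pseudo_labels(closed, open, model_cfg$labels)
    if (!("fixed_boundary" %in% config$ablations)) {
      model$boundary <- update_boundary(open, config$top_interval,
                                        model$boundary,
                                        config$boundary_momentum)
    }

    hist_df <- as.data.frame(do.call(rbind, history))
    hist_df$epoch <- seq_len(config$epochs)
    structure(list(model = model,
                   target_state = list(pseudo_labels = pseudo,
                                       boundary = model$boundary),
                   history = hist_df[, c("epoch", "kl", "recon", "sup_c",
                                         "sup_o", "sup_t", "total")]),
              class = "openanno_fit")
  })
}

#' @export
print.openanno_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<openanno_fit> %d epochs; final total loss %.4f; boundary [%s]\n",
              n, x$history$total[n],
              paste(sprintf("%.3f", x$model$boundary), collapse = ", ")))
  invisible(x)
}
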