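test_that("pseudo-label rule: closed argmax gated by the matching open head at 0.5", {
  closed <- matrix(c(0.7, 0.2, 0.1), 1, 3, byrow = TRUE)
  open_hi <- matrix(c(0.8, 0.1, 0.1), 1, 3, byrow = TRUE)
  open_lo <- matrix(c(0.3, 0.9, 0.9), 1, 3, byrow = TRUE)
  open_eq <- matrix(c(0.5, 0.9, 0.9), 1, 3, byrow = TRUE)
  expect_equal(assign_pseudo_labels(closed, open_hi), "C1")
  expect_equal(assign_pseudo_labels(closed, open_lo), "unknown")
  # exactly 0.5 is not "greater than 0.5"
  expect_equal(assign_pseudo_labels(closed, open_eq), "unknown")
  # closed-set tie breaks to the lowest index
  tie <- matrix(c(0.4, 0.4, 0.2), 1, 3, byrow = TRUE)
  expect_equal(assign_pseudo_labels(tie, open_hi), "C1")
})

test_that("boundary update is the nearest-rank upper quantile per head", {
  probs <- matrix(seq(0.05, 1.00, by = 0.05), 20, 1)   # 0.05, 0.10, ..., 1.00
  expect_equal(update_boundary(probs, 0.05), 0.95)
  # all equal -> that value
  expect_equal(update_boundary(matrix(0.42, 7, 1), 0.05), 0.42)
  # top_interval = 0 -> batch maximum
  expect_equal(update_boundary(probs, 0), 1.00)
  # momentum blends with the current value
  expect_equal(update_boundary(probs, 0.05, current = 0.5, momentum = 0.5),
               0.5 * 0.5 + 0.5 * 0.95)
})

test_that("boundary responds monotonically to elementwise-increased probabilities", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:40, 1); K <- sample(1:4, 1)
    p <- matrix(runif(n * K), n, K)
    up <- pmin(p + matrix(runif(n * K, 0, 0.3), n, K), 1)
    b0 <- update_boundary(p, 0.05)
    b1 <- update_boundary(up, 0.05)
    expect_true(all(b1 >= b0))
  }
})

test_that("analytic gradients match finite differences (no adversarial term)", {
  set.seed(21)
  m <- 14; K <- 3; L <- 3; ns <- 6; nt <- 5
  cfg <- model_config(m, K, "atac", encoder_widths = c(7L, 5L),
                      embedding_dim = L, labels = paste0("C", 1:K))
  model <- init_model(cfg, 2)
  xs <- matrix(rbinom(ns * m, 1, 0.4), ns); storage.mode(xs) <- "double"
  xt <- matrix(rbinom(nt * m, 1, 0.5), nt); storage.mode(xt) <- "double"
  ys <- c(1, 2, 3, 1, 2, 3)
  Pb <- c(0.5, 0.7, 0.6)
  eps_s <- matrix(rnorm(ns * L), ns); eps_t <- matrix(rnorm(nt * L), nt)
  w0 <- list(sup_t = 0)  # GRL term checked separately
  bw <- openanno:::backward_losses(model$params, cfg, xs, ys, xt, Pb,
                                   eps_s, eps_t, w0, 1, character())
  loss_at <- function(params) {
    fl <- openanno:::forward_losses(params, cfg, xs, ys, xt, Pb,
                                    eps_s, eps_t, character())
    fl$kl + fl$recon + fl$sup_c + fl$sup_o
  }
  h <- 1e-5
  check <- function(getter, setter, g, label) {
    for (k in seq_len(3)) {
      i <- sample(length(getter(model$params)), 1)
      p1 <- model$params; v <- getter(p1); v[i] <- v[i] + h; p1 <- setter(p1, v)
      p2 <- model$params; v <- getter(p2); v[i] <- v[i] - h; p2 <- setter(p2, v)
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_lt(abs(g[i] - fd), 1e-8 + 1e-4 * abs(fd))
    }
  }
  check(function(p) p$enc_W[[1]], function(p, v) { p$enc_W[[1]][] <- v; p },
        bw$grads$enc_W[[1]], "enc_W1")
  check(function(p) p$enc_W[[2]], function(p, v) { p$enc_W[[2]][] <- v; p },
        bw$grads$enc_W[[2]], "enc_W2")
  check(function(p) p$W_mu, function(p, v) { p$W_mu[] <- v; p },
        bw$grads$W_mu, "W_mu")
  check(function(p) p$W_lv, function(p, v) { p$W_lv[] <- v; p },
        bw$grads$W_lv, "W_lv")
  check(function(p) p$W_dec, function(p, v) { p$W_dec[] <- v; p },
        bw$grads$W_dec, "W_dec")
  check(function(p) p$W_cls, function(p, v) { p$W_cls[] <- v; p },
        bw$grads$W_cls, "W_cls")
  check(function(p) p$W_open, function(p, v) { p$W_open[] <- v; p },
        bw$grads$W_open, "W_open")
})

test_that("training step is deterministic under a fixed seed and separates bookkeeping from parameters", {
  tp <- tiny_pair(seed = 5)
  mc <- model_config(ncol(tp$pp$source$matrix), 2, "atac",
                     encoder_widths = c(16L, 8L), embedding_dim = 4L,
                     labels = sort(unique(tp$pp$source$labels)))
  tc <- train_config(epochs = 3L, seed = 42L, batch_size = 16L)
  f1 <- fit_annotator(tp$pp$source, tp$pp$target, tc, mc)
  f2 <- fit_annotator(tp$pp$source, tp$pp$target, tc, mc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$boundary, f2$model$boundary)
  expect_identical(f1$target_state$pseudo_labels, f2$target_state$pseudo_labels)
  expect_equal(nrow(f1$history), 3L)

  # boundary/pseudo-label updates never touch parameters: a pure re-run of
  # update_boundary/assign_pseudo_labels on stored outputs reproduces them
  model <- f1$model
  lat <- encode(as.matrix(tp$pp$target$matrix), model)
  open <- open_forward(lat$mu, model)
  closed <- closed_forward(lat$mu, model)
  expect_identical(assign_pseudo_labels(closed, open, model$config$labels),
                   f1$target_state$pseudo_labels)
})

test_that("the fixed-boundary ablation pins every boundary at 0.5", {
  tp <- tiny_pair(seed = 6)
  mc <- model_config(ncol(tp$pp$source$matrix), 2, "atac",
                     encoder_widths = c(16L, 8L), embedding_dim = 4L,
                     labels = sort(unique(tp$pp$source$labels)))
  f <- fit_annotator(tp$pp$source, tp$pp$target,
                     train_config(epochs = 3L, seed = 1L, batch_size = 16L,
                                  ablations = "fixed_boundary"), mc)
  expect_identical(f$model$boundary, rep(0.5, 2))
})

test_that("the R and compiled training engines produce the same trajectories", {
  tp <- tiny_pair(seed = 7)
  mc <- model_config(ncol(tp$pp$source$matrix), 2, "atac",
                     encoder_widths = c(16L, 8L), embedding_dim = 4L,
                     labels = sort(unique(tp$pp$source$labels)))
  tc <- train_config(epochs = 2L, seed = 9L, batch_size = 16L)
  fr <- fit_annotator(tp$pp$source, tp$pp$target, tc, mc, engine = "r")
  fc <- fit_annotator(tp$pp$source, tp$pp$target, tc, mc, engine = "cpp")
  expect_equal(as.matrix(fr$history), as.matrix(fc$history), tolerance = 1e-10)
  expect_equal(fr$model$boundary, fc$model$boundary, tolerance = 1e-10)
  expect_equal(fr$model$params$W_open, fc$model$params$W_open,
               tolerance = 1e-9)
})

test_that("training reduces the total loss on well-separated synthetic data", {
  tp <- tiny_pair(seed = 8, n = 80, n_peaks = 100)
  mc <- model_config(ncol(tp$pp$source$matrix), 2, "atac",
                     encoder_widths = c(32L, 16L), embedding_dim = 8L,
                     labels = sort(unique(tp$pp$source$labels)))
  f <- fit_annotator(tp$pp$source, tp$pp$target,
                     train_config(epochs = 40L, seed = 3L, batch_size = 16L),
                     mc)
  expect_lt(f$history$total[40], f$history$total[1])
})

test_that("fit validates its inputs", {
  tp <- tiny_pair(seed = 5)
  src <- tp$pp$source
  tgt <- tp$pp$target
  tgt_misaligned <- tgt
  tgt_misaligned$feature_ids <- rev(tgt$feature_ids)
  expect_error(fit_annotator(src, tgt_misaligned, train_config(epochs = 1L)),
               "aligned")
  unlabeled <- src; unlabeled$labels <- NULL
  expect_error(fit_annotator(unlabeled, tgt, train_config(epochs = 1L)),
               "labels")
})
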