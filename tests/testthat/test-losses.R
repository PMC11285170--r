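test_that("KL divergence matches closed forms", {
  expect_equal(kl_divergence(matrix(0, 1, 1), matrix(0, 1, 1)), 0)
  expect_equal(kl_divergence(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  expect_equal(kl_divergence(matrix(0, 1, 1), matrix(log(2), 1, 1)),
               0.5 * (1 - log(2)), tolerance = 1e-12)
})

test_that("KL is nonnegative and zero only at the prior", {
  for (mu in c(-2, -0.5, 0, 0.5, 2)) {
    for (s2 in c(0.1, 0.5, 1, 2, 5)) {
      v <- kl_divergence(matrix(mu, 1, 1), matrix(log(s2), 1, 1))
      expect_gte(v, 0)
      if (mu == 0 && s2 == 1) expect_equal(v, 0) else expect_gt(v, 1e-4)
    }
  }
  expect_error(kl_divergence(matrix(NA_real_, 1, 1), matrix(0, 1, 1)),
               "non-finite")
})

test_that("reconstruction loss is BCE for ATAC and MSE for RNA", {
  x <- matrix(c(1, 0), 1, 2)
  expect_equal(reconstruction_loss(matrix(c(0.5, 0.5), 1, 2), x, "atac"),
               -log(0.5), tolerance = 1e-12)
  xp <- matrix(c(1 - 1e-7, 1e-7), 1, 2)
  expect_lt(reconstruction_loss(xp, x, "atac"), 1e-6)
  xr <- matrix(rnorm(6), 2, 3)
  expect_equal(reconstruction_loss(xr, xr, "rna"), 0)
  expect_error(reconstruction_loss(matrix(0.5, 1, 1), matrix(2, 1, 1), "atac"),
               "binary")
})

test_that("closed-set cross-entropy matches hand computation and is permutation invariant", {
  p <- matrix(0.25, 3, 4)
  expect_equal(closed_loss(p, c(1, 2, 3)), log(4), tolerance = 1e-12)
  sure <- diag(4)[c(2, 4), ]
  expect_lt(closed_loss(pmax(sure, 1e-9), c(2, 4)), 1e-6)
  set.seed(1)
  pr <- matrix(runif(20), 5)
  pr <- pr / rowSums(pr)
  y <- sample(1:4, 5, replace = TRUE)
  o <- sample(5)
  expect_equal(closed_loss(pr, y), closed_loss(pr[o, ], y[o]))
  expect_error(closed_loss(pr, c(1, 2, 3, 4, 5)), "1..K")
})

test_that("alpha weights encode the negative:positive ratio", {
  y <- c(1, 1, 2, 2, 2, 2, 2, 2)       # head 1: 2 pos, 6 neg
  w <- alpha_weights(y, 1)
  expect_equal(w, c(3, 3, rep(1, 6)))
  # balanced batch -> all ones
  expect_equal(alpha_weights(c(1, 1, 2, 2), 1), rep(1, 4))
  # algebraic identity: sum of alpha over positives == number of negatives
  set.seed(2)
  for (i in 1:20) {
    y <- sample(1:3, 30, replace = TRUE)
    for (j in 1:3) {
      w <- alpha_weights(y, j)
      if (sum(y == j) > 0) expect_equal(sum(w[y == j]), sum(y != j))
    }
  }
  # no positives -> flagged
  expect_true(isTRUE(attr(alpha_weights(c(2, 2), 1), "skip_positive")))
})

test_that("one-vs-all source loss matches hand-computed values", {
  # 2 cells (1 pos, 1 neg), K=1, both p=0.5, alpha=1:
  # (1/2) * [-0.5*ln 0.5 - 0.5*ln 0.5] = 0.3466
  p <- matrix(0.5, 2, 1)
  expect_equal(open_source_loss(p, c(1, 2)),
               0.5 * (-0.5 * log(0.5) - 0.5 * log(0.5)), tolerance = 1e-6)
  # confident heads -> loss ~ 0
  pc <- matrix(c(1 - 1e-6, 1e-6), 2, 1)
  expect_lt(open_source_loss(pc, c(1, 2)), 1e-4)
  # invariant to cell ordering
  set.seed(3)
  pm <- matrix(runif(24, 0.05, 0.95), 8, 3)
  y <- sample(1:3, 8, replace = TRUE)
  o <- sample(8)
  expect_equal(open_source_loss(pm, y), open_source_loss(pm[o, ], y[o]),
               tolerance = 1e-12)
})

test_that("source loss decreases in a positive's probability; per-sample term never shrinks with hardness", {
  # fixed negatives, positive probability swept upward -> loss strictly down
  grid <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(grid, function(pp) {
    open_source_loss(matrix(c(pp, 0.3, 0.2), 3, 1), c(1, 2, 2))
  }, 0)
  expect_true(all(diff(losses) < 0))
  # per-sample term -phat*log(1-phat) is increasing in phat on (0,1)
  phat <- seq(0.01, 0.99, by = 0.01)
  term <- -phat * log(1 - phat)
  expect_true(all(diff(term) > 0))
})

test_that("beta weights follow the three printed branches and are continuous at the joins", {
  expect_equal(beta_weights(0.9, 0.8), 0.1)   # p > Pb -> 1 - p
  expect_equal(beta_weights(0.5, 0.8), 0.2)   # middle band -> 1 - Pb
  expect_equal(beta_weights(0.1, 0.8), 0.1)   # p <= 1 - Pb -> p
  for (pb in c(0.5, 0.6, 0.8, 0.95)) {
    eps <- 1e-9
    # at p = Pb: branch 1 limit equals branch 2 value
    expect_equal(beta_weights(pb + eps, pb), beta_weights(pb, pb),
                 tolerance = 1e-6)
    # at p = 1 - Pb: branch 2 equals branch 3
    expect_equal(beta_weights(1 - pb + eps, pb), beta_weights(1 - pb, pb),
                 tolerance = 1e-6)
    p <- runif(100)
    expect_true(all(beta_weights(p, pb) >= 0 & beta_weights(p, pb) <= 1))
  }
})

test_that("adversarial target loss matches hand-computed values", {
  expect_equal(open_target_loss(matrix(0.5, 1, 1), 0.5),
               0.5 * (-0.5 * log(0.5) - 0.5 * log(0.5)), tolerance = 1e-6)
  expect_equal(open_target_loss(matrix(0.9, 1, 1), 0.8),
               0.1 * (-0.8 * log(0.9) - 0.2 * log(0.1)), tolerance = 1e-6)
  # duplicating every cell leaves the mean unchanged
  set.seed(4)
  p <- matrix(runif(12, 0.1, 0.9), 4, 3)
  pb <- c(0.5, 0.7, 0.9)
  expect_equal(open_target_loss(p, pb),
               open_target_loss(rbind(p, p), pb), tolerance = 1e-12)
})

test_that("losses agree with independent scalar-loop oracles", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:8, 1); K <- sample(2:4, 1)
    p <- matrix(runif(n * K, 0.05, 0.95), n, K)
    y <- sample(seq_len(K), n, replace = TRUE)
    pb <- runif(K, 0.3, 0.95)

    # loop oracle for the source loss (Eqs: phat, alpha, 1/N normalization)
    acc <- 0
    for (j in seq_len(K)) {
      npos <- sum(y == j); nneg <- n - npos
      for (i in seq_len(n)) {
        if (y[i] == j) {
          if (npos == 0) next
          phat <- 1 - p[i, j]
          acc <- acc - (nneg / npos) * phat * log(1 - phat)
        } else {
          phat <- p[i, j]
          acc <- acc - phat * log(1 - phat)
        }
      }
    }
    expect_equal(open_source_loss(p, y), acc / n, tolerance = 1e-10)

    # loop oracle for the target loss
    acc_t <- 0
    for (j in seq_len(K)) {
      for (i in seq_len(n)) {
        pij <- p[i, j]
        beta <- if (pij > pb[j]) 1 - pij
                else if (1 - pb[j] < pij && pij <= pb[j]) 1 - pb[j]
                else pij
        acc_t <- acc_t + beta * (-pb[j] * log(pij) - (1 - pb[j]) * log(1 - pij))
      }
    }
    expect_equal(open_target_loss(p, pb), acc_t / (n * K), tolerance = 1e-10)

    # loop oracle for KL
    mu <- matrix(rnorm(n * 3), n); lv <- matrix(rnorm(n * 3, 0, 0.5), n)
    acc_kl <- 0
    for (i in seq_len(n)) for (l in 1:3) {
      acc_kl <- acc_kl + 0.5 * (-1 - lv[i, l] + mu[i, l]^2 + exp(lv[i, l]))
    }
    expect_equal(kl_divergence(mu, lv), acc_kl / n, tolerance = 1e-10)
  }
})

test_that("total loss is a weighted sum rejecting negative coefficients", {
  parts <- list(kl = 0, recon = 0, sup_c = 0, sup_o = 0, sup_t = 0)
  expect_equal(total_loss(parts), 0)
  parts2 <- list(kl = 1, recon = 2, sup_c = 3, sup_o = 4, sup_t = 5)
  expect_equal(total_loss(parts2), 15)
  expect_equal(total_loss(parts2, list(sup_t = 0)), 10)
  expect_error(total_loss(parts2, list(kl = -1)), "negative")
})
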