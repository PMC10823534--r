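zero_model <- function(G, H) {
  ae_model(matrix(0, G, H), numeric(H), matrix(0, H, G), numeric(G),
           activation = "sigmoid")
}

test_that("loss terms of the zero model are analytically forced", {
  set.seed(1)
  X <- matrix(runif(12), 4, 3)
  cfg <- ae_config(hidden_dim = 2, lambda_weight = 0.001,
                   sparsity_target = 0.05, sparsity_weight = 1,
                   scale_input_unit = FALSE)
  l <- ae_loss(zero_model(3, 2), X, cfg)
  # sigmoid(0) = 0.5 everywhere: reconstruction is constant 0.5
  expect_equal(l$recon, mean(rowSums((X - 0.5)^2)), tolerance = 1e-12)
  expect_identical(l$weight, 0)
  # every mean hidden activation is 0.5
  kl <- 0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5)
  expect_equal(l$sparsity, 2 * kl, tolerance = 1e-12)
  expect_equal(l$total, l$recon + l$weight + l$sparsity)
})

test_that("switching off penalty terms reduces the loss to reconstruction", {
  set.seed(2)
  X <- matrix(runif(20), 5, 4)
  m <- ae_model(matrix(rnorm(8, sd = 0.3), 4, 2), rnorm(2),
                matrix(rnorm(8, sd = 0.3), 2, 4), rnorm(4))
  cfg0 <- ae_config(hidden_dim = 2, lambda_weight = 0,
                    sparsity_weight = 0, scale_input_unit = FALSE)
  l <- ae_loss(m, X, cfg0)
  expect_identical(l$total, l$recon)
  expect_identical(l$weight, 0)
  expect_identical(l$sparsity, 0)
})

test_that("loss matches an independent straight-loop implementation", {
  set.seed(5)
  n <- 30; G <- 15; H <- 4
  X <- matrix(runif(n * G), n, G)
  W1 <- matrix(rnorm(G * H, sd = 0.4), G, H); b1 <- rnorm(H)
  W2 <- matrix(rnorm(H * G, sd = 0.4), H, G); b2 <- rnorm(G)
  m <- ae_model(W1, b1, W2, b2)
  cfg <- ae_config(hidden_dim = H, lambda_weight = 0.001,
                   sparsity_target = 0.05, sparsity_weight = 1,
                   scale_input_unit = FALSE)
  got <- ae_loss(m, X, cfg)
  want <- oracle_ae_loss(W1, b1, W2, b2, X, 0.001, 0.05, 1)
  expect_equal(got$total, want$total, tolerance = 1e-10)
  expect_equal(got$recon, want$recon, tolerance = 1e-10)
  expect_equal(got$weight, want$weight, tolerance = 1e-10)
  expect_equal(got$sparsity, want$sparsity, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(9)
  n <- 5; G <- 4; H <- 3
  X <- matrix(runif(n * G), n, G)
  W1 <- matrix(rnorm(G * H, sd = 0.4), G, H); b1 <- rnorm(H, sd = 0.2)
  W2 <- matrix(rnorm(H * G, sd = 0.4), H, G); b2 <- rnorm(G, sd = 0.2)
  cfg <- ae_config(hidden_dim = H, lambda_weight = 0.001,
                   sparsity_target = 0.05, sparsity_weight = 0.7,
                   scale_input_unit = FALSE)
  pack <- function(p) {
    i <- 0
    take <- function(k) { out <- p[i + seq_len(k)]; i <<- i + k; out }
    list(W1 = matrix(take(G * H), G, H), b1 = take(H),
         W2 = matrix(take(H * G), H, G), b2 = take(G))
  }
  f <- function(p) {
    q <- pack(p)
    m <- ae_model(q$W1, q$b1, q$W2, q$b2)
    ae_loss(m, X, cfg)$total
  }
  p0 <- c(W1, b1, W2, b2)
  g <- csaec:::.ae_grad(ae_model(W1, b1, W2, b2), X, cfg)
  g_ana <- c(g$W_enc, g$b_enc, g$W_dec, g$b_dec)
  h <- 1e-6
  g_num <- vapply(seq_along(p0), function(k) {
    e <- rep(0, length(p0)); e[k] <- h
    (f(p0 + e) - f(p0 - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_ana - g_num) / pmax(abs(g_num), 1e-4)), 1e-5)
})

test_that("training is seed-deterministic with an exactly decomposed trace", {
  set.seed(4)
  X <- matrix(runif(60), 12, 5)
  cfg <- ae_config(hidden_dim = 3, epochs = 40, learning_rate = 0.5,
                   seed = 11)
  f1 <- ae_train(X, cfg)
  f2 <- ae_train(X, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$W_enc, f2$model$W_enc)
  f3 <- ae_train(X, ae_config(hidden_dim = 3, epochs = 40,
                              learning_rate = 0.5, seed = 12))
  expect_false(isTRUE(all.equal(tail(f1$trace$total, 1),
                                tail(f3$trace$total, 1))))
  expect_equal(f1$trace$total,
               f1$trace$recon + f1$trace$weight + f1$trace$sparsity,
               tolerance = 1e-12)
  # one epoch -> one trace row
  expect_equal(nrow(ae_train(X, ae_config(hidden_dim = 3, epochs = 1,
                                          learning_rate = 0.1,
                                          seed = 1))$trace), 1)
})

test_that("low-rank representable data is reconstructed to <5% of start", {
  set.seed(21)
  n <- 60; G <- 12; r <- 2
  Z <- matrix(rnorm(n * r), n, r)
  A <- matrix(rnorm(r * G), r, G)
  X <- 1 / (1 + exp(-Z %*% A))      # rank-2 latent, values in (0,1)
  cfg <- ae_config(hidden_dim = 6, epochs = 2000, learning_rate = 2,
                   momentum = 0, lambda_weight = 0, sparsity_weight = 0,
                   seed = 3, scale_input_unit = FALSE)
  fit <- ae_train(X, cfg)
  expect_lt(tail(fit$trace$recon, 1), 0.05 * fit$trace$recon[1])
})

test_that("the total-loss trace is non-increasing at a small learning rate", {
  set.seed(8)
  X <- matrix(runif(80), 16, 5)
  fit <- ae_train(X, ae_config(hidden_dim = 3, epochs = 200,
                               learning_rate = 0.05, momentum = 0,
                               seed = 2))
  diffs <- diff(fit$trace$total[-(1:5)])
  expect_lt(max(diffs), 1e-9)
})

test_that("training diverges loudly at an absurd learning rate", {
  set.seed(10)
  X <- matrix(runif(40, 0, 1) * 50, 8, 5)
  expect_error(ae_train(X, ae_config(hidden_dim = 3, epochs = 500,
                                     learning_rate = 1e4,
                                     activation = "relu", seed = 1,
                                     scale_input_unit = FALSE)),
               "diverged|non-finite")
})

test_that("the encoder half embeds cells as documented", {
  X <- matrix(runif(12), 3, 4)
  emb <- ae_embed(zero_model(4, 2), X)
  expect_true(all(emb$coords == 0.5))
  expect_equal(dim(ae_embed(zero_model(4, 2), X[1, , drop = FALSE])$coords),
               c(1, 2))

  set.seed(6)
  W1 <- matrix(rnorm(8), 4, 2); b1 <- rnorm(2)
  m <- ae_model(W1, b1, matrix(0, 2, 4), numeric(4))
  got <- ae_embed(m, X)$coords
  want <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    want[i, j] <- 1 / (1 + exp(-(sum(X[i, ] * W1[, j]) + b1[j])))
  }
  expect_lt(max(abs(got - want)), 1e-12)

  # duplicated cells embed identically
  X2 <- rbind(X, X[1, ])
  e2 <- ae_embed(m, X2)$coords
  expect_identical(e2[4, ], e2[1, ])

  expect_error(ae_embed(m, X[, 1:3]), "expects")
})
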