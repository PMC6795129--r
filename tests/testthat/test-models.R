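test_that("mf_score is the dot product", {
  expect_equal(mf_score(rep(0, 4), rnorm(4)), 0)
  expect_equal(mf_score(c(1, 2, 3), c(1, 1, 1)), 6)
  expect_error(mf_score(1:3, 1:4), "mismatch")
  set.seed(1)
  for (r in 1:100) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(mf_score(a, b), oracle_mf_score(a, b), tolerance = 1e-12)
  }
})

test_that("mf_square_loss matches the double-loop Frobenius oracle", {
  A <- matrix(0, 4, 3); A[cbind(c(1, 2, 4), c(1, 3, 2))] <- 1
  expect_equal(mf_square_loss(A, matrix(0, 4, 2), matrix(0, 3, 2)), 3)
  set.seed(2)
  L <- matrix(rnorm(8), 4, 2); D <- matrix(rnorm(6), 3, 2)
  expect_equal(mf_square_loss(L %*% t(D), L, D), 0, tolerance = 1e-12)
  A2 <- matrix(rbinom(20, 1, 0.3), 5, 4)
  L2 <- matrix(rnorm(15), 5, 3); D2 <- matrix(rnorm(12), 4, 3)
  expect_equal(mf_square_loss(A2, L2, D2), oracle_square_loss(A2, L2, D2),
               tolerance = 1e-9)
})

test_that("nnmf_forward is the sigmoid of the dot product, saturating safely", {
  p <- random_params(6, 5, 4, layers = c(3), seed = 4, model = "nnmf")
  p$theta$L[1, ] <- c(1, 0, 0, 0); p$theta$D[1, ] <- c(0, 1, 0, 0)
  expect_equal(nnmf_forward(p, cbind(1, 1)), 0.5)
  p$theta$L[2, ] <- c(50, 0, 0, 0); p$theta$D[2, ] <- c(1, 0, 0, 0)
  expect_equal(nnmf_forward(p, cbind(2, 2)), 1, tolerance = 1e-15)
  expect_error(nnmf_forward(p, cbind(7, 1)), "out of range")
  for (r in 1:100) {
    q <- random_params(6, 5, 4, layers = c(3), seed = 100 + r, model = "nnmf")
    pairs <- cbind(sample(6, 10, TRUE), sample(5, 10, TRUE))
    expect_equal(nnmf_forward(q, pairs), oracle_nnmf(q, pairs), tolerance = 1e-6)
  }
})

test_that("nnlda_forward matches a scalar-loop oracle and reduces to NNMF", {
  # all-zero parameters give 0.5 everywhere
  z <- random_params(5, 4, 2, layers = c(2), seed = 1)
  z$theta <- lapply(z$theta, function(x) x * 0)
  expect_equal(nnlda_forward(z, cbind(1:4, 1:4)), rep(0.5, 4))

  # zero deep path + unit output weights on the MF slots = NNMF
  p <- random_params(5, 4, 3, layers = c(2), seed = 2)
  p$theta$W1 <- p$theta$W1 * 0
  p$theta$b1 <- p$theta$b1 * 0
  p$theta$out_w <- c(rep(1, 3), rep(0, 2))
  p$theta$out_b <- 0
  nm <- p; nm$model_kind <- "nnmf"
  pairs <- cbind(sample(5, 20, TRUE), sample(4, 20, TRUE))
  expect_equal(nnlda_forward(p, pairs), nnmf_forward(nm, pairs), tolerance = 1e-12)

  # random small networks against the hand-rolled oracle
  for (r in 1:100) {
    q <- random_params(5, 4, 2, layers = c(2), seed = 300 + r)
    pp <- cbind(sample(5, 8, TRUE), sample(4, 8, TRUE))
    expect_equal(nnlda_forward(q, pp), oracle_nnlda(q, pp), tolerance = 1e-6)
  }
  # separate deep embedding tables follow the same contract
  sep <- random_params(5, 4, 2, layers = c(2), seed = 9, shared = FALSE)
  pp <- cbind(sample(5, 8, TRUE), sample(4, 8, TRUE))
  expect_equal(nnlda_forward(sep, pp), oracle_nnlda(sep, pp), tolerance = 1e-6)
})

test_that("forward outputs lie strictly in (0,1)", {
  for (r in 1:20) {
    q <- random_params(6, 5, 3, layers = c(3, 2), seed = 700 + r, scale = 3)
    pairs <- cbind(sample(6, 30, TRUE), sample(5, 30, TRUE))
    pr <- nnlda_forward(q, pairs)
    expect_true(all(pr > 0 & pr < 1))
  }
})

test_that("bce_l2_loss: closed forms, stability, and the term-by-term oracle", {
  expect_lt(bce_l2_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-10)
  expect_equal(bce_l2_loss(rep(0.5, 8), rep(c(0, 1), 4)), log(2))
  # stable logit form stays finite at extreme scores
  expect_true(is.finite(bce_l2_loss(labels = c(1, 0), logits = c(-1e4, 1e4))))
  set.seed(5)
  for (r in 1:100) {
    p <- random_params(6, 5, 3, layers = c(2), seed = 500 + r)
    B <- 7
    i <- sample(6, B, TRUE); j <- sample(5, B, TRUE)
    prob <- runif(B, 0.05, 0.95); y <- rbinom(B, 1, 0.5)
    expect_equal(
      bce_l2_loss(prob, y, p, l2_rate = 0.01, lncrna_rows = i, disease_rows = j),
      oracle_bce_l2(prob, y, p, 0.01, i, j),
      tolerance = 1e-8
    )
  }
})

test_that("analytic gradients match central finite differences", {
  # tiny fused model: k = 2, one hidden layer of width 2, 5 examples
  for (shared in c(TRUE, FALSE)) {
    p <- random_params(4, 3, 2, layers = c(2), seed = 11, shared = shared)
    set.seed(12)
    i <- sample(4, 5, TRUE); j <- sample(3, 5, TRUE); y <- rbinom(5, 1, 0.5)
    g <- nnlda:::grad_batch(p, i, j, y, l2_rate = 0.01)
    fd <- fd_grads(p, i, j, y, l2_rate = 0.01)
    for (nm in names(g$grads)) {
      denom <- pmax(abs(fd[[nm]]), 1e-4)
      expect_lt(max(abs(g$grads[[nm]] - fd[[nm]]) / denom), 1e-4)
    }
  }
  # and for NNMF
  p2 <- random_params(4, 3, 2, layers = c(2), seed = 13, model = "nnmf")
  set.seed(14)
  i <- sample(4, 5, TRUE); j <- sample(3, 5, TRUE); y <- rbinom(5, 1, 0.5)
  g2 <- nnlda:::grad_batch(p2, i, j, y, l2_rate = 0.01)
  fd2 <- fd_grads(p2, i, j, y, l2_rate = 0.01)
  for (nm in names(g2$grads)) {
    denom <- pmax(abs(fd2[[nm]]), 1e-4)
    expect_lt(max(abs(g2$grads[[nm]] - fd2[[nm]]) / denom), 1e-4)
  }
})

test_that("training reduces the loss on planted low-rank data", {
  sim <- simulate_associations(synthetic_spec(n_l = 50, n_d = 10, k_true = 2,
                                              density_target = 0.4,
                                              degree_skew = 0, seed = 21))
  fit <- nnlda(sim$dataset, "nnmf",
               nnlda_config(latent_dim = 8, epochs = 100, batch_size = 256,
                            seed = 3))
  # final mean epoch objective below the first epoch's
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  # training cross-entropy well below its value at initialization
  expect_lt(fit$final_loss, 0.3 * fit$initial_loss)
  expect_true(all(is.finite(fit$loss)) && all(fit$loss >= 0))
})

test_that("epochs = 0 returns initialization and an empty loss trajectory", {
  sim <- simulate_associations(synthetic_spec(n_l = 40, n_d = 8,
                                              density_target = 0.2,
                                              degree_skew = 0, seed = 22))
  cfg <- nnlda_config(latent_dim = 4, epochs = 0, seed = 5)
  fit <- nnlda(sim$dataset, "nnlda", cfg)
  expect_length(fit$loss, 0)
  init <- nnlda:::with_seed(nnlda:::derive_seed(5, 11),
                            nnlda:::init_params(sim$dataset$n_l, sim$dataset$n_d,
                                                cfg, "nnlda"))
  expect_equal(fit$params$theta, init$theta)
})

test_that("identical seeds give identical fits and held-out rankings", {
  sim <- simulate_associations(synthetic_spec(n_l = 60, n_d = 12, k_true = 2,
                                              density_target = 0.15,
                                              degree_skew = 0, seed = 23))
  cfg <- nnlda_config(latent_dim = 4, epochs = 10, batch_size = 128, seed = 17)
  f1 <- nnlda(sim$dataset, "nnlda", cfg)
  f2 <- nnlda(sim$dataset, "nnlda", cfg)
  expect_identical(f1$params$theta, f2$params$theta)
  r1 <- predict(f1, disease = sim$dataset$disease[3])
  r2 <- predict(f2, disease = sim$dataset$disease[3])
  expect_identical(r1, r2)
})

test_that("malformed parameter shapes fail at construction", {
  p <- random_params(4, 3, 2, layers = c(2), seed = 30)
  p$theta$out_w <- c(p$theta$out_w, 0)
  expect_error(nnlda:::validate_params(p), "output layer")
  q <- random_params(4, 3, 2, layers = c(2), seed = 31)
  q$theta$W1 <- matrix(0, 3, 4)
  expect_error(nnlda:::validate_params(q), "layer 1")
})
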