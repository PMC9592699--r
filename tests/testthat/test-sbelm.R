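test_that("hidden_output follows the stored random projection", {
  # zero input, zero biases, sigmoid -> all 0.5
  model <- list(activation = "sigmoid", W_in = matrix(rnorm(6), 3, 2),
                b_in = c(0, 0))
  expect_equal(hidden_output(matrix(0, 4, 3), model), matrix(0.5, 4, 2))

  # identity hidden layer returns the raw features
  m2 <- list(activation = "identity")
  x <- matrix(rnorm(12), 4, 3)
  expect_identical(hidden_output(x, m2), x)

  # random case matches an explicit per-element loop
  set.seed(40)
  m3 <- list(activation = "sigmoid", W_in = matrix(rnorm(15), 3, 5),
             b_in = rnorm(5))
  X <- hidden_output(x, m3)
  for (i in 1:4) for (j in 1:5) {
    z <- sum(x[i, ] * m3$W_in[, j]) + m3$b_in[j]
    expect_equal(X[i, j], 1 / (1 + exp(-z)), tolerance = 1e-6)
  }
  expect_error(hidden_output(matrix(0, 2, 7), m3), "match")
})

test_that("the ARD posterior matches the worked scalar example and ridge", {
  X <- matrix(c(1, 1), 2, 1)
  t <- c(1, 1)
  post <- sbelm_posterior(X, t, alpha = 1, beta = 1)
  expect_equal(as.numeric(post$Sigma), 1 / 3)
  expect_equal(post$m, 2 / 3)

  # beta -> 0: the prior dominates and m -> 0
  post0 <- sbelm_posterior(X, t, alpha = 1, beta = 1e-12)
  expect_lt(abs(post0$m), 1e-10)

  # posterior mean equals the ridge solution (X'X + A/beta)^-1 X't
  set.seed(41)
  for (i in 1:100) {
    N <- sample(5:30, 1); D <- sample(1:8, 1)
    Xr <- matrix(rnorm(N * D), N, D)
    tr <- rnorm(N)
    alpha <- runif(D, 0.1, 10); beta <- runif(1, 0.1, 10)
    post <- sbelm_posterior(Xr, tr, alpha, beta)
    ridge <- solve(crossprod(Xr) + diag(alpha / beta, D), crossprod(Xr, tr))
    expect_lt(max(abs(post$m - as.vector(ridge))), 1e-8)
    ev <- eigen(post$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))          # SPD posterior covariance
  }
  expect_error(sbelm_posterior(matrix(NA_real_, 2, 1), t, 1, 1), "finite")
  expect_error(sbelm_posterior(X, t, -1, 1), "positive")
})

test_that("the log evidence matches the integrated Gaussian marginal", {
  # worked scalar case by direct plug-in
  X <- matrix(c(1, 1), 2, 1)
  t <- c(1, 1)
  le <- sbelm_log_evidence(X, t, 1, 1)
  plug <- 0.5 * (log(1) + 2 * log(1) + log(1 / 3) - 2 / 9 - 4 / 9 -
                   2 * log(2 * pi))
  expect_equal(le, plug)

  # dense alternative closed form: N(t | 0, beta^-1 I + X A^-1 X')
  set.seed(42)
  for (i in 1:20) {
    N <- sample(4:15, 1); D <- sample(1:6, 1)
    Xr <- matrix(rnorm(N * D), N, D)
    tr <- rnorm(Xr %*% rnorm(D), 1)
    alpha <- runif(D, 0.2, 5); beta <- runif(1, 0.2, 5)
    C <- diag(N) / beta + Xr %*% diag(1 / alpha, D) %*% t(Xr)
    direct <- -0.5 * (N * log(2 * pi) + determinant(C)$modulus +
                        as.numeric(t(tr) %*% solve(C, tr)))
    expect_equal(sbelm_log_evidence(Xr, tr, alpha, beta), as.numeric(direct),
                 tolerance = 1e-6)
  }
})

test_that("hyperparameter updates reproduce the worked example and prune", {
  X <- matrix(c(1, 1), 2, 1)
  t <- c(1, 1)
  post <- sbelm_posterior(X, t, 1, 1)
  up <- update_hyperparams(post$m, post$Sigma, X, t, alpha = 1)
  expect_equal(up$gamma, 2 / 3)
  expect_equal(up$alpha, 1.5)
  expect_equal(up$beta, 6)

  # an exactly-zero weight goes straight to the pruning cap
  up0 <- update_hyperparams(c(0, 0.5), diag(c(0.1, 0.1)), cbind(t, t),
                            t, alpha = c(1, 1), alpha_max = 1e8)
  expect_equal(up0$alpha[1], 1e8)
  # more well-determined weights than samples degenerates the noise update
  expect_error(update_hyperparams(c(0.5, 0.5), diag(c(1e-9, 1e-9)),
                                  matrix(1, 1, 2), 1, alpha = c(1, 1)),
               "degenerate")
})

test_that("fitting a separable toy gives perfect training AUC and rising
          evidence", {
  set.seed(43)
  n <- 40
  x <- cbind(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), matrix(rnorm(n * 3), n, 3))
  t <- rep(c(0, 1), each = n / 2)
  fit <- fit_sbelm(x, t, sbelm_config(width = 50, seed = 7))
  expect_equal(roc_auc(predict_sbelm(fit, x), t), 1)
  expect_equal(predict_sbelm(fit, x, type = "class"), t)
  ev <- fit$trace$log_evidence
  expect_gte(utils::tail(ev, 1), ev[1])
  expect_true(all(diff(ev) >= -1e-8 * pmax(1, abs(ev[-length(ev)]))))
  expect_true(all(fit$w_hat[fit$pruned] == 0))
})

test_that("ARD prunes the irrelevant features of the sparse test bed", {
  prec <- vapply(1:3, function(sd) {
    g <- gen_sparse_regression(200, 50, 5, noise_sd = 0.1, seed = sd)
    fit <- fit_sbelm(g$X, g$y, sbelm_config(activation = "identity"))
    pruned <- which(fit$pruned)
    expect_gt(length(pruned), 0)
    mean(g$w[pruned] == 0)
  }, numeric(1))
  expect_gte(stats::median(prec), 0.8)
})

test_that("prediction is linear in the learned weights and representation
          invariant", {
  set.seed(44)
  x <- matrix(rnorm(30), 10, 3)
  fit <- fit_sbelm(x, rbinom(10, 1, 0.5), sbelm_config(width = 8, seed = 1))
  z <- fit
  z$w_hat <- rep(0, length(fit$w_hat))
  expect_equal(predict_sbelm(z, x), rep(0, 10))
  # permuting feature columns together with the stored input weights leaves
  # scores unchanged
  perm <- c(3, 1, 2)
  fp <- fit
  fp$W_in <- fit$W_in[perm, , drop = FALSE]
  expect_equal(predict_sbelm(fp, x[, perm, drop = FALSE]),
               predict_sbelm(fit, x))
  expect_error(predict_sbelm(list(activation = "sigmoid"), x), "not fitted")
})

test_that("the ensemble bags, combines, and stays deterministic", {
  set.seed(45)
  n <- 40
  x <- cbind(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), matrix(rnorm(n * 2), n, 2))
  t <- rep(c(0, 1), each = n / 2)

  # M = 1: combiner output is affine in the single base score, AUC identical
  e1 <- fit_ensemble(x, t, M = 1, seed = 3)
  s_base <- predict_sbelm(e1$bases[[1]], x)
  s_ens <- predict_ensemble(e1, x)
  expect_equal(roc_auc(s_ens, t), roc_auc(s_base, t))

  e5 <- fit_ensemble(x, t, M = 5, seed = 3)
  expect_equal(roc_auc(predict_ensemble(e5, x), t), 1)
  expect_length(e5$bags, 5)
  expect_true(all(vapply(e5$bags, length, 0L) == n))

  e5b <- fit_ensemble(x, t, M = 5, seed = 3)
  expect_identical(predict_ensemble(e5b, x), predict_ensemble(e5, x))
  e5c <- fit_ensemble(x, t, M = 5, seed = 4)
  expect_false(identical(predict_ensemble(e5c, x), predict_ensemble(e5, x)))

  # degenerate rank-1 combiner design (all bases identical) is handled
  edup <- e5
  edup$bases <- rep(list(e5$bases[[1]]), 5)
  scores_dup <- vapply(edup$bases, function(b) predict_sbelm(b, x), numeric(n))
  comb <- fit_sbelm(scores_dup, t, sbelm_config(activation = "identity"))
  expect_true(all(is.finite(predict_sbelm(comb, scores_dup))))
})
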