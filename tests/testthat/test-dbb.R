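test_that("dbb forward equals per-branch reference convolution + BN summed", {
  set.seed(10)
  blk <- new_dbb_block(3, 5, K = 3, stride = 1)
  randomize_bn_stats(blk)
  x <- rand_image_batch(7, 7, 3, 2)
  got <- dbb_forward(blk, x, training = FALSE)

  p <- blk$pad; s <- blk$stride
  y6 <- bn_oracle_layer(conv_oracle(x, blk$conv6$par$w, stride = s, pad = p), blk$bn6)
  y1 <- bn_oracle_layer(conv_oracle(x, blk$conv1$par$w, stride = s, pad = 0), blk$bn1)
  z2 <- bn_oracle_layer(conv_oracle(x, blk$conv2$par$w, stride = 1, pad = p), blk$bn2)
  y23 <- bn_oracle_layer(conv_oracle(z2, blk$conv3$par$w, stride = s, pad = 0), blk$bn3)
  z4 <- bn_oracle_layer(conv_oracle(x, blk$conv4$par$w, stride = 1, pad = p), blk$bn4)
  y45 <- bn_oracle_layer(avgpool_oracle(z4, 3, s, 0), blk$bn5)
  expect_lt(max(abs(got - (y6 + y1 + y23 + y45))), 1e-5)
})

test_that("dbb forward degenerates correctly for zero kernels and a single branch", {
  blk <- new_dbb_block(2, 3, K = 3)
  for (cv in list(blk$conv6, blk$conv1, blk$conv2, blk$conv3, blk$conv4))
    cv$par$w[] <- 0
  for (bn in list(blk$bn1, blk$bn2, blk$bn3, blk$bn4, blk$bn5, blk$bn6))
    bn$par$beta[] <- 0
  x <- rand_image_batch(5, 5, 2, 1)
  expect_true(all(dbb_forward(blk, x) == 0))

  # only the KxK branch active with identity-effect BN = a plain convolution
  blk2 <- new_dbb_block(2, 3, K = 3)
  for (cv in list(blk2$conv1, blk2$conv2, blk2$conv3, blk2$conv4))
    cv$par$w[] <- 0
  for (bn in list(blk2$bn1, blk2$bn2, blk2$bn3, blk2$bn4, blk2$bn5))
    bn$par$beta[] <- 0
  blk2$bn6$eps <- 0   # exact identity BN: gamma=1, sigma=1, mu=0, beta=0
  got <- dbb_forward(blk2, x)
  expect_lt(max(abs(got - conv_oracle(x, blk2$conv6$par$w, stride = 1, pad = 1))),
            1e-10)
  expect_error(dbb_forward(blk2, rand_image_batch(5, 5, 4, 1)), "channels")
})

test_that("fuse_bn folds statistics into kernel scale and bias", {
  F <- array(rnorm(3 * 3 * 2 * 2), dim = c(3, 3, 2, 2))
  id <- fuse_bn(F, gamma = c(1, 1), sigma = c(1, 1), mu = c(0, 0), beta = c(0, 0))
  expect_equal(id$kernel, F)
  expect_equal(id$bias, c(0, 0))

  f2 <- fuse_bn(F, gamma = c(2, 2), sigma = c(1, 1), mu = c(1, 1), beta = c(0, 0))
  expect_equal(f2$kernel, 2 * F)
  expect_equal(f2$bias, c(-2, -2))
  expect_error(fuse_bn(F, c(1, 1), c(1, 0), c(0, 0), c(0, 0)), "positive")

  # conv-then-BN equals fused conv + bias numerically
  set.seed(11)
  x <- rand_image_batch(6, 6, 2, 2)
  gamma <- rnorm(2, 1, 0.2); beta <- rnorm(2); mu <- rnorm(2)
  v <- runif(2, 0.5, 2)
  y_ref <- bn_oracle(conv_oracle(x, F, stride = 1, pad = 1), gamma, beta, mu, v,
                     eps = 0)
  fz <- fuse_bn(F, gamma, sqrt(v), mu, beta)
  expect_lt(max(abs(y_ref - conv_oracle(x, fz$kernel, fz$bias, 1, 1))), 1e-6)
})

test_that("merge_sequential reproduces the composed 1x1 -> KxK convolution", {
  # identity pointwise kernel returns the spatial kernel
  D <- 3
  idp <- array(0, dim = c(1, 1, D, D))
  for (c in seq_len(D)) idp[1, 1, c, c] <- 1
  Fsp <- array(rnorm(3 * 3 * D * 4), dim = c(3, 3, D, 4))
  expect_equal(merge_sequential(idp, Fsp), Fsp)

  # spatial kernel = scaled center delta broadcasts the pointwise kernel
  Fpt <- array(rnorm(1 * 1 * 2 * 3), dim = c(1, 1, 2, 3))
  delta <- array(0, dim = c(3, 3, 3, 3))
  for (c in 1:3) delta[2, 2, c, c] <- 2.5
  merged <- merge_sequential(Fpt, delta)
  expect_equal(merged[2, 2, , ], 2.5 * Fpt[1, 1, , ])
  expect_true(all(merged[-2, , , ] == 0))

  # random pair: composed path equals merged-kernel path on random input
  set.seed(12)
  Fp <- array(rnorm(2 * 5), dim = c(1, 1, 2, 5))
  Fs <- array(rnorm(3 * 3 * 5 * 4), dim = c(3, 3, 5, 4))
  x <- rand_image_batch(6, 6, 2, 2)
  composed <- conv_oracle(conv_oracle(x, Fp, stride = 1, pad = 1), Fs,
                          stride = 1, pad = 0)
  direct <- conv_oracle(x, merge_sequential(Fp, Fs), stride = 1, pad = 1)
  expect_lt(max(abs(composed - direct)), 1e-5)
  expect_error(merge_sequential(Fs, Fs), "1x1")
})

test_that("avgpool_as_conv is the sliding-window mean", {
  expect_equal(avgpool_as_conv(3, 1)[1, 1, , ], diag(3))
  const <- array(0.4, dim = c(6, 6, 2, 1))
  got <- conv_oracle(const, avgpool_as_conv(2, 3), stride = 1, pad = 0)
  expect_true(all(abs(got - 0.4) < 1e-12))
  set.seed(13)
  x <- rand_image_batch(7, 7, 3, 2)
  ref <- array(0, dim = c(5, 5, 3, 2))
  for (n in 1:2) for (c in 1:3) for (i in 1:5) for (j in 1:5)
    ref[i, j, c, n] <- mean(x[i:(i + 2), j:(j + 2), c, n])
  expect_lt(max(abs(conv_oracle(x, avgpool_as_conv(3, 3)) - ref)), 1e-6)
})

test_that("reparameterization collapses special blocks exactly", {
  # only the KxK branch with identity BN: F' = F6, b' = 0
  blk <- new_dbb_block(2, 3, K = 3)
  for (cv in list(blk$conv1, blk$conv2, blk$conv3, blk$conv4)) cv$par$w[] <- 0
  for (bn in list(blk$bn1, blk$bn2, blk$bn3, blk$bn4, blk$bn5, blk$bn6)) {
    bn$par$beta[] <- 0; bn$eps <- 0
  }
  rc <- reparameterize(blk)
  expect_equal(rc$kernel, blk$conv6$par$w)
  expect_equal(rc$bias, rep(0, 3))

  # zero kernels: F' = 0, bias = accumulated BN shift terms
  blk2 <- new_dbb_block(2, 3, K = 3)
  for (cv in list(blk2$conv6, blk2$conv1, blk2$conv2, blk2$conv3, blk2$conv4))
    cv$par$w[] <- 0
  betas <- list()
  for (nm in c("bn1", "bn2", "bn3", "bn4", "bn5", "bn6")) {
    blk2[[nm]]$par$beta <- rnorm(3)
    blk2[[nm]]$eps <- 0
    betas[[nm]] <- blk2[[nm]]$par$beta
  }
  rc2 <- reparameterize(blk2)
  expect_true(all(rc2$kernel == 0))
  # terminal-branch shifts, plus the pooled beta of the 1x1 stage feeding the
  # pooling branch (beta2 dies against the zero KxK kernel of its branch)
  expect_equal(rc2$bias,
               betas$bn1 + betas$bn3 + betas$bn6 + betas$bn5 + betas$bn4)
  expect_error(new_dbb_block(2, 3, K = 4), "odd")
})

test_that("reparameterization equivalence holds across random configurations", {
  dev <- dbb_equivalence_check(50, seed = 1)
  expect_lt(dev, 1e-4)
  expect_length(attr(dev, "per_block"), 50)
})

test_that("collapse is homogeneous and additive in the branch kernels", {
  set.seed(14)
  mk <- function() {
    b <- new_dbb_block(3, 4, K = 3, stride = 1)
    randomize_bn_stats(b)
    b
  }
  # homogeneity: scaling the terminal BN gains of every branch scales the
  # block's output, hence (F', b') scale by the same factor
  a <- mk()
  rc0 <- reparameterize(a)
  for (nm in c("bn1", "bn3", "bn5", "bn6"))
    a[[nm]]$par$gamma <- 2 * a[[nm]]$par$gamma
  for (nm in c("bn1", "bn3", "bn5", "bn6"))
    a[[nm]]$par$beta <- 2 * a[[nm]]$par$beta
  rc2x <- reparameterize(a)
  expect_lt(max(abs(rc2x$kernel - 2 * rc0$kernel)), 1e-8)
  expect_lt(max(abs(rc2x$bias - 2 * rc0$bias)), 1e-8)

  # additivity: the sum of two blocks equals one convolution with summed
  # kernels and biases
  b1 <- mk(); b2 <- mk()
  x <- rand_image_batch(6, 6, 3, 2)
  y_sum <- dbb_forward(b1, x) + dbb_forward(b2, x)
  r1 <- reparameterize(b1); r2 <- reparameterize(b2)
  y_merged <- conv_oracle(x, r1$kernel + r2$kernel, r1$bias + r2$bias,
                          1, r1$pad)
  expect_lt(max(abs(y_sum - y_merged)), 1e-8)
})

test_that("network kernel counts follow the main-path output channels", {
  toy <- build_target_network(net_config("toy", widths = c(4, 8),
                                         input_size = 16))
  expect_equal(count_feature_channels(toy), 12)
  default_toy <- build_target_network(net_config("toy"))
  expect_equal(count_feature_channels(default_toy), 240)
  single <- build_network(net_config("toy", widths = 5, input_size = 8))
  expect_equal(count_feature_channels(single), 5)
  expect_error(net_config("alexnet"), "arg")
})

test_that("toy target forward returns class logits of the right shape", {
  net <- build_target_network(net_config("toy", widths = c(4, 8),
                                         input_size = 16, n_classes = 3))
  x <- rand_image_batch(224, 224, 3, 2)
  out <- net_forward(net, x)
  expect_equal(dim(out$logits), c(2, 3))
  expect_true(all(is.finite(out$logits)))
})

test_that("reparameterized network agrees with the trained multi-branch net", {
  set.seed(15)
  net <- build_target_network(net_config("toy", widths = c(4, 8),
                                         input_size = 16))
  # push some batches through in training mode so running stats move
  for (i in 1:3)
    net_forward(net, rand_image_batch(16, 16, 3, 4), training = TRUE)
  rp <- reparameterize_network(net)
  x <- rand_image_batch(16, 16, 3, 3)
  expect_lt(max(abs(net_forward(net, x)$logits - net_forward(rp, x)$logits)),
            1e-6)
})
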