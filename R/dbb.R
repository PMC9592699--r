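# Diverse branch block (DBB): a train-time convolution made of four parallel
# branches -- KxK conv, 1x1 conv, 1x1 conv -> KxK conv, and 1x1 conv -> KxK
# average pooling -- each followed by batch normalization, summed. By the
# homogeneity and additivity of convolution the whole block collapses exactly
# into a single KxK convolution plus bias once the batch-norm statistics are
# frozen. In the sequential branches the block's zero padding is carried by
# the *first* 1x1 convolution (the second stage runs unpadded); this is what
# makes the collapse exact at the borders, where the intermediate map's
# padded ring otherwise differs from the fused bias.

#' Create a diverse branch block
#'
#' @param C input channels
#' @param D output channels
#' @param K odd spatial kernel size
#' @param stride convolution stride (the pooling branch pools with the same
#'   stride)
#' @param init_sd standard deviation for kernel initialization (default He)
#' @return a mutable block object (environment) usable with [dbb_forward()],
#'   [dbb_backward()] and [reparameterize()]
#' @export
new_dbb_block <- function(C, D, K = 3L, stride = 1L, init_sd = NULL) {
  if (K %% 2L == 0L) stopf("diverse branch block requires an odd kernel size, got %d", K)
  p <- (K - 1L) %/% 2L
  e <- new.env(parent = emptyenv())
  e$kind <- "dbb"
  e$C <- as.integer(C); e$D <- as.integer(D); e$K <- as.integer(K)
  e$stride <- as.integer(stride); e$pad <- p
  e$conv6 <- new_conv(K, C, D, stride, p, init_sd)        # KxK branch
  e$bn6 <- new_bn(D)
  e$conv1 <- new_conv(1L, C, D, stride, 0L, init_sd)      # 1x1 branch
  e$bn1 <- new_bn(D)
  e$conv2 <- new_conv(1L, C, D, 1L, p, init_sd)           # 1x1 -> KxK branch
  e$bn2 <- new_bn(D)
  e$conv3 <- new_conv(K, D, D, stride, 0L, init_sd)
  e$bn3 <- new_bn(D)
  e$conv4 <- new_conv(1L, C, D, 1L, p, init_sd)           # 1x1 -> avgpool branch
  e$bn4 <- new_bn(D)
  e$pool <- new_pool(K, stride, 0L)
  e$bn5 <- new_bn(D)
  e
}

dbb_leaves <- function(e) {
  list(e$conv6, e$bn6, e$conv1, e$bn1, e$conv2, e$bn2, e$conv3, e$bn3,
       e$conv4, e$bn4, e$bn5)
}

#' Train-time forward pass of a diverse branch block
#'
#' @param block block from [new_dbb_block()]
#' @param x input array (H, W, C, N)
#' @param training if `TRUE`, batch statistics are used in the branch batch
#'   norms (and running statistics updated) and caches are kept for
#'   [dbb_backward()]; if `FALSE` the stored running statistics are used, which
#'   is the regime under which the block equals its reparameterized form
#' @return output array (H', W', D, N)
#' @export
dbb_forward <- function(block, x, training = FALSE) {
  if (dim(x)[3] != block$C)
    stopf("dbb_forward: input has %d channels, block expects %d", dim(x)[3], block$C)
  y6 <- bn_fwd(block$bn6, conv_fwd(block$conv6, x, training), training)
  y1 <- bn_fwd(block$bn1, conv_fwd(block$conv1, x, training), training)
  y23 <- bn_fwd(block$bn3,
                conv_fwd(block$conv3,
                         bn_fwd(block$bn2, conv_fwd(block$conv2, x, training),
                                training), training), training)
  y45 <- bn_fwd(block$bn5,
                pool_fwd(block$pool,
                         bn_fwd(block$bn4, conv_fwd(block$conv4, x, training),
                                training), training), training)
  y6 + y1 + y23 + y45
}

#' Backward pass of a diverse branch block
#' @param block block whose forward was run with `training = TRUE`
#' @param gy gradient w.r.t. the block output
#' @return gradient w.r.t. the block input; parameter gradients accumulate in
#'   the block's leaf layers
#' @export
dbb_backward <- function(block, gy) {
  g6 <- conv_bwd(block$conv6, bn_bwd(block$bn6, gy))
  g1 <- conv_bwd(block$conv1, bn_bwd(block$bn1, gy))
  g23 <- conv_bwd(block$conv2,
                  bn_bwd(block$bn2,
                         conv_bwd(block$conv3, bn_bwd(block$bn3, gy))))
  g45 <- conv_bwd(block$conv4,
                  bn_bwd(block$bn4,
                         pool_bwd(block$pool, bn_bwd(block$bn5, gy))))
  g6 + g1 + g23 + g45
}

#' Fold a batch-norm affine transform into a convolution kernel
#'
#' Returns the kernel/bias pair such that `conv(x, F_fused) + b_fused`
#' equals `BN(conv(x, F))` with the given (frozen) statistics.
#'
#' @param F kernel, (K, K, C, D) layout
#' @param gamma,beta batch-norm scale and shift, length D
#' @param sigma per-channel standard deviation (already including any
#'   variance-floor epsilon), length D; must be positive
#' @param mu per-channel mean, length D
#' @return list with `kernel` and `bias`
#' @export
fuse_bn <- function(F, gamma, sigma, mu, beta) {
  if (any(sigma <= 0)) stopf("fuse_bn: sigma must be positive")
  D <- dim(F)[4]
  scale <- gamma / sigma
  Ff <- F * rep(scale, each = prod(dim(F)[1:3]))
  list(kernel = Ff, bias = beta - mu * scale)
}

fuse_bn_layer <- function(conv, bn) {
  fuse_bn(conv$par$w, bn$par$gamma, sqrt(bn$running_var + bn$eps),
          bn$running_mean, bn$par$beta)
}

#' Merge a pointwise convolution followed by a spatial convolution
#'
#' Computes the single (K, K, C, D) kernel whose convolution equals applying
#' the 1x1 kernel `F_point` (C -> E channels) and then the KxK kernel
#' `F_spatial` (E -> D channels), with the composite's zero padding carried by
#' the pointwise stage.
#'
#' @param F_point (1, 1, C, E) kernel
#' @param F_spatial (K, K, E, D) kernel
#' @return merged (K, K, C, D) kernel
#' @export
merge_sequential <- function(F_point, F_spatial) {
  dp <- dim(F_point); ds <- dim(F_spatial)
  if (dp[1] != 1L || dp[2] != 1L) stopf("F_point must be a 1x1 kernel")
  if (dp[4] != ds[3])
    stopf("channel chain mismatch: pointwise gives %d channels, spatial expects %d",
          dp[4], ds[3])
  C <- dp[3]; E <- dp[4]; K1 <- ds[1]; K2 <- ds[2]; D <- ds[4]
  P <- matrix(F_point, nrow = C, ncol = E)                 # P[c, e]
  out <- array(0, dim = c(K1, K2, C, D))
  for (d in seq_len(D)) {
    sp <- matrix(F_spatial[, , , d], nrow = K1 * K2, ncol = E)
    out[, , , d] <- array(sp %*% t(P), dim = c(K1, K2, C))
  }
  out
}

#' Express KxK average pooling as a convolution kernel
#'
#' @param D channel count
#' @param K pooling window (odd)
#' @return (K, K, D, D) kernel with 1/K^2 on the matching channel diagonal
#' @export
avgpool_as_conv <- function(D, K) {
  w <- array(0, dim = c(K, K, D, D))
  for (d in seq_len(D)) w[, , d, d] <- 1 / (K * K)
  w
}

#' Collapse a diverse branch block into a single convolution
#'
#' Uses the blocks' running batch-norm statistics. For every input, the
#' returned convolution reproduces [dbb_forward()] in inference mode
#' (`training = FALSE`) up to floating-point roundoff.
#'
#' @param block block from [new_dbb_block()]
#' @return an object of class `reparam_conv`: list with `kernel`
#'   ((K, K, C, D)), `bias` (length D), `stride`, `pad`
#' @export
reparameterize <- function(block) {
  if (!identical(block$kind, "dbb")) stopf("not a diverse branch block")
  K <- block$K; D <- block$D; C <- block$C
  f6 <- fuse_bn_layer(block$conv6, block$bn6)
  f1 <- fuse_bn_layer(block$conv1, block$bn1)
  k1 <- array(0, dim = c(K, K, C, D))
  ctr <- (K + 1L) %/% 2L
  k1[ctr, ctr, , ] <- f1$kernel[1L, 1L, , ]
  f2 <- fuse_bn_layer(block$conv2, block$bn2)
  f3 <- fuse_bn_layer(block$conv3, block$bn3)
  k23 <- merge_sequential(f2$kernel, f3$kernel)
  b23 <- f3$bias + as.vector(apply(f3$kernel, 4L, function(k)
    sum(k * rep(f2$bias, each = K * K))))
  f4 <- fuse_bn_layer(block$conv4, block$bn4)
  f5 <- fuse_bn(avgpool_as_conv(D, K), block$bn5$par$gamma,
                sqrt(block$bn5$running_var + block$bn5$eps),
                block$bn5$running_mean, block$bn5$par$beta)
  k45 <- merge_sequential(f4$kernel, f5$kernel)
  b45 <- f5$bias + as.vector(apply(f5$kernel, 4L, function(k)
    sum(k * rep(f4$bias, each = K * K))))
  structure(list(kernel = f6$kernel + k1 + k23 + k45,
                 bias = f6$bias + f1$bias + b23 + b45,
                 stride = block$stride, pad = block$pad,
                 K = K, C = C, D = D),
            class = "reparam_conv")
}

#' Apply a reparameterized convolution
#' @param rc object from [reparameterize()]
#' @param x input array (H, W, C, N)
#' @return output array
#' @export
reparam_forward <- function(rc, x) {
  conv2d(as_image_batch(x), rc$kernel, rc$bias, rc$stride, rc$pad)
}

# scatter random running statistics / affine parameters over a block's batch
# norms (used by equivalence tests so the collapse is exercised away from the
# identity initialization)
randomize_bn_stats <- function(block) {
  for (bn in list(block$bn1, block$bn2, block$bn3, block$bn4, block$bn5, block$bn6)) {
    bn$running_mean <- rnorm(bn$D, sd = 0.5)
    bn$running_var <- runif(bn$D, 0.2, 2)
    bn$par$gamma <- rnorm(bn$D, mean = 1, sd = 0.3)
    bn$par$beta <- rnorm(bn$D, sd = 0.3)
  }
  invisible(block)
}
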