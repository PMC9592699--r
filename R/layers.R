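# Minimal mutable-layer framework. Each leaf layer is an environment holding
# parameters (`par`), accumulated gradients (`gr`), optimizer state (`opt`),
# and a forward cache. All feature maps are (H, W, C, N) arrays; kernels are
# (K, K, C, D); fully connected weights are (out x in).

new_conv <- function(K, C, D, stride = 1L, pad = (K - 1L) %/% 2L,
                     init_sd = NULL, use_bias = FALSE, trainable = TRUE,
                     kernel = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"
  if (is.null(kernel)) {
    if (is.null(init_sd)) init_sd <- sqrt(2 / (K * K * C))  # He init
    kernel <- array(rnorm(K * K * C * D, sd = init_sd), dim = c(K, K, C, D))
  }
  e$par <- list(w = kernel)
  if (use_bias) e$par$b <- numeric(D)
  e$use_bias <- use_bias
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$K <- as.integer(K); e$C <- as.integer(C); e$D <- as.integer(D)
  e$trainable <- trainable
  e$gr <- NULL; e$opt <- NULL; e$cache <- NULL
  e
}

# convolution lowered to im2col + one BLAS matrix product
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L) {
  dw <- dim(w); dx <- dim(x)
  Ho <- (dx[1] + 2L * pad - dw[1]) %/% stride + 1L
  Wo <- (dx[2] + 2L * pad - dw[2]) %/% stride + 1L
  col <- cpp_im2col(x, dw[1], dw[2], stride, pad)
  Y <- col %*% matrix(w, ncol = dw[4])
  if (!is.null(bias)) Y <- sweep(Y, 2L, bias, "+")
  structure(aperm(array(Y, dim = c(Ho, Wo, dx[4], dw[4])), c(1, 2, 4, 3)),
            col = NULL)
}

conv_fwd <- function(e, x, training = FALSE) {
  dw <- dim(e$par$w); dx <- dim(x)
  if (dx[3] != dw[3])
    stopf("conv2d: input has %d channels, kernel expects %d", dx[3], dw[3])
  Ho <- (dx[1] + 2L * e$pad - dw[1]) %/% e$stride + 1L
  Wo <- (dx[2] + 2L * e$pad - dw[2]) %/% e$stride + 1L
  if (Ho < 1L || Wo < 1L) stopf("conv2d: output would be empty")
  col <- cpp_im2col(x, dw[1], dw[2], e$stride, e$pad)
  Y <- col %*% matrix(e$par$w, ncol = e$D)
  if (e$use_bias) Y <- sweep(Y, 2L, e$par$b, "+")
  if (training) e$cache <- list(col = col, dx = dx, dims = c(Ho, Wo))
  aperm(array(Y, dim = c(Ho, Wo, dx[4], e$D)), c(1, 2, 4, 3))
}

conv_bwd <- function(e, gy) {
  dw <- dim(e$par$w); dx <- e$cache$dx
  gY <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = e$D)
  if (e$trainable) {
    gw <- array(crossprod(e$cache$col, gY), dim = dw)
    gb <- colSums(gY)
    if (is.null(e$gr)) e$gr <- list(w = gw, b = gb)
    else { e$gr$w <- e$gr$w + gw; e$gr$b <- e$gr$b + gb }
  }
  gcol <- gY %*% t(matrix(e$par$w, ncol = e$D))
  cpp_col2im(gcol, dw[1], dw[2], e$stride, e$pad, dx[1], dx[2], dx[3], dx[4])
}

new_bn <- function(D, eps = 1e-5, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"
  e$par <- list(gamma = rep(1, D), beta = numeric(D))
  e$running_mean <- numeric(D)
  e$running_var <- rep(1, D)
  e$eps <- eps; e$momentum <- momentum; e$D <- as.integer(D)
  e$trainable <- TRUE
  e$gr <- NULL; e$opt <- NULL; e$cache <- NULL
  e
}

bn_fwd <- function(e, x, training = FALSE) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))                  # (H, W, N, C)
  m <- matrix(xp, ncol = d[3])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu               # biased batch variance
    e$running_mean <- (1 - e$momentum) * e$running_mean + e$momentum * mu
    e$running_var <- (1 - e$momentum) * e$running_var + e$momentum * v
  } else {
    mu <- e$running_mean
    v <- e$running_var
  }
  invstd <- 1 / sqrt(v + e$eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, e$par$gamma, "*"), 2L, e$par$beta, "+")
  if (training) e$cache <- list(xhat = xhat, invstd = invstd, d = d,
                                batch_stats = training)
  aperm(array(y, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

bn_bwd <- function(e, gy) {
  d <- e$cache$d
  gm <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
  xhat <- e$cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  if (is.null(e$gr)) e$gr <- list(gamma = ggamma, beta = gbeta)
  else { e$gr$gamma <- e$gr$gamma + ggamma; e$gr$beta <- e$gr$beta + gbeta }
  mtot <- nrow(gm)
  gxhat <- sweep(gm, 2L, e$par$gamma, "*")
  gx <- sweep(
    gxhat - matrix(colMeans(gxhat), mtot, d[3], byrow = TRUE) -
      xhat * matrix(colMeans(gxhat * xhat), mtot, d[3], byrow = TRUE),
    2L, e$cache$invstd, "*")
  aperm(array(gx, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

new_pool <- function(K, stride = 1L, pad = (K - 1L) %/% 2L) {
  e <- new.env(parent = emptyenv())
  e$kind <- "pool"
  e$K <- as.integer(K); e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$par <- list(); e$trainable <- FALSE
  e$gr <- NULL; e$opt <- NULL; e$cache <- NULL
  e
}

pool_fwd <- function(e, x, training = FALSE) {
  if (training) e$cache <- list(hw = dim(x)[1:2])
  cpp_avgpool_fwd(x, e$K, e$stride, e$pad)
}

pool_bwd <- function(e, gy) {
  cpp_avgpool_bwd(gy, e$K, e$stride, e$pad, e$cache$hw[1], e$cache$hw[2])
}

new_fc <- function(n_in, n_out, init_sd = NULL, zero_init = FALSE) {
  e <- new.env(parent = emptyenv())
  e$kind <- "fc"
  if (zero_init) {
    W <- matrix(0, n_out, n_in)
  } else {
    if (is.null(init_sd)) init_sd <- sqrt(1 / n_in)
    W <- matrix(rnorm(n_out * n_in, sd = init_sd), n_out, n_in)
  }
  e$par <- list(W = W, b = numeric(n_out))
  e$trainable <- TRUE
  e$gr <- NULL; e$opt <- NULL; e$cache <- NULL
  e
}

fc_fwd <- function(e, x, training = FALSE) {            # x: N x n_in
  if (training) e$cache <- list(x = x)
  sweep(x %*% t(e$par$W), 2L, e$par$b, "+")
}

fc_bwd <- function(e, gy) {                             # gy: N x n_out
  gW <- t(gy) %*% e$cache$x
  gb <- colSums(gy)
  if (is.null(e$gr)) e$gr <- list(W = gW, b = gb)
  else { e$gr$W <- e$gr$W + gW; e$gr$b <- e$gr$b + gb }
  gy %*% e$par$W
}

layer_fwd <- function(e, x, training = FALSE) {
  switch(e$kind,
         conv = conv_fwd(e, x, training),
         bn = bn_fwd(e, x, training),
         pool = pool_fwd(e, x, training),
         fc = fc_fwd(e, x, training),
         stopf("unknown layer kind '%s'", e$kind))
}

layer_bwd <- function(e, gy) {
  switch(e$kind,
         conv = conv_bwd(e, gy),
         bn = bn_bwd(e, gy),
         pool = pool_bwd(e, gy),
         fc = fc_bwd(e, gy),
         stopf("unknown layer kind '%s'", e$kind))
}

zero_grads <- function(layers) {
  for (e in layers) e$gr <- NULL
  invisible(NULL)
}

# --- optimizers -------------------------------------------------------------

#' @noRd
sgd_momentum_step <- function(layers, lr, momentum = 0.9, weight_decay = 0) {
  for (e in layers) {
    if (!isTRUE(e$trainable) || is.null(e$gr)) next
    if (is.null(e$opt)) e$opt <- lapply(e$par, function(p) p * 0)
    for (nm in names(e$gr)) {
      if (is.null(e$par[[nm]])) next
      g <- e$gr[[nm]] + weight_decay * e$par[[nm]]
      e$opt[[nm]] <- momentum * e$opt[[nm]] + g
      e$par[[nm]] <- e$par[[nm]] - lr * e$opt[[nm]]
    }
  }
  invisible(NULL)
}

#' @noRd
adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (e in layers) {
    if (!isTRUE(e$trainable) || is.null(e$gr)) next
    if (is.null(e$opt))
      e$opt <- list(m = lapply(e$par, function(p) p * 0),
                    v = lapply(e$par, function(p) p * 0), t = 0)
    e$opt$t <- e$opt$t + 1
    for (nm in names(e$gr)) {
      if (is.null(e$par[[nm]])) next
      g <- e$gr[[nm]] + weight_decay * e$par[[nm]]
      e$opt$m[[nm]] <- beta1 * e$opt$m[[nm]] + (1 - beta1) * g
      e$opt$v[[nm]] <- beta2 * e$opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- e$opt$m[[nm]] / (1 - beta1^e$opt$t)
      vhat <- e$opt$v[[nm]] / (1 - beta2^e$opt$t)
      e$par[[nm]] <- e$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# flatten all parameters of a list of layers into one numeric vector (used by
# determinism checks and the meta-gradient's finite-difference probe)
flatten_params <- function(layers) {
  unlist(lapply(layers, function(e) lapply(e$par, as.vector)), use.names = FALSE)
}

set_params_from_vector <- function(layers, v) {
  i <- 0L
  for (e in layers) {
    for (nm in names(e$par)) {
      n <- length(e$par[[nm]])
      p <- e$par[[nm]]
      p[] <- v[(i + 1L):(i + n)]
      e$par[[nm]] <- p
      i <- i + n
    }
  }
  invisible(NULL)
}

flatten_grads <- function(layers) {
  unlist(lapply(layers, function(e) {
    lapply(names(e$par), function(nm) {
      g <- e$gr[[nm]]
      if (is.null(g)) rep(0, length(e$par[[nm]])) else as.vector(g)
    })
  }), use.names = FALSE)
}
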