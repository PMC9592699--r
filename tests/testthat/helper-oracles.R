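# Independent reference implementations used as oracles. These deliberately
# use naive loops / base-R interpolation so they share no code path with the
# package internals they check.

# plain-loop 2-D cross-correlation on (H, W, C, N) arrays with (K, K, C, D)
# kernels
conv_oracle <- function(x, w, bias = NULL, stride = 1L, pad = 0L) {
  dx <- dim(x); dw <- dim(w)
  Ho <- (dx[1] + 2L * pad - dw[1]) %/% stride + 1L
  Wo <- (dx[2] + 2L * pad - dw[2]) %/% stride + 1L
  xp <- array(0, dim = c(dx[1] + 2L * pad, dx[2] + 2L * pad, dx[3], dx[4]))
  xp[pad + seq_len(dx[1]), pad + seq_len(dx[2]), , ] <- x
  y <- array(0, dim = c(Ho, Wo, dw[4], dx[4]))
  for (n in seq_len(dx[4])) for (d in seq_len(dw[4])) {
    kd <- as.vector(w[, , , d])
    b <- if (is.null(bias)) 0 else bias[d]
    for (jo in seq_len(Wo)) for (io in seq_len(Ho)) {
      patch <- xp[(io - 1L) * stride + seq_len(dw[1]),
                  (jo - 1L) * stride + seq_len(dw[2]), , n, drop = FALSE]
      y[io, jo, d, n] <- sum(as.vector(patch) * kd) + b
    }
  }
  y
}

# per-channel affine batch norm with given (frozen) statistics
bn_oracle <- function(x, gamma, beta, mu, v, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[3]))
    out[, , c, ] <- gamma[c] * (x[, , c, ] - mu[c]) / sqrt(v[c] + eps) + beta[c]
  out
}

bn_oracle_layer <- function(x, bn) {
  bn_oracle(x, bn$par$gamma, bn$par$beta, bn$running_mean, bn$running_var, bn$eps)
}

# separable two-pass linear interpolation with half-pixel centres and edge
# clamping (matrix in, matrix out)
resize_oracle <- function(img, Ho, Wo) {
  H <- nrow(img); W <- ncol(img)
  coords <- function(S, So) pmin(pmax((seq_len(So) - 0.5) * S / So - 0.5, 0), S - 1)
  ri <- coords(H, Ho); ci <- coords(W, Wo)
  tmp <- apply(img, 2L, function(col)
    stats::approx(0:(H - 1), col, xout = ri, rule = 2)$y)
  tmp <- matrix(tmp, nrow = Ho)
  t(apply(tmp, 1L, function(row)
    stats::approx(0:(W - 1), row, xout = ci, rule = 2)$y))
}

# sliding-window mean with zero padding counted in the divisor
avgpool_oracle <- function(x, K, stride, pad) {
  conv_oracle(x, avgpool_as_conv(dim(x)[3], K), stride = stride, pad = pad)
}

rand_image_batch <- function(H, W, C, N, sd = 1) {
  array(rnorm(H * W * C * N, sd = sd), dim = c(H, W, C, N))
}

# small frozen source pair + cohort shared across training tests (built once)
tiny_sources <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s1 <- pretrain_source(gen_task(task_preset("source1", 16, 32, seed = 11)),
                            cfg = train_config(epochs = 6L, seed = 1L))
      s2 <- pretrain_source(gen_task(task_preset("source2", 16, 32, seed = 12)),
                            cfg = train_config(epochs = 6L, seed = 2L))
      cache <<- list(s1, s2)
    }
    cache
  }
})
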