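#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Coerce an image-like object to the internal (H, W, C, N) array layout
#'
#' Accepts a 2-D matrix (one grayscale image), a 3-D array (H, W, C), or a
#' 4-D array already in (H, W, C, N) layout.
#' @param x matrix or array
#' @return 4-D numeric array with dim (H, W, C, N)
#' @export
as_image_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 4L) stopf("expected a 2-D, 3-D or 4-D array")
  storage.mode(x) <- "double"
  x
}

#' Bilinear resize of an image batch
#'
#' Half-pixel centre alignment with edge clamping; a constant image resizes
#' to the same constant and same-size resizing is the identity.
#' @param x array in (H, W, C, N) layout (2-D/3-D inputs are promoted)
#' @param out_h,out_w output height and width in pixels
#' @return resized array, (out_h, out_w, C, N)
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  x <- as_image_batch(x)
  if (out_h < 1 || out_w < 1) stopf("output size must be positive")
  if (dim(x)[1] == out_h && dim(x)[2] == out_w) return(x)
  cpp_bilinear_resize(x, as.integer(out_h), as.integer(out_w))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu6 <- function(x) pmin(pmax(x, 0), 6)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax over the columns of a matrix (rows are observations)
#' @keywords internal
#' @noRd
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Global mean pooling of an (H, W, C, N) feature map
#' @param x 4-D array
#' @return N x C matrix of per-channel spatial means
#' @export
global_mean_pool <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, nrow = d[1] * d[2]))     # (C*N) means
  matrix(m, nrow = d[4], ncol = d[3], byrow = TRUE)
}

# inverse of global_mean_pool for backprop: spread an N x C gradient evenly
gap_backward <- function(g, d) {
  per_px <- as.vector(t(g)) / (d[1] * d[2])        # length C*N, channel-major
  array(rep(per_px, each = d[1] * d[2]), dim = d)
}

#' Cross-entropy loss with softmax over logits
#' @param logits N x n_classes matrix
#' @param labels integer vector in `0:(n_classes-1)`
#' @return list with `loss` (mean negative log-likelihood) and `grad`
#'   (N x n_classes gradient of the mean loss w.r.t. the logits)
#' @keywords internal
#' @noRd
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, prob = p)
}

# deterministic per-purpose seed derivation, kept below .Machine$integer.max
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
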