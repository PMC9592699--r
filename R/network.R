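# Network containers. Two backbones are provided:
#   * "toy"      -- a sequential CNN (conv/DBB units, each followed by batch
#                   norm folding inside the DBB or an explicit BN for plain
#                   convs, then ReLU), global mean pooling and a linear head.
#                   This is the desk-scale workhorse: it trains in seconds and
#                   supports full backpropagation.
#   * "resnet18" -- a resnet18-style architecture in which every main-path
#                   convolution is a diverse branch block while the 1x1
#                   shortcut projections stay plain convolutions. It is built
#                   for architecture inspection (kernel counting) and
#                   inference; training it is out of desk scope.

#' Network configuration
#'
#' @param backbone `"toy"` or `"resnet18"`
#' @param widths output channels of each conv unit (toy backbone)
#' @param strides per-unit strides; default stride 2 wherever the width
#'   changes (and at the first unit), 1 elsewhere
#' @param taps indices of units whose post-ReLU output is exposed as a
#'   feature-map tap; default the last unit of each width group
#' @param n_classes number of classes of the attached linear head
#' @param in_channels input image channels
#' @param input_size images are bilinearly resized to this square size before
#'   entering the network
#' @param K spatial kernel size of the units (odd)
#' @param dbb if `TRUE` units are diverse branch blocks, else plain conv+BN
#' @return a list of class `afmtl_net_config`
#' @export
net_config <- function(backbone = c("toy", "resnet18"),
                       widths = c(8, 8, 16, 16, 32, 32, 64, 64),
                       strides = NULL, taps = NULL, n_classes = 2L,
                       in_channels = 3L, input_size = 32L, K = 3L,
                       dbb = TRUE) {
  backbone <- match.arg(backbone)
  widths <- as.integer(widths)
  if (any(widths < 1L)) stopf("widths must be positive")
  if (is.null(strides))
    strides <- ifelse(seq_along(widths) == 1L | widths != c(widths[1], widths[-length(widths)]),
                      2L, 1L)
  if (is.null(taps)) {
    last_of_group <- which(widths != c(widths[-1], -1L))
    taps <- if (length(last_of_group)) last_of_group else length(widths)
  }
  structure(list(backbone = backbone, widths = widths,
                 strides = as.integer(strides), taps = as.integer(taps),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size), K = as.integer(K),
                 dbb = dbb),
            class = "afmtl_net_config")
}

new_unit <- function(kind, C, D, K, stride) {
  u <- new.env(parent = emptyenv())
  u$kind <- kind
  u$D <- as.integer(D)
  if (kind == "dbb") {
    u$block <- new_dbb_block(C, D, K, stride)
  } else {
    u$conv <- new_conv(K, C, D, stride)
    u$bn <- new_bn(D)
  }
  u$cache <- NULL
  u
}

unit_fwd <- function(u, x, training = FALSE) {
  pre <- switch(u$kind,
                dbb = dbb_forward(u$block, x, training),
                convbn = bn_fwd(u$bn, conv_fwd(u$conv, x, training), training),
                reparam = reparam_forward(u$rc, x),
                stopf("unknown unit kind '%s'", u$kind))
  y <- relu(pre)
  if (training) u$cache <- list(mask = pre > 0)
  u$pre <- pre
  y
}

unit_bwd <- function(u, gy) {
  gy <- gy * u$cache$mask
  switch(u$kind,
         dbb = dbb_backward(u$block, gy),
         convbn = conv_bwd(u$conv, bn_bwd(u$bn, gy)),
         stopf("unit kind '%s' does not support backward", u$kind))
}

unit_leaves <- function(u) {
  switch(u$kind,
         dbb = dbb_leaves(u$block),
         convbn = list(u$conv, u$bn),
         list())
}

#' Build a network from a configuration
#'
#' For the resnet18-style backbone, every main-path convolution is a diverse
#' branch block and the reparameterized feature-kernel count (the sum of
#' main-path output channels, shortcut projections excluded) is 3904.
#'
#' @param config from [net_config()]
#' @return mutable network object (environment) of class `afmtl_net`
#' @export
build_network <- function(config) {
  if (!inherits(config, "afmtl_net_config")) stopf("config must come from net_config()")
  net <- new.env(parent = emptyenv())
  class(net) <- "afmtl_net"
  net$config <- config
  net$backbone <- config$backbone
  net$n_classes <- config$n_classes
  net$input_size <- config$input_size
  if (config$backbone == "toy") {
    C <- config$in_channels
    net$units <- vector("list", length(config$widths))
    for (i in seq_along(config$widths)) {
      kind <- if (config$dbb) "dbb" else "convbn"
      net$units[[i]] <- new_unit(kind, C, config$widths[i], config$K,
                                 config$strides[i])
      C <- config$widths[i]
    }
    net$taps <- config$taps
    net$head <- new_fc(C, config$n_classes)
    net$feature_channels <- config$widths
  } else {
    net <- build_resnet18(net, config)
  }
  net
}

#' Build a target network (alias emphasizing the transfer-learning role)
#' @inheritParams build_network
#' @export
build_target_network <- function(config) build_network(config)

build_resnet18 <- function(net, config) {
  n_classes <- config$n_classes
  mk <- function(kind, C, D, K, stride) new_unit(kind, C, D, K, stride)
  net$stem <- mk(if (config$dbb) "dbb" else "convbn", config$in_channels, 64L, 7L, 2L)
  stage_w <- c(64L, 128L, 256L, 512L)
  blocks <- list()
  C <- 64L
  for (s in seq_along(stage_w)) {
    D <- stage_w[s]
    for (b in 1:2) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blk <- new.env(parent = emptyenv())
      blk$u1 <- mk(if (config$dbb) "dbb" else "convbn", C, D, 3L, stride)
      blk$u2 <- mk(if (config$dbb) "dbb" else "convbn", D, D, 3L, 1L)
      if (stride != 1L || C != D) {
        blk$short_conv <- new_conv(1L, C, D, stride, 0L)  # plain projection
        blk$short_bn <- new_bn(D)
      }
      blocks[[length(blocks) + 1L]] <- blk
      C <- D
    }
  }
  net$blocks <- blocks
  net$head <- new_fc(512L, n_classes)
  net$feature_channels <- c(64L, rep(rep(stage_w, each = 2L), each = 2L))
  net$taps <- c(4L, 8L, 12L, 16L)   # after each residual stage (unit index)
  net
}

#' Count reparameterized feature kernels of a network
#'
#' The number of deep features extracted per patient: the sum of output
#' channels over all main-path convolutions (diverse branch blocks or their
#' collapsed forms); shortcut projections are not feature extractors and are
#' excluded.
#'
#' @param net a network from [build_network()] or [reparameterize_network()]
#' @return integer kernel count L
#' @export
count_feature_channels <- function(net) {
  sum(net$feature_channels)
}

net_trainable_layers <- function(net) {
  if (net$backbone != "toy") stopf("only the toy backbone is trainable at desk scale")
  c(unlist(lapply(net$units, unit_leaves)), list(net$head))
}

#' Forward pass through a network
#'
#' @param net network object
#' @param x image batch; any spatial size (resized to the network input size)
#' @param training use batch statistics and keep caches for [net_backward()]
#' @param want_taps also return the tapped post-ReLU stage outputs
#' @return list with `logits` (N x n_classes), `gap` (N x C), and `taps`
#'   (named list of 4-D arrays) when requested
#' @export
net_forward <- function(net, x, training = FALSE, want_taps = FALSE) {
  x <- as_image_batch(x)
  if (dim(x)[1] != net$input_size || dim(x)[2] != net$input_size)
    x <- bilinear_resize(x, net$input_size, net$input_size)
  taps <- list()
  if (net$backbone == "toy") {
    z <- x
    for (i in seq_along(net$units)) {
      z <- unit_fwd(net$units[[i]], z, training)
      if (want_taps && i %in% net$taps) taps[[as.character(i)]] <- z
    }
  } else {
    z <- resnet_forward(net, x)
  }
  net$last_dim <- dim(z)
  g <- global_mean_pool(z)
  logits <- fc_fwd(net$head, g, training)
  out <- list(logits = logits, gap = g)
  if (want_taps) out$taps <- taps
  out
}

resnet_forward <- function(net, x) {
  z <- unit_fwd(net$stem, x, FALSE)
  z <- cpp_maxpool_fwd(z, 3L, 2L, 1L)
  for (blk in net$blocks) {
    idn <- z
    z1 <- unit_fwd(blk$u1, z, FALSE)
    pre <- switch(blk$u2$kind,
                  dbb = dbb_forward(blk$u2$block, z1, FALSE),
                  convbn = bn_fwd(blk$u2$bn, conv_fwd(blk$u2$conv, z1, FALSE), FALSE),
                  reparam = reparam_forward(blk$u2$rc, z1))
    if (!is.null(blk$short_conv))
      idn <- bn_fwd(blk$short_bn, conv_fwd(blk$short_conv, z, FALSE), FALSE)
    z <- relu(pre + idn)
  }
  z
}

#' Backward pass through a toy network
#'
#' @param net network whose forward ran with `training = TRUE`
#' @param grad_logits N x n_classes gradient of the loss w.r.t. the logits,
#'   or `NULL` when the loss does not touch the classification head
#' @param tap_grads named list (by unit index, as character) of gradients
#'   w.r.t. the tapped activations, or `NULL`
#' @return invisibly, the gradient w.r.t. the (resized) network input
#' @export
net_backward <- function(net, grad_logits = NULL, tap_grads = NULL) {
  if (net$backbone != "toy") stopf("backward is implemented for the toy backbone")
  if (!is.null(grad_logits)) {
    ggap <- fc_bwd(net$head, grad_logits)
    g <- gap_backward(ggap, net$last_dim)
  } else {
    g <- array(0, dim = net$last_dim)
  }
  for (i in rev(seq_along(net$units))) {
    key <- as.character(i)
    if (!is.null(tap_grads) && !is.null(tap_grads[[key]]))
      g <- g + tap_grads[[key]]
    g <- unit_bwd(net$units[[i]], g)
  }
  invisible(g)
}

#' Collapse every diverse branch block of a network into a single convolution
#'
#' @param net a trained network built with `dbb = TRUE`
#' @return a new network of the same architecture whose units are single
#'   convolutions with bias; forward passes agree with the original network
#'   in inference mode
#' @export
reparameterize_network <- function(net) {
  rp <- new.env(parent = emptyenv())
  class(rp) <- "afmtl_net"
  rp$config <- net$config
  rp$backbone <- net$backbone
  rp$n_classes <- net$n_classes
  rp$input_size <- net$input_size
  rp$head <- net$head
  rp$taps <- net$taps
  rp$feature_channels <- net$feature_channels
  collapse_unit <- function(u) {
    v <- new.env(parent = emptyenv())
    v$kind <- "reparam"
    v$D <- u$D
    v$rc <- if (u$kind == "dbb") reparameterize(u$block)
            else {
              f <- fuse_bn_layer(u$conv, u$bn)
              structure(list(kernel = f$kernel, bias = f$bias,
                             stride = u$conv$stride, pad = u$conv$pad),
                        class = "reparam_conv")
            }
    v
  }
  if (net$backbone == "toy") {
    rp$units <- lapply(net$units, collapse_unit)
  } else {
    rp$stem <- collapse_unit(net$stem)
    rp$blocks <- lapply(net$blocks, function(blk) {
      nb <- new.env(parent = emptyenv())
      nb$u1 <- collapse_unit(blk$u1)
      nb$u2 <- collapse_unit(blk$u2)
      nb$short_conv <- blk$short_conv
      nb$short_bn <- blk$short_bn
      nb
    })
  }
  rp
}

#' Per-image deep features from a reparameterized network
#'
#' Runs the batch through the collapsed network and returns the global mean
#' pooling of every reparameterized convolution's output (pre-activation),
#' concatenated in network order: one column per kernel.
#'
#' @param net network from [reparameterize_network()] (toy backbone)
#' @param x image batch
#' @return N x L matrix, L = [count_feature_channels()]
#' @export
net_deep_features <- function(net, x) {
  if (net$backbone != "toy")
    stopf("deep-feature extraction is implemented for the toy backbone")
  x <- as_image_batch(x)
  if (dim(x)[1] != net$input_size || dim(x)[2] != net$input_size)
    x <- bilinear_resize(x, net$input_size, net$input_size)
  z <- x
  feats <- vector("list", length(net$units))
  for (i in seq_along(net$units)) {
    z <- unit_fwd(net$units[[i]], z, FALSE)
    feats[[i]] <- global_mean_pool(net$units[[i]]$pre)
  }
  do.call(cbind, feats)
}

#' Copy the parameters of one toy network into another (same architecture)
#' @keywords internal
#' @noRd
net_clone_params <- function(from, to) {
  lf <- net_trainable_layers(from); lt <- net_trainable_layers(to)
  for (i in seq_along(lf)) {
    lt[[i]]$par <- lf[[i]]$par
    if (lf[[i]]$kind == "bn") {
      lt[[i]]$running_mean <- lf[[i]]$running_mean
      lt[[i]]$running_var <- lf[[i]]$running_var
    }
  }
  invisible(to)
}
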