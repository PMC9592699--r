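# Adaptive selection-based dual-source feature matching. For every candidate
# layer pair (m, n) between a frozen source network k and the target network,
# three small trainable pieces decide what gets transferred and how much:
#   * a pointwise-convolution adapter r_v maps the target map's channels onto
#     the source map's channels;
#   * a one-layer softmax head f on the source map's global mean pooling
#     yields per-channel weights w (a simplex: which feature maps matter);
#   * a one-layer ReLU6 head g on the same pooled vector yields the pair
#     weight lambda in [0, 6] (how transferable the layer pair is).
# The weighted matching loss averages, over the batch, the per-channel
# weighted squared distance between the adapted target map and the source
# map, normalized by the spatial size; the total transfer loss sums
# lambda-weighted pair losses over both sources.

#' Create the matching state for a dual-source transfer problem
#'
#' @param sources list of two frozen source networks (from
#'   [pretrain_source()] or [build_network()])
#' @param target the target network
#' @param pairs list (one per source) of 2-column integer matrices of
#'   candidate (m, n) tap-stage pairs; default: all combinations of source
#'   and target stages
#' @param zeta trade-off between the original task loss and the matching
#'   loss
#' @param lambda_bias initial pre-activation of the pair-weight heads (all
#'   pairs start at `relu6(lambda_bias)`); the heads' linear weights start at
#'   zero so initial channel weights are uniform
#' @return mutable `match_state` environment
#' @export
new_match_state <- function(sources, target, pairs = NULL, zeta = 0.5,
                            lambda_bias = 1) {
  if (length(sources) != 2L) stopf("expected exactly two source networks")
  st <- new.env(parent = emptyenv())
  class(st) <- "match_state"
  st$zeta <- zeta
  src_ch <- lapply(sources, function(s) s$feature_channels[s$taps])
  tgt_ch <- target$feature_channels[target$taps]
  if (is.null(pairs))
    pairs <- lapply(src_ch, function(ch)
      as.matrix(expand.grid(m = seq_along(ch), n = seq_along(tgt_ch))))
  if (any(vapply(pairs, nrow, 0L) == 0L)) stopf("candidate pair set must be non-empty")
  st$pairs <- lapply(pairs, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "integer"
    colnames(p) <- c("m", "n"); p
  })
  st$src_ch <- src_ch; st$tgt_ch <- tgt_ch
  st$adapters <- vector("list", 2L)
  st$f_heads <- vector("list", 2L)
  st$g_heads <- vector("list", 2L)
  for (k in 1:2) {
    np <- nrow(st$pairs[[k]])
    st$adapters[[k]] <- vector("list", np)
    st$f_heads[[k]] <- vector("list", np)
    st$g_heads[[k]] <- vector("list", np)
    for (p in seq_len(np)) {
      m <- st$pairs[[k]][p, "m"]; n <- st$pairs[[k]][p, "n"]
      cs <- src_ch[[k]][m]; ct <- tgt_ch[n]
      st$adapters[[k]][[p]] <- new_pointwise_adapter(ct, cs)
      st$f_heads[[k]][[p]] <- new_fc(cs, cs, zero_init = TRUE)
      g <- new_fc(cs, 1L, zero_init = TRUE)
      g$par$b[] <- lambda_bias
      st$g_heads[[k]][[p]] <- g
    }
  }
  st
}

# identity-initialized pointwise convolution when channel counts agree,
# otherwise a small random projection
new_pointwise_adapter <- function(C_in, C_out) {
  if (C_in == C_out) {
    k <- array(0, dim = c(1L, 1L, C_in, C_out))
    for (c in seq_len(C_in)) k[1L, 1L, c, c] <- 1
    new_conv(1L, C_in, C_out, 1L, 0L, kernel = k)
  } else {
    new_conv(1L, C_in, C_out, 1L, 0L, init_sd = sqrt(1 / C_in))
  }
}

#' Adapt a target feature map to a source's channel space
#'
#' @param target_map (H, W, C_T, N) array
#' @param adapter a pointwise-convolution layer (from the match state)
#' @param training keep caches for backpropagation
#' @return (H, W, C_S, N) array, spatial dimensions unchanged
#' @export
adapt <- function(target_map, adapter, training = FALSE) {
  conv_fwd(adapter, target_map, training)
}

#' Per-channel transfer weights for a source feature map
#'
#' Softmax over channels of a single linear layer applied to the map's
#' global mean pooling: each row is on the simplex.
#'
#' @param source_map (H, W, C, N) array
#' @param f_head single fully connected layer (from the match state)
#' @return N x C matrix of positive weights, rows summing to 1
#' @export
channel_weights <- function(source_map, f_head) {
  softmax_rows(fc_fwd(f_head, global_mean_pool(source_map)))
}

#' Layer-pair transfer weight
#'
#' ReLU6 of a single linear layer on the source map's global mean pooling:
#' one value per batch item, in \[0, 6\].
#'
#' @param source_map (H, W, C, N) array
#' @param g_head single fully connected layer (from the match state)
#' @return numeric vector, length N
#' @export
pair_weight <- function(source_map, g_head) {
  as.vector(relu6(fc_fwd(g_head, global_mean_pool(source_map))))
}

#' Weighted feature-matching loss between a source map and an adapted target map
#'
#' For each batch item: sum over channels of the channel weight times the sum
#' of squared pointwise differences, divided by the spatial size H*W; the
#' returned loss is the batch mean.
#'
#' @param source_map,adapted_target_map equal-shaped (H, W, C, N) arrays
#' @param w N x C channel-weight matrix (or a length-C vector reused for all
#'   batch items)
#' @return scalar loss (>= 0); attribute `"per_sample"` carries the per-item
#'   values
#' @export
weighted_matching_loss <- function(source_map, adapted_target_map, w) {
  if (!identical(dim(source_map), dim(adapted_target_map)))
    stopf("matching loss requires equal shapes after adaptation")
  d <- dim(source_map)
  if (is.null(dim(w))) w <- matrix(w, nrow = d[4], ncol = d[3], byrow = TRUE)
  diff <- adapted_target_map - source_map
  q <- matrix(colSums(matrix(diff * diff, nrow = d[1] * d[2])),
              nrow = d[4], byrow = TRUE) / (d[1] * d[2])   # N x C
  per_sample <- rowSums(w * q)
  structure(mean(per_sample), per_sample = per_sample)
}

# Full evaluation of the matching term for one batch. Returns the loss, a
# per-pair log, and (optionally) gradients: tap gradients w.r.t. the target
# maps (through the adapters, scaled by `scale`), plus cached per-pair
# quantities used by the meta-update.
matching_eval <- function(state, source_taps, target_taps, training = FALSE,
                          want_grads = FALSE, scale = 1) {
  tap_keys <- names(target_taps)
  tap_grads <- if (want_grads)
    stats::setNames(vector("list", length(target_taps)), tap_keys) else NULL
  total <- 0
  rows <- list()
  pair_cache <- list()
  for (k in 1:2) {
    prs <- state$pairs[[k]]
    for (p in seq_len(nrow(prs))) {
      m <- prs[p, "m"]; n <- prs[p, "n"]
      S <- source_taps[[k]][[m]]
      Tn <- target_taps[[n]]
      adapter <- state$adapters[[k]][[p]]
      A <- adapt(Tn, adapter, training = want_grads)
      dT <- dim(Tn)
      Sr <- if (all(dim(S)[1:2] == dT[1:2])) S
            else bilinear_resize(S, dT[1], dT[2])
      gapS <- global_mean_pool(S)
      zf <- fc_fwd(state$f_heads[[k]][[p]], gapS)
      w <- softmax_rows(zf)                                   # N x C_s
      zg <- as.vector(fc_fwd(state$g_heads[[k]][[p]], gapS))
      lam <- relu6(zg)                                        # per item
      dA <- dim(A)
      diff <- A - Sr
      q <- matrix(colSums(matrix(diff * diff, nrow = dA[1] * dA[2])),
                  nrow = dA[4], byrow = TRUE) / (dA[1] * dA[2])
      per_sample <- rowSums(w * q)
      contribution <- mean(lam * per_sample)
      total <- total + contribution
      rows[[length(rows) + 1L]] <- data.frame(
        source = k, m = m, n = n, lambda = mean(lam),
        pair_loss = mean(per_sample), contribution = contribution)
      pair_cache[[length(pair_cache) + 1L]] <- list(
        k = k, p = p, gapS = gapS, zg = zg, lam = lam, w = w, q = q)
      if (want_grads && scale != 0) {
        # d contribution / d A = (2 / (H W N)) * lam_n * w_nc * diff
        wl <- w * lam                                          # N x C
        gA <- diff * array(rep(as.vector(t(wl)), each = dA[1] * dA[2]),
                           dim = dA) * (2 * scale / (dA[1] * dA[2] * dA[4]))
        gT <- conv_bwd(adapter, gA)
        key <- tap_keys[n]
        tap_grads[[key]] <- if (is.null(tap_grads[[key]])) gT
                            else tap_grads[[key]] + gT
      }
    }
  }
  list(value = total, pairs = do.call(rbind, rows), tap_grads = tap_grads,
       cache = pair_cache)
}

#' Total matching loss over both sources and all candidate pairs
#'
#' @param state a [new_match_state()]
#' @param source_taps list (per source) of lists of source feature maps, in
#'   tap-stage order
#' @param target_taps named list of target feature maps (as returned in
#'   `net_forward(..., want_taps = TRUE)$taps`)
#' @return list with `value` (the scalar loss) and `pairs` (a data.frame
#'   logging lambda and the unweighted pair loss for every (source, m, n))
#' @export
total_matching_loss <- function(state, source_taps, target_taps) {
  r <- matching_eval(state, source_taps, target_taps)
  list(value = r$value, pairs = r$pairs)
}

#' Total training loss: original task loss plus the weighted matching term
#'
#' @param state a [new_match_state()]
#' @param logits target-network logits for the batch
#' @param labels integer labels (0-based)
#' @param source_taps,target_taps as in [total_matching_loss()]
#' @return a `loss_breakdown` list: `l_org` (cross-entropy), `l_wfm`,
#'   `l_total = l_org + zeta * l_wfm`, and the per-pair log
#' @export
total_loss <- function(state, logits, labels, source_taps, target_taps) {
  ce <- softmax_xent(logits, labels)
  mt <- total_matching_loss(state, source_taps, target_taps)
  structure(list(l_org = ce$loss, l_wfm = mt$value,
                 l_total = ce$loss + state$zeta * mt$value,
                 pairs = mt$pairs),
            class = "loss_breakdown")
}

# gradients of the matching loss w.r.t. the f/g head parameters, computed
# from a pair cache produced by matching_eval (the heads see only the frozen
# source maps, so these are exact at any probed value of theta)
matching_head_grads <- function(state, pair_cache) {
  gf <- list(); gg <- list()
  for (pc in pair_cache) {
    N <- nrow(pc$w)
    # g head: dL/dlam_n = per-sample weighted loss / N, through ReLU6
    per_sample <- rowSums(pc$w * pc$q)
    dlam <- per_sample / N
    act <- as.numeric(pc$zg > 0 & pc$zg < 6)
    dzg <- dlam * act
    gg[[length(gg) + 1L]] <- list(
      k = pc$k, p = pc$p,
      W = matrix(colSums(dzg * pc$gapS), nrow = 1L),
      b = sum(dzg))
    # f head: softmax Jacobian
    dz <- (pc$lam / N) * pc$w * (pc$q - rowSums(pc$w * pc$q))
    gf[[length(gf) + 1L]] <- list(
      k = pc$k, p = pc$p,
      W = t(dz) %*% pc$gapS,
      b = colSums(dz))
  }
  list(f = gf, g = gg)
}

match_adapter_layers <- function(state) {
  c(state$adapters[[1]], state$adapters[[2]])
}

match_head_layers <- function(state) {
  c(state$f_heads[[1]], state$f_heads[[2]],
    state$g_heads[[1]], state$g_heads[[2]])
}

#' Export the layer-pair weight grid
#'
#' Mean lambda per (source, m, n) pair for a given batch, in long format
#' (ready for a heat-map or CSV export).
#'
#' @param state a [new_match_state()]
#' @param source_taps,target_taps as in [total_matching_loss()]
#' @return data.frame with columns source, m, n, lambda
#' @export
lambda_grid <- function(state, source_taps, target_taps) {
  r <- matching_eval(state, source_taps, target_taps)
  r$pairs[, c("source", "m", "n", "lambda")]
}
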