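# Training: source pretraining (plain supervised CNN training, then frozen)
# and the four-stage alternating scheme for the target network.
#
# Per step, on one mini-batch reused across all four stages:
#   stage 1 -- one SGD-momentum step on (theta, upsilon) minimizing
#              L_total = L_org + zeta * L_wfm;
#   stage 2 -- T steps on (theta, upsilon) minimizing L_wfm alone (the target
#              selectively imitates source features);
#   stage 3 -- one step on (theta, upsilon) minimizing L_org;
#   stage 4 -- one Adam step on the matching-head parameters (phi, Phi),
#              driven by how fast stages 2-3 lowered the task loss.
#
# Stage 4 uses a first-order hypergradient: with theta' = theta - eta *
# grad_theta L_wfm(theta; phi, Phi), the gradient of L_org(theta') w.r.t. the
# head parameters is -eta * d/d(head) [ grad_theta L_wfm . grad_theta L_org ],
# and the mixed derivative is approximated by the symmetric finite difference
# of grad_head L_wfm at theta +/- eps v, v = grad_theta L_org. The heads'
# gradients at a probed theta are exact and cheap because their inputs (the
# frozen source maps' pooled vectors) do not depend on theta.

#' Training configuration
#'
#' @param epochs training epochs
#' @param batch_size mini-batch size
#' @param lr learning rate for (theta, upsilon): SGD with momentum
#' @param momentum SGD momentum
#' @param weight_decay weight decay for (theta, upsilon)
#' @param lr_meta Adam learning rate for the matching heads (phi, Phi)
#' @param weight_decay_meta weight decay for the heads
#' @param inner_T number of stage-2 steps per four-stage call (T >= 1)
#' @param zeta matching-loss trade-off; `zeta = 0` disables the matching
#'   machinery entirely (the no-transfer baseline)
#' @param fd_eps finite-difference probe size for the stage-4 hypergradient
#' @param seed RNG seed controlling initialization and batch order
#' @return list of class `train_config`
#' @export
train_config <- function(epochs = 10L, batch_size = 16L, lr = 1e-2,
                         momentum = 0.9, weight_decay = 1e-5,
                         lr_meta = 5e-2, weight_decay_meta = 1e-4,
                         inner_T = 2L, zeta = 0.5, fd_eps = 1e-2,
                         seed = 0L) {
  if (inner_T < 1L) stopf("inner_T must be >= 1")
  if (lr <= 0 || lr_meta <= 0) stopf("learning rates must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 lr_meta = lr_meta, weight_decay_meta = weight_decay_meta,
                 inner_T = as.integer(inner_T), zeta = zeta, fd_eps = fd_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pretrain a source network on a labeled task
#'
#' Plain supervised training with SGD momentum and cross-entropy; the
#' returned network is frozen (its parameters are no longer trainable) and
#' serves as a feature source through its stage taps.
#'
#' @param task a `labeled_image_batch` (e.g. from [gen_task()])
#' @param net_cfg a [net_config()]; source networks are plain conv+BN
#' @param cfg a [train_config()]
#' @return the frozen network; `$history` holds per-epoch loss/accuracy
#' @export
pretrain_source <- function(task, net_cfg = NULL,
                            cfg = train_config(epochs = 30L)) {
  if (is.null(net_cfg))
    net_cfg <- net_config("toy", widths = c(8, 16, 32, 64), dbb = FALSE,
                          n_classes = length(unique(task$labels)))
  net <- with_seed(cfg$seed, build_network(net_cfg))
  layers <- net_trainable_layers(net)
  N <- dim(task$images)[4]
  history <- data.frame()
  with_seed(derive_seed(cfg$seed, 1L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      losses <- c(); accs <- c()
      for (start in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
        xb <- task$images[, , , idx, drop = FALSE]
        yb <- task$labels[idx]
        zero_grads(layers)
        out <- net_forward(net, xb, training = TRUE)
        ce <- softmax_xent(out$logits, yb)
        if (!is.finite(ce$loss))
          stopf("source pretraining diverged (non-finite loss at epoch %d)", ep)
        net_backward(net, ce$grad)
        sgd_momentum_step(layers, cfg$lr, cfg$momentum, cfg$weight_decay)
        losses <- c(losses, ce$loss)
        accs <- c(accs, mean(max.col(ce$prob) - 1L == yb))
      }
      history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                           accuracy = mean(accs)))
    }
  })
  for (e in net_trainable_layers(net)) e$trainable <- FALSE
  net$frozen <- TRUE
  net$history <- history
  net
}

# forward the frozen sources once per batch; returns list (per source) of
# tap maps in stage order
source_taps_for <- function(sources, xb) {
  lapply(sources, function(s) {
    out <- net_forward(s, xb, training = FALSE, want_taps = TRUE)
    unname(out$taps)
  })
}

#' One four-stage training step on a mini-batch
#'
#' @param xb image batch (H, W, C, N)
#' @param yb integer labels (0-based)
#' @param sources list of two frozen source networks
#' @param target the target network (toy backbone, DBB units)
#' @param state a [new_match_state()]
#' @param cfg a [train_config()]
#' @return loss trace: list with `l_total`, `l_wfm` (per stage-2 step),
#'   `l_org`, and the per-pair log of stage 1
#' @export
four_stage_step <- function(xb, yb, sources, target, state, cfg) {
  theta_layers <- net_trainable_layers(target)
  adapter_layers <- match_adapter_layers(state)
  tu_layers <- c(theta_layers, adapter_layers)
  head_layers <- match_head_layers(state)
  src_taps <- source_taps_for(sources, xb)
  transfer_on <- cfg$zeta > 0

  # ---- stage 1: one step on L_total
  zero_grads(tu_layers)
  out <- net_forward(target, xb, training = TRUE, want_taps = TRUE)
  ce <- softmax_xent(out$logits, yb)
  me <- matching_eval(state, src_taps, out$taps, want_grads = transfer_on,
                      scale = state$zeta)
  l_total <- ce$loss + state$zeta * me$value
  if (!is.finite(l_total)) stopf("four-stage training diverged (non-finite loss)")
  net_backward(target, ce$grad, me$tap_grads)
  sgd_momentum_step(tu_layers, cfg$lr, cfg$momentum, cfg$weight_decay)
  n_theta <- 1L
  trace <- list(l_total = l_total, l_org_stage1 = ce$loss,
                l_wfm_stage1 = me$value, pairs = me$pairs, l_wfm = numeric(0))

  # ---- stage 2: T steps on L_wfm alone
  if (transfer_on) {
    for (t in seq_len(cfg$inner_T)) {
      zero_grads(tu_layers)
      out <- net_forward(target, xb, training = TRUE, want_taps = TRUE)
      me2 <- matching_eval(state, src_taps, out$taps, want_grads = TRUE, scale = 1)
      if (!is.finite(me2$value)) stopf("four-stage training diverged in stage 2")
      net_backward(target, NULL, me2$tap_grads)
      sgd_momentum_step(tu_layers, cfg$lr, cfg$momentum, cfg$weight_decay)
      n_theta <- n_theta + 1L
      trace$l_wfm <- c(trace$l_wfm, me2$value)
    }
  }

  # ---- stage 3: one step on L_org
  zero_grads(tu_layers)
  out <- net_forward(target, xb, training = TRUE)
  ce3 <- softmax_xent(out$logits, yb)
  if (!is.finite(ce3$loss)) stopf("four-stage training diverged in stage 3")
  net_backward(target, ce3$grad)
  v <- flatten_grads(theta_layers)           # grad_theta L_org, for stage 4
  sgd_momentum_step(tu_layers, cfg$lr, cfg$momentum, cfg$weight_decay)
  n_theta <- n_theta + 1L
  trace$l_org <- ce3$loss

  # ---- stage 4: one Adam step on the matching heads
  n_meta <- 0L
  if (transfer_on) {
    vnorm <- sqrt(sum(v * v))
    if (vnorm > 0) {
      theta0 <- flatten_params(theta_layers)
      eps <- cfg$fd_eps
      u <- v / vnorm
      set_params_from_vector(theta_layers, theta0 + eps * u)
      outp <- net_forward(target, xb, training = FALSE, want_taps = TRUE)
      gp <- matching_head_grads(state,
        matching_eval(state, src_taps, outp$taps)$cache)
      set_params_from_vector(theta_layers, theta0 - eps * u)
      outm <- net_forward(target, xb, training = FALSE, want_taps = TRUE)
      gm <- matching_head_grads(state,
        matching_eval(state, src_taps, outm$taps)$cache)
      set_params_from_vector(theta_layers, theta0)
      eta_eff <- cfg$inner_T * cfg$lr
      coef <- -eta_eff * vnorm / (2 * eps)
      zero_grads(head_layers)
      for (i in seq_along(gp$f)) {
        fh <- state$f_heads[[gp$f[[i]]$k]][[gp$f[[i]]$p]]
        fh$gr <- list(W = coef * (gp$f[[i]]$W - gm$f[[i]]$W),
                      b = coef * (gp$f[[i]]$b - gm$f[[i]]$b))
        gh <- state$g_heads[[gp$g[[i]]$k]][[gp$g[[i]]$p]]
        gh$gr <- list(W = coef * (gp$g[[i]]$W - gm$g[[i]]$W),
                      b = coef * (gp$g[[i]]$b - gm$g[[i]]$b))
      }
      adam_step(head_layers, cfg$lr_meta, weight_decay = cfg$weight_decay_meta)
      n_meta <- n_meta + 1L
    }
  }
  trace$n_theta_updates <- n_theta
  trace$n_meta_updates <- n_meta
  trace
}

# flatten a cohort's slices into one labeled image batch
cohort_to_batch <- function(cohort) {
  patients <- cohort$patients
  n_img <- sum(vapply(patients, function(p) length(p$slices), 0L))
  d <- dim(patients[[1]]$slices[[1]])
  images <- array(0, dim = c(d[1], d[2], 3L, n_img))
  labels <- integer(n_img)
  i <- 0L
  for (p in patients) {
    for (s in p$slices) {
      i <- i + 1L
      images[, , , i] <- s
      labels[i] <- p$label
    }
  }
  list(images = images, labels = labels)
}

#' Train the target network with dual-source adaptive feature matching
#'
#' Builds the target network and matching state, then iterates the
#' four-stage step over mini-batches of the cohort's slices (each slice
#' labeled with its patient's label).
#'
#' @param cohort a cohort from [gen_patient_cohort()] (or any list with a
#'   `patients` element of `patient_record`s)
#' @param sources list of two frozen source networks
#' @param net_cfg a [net_config()] for the target (DBB units)
#' @param cfg a [train_config()]
#' @return list with `net` (trained target), `state` (matching state),
#'   `history` (per-epoch mean losses), `lambda` (final pair-weight grid)
#' @export
train_target <- function(cohort, sources, net_cfg = NULL,
                         cfg = train_config()) {
  if (is.null(net_cfg)) net_cfg <- net_config("toy")
  target <- with_seed(derive_seed(cfg$seed, 2L), build_network(net_cfg))
  state <- with_seed(derive_seed(cfg$seed, 3L),
                     new_match_state(sources, target, zeta = cfg$zeta))
  batch <- cohort_to_batch(cohort)
  # resize the slice stack once, up front, rather than in every forward pass
  batch$images <- bilinear_resize(batch$images, target$input_size,
                                  target$input_size)
  N <- length(batch$labels)
  history <- data.frame()
  src_frozen_check <- lapply(sources, function(s) flatten_params(net_trainable_layers(s)))
  with_seed(derive_seed(cfg$seed, 4L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      l_tot <- c(); l_org <- c(); l_wfm <- c()
      for (start in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
        xb <- batch$images[, , , idx, drop = FALSE]
        yb <- batch$labels[idx]
        tr <- four_stage_step(xb, yb, sources, target, state, cfg)
        l_tot <- c(l_tot, tr$l_total); l_org <- c(l_org, tr$l_org)
        l_wfm <- c(l_wfm, tr$l_wfm_stage1)
      }
      history <- rbind(history, data.frame(
        epoch = ep, l_total = mean(l_tot), l_org = mean(l_org),
        l_wfm = mean(l_wfm)))
    }
  })
  for (k in seq_along(sources)) {
    now <- flatten_params(net_trainable_layers(sources[[k]]))
    if (!identical(now, src_frozen_check[[k]]))
      stopf("source network %d was modified during target training", k)
  }
  xb0 <- batch$images[, , , seq_len(min(16L, N)), drop = FALSE]
  lam <- lambda_grid(state, source_taps_for(sources, xb0),
                     net_forward(target, xb0, want_taps = TRUE)$taps)
  list(net = target, state = state, history = history, lambda = lam)
}

#' Per-patient class-1 probability from a trained network
#'
#' Runs every slice of each patient through the network and averages the
#' softmax probability of class 1 over slices (evaluation is per patient,
#' matching the per-patient feature extraction).
#'
#' @param net a (target) network
#' @param cohort list with `patients`
#' @return numeric vector of per-patient scores in \[0, 1\]
#' @export
patient_class_scores <- function(net, cohort) {
  vapply(cohort$patients, function(p) {
    b <- array(0, dim = c(dim(p$slices[[1]]), length(p$slices)))
    for (i in seq_along(p$slices)) b[, , , i] <- p$slices[[i]]
    o <- net_forward(net, b)
    mean(softmax_rows(o$logits)[, 2L])
  }, numeric(1))
}
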