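# small helper: a match state over two tiny frozen "source" nets and a tiny
# target, cheap enough to build per test
tiny_match_setup <- function(seed = 21) {
  set.seed(seed)
  s_cfg <- net_config("toy", widths = c(4, 8), input_size = 16, dbb = FALSE)
  t_cfg <- net_config("toy", widths = c(4, 8), input_size = 16, dbb = TRUE)
  s1 <- build_network(s_cfg); s2 <- build_network(s_cfg)
  for (n in list(s1, s2)) for (e in afmtl:::net_trainable_layers(n))
    e$trainable <- FALSE
  tgt <- build_network(t_cfg)
  st <- new_match_state(list(s1, s2), tgt)
  x <- rand_image_batch(16, 16, 3, 3)
  src_taps <- afmtl:::source_taps_for(list(s1, s2), x)
  tgt_taps <- net_forward(tgt, x, want_taps = TRUE)$taps
  list(s1 = s1, s2 = s2, tgt = tgt, st = st, x = x,
       src_taps = src_taps, tgt_taps = tgt_taps)
}

test_that("adapters preserve shape and equal a per-pixel matrix multiply", {
  set.seed(20)
  # identity-initialized adapter with equal channel counts is the identity
  ad_id <- afmtl:::new_pointwise_adapter(4, 4)
  x <- rand_image_batch(5, 6, 4, 2)
  expect_equal(adapt(x, ad_id), x)

  ad <- afmtl:::new_pointwise_adapter(4, 8)
  y <- adapt(x, ad)
  expect_equal(dim(y), c(5, 6, 8, 2))
  # oracle: per-pixel matrix multiply with the 1x1 kernel
  A <- matrix(ad$par$w, nrow = 4, ncol = 8)   # [c_in, c_out]
  ref <- array(0, dim = c(5, 6, 8, 2))
  for (n in 1:2) for (i in 1:5) for (j in 1:6)
    ref[i, j, , n] <- as.vector(t(A) %*% x[i, j, , n])
  expect_lt(max(abs(y - ref)), 1e-6)
})

test_that("channel weights are a softmax over a linear head of pooled maps", {
  set.seed(22)
  f0 <- afmtl:::new_fc(3, 3, zero_init = TRUE)
  m <- rand_image_batch(4, 4, 3, 2)
  w <- channel_weights(m, f0)
  expect_equal(w, matrix(1 / 3, 2, 3))        # zero head: uniform weights

  # two channels with logits (log 3, 0) -> weights (0.75, 0.25)
  f <- afmtl:::new_fc(2, 2, zero_init = TRUE)
  f$par$b <- c(log(3), 0)
  w2 <- channel_weights(rand_image_batch(4, 4, 2, 1), f)
  expect_equal(as.vector(w2), c(0.75, 0.25))

  # simplex invariant over random heads
  for (i in 1:20) {
    fr <- afmtl:::new_fc(5, 5)
    wr <- channel_weights(rand_image_batch(3, 3, 5, 4), fr)
    expect_true(all(wr > 0))
    expect_lt(max(abs(rowSums(wr) - 1)), 1e-6)
  }
})

test_that("pair weights pass through ReLU6", {
  g <- afmtl:::new_fc(2, 1, zero_init = TRUE)
  m <- rand_image_batch(4, 4, 2, 1)
  for (pre in c(-1, 0, 2.5, 6, 7)) {
    g$par$b[] <- pre
    expect_equal(pair_weight(m, g), min(max(pre, 0), 6))
  }
})

test_that("the weighted matching loss follows its closed form", {
  a <- rand_image_batch(4, 4, 2, 3)
  expect_equal(as.numeric(weighted_matching_loss(a, a, c(0.5, 0.5))), 0)

  # single channel 2x2, all pointwise differences 1, w = 1 -> loss 1
  s <- array(0, dim = c(2, 2, 1, 1))
  t2 <- array(1, dim = c(2, 2, 1, 1))
  expect_equal(as.numeric(weighted_matching_loss(s, t2, 1)), 1)
  # doubling the difference quadruples the loss
  expect_equal(as.numeric(weighted_matching_loss(s, 2 * t2, 1)), 4)
  expect_error(weighted_matching_loss(s, array(1, dim = c(3, 3, 1, 1)), 1),
               "equal shapes")
})

test_that("matching loss is invariant to joint channel permutation", {
  set.seed(23)
  s <- rand_image_batch(4, 4, 5, 2)
  a <- rand_image_batch(4, 4, 5, 2)
  w <- matrix(runif(2 * 5), 2, 5); w <- w / rowSums(w)
  base <- as.numeric(weighted_matching_loss(s, a, w))
  perm <- sample(5)
  permuted <- as.numeric(weighted_matching_loss(
    s[, , perm, , drop = FALSE], a[, , perm, , drop = FALSE],
    w[, perm, drop = FALSE]))
  expect_equal(permuted, base)
})

test_that("the total matching loss equals a hand-summed oracle over pairs", {
  ts <- tiny_match_setup()
  r <- total_matching_loss(ts$st, ts$src_taps, ts$tgt_taps)
  # oracle: recompute every pair by hand from exported primitives
  manual <- 0
  for (k in 1:2) {
    prs <- ts$st$pairs[[k]]
    for (p in seq_len(nrow(prs))) {
      m <- prs[p, "m"]; n <- prs[p, "n"]
      S <- ts$src_taps[[k]][[m]]; Tn <- ts$tgt_taps[[n]]
      A <- adapt(Tn, ts$st$adapters[[k]][[p]])
      Sr <- if (all(dim(S)[1:2] == dim(Tn)[1:2])) S
            else bilinear_resize(S, dim(Tn)[1], dim(Tn)[2])
      w <- channel_weights(S, ts$st$f_heads[[k]][[p]])
      lam <- pair_weight(S, ts$st$g_heads[[k]][[p]])
      per <- attr(weighted_matching_loss(Sr, A, w), "per_sample")
      manual <- manual + mean(lam * per)
    }
  }
  expect_equal(r$value, manual, tolerance = 1e-10)
  expect_equal(nrow(r$pairs), 8)            # 2 sources x (2 x 2) stage pairs

  # all lambda = 0 zeroes the loss
  for (k in 1:2) for (g in ts$st$g_heads[[k]]) g$par$b[] <- -1
  expect_equal(total_matching_loss(ts$st, ts$src_taps, ts$tgt_taps)$value, 0)
})

test_that("the total loss composes cross-entropy and the matching term", {
  ts <- tiny_match_setup()
  labels <- c(0L, 1L, 0L)
  out <- net_forward(ts$tgt, ts$x, want_taps = TRUE)
  lb <- total_loss(ts$st, out$logits, labels, ts$src_taps, out$taps)
  expect_equal(lb$l_total, lb$l_org + ts$st$zeta * lb$l_wfm)
  expect_gte(lb$l_wfm, 0)

  ts$st$zeta <- 0
  lb0 <- total_loss(ts$st, out$logits, labels, ts$src_taps, out$taps)
  expect_equal(lb0$l_total, lb0$l_org)

  # identical source and adapted-target maps reduce L_total to L_org exactly
  fake_src <- list(unname(out$taps), unname(out$taps))
  diag_pairs <- cbind(m = 1:2, n = 1:2)     # matched stages, identity adapters
  st_same <- new_match_state(list(ts$tgt, ts$tgt), ts$tgt,
                             pairs = list(diag_pairs, diag_pairs), zeta = 0.5)
  lb_same <- total_loss(st_same, out$logits, labels, fake_src, out$taps)
  expect_equal(lb_same$l_wfm, 0)
  expect_equal(lb_same$l_total, lb_same$l_org)
})

test_that("matching gradients flow into theta and the adapters, not the sources", {
  ts <- tiny_match_setup()
  src_layers <- c(afmtl:::net_trainable_layers(ts$s1),
                  afmtl:::net_trainable_layers(ts$s2))
  src_before <- afmtl:::flatten_params(src_layers)
  tgt_layers <- afmtl:::net_trainable_layers(ts$tgt)
  ad_layers <- afmtl:::match_adapter_layers(ts$st)
  afmtl:::zero_grads(c(tgt_layers, ad_layers))
  out <- net_forward(ts$tgt, ts$x, training = TRUE, want_taps = TRUE)
  me <- afmtl:::matching_eval(ts$st, ts$src_taps, out$taps,
                              want_grads = TRUE, scale = 1)
  net_backward(ts$tgt, NULL, me$tap_grads)
  g_tgt <- afmtl:::flatten_grads(tgt_layers)
  g_ad <- afmtl:::flatten_grads(ad_layers)
  expect_gt(max(abs(g_tgt)), 0)
  expect_gt(max(abs(g_ad)), 0)
  # frozen sources accumulate nothing and are unchanged
  expect_true(all(vapply(src_layers, function(e) is.null(e$gr), logical(1))))
  expect_identical(afmtl:::flatten_params(src_layers), src_before)
})

test_that("lambda stays in [0, 6] and weights stay on the simplex during use", {
  ts <- tiny_match_setup()
  r <- afmtl:::matching_eval(ts$st, ts$src_taps, ts$tgt_taps)
  for (pc in r$cache) {
    expect_true(all(pc$lam >= 0 & pc$lam <= 6))
    expect_lt(max(abs(rowSums(pc$w) - 1)), 1e-6)
    expect_true(all(pc$w > 0))
  }
})
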