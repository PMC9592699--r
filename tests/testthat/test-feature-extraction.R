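reparam_fixture <- function(seed = 30) {
  set.seed(seed)
  net <- build_network(net_config("toy", widths = c(4, 8), input_size = 16))
  for (i in 1:2) net_forward(net, rand_image_batch(16, 16, 3, 4), training = TRUE)
  reparameterize_network(net)
}

mk_patient <- function(slices, id = "P001", label = 1L, S = 32) {
  structure(list(patient_id = id, slices = slices, label = label,
                 features = NULL), class = "patient_record")
}

test_that("patient features average the per-slice pooled kernel outputs", {
  rp <- reparam_fixture()
  set.seed(31)
  s1 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  s2 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  s3 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))

  one <- extract_patient_features(rp, mk_patient(list(s1)))
  expect_length(one, count_feature_channels(rp))

  # two identical slices equal the single-slice vector
  twin <- extract_patient_features(rp, mk_patient(list(s1, s1)))
  expect_equal(twin, one, tolerance = 1e-12)

  # 3-slice patient equals the hand-averaged per-slice vectors
  per_slice <- lapply(list(s1, s2, s3), function(s)
    extract_patient_features(rp, mk_patient(list(s))))
  avg <- Reduce(`+`, per_slice) / 3
  got <- extract_patient_features(rp, mk_patient(list(s1, s2, s3)))
  expect_lt(max(abs(got - avg)), 1e-6)

  # slice order does not matter
  perm <- extract_patient_features(rp, mk_patient(list(s3, s1, s2)))
  expect_equal(perm, got, tolerance = 1e-12)
  expect_error(extract_patient_features(rp, mk_patient(list())), "no slice")
})

test_that("feature count equals the sum of main-path output channels", {
  expect_equal(count_feature_channels(reparam_fixture()), 12)
  expect_equal(count_feature_channels(build_network(net_config("toy"))), 240)
})

test_that("Mann-Whitney U matches exact enumeration and handles ties", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)            # 2 of the 20 assignments are as extreme
  mw_rev <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw_rev$U, 9)
  expect_equal(mw_rev$p, 0.1)

  tied <- mann_whitney_u(rep(1, 8), rep(1, 9))
  expect_equal(tied$U, 8 * 9 / 2)
  expect_equal(tied$p, 1)

  # U equals the brute-force concordant-pair count with half ties
  set.seed(32)
  x <- sample(round(rnorm(30), 1)); y <- sample(round(rnorm(30), 1))
  brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mann_whitney_u(x, y)$U, brute)
  # orientation identity U + U' = n1 n0
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 900)
})

test_that("normal-approximation p-values agree with wilcox.test", {
  set.seed(33)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  mw <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(mw$U, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  # with heavy ties the tie-corrected variance still matches
  xt <- sample(1:4, 25, TRUE); yt <- sample(2:5, 30, TRUE)
  mwt <- mann_whitney_u(xt, yt)
  reft <- suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE,
                                              exact = FALSE))
  expect_equal(mwt$p, reft$p.value, tolerance = 1e-10)
})

test_that("screening selects differentiating features and respects bounds", {
  set.seed(34)
  n <- 40
  labels <- rep(0:1, each = n / 2)
  signal <- matrix(rnorm(n * 3), n, 3) + outer(labels, c(2, 1.5, 2.5))
  noise <- matrix(rnorm(n * 20), n, 20)
  feats <- cbind(signal, noise)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  sr <- mann_whitney_screen(feats, labels)
  expect_s3_class(sr, "screen_result")
  expect_true(all(sr$selected[1:3]))
  expect_lt(sum(sr$selected[-(1:3)]), 5)
  expect_true(all(sr$U >= 0 & sr$U <= (n / 2)^2))
  expect_true(all(sr$p > 0 & sr$p <= 1))
  expect_error(mann_whitney_screen(feats, rep(1, n)), "both classes")
})

test_that("assembled tables join clinical columns by id with level encoding", {
  feats <- matrix(rnorm(12), 4, 3,
                  dimnames = list(paste0("P", 1:4), c("a", "b", "c")))
  screen <- data.frame(feature = c("a", "b", "c"), U = 1, p = c(0.01, 0.2, 0.03),
                       p_adj = c(0.01, 0.2, 0.03),
                       selected = c(TRUE, FALSE, TRUE))
  expect_equal(assemble_feature_table(feats), feats)
  expect_equal(colnames(assemble_feature_table(feats, screen)), c("a", "c"))

  clinical <- data.frame(patient_id = paste0("P", 4:1),   # shuffled order
                         age = c(70, 60, 50, 40),
                         gender = c("m", "f", "m", "f"),
                         stringsAsFactors = FALSE)
  out <- assemble_feature_table(feats, screen, clinical)
  expect_equal(ncol(out), 2 + 1 + 2)        # 2 deep + age + 2 gender levels
  expect_equal(rownames(out), paste0("P", 1:4))
  expect_equal(out[, "age"], c(P1 = 40, P2 = 50, P3 = 60, P4 = 70))
  expect_equal(unname(out[, "gender_m"] + out[, "gender_f"]), rep(1, 4))
  bad <- data.frame(patient_id = c("P1", "P2"), age = c(1, 2))
  expect_error(assemble_feature_table(feats, screen, bad), "missing patients")
})

test_that("scaling is fitted on one cohort and applied to another", {
  set.seed(35)
  a <- matrix(rnorm(40, 5, 2), 10, 4)
  b <- matrix(rnorm(20, 5, 2), 5, 4)
  sc <- fit_scaler(a)
  za <- apply_scaler(a, sc)
  expect_lt(max(abs(colMeans(za))), 1e-12)
  expect_lt(max(abs(apply(za, 2, sd) - 1)), 1e-12)
  zb <- apply_scaler(b, sc)
  expect_equal(zb[1, ], (b[1, ] - sc$center) / sc$scale)
  const <- cbind(a, 7)
  expect_silent(apply_scaler(const, fit_scaler(const)))
})
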