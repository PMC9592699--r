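# Synthetic study data. Real cohorts (CT slice stacks of solitary pulmonary
# nodules, whole-slide-image tiles, natural images) are not deposited with
# the method, so every input of the pipeline is emulated by controllable
# generators: class-conditional oriented band-pass textures plus per-class
# blob counts for the image tasks, per-patient slice stacks with a
# class-dependent nodule texture, slides with blank margins, and sparse
# linear-regression test beds for the ARD classifier.

#' Specification of a synthetic labeled image task
#'
#' @param n_per_class images per class
#' @param n_classes number of classes
#' @param image_size square image side in pixels
#' @param texture_params list with one entry per class, each a list with
#'   `freq` (cycles per image), `theta` (grating orientation, radians) and
#'   `n_blobs` (count of bright Gaussian blobs); defaults give two classes
#'   with orthogonal gratings and 1 vs 3 blobs
#' @param noise_sd pixel-wise Gaussian noise standard deviation
#' @param jitter if `TRUE`, grating phase and blob placement vary per image;
#'   with `jitter = FALSE` and `noise_sd = 0` all images of a class are
#'   identical
#' @param channel_gain length-3 multiplier applied to the RGB channels
#'   (e.g. a purple tint for microscopy-like tiles)
#' @param task_id one of `"source1"`, `"source2"`, `"target"`
#' @param seed RNG seed; identical specs produce bit-identical batches
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_per_class, n_classes = 2L, image_size = 32L,
                           texture_params = NULL, noise_sd = 0.05,
                           jitter = TRUE, channel_gain = c(1, 1, 1),
                           task_id = "source1", seed = 0L) {
  if (n_per_class < 1L || n_classes < 1L || image_size < 4L)
    stopf("invalid synthetic spec: sizes must be positive (image_size >= 4)")
  if (is.null(texture_params))
    texture_params <- lapply(seq_len(n_classes) - 1L, function(cl)
      list(freq = 4 + 2 * cl, theta = pi / 2 * (cl %% 2L), n_blobs = 1L + 2L * cl))
  if (length(texture_params) != n_classes)
    stopf("texture_params must have one entry per class")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 texture_params = texture_params, noise_sd = noise_sd,
                 jitter = jitter, channel_gain = channel_gain,
                 task_id = task_id, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one grayscale texture field for a class on an S x S grid
render_texture <- function(S, tp, jitter) {
  gx <- matrix(seq_len(S), S, S) / S
  gy <- matrix(seq_len(S), S, S, byrow = TRUE) / S
  phase <- if (jitter) runif(1, 0, 2 * pi) else 0
  img <- 0.45 + 0.25 * sin(2 * pi * tp$freq * (cos(tp$theta) * gx +
                                                 sin(tp$theta) * gy) + phase)
  if (tp$n_blobs > 0) {
    sig <- S / 10
    for (b in seq_len(tp$n_blobs)) {
      if (jitter) {
        cx <- runif(1, 0.2, 0.8) * S; cy <- runif(1, 0.2, 0.8) * S
      } else {
        cx <- (0.25 + 0.5 * (b - 1) / max(1, tp$n_blobs - 1)) * S
        cy <- cx
      }
      img <- img + 0.35 * exp(-((gx * S - cx)^2 + (gy * S - cy)^2) / (2 * sig^2))
    }
  }
  img
}

#' Generate a labeled synthetic image task
#'
#' Classes are separable by construction (distinct grating orientation or
#' frequency plus blob count, so both texture-sensitive convolutions and a
#' linear probe on pixel statistics can tell them apart).
#'
#' @param spec a [synthetic_spec()]
#' @return a `labeled_image_batch`: list with `images` ((H, W, 3, N) array of
#'   values in \[0, 1\]), `labels` (integer, 0-based), `task_id`
#' @export
gen_task <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stopf("spec must come from synthetic_spec()")
  with_seed(spec$seed, {
    S <- spec$image_size
    N <- spec$n_per_class * spec$n_classes
    images <- array(0, dim = c(S, S, 3L, N))
    labels <- integer(N)
    i <- 0L
    for (cl in seq_len(spec$n_classes) - 1L) {
      tp <- spec$texture_params[[cl + 1L]]
      for (r in seq_len(spec$n_per_class)) {
        i <- i + 1L
        base <- render_texture(S, tp, spec$jitter)
        if (spec$noise_sd > 0)
          base <- base + matrix(rnorm(S * S, sd = spec$noise_sd), S, S)
        for (ch in 1:3)
          images[, , ch, i] <- pmin(pmax(base * spec$channel_gain[ch], 0), 1)
        labels[i] <- cl
      }
    }
    structure(list(images = images, labels = labels, task_id = spec$task_id),
              class = "labeled_image_batch")
  })
}

#' Built-in task presets for the dual-source transfer problem
#'
#' `"source1"` emulates a natural-texture task (orientation discrimination,
#' the same texture family the target nodules carry, i.e. an informative
#' source); `"source2"` a microscopy-tile task (blob-density discrimination
#' with a purple tint); `"target"` directly as images (mostly used through
#' [gen_patient_cohort()]).
#'
#' @param task one of `"source1"`, `"source2"`, `"target"`
#' @param n_per_class,image_size,seed forwarded to [synthetic_spec()]
#' @return a [synthetic_spec()]
#' @export
task_preset <- function(task = c("source1", "source2", "target"),
                        n_per_class = 24L, image_size = 32L, seed = 0L) {
  task <- match.arg(task)
  switch(task,
    source1 = synthetic_spec(n_per_class, 2L, image_size,
      texture_params = list(list(freq = 6, theta = 0, n_blobs = 1L),
                            list(freq = 6, theta = pi / 2, n_blobs = 3L)),
      noise_sd = 0.05, task_id = "source1", seed = seed),
    source2 = synthetic_spec(n_per_class, 2L, image_size,
      texture_params = list(list(freq = 12, theta = pi / 4, n_blobs = 2L),
                            list(freq = 12, theta = pi / 4, n_blobs = 6L)),
      noise_sd = 0.08, channel_gain = c(0.8, 0.55, 0.9),
      task_id = "source2", seed = seed),
    target = synthetic_spec(n_per_class, 2L, image_size,
      texture_params = list(list(freq = 4, theta = 0, n_blobs = 1L),
                            list(freq = 4, theta = pi / 2, n_blobs = 2L)),
      noise_sd = 0.05, task_id = "target", seed = seed))
}

#' Generate a synthetic patient cohort
#'
#' Each patient carries a uniformly drawn number of 3-channel 224 x 224 slice
#' images (consecutive grayscale slices stacked by [stack_slices()]), a
#' binary label (0 = granuloma-like, 1 = adenocarcinoma-like), and a
#' class-dependent nodule texture injected into every slice. A synthetic
#' clinical table (gender, age, lesion size, shape/lobulation/spiculation
#' signs) with class-correlated distributions accompanies the records.
#'
#' @param n_patients number of patients
#' @param slices_range integer range (lo, hi) of per-patient slice counts,
#'   lo >= 3
#' @param class_balance probability of label 1
#' @param seed RNG seed
#' @param image_size slice side in pixels (default 224)
#' @return list with `patients` (list of `patient_record`: `patient_id`,
#'   `slices` (list of (S, S, 3) arrays), `label`, `features` (NULL until
#'   extraction)) and `clinical` (data.frame keyed by `patient_id`)
#' @export
gen_patient_cohort <- function(n_patients, slices_range = c(3L, 6L),
                               class_balance = 0.5, seed = 0L,
                               image_size = 224L) {
  if (length(slices_range) != 2L || any(!is.finite(slices_range)) ||
      slices_range[1] > slices_range[2])
    stopf("slices_range must be a non-empty (lo, hi) range")
  if (slices_range[1] < 3L) stopf("slices_range minimum must be >= 3")
  with_seed(seed, {
    S <- as.integer(image_size)
    gx <- matrix(seq_len(S), S, S) / S
    gy <- matrix(seq_len(S), S, S, byrow = TRUE) / S
    patients <- vector("list", n_patients)
    clin <- data.frame()
    for (p in seq_len(n_patients)) {
      label <- as.integer(runif(1) < class_balance)
      n_out <- sample(seq.int(slices_range[1], slices_range[2]), 1L)
      n_raw <- n_out + 2L
      cx <- runif(1, 0.35, 0.65); cy <- runif(1, 0.35, 0.65)
      nod_r <- runif(1, 0.12, 0.2)
      theta <- if (label == 1L) pi / 2 else 0
      raw <- vector("list", n_raw)
      for (s in seq_len(n_raw)) {
        bg <- 0.35 + 0.1 * sin(2 * pi * 1.5 * gx + runif(1, 0, 2 * pi)) *
          sin(2 * pi * 1.5 * gy + runif(1, 0, 2 * pi))
        tex <- 0.5 + 0.3 * sin(2 * pi * 4 * (cos(theta) * gx + sin(theta) * gy) +
                                 runif(1, 0, 0.5))
        mask <- ((gx - cx)^2 + (gy - cy)^2) < nod_r^2
        img <- bg
        img[mask] <- tex[mask] + 0.15 * label
        img <- img + matrix(rnorm(S * S, sd = 0.03), S, S)
        raw[[s]] <- pmin(pmax(img, 0), 1)
      }
      slices <- stack_slices(raw)
      patients[[p]] <- structure(
        list(patient_id = sprintf("P%03d", p), slices = slices,
             label = label, features = NULL),
        class = "patient_record")
      clin <- rbind(clin, data.frame(
        patient_id = sprintf("P%03d", p),
        gender = sample(c("male", "female"), 1L,
                        prob = if (label == 1L) c(0.45, 0.55) else c(0.6, 0.4)),
        age = round(rnorm(1, mean = if (label == 1L) 60 else 52, sd = 11), 1),
        lesion_size = round(rnorm(1, mean = if (label == 1L) 18 else 12, sd = 7), 1),
        shape = sample(c("regular", "irregular"), 1L,
                       prob = if (label == 1L) c(0.15, 0.85) else c(0.45, 0.55)),
        lobulation = sample(0:1, 1L, prob = if (label == 1L) c(0.2, 0.8) else c(0.55, 0.45)),
        spiculation = sample(0:1, 1L, prob = if (label == 1L) c(0.45, 0.55) else c(0.65, 0.35)),
        stringsAsFactors = FALSE))
    }
    list(patients = patients, clinical = clin)
  })
}

#' Generate a synthetic whole-slide image with blank regions
#'
#' A tissue-textured slide in which a `blank_fraction` share of the
#' ceil(X/224) x ceil(Y/224) tile grid is near-white (mean intensity above
#' 0.95). Exact when X and Y are multiples of 224; partial edge tiles are
#' zero-padded downstream, which can pull a blank edge tile below the
#' threshold.
#'
#' @param X,Y slide width and height in pixels (>= 224)
#' @param blank_fraction fraction of tiles rendered blank, in \[0, 1\]
#' @param seed RNG seed
#' @return (Y, X, 3) array in \[0, 1\]
#' @export
gen_synthetic_wsi <- function(X, Y, blank_fraction = 0.3, seed = 0L) {
  if (X < 224L || Y < 224L) stopf("slide must be at least 224 x 224")
  if (blank_fraction < 0 || blank_fraction > 1)
    stopf("blank_fraction must lie in [0, 1]")
  with_seed(seed, {
    nx <- ceiling(X / 224); ny <- ceiling(Y / 224)
    K <- nx * ny
    img <- array(0, dim = c(Y, X, 3L))
    base <- 0.55 + 0.15 * matrix(rnorm(Y * X), Y, X)
    base <- pmin(pmax(base, 0), 0.9)
    img[, , 1] <- pmin(base * 1.15, 0.92); img[, , 2] <- base * 0.75
    img[, , 3] <- pmin(base * 1.05, 0.92)
    n_blank <- round(blank_fraction * K)
    blank_tiles <- if (n_blank > 0) sample.int(K, n_blank) else integer(0)
    for (tid in blank_tiles) {
      tr <- (tid - 1L) %/% nx; tc <- (tid - 1L) %% nx
      rows <- (tr * 224L + 1L):min((tr + 1L) * 224L, Y)
      cols <- (tc * 224L + 1L):min((tc + 1L) * 224L, X)
      img[rows, cols, ] <- pmin(0.97 +
        array(abs(rnorm(length(rows) * length(cols) * 3, sd = 0.01)),
              dim = c(length(rows), length(cols), 3L)), 1)
    }
    img
  })
}

#' Generate a sparse linear-regression problem
#'
#' Standard-normal design, exactly `k_relevant` nonzero coefficients (signs
#' random, magnitudes in \[0.5, 1.5\]), Gaussian noise on the targets. A test
#' bed for automatic relevance determination.
#'
#' @param n samples (>= 2)
#' @param D features
#' @param k_relevant number of truly nonzero coefficients (<= D)
#' @param noise_sd target noise standard deviation
#' @param seed RNG seed
#' @return list with `X` (n x D), `y` (length n), `w` (length D true weights)
#' @export
gen_sparse_regression <- function(n, D, k_relevant, noise_sd = 0.1, seed = 0L) {
  if (n < 2L) stopf("need at least 2 samples")
  if (k_relevant > D) stopf("k_relevant must not exceed D")
  with_seed(seed, {
    X <- matrix(rnorm(n * D), n, D)
    w <- numeric(D)
    if (k_relevant > 0) {
      idx <- sample.int(D, k_relevant)
      w[idx] <- sample(c(-1, 1), k_relevant, replace = TRUE) *
        runif(k_relevant, 0.5, 1.5)
    }
    y <- as.vector(X %*% w)
    if (noise_sd > 0) y <- y + rnorm(n, sd = noise_sd)
    list(X = X, y = y, w = w)
  })
}
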