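# Per-patient deep features: every slice image runs through the
# reparameterized target network; each collapsed convolution kernel
# contributes the global mean pooling of its output map; the patient's
# L-vector is the arithmetic mean of the per-slice vectors. Features are then
# screened by a two-sided Mann-Whitney U test at p < 0.05.

#' Extract the L deep features of one patient
#'
#' @param reparam_net a reparameterized target network
#'   ([reparameterize_network()])
#' @param patient a `patient_record` (>= 1 slice)
#' @return numeric vector of length L = [count_feature_channels()]
#' @export
extract_patient_features <- function(reparam_net, patient) {
  if (length(patient$slices) < 1L) stopf("patient has no slice images")
  batch <- array(0, dim = c(dim(patient$slices[[1]]), length(patient$slices)))
  for (i in seq_along(patient$slices)) batch[, , , i] <- patient$slices[[i]]
  feats <- net_deep_features(reparam_net, batch)   # n_slices x L
  colMeans(feats)
}

#' Per-patient feature matrix for a whole cohort
#'
#' @param reparam_net reparameterized target network
#' @param cohort list with `patients`
#' @return list with `features` (patients x L matrix; rownames are patient
#'   ids, colnames encode unit and kernel index), `labels` (integer vector)
#' @export
cohort_features <- function(reparam_net, cohort) {
  patients <- cohort$patients
  feats <- t(vapply(patients,
                    function(p) extract_patient_features(reparam_net, p),
                    numeric(count_feature_channels(reparam_net))))
  rownames(feats) <- vapply(patients, function(p) p$patient_id, "")
  colnames(feats) <- unlist(lapply(seq_along(reparam_net$feature_channels),
    function(u) sprintf("u%d_k%d", u, seq_len(reparam_net$feature_channels[u]))))
  list(features = feats,
       labels = vapply(patients, function(p) p$label, 0L))
}

#' Mann-Whitney U statistic and two-sided p-value for two samples
#'
#' U counts pairs where an `x` observation exceeds a `y` observation, with
#' half credit for ties (so U / (n_x n_y) is the concordance probability and
#' equals the ROC AUC of `x` vs `y`). The two-sided p-value is exact (full
#' enumeration of group assignments) when n_x + n_y <= `exact_max`, and
#' otherwise uses the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction.
#'
#' @param x,y numeric samples (each of length >= 1)
#' @param exact_max largest pooled size for exact enumeration
#' @return list with `U`, `p`
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stopf("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx + ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    devs <- apply(combs, 2L, function(idx) {
      abs(sum(r[idx]) - nx * (nx + 1) / 2 - mu)
    })
    p <- mean(devs >= abs(U - mu) - 1e-9)
  } else {
    n <- nx + ny
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(U = U, p = p)
}

#' Screen features by the Mann-Whitney U test
#'
#' Tests every feature column for a distributional difference between the
#' two classes; features with two-sided p < `alpha` are selected. No
#' multiple-testing correction is applied by default (set
#' `adjust = "BH"` for a Benjamini-Hochberg variant).
#'
#' @param features patients x L numeric matrix
#' @param labels binary labels (0/1), both classes present with n >= 2 each
#' @param alpha selection threshold on the p-value
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame of class `screen_result`: `feature`, `U`, `p`,
#'   `selected`
#' @export
mann_whitney_screen <- function(features, labels, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("screening needs both classes present")
  if (min(table(labels)) < 2L) stopf("each class needs at least 2 patients")
  features <- as.matrix(features)
  res <- t(apply(features, 2L, function(col) {
    mw <- mann_whitney_u(col[labels == 1L], col[labels == 0L])
    c(U = mw$U, p = mw$p)
  }))
  p <- res[, "p"]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = colnames(features), U = res[, "U"],
                    p = res[, "p"], p_adj = p, selected = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Assemble the classifier input table
#'
#' Joins the screened deep features with a clinical/CT-findings table on
#' patient id, expanding character/factor columns into one indicator column
#' per level. Row order follows the feature matrix.
#'
#' @param deep_features patients x L matrix with patient-id rownames
#' @param screen optional `screen_result`; when given, only selected
#'   features are kept
#' @param clinical optional data.frame with a `patient_id` column
#' @param encoding optional named list of factor levels per categorical
#'   column (as returned in the `"encoding"` attribute of a previous call);
#'   pass the training cohort's encoding when assembling a test cohort so
#'   both tables share identical columns even if a level is absent
#' @return numeric matrix, rownames = patient ids; attribute `"encoding"`
#'   carries the level map used
#' @export
assemble_feature_table <- function(deep_features, screen = NULL,
                                   clinical = NULL, encoding = NULL) {
  feats <- as.matrix(deep_features)
  if (!is.null(screen)) feats <- feats[, screen$selected, drop = FALSE]
  if (is.null(clinical)) return(feats)
  if (!"patient_id" %in% names(clinical))
    stopf("clinical table must have a patient_id column")
  idx <- match(rownames(feats), clinical$patient_id)
  if (anyNA(idx)) stopf("clinical table is missing patients: %s",
                        paste(rownames(feats)[is.na(idx)], collapse = ", "))
  clin <- clinical[idx, setdiff(names(clinical), "patient_id"), drop = FALSE]
  cols <- list()
  enc <- list()
  for (nm in names(clin)) {
    v <- clin[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      lvls <- if (!is.null(encoding[[nm]])) encoding[[nm]]
              else sort(unique(as.character(v)))
      enc[[nm]] <- lvls
      for (lv in lvls)
        cols[[paste(nm, lv, sep = "_")]] <- as.numeric(as.character(v) == lv)
    }
  }
  clin_mat <- do.call(cbind, cols)
  rownames(clin_mat) <- rownames(feats)
  structure(cbind(feats, clin_mat), encoding = enc)
}

#' Column z-scoring fitted on a training cohort
#'
#' @param x numeric matrix
#' @return list with `center`, `scale` (zero-variance columns get scale 1)
#' @export
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  sc <- apply(x, 2L, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  list(center = ctr, scale = sc)
}

#' Apply a fitted scaler
#' @param x numeric matrix
#' @param scaler from [fit_scaler()]
#' @return scaled matrix
#' @export
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}
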