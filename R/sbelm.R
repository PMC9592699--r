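# Sparse Bayesian extreme learning machine. The ELM's input->hidden weights
# and biases are drawn once from a standard normal and fixed; only the
# hidden->output weights w are learned, by sparse Bayesian regression with
# an automatic-relevance-determination (ARD) prior: per-weight Gaussian
# precisions alpha_i and noise precision beta, alternating the closed-form
# Gaussian posterior
#     Sigma = (A + beta X'X)^-1,  m = beta Sigma X' t,  A = diag(alpha)
# with the evidence-maximizing re-estimates
#     gamma_i = 1 - alpha_i Sigma_ii,  alpha_i <- gamma_i / m_i^2,
#     1/beta <- ||t - X m||^2 / (N - sum gamma).
# Precisions that reach alpha_max prune their weight to exactly zero.
# Binary classification is handled as regression on {0, 1} labels with a 0.5
# decision threshold. The bagging ensemble trains M base machines on
# bootstrap subsets; their continuous scores form the hidden-layer output of
# one further sparse Bayes ELM acting as the combiner.

#' Sparse Bayes ELM configuration
#'
#' @param width hidden-layer width L_h (ignored when `activation` is
#'   `"identity"`)
#' @param activation `"sigmoid"` (default), `"linear"` (random projection,
#'   no squashing) or `"identity"` (no hidden layer: ARD linear regression
#'   on the raw features, giving pruning a direct feature interpretation)
#' @param alpha0 initial per-weight precision
#' @param beta0 initial noise precision (default 1/var(t))
#' @param alpha_max pruning cap for alpha
#' @param max_iter maximum posterior/hyperparameter alternations
#' @param tol convergence tolerance on the max absolute weight change
#' @param seed seed for the random hidden layer
#' @return list of class `sbelm_config`
#' @export
sbelm_config <- function(width = 100L, activation = c("sigmoid", "linear", "identity"),
                         alpha0 = 1, beta0 = NULL, alpha_max = 1e8,
                         max_iter = 300L, tol = 1e-6, seed = 0L) {
  activation <- match.arg(activation)
  structure(list(width = as.integer(width), activation = activation,
                 alpha0 = alpha0, beta0 = beta0, alpha_max = alpha_max,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "sbelm_config")
}

#' Hidden-layer output of an ELM
#'
#' @param x N x p raw feature matrix
#' @param model fitted `sbelm` model (or a list with `W_in`, `b_in`,
#'   `activation`)
#' @return N x L_h design matrix X
#' @export
hidden_output <- function(x, model) {
  x <- as.matrix(x)
  if (model$activation == "identity") return(x)
  if (ncol(x) != nrow(model$W_in))
    stopf("feature count %d does not match the hidden layer (%d)",
          ncol(x), nrow(model$W_in))
  z <- sweep(x %*% model$W_in, 2L, model$b_in, "+")
  switch(model$activation,
         sigmoid = sigmoid(z),
         linear = z,
         stopf("unknown activation '%s'", model$activation))
}

#' ARD posterior of the output weights
#'
#' @param X N x D design matrix (hidden-layer output)
#' @param t numeric targets
#' @param alpha per-weight precisions (> 0), length D
#' @param beta noise precision (> 0)
#' @return list with `m` (posterior mean), `Sigma` (posterior covariance),
#'   `logdet_Sigma`
#' @export
sbelm_posterior <- function(X, t, alpha, beta) {
  if (any(!is.finite(X)) || any(!is.finite(t)))
    stopf("non-finite design or targets")
  if (any(alpha <= 0) || beta <= 0) stopf("alpha and beta must be positive")
  D <- ncol(X)
  P <- beta * crossprod(X)
  diag(P) <- diag(P) + alpha
  R <- chol(P)                           # P = Sigma^-1, SPD by construction
  Sigma <- chol2inv(R)
  m <- beta * as.vector(Sigma %*% crossprod(X, t))
  list(m = m, Sigma = Sigma, logdet_Sigma = -2 * sum(log(diag(R))))
}

#' Log marginal likelihood (evidence) of the ARD model
#'
#' (sum_i log alpha_i + N log beta + log|Sigma| - beta ||t - X m||^2
#'  - m' A m - N log 2 pi) / 2, evaluated at the posterior mode.
#'
#' @param X,t,alpha,beta as in [sbelm_posterior()]
#' @param post optional posterior from [sbelm_posterior()] (recomputed if
#'   missing)
#' @return scalar log evidence
#' @export
sbelm_log_evidence <- function(X, t, alpha, beta, post = NULL) {
  if (is.null(post)) post <- sbelm_posterior(X, t, alpha, beta)
  N <- nrow(X)
  resid <- t - as.vector(X %*% post$m)
  0.5 * (sum(log(alpha)) + N * log(beta) + post$logdet_Sigma -
           beta * sum(resid^2) - sum(alpha * post$m^2) - N * log(2 * pi))
}

#' Evidence-maximizing hyperparameter re-estimates
#'
#' @param m,Sigma posterior from [sbelm_posterior()]
#' @param X,t design and targets
#' @param alpha current precisions (for the well-determinedness gamma)
#' @param alpha_max pruning cap; weights with `m_i = 0` go straight to it
#' @param beta_max numerical cap on the noise precision
#' @return list with `alpha`, `beta`, `gamma`
#' @export
update_hyperparams <- function(m, Sigma, X, t, alpha, alpha_max = 1e8,
                               beta_max = 1e12) {
  gam <- 1 - alpha * diag(Sigma)
  alpha_new <- ifelse(m == 0, alpha_max, gam / (m * m))
  alpha_new[!is.finite(alpha_new) | alpha_new <= 0] <- alpha_max
  alpha_new <- pmin(alpha_new, alpha_max)
  denom <- nrow(X) - sum(gam)
  if (denom <= 0)
    stopf("degenerate noise update: N - sum(gamma) = %g <= 0", denom)
  resid <- t - as.vector(X %*% m)
  beta_new <- min(denom / sum(resid^2), beta_max)
  list(alpha = alpha_new, beta = beta_new, gamma = gam)
}

#' Fit a sparse Bayesian extreme learning machine
#'
#' @param x N x p raw features (N >= 2)
#' @param t binary labels in 0/1 (or continuous regression targets)
#' @param config a [sbelm_config()]
#' @return object of class `sbelm`: the fixed hidden layer, the ARD
#'   posterior (`m`, `Sigma`, `alpha`, `beta`), `w_hat` (posterior mean with
#'   pruned weights set to exactly zero), `pruned` flags, and `trace`
#'   (per-iteration log evidence and convergence flag)
#' @export
fit_sbelm <- function(x, t, config = sbelm_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 samples")
  if (length(t) != nrow(x)) stopf("targets do not match the rows of x")
  model <- list(activation = config$activation)
  if (config$activation != "identity") {
    with_seed(config$seed, {
      model$W_in <- matrix(rnorm(ncol(x) * config$width), ncol(x), config$width)
      model$b_in <- rnorm(config$width)
    })
  }
  X <- hidden_output(x, model)
  D <- ncol(X); N <- nrow(X)
  alpha <- rep(config$alpha0, D)
  beta <- if (is.null(config$beta0)) {
    vt <- stats::var(t); if (!is.finite(vt) || vt <= 0) 1 else 1 / vt
  } else config$beta0
  evid <- numeric(0)
  converged <- FALSE
  m_old <- rep(0, D)
  post <- NULL
  for (it in seq_len(config$max_iter)) {
    post <- sbelm_posterior(X, t, alpha, beta)
    evid <- c(evid, sbelm_log_evidence(X, t, alpha, beta, post))
    if (max(abs(post$m - m_old)) < config$tol) { converged <- TRUE; break }
    m_old <- post$m
    up <- update_hyperparams(post$m, post$Sigma, X, t, alpha,
                             alpha_max = config$alpha_max)
    alpha <- up$alpha; beta <- up$beta
  }
  pruned <- alpha >= config$alpha_max
  w_hat <- post$m
  w_hat[pruned] <- 0
  structure(c(model,
              list(w_hat = w_hat, m = post$m, Sigma = post$Sigma,
                   alpha = alpha, beta = beta, pruned = pruned,
                   trace = list(log_evidence = evid, converged = converged),
                   config = config)),
            class = "sbelm")
}

#' Predict with a fitted sparse Bayes ELM
#'
#' @param model a fitted `sbelm`
#' @param x N x p raw features
#' @param type `"score"` (hidden output times the posterior-mean weights) or
#'   `"class"` (score thresholded at 0.5)
#' @return numeric scores or integer classes
#' @export
predict_sbelm <- function(model, x, type = c("score", "class")) {
  type <- match.arg(type)
  if (is.null(model$w_hat)) stopf("model is not fitted")
  s <- as.vector(hidden_output(x, model) %*% model$w_hat)
  if (type == "class") as.integer(s >= 0.5) else s
}

#' Fit a bagging ensemble of sparse Bayes ELMs
#'
#' M bootstrap subsets (size `bag_fraction * N`, drawn with replacement;
#' subsets with only one class are redrawn up to 10 times) each train a base
#' machine; the N x M matrix of base scores on the full training set is the
#' hidden-layer output of the combiner, itself fitted by sparse Bayes.
#'
#' @param x N x p raw features
#' @param t binary 0/1 labels
#' @param M number of base classifiers
#' @param bag_fraction bootstrap subset size as a fraction of N
#' @param config a [sbelm_config()] for the base machines
#' @param seed master seed (per-base seeds are derived from it)
#' @return object of class `sbelm_ensemble`
#' @export
fit_ensemble <- function(x, t, M = 10L, bag_fraction = 1,
                         config = sbelm_config(), seed = 0L) {
  if (M < 1L) stopf("M must be >= 1")
  x <- as.matrix(x)
  N <- nrow(x)
  n_bag <- max(2L, round(bag_fraction * N))
  bases <- vector("list", M)
  bags <- vector("list", M)
  for (j in seq_len(M)) {
    idx <- NULL
    with_seed(derive_seed(seed, 10L + j), {
      for (try in 1:10) {
        cand <- sample.int(N, n_bag, replace = TRUE)
        if (length(unique(t[cand])) > 1L || length(unique(t)) == 1L) {
          idx <- cand; break
        }
      }
    })
    if (is.null(idx)) stopf("could not draw a two-class bootstrap subset")
    cfg_j <- config
    cfg_j$seed <- derive_seed(seed, 100L + j)
    bases[[j]] <- fit_sbelm(x[idx, , drop = FALSE], t[idx], cfg_j)
    bags[[j]] <- idx
  }
  base_scores <- vapply(bases, function(b) predict_sbelm(b, x), numeric(N))
  comb_cfg <- sbelm_config(activation = "identity",
                           alpha0 = config$alpha0, alpha_max = config$alpha_max,
                           max_iter = config$max_iter, tol = config$tol,
                           seed = derive_seed(seed, 999L))
  combiner <- fit_sbelm(base_scores, t, comb_cfg)
  structure(list(bases = bases, bags = bags, combiner = combiner,
                 M = M, bag_fraction = bag_fraction, seed = seed),
            class = "sbelm_ensemble")
}

#' Predict with a sparse Bayes ELM ensemble
#'
#' @param ensemble from [fit_ensemble()]
#' @param x N x p raw features
#' @param type `"score"` or `"class"`
#' @return numeric scores or integer classes
#' @export
predict_ensemble <- function(ensemble, x, type = c("score", "class")) {
  type <- match.arg(type)
  if (is.null(ensemble$combiner)) stopf("ensemble is not fitted")
  base_scores <- vapply(ensemble$bases, function(b) predict_sbelm(b, x),
                        numeric(nrow(as.matrix(x))))
  if (is.null(dim(base_scores)))
    base_scores <- matrix(base_scores, nrow = 1L)
  predict_sbelm(ensemble$combiner, base_scores, type = type)
}
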