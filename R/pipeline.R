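# End-to-end desk-scale pipeline: synthesize the two source tasks and the
# patient cohorts, pretrain and freeze the sources, train the DBB target
# network under adaptive dual-source feature matching, collapse it, extract
# and screen per-patient features, fit the sparse-Bayes ELM ensemble, and
# evaluate on held-out patients.

#' Pipeline configuration
#'
#' Defaults are the desk-scale study conditions: 32 x 32 source tasks with
#' 24 images per class, cohorts of 224 x 224 slice stacks, a four-stage
#' toy DBB target (240 reparameterized kernels), and a 10-machine ensemble.
#'
#' @param seed master seed; every stage derives its own stream from it
#' @param source_n_per_class images per class for each source task
#' @param source_image_size source image side
#' @param source_epochs source pretraining epochs
#' @param n_train,n_test patients in the training and test cohorts
#' @param slices_range per-patient slice-count range
#' @param cohort_image_size slice side in pixels
#' @param target_cfg [net_config()] for the target network
#' @param train_cfg [train_config()] for target training
#' @param M,elm_width ensemble size and base hidden width
#' @param screen_alpha screening threshold
#' @param threshold decision threshold on combiner scores
#' @param n_boot bootstrap replicates for AUC intervals
#' @param include_clinical append the synthetic clinical/CT-findings columns
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 0L, source_n_per_class = 24L,
                            source_image_size = 32L, source_epochs = 12L,
                            n_train = 14L, n_test = 20L,
                            slices_range = c(3L, 5L),
                            cohort_image_size = 224L,
                            target_cfg = net_config("toy"),
                            train_cfg = train_config(epochs = 5L, seed = seed),
                            M = 10L, elm_width = 100L,
                            screen_alpha = 0.05, threshold = 0.5,
                            n_boot = 500L, include_clinical = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# short polynomial fingerprint of the serialized configuration
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()]
#' @param out_dir directory for artifacts (created if missing); `NULL`
#'   skips writing
#' @param verbose log progress to stderr
#' @return list with `metrics` (train/test evaluation), `screen`, `lambda`,
#'   `history`, `L`, `n_selected`, and the trained objects
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("[1/8] generating source tasks")
  task1 <- gen_task(task_preset("source1", config$source_n_per_class,
                                config$source_image_size,
                                seed = derive_seed(seed, 11L)))
  task2 <- gen_task(task_preset("source2", config$source_n_per_class,
                                config$source_image_size,
                                seed = derive_seed(seed, 12L)))

  say("[2/8] pretraining the two source networks")
  scfg <- train_config(epochs = config$source_epochs,
                       seed = derive_seed(seed, 21L))
  src1 <- pretrain_source(task1, cfg = scfg)
  scfg2 <- train_config(epochs = config$source_epochs,
                        seed = derive_seed(seed, 22L))
  src2 <- pretrain_source(task2, cfg = scfg2)

  say("[3/8] generating patient cohorts")
  train_cohort <- gen_patient_cohort(config$n_train, config$slices_range,
                                     seed = derive_seed(seed, 31L),
                                     image_size = config$cohort_image_size)
  test_cohort <- gen_patient_cohort(config$n_test, config$slices_range,
                                    seed = derive_seed(seed, 32L),
                                    image_size = config$cohort_image_size)

  say("[4/8] training the target network (four-stage feature matching)")
  tcfg <- config$train_cfg
  tcfg$seed <- derive_seed(seed, 41L)
  fit <- train_target(train_cohort, list(src1, src2), config$target_cfg, tcfg)

  say("[5/8] reparameterizing and extracting per-patient features")
  rp <- reparameterize_network(fit$net)
  L <- count_feature_channels(rp)
  tr_feat <- cohort_features(rp, train_cohort)
  te_feat <- cohort_features(rp, test_cohort)

  say("[6/8] screening %d deep features (Mann-Whitney, training cohort only)", L)
  screen <- mann_whitney_screen(tr_feat$features, tr_feat$labels,
                                alpha = config$screen_alpha)
  n_sel <- sum(screen$selected)
  say("      %d features selected", n_sel)
  if (n_sel == 0L) screen$selected[which.min(screen$p)] <- TRUE

  clin_tr <- if (config$include_clinical) train_cohort$clinical else NULL
  clin_te <- if (config$include_clinical) test_cohort$clinical else NULL
  xtr <- assemble_feature_table(tr_feat$features, screen, clin_tr)
  xte <- assemble_feature_table(te_feat$features, screen, clin_te,
                                encoding = attr(xtr, "encoding"))
  scaler <- fit_scaler(xtr)
  xtr <- apply_scaler(xtr, scaler)
  xte <- apply_scaler(xte, scaler)

  say("[7/8] fitting the sparse-Bayes ELM bagging ensemble (M = %d)", config$M)
  ens <- fit_ensemble(xtr, tr_feat$labels, M = config$M,
                      config = sbelm_config(width = config$elm_width),
                      seed = derive_seed(seed, 71L))
  s_tr <- predict_ensemble(ens, xtr)
  s_te <- predict_ensemble(ens, xte)

  say("[8/8] evaluating")
  metrics <- list(
    train = evaluate_scores(s_tr, tr_feat$labels, config$threshold,
                            n_boot = config$n_boot,
                            seed = derive_seed(seed, 81L)),
    test = evaluate_scores(s_te, te_feat$labels, config$threshold,
                           n_boot = config$n_boot,
                           seed = derive_seed(seed, 82L)))

  result <- list(metrics = metrics, screen = screen, lambda = fit$lambda,
                 history = fit$history, L = L, n_selected = n_sel,
                 target = fit$net, reparam = rp, ensemble = ens,
                 scores = list(train = s_tr, test = s_te),
                 labels = list(train = tr_feat$labels, test = te_feat$labels))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_yaml <- yaml::as.yaml(config[!vapply(config, is.environment, TRUE)])
    writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
    write.csv(fit$history, file.path(out_dir, "target_history.csv"),
              row.names = FALSE)
    write.csv(fit$lambda, file.path(out_dir, "lambda_grid.csv"),
              row.names = FALSE)
    write.csv(screen, file.path(out_dir, "screen.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = rownames(xtr), label = tr_feat$labels,
                         score = s_tr),
              file.path(out_dir, "scores_train.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = rownames(xte), label = te_feat$labels,
                         score = s_te),
              file.path(out_dir, "scores_test.csv"), row.names = FALSE)
    write.csv(roc_curve(s_te, te_feat$labels),
              file.path(out_dir, "roc_test.csv"), row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash(cfg_yaml),
           kernel_count = L, n_selected = n_sel,
           r_version = as.character(getRversion())),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  result
}

#' Numerical check of the diverse-branch-block collapse
#'
#' Builds random blocks over a grid of channel counts, kernel sizes K in
#' {1, 3, 5} and strides {1, 2}, with randomized batch-norm statistics, and
#' reports the maximum absolute deviation between the multi-branch forward
#' (inference mode) and the collapsed single convolution on random inputs.
#'
#' @param n_blocks number of random configurations
#' @param seed RNG seed
#' @param input_size spatial size of the random test inputs
#' @return max absolute deviation over all configurations; attribute
#'   `"per_block"` carries the per-configuration deviations
#' @export
dbb_equivalence_check <- function(n_blocks = 50L, seed = 0L, input_size = 11L) {
  devs <- with_seed(seed, vapply(seq_len(n_blocks), function(i) {
    C <- sample(1:16, 1L); D <- sample(1:16, 1L)
    K <- sample(c(1L, 3L, 5L), 1L)
    stride <- sample(1:2, 1L)
    blk <- new_dbb_block(C, D, K, stride)
    randomize_bn_stats(blk)
    x <- array(rnorm(input_size^2 * C * 2L), dim = c(input_size, input_size, C, 2L))
    y_train <- dbb_forward(blk, x, training = FALSE)
    y_rep <- reparam_forward(reparameterize(blk), x)
    max(abs(y_train - y_rep))
  }, numeric(1)))
  structure(max(devs), per_block = devs)
}
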