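#' Metaheuristic tuning of the two pipeline tiers
#'
#' These orchestrators reproduce the study protocol at configurable scale:
#' tune the L1 CNN by maximizing the multiclass MCC on an internal validation
#' split, freeze the best feature extractor, then tune the L2 booster over
#' its embeddings, and report both tiers on a shared held-out test partition
#' that no training or tuning stage has seen.
#'
#' @name pipeline
NULL

# The objective memoizes the fitted model of the best genotype seen so far,
# so the tuner's winner does not need a redundant retraining afterwards.
l1_objective <- function(inner_tr, inner_val, protocol) {
  store <- new.env(parent = emptyenv())
  store$best_mcc <- -Inf
  obj <- function(genotype) {
    cnn_seed <- sample.int(.Machine$integer.max, 1L)
    fit <- train_eval_cnn(build_cnn(genotype, protocol), inner_tr, inner_val,
                          seed = cnn_seed)
    if (fit$report$mcc > store$best_mcc) {
      store$best_mcc <- fit$report$mcc
      store$best_model <- fit$model
    }
    fit$report$mcc
  }
  attr(obj, "store") <- store
  obj
}

l2_objective <- function(emb_tr, emb_val, kind, protocol) {
  function(genotype) {
    seed <- sample.int(.Machine$integer.max, 1L)
    b <- fit_booster(build_booster(kind, genotype, protocol), emb_tr, seed = seed)
    booster_report(b, emb_val, protocol$n_classes)$mcc
  }
}

#' Tune the L1 CNN on an image dataset
#'
#' Splits the training images 80/20 (stratified); each fitness evaluation
#' trains a candidate CNN on the 80% and scores MCC on the 20%. The best
#' genotype is then retrained once with a fixed derived seed to produce the
#' returned feature extractor.
#'
#' @param train_img Training-partition `image_dataset`.
#' @param config An [optimizer_config()].
#' @param algorithm `"qsavns"` (default) or `"vns"`.
#' @param protocol A [train_protocol()].
#' @return List: `result` (optimization_result), `cnn` (fitted best model),
#'   `fitness` (validation MCC of the best genotype).
#' @export
optimize_l1 <- function(train_img, config, algorithm = c("qsavns", "vns"),
                        protocol = train_protocol()) {
  algorithm <- match.arg(algorithm)
  set.seed(config$seed)
  inner <- stratified_split_idx(train_img$y, 1 - protocol$val_fraction)
  inner_tr <- subset_images(train_img, inner)
  inner_val <- subset_images(train_img, setdiff(seq_along(train_img$y), inner))
  obj <- l1_objective(inner_tr, inner_val, protocol)
  runner <- if (algorithm == "qsavns") run_qsavns else run_vns
  res <- runner(builtin_space("L1_CNN"), obj, config)
  store <- attr(obj, "store")
  list(result = res, cnn = store$best_model, fitness = res$best$fitness)
}

#' Tune an L2 booster on embeddings
#'
#' Splits the training embeddings 80/20 (stratified); fitness is the MCC of a
#' candidate booster trained on the 80% and scored on the 20%. The best
#' genotype is refit on the full training embeddings.
#'
#' @param emb_train Training-partition `embedding_set`.
#' @param kind `"xgb"` or `"lgbm"`.
#' @param config An [optimizer_config()].
#' @param algorithm `"qsavns"` or `"vns"`.
#' @param protocol A [train_protocol()].
#' @return List: `result`, `booster` (fitted), `fitness`.
#' @export
optimize_l2 <- function(emb_train, kind, config,
                        algorithm = c("qsavns", "vns"),
                        protocol = train_protocol()) {
  algorithm <- match.arg(algorithm)
  set.seed(config$seed)
  inner <- stratified_split_idx(emb_train$labels, 1 - protocol$val_fraction)
  emb_tr <- subset_embeddings(emb_train, inner)
  emb_val <- subset_embeddings(emb_train,
                               setdiff(seq_along(emb_train$labels), inner))
  obj <- l2_objective(emb_tr, emb_val, kind, protocol)
  runner <- if (algorithm == "qsavns") run_qsavns else run_vns
  space <- builtin_space(if (kind == "xgb") "L2_XGB" else "L2_LGBM")
  res <- runner(space, obj, config)
  refit_seed <- config$seed * 1000L + 2L
  booster <- fit_booster(build_booster(kind, res$best$genotype, protocol),
                         emb_train, seed = refit_seed)
  list(result = res, booster = booster, fitness = res$best$fitness)
}

#' Run the full tuned dual-layer experiment on one dataset
#'
#' One complete protocol instance: stratified 70/30 image split; L1 tuning on
#' the training partition ([optimize_l1()]); L1 test report from the tuned
#' CNN; embedding of all images; L2 tuning on the training embeddings
#' ([optimize_l2()]); L2 test report. Deterministic given `seed`.
#'
#' @param data An `image_dataset`.
#' @param l1_config,l2_config [optimizer_config()]s for the two tiers (the
#'   study protocol used N = 8, T = 5 for L1 and N = 10, T = 10 for L2); the
#'   `seed` fields are overridden by `seed`.
#' @param booster_kind `"xgb"` or `"lgbm"`.
#' @param algorithm `"qsavns"` or `"vns"`.
#' @param protocol A [train_protocol()].
#' @param seed Experiment seed.
#' @return List with `l1_report`, `l2_report` (test-partition reports),
#'   `l1_mcc`, `l2_mcc`, `l1`, `l2` (tuning outputs), `embeddings` (all
#'   samples through the tuned truncated CNN), and split indices.
#' @export
run_dual_layer_experiment <- function(data,
                                      l1_config = optimizer_config(8, 5),
                                      l2_config = optimizer_config(10, 10),
                                      booster_kind = "lgbm",
                                      algorithm = "qsavns",
                                      protocol = train_protocol(),
                                      seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  tr_idx <- stratified_split_idx(data$y, 0.7)
  te_idx <- setdiff(seq_along(data$y), tr_idx)
  train_img <- subset_images(data, tr_idx)
  test_img <- subset_images(data, te_idx)

  l1_config$seed <- seed
  l1 <- optimize_l1(train_img, l1_config, algorithm, protocol)
  l1_pred <- predict_cnn(l1$cnn, test_img)
  l1_report <- classification_report(test_img$y, max.col(l1_pred) - 1L,
                                     labels = 0:(protocol$n_classes - 1L))

  emb_all <- truncate_and_embed(l1$cnn, data)
  emb_train <- subset_embeddings(emb_all, tr_idx)
  emb_test <- subset_embeddings(emb_all, te_idx)

  l2_config$seed <- seed + 1L
  l2 <- optimize_l2(emb_train, booster_kind, l2_config, algorithm, protocol)
  l2_report <- booster_report(l2$booster, emb_test, protocol$n_classes)

  list(l1_report = l1_report, l2_report = l2_report,
       l1_mcc = l1_report$mcc, l2_mcc = l2_report$mcc,
       l1 = l1, l2 = l2, embeddings = emb_all,
       train_idx = tr_idx, test_idx = te_idx)
}
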