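#' The two-tier classification pipeline
#'
#' Layer 1 (L1) is a lightweight CNN trained end-to-end on 32 x 32 RGB images;
#' its output layer is then discarded and the activations at the dropout layer
#' (inference mode, so the dropout is inactive and the embedding equals the
#' last dense layer's rectified output) become per-sample feature embeddings.
#' Layer 2 (L2) is a gradient-boosted tree classifier trained on those
#' embeddings. Hyperparameters of both tiers are genotypes over the built-in
#' search spaces and are tuned by the optimizer module with the multiclass
#' MCC as fitness.
#'
#' @name dual_layer
NULL

#' Training protocol constants
#'
#' @param batch_size Minibatch size (default 512).
#' @param image_size Input side in pixels (32).
#' @param n_classes Number of classes (4).
#' @param channels Color channels (3).
#' @param booster_nrounds Boosting rounds for the XGBoost kind, which has no
#'   round count in its search space (default 100, the reference library
#'   default); the leaf-wise kind takes its rounds from the genotype.
#' @param val_fraction Fraction of the training partition held out as the
#'   internal validation split used for early stopping and L1 fitness
#'   (default 0.2).
#' @return A `train_protocol` list. Early-stopping patience is derived per
#'   model as `floor(epochs / 3)` of its genotype.
#' @export
train_protocol <- function(batch_size = 512L, image_size = 32L,
                           n_classes = 4L, channels = 3L,
                           booster_nrounds = 100L, val_fraction = 0.2) {
  structure(list(batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels),
                 booster_nrounds = as.integer(booster_nrounds),
                 val_fraction = val_fraction),
            class = "train_protocol")
}

#' Decode an L1 genotype into CNN hyperparameters
#'
#' Widths of absent layers (layer count 1) are present in the genotype but
#' ignored here, keeping the genotype length fixed for the optimizer.
#'
#' @param genotype Named genotype over `builtin_space("L1_CNN")`.
#' @param protocol A [train_protocol()].
#' @return List of decoded hyperparameters as consumed by the CNN engine.
#' @export
decode_cnn_genotype <- function(genotype, protocol = train_protocol()) {
  validate_genotype(genotype, builtin_space("L1_CNN"))
  n_conv <- as.integer(genotype[["n_conv_layers"]])
  n_dense <- as.integer(genotype[["n_dense_layers"]])
  conv_w <- as.integer(c(genotype[["conv1_width"]], genotype[["conv2_width"]]))[seq_len(n_conv)]
  dense_w <- as.integer(c(genotype[["dense1_width"]], genotype[["dense2_width"]]))[seq_len(n_dense)]
  epochs <- as.integer(genotype[["epochs"]])
  list(n_conv = n_conv, n_dense = n_dense,
       conv_widths = conv_w, dense_widths = dense_w,
       dropout = genotype[["dropout"]],
       learning_rate = genotype[["learning_rate"]],
       epochs = epochs,
       batch_size = protocol$batch_size,
       patience = max(1L, epochs %/% 3L),
       n_classes = protocol$n_classes,
       image_size = protocol$image_size,
       channels = protocol$channels)
}

#' Build an (untrained) CNN classifier from a genotype
#'
#' Architecture: `n_conv_layers` blocks of 3x3 same-padded convolution
#' (widths `conv*_width`) + ReLU + 2x2 max-pool, flatten, `n_dense_layers`
#' dense+ReLU layers (widths `dense*_width`), dropout, 4-way softmax. Trained
#' with Adam at the genotype learning rate under one-hot cross-entropy.
#'
#' @param genotype L1 genotype (named vector or list coercible to it).
#' @param protocol A [train_protocol()].
#' @return A `stage_cnn` model object (unfitted).
#' @export
build_cnn <- function(genotype, protocol = train_protocol()) {
  hp <- decode_cnn_genotype(genotype, protocol)
  structure(list(hp = hp, genotype = genotype, weights = NULL, fitted = FALSE,
                 protocol = protocol),
            class = "stage_cnn")
}

#' @export
print.stage_cnn <- function(x, ...) {
  cat(sprintf("stage_cnn: %d conv (%s) + %d dense (%s), dropout %.3f, lr %.4g, epochs %d [%s]\n",
              x$hp$n_conv, paste(x$hp$conv_widths, collapse = ","),
              x$hp$n_dense, paste(x$hp$dense_widths, collapse = ","),
              x$hp$dropout, x$hp$learning_rate, x$hp$epochs,
              if (x$fitted) "fitted" else "unfitted"))
  invisible(x)
}

#' Number of trainable parameters of a CNN model
#' @param model A `stage_cnn`.
#' @return Integer parameter count.
#' @export
cnn_n_params <- function(model) {
  hp <- model$hp
  cin <- hp$channels; n <- 0
  for (w in hp$conv_widths) { n <- n + (9 * cin + 1) * w; cin <- w }
  side <- hp$image_size / 2^hp$n_conv
  din <- side * side * cin
  for (w in hp$dense_widths) { n <- n + (din + 1) * w; din <- w }
  n + (din + 1) * hp$n_classes
}

#' Train a CNN and evaluate it
#'
#' Trains for at most `epochs` epochs with validation-loss early stopping at
#' patience `floor(epochs / 3)` (best weights restored), then reports on the
#' evaluation set. The report's `mcc` is the L1 fitness value used by the
#' optimizer.
#'
#' @param model A `stage_cnn` from [build_cnn()].
#' @param train,eval `image_dataset`s (non-empty). `eval` doubles as the
#'   early-stopping validation set.
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout.
#' @return `list(model = fitted stage_cnn, report = classification_report)`.
#' @export
train_eval_cnn <- function(model, train, eval, seed = 1L) {
  stopifnot(inherits(model, "stage_cnn"))
  if (nrow(train$x) == 0 || nrow(eval$x) == 0)
    stop("train_eval_cnn: empty split")
  fit <- cnn_train_cpp(train$x, as.integer(train$y), eval$x,
                       as.integer(eval$y), model$hp, as.integer(seed))
  model$weights <- fit$weights
  model$fitted <- TRUE
  model$train_loss <- fit$train_loss
  model$val_loss <- fit$val_loss
  model$epochs_run <- fit$epochs_run
  pred <- cnn_forward_cpp(model$weights, model$hp, eval$x)
  y_hat <- max.col(pred$probs) - 1L
  report <- classification_report(eval$y, y_hat,
                                  labels = 0:(model$hp$n_classes - 1L))
  list(model = model, report = report)
}

#' Predict class probabilities with a fitted CNN
#' @param model Fitted `stage_cnn`.
#' @param data An `image_dataset`.
#' @return Numeric matrix n x K of softmax probabilities.
#' @export
predict_cnn <- function(model, data) {
  if (!isTRUE(model$fitted)) stop("predict_cnn: model is not fitted")
  cnn_forward_cpp(model$weights, model$hp, data$x)$probs
}

#' Truncate a fitted CNN and extract embeddings
#'
#' Runs the forward pass up to and including the dropout layer in inference
#' mode (dropout inactive), so the embedding width equals the last dense
#' width.
#'
#' @param model Fitted `stage_cnn`.
#' @param data An `image_dataset`.
#' @return An `embedding_set` with provenance recording the genotype.
#' @export
truncate_and_embed <- function(model, data) {
  if (!isTRUE(model$fitted)) stop("truncate_and_embed: model is not fitted")
  out <- cnn_forward_cpp(model$weights, model$hp, data$x)
  embedding_set(out$embedding, data$y,
                provenance = list(genotype = model$genotype))
}

stratified_split_idx <- function(labels, fraction) {
  first <- integer(0)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    n1 <- round(fraction * length(idx))
    first <- c(first, sample(idx, n1))
  }
  sort(first)
}

#' Stratified 70/30 split of an embedding set
#'
#' Per-class sizes round to nearest; the two parts are disjoint and
#' exhaustive.
#'
#' @param embeddings An `embedding_set` with at least 10 samples per class.
#' @param seed Split seed.
#' @param fraction Training fraction (default 0.7).
#' @return `list(train, test)` of `embedding_set`s.
#' @export
split_70_30 <- function(embeddings, seed = 1L, fraction = 0.7) {
  counts <- table(embeddings$labels)
  if (any(counts < 10)) stop("split_70_30: every class needs >= 10 samples")
  set.seed(seed)
  tr <- stratified_split_idx(embeddings$labels, fraction)
  list(train = subset_embeddings(embeddings, tr),
       test = subset_embeddings(embeddings, setdiff(seq_along(embeddings$labels), tr)))
}

#' Build a boosted-tree classifier from an L2 genotype
#'
#' Both kinds are gradient-boosted multiclass (softmax) tree ensembles fit
#' through xgboost. `kind = "xgb"` uses depth-wise growth with the 6 genotype
#' hyperparameters (learning rate, minimum child weight, subsample, column
#' sample per tree, max depth, gamma) and the protocol's round count.
#' `kind = "lgbm"` uses leaf-wise (lossguide) growth in the LightGBM style;
#' its 10 genotype hyperparameters map to number of rounds, max depth, max
#' leaves, minimum child weight, per-tree feature fraction, bagging fraction,
#' minimum split gain, L1 and L2 penalties, and learning rate. Everything
#' else stays at library defaults.
#'
#' @param kind `"xgb"` or `"lgbm"`.
#' @param genotype Genotype over the matching builtin space.
#' @param protocol A [train_protocol()].
#' @return A `stage_booster` (unfitted).
#' @export
build_booster <- function(kind = c("xgb", "lgbm"), genotype,
                          protocol = train_protocol()) {
  kind <- match.arg(kind)
  space <- builtin_space(if (kind == "xgb") "L2_XGB" else "L2_LGBM")
  ok <- tryCatch({ validate_genotype(genotype, space); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    stop("build_booster: genotype does not match the '", kind, "' space")
  if (kind == "xgb") {
    params <- list(objective = "multi:softprob",
                   num_class = protocol$n_classes,
                   eta = genotype[["learning_rate"]],
                   min_child_weight = genotype[["min_child_weight"]],
                   subsample = genotype[["subsample"]],
                   colsample_bytree = genotype[["colsample_bytree"]],
                   max_depth = as.integer(genotype[["max_depth"]]),
                   gamma = genotype[["gamma"]],
                   nthread = 1)
    nrounds <- protocol$booster_nrounds
  } else {
    params <- list(objective = "multi:softprob",
                   num_class = protocol$n_classes,
                   tree_method = "hist",
                   grow_policy = "lossguide",
                   max_depth = as.integer(genotype[["max_depth"]]),
                   max_leaves = as.integer(genotype[["n_leaves"]]),
                   min_child_weight = genotype[["min_child_weight"]],
                   colsample_bytree = genotype[["feature_fraction"]],
                   subsample = genotype[["bagging_fraction"]],
                   gamma = genotype[["min_split_gain"]],
                   alpha = genotype[["lambda_l1"]],
                   lambda = genotype[["lambda_l2"]],
                   eta = genotype[["learning_rate"]],
                   nthread = 1)
    nrounds <- as.integer(genotype[["n_rounds"]])
  }
  structure(list(kind = kind, params = params, nrounds = nrounds,
                 genotype = genotype, fit = NULL),
            class = "stage_booster")
}

#' Fit a booster on an embedding set
#' @param booster A `stage_booster`.
#' @param train An `embedding_set`.
#' @param seed Seed pinned onto the boosting randomness.
#' @return The fitted `stage_booster`.
#' @export
fit_booster <- function(booster, train, seed = 1L) {
  stopifnot(inherits(booster, "stage_booster"))
  dtrain <- xgboost::xgb.DMatrix(train$features, label = train$labels)
  params <- c(booster$params, list(seed = as.integer(seed)))
  booster$fit <- xgboost::xgb.train(params = params, data = dtrain,
                                    nrounds = booster$nrounds, verbose = 0)
  booster
}

#' Predict class probabilities with a fitted booster
#' @param booster Fitted `stage_booster`.
#' @param embeddings An `embedding_set`.
#' @return Numeric matrix n x K of class probabilities.
#' @export
predict_booster <- function(booster, embeddings) {
  if (is.null(booster$fit)) stop("predict_booster: booster is not fitted")
  p <- predict(booster$fit, xgboost::xgb.DMatrix(embeddings$features))
  if (is.null(dim(p)))
    p <- matrix(p, ncol = booster$params$num_class, byrow = TRUE)
  p
}

booster_report <- function(booster, embeddings, n_classes = 4L) {
  p <- predict_booster(booster, embeddings)
  classification_report(embeddings$labels, max.col(p) - 1L,
                        labels = 0:(n_classes - 1L))
}

#' Fit the full dual-layer pipeline
#'
#' Protocol: stratified 70/30 train/test split of the images; the CNN trains
#' on the training partition (with an internal stratified 80/20 validation
#' split for early stopping) and is reported on the test partition (L1
#' report); all samples are embedded through the truncated CNN; the booster
#' trains on the training-partition embeddings and is reported on the
#' test-partition embeddings (L2 report). Both tiers therefore share one test
#' set that no training stage has seen.
#'
#' @param data An `image_dataset`.
#' @param cnn_genotype L1 genotype.
#' @param booster_kind `"xgb"` or `"lgbm"`.
#' @param booster_genotype Matching L2 genotype.
#' @param protocol A [train_protocol()].
#' @param seed Pipeline seed (drives the splits, CNN training and booster).
#' @return List with `l1_report`, `l2_report`, `embeddings` (all samples),
#'   `cnn`, `booster`, and the split indices.
#' @export
fit_dual_layer <- function(data, cnn_genotype, booster_kind, booster_genotype,
                           protocol = train_protocol(), seed = 1L) {
  set.seed(seed)
  tr_idx <- stratified_split_idx(data$y, 0.7)
  te_idx <- setdiff(seq_along(data$y), tr_idx)
  train_img <- subset_images(data, tr_idx)
  test_img <- subset_images(data, te_idx)

  inner <- stratified_split_idx(train_img$y, 1 - protocol$val_fraction)
  inner_tr <- subset_images(train_img, inner)
  inner_val <- subset_images(train_img, setdiff(seq_along(train_img$y), inner))

  cnn_seed <- sample.int(.Machine$integer.max, 1L)
  cnn <- build_cnn(cnn_genotype, protocol)
  fit <- train_eval_cnn(cnn, inner_tr, inner_val, seed = cnn_seed)
  cnn <- fit$model

  l1_pred <- predict_cnn(cnn, test_img)
  l1_report <- classification_report(test_img$y, max.col(l1_pred) - 1L,
                                     labels = 0:(protocol$n_classes - 1L))

  emb_all <- truncate_and_embed(cnn, data)
  emb_train <- subset_embeddings(emb_all, tr_idx)
  emb_test <- subset_embeddings(emb_all, te_idx)

  booster <- build_booster(booster_kind, booster_genotype, protocol)
  booster <- fit_booster(booster, emb_train, seed = seed)
  l2_report <- booster_report(booster, emb_test, protocol$n_classes)

  list(l1_report = l1_report, l2_report = l2_report, embeddings = emb_all,
       cnn = cnn, booster = booster,
       train_idx = tr_idx, test_idx = te_idx)
}
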