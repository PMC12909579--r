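test_that("genotype decoding activates exactly the encoded layers", {
  g <- c(learning_rate = 0.0001, dropout = 0.05, epochs = 10,
         n_conv_layers = 1, n_dense_layers = 1,
         conv1_width = 32, conv2_width = 77, dense1_width = 32,
         dense2_width = 88)
  hp <- decode_cnn_genotype(g)
  expect_equal(hp$n_conv, 1L)
  expect_equal(hp$conv_widths, 32L)       # inactive conv2 width ignored
  expect_equal(hp$dense_widths, 32L)
  expect_equal(hp$patience, 3L)
  expect_equal(hp$batch_size, 512L)

  g2 <- g; g2["n_conv_layers"] <- 2; g2["n_dense_layers"] <- 2
  hp2 <- decode_cnn_genotype(g2)
  expect_equal(hp2$conv_widths, c(32L, 77L))
  expect_equal(hp2$dense_widths, c(32L, 88L))

  bad <- g; bad["dropout"] <- 0.5
  expect_error(build_cnn(bad), "bounds")
  expect_gt(cnn_n_params(build_cnn(g)), 0)
})

test_that("training is seed-deterministic and the truncated model emits embeddings", {
  ds <- tiny_image_set(25L, separability = 2, seed = 13)
  set.seed(1)
  tr <- sort(unlist(lapply(0:3, function(k) sample(which(ds$y == k), 18))))
  train <- subset_images(ds, tr)
  eval <- subset_images(ds, setdiff(seq_along(ds$y), tr))
  g <- small_cnn_genotype(epochs = 10)
  g["dense1_width"] <- 40

  f1 <- train_eval_cnn(build_cnn(g), train, eval, seed = 77)
  f2 <- train_eval_cnn(build_cnn(g), train, eval, seed = 77)
  expect_identical(f1$report$confusion, f2$report$confusion)
  expect_identical(f1$model$weights$outW, f2$model$weights$outW)

  emb <- truncate_and_embed(f1$model, ds)
  expect_equal(ncol(emb$features), 40)     # width = last dense width
  expect_equal(nrow(emb$features), nrow(ds$x))
  emb2 <- truncate_and_embed(f1$model, ds)
  expect_identical(emb$features, emb2$features)
  expect_error(truncate_and_embed(build_cnn(g), ds), "not fitted")
  expect_error(train_eval_cnn(build_cnn(g), subset_images(ds, integer(0)),
                              eval, seed = 1), "empty")
})

test_that("shuffled labels yield chance-level evaluation", {
  ds <- tiny_image_set(30L, separability = 2, seed = 19)
  set.seed(5)
  ds$y <- sample(ds$y)                     # destroy the image-label link
  tr <- sort(unlist(lapply(0:3, function(k) sample(which(ds$y == k), 22))))
  fit <- train_eval_cnn(build_cnn(small_cnn_genotype(epochs = 10)),
                        subset_images(ds, tr),
                        subset_images(ds, setdiff(seq_along(ds$y), tr)),
                        seed = 3)
  expect_lt(abs(fit$report$mcc), 0.3)
})

test_that("a capable network learns high-separability images", {
  mccs <- vapply(1:3, function(s) {
    ds <- generate_images(synthetic_image_spec(rep(200L, 4), separability = 3,
                                               seed = 300 + s))
    set.seed(s)
    tr <- sort(unlist(lapply(0:3, function(k) sample(which(ds$y == k), 160))))
    fit <- train_eval_cnn(build_cnn(capable_cnn_genotype(epochs = 15)),
                          subset_images(ds, tr),
                          subset_images(ds, setdiff(seq_along(ds$y), tr)),
                          seed = s)
    fit$report$mcc
  }, numeric(1))
  expect_gte(median(mccs), 0.8)
})

test_that("the stratified 70/30 split is exact, disjoint and conserving", {
  es <- generate_tabular(c(384L, 336L, 300L, 300L), 5, 1, seed = 4)
  sp <- split_70_30(es, seed = 9)
  expect_equal(nrow(sp$train$features), 924)
  expect_equal(nrow(sp$test$features), 396)
  for (k in 0:3) {
    n_tr <- sum(sp$train$labels == k)
    n_all <- sum(es$labels == k)
    expect_lte(abs(n_tr - 0.7 * n_all), 1)
  }
  # union = input, intersection = empty (feature rows partition exactly)
  joined <- rbind(sp$train$features, sp$test$features)
  expect_equal(dim(joined), dim(es$features))
  expect_equal(sort(joined[, 1]), sort(es$features[, 1]))
  tiny <- embedding_set(matrix(rnorm(24), 12), rep(0:3, 3))
  expect_error(split_70_30(tiny), ">= 10")
})

test_that("booster construction maps genotypes onto the learner exactly", {
  xgb_hi <- c(learning_rate = 0.9, min_child_weight = 5, subsample = 1,
              colsample_bytree = 1, max_depth = 5, gamma = 0.8)
  b <- build_booster("xgb", xgb_hi)
  expect_equal(b$params$max_depth, 5L)
  expect_equal(b$params$eta, 0.9)
  expect_equal(b$params$gamma, 0.8)
  expect_equal(b$nrounds, 100L)           # protocol default round count

  lgbm_lo <- c(n_rounds = 5, max_depth = 3, n_leaves = 3, min_child_weight = 1,
               feature_fraction = 0.1, bagging_fraction = 0.5,
               min_split_gain = 0.001, lambda_l1 = 0, lambda_l2 = 0,
               learning_rate = 0.01)
  bl <- build_booster("lgbm", lgbm_lo)
  expect_equal(bl$nrounds, 5L)
  expect_equal(bl$params$grow_policy, "lossguide")
  expect_equal(bl$params$max_leaves, 3L)

  es <- generate_tabular(rep(30L, 4), 6, 3, seed = 2)
  fit <- fit_booster(bl, es, seed = 1)
  expect_equal(xgboost::xgb.get.num.boosted.rounds(fit$fit), 5L)
  p <- predict_booster(fit, es)
  expect_equal(dim(p), c(120L, 4L))
  expect_equal(rowSums(p), rep(1, 120), tolerance = 1e-5)

  expect_error(build_booster("xgb", lgbm_lo), "does not match")
  expect_error(build_booster("gbm", xgb_hi), "arg")
})

test_that("the full dual-layer pipeline runs, reports both tiers and embeds all samples", {
  ds <- tiny_image_set(25L, separability = 3, seed = 23)
  lgbm_geno <- c(n_rounds = 20, max_depth = 6, n_leaves = 8,
                 min_child_weight = 1, feature_fraction = 0.9,
                 bagging_fraction = 1, min_split_gain = 0.001,
                 lambda_l1 = 0, lambda_l2 = 0, learning_rate = 0.3)
  out <- fit_dual_layer(ds, small_cnn_genotype(epochs = 10), "lgbm", lgbm_geno,
                        seed = 4)
  expect_s3_class(out$l1_report, "classification_report")
  expect_s3_class(out$l2_report, "classification_report")
  expect_equal(nrow(out$embeddings$features), 100)
  expect_equal(length(out$test_idx) + length(out$train_idx), 100)
  # the separable task is learnable through the chain
  expect_gt(out$l2_report$mcc, 0.3)
})
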