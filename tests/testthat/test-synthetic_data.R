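test_that("image generation matches the requested counts and is seed-reproducible", {
  spec <- synthetic_image_spec(n_per_class = c(20L, 18L, 15L, 15L),
                               separability = 2, seed = 42)
  ds1 <- generate_images(spec)
  ds2 <- generate_images(spec)
  expect_equal(nrow(ds1$x), 68)
  expect_equal(unname(table(ds1$y)), c(20L, 18L, 15L, 15L),
               ignore_attr = TRUE)
  expect_identical(ds1$x, ds2$x)
  expect_true(all(ds1$x >= 0 & ds1$x <= 1))
  # grayscale replicated onto 3 channels
  expect_equal(ds1$x[1, 1:1024], ds1$x[1, 1025:2048])
})

test_that("PNG export round-trips through the directory-per-class loader", {
  dir <- tempfile("imgset")
  on.exit(unlink(dir, recursive = TRUE))
  ds <- generate_images(synthetic_image_spec(n_per_class = c(4L, 3L, 2L, 2L),
                                             seed = 9), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(file.path(dir, "class_0")), 4)
  back <- load_image_dir(dir)
  expect_equal(sort(back$y), sort(ds$y))
  # 8-bit quantization bounds the reload error
  expect_lt(max(abs(back$x[order(back$y), ] - ds$x[order(ds$y), ])), 1 / 255)
})

test_that("separability 0 collapses the class-conditional distributions", {
  ds <- generate_images(synthetic_image_spec(n_per_class = rep(40L, 4),
                                             separability = 0, seed = 5))
  # per-class mean images agree up to noise (no systematic class signal)
  mu <- vapply(0:3, function(k) colMeans(ds$x[ds$y == k, 1:1024]),
               numeric(1024))
  expect_lt(max(abs(mu[, 1] - mu[, 4])), 0.2)   # pixel noise + jitter only
  # a boosted tree cannot beat chance in expectation
  es <- generate_tabular(rep(120L, 4), 10, separability = 0, seed = 2)
  sp <- split_70_30(es, seed = 3)
  b <- fit_booster(build_booster("xgb", c(learning_rate = 0.3,
                                          min_child_weight = 1, subsample = 1,
                                          colsample_bytree = 1, max_depth = 3,
                                          gamma = 0),
                                 train_protocol(booster_nrounds = 30L)),
                   sp$train, seed = 1)
  p <- predict_booster(b, sp$test)
  mcc <- classification_report(sp$test$labels, max.col(p) - 1L, 0:3)$mcc
  expect_lt(abs(mcc), 0.15)
})

test_that("tabular clusters are learnable at high separability", {
  es <- generate_tabular(rep(100L, 4), 8, separability = 4, seed = 11)
  sp <- split_70_30(es, seed = 1)
  b <- fit_booster(build_booster("xgb", c(learning_rate = 0.3,
                                          min_child_weight = 1, subsample = 1,
                                          colsample_bytree = 1, max_depth = 3,
                                          gamma = 0),
                                 train_protocol(booster_nrounds = 50L)),
                   sp$train, seed = 1)
  p <- predict_booster(b, sp$test)
  mcc <- classification_report(sp$test$labels, max.col(p) - 1L, 0:3)$mcc
  expect_gte(mcc, 0.9)
  # determinism
  es2 <- generate_tabular(rep(100L, 4), 8, separability = 4, seed = 11)
  expect_identical(es$features, es2$features)
})

test_that("expected classifier quality is monotone in separability", {
  proto <- train_protocol(booster_nrounds = 30L)
  geno <- c(learning_rate = 0.3, min_child_weight = 1, subsample = 1,
            colsample_bytree = 1, max_depth = 3, gamma = 0)
  mean_mcc <- function(sep) {
    mean(vapply(1:10, function(s) {
      es <- generate_tabular(rep(60L, 4), 8, separability = sep, seed = 100 + s)
      sp <- split_70_30(es, seed = s)
      b <- fit_booster(build_booster("xgb", geno, proto), sp$train, seed = s)
      p <- predict_booster(b, sp$test)
      classification_report(sp$test$labels, max.col(p) - 1L, 0:3)$mcc
    }, numeric(1)))
  }
  m <- vapply(c(0, 1, 3), mean_mcc, numeric(1))
  expect_true(all(diff(m) >= 0))
  # image pathway shows the same direction at the extremes
  img_mcc <- function(sep, s) {
    ds <- generate_images(synthetic_image_spec(rep(50L, 4), separability = sep,
                                               seed = 200 + s))
    idx <- seq_along(ds$y)
    set.seed(s); tr <- sort(unlist(lapply(0:3, function(k)
      sample(which(ds$y == k), 35))))
    dtr <- xgboost::xgb.DMatrix(ds$x[tr, 1:1024], label = ds$y[tr])
    fit <- xgboost::xgb.train(list(objective = "multi:softmax", num_class = 4,
                                   max_depth = 3, nthread = 1), dtr, nrounds = 20)
    te <- setdiff(idx, tr)
    pred <- predict(fit, xgboost::xgb.DMatrix(ds$x[te, 1:1024]))
    classification_report(ds$y[te], pred, 0:3)$mcc
  }
  lo <- mean(vapply(1:3, function(s) img_mcc(0, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) img_mcc(3, s), numeric(1)))
  expect_lt(abs(lo), 0.2)
  expect_gt(hi, lo + 0.3)
})

test_that("benchmark objectives expose their optima and count evaluations", {
  f <- benchmark_objective("sphere", 3)
  expect_equal(f(c(0, 0, 0)), 0)
  expect_equal(f(c(1, 2, 3)), -14)
  expect_equal(evaluation_count(f), 2L)
  g <- benchmark_objective("rastrigin", 4)
  expect_equal(g(rep(0, 4)), 0)
  h <- benchmark_objective("rosenbrock", 2)
  expect_equal(h(c(1, 1)), 0)
  expect_error(benchmark_objective("ackley", 2), "arg")
  expect_error(benchmark_objective("rosenbrock", 1), "dim")
})
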