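test_that("confusion matrices count label pairs correctly", {
  expect_equal(unname(confusion_matrix(c(0, 1), c(0, 1), 0:1)),
               matrix(c(1L, 0L, 0L, 1L), 2, byrow = TRUE))
  expect_equal(unname(confusion_matrix(c(0, 0, 1), c(1, 0, 1), 0:1)),
               matrix(c(1L, 1L, 0L, 1L), 2, byrow = TRUE))
  expect_equal(sum(confusion_matrix(integer(0), integer(0), 0:1)), 0L)
  expect_error(confusion_matrix(0:1, 0:2), "length")
  expect_error(confusion_matrix(c(0, 2), c(0, 0), labels = 0:1), "label")
})

test_that("the F1 identity holds on printed per-class values", {
  tbl <- reported_tables()
  for (model in c("cnn_qsavns", "cnn_xgb_qsavns", "cnn_lgbm_qsavns")) {
    p <- reported_row(tbl, model, "precision")
    r <- reported_row(tbl, model, "recall")
    f1 <- reported_row(tbl, model, "f1")
    got <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    expect_equal(got, f1, tolerance = 5e-6)
  }
})

test_that("per-class metrics follow the one-vs-rest definitions and conventions", {
  cm <- matrix(c(5L, 2L, 1L,
                 0L, 3L, 1L,
                 2L, 0L, 6L), 3, byrow = TRUE,
               dimnames = list(0:2, 0:2))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision[1], 5 / 7)
  expect_equal(pc$recall[1], 5 / 8)
  expect_equal(pc$support, c(8, 4, 8))
  # empty predicted class: precision convention 0
  cm0 <- matrix(c(0L, 2L, 0L, 3L), 2, byrow = TRUE, dimnames = list(0:1, 0:1))
  expect_equal(per_class_metrics(cm0)$precision[1], 0)
  expect_equal(per_class_metrics(cm0)$recall[1], 0)
})

test_that("accuracy, error rate and their identities hold", {
  cm <- diag(c(346L, 273L, 266L, 297L))
  cm[1, 2] <- 138L                       # arbitrary off-diagonal mass
  ae <- accuracy_error(cm)
  expect_equal(ae$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(ae$accuracy + ae$error_rate, 1)
  expect_equal(accuracy_error(diag(4L) * 5L)$accuracy, 1)
  expect_equal(accuracy_error(matrix(c(0L, 3L, 2L, 0L), 2))$accuracy, 0)
  expect_error(accuracy_error(matrix(0L, 2, 2)), "empty")
})

test_that("binary MCC matches its closed form and conventions", {
  expect_equal(mcc_binary(1, 1, 0, 0), 1)
  expect_equal(mcc_binary(0, 0, 1, 1), -1)
  expect_equal(mcc_binary(5, 5, 5, 5), 0)
  expect_equal(mcc_binary(0, 5, 0, 0), 0)  # zero factor convention
})

test_that("multiclass MCC reduces to binary MCC on 2x2 matrices (exhaustive)", {
  for (tp in 0:6) for (fn in 0:6) for (fp in 0:6) for (tn in 0:6) {
    if (tp + fn + fp + tn == 0) next
    cm <- matrix(c(tp, fn, fp, tn), 2, byrow = TRUE,
                 dimnames = list(0:1, 0:1))
    expect_equal(mcc_multiclass(cm), mcc_binary(tp, tn, fp, fn),
                 tolerance = 1e-12)
  }
})

test_that("multiclass MCC degenerates and saturates correctly", {
  # perfect diagonal on arbitrary supports
  expect_equal(mcc_multiclass(diag(c(384L, 336L, 300L, 300L))), 1)
  # prediction independent of truth: identical rows give exactly 0
  cm <- matrix(rep(c(10L, 5L, 3L, 2L), 4), 4, byrow = TRUE,
               dimnames = list(0:3, 0:3))
  expect_equal(mcc_multiclass(cm), 0)
})

test_that("macro and weighted aggregation reproduce printed summary values", {
  tbl <- reported_tables()
  sup <- reported_row(tbl, "supports", "support")
  for (model in c("cnn_xgb_qsavns", "cnn_lgbm_qsavns")) {
    for (metric in c("precision", "recall", "f1")) {
      row <- tbl[tbl$model == model & tbl$metric == metric, ]
      v <- reported_row(tbl, model, metric)
      agg <- aggregate_metrics(v, sup)
      expect_equal(agg$macro, row$macro_avg, tolerance = 5e-6)
      expect_equal(agg$weighted, row$weighted_avg, tolerance = 5e-6)
    }
  }
  expect_equal(aggregate_metrics(rep(0.7, 4), c(1, 2, 3, 4)),
               list(macro = 0.7, weighted = 0.7))
})

test_that("marginal reconstruction recovers diagonals and column totals", {
  tbl <- reported_tables()
  sup <- reported_row(tbl, "supports", "support")
  m7 <- reconstruct_marginals(reported_row(tbl, "cnn_lgbm_qsavns", "precision"),
                              reported_row(tbl, "cnn_lgbm_qsavns", "recall"), sup)
  expect_equal(m7$diagonal, c(346, 273, 266, 297))
  expect_equal(m7$columns, c(394, 310, 302, 314))
  expect_equal(sum(m7$columns), 1320)

  m5 <- reconstruct_marginals(reported_row(tbl, "cnn_xgb_qsavns", "precision"),
                              reported_row(tbl, "cnn_xgb_qsavns", "recall"), sup)
  expect_equal(m5$diagonal, c(341, 254, 249, 290))
  expect_equal(m5$columns, c(404, 298, 302, 316))

  # perfect classifier round trip
  mp <- reconstruct_marginals(rep(1, 4), rep(1, 4), sup)
  expect_equal(mp$diagonal, sup)
  expect_equal(mp$columns, sup)
})

test_that("reconstruction round-trips any integer confusion matrix", {
  set.seed(21)
  for (i in 1:40) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 20) + diag(K) * 30, K,
                 dimnames = list(seq_len(K) - 1, seq_len(K) - 1))
    storage.mode(cm) <- "integer"
    pc <- per_class_metrics(cm)
    m <- reconstruct_marginals(pc$precision, pc$recall, pc$support)
    expect_equal(m$diagonal, unname(diag(cm)))
    expect_equal(m$columns, unname(colSums(cm)))
    expect_equal(mcc_from_marginals(m), mcc_multiclass(cm), tolerance = 1e-12)
  }
})

test_that("classification reports satisfy their internal identities", {
  set.seed(31)
  for (i in 1:30) {
    n <- 200
    y <- sample(0:3, n, TRUE)
    p <- ifelse(runif(n) < 0.6, y, sample(0:3, n, TRUE))
    rep <- classification_report(y, p, labels = 0:3)
    expect_equal(rep$accuracy + rep$error_rate, 1)
    expect_equal(unname(rep$weighted_avg["recall"]), rep$accuracy,
                 tolerance = 1e-12)
    expect_true(rep$mcc >= -1 && rep$mcc <= 1)
    expect_true(all(rep$per_class$f1 <= pmax(rep$per_class$precision,
                                             rep$per_class$recall) + 1e-12))
  }
  # perfect and constant predictions
  y <- rep(0:3, c(38, 33, 30, 30))
  perfect <- classification_report(y, y, 0:3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  const <- classification_report(y, rep(0L, length(y)), 0:3)
  expect_equal(unname(const$weighted_avg["recall"]), 38 / 131)
  expect_equal(const$mcc, 0)              # zero-denominator convention
})

test_that("reports serialize to JSON with the table layout", {
  y <- rep(0:3, each = 25)
  p <- c(y[1:80], rep(0L, 20))
  rep <- classification_report(y, p, 0:3)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_report(rep, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$mcc, rep$mcc)
  expect_equal(back$per_class$precision, rep$per_class$precision)
})
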