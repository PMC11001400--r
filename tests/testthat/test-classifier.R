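test_that("every classifier kind separates the toy descriptor sets", {
  toy <- toy_descriptor_set(40, seed = 42)
  hold <- c(1:8, 41:48)                     # stratified held-out block
  for (kind in c("mlp", "svm", "rf", "nb")) {
    spec <- classifier_spec(kind, seed = 5)
    m <- train_classifier(toy$features[-hold, ], toy$labels[-hold], spec)
    pred <- predict(m, toy$features[hold, ])
    expect_identical(as.character(pred), toy$labels[hold],
                     info = paste("kind:", kind))
  }
})

test_that("the zero vector classifies as miss on the toy model", {
  toy <- toy_descriptor_set(30, seed = 1)
  m <- train_classifier(toy$features, toy$labels, classifier_spec("mlp"))
  expect_identical(as.character(predict(m, matrix(0, 1, 8))), "miss")
  # training points reproduce training labels on separable data
  expect_identical(as.character(predict(m, toy$features)), toy$labels)
})

test_that("training is reproducible and validates its inputs", {
  toy <- toy_descriptor_set(25, seed = 9)
  set.seed(77); probe <- matrix(rpois(80, 4), 10, 8)
  for (kind in c("mlp", "rf")) {
    m1 <- train_classifier(toy$features, toy$labels,
                           classifier_spec(kind, seed = 123))
    m2 <- train_classifier(toy$features, toy$labels,
                           classifier_spec(kind, seed = 123))
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
  expect_error(train_classifier(toy$features, rep("hit", 50),
                                classifier_spec("svm")), "single class")
  expect_error(train_classifier(toy$features, toy$labels[-1],
                                classifier_spec("nb")), "mismatch")
  m <- train_classifier(toy$features, toy$labels, classifier_spec("nb"))
  expect_error(predict(m, matrix(0, 2, 5)), "width")
})

test_that("confusion counts match a hand tally", {
  y_true <- c("h", "h", "h", "h", "m", "m", "m", "m", "m", "m")
  y_pred <- c("h", "h", "h", "m", "h", "m", "m", "m", "m", "m")
  cc <- confusion(y_true, y_pred, positive = "h")
  expect_identical(cc$TP, 3L); expect_identical(cc$FN, 1L)
  expect_identical(cc$FP, 1L); expect_identical(cc$TN, 5L)

  perfect <- confusion(rep("hit", 4), rep("hit", 4))
  expect_identical(perfect$FP + perfect$FN, 0L)
  empty <- confusion(character(0), character(0))
  expect_identical(unlist(empty[c("TP", "TN", "FP", "FN")]),
                   c(TP = 0L, TN = 0L, FP = 0L, FN = 0L))
  expect_error(confusion(c("h", "m"), "h"), "length")
})

test_that("metric formulas and conventions are exact", {
  m <- classification_metrics(list(TP = 3, FN = 1, FP = 1, TN = 5))
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 75)
  expect_equal(m$f1, 75)
  expect_equal(m$accuracy, 80)

  perfect <- classification_metrics(list(TP = 7, FN = 0, FP = 0, TN = 3))
  expect_equal(unlist(perfect[c("f1", "precision", "recall", "accuracy")]),
               c(f1 = 100, precision = 100, recall = 100, accuracy = 100))

  degen <- classification_metrics(list(TP = 0, FP = 0, FN = 3, TN = 2))
  expect_equal(degen$precision, 0)
  expect_equal(degen$recall, 0)
  expect_equal(degen$f1, 0)
  expect_error(classification_metrics(list(TP = 0, FP = 0, FN = 0, TN = 0)),
               "zero")
})

test_that("metric identities hold for random confusion counts", {
  set.seed(12)
  for (i in 1:25) {
    cc <- list(TP = rpois(1, 8) + 1, FN = rpois(1, 3),
               FP = rpois(1, 3), TN = rpois(1, 8))
    m <- classification_metrics(cc)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 100))
    if (m$precision + m$recall > 0)
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    # accuracy ignores which label is positive
    swapped <- classification_metrics(list(TP = cc$TN, TN = cc$TP,
                                           FP = cc$FN, FN = cc$FP))
    expect_equal(swapped$accuracy, m$accuracy)
  }
})

test_that("multi-class evaluation macro-averages one-vs-rest metrics", {
  y_true <- c("a", "a", "b", "b", "c", "c")
  y_pred <- c("a", "b", "b", "b", "c", "a")
  m <- evaluate_predictions(y_true, y_pred)
  expect_equal(m$accuracy, 100 * 4 / 6)
  expect_true(m$f1 > 0 && m$f1 < 100)
})

test_that("cross-data-set evaluation handles identical and invalid inputs", {
  toy <- toy_descriptor_set(30, seed = 3)
  ds <- list(A = toy, B = toy)
  acc <- cross_dataset_eval(ds, classifier_spec("rf", seed = 2))
  expect_identical(dim(acc), c(2L, 2L))
  # identical sets: off-diagonal >= diagonal held-out accuracy (same data)
  expect_true(acc["A", "B"] >= acc["A", "A"] - 1e-9)
  expect_error(cross_dataset_eval(list(A = toy), classifier_spec("rf")),
               "at least 2")
  bad <- list(A = toy, B = list(features = toy$features[, 1:4],
                                labels = toy$labels))
  expect_error(cross_dataset_eval(bad, classifier_spec("rf")),
               "width")
})

test_that("grid search returns the spec that can actually fit the data", {
  toy <- toy_descriptor_set(24, seed = 21)
  good <- classifier_spec("mlp", seed = 4)
  crippled <- classifier_spec("mlp", list(learning_rate_init = 0,
                                          max_epochs = 2L), seed = 4)
  single <- tune_hyperparameters(toy$features, toy$labels, list(crippled),
                                 cv_folds = 3, seed = 1)
  expect_identical(single$hyperparams$learning_rate_init, 0)

  best <- tune_hyperparameters(toy$features, toy$labels,
                               list(good, crippled), cv_folds = 3, seed = 1)
  expect_identical(best$hyperparams$learning_rate_init,
                   good$hyperparams$learning_rate_init)
  expect_gte(attr(best, "cv_accuracy"), 95)

  expect_error(tune_hyperparameters(toy$features, toy$labels, list(),
                                    cv_folds = 3), "non-empty")
  tiny_labels <- c(rep("hit", 46), rep("miss", 2))
  expect_error(tune_hyperparameters(toy$features, tiny_labels, list(good),
                                    cv_folds = 3, seed = 1), "degenerate")
})

test_that("held-out accuracy improves with class separation", {
  set.seed(31)
  accs <- vapply(c(0.4, 1.5, 6), function(sep) {
    n <- 60
    X <- rbind(matrix(rpois(n * 8, 0.3), n, 8),
               matrix(rpois(n * 8, 0.3 + sep), n, 8))
    y <- rep(c("miss", "hit"), each = n)
    hold <- c(1:12, n + 1:12)
    m <- train_classifier(X[-hold, ], y[-hold],
                          classifier_spec("rf", seed = 7))
    mean(as.character(predict(m, X[hold, ])) == y[hold])
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[3], 0.99)
})

test_that("models survive serialization round trips", {
  toy <- toy_descriptor_set(20, seed = 13)
  m <- train_classifier(toy$features, toy$labels, classifier_spec("nb"))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, toy$features), predict(m, toy$features))
  expect_error(load_model({
    p <- tempfile(); saveRDS(list(a = 1), p); p
  }), "model container")
})
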