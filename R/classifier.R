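#' Classifier specification
#'
#' Describes one of the four supervised hit/miss classifiers compared in
#' the pipeline, with its default hyperparameters:
#'
#' * `mlp` -- multilayer perceptron with four hidden layers of
#'   50/30/20/20 neurons, logistic activation, minibatch SGD with a constant
#'   learning rate, and L2 regularization term `alpha = 1e-5`. Trained by
#'   the package's own implementation (softmax output, cross-entropy loss).
#' * `svm` -- support vector machine, RBF kernel, `C = 10` (via
#'   \pkg{e1071}).
#' * `rf` -- random forest, Gini impurity, maximum depth 30, 100 trees
#'   (via \pkg{ranger}).
#' * `nb` -- Gaussian naive Bayes with `var_smoothing = 1e-9` (the fraction
#'   of the largest feature variance added to every variance for numeric
#'   stability, which also handles the zero-variance all-zero miss
#'   descriptors).
#'
#' Descriptor counts are small and commensurable, so no feature scaling is
#' applied by default; set `hyperparams$standardize = TRUE` to z-score
#' features for the mlp/svm.
#'
#' @param kind One of `"mlp"`, `"svm"`, `"rf"`, `"nb"`.
#' @param hyperparams Named list overriding the defaults above.
#' @param seed Integer seed controlling weight initialization, minibatch
#'   shuffling and tree growing.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("mlp", "svm", "rf", "nb"),
                            hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    mlp = list(hidden = c(50L, 30L, 20L, 20L), activation = "logistic",
               solver = "sgd", alpha = 1e-5, learning_rate = "constant",
               learning_rate_init = 0.2, batch_size = 32L,
               max_epochs = 1000L, standardize = FALSE),
    svm = list(cost = 10, kernel = "radial", standardize = FALSE),
    rf  = list(num_trees = 100L, max_depth = 30L, splitrule = "gini"),
    nb  = list(var_smoothing = 1e-9))
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(kind = kind, hyperparams = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  storage.mode(features) <- "double"
  # canonical column names so model backends see one stable schema
  colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  features
}

#' Train a hit/miss classifier on descriptor vectors
#'
#' @param features Numeric matrix (or data frame), one descriptor vector per
#'   row.
#' @param labels Vector of class labels, same length as `nrow(features)`;
#'   at least two distinct classes must be present.
#' @param spec A [classifier_spec()].
#' @return An object of class `trained_classifier` recording the spec, the
#'   fitted model, the label levels and the feature width.
#' @export
train_classifier <- function(features, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_feature_matrix(features)
  y <- factor(labels)
  if (nrow(X) != length(y))
    stop("features and labels have mismatched lengths")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (nlevels(y) < 2L)
    stop("training labels contain a single class; need at least two")
  hp <- spec$hyperparams
  scaler <- NULL
  if (isTRUE(hp$standardize)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
    X <- scale(X, center = ctr, scale = scl)
    scaler <- list(center = ctr, scale = scl)
  }
  fit <- switch(spec$kind,
    mlp = mlp_fit(X, y, hidden = hp$hidden, activation = hp$activation,
                  alpha = hp$alpha, lr = hp$learning_rate_init,
                  lr_schedule = hp$learning_rate,
                  batch_size = hp$batch_size, max_epochs = hp$max_epochs,
                  seed = spec$seed),
    svm = e1071::svm(x = X, y = y, type = "C-classification",
                     kernel = hp$kernel, cost = hp$cost, scale = FALSE),
    rf  = {
      df <- data.frame(..y.. = y, X)
      ranger::ranger(dependent.variable.name = "..y..", data = df,
                     num.trees = hp$num_trees, max.depth = hp$max_depth,
                     splitrule = hp$splitrule, seed = spec$seed,
                     num.threads = 1L)
    },
    nb  = gnb_fit(X, y, var_smoothing = hp$var_smoothing))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 feature_width = ncol(X), scaler = scaler),
            class = "trained_classifier")
}

#' Predict labels for descriptor vectors
#'
#' @param object A [train_classifier()] model.
#' @param newdata Numeric matrix of descriptor vectors (one per row) with
#'   the training feature width.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$feature_width)
    stop("feature width ", ncol(X), " does not match training width ",
         object$feature_width)
  if (!is.null(object$scaler))
    X <- scale(X, center = object$scaler$center, scale = object$scaler$scale)
  out <- switch(object$spec$kind,
    mlp = mlp_predict(object$fit, X),
    svm = as.character(stats::predict(object$fit, X)),
    rf  = as.character(stats::predict(object$fit,
                                      data = data.frame(X),
                                      num.threads = 1L)$predictions),
    nb  = gnb_predict(object$fit, X))
  factor(out, levels = object$levels)
}

# ---------------------------------------------------------------------------
# Multilayer perceptron (minibatch SGD, softmax output, cross-entropy + L2)

mlp_activate <- function(z, activation) {
  switch(activation,
    logistic = 1 / (1 + exp(-z)),
    tanh = tanh(z),
    relu = pmax(z, 0),
    stop("unknown activation: ", activation))
}

mlp_act_grad <- function(a, activation) {
  switch(activation,
    logistic = a * (1 - a),
    tanh = 1 - a^2,
    relu = (a > 0) * 1)
}

mlp_fit <- function(X, y, hidden, activation, alpha, lr, lr_schedule,
                    batch_size, max_epochs, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  classes <- levels(y)
  C <- length(classes)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), as.integer(y))] <- 1
  sizes <- c(p, hidden, C)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  batch_size <- min(batch_size, n)
  eta <- lr
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    if (lr_schedule == "adaptive") eta <- lr / (1 + 0.01 * (epoch - 1))
    epoch_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      m <- length(idx)
      A <- vector("list", L + 1L)
      A[[1L]] <- X[idx, , drop = FALSE]
      for (l in seq_len(L - 1L)) {
        A[[l + 1L]] <- mlp_activate(
          sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+"), activation)
      }
      Z <- sweep(A[[L]] %*% W[[L]], 2L, b[[L]], "+")
      Z <- Z - apply(Z, 1L, max)
      P <- exp(Z); P <- P / rowSums(P)
      A[[L + 1L]] <- P
      Yb <- Y[idx, , drop = FALSE]
      epoch_loss <- epoch_loss - sum(Yb * log(pmax(P, 1e-300)))
      delta <- (P - Yb) / m
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + alpha * W[[l]]
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * mlp_act_grad(A[[l]], activation)
        W[[l]] <- W[[l]] - eta * gW
        b[[l]] <- b[[l]] - eta * gb
      }
    }
    if (epoch_loss / n < 1e-5) break
  }
  list(W = W, b = b, activation = activation, classes = classes)
}

mlp_forward <- function(fit, X) {
  L <- length(fit$W)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- mlp_activate(sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+"),
                      fit$activation)
  }
  Z <- sweep(A %*% fit$W[[L]], 2L, fit$b[[L]], "+")
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z)
  P / rowSums(P)
}

mlp_predict <- function(fit, X) {
  P <- mlp_forward(fit, X)
  fit$classes[max.col(P, ties.method = "first")]
}

# ---------------------------------------------------------------------------
# Gaussian naive Bayes with var_smoothing (fraction of the largest feature
# variance added to all variances for calculation stability)

gnb_fit <- function(X, y, var_smoothing = 1e-9) {
  classes <- levels(y)
  p <- ncol(X)
  mu <- matrix(0, length(classes), p)
  va <- matrix(0, length(classes), p)
  prior <- numeric(length(classes))
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    va[i, ] <- apply(Xi, 2L, function(v) mean((v - mean(v))^2))
    prior[i] <- nrow(Xi) / nrow(X)
  }
  feat_var <- apply(X, 2L, function(v) mean((v - mean(v))^2))
  eps <- var_smoothing * max(feat_var)
  if (!is.finite(eps) || eps <= 0) eps <- var_smoothing
  va <- va + eps
  list(classes = classes, mu = mu, va = va, log_prior = log(prior))
}

gnb_predict <- function(fit, X) {
  n <- nrow(X)
  ll <- matrix(0, n, length(fit$classes))
  for (i in seq_along(fit$classes)) {
    mu <- fit$mu[i, ]; va <- fit$va[i, ]
    ll[, i] <- fit$log_prior[i] -
      0.5 * sum(log(2 * pi * va)) -
      rowSums(sweep(sweep(X, 2L, mu, "-")^2, 2L, 2 * va, "/"))
  }
  fit$classes[max.col(ll, ties.method = "first")]
}

# ---------------------------------------------------------------------------
# Evaluation

#' Binary confusion counts
#'
#' Tallies TP/TN/FP/FN with `positive` (default `"hit"`) as the positive
#' class; all labels other than `positive` count as negative.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The positive class label.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive = "hit") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, each reported as a percentage.
#' Zero-denominator cases return 0 by convention so degenerate folds stay
#' defined.
#'
#' @param counts A [confusion()] object (or list with TP/TN/FP/FN).
#' @return A list of class `classification_metrics` with fields `f1`,
#'   `precision`, `recall`, `accuracy` in `[0, 100]`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- (tp + tn) / total
  structure(list(f1 = 100 * f1, precision = 100 * precision,
                 recall = 100 * recall, accuracy = 100 * accuracy),
            class = "classification_metrics")
}

#' Metrics directly from label vectors
#'
#' Binary problems report the standard positive-class metrics; problems
#' with more than two classes report macro-averaged one-vs-rest precision,
#' recall and F1 plus overall accuracy.
#'
#' @inheritParams confusion
#' @return A `classification_metrics` object.
#' @export
evaluate_predictions <- function(y_true, y_pred, positive = "hit") {
  lv <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(lv) <= 2L) {
    if (!positive %in% lv) positive <- lv[1]
    return(classification_metrics(confusion(y_true, y_pred, positive)))
  }
  per <- lapply(lv, function(cl)
    classification_metrics(confusion(y_true, y_pred, cl)))
  structure(list(
    f1 = mean(vapply(per, `[[`, 0, "f1")),
    precision = mean(vapply(per, `[[`, 0, "precision")),
    recall = mean(vapply(per, `[[`, 0, "recall")),
    accuracy = 100 * mean(y_true == y_pred)),
    class = "classification_metrics")
}

# Stratified held-out indices: per class, round(frac * n) samples (at least
# 1 when the class has >= 2 members), seeded.
stratified_holdout <- function(labels, frac, seed) {
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- round(frac * length(idx))
    if (length(idx) >= 2L) k <- max(1L, min(k, length(idx) - 1L))
    if (k > 0L) test_idx <- c(test_idx, sample(idx, k))
  }
  sort(test_idx)
}

#' Cross-data-set training and testing
#'
#' For every ordered pair of named data sets, trains on the full training
#' set and reports accuracy (%) on the test set; the diagonal uses a
#' stratified held-out split of the same set. This is the protocol used to
#' probe domain-gap robustness: a feature that transfers keeps off-diagonal
#' accuracies close to the diagonal.
#'
#' @param datasets Named list (length >= 2) of lists with elements
#'   `features` and `labels`; all feature widths must agree.
#' @param spec A [classifier_spec()].
#' @param holdout_frac Diagonal held-out fraction (default 0.2).
#' @return Square numeric matrix of accuracies (%), rows = training set,
#'   columns = test set.
#' @export
cross_dataset_eval <- function(datasets, spec = classifier_spec(),
                               holdout_frac = 0.2) {
  if (length(datasets) < 2L)
    stop("need at least 2 named data sets")
  widths <- vapply(datasets,
                   function(d) ncol(as_feature_matrix(d$features)), 0L)
  if (length(unique(widths)) != 1L)
    stop("incompatible feature widths across data sets")
  nm <- names(datasets)
  acc <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    tr <- datasets[[i]]
    model_full <- train_classifier(tr$features, tr$labels, spec)
    for (j in seq_along(nm)) {
      if (i == j) {
        labels <- as.character(tr$labels)
        hold <- stratified_holdout(labels, holdout_frac, spec$seed)
        Xtr <- as_feature_matrix(tr$features)
        m <- train_classifier(Xtr[-hold, , drop = FALSE], labels[-hold], spec)
        pred <- predict(m, Xtr[hold, , drop = FALSE])
        acc[i, j] <- 100 * mean(as.character(pred) == labels[hold])
      } else {
        te <- datasets[[j]]
        pred <- predict(model_full, te$features)
        acc[i, j] <- 100 * mean(as.character(pred) == as.character(te$labels))
      }
    }
  }
  acc
}

# Stratified fold assignment (1..k) or error when a class cannot reach
# every fold.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("degenerate fold: class '", cl, "' has fewer samples (",
           length(idx), ") than cv_folds (", k, ")")
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Grid-search hyperparameter tuning with stratified cross-validation
#'
#' Exhaustively evaluates each candidate spec by stratified k-fold
#' cross-validated accuracy and returns the best; ties go to the earliest
#' grid entry.
#'
#' @param features,labels Training data as in [train_classifier()].
#' @param grid Non-empty list of [classifier_spec()] objects.
#' @param cv_folds Number of folds (>= 2).
#' @param seed Seed for fold assignment.
#' @return The winning `classifier_spec`, with the attained mean CV accuracy
#'   attached as attribute `cv_accuracy`.
#' @export
tune_hyperparameters <- function(features, labels, grid, cv_folds = 3L,
                                 seed = 1L) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  X <- as_feature_matrix(features)
  labels <- as.character(labels)
  folds <- stratified_folds(labels, cv_folds, seed)
  best <- NULL; best_acc <- -Inf
  for (spec in grid) {
    accs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      m <- train_classifier(X[tr, , drop = FALSE], labels[tr], spec)
      pred <- predict(m, X[!tr, , drop = FALSE])
      accs[f] <- mean(as.character(pred) == labels[!tr])
    }
    if (mean(accs) > best_acc) {
      best_acc <- mean(accs); best <- spec
    }
  }
  attr(best, "cv_accuracy") <- 100 * best_acc
  best
}

#' Save / load a trained classifier
#'
#' @param model A `trained_classifier`.
#' @param path File path.
#' @return `load_model` returns the `trained_classifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  saveRDS(list(format = "mpfast_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mpfast_model"))
    stop("file is not an mpfast model container")
  obj$model
}
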