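#' Base learner configuration
#'
#' Five classical classifiers serve as first-stage learners of the stack;
#' each must expose class probabilities. Defaults (overridable via
#' `hyperparameters`):
#' * `rf` — random forest, 100 trees, `mtry = floor(sqrt(d))`.
#' * `xgb` — gradient-boosted trees with shrinkage/regularization, 100
#'   rounds, depth 6, learning rate 0.3, L2 lambda 1.
#' * `gb` — classical gradient boosting profile (100 stages, learning rate
#'   0.1, depth 3).
#' * `knn` — k-nearest neighbors, k = 5, Euclidean, vote-fraction
#'   probabilities.
#' * `lr` — multinomial logistic regression (softmax over `w'x + b`)
#'   trained by full-batch gradient descent with an L2 penalty; strength
#'   1.0, up to 1000 iterations.
#'
#' @param name One of `"rf"`, `"xgb"`, `"gb"`, `"knn"`, `"lr"`.
#' @param hyperparameters Named list of per-learner overrides.
#' @param seed Integer seed.
#' @return Object of class `base_learner_config`.
#' @export
base_learner_config <- function(name, hyperparameters = list(), seed = 0) {
  name <- match.arg(name, c("rf", "xgb", "gb", "knn", "lr"))
  defaults <- switch(name,
    rf  = list(ntree = 100),
    xgb = list(nrounds = 100, max_depth = 6, eta = 0.3, lambda = 1),
    gb  = list(nrounds = 100, max_depth = 3, eta = 0.1, lambda = 0),
    knn = list(k = 5),
    lr  = list(lambda = 1.0, max_iter = 1000, learning_rate = 0.5))
  bad <- setdiff(names(hyperparameters), names(defaults))
  if (length(bad))
    stop("unknown hyperparameters for '", name, "': ",
         paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "base_learner_config")
}

# softmax over rows of a logit matrix, numerically stabilized
row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# multinomial logistic regression by full-batch gradient descent with L2
# penalty; objective (1/n) sum CE + (lambda / (2n)) ||W||^2
fit_softmax_lr <- function(X, y_int, m, lambda = 1, max_iter = 1000,
                           learning_rate = 0.5, tol = 1e-7) {
  n <- nrow(X); d <- ncol(X)
  W <- matrix(0, d, m); b <- numeric(m)
  Yh <- matrix(0, n, m); Yh[cbind(seq_len(n), y_int)] <- 1
  prev <- Inf
  for (it in seq_len(max_iter)) {
    P <- row_softmax(X %*% W + matrix(b, n, m, byrow = TRUE))
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y_int)], 1e-300))) +
      lambda / (2 * n) * sum(W^2)
    G <- (P - Yh) / n
    W <- W - learning_rate * (crossprod(X, G) + lambda / n * W)
    b <- b - learning_rate * colSums(G)
    if (abs(prev - loss) < tol) break
    prev <- loss
  }
  list(W = W, b = b)
}

#' Fit a base learner
#'
#' @param cfg A [base_learner_config()].
#' @param Z n x d feature matrix (typically PCA scores).
#' @param y Labels (length n; at least 2 classes, each with >= 2 samples
#'   recommended).
#' @return Object of class `base_model` supporting [predict_proba()].
#' @export
fit_base <- function(cfg, Z, y) {
  stopifnot(inherits(cfg, "base_learner_config"))
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("non-finite features")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2) stop("need at least 2 classes")
  yf <- factor(as.character(y), levels = classes)
  hp <- cfg$hyperparameters
  set.seed(cfg$seed)
  fit <- switch(cfg$name,
    rf = randomForest::randomForest(
      x = Z, y = yf, ntree = hp$ntree, mtry = max(1, floor(sqrt(ncol(Z))))),
    xgb = ,
    gb = xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    max_depth = hp$max_depth, eta = hp$eta,
                    lambda = hp$lambda, nthread = 1,
                    seed = cfg$seed),
      data = xgboost::xgb.DMatrix(Z, label = as.integer(yf) - 1L),
      nrounds = hp$nrounds, verbose = 0),
    knn = caret::knn3(x = Z, y = yf, k = hp$k),
    lr = fit_softmax_lr(Z, as.integer(yf), length(classes),
                        lambda = hp$lambda, max_iter = hp$max_iter,
                        learning_rate = hp$learning_rate))
  structure(list(name = cfg$name, fit = fit, classes = classes,
                 config = cfg, d = ncol(Z)),
            class = "base_model")
}

#' Class probabilities from a fitted base learner
#'
#' @param model A [fit_base()] result.
#' @param Z New feature matrix (same dimensionality as training).
#' @return n x m row-stochastic matrix, columns in sorted class order.
#' @export
predict_proba <- function(model, Z) {
  stopifnot(inherits(model, "base_model"))
  Z <- as.matrix(Z)
  if (ncol(Z) != model$d)
    stop("feature dimension ", ncol(Z), " != training dimension ", model$d)
  m <- length(model$classes)
  P <- switch(model$name,
    rf = {
      pr <- stats::predict(model$fit, Z, type = "prob")
      pr[, model$classes, drop = FALSE]
    },
    xgb = ,
    gb = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(Z))
      if (is.matrix(pr)) pr else matrix(pr, nrow(Z), m, byrow = TRUE)
    },
    knn = {
      pr <- stats::predict(model$fit, Z, type = "prob")
      pr[, model$classes, drop = FALSE]
    },
    lr = row_softmax(Z %*% model$fit$W +
                       matrix(model$fit$b, nrow(Z), m, byrow = TRUE)))
  P <- pmin(pmax(as.matrix(P), 0), 1)
  P <- P / rowSums(P)
  colnames(P) <- model$classes
  rownames(P) <- NULL
  P
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  assign <- integer(length(y))
  for (cl in sort(unique(as.character(y)))) {
    idx <- which(as.character(y) == cl)
    if (length(idx) < folds)
      stop("class '", cl, "' has ", length(idx), " members; need >= ",
           folds, " for ", folds, "-fold stacking")
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Out-of-fold class probabilities for stacking
#'
#' Stratified k-fold protocol: row i's probabilities come from the model
#' trained on all folds except the one containing i, so no row is ever
#' scored by a model that saw its label (no stacking leakage).
#'
#' @param cfg A [base_learner_config()].
#' @param Z n x d feature matrix.
#' @param y Labels; every class needs at least `folds` members.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return n x m row-stochastic matrix with attribute `fold` (per-row fold
#'   id).
#' @export
oof_probabilities <- function(cfg, Z, y, folds = 5, seed = 0) {
  Z <- as.matrix(Z)
  classes <- sort(unique(as.character(y)))
  fold <- stratified_folds(y, folds, seed)
  P <- matrix(NA_real_, nrow(Z), length(classes),
              dimnames = list(NULL, classes))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- fit_base(cfg, Z[tr, , drop = FALSE], y[tr])
    P[!tr, ] <- predict_proba(model, Z[!tr, , drop = FALSE])
  }
  attr(P, "fold") <- fold
  P
}
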