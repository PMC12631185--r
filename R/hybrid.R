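#' Fit a two-stage hybrid stack: base learner -> DNN head
#'
#' Stage one produces a class-probability matrix `p = M(Z)` from the base
#' learner; stage two trains the dense network head on those probabilities.
#' To avoid stacking leakage, the head's training inputs are out-of-fold
#' probabilities by default (each training row scored by a model that never
#' saw it); `naive = TRUE` uses in-sample probabilities instead (the literal
#' single-pass reading, kept for comparison). The base learner is then refit
#' on all training rows, and its probabilities on the validation set drive
#' early stopping of the head.
#'
#' @param cfg A [base_learner_config()].
#' @param Z_train,y_train Training features (n x d) and labels.
#' @param Z_val,y_val Validation features and labels.
#' @param train_cfg List of head-training settings: `epochs` (300),
#'   `batch_size` (32), `learning_rate` (1e-3), `patience` (30), `folds`
#'   (5), `naive` (FALSE).
#' @param seed Master seed (folds, initialization, shuffling derive from it).
#' @return Object of class `stack_model`: `base`, `head`, `classes`,
#'   `history`, `config`.
#' @export
fit_hybrid <- function(cfg, Z_train, y_train, Z_val, y_val,
                       train_cfg = list(), seed = 0) {
  tc <- utils::modifyList(list(epochs = 300, batch_size = 32,
                               learning_rate = 1e-3, patience = 30,
                               folds = 5, naive = FALSE), train_cfg)
  Z_train <- as.matrix(Z_train); Z_val <- as.matrix(Z_val)
  classes <- sort(unique(as.character(y_train)))
  m <- length(classes)
  if (!all(as.character(y_val) %in% classes))
    stop("validation labels outside the training class set")
  y_tr_int <- match(as.character(y_train), classes)
  y_va_int <- match(as.character(y_val), classes)

  base_cfg <- cfg; base_cfg$seed <- derive_seed(seed, 1)
  P_train <- if (tc$naive) {
    predict_proba(fit_base(base_cfg, Z_train, y_train), Z_train)
  } else {
    oof_probabilities(base_cfg, Z_train, y_train, folds = tc$folds,
                      seed = derive_seed(seed, 2))
  }
  base <- fit_base(base_cfg, Z_train, y_train)   # refit on all rows
  P_val <- predict_proba(base, Z_val)

  head <- build_dnn(m, seed = derive_seed(seed, 3))
  head <- train_dnn(head, P_train, y_tr_int, P_val, y_va_int,
                    epochs = tc$epochs, batch_size = tc$batch_size,
                    learning_rate = tc$learning_rate, patience = tc$patience,
                    seed = derive_seed(seed, 4))
  structure(list(base = base, head = head, classes = classes,
                 history = head$history, config = list(
                   learner = cfg$name, train = tc, seed = seed)),
            class = "stack_model")
}

#' Predict labels and probabilities from a hybrid stack
#'
#' Composition of the two stages: base-learner probabilities feed the DNN
#' head in inference mode (deterministic); the label is the argmax class,
#' ties broken toward the lowest class index.
#'
#' @param object A [fit_hybrid()] result.
#' @param Z Feature matrix matching the training dimensionality.
#' @param ... Unused.
#' @return List with `labels` (character) and `probabilities`
#'   (row-stochastic n x m matrix, sorted class order).
#' @export
predict.stack_model <- function(object, Z, ...) {
  P_base <- predict_proba(object$base, as.matrix(Z))
  probs <- dnn_forward(object$head, P_base, mode = "infer")
  colnames(probs) <- object$classes
  labels <- object$classes[max.col(probs, ties.method = "first")]
  list(labels = labels, probabilities = probs)
}

#' @export
print.stack_model <- function(x, ...) {
  cat("Hybrid stack:", x$config$learner, "-> DNN head |",
      length(x$classes), "classes | best epoch", x$head$best_epoch, "\n")
  invisible(x)
}
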