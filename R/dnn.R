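#' Build the dense neural network head
#'
#' The meta-learner of the stack: a fully connected network taking the base
#' learner's m class probabilities as input. Architecture (fixed widths):
#' Dense(512, ReLU) -> Dropout(0.3) -> Dense(256, ReLU) -> Dropout(0.3) ->
#' Dense(128, ReLU) -> Dropout(0.3) -> Dense(m, softmax). Forward pass per
#' layer: `z = W a + b`, `a = g(z)` with g = ReLU on hidden layers and
#' softmax on the output. Weights use He-uniform initialization
#' (`limit = sqrt(6 / fan_in)`) from the seed; biases start at zero.
#'
#' @param m Number of classes (>= 2); also the input dimension.
#' @param seed Integer seed for initialization.
#' @param widths Hidden layer widths (default `c(512, 256, 128)`).
#' @param dropout Dropout rate after each hidden layer (default 0.3,
#'   inverted scaling, active only in training mode).
#' @param input_dim Input dimension (default `m`, the probability vector).
#' @return Object of class `dnn_model` with fields `W`, `b` (lists),
#'   `widths`, `m`, `dropout`, `seed`.
#' @export
build_dnn <- function(m, seed = 0, widths = c(512, 256, 128), dropout = 0.3,
                      input_dim = m) {
  if (m < 2) stop("need at least 2 classes")
  stopifnot(dropout >= 0, dropout < 1, all(widths >= 1))
  set.seed(as.integer(seed))
  dims <- c(input_dim, widths, m)
  W <- b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    limit <- sqrt(6 / fan_in)
    W[[l]] <- matrix(runif(fan_in * dims[l + 1], -limit, limit),
                     fan_in, dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  structure(list(W = W, b = b, widths = widths, m = as.integer(m),
                 dropout = dropout, seed = as.integer(seed),
                 input_dim = as.integer(input_dim)),
            class = "dnn_model")
}

# forward pass keeping intermediate activations (and dropout masks when
# training) for backpropagation
dnn_forward_cache <- function(model, X, mode = "infer") {
  n <- nrow(X)
  L <- length(model$W)
  A <- vector("list", L + 1)
  Zs <- masks <- vector("list", L)
  A[[1]] <- X
  keep <- 1 - model$dropout
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% model$W[[l]] +
      matrix(model$b[[l]], n, length(model$b[[l]]), byrow = TRUE)
    Zs[[l]] <- Zl
    if (l < L) {
      Al <- pmax(Zl, 0)
      if (mode == "train" && model$dropout > 0) {
        mask <- matrix(runif(length(Al)) < keep, nrow(Al), ncol(Al)) / keep
        Al <- Al * mask
        masks[[l]] <- mask
      }
      A[[l + 1]] <- Al
    } else {
      A[[l + 1]] <- row_softmax(Zl)
    }
  }
  list(A = A, Z = Zs, masks = masks)
}

#' Forward pass of the DNN head
#'
#' Affine maps with ReLU hidden activations and a softmax output; every
#' output row sums to 1. Dropout (inverted scaling) is applied after each
#' hidden activation only in `"train"` mode, with masks drawn from
#' `dropout_seed`; `"infer"` mode is deterministic.
#'
#' @param model A [build_dnn()] result.
#' @param P n x input_dim matrix (base-learner probabilities).
#' @param mode `"infer"` or `"train"`.
#' @param dropout_seed Seed for the training-mode dropout masks.
#' @return n x m row-stochastic matrix.
#' @export
dnn_forward <- function(model, P, mode = c("infer", "train"),
                        dropout_seed = 0) {
  mode <- match.arg(mode)
  P <- as.matrix(P)
  if (ncol(P) != model$input_dim)
    stop("input has ", ncol(P), " columns; model expects ", model$input_dim)
  if (mode == "train") set.seed(as.integer(dropout_seed))
  cache <- dnn_forward_cache(model, P, mode)
  cache$A[[length(cache$A)]]
}

# one Adam update step over lists of weight/bias gradients
adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the DNN head with cross-entropy and early stopping
#'
#' Mini-batch backpropagation with the Adam optimizer; dropout active during
#' training; early stopping restores the weights of the epoch with the best
#' validation loss.
#'
#' @param model A [build_dnn()] result.
#' @param X,y_int Training inputs and 1-based integer class labels.
#' @param X_val,y_val_int Validation set for early stopping.
#' @param epochs Maximum epochs (default 300).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param seed Seed for shuffling and dropout masks.
#' @return The trained `dnn_model` with a `history` data frame
#'   (`epoch, train_loss, train_acc, val_loss, val_acc`) attached.
#' @export
train_dnn <- function(model, X, y_int, X_val, y_val_int, epochs = 300,
                      batch_size = 32, learning_rate = 1e-3, patience = 30,
                      seed = 0) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  n <- nrow(X); m <- model$m
  L <- length(model$W)
  Y <- matrix(0, n, m); Y[cbind(seq_len(n), y_int)] <- 1
  ce_acc <- function(P, yi) {
    list(loss = -mean(log(pmax(P[cbind(seq_along(yi), yi)], 1e-300))),
         acc = mean(max.col(P, ties.method = "first") == yi))
  }
  par <- c(setNames(model$W, paste0("W", seq_len(L))),
           setNames(model$b, paste0("b", seq_len(L))))
  zero <- lapply(par, function(p) p * 0)
  state <- list(par = par, m = zero, v = zero)
  best <- list(loss = Inf, par = par, epoch = 0L)
  hist <- vector("list", epochs)
  set.seed(as.integer(seed))
  t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      nb <- length(idx)
      model$W <- state$par[paste0("W", seq_len(L))]
      model$b <- state$par[paste0("b", seq_len(L))]
      cache <- dnn_forward_cache(model, X[idx, , drop = FALSE], mode = "train")
      # output layer gradient of mean cross-entropy w.r.t. logits
      delta <- (cache$A[[L + 1]] - Y[idx, , drop = FALSE]) / nb
      grads <- list()
      for (l in L:1) {
        grads[[paste0("W", l)]] <- crossprod(cache$A[[l]], delta)
        grads[[paste0("b", l)]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(model$W[[l]])
          if (!is.null(cache$masks[[l - 1]])) delta <- delta * cache$masks[[l - 1]]
          delta <- delta * (cache$Z[[l - 1]] > 0)
        }
      }
      t <- t + 1L
      state <- adam_step(state, grads, learning_rate, t)
    }
    model$W <- state$par[paste0("W", seq_len(L))]
    model$b <- state$par[paste0("b", seq_len(L))]
    tr <- ce_acc(dnn_forward_cache(model, X, "infer")$A[[L + 1]], y_int)
    va <- ce_acc(dnn_forward_cache(model, X_val, "infer")$A[[L + 1]], y_val_int)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                             train_acc = tr$acc, val_loss = va$loss,
                             val_acc = va$acc)
    if (va$loss < best$loss - 1e-9) {
      best <- list(loss = va$loss, par = state$par, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  model$W <- best$par[paste0("W", seq_len(L))]
  model$b <- best$par[paste0("b", seq_len(L))]
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model
}
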