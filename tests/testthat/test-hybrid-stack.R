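# shared fixture: separable 3-class blobs
sep6 <- generate_feature_table(200, 3, 10, separation = 6, seed = 42)
sep0 <- generate_feature_table(200, 3, 10, separation = 0, seed = 42)
spl6 <- blob_split(sep6, seed = 42)
spl0 <- blob_split(sep0, seed = 42)

test_that("1-nearest-neighbor probabilities are one-hot on training rows", {
  idx <- c(1:20, 201:220, 401:420)   # rows are grouped by class
  cfg <- base_learner_config("knn", list(k = 1), seed = 1)
  fit <- fit_base(cfg, sep6$X[idx, ], sep6$y[idx])
  P <- predict_proba(fit, sep6$X[idx, ])
  expect_row_stochastic(P)
  expect_equal(colnames(P)[max.col(P)], sep6$y[idx])
  expect_true(all(apply(P, 1, max) == 1))
})

test_that("logistic regression separates 2-class blobs perfectly", {
  tab <- generate_feature_table(100, 2, 5, separation = 8, seed = 7)
  fit <- fit_base(base_learner_config("lr", seed = 7), tab$X, tab$y)
  P <- predict_proba(fit, tab$X)
  expect_equal(mean(colnames(P)[max.col(P)] == tab$y), 1)
})

test_that("every base learner generalizes on separable blobs", {
  for (nm in c("rf", "xgb", "gb", "knn", "lr")) {
    fit <- fit_base(base_learner_config(nm, seed = 1),
                    sep6$X[spl6$tr, ], sep6$y[spl6$tr])
    P <- predict_proba(fit, sep6$X[spl6$te, ])
    expect_row_stochastic(P)
    acc <- mean(colnames(P)[max.col(P)] == sep6$y[spl6$te])
    expect_gte(acc, 0.95)
  }
  expect_error(fit_base(base_learner_config("rf"), sep6$X[1:10, ],
                        rep("a", 10)), "2 classes")
})

test_that("out-of-fold probabilities never come from a model that saw the row", {
  cfg <- base_learner_config("lr", seed = 2)
  idx <- c(1:40, 201:240, 401:440)   # rows are grouped by class
  Z <- sep6$X[idx, ]; y <- sep6$y[idx]
  P <- oof_probabilities(cfg, Z, y, folds = 4, seed = 9)
  expect_equal(dim(P), c(120, 3))
  expect_row_stochastic(P)
  fold <- attr(P, "fold")
  expect_length(fold, 120)
  expect_true(all(fold %in% 1:4))
  # stratification: every class appears in every fold
  expect_true(all(table(y, fold) > 0))
  # leakage check by reconstruction: refitting fold f's model on the same
  # rows reproduces exactly the probabilities of the held-out rows
  for (f in 1:2) {
    cfg_f <- cfg
    m <- fit_base(cfg_f, Z[fold != f, ], y[fold != f])
    expect_equal(unname(predict_proba(m, Z[fold == f, , drop = FALSE])),
                 unname(P[fold == f, , drop = FALSE]), tolerance = 1e-12)
  }
  small <- c(1:8, 41:43)   # second class has only 3 members
  expect_error(oof_probabilities(cfg, Z[small, ], y[small], folds = 5),
               "need >= 5")
})

test_that("signal-free data yields near-uniform out-of-fold probabilities", {
  cfg <- base_learner_config("lr", seed = 3)
  P <- oof_probabilities(cfg, sep0$X, sep0$y, folds = 5, seed = 3)
  expect_lt(abs(mean(apply(P, 1, max)) - 1 / 3), 0.1)
})

test_that("the DNN head is built exactly to the documented architecture", {
  net <- build_dnn(15, seed = 1)
  expect_equal(vapply(net$W, ncol, integer(1)), c(512L, 256L, 128L, 15L))
  expect_equal(vapply(net$W, nrow, integer(1)), c(15L, 512L, 256L, 128L))
  expect_equal(net$dropout, 0.3)
  net5 <- build_dnn(5, seed = 1)
  expect_equal(ncol(net5$W[[1]]), 512L)  # first dense layer width fixed
  expect_equal(ncol(net5$W[[4]]), 5L)
  expect_error(build_dnn(1), "2 classes")
  # all-zero weights: equal logits give the uniform softmax
  net5$W <- lapply(net5$W, function(w) w * 0)
  P <- dnn_forward(net5, matrix(runif(10 * 5), 10))
  expect_equal(unname(P), matrix(1 / 5, 10, 5))
})

test_that("the forward pass is a proper softmax network", {
  net <- build_dnn(4, seed = 2)
  X <- matrix(runif(12 * 4), 12)
  P1 <- dnn_forward(net, X, mode = "infer")
  P2 <- dnn_forward(net, X, mode = "infer")
  expect_identical(P1, P2)          # no dropout at inference
  expect_row_stochastic(P1)
  # dropout only acts in training mode
  Pt <- dnn_forward(net, X, mode = "train", dropout_seed = 1)
  expect_false(identical(P1, Pt))
  expect_row_stochastic(Pt)
  # hand softmax oracle on a single identity-weight layer
  one_layer <- structure(list(W = list(diag(2)), b = list(c(0, 0)),
                              widths = integer(0), m = 2L, dropout = 0,
                              seed = 0L, input_dim = 2L),
                         class = "dnn_model")
  out <- dnn_forward(one_layer, matrix(c(0.9, 0.1), 1))
  expect_equal(round(as.numeric(out), 4), c(0.6900, 0.3100))
})

test_that("the hybrid stack recovers separable classes and stays at chance without signal", {
  m6 <- fit_hybrid(base_learner_config("lr", seed = 42),
                   sep6$X[spl6$tr, ], sep6$y[spl6$tr],
                   sep6$X[spl6$va, ], sep6$y[spl6$va], seed = 42)
  pred <- predict(m6, sep6$X[spl6$te, ])
  acc <- mean(pred$labels == sep6$y[spl6$te])
  expect_gte(acc, 0.95)
  expect_row_stochastic(pred$probabilities)
  expect_true(all(pred$labels %in% m6$classes))
  expect_equal(m6$classes[max.col(pred$probabilities, ties.method = "first")],
               pred$labels)
  cm <- confusion_matrix(sep6$y[spl6$te], pred$labels, m6$classes)
  expect_lte(1 - sum(diag(cm)) / sum(cm), 0.05)
  # training history is well-formed
  h <- m6$history
  expect_equal(h$epoch, seq_len(nrow(h)))
  expect_true(all(is.finite(unlist(h))))

  m0 <- fit_hybrid(base_learner_config("lr", seed = 42),
                   sep0$X[spl0$tr, ], sep0$y[spl0$tr],
                   sep0$X[spl0$va, ], sep0$y[spl0$va], seed = 42)
  p0 <- predict(m0, sep0$X[spl0$te, ])
  expect_lt(abs(mean(p0$labels == sep0$y[spl0$te]) - 1 / 3), 0.1)
})

test_that("the entire stack fit is reproducible from its seeds", {
  args <- list(base_learner_config("knn", seed = 5),
               sep6$X[spl6$tr, ], sep6$y[spl6$tr],
               sep6$X[spl6$va, ], sep6$y[spl6$va])
  fast <- list(epochs = 40, patience = 10)
  m1 <- do.call(fit_hybrid, c(args, list(train_cfg = fast, seed = 5)))
  m2 <- do.call(fit_hybrid, c(args, list(train_cfg = fast, seed = 5)))
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, sep6$X[spl6$te, ]),
                   predict(m2, sep6$X[spl6$te, ]))
})

test_that("held-out accuracy responds monotonically to class separation", {
  accs <- sapply(c(0, 1, 6), function(sep) {
    vapply(1:3, function(s) {
      tab <- generate_feature_table(80, 3, 8, separation = sep, seed = 100 + s)
      sp <- blob_split(tab, seed = 100 + s)
      m <- fit_hybrid(base_learner_config("lr", seed = s),
                      tab$X[sp$tr, ], tab$y[sp$tr],
                      tab$X[sp$va, ], tab$y[sp$va],
                      train_cfg = list(epochs = 60, patience = 10,
                                       folds = 4), seed = s)
      mean(predict(m, tab$X[sp$te, ])$labels == tab$y[sp$te])
    }, numeric(1))
  })
  mean_acc <- colMeans(accs)
  expect_true(mean_acc[2] >= mean_acc[1] - 0.05)
  expect_true(mean_acc[3] >= mean_acc[2] - 0.05)
})
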