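#' Balance classes by random down-sampling to a cap
#'
#' Each class keeps at most `cap` records, sampled without replacement with
#' the given seed; classes already at or below the cap are kept whole (with
#' a warning, since the result is then unbalanced). Default cap 150.
#'
#' @param manifest Data frame with a `label` column.
#' @param cap Maximum records per class (>= 1, default 150).
#' @param seed Integer seed.
#' @return The balanced manifest (rows grouped by class, classes in sorted
#'   order; deterministic given the seed).
#' @export
balance_classes <- function(manifest, cap = 150, seed = 0) {
  stopifnot(cap >= 1)
  if (is.null(manifest) || nrow(manifest) == 0) stop("empty manifest")
  set.seed(as.integer(seed))
  classes <- sort(unique(manifest$label))
  keep <- integer(0)
  short <- character(0)
  for (cl in classes) {
    idx <- which(manifest$label == cl)
    if (length(idx) > cap) {
      keep <- c(keep, sort(sample(idx, cap)))
    } else {
      if (length(idx) < cap) short <- c(short, cl)
      keep <- c(keep, idx)
    }
  }
  if (length(short))
    warning("classes below the cap retained whole: ",
            paste(short, collapse = ", "), call. = FALSE)
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_set") <- classes
  out
}

#' Fit a PCA model by eigendecomposition of the covariance matrix
#'
#' Columns are standardized (mean 0, sd 1; zero-variance columns get scale
#' 1), the covariance `C = X'X / (n - 1)` is eigendecomposed, and the top-k
#' eigenvectors form the projection. When `d > n` the n x n Gram matrix is
#' decomposed instead (same nonzero spectrum). Each eigenvector's sign is
#' fixed so its largest-magnitude entry is positive. `k` is either given or
#' the smallest number of components reaching `variance_threshold` of the
#' total variance, capped at `min(d, n - 1)`.
#'
#' @param X n x d numeric matrix (n >= 2, finite).
#' @param k Number of components, or NULL to use the threshold.
#' @param variance_threshold Cumulative variance fraction (default 0.95).
#' @param standardize Scale columns to unit variance before decomposition
#'   (default TRUE; FALSE centers only).
#' @return Object of class `pca_model`: `mean`, `scale`, `eigenvalues`
#'   (descending, clipped at 0), `components` (d x k, orthonormal), `k`,
#'   `retained_fraction`.
#' @export
fit_pca <- function(X, k = NULL, variance_threshold = 0.95,
                    standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 rows")
  if (any(!is.finite(X))) stop("non-finite entries in X")
  mu <- colMeans(X)
  sc <- if (standardize) {
    s <- apply(X, 2, stats::sd)
    s[s < 1e-12] <- 1
    s
  } else rep(1, d)
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  kmax <- min(d, n - 1)
  if (d <= n) {
    C <- crossprod(Xs) / (n - 1)
    eig <- eigen(C, symmetric = TRUE)
    lambda <- eig$values
    V <- eig$vectors
  } else {
    # Gram trick: X X'/(n-1) shares the nonzero spectrum with X'X/(n-1)
    G <- tcrossprod(Xs) / (n - 1)
    eig <- eigen(G, symmetric = TRUE)
    lambda <- eig$values[seq_len(kmax)]
    U <- eig$vectors[, seq_len(kmax), drop = FALSE]
    denom <- sqrt(pmax(lambda, 1e-300) * (n - 1))
    V <- crossprod(Xs, U) / matrix(denom, d, kmax, byrow = TRUE)
    nrm <- sqrt(colSums(V^2)); nrm[nrm < 1e-12] <- 1
    V <- V / matrix(nrm, d, kmax, byrow = TRUE)
  }
  lambda <- pmax(lambda, 0)
  if (is.null(k)) {
    stopifnot(variance_threshold > 0, variance_threshold <= 1)
    cumfrac <- cumsum(lambda) / sum(lambda)
    k <- which(cumfrac >= variance_threshold - 1e-12)[1]
    if (is.na(k)) k <- kmax
  }
  k <- min(k, kmax)
  W <- V[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {           # deterministic sign convention
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(X)
  structure(list(mean = mu, scale = sc, eigenvalues = lambda,
                 components = W, k = k,
                 retained_fraction = sum(lambda[seq_len(k)]) / sum(lambda),
                 standardize = standardize, d = d),
            class = "pca_model")
}

#' Project data through a fitted PCA model
#'
#' `Z = ((X - mu) / scale) W_k`.
#'
#' @param model A [fit_pca()] result.
#' @param X n x d matrix with d matching the model.
#' @return n x k score matrix.
#' @export
transform_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("X has ", ncol(X), " columns; model expects ", model$d)
  Z <- sweep(sweep(X, 2, model$mean), 2, model$scale, "/") %*% model$components
  colnames(Z) <- sprintf("pc%03d", seq_len(model$k))
  Z
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model: d =", x$d, "-> k =", x$k,
      sprintf("(%.1f%% variance retained)\n", 100 * x$retained_fraction))
  invisible(x)
}

#' Save / load a PCA model as a JSON sidecar
#'
#' @param model A `pca_model`.
#' @param path Output JSON path.
#' @export
save_pca <- function(model, path) {
  obj <- list(mean = model$mean, scale = model$scale,
              eigenvalues = model$eigenvalues,
              components = model$components, k = model$k,
              retained_fraction = model$retained_fraction,
              standardize = model$standardize, d = model$d)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pca
#' @export
load_pca <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$components <- as.matrix(obj$components)
  structure(obj, class = "pca_model")
}
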