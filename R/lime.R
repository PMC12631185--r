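#' Configuration for local surrogate explanations
#'
#' Tabular LIME: Gaussian perturbations around the instance (in standardized
#' units), an exponential locality kernel
#' `pi_x(z) = exp(-D(x, z)^2 / sigma^2)` with Euclidean distance D on
#' standardized features, hard K-sparsity plus a ridge penalty on the linear
#' surrogate.
#'
#' @param n_samples Number of perturbed samples N_s (>= 10, default 1000).
#' @param kernel_width Kernel width sigma; NULL means `0.75 * sqrt(d)` at
#'   explanation time.
#' @param n_features Number of features K retained in the surrogate
#'   (default 10, capped at d).
#' @param ridge Ridge penalty on the surrogate coefficients (default 1.0).
#' @param seed Integer seed.
#' @return Object of class `lime_config`.
#' @export
lime_config <- function(n_samples = 1000, kernel_width = NULL,
                        n_features = 10, ridge = 1.0, seed = 0) {
  stopifnot(n_samples >= 10, n_features >= 1, ridge >= 0)
  if (!is.null(kernel_width) && kernel_width <= 0)
    stop("kernel_width must be > 0")
  structure(list(n_samples = as.integer(n_samples),
                 kernel_width = kernel_width,
                 n_features = as.integer(n_features),
                 ridge = ridge, seed = as.integer(seed)),
            class = "lime_config")
}

#' Locality kernel weight
#'
#' `exp(-D(x, z)^2 / sigma^2)` with Euclidean D; equals 1 at `z = x` and
#' `exp(-1)` at distance sigma.
#'
#' @param x,z Numeric vectors of equal length.
#' @param sigma Kernel width (> 0).
#' @return Scalar weight in `(0, 1]`.
#' @export
kernel_weight <- function(x, z, sigma) {
  if (length(x) != length(z)) stop("x and z must have the same length")
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-sum((x - z)^2) / sigma^2)
}

#' Perturb an instance for local surrogate fitting
#'
#' Draws `n_samples` points `z ~ Normal(x, diag(sd^2))` (the first sample is
#' x itself) and computes locality weights from the kernel on standardized
#' distances `(z - x) / sd`.
#'
#' @param x Instance (length d).
#' @param stats List with `mean` and `sd` vectors of the training features
#'   (all `sd > 0`).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param sigma Kernel width (default `0.75 * sqrt(d)`).
#' @return List with `samples` (n_samples x d) and `weights`
#'   (length n_samples; first entry exactly 1).
#' @export
perturb_instance <- function(x, stats, n_samples, seed = 0, sigma = NULL) {
  d <- length(x)
  if (any(!is.finite(stats$sd)) || any(stats$sd <= 0))
    stop("degenerate feature sd")
  if (is.null(sigma)) sigma <- 0.75 * sqrt(d)
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(n_samples * d), n_samples, d) *
    matrix(stats$sd, n_samples, d, byrow = TRUE) +
    matrix(x, n_samples, d, byrow = TRUE)
  Z[1, ] <- x
  Du2 <- rowSums((sweep(Z, 2, x) / matrix(stats$sd, n_samples, d,
                                          byrow = TRUE))^2)
  w <- exp(-Du2 / sigma^2)
  colnames(Z) <- names(x)
  list(samples = Z, weights = w, sigma = sigma)
}

#' Explain one prediction with a sparse weighted linear surrogate
#'
#' Perturbs the instance, queries the black box for the target class
#' probability, selects the K features with the largest absolute
#' kernel-weighted covariance with the response (the sparsity part of the
#' surrogate's complexity penalty), and fits a kernel-weighted ridge
#' regression on the standardized selected features. Local fidelity is the
#' kernel-weighted R-squared of the surrogate.
#'
#' @param f Black-box function: `f(Z)` returns an n x m row-stochastic
#'   probability matrix with class columns (named, or indexable by
#'   `target_class`).
#' @param x Instance to explain (named length-d vector).
#' @param target_class Column of `f`'s output to explain.
#' @param cfg A [lime_config()].
#' @param stats List with training `mean` and `sd` per feature.
#' @param instance_id Optional identifier stored in the explanation.
#' @return Object of class `lime_explanation`: `instance_id`,
#'   `target_class`, `intercept`, `weights` (named, length K, sorted by
#'   absolute value), `fidelity`, `config`.
#' @export
explain_instance <- function(f, x, target_class, cfg = lime_config(),
                             stats, instance_id = NA) {
  d <- length(x)
  K <- min(cfg$n_features, d)
  sigma <- cfg$kernel_width %||% (0.75 * sqrt(d))
  pert <- perturb_instance(x, stats, cfg$n_samples, seed = cfg$seed,
                           sigma = sigma)
  probs <- f(pert$samples)
  if (is.character(target_class)) {
    if (!target_class %in% colnames(probs))
      stop("target class '", target_class, "' unknown to the classifier")
    y <- probs[, target_class]
  } else {
    if (target_class < 1 || target_class > ncol(probs))
      stop("target class index out of range")
    y <- probs[, target_class]
  }
  w <- pert$weights
  Zs <- sweep(sweep(pert$samples, 2, stats$mean), 2, stats$sd, "/")
  # kernel-weighted covariance screening for the K-sparse support
  wm <- sum(w)
  ybar <- sum(w * y) / wm
  zbar <- colSums(w * Zs) / wm
  covs <- colSums(w * sweep(Zs, 2, zbar) * (y - ybar)) / wm
  sel <- order(-abs(covs))[seq_len(K)]
  sel <- sort(sel)
  # weighted ridge on [1, Z_sel]; intercept unpenalized
  Xr <- cbind(1, Zs[, sel, drop = FALSE])
  A <- crossprod(Xr * w, Xr)
  diag(A)[-1] <- diag(A)[-1] + cfg$ridge
  beta <- solve(A, crossprod(Xr * w, y))
  yhat <- Xr %*% beta
  ss_res <- sum(w * (y - yhat)^2)
  ss_tot <- sum(w * (y - ybar)^2)
  fidelity <- if (ss_tot < 1e-300) 0 else 1 - ss_res / ss_tot
  weights <- beta[-1]
  names(weights) <- (names(x) %||% sprintf("f%03d", seq_len(d)))[sel]
  ord <- order(-abs(weights))
  structure(list(instance_id = instance_id, target_class = target_class,
                 intercept = beta[1], weights = weights[ord],
                 fidelity = fidelity,
                 config = list(n_samples = cfg$n_samples, sigma = sigma,
                               n_features = K, ridge = cfg$ridge,
                               seed = cfg$seed)),
            class = "lime_explanation")
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat("Local explanation (class ", x$target_class, ", fidelity ",
      sprintf("%.3f", x$fidelity), ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Write an explanation to JSON
#'
#' @param explanation A `lime_explanation`.
#' @param path Output path.
#' @export
write_explanation <- function(explanation, path) {
  obj <- unclass(explanation)
  obj$weights <- as.list(obj$weights)
  jsonlite::write_json(obj, path, digits = 10, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
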