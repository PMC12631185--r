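#' Backbone specification for deep feature extraction
#'
#' The pipeline's deep descriptor is the global-average-pooled output of a
#' convolutional feature extractor, `f_deep = GAP(phi(x; theta))`. The
#' mathematics downstream (fusion, PCA, stacking) is backbone-agnostic, so
#' the extractor is pluggable:
#' * `surrogate` — a seeded random-weight convolutional network (3 stride-2
#'   3x3 layers, ReLU by default) whose weights are a pure function of the
#'   seed; fully self-contained and deterministic.
#' * `external` — a user-supplied function `fun(img) -> numeric(output_dim)`
#'   adapting any pretrained network whose weights the user has.
#'
#' @param kind `"surrogate"` or `"external"`.
#' @param seed Integer seed (surrogate weights).
#' @param output_dim Deep feature dimension D (>= 1, default 64).
#' @param input_side Expected input side in pixels (default 224).
#' @param fun For `kind = "external"`: function of the image.
#' @param activation Surrogate hidden activation, `"relu"` or `"linear"`.
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(kind = c("surrogate", "external"), seed = 0,
                          output_dim = 64, input_side = 224, fun = NULL,
                          activation = c("relu", "linear")) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  stopifnot(output_dim >= 1, input_side >= 8)
  if (kind == "external" && !is.function(fun))
    stop("external backbone requires 'fun'")
  structure(list(kind = kind, seed = as.integer(seed),
                 output_dim = as.integer(output_dim),
                 input_side = as.integer(input_side), fun = fun,
                 activation = activation),
            class = "backbone_spec")
}

# 3x3 stride-2 same-padded convolution via patch matrix multiplication
conv3x3_s2 <- function(x, weights, bias) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Ho <- floor((H - 1) / 2) + 1; Wo <- floor((W - 1) / 2) + 1
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  rows <- seq(1, H, by = 2); cols <- seq(1, W, by = 2)
  patch <- matrix(0, Ho * Wo, 9 * Cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) for (ch in seq_len(Cin)) {
    k <- k + 1L
    patch[, k] <- as.vector(xp[rows + di, cols + dj, ch])
  }
  out <- patch %*% weights + matrix(bias, Ho * Wo, length(bias), byrow = TRUE)
  array(out, c(Ho, Wo, length(bias)))
}

surrogate_weights <- function(seed, channels_in, channels_out) {
  # He-style scaling keeps activations in a stable range through the stack
  lapply(seq_along(channels_out), function(l) {
    fan_in <- 9 * channels_in[l]
    w <- matrix(rnorm(fan_in * channels_out[l], 0, sqrt(2 / fan_in)),
                fan_in, channels_out[l])
    list(w = w, b = numeric(channels_out[l]))
  })
}

#' Deep features by global average pooling of convolutional maps
#'
#' Runs the backbone on the (resized) image and reduces the final feature
#' maps by global average pooling: the mean over spatial positions of each
#' channel, giving a fixed-length D-vector.
#'
#' @param img `input_side x input_side x 3` numeric array, 0-255.
#' @param backbone A [backbone_spec()].
#' @return Named numeric vector of length `output_dim`.
#' @export
deep_features <- function(img, backbone) {
  stopifnot(inherits(backbone, "backbone_spec"))
  d <- dim(img)
  if (length(d) != 3L || d[1] != backbone$input_side ||
      d[2] != backbone$input_side || d[3] != 3L)
    stop("image must be ", backbone$input_side, "x", backbone$input_side,
         "x3; got ", paste(d, collapse = "x"))
  if (backbone$kind == "external") {
    v <- as.numeric(backbone$fun(img))
    if (length(v) != backbone$output_dim)
      stop("external backbone returned length ", length(v),
           ", expected ", backbone$output_dim)
  } else {
    set.seed(backbone$seed)
    ch_in <- c(3L, 16L, 32L)
    ch_out <- c(16L, 32L, backbone$output_dim)
    layers <- surrogate_weights(backbone$seed, ch_in, ch_out)
    x <- img / 255
    for (l in seq_along(layers)) {
      x <- conv3x3_s2(x, layers[[l]]$w, layers[[l]]$b)
      if (backbone$activation == "relu" && l < length(layers))
        x <- pmax(x, 0)
    }
    v <- apply(x, 3, mean)  # global average pooling
  }
  names(v) <- sprintf("deep.%03d", seq_along(v) - 1L)
  v
}

#' Fuse handcrafted and deep feature vectors
#'
#' Ordered concatenation with the handcrafted block first:
#' `F = [f_traditional || f_deep]`. An empty deep vector (D = 0) is allowed
#' for ablation and returns the handcrafted vector unchanged.
#'
#' @param f_trad Handcrafted feature vector (finite).
#' @param f_deep Deep feature vector (finite; may be length 0).
#' @return Named numeric vector of length `length(f_trad) + length(f_deep)`
#'   with attribute `block_boundary` (index of the last handcrafted entry).
#' @export
fuse <- function(f_trad, f_deep) {
  if (any(!is.finite(f_trad)) || (length(f_deep) && any(!is.finite(f_deep))))
    stop("non-finite entries in feature vectors")
  out <- c(f_trad, f_deep)
  attr(out, "block_boundary") <- length(f_trad)
  out
}

#' Fused feature matrix for a manifest of images
#'
#' Convenience driver: reads each manifest image, extracts the handcrafted
#' vector and the deep vector, and fuses them row-wise.
#'
#' @param manifest Data frame `(path, label)`; paths relative to `base_dir`.
#' @param base_dir Directory the manifest paths are relative to.
#' @param backbone A [backbone_spec()] (or NULL to skip deep features).
#' @param params Handcrafted parameter overrides (see
#'   [extract_handcrafted()]).
#' @return List with `X` (n x d fused matrix, block-prefixed column names),
#'   `y` (labels), `block_boundary`.
#' @export
fuse_manifest <- function(manifest, base_dir, backbone = backbone_spec(),
                          params = list()) {
  n <- nrow(manifest)
  stopifnot(n >= 1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(base_dir, manifest$path[i])) * 255
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    f_trad <- extract_handcrafted(img, params)
    f_deep <- if (is.null(backbone)) numeric(0) else {
      side <- backbone$input_side
      deep_features(resize_image(img, side), backbone)
    }
    rows[[i]] <- fuse(f_trad, f_deep)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- manifest$path
  list(X = X, y = manifest$label,
       block_boundary = attr(rows[[1]], "block_boundary"))
}
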