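#' Class specification for synthetic leaf images
#'
#' Describes one disease category of the synthetic image generator: a flat
#' elliptical "leaf" of `base_color` on a uniform background, carrying a
#' class-dependent number of circular lesions of `lesion_color`, plus additive
#' Gaussian texture noise restricted to the leaf region. This emulates the
#' controlled-condition imagery the pipeline targets: single leaves, uniform
#' background, disease expressed as discoloration, spotting and texture.
#'
#' @param name Class label (character scalar).
#' @param base_color RGB triple in 0-255, healthy leaf tissue color.
#' @param lesion_count_range Integer interval `c(lo, hi)`, `0 <= lo <= hi`.
#' @param lesion_color RGB triple in 0-255.
#' @param lesion_radius_range Pixel interval `c(lo, hi)` for lesion radii.
#' @param texture_noise_sd Gray-level standard deviation (>= 0) of the
#'   additive per-channel noise applied inside the leaf.
#' @param eccentricity Eccentricity of the leaf ellipse in `[0, 1)`; the minor
#'   semi-axis is `a * sqrt(1 - e^2)`.
#' @param background_color RGB triple in 0-255 (default dark gray so that
#'   foreground segmentation is well-posed).
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(name, base_color, lesion_count_range, lesion_color,
                       lesion_radius_range, texture_noise_sd = 0,
                       eccentricity = 0.6, background_color = c(40, 40, 40)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_rgb <- function(x, what) {
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) || any(x > 255))
      stop(what, " must be an RGB triple in [0, 255]", call. = FALSE)
    as.numeric(x)
  }
  base_color <- check_rgb(base_color, "base_color")
  lesion_color <- check_rgb(lesion_color, "lesion_color")
  background_color <- check_rgb(background_color, "background_color")
  stopifnot(length(lesion_count_range) == 2L, lesion_count_range[1] >= 0,
            lesion_count_range[1] <= lesion_count_range[2])
  stopifnot(length(lesion_radius_range) == 2L, lesion_radius_range[1] > 0,
            lesion_radius_range[1] <= lesion_radius_range[2])
  stopifnot(texture_noise_sd >= 0)
  if (!(eccentricity >= 0 && eccentricity < 1))
    stop("eccentricity must lie in [0, 1)", call. = FALSE)
  structure(list(
    name = name, base_color = base_color,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_color = lesion_color,
    lesion_radius_range = as.numeric(lesion_radius_range),
    texture_noise_sd = as.numeric(texture_noise_sd),
    eccentricity = as.numeric(eccentricity),
    background_color = background_color
  ), class = "class_spec")
}

#' Default synthetic disease classes
#'
#' A palette of up to 15 leaf disease categories differing in base hue,
#' lesion color/count/size, texture noise and leaf elongation, loosely
#' following common foliar disease phenotypes (spots, blights, molds, rusts,
#' mosaics, mites, healthy tissue).
#'
#' @param n Number of classes (1-15).
#' @return List of [class_spec()] objects.
#' @export
default_class_specs <- function(n = 15) {
  stopifnot(n >= 1, n <= 15)
  tab <- list(
    #     name               base          n_lesions  lesion col     rad     noise  ecc
    list("healthy",          c( 60,150, 60), c(0, 0),  c( 60,150,60), c(4, 8),  3, 0.55),
    list("bacterial_spot",   c( 70,140, 55), c(6,12),  c( 70, 50,25), c(3, 6),  6, 0.60),
    list("early_blight",     c( 85,135, 50), c(3, 7),  c(110, 80,30), c(6,12),  8, 0.65),
    list("late_blight",      c( 55,120, 60), c(2, 5),  c( 60, 45,40), c(10,18), 10, 0.60),
    list("leaf_mold",        c( 90,150, 70), c(4, 9),  c(150,140,60), c(5,10),  7, 0.50),
    list("septoria_spot",    c( 75,145, 65), c(8,16),  c(120,110,90), c(2, 5),  5, 0.70),
    list("spider_mites",     c(110,140, 70), c(0, 2),  c(130,110,60), c(3, 6), 14, 0.62),
    list("target_spot",      c( 80,130, 55), c(3, 6),  c( 90, 70,45), c(8,14),  6, 0.58),
    list("mosaic_virus",     c(120,160, 60), c(5,10),  c(170,180,80), c(6,11),  9, 0.55),
    list("yellow_curl",      c(140,160, 55), c(0, 1),  c(180,170,70), c(5, 9), 12, 0.80),
    list("powdery_mildew",   c( 95,155, 75), c(6,12),  c(200,200,190), c(4, 8),  5, 0.52),
    list("cercospora_spot",  c( 65,125, 55), c(5,10),  c( 95, 60,50), c(3, 7),  7, 0.66),
    list("common_rust",      c( 85,140, 60), c(10,18), c(140, 70,35), c(2, 4),  6, 0.74),
    list("northern_blight",  c( 70,130, 65), c(2, 4),  c(115, 95,60), c(12,20),  9, 0.78),
    list("black_rot",        c( 90,145, 60), c(4, 8),  c( 45, 35,30), c(5,10),  8, 0.60)
  )
  lapply(tab[seq_len(n)], function(r)
    class_spec(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]],
               texture_noise_sd = r[[6]], eccentricity = r[[7]]))
}

#' Generate one synthetic leaf image
#'
#' Renders a centered ellipse of `base_color` on `background_color`, draws the
#' sampled number of non-overlapping circular lesions fully inside the leaf,
#' then adds seeded Gaussian noise to the leaf region (texture). All
#' randomness is a pure function of `(spec, seed)`.
#'
#' @param spec A [class_spec()].
#' @param seed Integer seed.
#' @param side Image side in pixels (square output; default 256).
#' @return `side x side x 3` numeric array of 8-bit RGB values (0-255), with
#'   attributes `lesions` (data frame of centers/radii) and `leaf_mask`.
#' @export
generate_leaf_image <- function(spec, seed, side = 256) {
  stopifnot(inherits(spec, "class_spec"), side >= 32)
  set.seed(as.integer(seed))
  a <- 0.40 * side                       # semi-major axis
  b <- a * sqrt(1 - spec$eccentricity^2) # semi-minor axis
  if (max(spec$lesion_radius_range) >= b)
    stop("lesion radius (", max(spec$lesion_radius_range),
         ") exceeds leaf minor semi-axis (", round(b, 1), ")", call. = FALSE)
  theta <- runif(1, -pi / 8, pi / 8)     # leaf orientation
  cx <- side / 2; cy <- side / 2
  rr <- matrix(seq_len(side), side, side)        # row index
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  u <- (cc - cx) * cos(theta) + (rr - cy) * sin(theta)
  v <- -(cc - cx) * sin(theta) + (rr - cy) * cos(theta)
  leaf <- (u / a)^2 + (v / b)^2 <= 1

  img <- array(0, c(side, side, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_color[ch], side, side)
    plane[leaf] <- spec$base_color[ch]
    img[, , ch] <- plane
  }

  lo <- spec$lesion_count_range[1]; hi <- spec$lesion_count_range[2]
  n_les <- lo + (if (hi > lo) sample.int(hi - lo + 1L, 1L) - 1L else 0L)
  lesions <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (n_les > 0) {
    for (i in seq_len(n_les)) {
      placed <- FALSE
      for (try in 1:300) {
        rad <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        # sample center in unrotated ellipse coords, shrunk so the whole
        # disk stays inside the leaf
        su <- runif(1, -1, 1) * (a - rad - 1)
        sv <- runif(1, -1, 1) * (b - rad - 1)
        if ((su / (a - rad - 1))^2 + (sv / (b - rad - 1))^2 > 1) next
        pc <- cx + su * cos(theta) - sv * sin(theta)
        pr <- cy + su * sin(theta) + sv * cos(theta)
        if (nrow(lesions) > 0 &&
            any(sqrt((lesions$row - pr)^2 + (lesions$col - pc)^2) <
                lesions$radius + rad + 1)) next
        lesions <- rbind(lesions, data.frame(row = pr, col = pc, radius = rad))
        disk <- (rr - pr)^2 + (cc - pc)^2 <= rad^2
        for (ch in 1:3) {
          plane <- img[, , ch]; plane[disk] <- spec$lesion_color[ch]
          img[, , ch] <- plane
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place lesion ", i, " without overlap", call. = FALSE)
    }
  }

  if (spec$texture_noise_sd > 0) {
    n_fg <- sum(leaf)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[leaf] <- plane[leaf] + rnorm(n_fg, 0, spec$texture_noise_sd)
      img[, , ch] <- plane
    }
  }
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "lesions") <- lesions
  attr(img, "leaf_mask") <- leaf
  img
}

#' Generate a synthetic leaf-image dataset on disk
#'
#' Writes one 8-bit RGB PNG per image plus a `manifest.csv` with header
#' `path,label` (paths relative to the manifest). Per-image seeds are derived
#' deterministically from the master seed and the (class, image) indices, so
#' regeneration with the same arguments is byte-identical.
#'
#' @param specs List of [class_spec()] (>= 2).
#' @param n_per_class Images per class (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param side Image side in pixels.
#' @return The manifest as a data frame `(path, label)` with attribute
#'   `class_set`; also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(specs, n_per_class, out_dir, seed, side = 256) {
  stopifnot(length(specs) >= 2, n_per_class >= 1)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", length(specs) * n_per_class)
  k <- 0L
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (ii in seq_len(n_per_class)) {
      img <- generate_leaf_image(spec, derive_seed(seed, ci, ii), side = side)
      fname <- sprintf("%s_%03d.png", spec$name, ii)
      png::writePNG(img / 255, file.path(out_dir, fname))
      k <- k + 1L
      rows[[k]] <- data.frame(path = fname, label = spec$name,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "class_set") <- sort(unique(manifest$label))
  manifest
}

#' Read / write a dataset manifest
#'
#' The manifest is a UTF-8 CSV with header `path,label`; paths are relative
#' to the manifest's directory.
#'
#' @param path CSV file path.
#' @return `read_manifest`: data frame `(path, label)` with attribute
#'   `class_set`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have columns 'path' and 'label'")
  if (nrow(m) == 0) stop("empty manifest")
  if (anyDuplicated(m$path)) stop("manifest paths must be unique")
  attr(m, "class_set") <- sort(unique(m$label))
  m
}

#' @rdname read_manifest
#' @param manifest Data frame `(path, label)`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("path", "label")], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a synthetic labeled feature table
#'
#' Draws `n_per_class` points per class from spherical Gaussians whose
#' class means sit `separation * noise_sd` apart (pairwise, exactly when
#' `n_classes <= dim`: means are placed on distinct coordinate axes at
#' distance `separation * noise_sd / sqrt(2)` from the origin). This is the
#' statistical stand-in for a reduced feature matrix with a tunable class
#' signal: `separation = 0` carries no signal at all.
#'
#' @param n_per_class Points per class (>= 1).
#' @param n_classes Number of classes m (>= 1).
#' @param dim Feature dimension d (>= 1).
#' @param separation Distance between class means in noise-sd units (>= 0).
#' @param noise_sd Per-feature standard deviation (> 0).
#' @param seed Integer seed.
#' @return List with `X` (n x d matrix, n = n_per_class * m), `y` (character
#'   labels), and `means` (m x d design means).
#' @export
generate_feature_table <- function(n_per_class, n_classes, dim, separation,
                                   noise_sd = 1, seed = 1) {
  stopifnot(n_per_class >= 1, n_classes >= 1, dim >= 1,
            separation >= 0, noise_sd > 0)
  set.seed(as.integer(seed))
  scale <- separation * noise_sd / sqrt(2)
  means <- matrix(0, n_classes, dim)
  if (n_classes <= dim) {
    for (c in seq_len(n_classes)) means[c, c] <- scale
  } else {
    # more classes than dimensions: random unit directions (approximate
    # pairwise spacing only)
    for (c in seq_len(n_classes)) {
      v <- rnorm(dim)
      means[c, ] <- scale * v / sqrt(sum(v^2))
    }
  }
  n <- n_per_class * n_classes
  X <- matrix(0, n, dim)
  y <- character(n)
  labels <- sprintf("class%02d", seq_len(n_classes))
  for (c in seq_len(n_classes)) {
    idx <- ((c - 1) * n_per_class + 1):(c * n_per_class)
    X[idx, ] <- matrix(rnorm(n_per_class * dim, 0, noise_sd),
                       n_per_class, dim) +
      matrix(means[c, ], n_per_class, dim, byrow = TRUE)
    y[idx] <- labels[c]
  }
  colnames(X) <- sprintf("f%03d", seq_len(dim))
  list(X = X, y = y, means = means)
}
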