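#' Resize an RGB image
#'
#' Plain bilinear rescale to a square side (aspect ratio not preserved), the
#' preprocessing step every descriptor shares. Default side is 224 pixels.
#'
#' @param img H x W x 3 numeric array, values 0-255.
#' @param side Output side in pixels (>= 1).
#' @return `side x side x 3` numeric array, 0-255.
#' @export
resize_image <- function(img, side = 224) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (side < 1) stop("side must be >= 1")
  if (dim(img)[1] == side && dim(img)[2] == side) return(img)
  out <- EBImage::resize(EBImage::Image(img / 255, colormode = "Color"),
                         w = side, h = side, filter = "bilinear")
  pmin(pmax(EBImage::imageData(out) * 255, 0), 255)
}

#' Convert RGB to grayscale (BT.601 luma)
#'
#' @param img H x W x 3 numeric array, 0-255.
#' @return H x W matrix of intensities in `[0, 1]`.
#' @export
to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
}

# map pixel matrix (n x 3, 0-255) into the named color space with each
# channel on [0, 1]
convert_pixels <- function(px, space) {
  if (space == "hsv") {
    t(grDevices::rgb2hsv(t(px), maxColorValue = 255))
  } else if (space == "lab") {
    lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
    out <- cbind(lab[, 1] / 100, (lab[, 2] + 128) / 255, (lab[, 3] + 128) / 255)
    pmin(pmax(out, 0), 1)
  } else stop("unknown color space: ", space)
}

#' Per-channel color histogram in HSV or LAB space
#'
#' Counts pixels into `bins` equal-width bins per channel after mapping each
#' channel to `[0, 1]` (HSV channels are natively 0-1; LAB uses L/100 and
#' (a|b + 128)/255). Un-normalized, each channel's counts sum to the pixel
#' count; normalized, each channel block sums to 1.
#'
#' @param img H x W x 3 numeric array, 0-255.
#' @param space `"hsv"` or `"lab"`.
#' @param bins Bins per channel B (>= 1, default 8).
#' @param normalize Normalize each channel block to sum 1 (default TRUE).
#' @return Named numeric vector of length `3 * bins`.
#' @export
color_histogram <- function(img, space = c("hsv", "lab"), bins = 8,
                            normalize = TRUE) {
  space <- match.arg(space)
  stopifnot(bins >= 1)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  conv <- convert_pixels(px, space)
  out <- numeric(0)
  ch_names <- list(hsv = c("h", "s", "v"), lab = c("l", "a", "b"))[[space]]
  for (ch in 1:3) {
    b <- pmin(floor(conv[, ch] * bins), bins - 1)
    h <- tabulate(b + 1L, nbins = bins)
    if (normalize) h <- h / sum(h)
    names(h) <- sprintf("%s.%s.%02d", space, ch_names[ch], seq_len(bins) - 1L)
    out <- c(out, h)
  }
  out
}

# k-means++ seeding on a pixel matrix; returns k initial centers
kmeanspp_init <- function(px, k) {
  n <- nrow(px)
  centers <- matrix(0, k, ncol(px))
  centers[1, ] <- px[sample.int(n, 1L), ]
  d2 <- rowSums((px - matrix(centers[1, ], n, ncol(px), byrow = TRUE))^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- px[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums((px - matrix(centers[j, ], n, ncol(px), byrow = TRUE))^2))
  }
  centers
}

#' Dominant colors by k-means clustering of RGB pixels
#'
#' Lloyd's algorithm (k-means++ seeding) on the raw RGB triples; clusters are
#' returned in descending size order (ties broken lexicographically on the
#' centroid), so the first centroid is "the dominant color". Images with at
#' most `k` distinct colors are solved exactly (each distinct color is its
#' own centroid; unused centroids replicate the dominant color with
#' proportion 0).
#'
#' @param img H x W x 3 numeric array, 0-255.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the (stochastic) initialization.
#' @return List with `centroids` (k x 3 RGB matrix, size-descending),
#'   `proportions` (length k, sums to 1) and `objective` (total
#'   within-cluster sum of squares).
#' @export
dominant_colors <- function(img, k = 3, seed = 0) {
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  n <- nrow(px)
  if (n < k) stop("image must have at least k pixels")
  uni <- unique(px)
  if (nrow(uni) <= k) {
    # exact optimum: one centroid per distinct color, zero within-cluster SS
    cnt <- integer(nrow(uni))
    key_px <- px[, 1] * 1e6 + px[, 2] * 1e3 + px[, 3]
    key_un <- uni[, 1] * 1e6 + uni[, 2] * 1e3 + uni[, 3]
    for (i in seq_len(nrow(uni))) cnt[i] <- sum(key_px == key_un[i])
    ord <- order(-cnt, uni[, 1], uni[, 2], uni[, 3])
    uni <- uni[ord, , drop = FALSE]; cnt <- cnt[ord]
    centroids <- matrix(uni[1, ], k, 3, byrow = TRUE)
    props <- numeric(k)
    centroids[seq_len(nrow(uni)), ] <- uni
    props[seq_len(nrow(uni))] <- cnt / n
    colnames(centroids) <- c("r", "g", "b")
    return(list(centroids = centroids, proportions = props, objective = 0))
  }
  set.seed(as.integer(seed))
  init <- kmeanspp_init(px, k)
  fit <- tryCatch(
    stats::kmeans(px, centers = init, iter.max = 100, algorithm = "Lloyd"),
    error = function(e) stats::kmeans(px, centers = k, iter.max = 100,
                                      nstart = 5)
  )
  ord <- order(-fit$size, fit$centers[, 1], fit$centers[, 2], fit$centers[, 3])
  centroids <- fit$centers[ord, , drop = FALSE]
  dimnames(centroids) <- list(NULL, c("r", "g", "b"))
  list(centroids = centroids, proportions = fit$size[ord] / n,
       objective = fit$tot.withinss)
}

#' Local binary pattern histogram
#'
#' For every pixel with a complete neighborhood, the LBP code compares each
#' of the P ring neighbors (integer offsets at radius R, counter-clockwise
#' starting from the right neighbor) to the center:
#' `code = sum_p s(g_p - g_c) 2^p` with `s(z) = 1` iff `z >= 0`. The
#' histogram runs over codes `0 .. 2^P - 1`.
#'
#' @param gray H x W matrix in `[0, 1]`.
#' @param P Neighbors (only the canonical 8 supported).
#' @param R Integer radius (default 1).
#' @param normalize Normalize the histogram to sum 1 (default TRUE).
#' @return Named numeric vector of length `2^P`.
#' @export
lbp_histogram <- function(gray, P = 8, R = 1, normalize = TRUE) {
  stopifnot(is.matrix(gray), P == 8, R >= 1)
  H <- nrow(gray); W <- ncol(gray)
  if (H <= 2 * R || W <= 2 * R) stop("image too small for LBP radius ", R)
  # counter-clockwise from (row, col + R); rows grow downward
  offs <- R * rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                    c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  ri <- (R + 1):(H - R); ci <- (R + 1):(W - R)
  center <- gray[ri, ci]
  code <- matrix(0, length(ri), length(ci))
  for (p in 1:8) {
    nb <- gray[ri + offs[p, 1], ci + offs[p, 2]]
    code <- code + (nb >= center) * 2^(p - 1)
  }
  h <- tabulate(as.vector(code) + 1L, nbins = 2^P)
  if (normalize) h <- h / sum(h)
  names(h) <- sprintf("lbp.%03d", 0:(2^P - 1))
  h
}

#' Gray-level co-occurrence contrast and angular second moment
#'
#' Quantizes intensities to `levels` gray levels
#' (`min(floor(g * L), L - 1)`), accumulates the co-occurrence matrix at the
#' given pixel distance for each angle, symmetrizes, normalizes to a
#' probability table P(i, j), and computes
#' `contrast = sum (i - j)^2 P(i, j)` and `ASM = sum P(i, j)^2`, averaged
#' over the angles.
#'
#' @param gray H x W matrix in `[0, 1]`.
#' @param levels Gray levels L (>= 2, default 8).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @param distance Pixel offset distance (default 1).
#' @param symmetric Add the transposed counts (default TRUE).
#' @return Named numeric vector `c(contrast, asm)`.
#' @export
glcm_features <- function(gray, levels = 8, angles = c(0, 45, 90, 135),
                          distance = 1, symmetric = TRUE) {
  stopifnot(is.matrix(gray), nrow(gray) >= 2, ncol(gray) >= 2)
  if (levels < 2) stop("levels must be >= 2")
  stopifnot(all(angles %in% c(0, 45, 90, 135)))
  q <- pmin(floor(gray * levels), levels - 1)
  H <- nrow(q); W <- ncol(q)
  d <- distance
  shift <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
  ii <- rep(0:(levels - 1), times = levels)
  jj <- rep(0:(levels - 1), each = levels)
  con <- asm <- numeric(length(angles))
  for (a in seq_along(angles)) {
    s <- shift[[as.character(angles[a])]]
    r0 <- max(1, 1 - s[1]):min(H, H - s[1])
    c0 <- max(1, 1 - s[2]):min(W, W - s[2])
    from <- q[r0, c0]
    to <- q[r0 + s[1], c0 + s[2]]
    idx <- as.vector(from) * levels + as.vector(to) + 1L
    cooc <- tabulate(idx, nbins = levels^2)
    if (symmetric) {
      rev_idx <- as.vector(to) * levels + as.vector(from) + 1L
      cooc <- cooc + tabulate(rev_idx, nbins = levels^2)
    }
    p <- cooc / sum(cooc)
    con[a] <- sum((ii - jj)^2 * p)
    asm[a] <- sum(p^2)
  }
  c(contrast = mean(con), asm = mean(asm))
}

#' Segment the leaf from a uniform background
#'
#' Otsu-thresholds the grayscale image; the foreground is the binary class
#' with fewer border-touching pixels (robust to contrast inversion); then
#' the largest 8-connected component is kept and interior holes are filled.
#'
#' @param img H x W x 3 numeric array, 0-255.
#' @return Logical H x W matrix (TRUE = leaf).
#' @export
segment_leaf <- function(img) {
  g <- to_gray(img)
  if (diff(range(g)) < 1e-12)
    stop("unsegmentable input: constant image has no threshold", call. = FALSE)
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  fg <- g > th
  border <- function(m) sum(m[1, ]) + sum(m[nrow(m), ]) +
    sum(m[, 1]) + sum(m[, ncol(m)])
  if (border(fg) > border(!fg)) fg <- !fg
  lab <- label_components8(fg)
  if (max(lab) == 0) stop("unsegmentable input: empty foreground", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(keep * 1))
  EBImage::imageData(filled) > 0.5
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel) plus a
# union-find merge of labels adjacent along either diagonal
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nl <- max(lab)
  if (nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Shape descriptors of a binary mask
#'
#' Area A is the foreground pixel count; perimeter P is a sub-pixel estimate
#' of the outer contour length at the 0.5 level: the Moore-traced boundary
#' polygon is smoothed with a short circular moving average (removing the
#' rasterization staircase, which would otherwise inflate the length of
#' oblique arcs by up to 8%) and offset by half a pixel outward (`+ pi` for
#' a closed curve). Circularity is `C = 4 pi A / P^2` (1 for an ideal disk).
#'
#' @param mask Logical H x W matrix.
#' @return Named numeric vector `c(area, perimeter, circularity)`.
#' @export
shape_descriptors <- function(mask) {
  stopifnot(is.matrix(mask))
  A <- sum(mask)
  if (A == 0) stop("empty mask", call. = FALSE)
  P <- contour_perimeter(mask)
  c(area = A, perimeter = P, circularity = 4 * pi * A / P^2)
}

# boundary trace of the outer contour by radial sweep: from each boundary
# pixel, the next one is the first foreground 8-neighbor found scanning
# clockwise starting just past the direction of the previous pixel
moore_trace <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- matrix(FALSE, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- mask
  fg <- which(m, arr.ind = TRUE)
  start <- fg[order(fg[, 1], fg[, 2])[1], ]
  # clockwise neighborhood, starting north
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  limit <- 4L * sum(m) + 8L
  path <- matrix(NA_real_, limit, 2)
  np <- 1L
  path[1, ] <- start
  p <- start
  back_dir <- 7L   # virtual previous pixel: west of start (background)
  first <- NULL
  repeat {
    move <- 0L
    for (s in 1:8) {
      k <- ((back_dir + s - 1L) %% 8L) + 1L
      q <- p + dirs[k, ]
      if (m[q[1], q[2]]) { move <- k; break }
    }
    if (move == 0L) return(path[1, , drop = FALSE])  # isolated pixel
    if (is.null(first)) {
      first <- c(p, move)
    } else if (all(c(p, move) == first)) {
      return(path[seq_len(np - 1L), , drop = FALSE])
    }
    q <- p + dirs[move, ]
    np <- np + 1L
    if (np > limit) return(path[seq_len(np - 1L), , drop = FALSE])
    path[np, ] <- q
    back_dir <- which(dirs[, 1] == p[1] - q[1] & dirs[, 2] == p[2] - q[2])
    p <- q
  }
}

# sub-pixel outer-contour length: smoothed Moore trace plus the half-pixel
# outward offset of the 0.5-level crack boundary (adds 2*pi*0.5 on a closed
# curve); tiny shapes fall back to the raw marching-squares length
contour_perimeter <- function(mask) {
  pts <- moore_trace(mask)
  n <- nrow(pts)
  if (n < 8) return(marching_squares_perimeter(mask))
  w <- 5L
  idx <- function(sh) ((seq_len(n) - 1L + sh) %% n) + 1L
  sm <- pts
  for (sh in c(-2L, -1L, 1L, 2L)) sm <- sm + pts[idx(sh), ]
  sm <- sm / w
  d <- sm[idx(1L), ] - sm
  sum(sqrt(rowSums(d^2))) + pi
}

# total length of the 0.5-level contour of a binary image via marching
# squares; binary values put every crossing at an edge midpoint
marching_squares_perimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]  # top-left corner of each 2x2 cell
  b <- m[-nr, -1]   # top-right
  cc <- m[-1, -1]   # bottom-right
  d <- m[-1, -nc]   # bottom-left
  case <- a + 2 * b + 4 * cc + 8 * d
  s <- sqrt(2) / 2
  lens <- c(0, s, s, 1, s, 2 * s, 1, s, s, 1, 2 * s, s, 1, s, s, 0)
  sum(lens[case + 1])
}

handcrafted_default_params <- function() {
  list(side = 224, bins = 8, lbp_p = 8, lbp_r = 1, glcm_levels = 8,
       k_dominant = 3, seed = 0)
}

#' Extract the full handcrafted feature vector
#'
#' Resizes the image, then concatenates, in fixed order: HSV histogram
#' (3B), LAB histogram (3B), dominant colors (3 RGB centroids scaled to
#' 0-1 + 3 proportions = 12), LBP histogram (2^P), GLCM contrast + ASM (2),
#' and shape area/perimeter/circularity (3). With defaults (B = 8, P = 8)
#' the dimension is 24 + 24 + 12 + 256 + 2 + 3 = 321. If the image cannot be
#' segmented the shape block is zero with a warning (batch robustness).
#'
#' @param img H x W x 3 numeric array, 0-255.
#' @param params List overriding [handcrafted_default_params()]: `side`,
#'   `bins`, `lbp_p`, `lbp_r`, `glcm_levels`, `k_dominant`, `seed`.
#' @return Named numeric vector with attribute `blocks` (named block
#'   lengths, in order) and attribute `segmentation_failed` (logical).
#' @export
extract_handcrafted <- function(img, params = list()) {
  p <- utils::modifyList(handcrafted_default_params(), params)
  img <- resize_image(img, p$side)
  hsv <- color_histogram(img, "hsv", bins = p$bins, normalize = TRUE)
  lab <- color_histogram(img, "lab", bins = p$bins, normalize = TRUE)
  dom <- dominant_colors(img, k = p$k_dominant, seed = p$seed)
  dom_v <- c(as.vector(t(dom$centroids)) / 255, dom$proportions)
  names(dom_v) <- c(sprintf("dom.c%d.%s", rep(seq_len(p$k_dominant), each = 3),
                            rep(c("r", "g", "b"), p$k_dominant)),
                    sprintf("dom.prop%d", seq_len(p$k_dominant)))
  g <- to_gray(img)
  lbp <- lbp_histogram(g, P = p$lbp_p, R = p$lbp_r, normalize = TRUE)
  glcm <- glcm_features(g, levels = p$glcm_levels)
  names(glcm) <- c("glcm.contrast", "glcm.asm")
  seg_failed <- FALSE
  shp <- tryCatch(shape_descriptors(segment_leaf(img)), error = function(e) {
    seg_failed <<- TRUE
    warning("segmentation failed; shape block set to zero: ",
            conditionMessage(e), call. = FALSE)
    c(area = 0, perimeter = 0, circularity = 0)
  })
  names(shp) <- c("shape.area", "shape.perimeter", "shape.circularity")
  out <- c(hsv, lab, dom_v, lbp, glcm, shp)
  attr(out, "blocks") <- c(hsv = length(hsv), lab = length(lab),
                           dominant = length(dom_v), lbp = length(lbp),
                           glcm = length(glcm), shape = length(shp))
  attr(out, "segmentation_failed") <- seg_failed
  out
}
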