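test_that("resize produces the requested side and preserves constants", {
  img <- generate_leaf_image(flat_leaf_spec(), 1, side = 256)
  out <- resize_image(img, 224)
  expect_equal(dim(out), c(224, 224, 3))
  same <- resize_image(out, 224)
  expect_equal(dim(same), c(224, 224, 3))
  flat <- make_flat_image(c(10, 200, 30), 64, 64)
  rs <- resize_image(flat, 48)
  for (ch in 1:3) expect_equal(range(rs[, , ch]), rep(c(10, 200, 30)[ch], 2),
                               tolerance = 1e-9)
  expect_error(resize_image(flat, 0), "side")
})

test_that("color histograms conserve pixel counts for any image and bin count", {
  set.seed(4)
  img <- array(sample(0:255, 3 * 19 * 23, replace = TRUE), c(19, 23, 3))
  for (space in c("hsv", "lab")) for (B in c(4, 8, 13)) {
    h <- color_histogram(img, space, bins = B, normalize = FALSE)
    expect_length(h, 3 * B)
    for (ch in 1:3)
      expect_equal(sum(h[((ch - 1) * B + 1):(ch * B)]), 19 * 23)
    hn <- color_histogram(img, space, bins = B, normalize = TRUE)
    for (ch in 1:3)
      expect_equal(sum(hn[((ch - 1) * B + 1):(ch * B)]), 1)
  }
})

test_that("constant image concentrates each channel histogram in one bin", {
  img <- make_flat_image(c(37, 142, 201))
  for (space in c("hsv", "lab")) {
    h <- color_histogram(img, space, bins = 8, normalize = FALSE)
    for (ch in 1:3)
      expect_equal(sum(h[((ch - 1) * 8 + 1):(ch * 8)] > 0), 1)
  }
})

test_that("HSV histogram of a four-pixel image matches hand enumeration", {
  # 2x2 image: three pure-red pixels, one pure-blue
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- matrix(c(255, 255, 255, 0), 2, 2)
  img[, , 3] <- matrix(c(0, 0, 0, 255), 2, 2)
  h <- color_histogram(img, "hsv", bins = 8, normalize = FALSE)
  # oracle: convert the two distinct pixels independently and bin by hand
  hsv_red <- grDevices::rgb2hsv(c(255, 0, 0), maxColorValue = 255)[, 1]
  hsv_blue <- grDevices::rgb2hsv(c(0, 0, 255), maxColorValue = 255)[, 1]
  expected <- numeric(24)
  for (px in list(list(hsv_red, 3), list(hsv_blue, 1)))
    for (ch in 1:3) {
      b <- min(floor(px[[1]][ch] * 8), 7)
      expected[(ch - 1) * 8 + b + 1] <- expected[(ch - 1) * 8 + b + 1] + px[[2]]
    }
  expect_equal(unname(h), expected)
})

test_that("dominant colors recover an exact three-color composition", {
  img <- array(0, c(10, 10, 3))
  cols <- rbind(c(200, 20, 20), c(20, 200, 20), c(20, 20, 200))
  assign <- rep(1:3, times = c(60, 30, 10))
  for (ch in 1:3) img[, , ch] <- matrix(cols[assign, ch], 10, 10)
  dc <- dominant_colors(img, k = 3, seed = 1)
  expect_equal(unname(dc$centroids), unname(cols))
  expect_equal(dc$proportions, c(0.6, 0.3, 0.1))
  expect_equal(dc$objective, 0)
})

test_that("dominant colors handle degenerate inputs per the empty-cluster policy", {
  flat <- make_flat_image(c(13, 77, 200), 8, 8)
  dc <- dominant_colors(flat, k = 3, seed = 1)
  for (j in 1:3) expect_equal(unname(dc$centroids[j, ]), c(13, 77, 200))
  expect_equal(dc$proportions, c(1, 0, 0))
  # two distinct colors, k = 3: optimum is zero within-cluster variance,
  # matching the exhaustive assignment over <= 2 distinct values
  two <- make_flat_image(c(0, 0, 0), 8, 8)
  two[1:4, , 1] <- 250
  dc2 <- dominant_colors(two, k = 3, seed = 1)
  expect_equal(dc2$objective, 0)
})

test_that("k-means objective on a real image never exceeds the trivial bound", {
  img <- generate_leaf_image(lesion_leaf_spec(3), 2, side = 64)
  dc <- dominant_colors(img, k = 3, seed = 5)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  tss <- sum(sweep(px, 2, colMeans(px))^2)  # k = 1 solution
  expect_lt(dc$objective, tss)
  expect_equal(sum(dc$proportions), 1)
})

test_that("grayscale conversion follows the BT.601 weights", {
  expect_equal(to_gray(make_flat_image(c(255, 255, 255), 2, 2))[1, 1], 1)
  expect_equal(to_gray(make_flat_image(c(0, 255, 0), 2, 2))[1, 1], 0.587)
  set.seed(1)
  img <- array(runif(3 * 25, 0, 255), c(5, 5, 3))
  g <- to_gray(img)
  expect_true(all(g >= 0 & g <= 1))
})

test_that("LBP codes follow the thresholded ring definition", {
  # constant image: every neighbor ties the center, s(0) = 1, code 255
  g <- matrix(0.4, 12, 12)
  h <- lbp_histogram(g, normalize = FALSE)
  expect_equal(unname(h[256]), 100)
  expect_equal(sum(h), 100)
  # hand-evaluated 3x3 patch: neighbors ccw from the right neighbor
  nb <- c(0.6, 0.5, 0.4, 0.4, 0.4, 0.6, 0.6, 0.4)
  p <- matrix(0, 3, 3)
  p[2, 2] <- 0.5
  pos <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1), c(2, 1), c(3, 1),
               c(3, 2), c(3, 3))
  for (i in 1:8) p[pos[i, 1], pos[i, 2]] <- nb[i]
  h1 <- lbp_histogram(p, normalize = FALSE)
  expect_equal(sum(h1), 1)
  expect_equal(unname(h1[99 + 1]), 1)  # 1 + 2 + 32 + 64
  expect_error(lbp_histogram(matrix(0.5, 2, 2)), "too small")
})

test_that("LBP histograms stay closed over random images", {
  set.seed(2)
  for (i in 1:3) {
    g <- matrix(runif(15 * 17), 15, 17)
    h <- lbp_histogram(g, normalize = FALSE)
    expect_length(h, 256)
    expect_equal(sum(h), 13 * 15)
    expect_true(all(h >= 0))
  }
})

test_that("GLCM contrast and ASM match hand counts and bounds", {
  # constant image: single occupied co-occurrence cell
  g0 <- glcm_features(matrix(0.3, 6, 6))
  expect_equal(unname(g0["contrast"]), 0)
  expect_equal(unname(g0["asm"]), 1)
  # 2x2 image quantizing to [[0,7],[0,7]], horizontal pairs only
  g <- rbind(c(0.01, 0.99), c(0.01, 0.99))
  f <- glcm_features(g, levels = 8, angles = 0, symmetric = TRUE)
  expect_equal(unname(f["contrast"]), 49)
  expect_equal(unname(f["asm"]), 0.5)
  # bounds on random images
  set.seed(3)
  for (i in 1:3) {
    gi <- matrix(runif(12 * 12), 12, 12)
    fi <- glcm_features(gi, levels = 8)
    expect_gte(fi[["contrast"]], 0)
    expect_lte(fi[["contrast"]], 49)
    expect_gt(fi[["asm"]], 0)
    expect_lte(fi[["asm"]], 1)
  }
  expect_error(glcm_features(matrix(0.5, 4, 4), levels = 1), "levels")
})

test_that("segmentation finds the centered object under either contrast polarity", {
  img <- make_flat_image(c(30, 30, 30), 64, 64)
  disk <- make_disk(20, 64)
  for (ch in 1:3) { p <- img[, , ch]; p[disk] <- 220; img[, , ch] <- p }
  mask <- segment_leaf(img)
  expect_lt(sum(xor(mask, disk)), 0.02 * sum(disk))
  # inverted contrast: dark object on bright background, same mask
  inv <- 255 - img
  mask_inv <- segment_leaf(inv)
  expect_lt(sum(xor(mask_inv, disk)), 0.02 * sum(disk))
  expect_error(segment_leaf(make_flat_image(c(9, 9, 9))), "unsegmentable")
})

test_that("largest-component rule removes speckle noise", {
  img <- make_flat_image(c(30, 30, 30), 64, 64)
  disk <- make_disk(15, 64)
  for (ch in 1:3) { p <- img[, , ch]; p[disk] <- 220; img[, , ch] <- p }
  set.seed(8)
  speck <- matrix(FALSE, 64, 64)
  speck[cbind(sample(1:10, 6), sample(40:63, 6))] <- TRUE
  for (ch in 1:3) { p <- img[, , ch]; p[speck] <- 220; img[, , ch] <- p }
  mask <- segment_leaf(img)
  expect_true(all(!mask[speck]))
  expect_lt(sum(xor(mask, disk)), 0.02 * sum(disk))
})

test_that("shape descriptors match closed forms for square, disk and ellipse", {
  sq <- matrix(FALSE, 80, 80); sq[15:64, 15:64] <- TRUE
  s <- shape_descriptors(sq)
  expect_equal(s[["area"]], 2500)
  expect_lt(abs(s[["circularity"]] - pi / 4) / (pi / 4), 0.05)
  for (r in c(30, 60)) {
    cd <- shape_descriptors(make_disk(r))[["circularity"]]
    expect_gte(cd, 0.95); expect_lte(cd, 1.08)
  }
  # 2:1 ellipse against the analytic Ramanujan perimeter
  m <- matrix(FALSE, 201, 201)
  m[((row(m) - 101) / 60)^2 + ((col(m) - 101) / 30)^2 <= 1] <- TRUE
  e <- shape_descriptors(m)
  a <- 60; b <- 30; h <- ((a - b) / (a + b))^2
  p_ram <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(abs(e[["circularity"]] - 4 * pi * e[["area"]] / p_ram^2) /
              (4 * pi * e[["area"]] / p_ram^2), 0.05)
  expect_error(shape_descriptors(matrix(FALSE, 5, 5)), "empty")
})

test_that("circularity is asymptotically scale invariant", {
  cs <- vapply(c(30, 60, 120), function(r)
    shape_descriptors(make_disk(r))[["circularity"]], numeric(1))
  expect_lt(diff(range(cs)) / mean(cs), 0.05)
})

test_that("the fused handcrafted vector has the documented layout", {
  img <- generate_leaf_image(default_class_specs(2)[[2]], 3, side = 128)
  v <- extract_handcrafted(img)
  expect_length(v, 321)
  blocks <- attr(v, "blocks")
  expect_equal(unname(blocks),
               c(24, 24, 12, 256, 2, 3))
  expect_equal(names(blocks),
               c("hsv", "lab", "dominant", "lbp", "glcm", "shape"))
  expect_true(all(is.finite(v)))
  v2 <- extract_handcrafted(img)
  expect_identical(as.numeric(v), as.numeric(v2))
  expect_false(attr(v, "segmentation_failed"))
})

test_that("background color moves histogram blocks but not the shape block", {
  spec_a <- flat_leaf_spec()
  spec_b <- class_spec("flat2", spec_a$base_color, c(0, 0),
                       spec_a$lesion_color, c(4, 8), 0, 0.5,
                       background_color = c(210, 210, 210))
  img_a <- generate_leaf_image(spec_a, 6)
  img_b <- generate_leaf_image(spec_b, 6)
  va <- extract_handcrafted(img_a)
  vb <- extract_handcrafted(img_b)
  hist_idx <- 1:48
  shape_idx <- 319:321
  expect_gt(sum(abs(va[hist_idx] - vb[hist_idx])), 0.1)
  expect_equal(as.numeric(va[shape_idx]), as.numeric(vb[shape_idx]),
               tolerance = 0.02)
})

test_that("unsegmentable input degrades to a zero shape block with a warning", {
  flat <- make_flat_image(c(50, 120, 60), 64, 64)
  expect_warning(v <- extract_handcrafted(flat), "segmentation failed")
  expect_equal(as.numeric(v[319:321]), c(0, 0, 0))
  expect_true(attr(v, "segmentation_failed"))
})
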