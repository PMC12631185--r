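# shared fixtures, all generated in code

# filled disk mask of radius r centered in a square canvas
make_disk <- function(r, side = 2 * r + 41) {
  m <- matrix(FALSE, side, side)
  c0 <- (side + 1) / 2
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- TRUE
  m
}

# constant-color image
make_flat_image <- function(color, h = 32, w = 32) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}

# spec with no randomness sources in the leaf interior
flat_leaf_spec <- function(name = "flat") {
  class_spec(name, base_color = c(80, 160, 70), lesion_count_range = c(0, 0),
             lesion_color = c(120, 80, 40), lesion_radius_range = c(4, 8),
             texture_noise_sd = 0, eccentricity = 0.5)
}

# spec carrying lesions but no noise (lesion-conservation fixtures)
lesion_leaf_spec <- function(n_lesions = 3) {
  class_spec("lesioned", base_color = c(80, 160, 70),
             lesion_count_range = c(n_lesions, n_lesions),
             lesion_color = c(120, 80, 40), lesion_radius_range = c(5, 9),
             texture_noise_sd = 0, eccentricity = 0.5)
}

# deterministic 70/15/15 index split of a feature table
blob_split <- function(tab, seed = 42) {
  set.seed(seed)
  n <- nrow(tab$X)
  o <- sample.int(n)
  n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
  list(tr = o[seq_len(n_tr)],
       va = o[(n_tr + 1):(n_tr + n_va)],
       te = o[(n_tr + n_va + 1):n])
}

expect_row_stochastic <- function(P, tol = 1e-9) {
  expect_true(all(P >= -tol & P <= 1 + tol))
  expect_true(max(abs(rowSums(P) - 1)) < tol)
}
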