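## Synthetic fundus generator: vessel trees, rendering, photometric style
## views and affine transforms.

test_that("vessel tree parameters are validated", {
  expect_error(vessel_tree_params(n_roots = 0), "n_roots")
  expect_error(vessel_tree_params(canvas_size = c(16, 16)), "canvas_size")
  expect_error(vessel_tree_params(width_decay = 1), "width_decay")
  expect_error(vessel_tree_params(thin_fraction = 1.2), "thin_fraction")
})

test_that("vessel masks are binary, reproducible, in-range and connected", {
  params <- vessel_tree_params(seed = 7, canvas_size = c(128L, 128L),
                               n_roots = 2L, max_depth = 5L)
  m1 <- generate_vessel_mask(params, return_roots = TRUE)
  m2 <- generate_vessel_mask(params, return_roots = TRUE)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0, 1)))
  frac <- mean(m1)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.25)
  ## every root's pixels form a single 8-connected component
  for (root in attr(m1, "roots")) {
    expect_gt(sum(root), 0)
    expect_identical(count_components_8(root), 1L)
  }
})

test_that("rendered fundus has the configured vessel/background contrast", {
  mask <- generate_vessel_mask(vessel_tree_params(seed = 3, canvas_size = c(96L, 96L)))
  img <- render_fundus(mask, seed = 2, contrast = 1, noise_sd = 0)
  expect_identical(img, render_fundus(mask, seed = 2, contrast = 1, noise_sd = 0))
  expect_true(all(img >= 0 & img <= 1))
  fov <- fov_mask(96, 96)
  vi <- as.logical(mask)
  bi <- as.logical(fov * (1 - mask))
  for (ch in 1:3) {
    gap <- mean(img[, , ch][bi]) - mean(img[, , ch][vi])
    expect_gt(gap, 0) # vessels darker than background
    expected <- 0.6 * 1 * mean(img[, , ch][bi])
    expect_lt(abs(gap - expected) / expected, 0.10)
  }
  g_lo <- render_fundus(mask, seed = 2, contrast = 0.2, noise_sd = 0)
  g_hi <- render_fundus(mask, seed = 2, contrast = 0.8, noise_sd = 0)
  gap_of <- function(img) mean(img[, , 2][bi]) - mean(img[, , 2][vi])
  expect_gt(abs(gap_of(g_hi)), abs(gap_of(g_lo)))
})

test_that("style transform is a seeded, monotone, crop-commuting photometric map", {
  mask <- generate_vessel_mask(vessel_tree_params(seed = 4, canvas_size = c(64L, 64L)))
  img <- render_fundus(mask, seed = 4)
  ## zero amplitudes give the identity
  expect_equal(style_transform(img, seed = 1, gamma_range = c(1, 1), brightness = 0,
                               contrast_range = c(1, 1), mix = 0), img)
  s1 <- style_transform(img, seed = 11)
  expect_identical(s1, style_transform(img, seed = 11))
  ## near-monotone per channel
  for (ch in 1:3) {
    expect_gte(cor(as.numeric(img[, , ch]), as.numeric(s1[, , ch]),
                   method = "spearman"), 0.9)
  }
  ## photometric-only: commutes with cropping
  rows <- 10:40; cols <- 5:50
  expect_equal(s1[rows, cols, ], style_transform(img[rows, cols, , drop = FALSE],
                                                 seed = 11))
})

test_that("sampled affines respect their bounds and invert cleanly", {
  expect_equal(sample_affine(1, 0, 0, 0, 0)$matrix,
               cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  for (s in 1:20) {
    A <- sample_affine(s, max_rotation = 20, max_scale_dev = 0.2,
                       max_shear = 0.1, max_translate = 6)
    C <- compose_affine(invert_affine(A), A)
    expect_lt(max(abs(C$matrix - cbind(diag(2), c(0, 0)))), 1e-9)
  }
  expect_identical(sample_affine(3)$matrix, sample_affine(3)$matrix)
})

test_that("the printed reference matrix behaves as computed by hand", {
  A <- reference_affine()
  ## determinant by direct arithmetic
  det_oracle <- 0.90411 * 0.82583 - 0.17613 * 0.05871
  expect_equal(det(A$matrix[, 1:2]), det_oracle, tolerance = 1e-12)
  expect_equal(det_oracle, 0.7363, tolerance = 1e-4)
  ## point image by direct matrix-vector product
  p <- apply_affine_points(A, cbind(100, 100))
  expect_equal(as.numeric(p), c(108.024, 88.454), tolerance = 1e-9)
  ## round trip
  pts <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  back <- apply_affine_points(invert_affine(A), apply_affine_points(A, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("affine image warps: identity, exact integer shifts, round trips", {
  mask <- generate_vessel_mask(vessel_tree_params(seed = 6, canvas_size = c(64L, 64L)))
  I <- affine_transform(cbind(diag(2), c(0, 0)))
  expect_equal(apply_affine_image(I, mask, "nearest"), mask)

  ## pure integer translation with nearest resampling is an index shift
  Tr <- affine_transform(cbind(diag(2), c(3, -2)))
  shifted <- apply_affine_image(Tr, mask, "nearest")
  oracle <- matrix(0, 64, 64)
  oracle[4:64, 1:62] <- mask[1:61, 3:64]
  expect_equal(shifted, oracle)

  ## warp then inverse-warp a smooth image: small error away from borders
  g <- lavs:::coord_grid(64, 64)
  smooth <- matrix(0.5 + 0.4 * sin(g[, 1] / 9) * cos(g[, 2] / 7), 64, 64)
  A <- center_affine(sample_affine(2, 5, 0.05, 0.02, 2), c(64, 64))
  rt <- apply_affine_image(invert_affine(A), apply_affine_image(A, smooth))
  core <- 17:48
  expect_lt(mean(abs(rt[core, core] - smooth[core, core])), 0.02)

  expect_error(affine_transform(rbind(c(1, 1, 0), c(2, 2, 0))), "singular")
})
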