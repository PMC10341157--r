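## Landmark detector: spatial softmax, soft-argmax readout, consistency and
## contrastive objectives, Gaussian map rendering.

test_that("project_heads is a 1x1 channel projection", {
  m3 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  ## identity projection reproduces the input
  expect_equal(project_heads(m3, list(w = diag(3), b = numeric(3))), m3)
  out <- project_heads(m3, list(w = matrix(rnorm(15), 3, 5), b = rnorm(5)))
  expect_identical(dim(out), c(4L, 4L, 5L))
  expect_error(project_heads(m3, list(w = diag(2), b = numeric(2))), "3 x K")
})

test_that("spatial softmax produces per-channel distributions", {
  z <- array(0, c(2, 2, 1))
  expect_equal(spatial_softmax(z)[, , 1], matrix(0.25, 2, 2))

  z <- array(0, c(3, 3, 1))
  z[2, 3, 1] <- 20
  p <- spatial_softmax(z)
  expect_gt(p[2, 3, 1], 0.999)

  set.seed(4)
  z <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  p <- spatial_softmax(z)
  expect_true(all(abs(apply(p, 3, sum) - 1) < 1e-5))
  ## exhaustive exp/sum oracle per channel
  for (k in 1:5) {
    e <- exp(z[, , k])
    expect_lt(max(abs(p[, , k] - e / sum(e))), 1e-6)
  }
  ## shift invariance
  expect_equal(spatial_softmax(z + 3.7), p, tolerance = 1e-9)
})

test_that("soft-argmax is the probability-weighted coordinate mean", {
  p <- array(0, c(6, 8, 1))
  p[4, 6, 1] <- 1 # one-hot at 0-based (3, 5)
  expect_equal(as.numeric(soft_argmax(p)), c(3, 5))

  u <- array(1 / 48, c(6, 8, 1))
  expect_equal(as.numeric(soft_argmax(u)), c((6 - 1) / 2, (8 - 1) / 2))

  set.seed(5)
  z <- array(rexp(6 * 8 * 3), c(6, 8, 3))
  z <- sweep(z, 3, apply(z, 3, sum), "/")
  R <- soft_argmax(z)
  ## brute-force sum over all sites
  for (k in 1:3) {
    er <- 0; ec <- 0
    for (i in 1:6) for (j in 1:8) {
      er <- er + z[i, j, k] * (i - 1)
      ec <- ec + z[i, j, k] * (j - 1)
    }
    expect_lt(max(abs(R[k, ] - c(er, ec))), 1e-6)
  }
})

test_that("soft-argmax is equivariant to interior integer translations", {
  sigma <- 0.8
  base <- render_gaussian_map(cbind(7.3, 6.6), c(16, 16), sigma)
  p0 <- spatial_softmax(base * 12)
  r0 <- soft_argmax(p0)
  shifted <- array(0, dim(base))
  shifted[3:16, 2:16, 1] <- base[1:14, 1:15, 1]
  p1 <- spatial_softmax(shifted * 12)
  r1 <- soft_argmax(p1)
  expect_lt(max(abs(r1 - (r0 + c(2, 1)))), 0.05)
})

test_that("consistency loss vanishes exactly on transported landmarks", {
  set.seed(6)
  R <- cbind(runif(5, 2, 10), runif(5, 2, 10))
  A <- reference_affine()
  expect_lt(consistency_loss(R, apply_affine_points(A, R), A), 1e-18)
  ## identity transform, unit row offset: mean squared distance is 1
  I <- affine_transform(cbind(diag(2), c(0, 0)))
  expect_equal(consistency_loss(R, R + cbind(rep(1, 5), 0), I), 1)
  expect_error(consistency_loss(R, R[1:3, ], I), "size")
})

test_that("contrastive loss matches an exhaustive NT-Xent enumeration", {
  ## identical, well-separated views at low temperature: loss near zero
  d0 <- diag(3) * 5
  expect_lt(contrastive_loss(d0, d0, temperature = 0.05), 1e-6)

  set.seed(7)
  a <- matrix(rnorm(6), 3, 2)
  b <- a + matrix(rnorm(6, sd = 0.1), 3, 2)
  aligned <- contrastive_loss(a, b, temperature = 0.5)
  shuffled <- contrastive_loss(a, b[c(2, 3, 1), ], temperature = 0.5)
  expect_gt(shuffled, aligned)
  ## symmetry
  expect_equal(contrastive_loss(a, b, 0.5), contrastive_loss(b, a, 0.5))

  ## exhaustive oracle: per-anchor log-softmax over the 2K - 1 others
  tau <- 0.3
  z <- rbind(a, b)
  z <- z / sqrt(rowSums(z^2))
  n <- 6
  total <- 0
  for (i in 1:n) {
    pos <- if (i <= 3) i + 3 else i - 3
    denom <- 0
    for (j in setdiff(1:n, i)) denom <- denom + exp(sum(z[i, ] * z[j, ]) / tau)
    total <- total - log(exp(sum(z[i, ] * z[pos, ]) / tau) / denom)
  }
  expect_equal(contrastive_loss(a, b, tau), total / n, tolerance = 1e-9)

  expect_error(contrastive_loss(a[1, , drop = FALSE], b[1, , drop = FALSE], 0.5),
               "at least 2")
  ## the in-graph version agrees with the reference implementation
  ga <- lavs:::ad_input(a)
  gb <- lavs:::ad_input(b)
  gl <- lavs:::graph_contrastive_loss(ga, gb, tau)
  expect_equal(as.numeric(lavs:::ad_value(gl)), contrastive_loss(a, b, tau),
               tolerance = 1e-7)
})

test_that("extract_landmarks is deterministic, bounded, and centroid-seeking", {
  net <- vessel_net(tiny_cfg("transunet_sld"), seed = 8)
  pair <- toy_pair(c(32L, 32L), seed = 3)
  R1 <- extract_landmarks(net, pair$image)
  expect_identical(R1, extract_landmarks(net, pair$image))
  expect_identical(dim(R1), c(4L, 2L))
  expect_true(all(R1[, 1] >= 0 & R1[, 1] <= 7))
  expect_true(all(R1[, 2] >= 0 & R1[, 2] <= 7))
  ## masks are accepted as pseudo-label sources
  RY <- extract_landmarks(net, pair$mask)
  expect_identical(dim(RY), dim(R1))
  expect_error(extract_landmarks(vessel_net(tiny_cfg("unet"), seed = 1),
                                 pair$image), "landmark head")

  ## near-one-hot responses on a single bright blob: soft-argmax lands
  ## within a pixel of the blob centroid
  blob_centre <- c(4.4, 9.7)
  heads <- render_gaussian_map(rbind(blob_centre), c(16, 16), sigma = 1.2) * 25
  R <- soft_argmax(spatial_softmax(heads))
  expect_lt(sqrt(sum((R[1, ] - blob_centre)^2)), 1)
})

test_that("Gaussian landmark maps follow the closed form", {
  R <- rbind(c(4, 4), c(2.4, 7.2))
  g <- render_gaussian_map(R, c(12, 12), sigma = 0.7)
  expect_identical(dim(g), c(12L, 12L, 2L))
  expect_equal(g[5, 5, 1], 1) # landmark exactly on a site
  ## value at distance sigma is exp(-1/2)
  d <- sqrt((lavs:::coord_grid(12, 12)[, 1] - 4)^2 +
              (lavs:::coord_grid(12, 12)[, 2] - 4)^2)
  probe <- render_gaussian_map(rbind(c(4, 4 + 0.7)), c(12, 12), 0.7)
  expect_equal(probe[5, 5, 1], exp(-1 / 2), tolerance = 1e-12)
  ## channel argmax sits at the nearest grid site
  idx <- which(g[, , 2] == max(g[, , 2]), arr.ind = TRUE)
  expect_identical(as.integer(idx), as.integer(round(R[2, ]) + 1))
  expect_true(all(g > 0 & g <= 1))
  ## strictly decreasing with distance from the landmark
  vals <- g[5, 5:12, 1]
  expect_true(all(diff(vals) < 0))
  expect_error(render_gaussian_map(R, c(12, 12), sigma = 0), "sigma")
})
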