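## Shared fixtures and independent oracles for the test suite.

## Tiny configurations that keep forward/backward passes fast.
tiny_cfg <- function(variant = "transunet_sld", size = c(32L, 32L),
                     patch = 2L, K = 4L) {
  net_config(variant = variant, channels = c(4L, 6L, 8L),
             transformer = transformer_config(n_layers = 2L, n_heads = 2L,
                                              patch_size = patch, embed_dim = 8L,
                                              mlp_ratio = 2),
             landmark_channels = K, image_size = size)
}

tiny_train_cfg <- function(variant = "transunet_sld", epochs = 1L, seed = 1L,
                           size = c(32L, 32L), weights = loss_weights()) {
  train_config(epochs = epochs, seed = seed, net = tiny_cfg(variant, size),
               image_size = size, weights = weights,
               disc_channels = c(4L, 6L, 8L, 10L))
}

## Central-difference numerical gradient of scalar f at x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

## Independent 8-connected component count (breadth-first flood fill).
count_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (start in which(mask > 0 & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- (cur - 1L) %% h
      cj <- (cur - 1L) %/% h
      for (di in -1:1) for (dj in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) next
        nl <- ni + 1L + h * nj
        if (mask[nl] > 0 && !seen[nl]) {
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
  }
  ncomp
}

## A small deterministic synthetic pair at the requested size.
toy_pair <- function(size = c(32L, 32L), seed = 5L) {
  params <- vessel_tree_params(seed = seed, canvas_size = pmax(size, 32L),
                               n_roots = 2L, max_depth = 4L)
  mask <- generate_vessel_mask(params)
  img <- render_fundus(mask, seed = seed + 1L, contrast = 0.7, noise_sd = 0.02)
  sample_pair(img, mask, id = sprintf("toy_%d", seed))
}

## The printed reference affine matrix used across affine tests.
reference_affine <- function() {
  affine_transform(rbind(c(0.90411, 0.17613, 0), c(0.05871, 0.82583, 0)))
}
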