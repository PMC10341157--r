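## Self-supervised landmark detection: a 1x1 projection of the deepest
## encoder features into K channels, spatial softmax per channel, and a
## differentiable soft-argmax coordinate readout. Landmarks live on the
## H/4 x W/4 feature grid in 0-based (row, col) units.

#' Project encoder features to K landmark channels
#'
#' A 1x1 convolution (matrix multiply over channels) from `C3` encoder
#' channels to `K` landmark response channels.
#'
#' @param m3 Feature map `[h, w, C3]`.
#' @param weights List with `w` (`C3 x K` matrix) and `b` (length-K bias).
#' @return Array `[h, w, K]`.
#' @export
project_heads <- function(m3, weights) {
  d <- dim(m3)
  stop_if(is.null(weights$w) || nrow(weights$w) != d[3],
          "projection weights must be a %d x K matrix", d[3])
  K <- ncol(weights$w)
  flat <- matrix(m3, d[1] * d[2], d[3])
  out <- flat %*% weights$w
  out <- out + rep(weights$b, each = nrow(out))
  array(out, dim = c(d[1], d[2], K))
}

graph_project_heads <- function(pn, m3) {
  d <- dim(ad_value(m3))
  K <- ncol(ad_value(pn[["head.w"]]))
  flat <- ad_reshape(m3, c(d[1] * d[2], d[3]))
  out <- ad_add_bias(ad_matmul(flat, pn[["head.w"]]), pn[["head.b"]])
  ad_reshape(out, c(d[1], d[2], K))
}

#' Spatial softmax over each channel
#'
#' Converts every channel of a `[h, w, K]` response map into a spatial
#' probability distribution: softmax over all `h * w` sites, so each channel
#' sums to 1. Invariant to adding a constant to a channel.
#'
#' @param heads Array `[h, w, K]` of finite responses.
#' @return Array `[h, w, K]`; each channel non-negative and summing to 1.
#' @export
spatial_softmax <- function(heads) {
  d <- dim(heads)
  stop_if(any(!is.finite(heads)), "responses must be finite")
  flat <- t(matrix(heads, d[1] * d[2], d[3])) # [K, hw]
  mx <- apply(flat, 1L, max)
  e <- exp(flat - mx)
  p <- e / rowSums(e)
  array(t(p), dim = d)
}

graph_spatial_softmax <- function(heads) {
  d <- dim(ad_value(heads))
  flat <- ad_transpose(ad_reshape(heads, c(d[1] * d[2], d[3])))
  ad_softmax_rows(flat) # [K, hw]
}

#' Soft-argmax coordinate readout
#'
#' The probability-weighted mean of site coordinates per channel:
#' `R_c = sum_r p[c, r] * (row_r, col_r)`, the differentiable surrogate of
#' the spatial argmax.
#'
#' @param p Probability maps `[h, w, K]` (each channel sums to 1), as
#'   produced by [spatial_softmax()].
#' @return `[K, 2]` matrix of 0-based `(row, col)` coordinates, each within
#'   the grid bounds.
#' @export
soft_argmax <- function(p) {
  d <- dim(p)
  sums <- apply(p, 3L, sum)
  stop_if(any(abs(sums - 1) > 1e-5) || any(p < 0),
          "p must hold per-channel spatial distributions")
  flat <- t(matrix(p, d[1] * d[2], d[3])) # [K, hw]
  out <- flat %*% coord_grid(d[1], d[2])
  colnames(out) <- c("row", "col")
  out
}

## p_flat: [K, hw] node; returns [K, 2] node.
graph_soft_argmax <- function(p_flat, h, w) {
  ad_matmul(p_flat, coord_grid(h, w))
}

#' Affine consistency loss for landmarks
#'
#' Mean (over landmarks) squared Euclidean distance between the landmarks of
#' the original view and the inverse-transformed landmarks of the affine
#' view: landmarks are stable when `A^{-1}(R_warped)` coincides with
#' `R_orig`.
#'
#' @param R_orig,R_warped `[K, 2]` landmark matrices (same K, same order).
#' @param A The `affine_transform` that produced the warped view, expressed
#'   in the landmark coordinate system.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(R_orig, R_warped, A) {
  R_orig <- matrix(as.numeric(R_orig), ncol = 2)
  R_warped <- matrix(as.numeric(R_warped), ncol = 2)
  stop_if(nrow(R_orig) != nrow(R_warped),
          "landmark sets differ in size (%d vs %d)", nrow(R_orig), nrow(R_warped))
  back <- apply_affine_points(invert_affine(A), R_warped)
  mean(rowSums((R_orig - back)^2))
}

#' Contrastive loss over landmark descriptors
#'
#' Normalised-temperature cross-entropy (NT-Xent) between two descriptor
#' views of the same K landmarks: for each of the 2K descriptors the positive
#' is the same landmark index in the other view and the negatives are the
#' remaining 2K - 2 descriptors. Descriptor rows are L2-normalised before
#' the cosine similarities are formed. Symmetric in its two arguments.
#'
#' @param desc_a,desc_b `[K, d]` descriptor matrices (K >= 2).
#' @param temperature Positive softmax temperature.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(desc_a, desc_b, temperature = 0.2) {
  desc_a <- as.matrix(desc_a)
  desc_b <- as.matrix(desc_b)
  K <- nrow(desc_a)
  stop_if(K < 2, "contrastive loss needs at least 2 landmarks (no negatives)")
  stop_if(nrow(desc_b) != K || ncol(desc_b) != ncol(desc_a),
          "descriptor matrices must share dimensions")
  stop_if(temperature <= 0, "temperature must be positive")
  z <- rbind(desc_a, desc_b)
  z <- z / (sqrt(rowSums(z^2)) + 1e-12)
  sim <- (z %*% t(z)) / temperature
  n <- 2L * K
  total <- 0
  for (i in seq_len(n)) {
    pos <- if (i <= K) i + K else i - K
    others <- setdiff(seq_len(n), i)
    m <- max(sim[i, others])
    total <- total - (sim[i, pos] - m - log(sum(exp(sim[i, others] - m))))
  }
  total / n
}

## In-graph NT-Xent on two [K, d] descriptor nodes.
graph_contrastive_loss <- function(desc_a, desc_b, temperature = 0.2) {
  K <- nrow(ad_value(desc_a))
  za <- ad_l2norm_rows(desc_a)
  zb <- ad_l2norm_rows(desc_b)
  z <- ad_node(rbind(za$value, zb$value), list(za, zb), function(g) {
    list(g[seq_len(K), , drop = FALSE], g[K + seq_len(K), , drop = FALSE])
  })
  sim <- ad_scale(ad_matmul(z, ad_transpose(z)), 1 / temperature)
  n <- 2L * K
  ## mask the diagonal with -Inf equivalent (large negative constant) so the
  ## softmax over "others" is a plain row softmax
  mask <- diag(n) * (-1e9)
  logits <- ad_add(sim, ad_input(mask))
  p <- ad_softmax_rows(logits)
  pos_idx <- cbind(seq_len(n), c(K + seq_len(K), seq_len(K)))
  pick <- matrix(0, n, n)
  pick[pos_idx] <- 1
  pos_p <- ad_sum_all(ad_mul(ad_log(ad_clamp(p, 1e-12, 1)), ad_input(pick)))
  ad_scale(pos_p, -1 / n)
}

#' Extract landmarks from an image
#'
#' Composition encoder -> 1x1 projection -> spatial softmax -> soft-argmax,
#' using the segmentation network's own (shared) encoder weights. A binary
#' mask may be passed instead of an RGB image (it is replicated to three
#' channels), which is how pseudo-label landmarks are read off the ground
#' truth.
#'
#' @param net A [vessel_net()] with `variant = "transunet_sld"`.
#' @param x RGB raster `[H, W, 3]` or binary raster `[H, W]`.
#' @return `[K, 2]` matrix of 0-based `(row, col)` landmarks on the
#'   `H/4 x W/4` grid.
#' @export
extract_landmarks <- function(net, x) {
  stopifnot(inherits(net, "vessel_net"))
  stop_if(is.null(net$params$head), "variant '%s' has no landmark head", net$cfg$variant)
  if (length(dim(x)) == 2L) x <- as_rgb(x)
  pn <- param_nodes(net)
  feats <- graph_encode(pn, net$cfg, ad_input(x))
  heads <- ad_scale(graph_project_heads(pn, feats$m3), net$cfg$head_gain)
  d <- dim(ad_value(heads))
  p <- graph_spatial_softmax(heads)
  ad_value(graph_soft_argmax(p, d[1], d[2]))
}

#' Render Gaussian landmark maps
#'
#' Channel `c` holds `exp(-((row - R_c1)^2 + (col - R_c2)^2) / (2 sigma^2))`
#' evaluated at every grid site: an isotropic Gaussian bump of unit peak
#' centred at the (continuous) landmark.
#'
#' @param R `[K, 2]` landmark matrix in 0-based grid units.
#' @param grid `(h, w)` of the target grid.
#' @param sigma Gaussian standard deviation in grid units.
#' @return Array `[h, w, K]` with values in `(0, 1]`.
#' @export
render_gaussian_map <- function(R, grid, sigma = 0.7) {
  stop_if(sigma <= 0, "sigma must be positive")
  R <- matrix(as.numeric(R), ncol = 2)
  h <- grid[1]; w <- grid[2]
  g <- coord_grid(h, w)
  out <- array(0, dim = c(h, w, nrow(R)))
  for (k in seq_len(nrow(R))) {
    d2 <- (g[, 1] - R[k, 1])^2 + (g[, 2] - R[k, 2])^2
    out[, , k] <- matrix(exp(-d2 / (2 * sigma^2)), h, w)
  }
  out
}
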