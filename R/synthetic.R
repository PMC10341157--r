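## Synthetic fundus generator: branching vessel trees on a fundus-like disc,
## plus the photometric ("style") and geometric (affine) views needed by the
## self-supervised landmark objectives. Everything is seeded and reproducible,
## so the whole framework trains and tests without external datasets.

#' Parameters of a synthetic vessel tree
#'
#' @param seed Integer seed; the tree is a deterministic function of it.
#' @param canvas_size `(height, width)` in pixels, at least 32 x 32.
#' @param n_roots Number of primary vessels emanating from the optic-disc
#'   region.
#' @param max_depth Branching depth; each branch spawns two children.
#' @param root_width Stroke width of a primary vessel, in pixels.
#' @param width_decay Per-level width multiplier in (0, 1).
#' @param tortuosity Dimensionless scale of midpoint displacement; 0 gives
#'   straight segments.
#' @param thin_fraction Fraction of terminal branches rendered at ~1 px, the
#'   thin-vessel content that segmentation methods typically miss.
#' @return An object of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(seed = 1L, canvas_size = c(128L, 128L),
                               n_roots = 3L, max_depth = 5L, root_width = 3,
                               width_decay = 0.72, tortuosity = 0.35,
                               thin_fraction = 0.3) {
  stop_if(length(canvas_size) != 2 || any(canvas_size < 32),
          "canvas_size must be at least 32 x 32")
  stop_if(n_roots < 1, "n_roots must be a positive count")
  stop_if(max_depth < 1, "max_depth must be at least 1")
  stop_if(width_decay <= 0 || width_decay >= 1, "width_decay must lie in (0, 1)")
  stop_if(thin_fraction < 0 || thin_fraction > 1, "thin_fraction must lie in [0, 1]")
  stop_if(root_width <= 0, "root_width must be positive")
  structure(list(seed = as.integer(seed), canvas_size = as.integer(canvas_size),
                 n_roots = as.integer(n_roots), max_depth = as.integer(max_depth),
                 root_width = root_width, width_decay = width_decay,
                 tortuosity = tortuosity, thin_fraction = thin_fraction),
            class = "vessel_tree_params")
}

## Midpoint-displaced polyline between p and q (0-based (row, col)).
midpoint_polyline <- function(p, q, scale, depth = 3L) {
  if (depth == 0L) return(rbind(p, q))
  mid <- (p + q) / 2
  d <- q - p
  nrm <- c(-d[2], d[1])
  len <- sqrt(sum(d^2))
  if (len > 1e-9) nrm <- nrm / sqrt(sum(nrm^2))
  mid <- mid + nrm * stats::rnorm(1, 0, scale * len * 0.25)
  left <- midpoint_polyline(p, mid, scale, depth - 1L)
  right <- midpoint_polyline(mid, q, scale, depth - 1L)
  rbind(left, right[-1, , drop = FALSE])
}

## Stamp a thick segment onto a coverage canvas (matrix), returning the canvas.
stamp_segment <- function(canvas, p, q, width) {
  h <- nrow(canvas); w <- ncol(canvas)
  rad <- max(width / 2, 0.75) # floor keeps 1 px branches 8-connected
  r0 <- max(floor(min(p[1], q[1]) - rad - 1), 0)
  r1 <- min(ceiling(max(p[1], q[1]) + rad + 1), h - 1)
  c0 <- max(floor(min(p[2], q[2]) - rad - 1), 0)
  c1 <- min(ceiling(max(p[2], q[2]) + rad + 1), w - 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  ri <- r0:r1; ci <- c0:c1
  gi <- matrix(rep(ri, length(ci)), ncol = length(ci))
  gj <- matrix(rep(ci, each = length(ri)), ncol = length(ci))
  d <- q - p
  l2 <- sum(d^2)
  if (l2 < 1e-12) {
    dist <- sqrt((gi - p[1])^2 + (gj - p[2])^2)
  } else {
    t <- ((gi - p[1]) * d[1] + (gj - p[2]) * d[2]) / l2
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((gi - (p[1] + t * d[1]))^2 + (gj - (p[2] + t * d[2]))^2)
  }
  cov <- pmin(pmax(rad + 0.5 - dist, 0), 1)
  sub <- canvas[ri + 1, ci + 1]
  canvas[ri + 1, ci + 1] <- pmax(sub, cov)
  canvas
}

## 8-connected component containing `start` (0-based (row, col)) of a binary
## matrix; returns the component as a binary matrix.
connected_from <- function(mask, start) {
  h <- nrow(mask); w <- ncol(mask)
  lin <- function(i, j) i + 1 + h * j
  keep <- matrix(FALSE, h, w)
  si <- round(start[1]); sj <- round(start[2])
  ## snap to the nearest foreground pixel in a small window
  if (mask[lin(si, sj)] == 0) {
    found <- FALSE
    for (rad in 1:3) {
      ii <- max(0, si - rad):min(h - 1, si + rad)
      jj <- max(0, sj - rad):min(w - 1, sj + rad)
      cand <- expand.grid(i = ii, j = jj)
      cand <- cand[mask[lin(cand$i, cand$j)] > 0, , drop = FALSE]
      if (nrow(cand) > 0) {
        si <- cand$i[1]; sj <- cand$j[1]
        found <- TRUE
        break
      }
    }
    if (!found) return(keep)
  }
  nfg <- sum(mask > 0)
  if (nfg == 0L) return(keep)
  queue <- integer(nfg)
  queue[1] <- lin(si, sj)
  keep[queue[1]] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    cur <- queue[head]; head <- head + 1L
    ci <- (cur - 1L) %% h
    cj <- (cur - 1L) %/% h
    for (di in -1:1) for (dj in -1:1) {
      ni <- ci + di; nj <- cj + dj
      if (ni < 0 || ni >= h || nj < 0 || nj >= w) next
      nl <- ni + 1L + h * nj
      if (mask[nl] > 0 && !keep[nl]) {
        keep[nl] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nl
      }
    }
  }
  keep * 1
}

#' Generate a binary vessel-tree mask
#'
#' Draws `n_roots` recursively branching vessels from an optic-disc point,
#' using midpoint-displaced polylines with per-level width
#' `root_width * width_decay^level`, anti-aliased then thresholded. The mask
#' is clipped to the circular field of view and each root's pixels are pruned
#' to the 8-connected component reachable from its origin, so every tree is
#' guaranteed connected.
#'
#' @param params A [vessel_tree_params()] object.
#' @param return_roots If `TRUE`, attach a `"roots"` attribute: a list of
#'   per-root binary masks.
#' @return Binary matrix `[h, w]` with vessel pixels set to 1; typical
#'   foreground fraction 2-25% of the frame.
#' @export
generate_vessel_mask <- function(params, return_roots = FALSE) {
  stopifnot(inherits(params, "vessel_tree_params"))
  h <- params$canvas_size[1]; w <- params$canvas_size[2]
  fov <- fov_mask(h, w)
  rmin <- min(h, w)
  with_seed(params$seed, {
    centre <- c((h - 1) / 2, (w - 1) / 2)
    ## optic-disc point offset towards one side, as in real fundus geometry
    disc <- centre + c(stats::runif(1, -0.08, 0.08), stats::runif(1, 0.10, 0.22)) * rmin
    root_masks <- vector("list", params$n_roots)
    base_angle <- stats::runif(1, 0, 2 * pi)
    for (root in seq_len(params$n_roots)) {
      canvas <- matrix(0, h, w)
      ang <- base_angle + 2 * pi * (root - 1) / params$n_roots +
        stats::runif(1, -0.35, 0.35)
      draw_branch <- function(canvas, p0, angle, level) {
        len <- 0.30 * rmin * 0.72^level * stats::runif(1, 0.85, 1.15)
        p1 <- p0 + len * c(sin(angle), cos(angle))
        wd <- params$root_width * params$width_decay^level
        if (level == params$max_depth - 1L &&
            stats::runif(1) < params$thin_fraction) wd <- min(wd, 1)
        poly <- midpoint_polyline(p0, p1, params$tortuosity)
        for (s in seq_len(nrow(poly) - 1L)) {
          canvas <- stamp_segment(canvas, poly[s, ], poly[s + 1L, ], wd)
        }
        if (level + 1L < params$max_depth) {
          spread <- stats::runif(2, 0.30, 0.75)
          canvas <- draw_branch(canvas, p1, angle - spread[1], level + 1L)
          canvas <- draw_branch(canvas, p1, angle + spread[2], level + 1L)
        }
        canvas
      }
      canvas <- draw_branch(canvas, disc, ang, 0L)
      m <- (canvas >= 0.5) * fov
      root_masks[[root]] <- connected_from(m, disc)
    }
    mask <- Reduce(pmax, root_masks)
    if (return_roots) attr(mask, "roots") <- root_masks
    mask
  })
}

#' Render a fundus-like RGB image from a vessel mask
#'
#' Produces a warm-tinted circular field-of-view disc on a dark surround,
#' with a seeded low-frequency luminance field and vignetting. Vessel pixels
#' are darkened multiplicatively by a factor `1 - 0.6 * contrast` (Weber-type
#' contrast: the vessel/background mean gap scales linearly with `contrast`),
#' emulating the low vessel/background contrast of real fundus photographs.
#'
#' @param mask Binary vessel mask `[h, w]`.
#' @param seed Integer seed for the background field and the pixel noise.
#' @param contrast Relative vessel darkening in (0, 1].
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @return RGB array `[h, w, 3]` with values in `[0, 1]`.
#' @export
render_fundus <- function(mask, seed = 1L, contrast = 0.6, noise_sd = 0.03) {
  stop_if(!is_binary(mask), "mask must be binary")
  stop_if(contrast <= 0 || contrast > 1, "contrast must lie in (0, 1]")
  stop_if(noise_sd < 0, "noise_sd must be non-negative")
  h <- nrow(mask); w <- ncol(mask)
  fov <- fov_mask(h, w)
  tint <- c(1.00, 0.72, 0.45)
  with_seed(seed, {
    phase <- stats::runif(2, 0, 2 * pi)
    g <- coord_grid(h, w)
    cy <- (h - 1) / 2; cx <- (w - 1) / 2
    r <- 0.48 * min(h, w)
    d2 <- ((g[, 1] - cy)^2 + (g[, 2] - cx)^2) / r^2
    lum <- 0.80 - 0.12 * d2 +
      0.04 * sin(2 * pi * (2.5 * g[, 1] / h + 1.5 * g[, 2] / w) + phase[1]) +
      0.03 * sin(2 * pi * (1.0 * g[, 1] / h - 2.0 * g[, 2] / w) + phase[2])
    lum <- pmin(pmax(lum, 0.5), 0.95)
    vfac <- 1 - 0.6 * contrast * as.numeric(mask)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- tint[ch] * lum * vfac * as.numeric(fov)
      if (noise_sd > 0) {
        plane <- plane + stats::rnorm(h * w, 0, noise_sd) * as.numeric(fov)
      }
      img[, , ch] <- matrix(clamp01(plane), h, w)
    }
    img
  })
}

#' Photometric style jitter
#'
#' A seeded, purely pixelwise photometric map standing in for a
#' style-transformed view of the image: per-channel gamma, contrast scaling
#' about 0.5, brightness offset, and mild channel mixing. Geometry is
#' untouched, so the transform commutes with cropping.
#'
#' @param image RGB array in `[0, 1]`.
#' @param seed Integer seed for the jitter parameters.
#' @param gamma_range Per-channel gamma range; `c(1, 1)` disables.
#' @param brightness Max absolute brightness offset; 0 disables.
#' @param contrast_range Contrast-scale range about 0.5; `c(1, 1)` disables.
#' @param mix Max absolute off-diagonal channel-mixing weight; 0 disables.
#' @return RGB array of the same shape, values in `[0, 1]`.
#' @export
style_transform <- function(image, seed = 1L, gamma_range = c(0.7, 1.4),
                            brightness = 0.15, contrast_range = c(0.8, 1.25),
                            mix = 0.1) {
  stopifnot(length(dim(image)) == 3L)
  with_seed(seed, {
    gam <- stats::runif(3, gamma_range[1], gamma_range[2])
    con <- stats::runif(3, contrast_range[1], contrast_range[2])
    bri <- stats::runif(3, -brightness, brightness)
    M <- diag(3)
    if (mix > 0) {
      off <- stats::runif(6, -mix, mix)
      M[upper.tri(M) | lower.tri(M)] <- off
    }
    out <- image
    for (ch in 1:3) {
      out[, , ch] <- (image[, , ch]^gam[ch] - 0.5) * con[ch] + 0.5 + bri[ch]
    }
    mixed <- out
    for (ch in 1:3) {
      mixed[, , ch] <- M[ch, 1] * out[, , 1] + M[ch, 2] * out[, , 2] +
        M[ch, 3] * out[, , 3]
    }
    clamp01(mixed)
  })
}

## ---- affine transforms on (row, col) coordinates ----

#' Construct a 2 x 3 affine transform
#'
#' The matrix `[L | t]` maps a 0-based `(row, col)` point `p` to `L p + t`.
#' @param matrix Numeric 2 x 3 matrix.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2, 3)
  stop_if(abs(det(m[, 1:2])) <= 1e-8, "affine linear block is singular")
  structure(list(matrix = m), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine transform [L | t] on (row, col):\n")
  print(x$matrix)
  invisible(x)
}

#' Sample a random invertible affine transform
#'
#' Composes rotation, anisotropic scaling and shear about the origin plus a
#' translation, each drawn uniformly within the given bounds. With all bounds
#' zero the identity transform is returned.
#'
#' @param seed Integer seed.
#' @param max_rotation Max absolute rotation, degrees.
#' @param max_scale_dev Max absolute deviation of the per-axis scale from 1.
#' @param max_shear Max absolute shear coefficient.
#' @param max_translate Max absolute translation, pixels.
#' @return An `affine_transform`.
#' @export
sample_affine <- function(seed = 1L, max_rotation = 10, max_scale_dev = 0.1,
                          max_shear = 0.05, max_translate = 4) {
  stop_if(any(c(max_rotation, max_scale_dev, max_shear, max_translate) < 0),
          "affine sampling bounds must be non-negative")
  with_seed(seed, {
    th <- stats::runif(1, -max_rotation, max_rotation) * pi / 180
    sc <- 1 + stats::runif(2, -max_scale_dev, max_scale_dev)
    sh <- stats::runif(1, -max_shear, max_shear)
    tr <- stats::runif(2, -max_translate, max_translate)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    L <- R %*% diag(sc) %*% rbind(c(1, sh), c(0, 1))
    affine_transform(cbind(L, tr))
  })
}

#' Invert an affine transform
#' @param A An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(A) {
  stopifnot(inherits(A, "affine_transform"))
  L <- A$matrix[, 1:2]
  Li <- solve(L)
  affine_transform(cbind(Li, -Li %*% A$matrix[, 3]))
}

#' Compose two affine transforms (`A` after `B`)
#' @param A,B `affine_transform` objects.
#' @return The composition as an `affine_transform`.
#' @export
compose_affine <- function(A, B) {
  La <- A$matrix[, 1:2]; Lb <- B$matrix[, 1:2]
  affine_transform(cbind(La %*% Lb, La %*% B$matrix[, 3] + A$matrix[, 3]))
}

#' Re-centre an affine transform on an image
#'
#' Conjugates `A` so rotation/scale/shear act about the centre of an
#' `h x w` frame rather than the origin.
#' @param A An `affine_transform`.
#' @param shape `(h, w)` of the frame.
#' @return An `affine_transform`.
#' @export
center_affine <- function(A, shape) {
  ctr <- (shape[1:2] - 1) / 2
  L <- A$matrix[, 1:2]
  affine_transform(cbind(L, ctr - L %*% ctr + A$matrix[, 3]))
}

#' Rescale the translation component of an affine transform
#'
#' Converts a transform between coordinate systems that differ by an
#' isotropic scale `s` (e.g. image pixels to the H/4 feature grid uses
#' `s = 1/4`); the linear block is unchanged.
#' @param A An `affine_transform`.
#' @param s Scale factor applied to the translation.
#' @return An `affine_transform`.
#' @export
rescale_affine <- function(A, s) {
  affine_transform(cbind(A$matrix[, 1:2], A$matrix[, 3] * s))
}

#' Apply an affine transform to a set of points
#' @param A An `affine_transform`.
#' @param pts `[K, 2]` matrix of 0-based `(row, col)` points.
#' @return `[K, 2]` matrix of transformed points.
#' @export
apply_affine_points <- function(A, pts) {
  stopifnot(inherits(A, "affine_transform"))
  pts <- base::matrix(as.numeric(pts), ncol = 2)
  stop_if(any(!is.finite(pts)), "points must be finite")
  out <- pts %*% t(A$matrix[, 1:2])
  out[, 1] <- out[, 1] + A$matrix[1, 3]
  out[, 2] <- out[, 2] + A$matrix[2, 3]
  colnames(out) <- c("row", "col")
  out
}

#' Warp a raster with an affine transform
#'
#' Inverse-mapping warp: output pixel `q` reads the input at `A^{-1} q`,
#' bilinearly for intensity images or nearest-neighbour for binary masks.
#' Out-of-bounds samples are filled with 0.
#'
#' @param A An `affine_transform` (must be invertible).
#' @param img Raster `[h, w]` or `[h, w, c]`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Raster of the same shape.
#' @export
apply_affine_image <- function(A, img, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(A, "affine_transform"))
  Ai <- invert_affine(A)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(img) <- c(h, w, 1L)
  g <- coord_grid(h, w)
  src <- apply_affine_points(Ai, g)
  out <- array(0, dim = c(h, w, nc))
  if (method == "nearest") {
    ri <- round(src[, 1]); ci <- round(src[, 2])
    ok <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
    lin <- ri[ok] + 1 + h * ci[ok]
    for (ch in seq_len(nc)) {
      plane <- numeric(h * w)
      plane[ok] <- as.numeric(img[, , ch])[lin]
      out[, , ch] <- matrix(plane, h, w)
    }
  } else {
    r <- src[, 1]; cc <- src[, 2]
    ok <- r >= 0 & r <= h - 1 & cc >= 0 & cc <= w - 1
    i0 <- pmax(pmin(floor(r), h - 2), 0)
    j0 <- pmax(pmin(floor(cc), w - 2), 0)
    fi <- r - i0; fj <- cc - j0
    l00 <- i0 + 1 + h * j0
    for (ch in seq_len(nc)) {
      v <- as.numeric(img[, , ch])
      val <- (1 - fi) * (1 - fj) * v[l00] + fi * (1 - fj) * v[l00 + 1] +
        (1 - fi) * fj * v[l00 + h] + fi * fj * v[l00 + h + 1]
      val[!ok] <- 0
      out[, , ch] <- matrix(val, h, w)
    }
  }
  if (length(d) == 2L) out[, , 1] else out
}
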