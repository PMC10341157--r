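## Shared helpers: seeded evaluation, validation, raster conventions.
## Rasters are numeric arrays [h, w] or [h, w, c]; coordinates are (row, col),
## 0-based, with pixel centres at integer positions.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not perturb
#' the caller's random stream.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Derive a child seed from a base seed and a stream index, kept < 2^31.
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(idx) * 104729) %% 2147483647)
}

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

is_binary <- function(x) all(x %in% c(0, 1))

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Ensure an image array is [h, w, 3]; grayscale is replicated.
as_rgb <- function(img) {
  if (length(dim(img)) == 2L) {
    array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 1L) {
    array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  } else {
    img[, , 1:3, drop = FALSE]
  }
}

## 0-based pixel-centre coordinate grid for an h x w raster:
## a matrix [h*w, 2] of (row, col) in column-major (R array) order.
coord_grid <- function(h, w) {
  cbind(rep(0:(h - 1), times = w), rep(0:(w - 1), each = h))
}

#' Circular field-of-view mask
#'
#' Binary disc of radius `0.48 * min(h, w)` centred in the frame, mimicking
#' the circular usable region of a fundus photograph.
#' @param h,w Raster dimensions in pixels.
#' @return Binary matrix `[h, w]`.
#' @export
fov_mask <- function(h, w) {
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  r <- 0.48 * min(h, w)
  g <- coord_grid(h, w)
  m <- as.numeric((g[, 1] - cy)^2 + (g[, 2] - cx)^2 <= r^2)
  matrix(m, h, w)
}
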