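## Dataset reading and augmentation. Pairs are lists (image [h,w,3] in
## [0,1], mask binary [h,w], optional fov, id). Supported codecs: PNG, TIFF
## and binary/ASCII PPM/PGM; masks are binarised at 50% of their maximum.

read_raster_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    ppm = ,
    pgm = read_pnm(path),
    stop_if(TRUE, "unreadable codec '%s' for file %s (supported: png, tif, ppm, pgm)",
            ext, path)
  )
  img
}

## Minimal PNM (P2/P3/P5/P6) reader; returns [h, w] or [h, w, 3] in [0, 1].
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  stop_if(!magic %in% c("P2", "P3", "P5", "P6"), "unreadable codec for file %s", path)
  vals <- integer(0)
  header <- integer(0)
  repeat {
    line <- readLines(con, 1L)
    line <- sub("#.*$", "", line)
    header <- c(header, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
    header <- header[!is.na(header)]
    if (length(header) >= 3L) break
  }
  w <- header[1]; h <- header[2]; mx <- header[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    raw <- readBin(con, "integer", n, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  ## PNM is row-major, R arrays column-major: fill by row
  if (nch == 1L) {
    matrix(raw / mx, h, w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      a[, , ch] <- matrix(raw[seq(ch, n, by = 3L)] / mx, h, w, byrow = TRUE)
    }
    a
  }
}

write_png_raster <- function(x, path) {
  png::writePNG(clamp01(x), path)
}

#' Construct an image/mask sample pair
#'
#' @param image RGB raster `[h, w, 3]` in `[0, 1]` (grayscale is promoted).
#' @param mask Binary raster `[h, w]`.
#' @param fov Optional binary field-of-view raster `[h, w]`.
#' @param id Sample identifier.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(image, mask, fov = NULL, id = "sample") {
  image <- as_rgb(image)
  stop_if(!identical(dim(image)[1:2], dim(mask)[1:2]),
          "image and mask dimensions differ for id '%s'", id)
  stop_if(!is_binary(mask), "mask must be binary for id '%s'", id)
  if (!is.null(fov)) {
    stop_if(!identical(dim(image)[1:2], dim(fov)[1:2]),
            "image and fov dimensions differ for id '%s'", id)
  }
  structure(list(image = image, mask = mask, fov = fov, id = id),
            class = "sample_pair")
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` vessel-tree masks and rendered fundus images (8-bit PNG;
#' masks use 0/255) under `root/images` and `root/masks`, plus a
#' `manifest.csv` recording filename, per-sample seed and the generator
#' parameters.
#'
#' @param root Output directory (created if missing).
#' @param n Number of pairs.
#' @param size `(h, w)` canvas.
#' @param seed Base seed; sample i uses a seed derived from it.
#' @param contrast,noise_sd Passed to [render_fundus()].
#' @param ... Further arguments to [vessel_tree_params()].
#' @return The manifest data frame, invisibly.
#' @export
write_synthetic_dataset <- function(root, n = 16L, size = c(128L, 128L),
                                    seed = 1L, contrast = 0.6, noise_sd = 0.03,
                                    ...) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    params <- vessel_tree_params(seed = si, canvas_size = size, ...)
    mask <- generate_vessel_mask(params)
    img <- render_fundus(mask, seed = derive_seed(si, 1L), contrast = contrast,
                         noise_sd = noise_sd)
    id <- sprintf("synth_%03d", i)
    write_png_raster(img, file.path(root, "images", paste0(id, ".png")))
    write_png_raster(mask, file.path(root, "masks", paste0(id, ".png")))
    rows[[i]] <- data.frame(id = id, filename = paste0(id, ".png"), seed = si,
                            h = size[1], w = size[2], contrast = contrast,
                            noise_sd = noise_sd)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

## Filename layouts for the supported datasets. `id_from` strips the pattern
## suffix to recover the shared id.
dataset_layouts <- list(
  synthetic = list(images = "images", masks = "masks", fov = NULL,
                   strip = "\\.(png|tif|tiff|ppm|pgm)$"),
  drive = list(images = "images", masks = "1st_manual", fov = "mask",
               strip = "(_training|_test)?(_manual1|_mask)?\\.(png|tif|tiff|ppm|pgm|gif)$"),
  chase = list(images = "images", masks = "labels", fov = NULL,
               strip = "(_1stHO)?\\.(png|tif|tiff|ppm|pgm|gif)$"),
  stare = list(images = "images", masks = "labels", fov = NULL,
               strip = "(\\.ah)?\\.(png|tif|tiff|ppm|pgm|gif)$")
)

#' Load an image/mask dataset from disk
#'
#' Pairs image and label files by shared id under the named directory
#' layout. Masks are binarised at 50% of their maximum value; DRIVE-style
#' layouts use the first annotator's manual segmentation as the label.
#' Supported codecs: PNG, TIFF, PPM/PGM (GIF labels must be converted
#' first; unreadable files raise an error naming the file).
#'
#' @param root Dataset directory.
#' @param layout One of `"synthetic"`, `"drive"`, `"chase"`, `"stare"`.
#' @return List of [sample_pair()] objects, ordered by id.
#' @export
load_dataset <- function(root, layout = c("synthetic", "drive", "chase", "stare")) {
  layout <- match.arg(layout)
  ly <- dataset_layouts[[layout]]
  stop_if(!dir.exists(root), "dataset directory not found: %s", root)
  img_dir <- file.path(root, ly$images)
  msk_dir <- file.path(root, ly$masks)
  stop_if(!dir.exists(img_dir), "missing image directory: %s", img_dir)
  stop_if(!dir.exists(msk_dir), "missing mask directory: %s", msk_dir)
  imgs <- list.files(img_dir)
  msks <- list.files(msk_dir)
  img_ids <- sub(ly$strip, "", imgs)
  msk_ids <- sub(ly$strip, "", msks)
  orphans <- setdiff(img_ids, msk_ids)
  stop_if(length(orphans) > 0, "missing mask for image id(s): %s",
          paste(orphans, collapse = ", "))
  fov_files <- NULL
  if (!is.null(ly$fov) && dir.exists(file.path(root, ly$fov))) {
    fov_files <- list.files(file.path(root, ly$fov))
    names(fov_files) <- sub(ly$strip, "", fov_files)
  }
  ord <- order(img_ids)
  pairs <- vector("list", length(imgs))
  for (k in seq_along(ord)) {
    i <- ord[k]
    id <- img_ids[i]
    img <- as_rgb(read_raster_file(file.path(img_dir, imgs[i])))
    mraw <- read_raster_file(file.path(msk_dir, msks[match(id, msk_ids)]))
    if (length(dim(mraw)) == 3L) mraw <- mraw[, , 1]
    mask <- (mraw >= 0.5 * max(mraw)) * 1
    fov <- NULL
    if (!is.null(fov_files) && id %in% names(fov_files)) {
      fraw <- read_raster_file(file.path(root, ly$fov, fov_files[[id]]))
      if (length(dim(fraw)) == 3L) fraw <- fraw[, , 1]
      fov <- (fraw >= 0.5 * max(fraw)) * 1
    }
    pairs[[k]] <- sample_pair(img, mask, fov, id)
  }
  pairs
}

#' Train/test split specification
#'
#' @param ids All sample ids.
#' @param scheme `"fixed"` (first `n_test` ids test, rest train — the
#'   reference protocol trains on the *last* images and tests on the first),
#'   `"random"`, or `"leave_one_out"`.
#' @param n_train Training-set size for `fixed`/`random`.
#' @param seed Seed for the random scheme.
#' @param swap Swap the roles of the two fixed blocks.
#' @return List with disjoint `train_ids` and `test_ids` (for
#'   `leave_one_out`, a list of folds).
#' @export
make_split <- function(ids, scheme = c("fixed", "random", "leave_one_out"),
                       n_train = NULL, seed = 1L, swap = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme == "leave_one_out") {
    return(lapply(seq_along(ids), function(i) {
      list(train_ids = ids[-i], test_ids = ids[i])
    }))
  }
  if (is.null(n_train)) n_train <- ceiling(length(ids) / 2)
  if (scheme == "random") {
    ids <- with_seed(seed, sample(ids))
  }
  test <- ids[seq_len(length(ids) - n_train)]
  train <- setdiff(ids, test)
  if (swap) {
    tmp <- train; train <- test; test <- tmp
  }
  list(train_ids = train, test_ids = test, scheme = scheme)
}

## ---- cropping and augmentation ----

crop_pair <- function(pair, r0, c0, ch, cw) {
  idx_r <- r0 + seq_len(ch)
  idx_c <- c0 + seq_len(cw)
  sample_pair(pair$image[idx_r, idx_c, , drop = FALSE],
              pair$mask[idx_r, idx_c],
              if (!is.null(pair$fov)) pair$fov[idx_r, idx_c] else NULL,
              pair$id)
}

#' Foreground-maximising sliding-window crop
#'
#' Places a window of `round(window_ratio * H) x round(window_ratio * W)` at
#' a 3 x 3 grid of positions (top/centre/bottom x left/centre/right) and
#' returns the slice with the highest mask-foreground fraction; ties are
#' broken in row-major grid order (top-left first).
#'
#' @param pair A [sample_pair()].
#' @param window_ratio Window size as a fraction of each dimension.
#' @return The cropped `sample_pair`.
#' @export
select_best_slice <- function(pair, window_ratio = 0.6) {
  h <- nrow(pair$mask); w <- ncol(pair$mask)
  ch <- round(window_ratio * h)
  cw <- round(window_ratio * w)
  stop_if(ch < 1 || cw < 1 || ch > h || cw > w, "window does not fit the image")
  offs_r <- round(c(0, 0.5, 1) * (h - ch))
  offs_c <- round(c(0, 0.5, 1) * (w - cw))
  best <- -1
  best_crop <- NULL
  for (i in 1:3) { # row-major: rows outer, cols inner
    for (j in 1:3) {
      frac <- mean(pair$mask[offs_r[i] + seq_len(ch), offs_c[j] + seq_len(cw)])
      if (frac > best) {
        best <- frac
        best_crop <- c(offs_r[i], offs_c[j])
      }
    }
  }
  crop_pair(pair, best_crop[1], best_crop[2], ch, cw)
}

#' Flip a pair horizontally or vertically
#' @param pair A [sample_pair()].
#' @param direction `"horizontal"` (mirror columns) or `"vertical"`.
#' @return The flipped `sample_pair`.
#' @export
flip_pair <- function(pair, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  fl <- function(m) {
    if (direction == "horizontal") {
      if (length(dim(m)) == 3L) m[, ncol(m[, , 1]):1, , drop = FALSE] else m[, ncol(m):1]
    } else {
      if (length(dim(m)) == 3L) m[nrow(m[, , 1]):1, , , drop = FALSE] else m[nrow(m):1, ]
    }
  }
  sample_pair(fl(pair$image), fl(pair$mask),
              if (!is.null(pair$fov)) fl(pair$fov) else NULL, pair$id)
}

#' Rotate a pair
#'
#' Multiples of 90 degrees are exact index permutations (applied identically
#' to image, mask and fov); other angles use a centred affine warp, bilinear
#' for the image and nearest-neighbour for mask/fov. Positive angles rotate
#' counter-clockwise in the usual (x up) orientation.
#'
#' @param pair A [sample_pair()].
#' @param angle Rotation in degrees.
#' @return The rotated `sample_pair`.
#' @export
rotate_pair <- function(pair, angle) {
  a <- angle %% 360
  if (a %in% c(0, 90, 180, 270)) {
    rot90 <- function(m, k) {
      for (i in seq_len(k)) {
        m <- if (length(dim(m)) == 3L) {
          aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
        } else {
          t(m)[ncol(m):1, , drop = FALSE]
        }
      }
      m
    }
    k <- a / 90
    return(sample_pair(rot90(pair$image, k), rot90(pair$mask, k),
                       if (!is.null(pair$fov)) rot90(pair$fov, k) else NULL,
                       pair$id))
  }
  th <- a * pi / 180
  A <- center_affine(affine_transform(cbind(rbind(c(cos(th), -sin(th)),
                                                  c(sin(th), cos(th))), c(0, 0))),
                     dim(pair$mask))
  sample_pair(apply_affine_image(A, pair$image, "bilinear"),
              apply_affine_image(A, pair$mask, "nearest"),
              if (!is.null(pair$fov)) apply_affine_image(A, pair$fov, "nearest") else NULL,
              pair$id)
}

scale_pair_about_center <- function(pair, s) {
  A <- center_affine(affine_transform(cbind(diag(2) * s, c(0, 0))), dim(pair$mask))
  sample_pair(apply_affine_image(A, pair$image, "bilinear"),
              apply_affine_image(A, pair$mask, "nearest"),
              if (!is.null(pair$fov)) apply_affine_image(A, pair$fov, "nearest") else NULL,
              pair$id)
}

#' Random augmentation of a sample pair
#'
#' Seeded composition of horizontal/vertical flips, rotation (a 90-degree
#' multiple or a small angle within +/-15 degrees), isotropic scaling in
#' [0.8, 1.2], and photometric contrast/brightness jitter (image only).
#' Geometric operations are applied identically to image, mask and fov
#' (nearest-neighbour resampling for the masks). With every flag off the
#' pair is returned unchanged.
#'
#' @param pair A [sample_pair()].
#' @param seed Integer seed.
#' @param flip,rotate,scale,contrast,brightness Logical flags enabling each
#'   operation family.
#' @return The augmented `sample_pair`.
#' @export
augment <- function(pair, seed = 1L, flip = TRUE, rotate = TRUE, scale = TRUE,
                    contrast = TRUE, brightness = TRUE) {
  with_seed(seed, {
    if (flip && stats::runif(1) < 0.5) {
      pair <- flip_pair(pair, if (stats::runif(1) < 0.5) "horizontal" else "vertical")
    }
    if (rotate && stats::runif(1) < 0.5) {
      ang <- if (stats::runif(1) < 0.5) {
        sample(c(90, 180, 270), 1)
      } else {
        stats::runif(1, -15, 15)
      }
      pair <- rotate_pair(pair, ang)
    }
    if (scale && stats::runif(1) < 0.5) {
      pair <- scale_pair_about_center(pair, stats::runif(1, 0.8, 1.2))
    }
    img <- pair$image
    if (contrast && stats::runif(1) < 0.5) {
      img <- clamp01((img - 0.5) * stats::runif(1, 0.8, 1.25) + 0.5)
    }
    if (brightness && stats::runif(1) < 0.5) {
      img <- clamp01(img + stats::runif(1, -0.15, 0.15))
    }
    sample_pair(img, pair$mask, pair$fov, pair$id)
  })
}

## Resize a raster ([h,w] or [h,w,c]) to size (h', w').
resize_raster <- function(x, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  if (d[1] == size[1] && d[2] == size[2]) return(x)
  two_d <- length(d) == 2L
  if (two_d) dim(x) <- c(d, 1L)
  nc <- dim(x)[3]
  if (method == "bilinear") {
    out <- cpp_resize_bilinear_fwd(as.numeric(x), d[1], d[2], nc,
                                   as.integer(size[1]), as.integer(size[2]))
    dim(out) <- c(size[1], size[2], nc)
  } else {
    si <- pmin(pmax(floor((seq_len(size[1]) - 0.5) * d[1] / size[1]) + 1, 1), d[1])
    sj <- pmin(pmax(floor((seq_len(size[2]) - 0.5) * d[2] / size[2]) + 1, 1), d[2])
    out <- x[si, sj, , drop = FALSE]
  }
  if (two_d) out[, , 1] else out
}

#' Resize a pair to a target resolution
#'
#' Plain (aspect-ignoring) resize: bilinear for the image, nearest-neighbour
#' then re-binarisation for mask and fov.
#'
#' @param pair A [sample_pair()].
#' @param size Target `(H, W)`, at least 32 x 32.
#' @return The resized `sample_pair`.
#' @export
resize_pair <- function(pair, size) {
  stop_if(any(size < 32), "target size must be at least 32 x 32")
  if (all(dim(pair$mask) == size)) return(pair)
  sample_pair(resize_raster(pair$image, size, "bilinear"),
              (resize_raster(pair$mask, size, "nearest") >= 0.5) * 1,
              if (!is.null(pair$fov)) (resize_raster(pair$fov, size, "nearest") >= 0.5) * 1 else NULL,
              pair$id)
}
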