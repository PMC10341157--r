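## Dataset round trips, the foreground-maximising sliding window, and
## augmentation geometry.

test_that("a written synthetic dataset loads back aligned with its manifest", {
  dir <- withr::local_tempdir()
  man <- write_synthetic_dataset(dir, n = 3, size = c(64L, 64L), seed = 21)
  pairs <- load_dataset(dir, "synthetic")
  expect_length(pairs, 3)
  expect_identical(vapply(pairs, `[[`, character(1), "id"), sort(man$id))
  for (pair in pairs) {
    expect_true(all(pair$mask %in% c(0, 1)))
    expect_identical(dim(pair$image), c(64L, 64L, 3L))
  }
})

test_that("an image without a mask is reported by id", {
  dir <- withr::local_tempdir()
  write_synthetic_dataset(dir, n = 2, size = c(64L, 64L), seed = 22)
  file.remove(file.path(dir, "masks", "synth_002.png"))
  expect_error(load_dataset(dir, "synthetic"), "synth_002")
})

test_that("an unreadable codec is reported by filename", {
  dir <- withr::local_tempdir()
  write_synthetic_dataset(dir, n = 1, size = c(64L, 64L), seed = 23)
  gif <- file.path(dir, "images", "synth_001.gif")
  file.rename(file.path(dir, "images", "synth_001.png"), gif)
  file.rename(file.path(dir, "masks", "synth_001.png"),
              file.path(dir, "masks", "synth_001.gif"))
  expect_error(load_dataset(dir, "synthetic"), "synth_001.gif")
})

test_that("masks stored as 0/255 load as 0/1", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images"))
  dir.create(file.path(dir, "masks"))
  m <- matrix(0, 40, 40)
  m[10:20, 10:20] <- 1
  png::writePNG(array(0.5, c(40, 40, 3)), file.path(dir, "images", "a.png"))
  png::writePNG(m, file.path(dir, "masks", "a.png")) # stored as 0/255 bytes
  pairs <- load_dataset(dir, "synthetic")
  expect_identical(sort(unique(as.numeric(pairs[[1]]$mask))), c(0, 1))
})

test_that("PPM images round-trip through the reader", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "img.ppm")
  vals <- array(runif(6 * 4 * 3), c(6, 4, 3))
  bytes <- round(vals * 255)
  con <- file(path, "wb")
  writeChar(sprintf("P6\n%d %d\n255\n", 4L, 6L), con, eos = NULL)
  ## PPM is row-major RGB-interleaved
  interleaved <- integer(6 * 4 * 3)
  k <- 1
  for (i in 1:6) for (j in 1:4) for (ch in 1:3) {
    interleaved[k] <- bytes[i, j, ch]
    k <- k + 1
  }
  writeBin(as.raw(interleaved), con)
  close(con)
  got <- lavs:::read_raster_file(path)
  expect_equal(got, bytes / 255, tolerance = 1e-12)
})

test_that("select_best_slice picks the exhaustive argmax with row-major ties", {
  ## all-background: every slice ties, top-left wins
  pair <- sample_pair(array(0.5, c(10, 10, 3)), matrix(0, 10, 10), id = "t")
  crop <- select_best_slice(pair)
  expect_identical(dim(crop$mask), c(6L, 6L))
  expect_equal(crop$image, pair$image[1:6, 1:6, , drop = FALSE])

  ## foreground in the bottom-right corner
  m <- matrix(0, 10, 10)
  m[5:10, 5:10] <- 1
  pair <- sample_pair(array(0.5, c(10, 10, 3)), m, id = "t")
  crop <- select_best_slice(pair)
  expect_equal(crop$mask, m[5:10, 5:10])

  ## window dimensions follow round(0.6 * H) x round(0.6 * W)
  pair <- sample_pair(array(0.5, c(23, 37, 3)), matrix(0, 23, 37), id = "t")
  crop <- select_best_slice(pair)
  expect_identical(dim(crop$mask), as.integer(c(round(0.6 * 23), round(0.6 * 37))))

  ## property: chosen fraction >= every grid slice's fraction
  for (s in 1:5) {
    pair <- toy_pair(c(40L, 40L), seed = s)
    crop <- select_best_slice(pair)
    ch <- round(0.6 * 40)
    offs <- round(c(0, 0.5, 1) * (40 - ch))
    fracs <- c()
    for (i in offs) for (j in offs) {
      fracs <- c(fracs, mean(pair$mask[i + seq_len(ch), j + seq_len(ch)]))
    }
    expect_gte(mean(crop$mask), max(fracs) - 1e-12)
  }
})

test_that("augmentation building blocks are exact and aligned", {
  pair <- toy_pair(c(32L, 32L), seed = 9)
  ## flips are involutions
  expect_equal(flip_pair(flip_pair(pair, "horizontal"), "horizontal"), pair)
  expect_equal(flip_pair(flip_pair(pair, "vertical"), "vertical"), pair)

  ## rotation by 90 degrees matches the index-permutation oracle
  m <- matrix(0, 10, 10)
  m[3, 6] <- 1 # 0-based (2, 5)
  p0 <- sample_pair(array(rep(m, 3), c(10, 10, 3)), m, id = "px")
  r <- rotate_pair(p0, 90)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) oracle[i, j] <- m[j, 10 + 1 - i]
  expect_equal(r$mask, oracle)
  ## image and mask transported identically
  expect_equal(r$image[, , 1], oracle)
  ## four quarter turns restore the original
  r4 <- rotate_pair(rotate_pair(rotate_pair(rotate_pair(p0, 90), 90), 90), 90)
  expect_equal(r4$mask, m)

  ## all augmentation flags off leaves the pair unchanged
  expect_equal(augment(pair, seed = 3, flip = FALSE, rotate = FALSE,
                       scale = FALSE, contrast = FALSE, brightness = FALSE),
               pair)
  ## fixed seed reproduces
  expect_equal(augment(pair, seed = 17), augment(pair, seed = 17))
  ## masks stay binary through augmentation
  a <- augment(pair, seed = 20)
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("resize_pair follows the spatial contract", {
  pair <- toy_pair(c(40L, 40L), seed = 12)
  expect_identical(resize_pair(pair, c(40L, 40L)), pair)
  big <- resize_pair(toy_pair(c(64L, 64L), seed = 13), c(48L, 48L))
  expect_identical(dim(big$image), c(48L, 48L, 3L))
  expect_identical(dim(big$mask), c(48L, 48L))
  expect_true(all(big$mask %in% c(0, 1)))
  ## the reference training protocol: native frames resized to 512 x 512
  fake <- sample_pair(array(0.5, c(584, 565, 3)),
                      matrix(0, 584, 565), id = "native")
  rs <- resize_pair(fake, c(512L, 512L))
  expect_identical(dim(rs$image), c(512L, 512L, 3L))
})

test_that("splits are disjoint and leave-one-out covers every sample", {
  ids <- sprintf("s%02d", 1:10)
  sp <- make_split(ids, "fixed", n_train = 6)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  folds <- make_split(ids, "leave_one_out")
  expect_length(folds, 10)
  for (i in seq_along(folds)) {
    expect_identical(folds[[i]]$test_ids, ids[i])
    expect_false(ids[i] %in% folds[[i]]$train_ids)
  }
})
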