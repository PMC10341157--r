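## Pixel-level evaluation: confusion counts, metrics, pooling conventions,
## leave-one-out orchestration, and the colour-coded error overlay.

test_that("confusion counts match a hand-counted worked example", {
  y <- matrix(0, 10, 10)
  y[2, 1:10] <- 1 # ten true vessel pixels
  pred <- matrix(0, 10, 10)
  pred[2, 1:8] <- 1 # hits 8 of them
  pred[5, 3:4] <- 1 # plus two background pixels
  cc <- confusion(pred, y)
  expect_identical(cc$tp, 8L)
  expect_identical(cc$fp, 2L)
  expect_identical(cc$fn, 2L)
  expect_identical(cc$tn, 88L)

  expect_identical(confusion(y, y)$fp, 0L)
  expect_identical(confusion(y, y)$fn, 0L)
  inv <- confusion(1 - y, y)
  expect_identical(inv$tp, 0L)
  expect_identical(inv$tn, 0L)
  expect_error(confusion(matrix(0, 4, 4), y), "shapes differ")
})

test_that("metrics follow their formulas, undefined cases are NA", {
  m <- metrics(list(tp = 8, tn = 88, fp = 2, fn = 2))
  expect_equal(m$se, 0.8)
  expect_equal(m$sp, 88 / 90, tolerance = 1e-9)
  expect_equal(m$acc, 0.96)
  expect_equal(m$f1, 0.8)

  perfect <- metrics(list(tp = 10, tn = 90, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("acc", "se", "sp", "f1")]),
               c(acc = 1, se = 1, sp = 1, f1 = 1))

  degenerate <- metrics(list(tp = 0, tn = 50, fp = 0, fn = 0))
  expect_equal(degenerate$sp, 1)
  expect_true(is.na(degenerate$se))
})

test_that("confusion agrees with an independent tally and is additive", {
  set.seed(13)
  for (rep in 1:10) {
    pred <- matrix(runif(32 * 32), 32, 32)
    y <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    cc <- confusion(pred, y)
    ## independent route: cross-tabulate the two binarised label vectors
    tab <- table(factor(as.numeric(pred >= 0.5), levels = c(0, 1)),
                 factor(as.numeric(y), levels = c(0, 1)))
    expect_identical(cc$tp, as.integer(tab["1", "1"]))
    expect_identical(cc$tn, as.integer(tab["0", "0"]))
    expect_identical(cc$fp, as.integer(tab["1", "0"]))
    expect_identical(cc$fn, as.integer(tab["0", "1"]))

    ## additive over a disjoint FOV partition
    fov_a <- matrix(0, 32, 32)
    fov_a[1:16, ] <- 1
    fov_b <- 1 - fov_a
    ca <- confusion(pred, y, fov = fov_a)
    cb <- confusion(pred, y, fov = fov_b)
    expect_identical(cc$tp, ca$tp + cb$tp)
    expect_identical(cc$fn, ca$fn + cb$fn)

    ## permutation invariance of the counts
    perm <- sample(32 * 32)
    cp <- confusion(matrix(pred[perm], 32), matrix(y[perm], 32))
    expect_identical(cp, cc)
  }
})

test_that("converting one FN to TP never lowers F1", {
  f1 <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  set.seed(14)
  for (rep in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(1:50, 1)
    expect_gte(f1(tp + 1, fp, fn - 1), f1(tp, fp, fn))
  }
})

test_that("error overlays colour-code FN blue and FP red", {
  pair <- toy_pair(c(32L, 32L), seed = 6)
  y <- pair$mask
  ## perfect prediction: no pure red or blue pixels
  ov <- render_error_overlay(y, y, pair$image)
  is_red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  is_blue <- ov[, , 3] == 1 & ov[, , 1] == 0 & ov[, , 2] == 0
  expect_identical(sum(is_red), 0L)
  expect_identical(sum(is_blue), 0L)

  ## all-zero prediction: every vessel pixel becomes a blue FN
  ov0 <- render_error_overlay(y * 0, y, pair$image)
  blue0 <- ov0[, , 3] == 1 & ov0[, , 1] == 0 & ov0[, , 2] == 0
  expect_identical(sum(blue0), as.integer(sum(y)))

  ## red pixel count equals fp from confusion() on the same inputs
  set.seed(15)
  pred <- (matrix(runif(32 * 32), 32) > 0.5) * 1
  ovr <- render_error_overlay(pred, y, pair$image)
  redr <- ovr[, , 1] == 1 & ovr[, , 2] == 0 & ovr[, , 3] == 0
  expect_identical(sum(redr), confusion(pred, y)$fp)
})

test_that("evaluate_split reports both pooling conventions consistently", {
  pairs <- lapply(1:2, function(s) toy_pair(c(32L, 32L), seed = s))
  cfg <- tiny_train_cfg("unet", epochs = 1L, seed = 5L)
  fit <- train(pairs, cfg)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "report.csv")
  ev <- evaluate_split(fit, pairs, csv = csv)
  expect_s3_class(ev$pixel_pooled, "metric_report")
  expect_identical(nrow(ev$per_image), 2L)
  got <- utils::read.csv(csv)
  expect_identical(nrow(got), 3L) # one row per image plus the pooled summary
  expect_identical(got$id[3], "POOLED")

  ## identical images: per-image mean equals pixel pooling
  same <- list(pairs[[1]], pairs[[1]])
  ev2 <- evaluate_split(fit, same)
  expect_equal(ev2$per_image_mean$f1, ev2$pixel_pooled$f1, tolerance = 1e-12)
  expect_equal(ev2$per_image_mean$acc, ev2$pixel_pooled$acc, tolerance = 1e-12)
})

test_that("leave-one-out trains one fold per pair and averages them", {
  pairs <- lapply(1:3, function(s) toy_pair(c(32L, 32L), seed = s + 10))
  cfg <- tiny_train_cfg("unet", epochs = 1L, seed = 7L)
  loo <- leave_one_out(pairs, cfg)
  expect_length(loo$folds, 3)
  expect_length(loo$fits, 3)
  for (k in c("acc", "se", "sp", "f1")) {
    folds_k <- vapply(loo$folds, `[[`, numeric(1), k)
    expect_equal(loo$aggregate[[k]], mean(folds_k, na.rm = TRUE),
                 tolerance = 1e-9)
  }
  expect_error(leave_one_out(pairs[1], cfg), "at least 2")
})
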