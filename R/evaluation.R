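## Pixel-classification evaluation: confusion counts inside an optional
## field of view, Acc/Se/Sp/F1, split evaluation with both pooling
## conventions, leave-one-out orchestration, and colour-coded error
## overlays (false negatives blue, false positives red).

#' Pixel confusion counts
#'
#' Binarises the prediction at `threshold` and tallies TP/TN/FP/FN against
#' the binary ground truth, restricted to the field of view when one is
#' given.
#'
#' @param y_pre Probability raster (values in `[0, 1]`).
#' @param y Binary ground-truth raster of the same spatial size.
#' @param threshold Binarisation threshold, default 0.5 (`>=`).
#' @param fov Optional binary mask restricting the counted pixels.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(y_pre, y, threshold = 0.5, fov = NULL) {
  stop_if(!identical(dim_hw(y_pre), dim_hw(y)),
          "prediction and target shapes differ")
  p <- as.numeric(y_pre) >= threshold
  t <- as.numeric(y) > 0.5
  keep <- if (is.null(fov)) rep(TRUE, length(p)) else as.numeric(fov) > 0.5
  stop_if(!is.null(fov) && length(keep) != length(p),
          "fov shape differs from prediction")
  p <- p[keep]; t <- t[keep]
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/total`,
#' `F1 = 2TP/(2TP+FP+FN)`. A metric whose denominator is zero is reported
#' as `NA` (undefined), not as 0.
#'
#' @param c A `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return An object of class `metric_report` with `acc`, `se`, `sp`, `f1`.
#' @export
metrics <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(acc = safe(c$tp + c$tn, tot),
                 se = safe(c$tp, c$tp + c$fn),
                 sp = safe(c$tn, c$tn + c$fp),
                 f1 = safe(2 * c$tp, 2 * c$tp + c$fp + c$fn)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Acc %.4f  Se %.4f  Sp %.4f  F1 %.4f\n", x$acc, x$se, x$sp, x$f1))
  invisible(x)
}

#' Evaluate a trained model on a set of pairs
#'
#' Predicts each image at the training resolution, resizes the probability
#' map back to the native mask resolution, counts confusion within the pair's
#' fov (if any), and reports both pooling conventions: `pixel_pooled`
#' (counts summed over images before computing metrics) and
#' `per_image_mean` (metrics averaged over images).
#'
#' @param fit A [train()] result, checkpoint list, or bare `vessel_net`.
#' @param pairs List of [sample_pair()] objects.
#' @param threshold Binarisation threshold.
#' @param csv Optional path for a per-image CSV
#'   (`id, acc, se, sp, f1, tp, tn, fp, fn` plus a pooled summary row).
#' @return List with `pixel_pooled` and `per_image_mean` metric reports and
#'   the per-image data frame `per_image`.
#' @export
evaluate_split <- function(fit, pairs, threshold = 0.5, csv = NULL) {
  net <- if (inherits(fit, "vessel_net")) fit else fit$net
  rows <- vector("list", length(pairs))
  pooled <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    p <- predict_vessels(net, pair$image)
    cc <- confusion(p, pair$mask, threshold, pair$fov)
    m <- metrics(cc)
    pooled <- list(tp = pooled$tp + cc$tp, tn = pooled$tn + cc$tn,
                   fp = pooled$fp + cc$fp, fn = pooled$fn + cc$fn)
    rows[[i]] <- data.frame(id = pair$id, acc = m$acc, se = m$se, sp = m$sp,
                            f1 = m$f1, tp = cc$tp, tn = cc$tn, fp = cc$fp,
                            fn = cc$fn)
  }
  per_image <- do.call(rbind, rows)
  pm <- metrics(structure(pooled, class = "confusion_counts"))
  mean_rep <- structure(list(acc = mean(per_image$acc, na.rm = TRUE),
                             se = mean(per_image$se, na.rm = TRUE),
                             sp = mean(per_image$sp, na.rm = TRUE),
                             f1 = mean(per_image$f1, na.rm = TRUE)),
                        class = "metric_report")
  if (!is.null(csv)) {
    summary_row <- data.frame(id = "POOLED", acc = pm$acc, se = pm$se,
                              sp = pm$sp, f1 = pm$f1, tp = pooled$tp,
                              tn = pooled$tn, fp = pooled$fp, fn = pooled$fn)
    utils::write.csv(rbind(per_image, summary_row), csv, row.names = FALSE)
  }
  list(pixel_pooled = pm, per_image_mean = mean_rep, per_image = per_image)
}

#' Leave-one-out cross-validation
#'
#' Trains one model per fold on all pairs but one, evaluates on the held-out
#' pair, and aggregates by the arithmetic mean of per-fold metrics. Fold `i`
#' trains with seed `cfg$seed + i`.
#'
#' @param pairs At least two [sample_pair()] objects.
#' @param cfg A [train_config()].
#' @return List with `aggregate` (mean metric report), `folds` (per-fold
#'   reports) and `fits` (per-fold training results).
#' @export
leave_one_out <- function(pairs, cfg) {
  stop_if(length(pairs) < 2, "leave-one-out needs at least 2 pairs")
  folds <- vector("list", length(pairs))
  fits <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    fit <- train(pairs[-i], fold_cfg)
    ev <- evaluate_split(fit, pairs[i])
    folds[[i]] <- ev$pixel_pooled
    fits[[i]] <- fit
  }
  agg <- structure(lapply(c(acc = "acc", se = "se", sp = "sp", f1 = "f1"),
                          function(k) mean(vapply(folds, `[[`, numeric(1), k),
                                           na.rm = TRUE)),
                   class = "metric_report")
  list(aggregate = agg, folds = folds, fits = fits)
}

#' Colour-coded segmentation error overlay
#'
#' True positives are drawn white, false negatives blue (missed vessels),
#' false positives red (over-segmentation); true-negative background shows
#' the dimmed input image.
#'
#' @param y_pre Binary (or probability, thresholded at 0.5) prediction.
#' @param y Binary ground truth.
#' @param image RGB raster of the same spatial size.
#' @return RGB raster `[h, w, 3]`.
#' @export
render_error_overlay <- function(y_pre, y, image) {
  stop_if(!identical(dim_hw(y_pre), dim_hw(y)), "prediction and target shapes differ")
  image <- as_rgb(image)
  stop_if(!identical(dim(image)[1:2], dim_hw(y)), "image shape differs")
  p <- matrix(as.numeric(y_pre) >= 0.5, nrow(y), ncol(y))
  t <- matrix(as.numeric(y) > 0.5, nrow(y), ncol(y))
  out <- image * 0.4
  tp <- p & t
  fn <- !p & t
  fp <- p & !t
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[tp] <- 1
    plane[fn] <- if (ch == 3) 1 else 0
    plane[fp] <- if (ch == 1) 1 else 0
    out[, , ch] <- plane
  }
  out
}
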