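## Composite training objective: pixel-level Dice + BCE segmentation loss,
## an adversarial term from a small patch discriminator (global shape
## realism), the landmark consistency/contrastive terms, and the
## landmark-coordinate pseudo-label loss, combined as
## total = l1*seg + l2*adv + l3*(ctr + cst) + l4*lmd.

#' Loss balance weights
#'
#' Defaults `(0.2, 0.3, 0.4, 0.1)` for the segmentation, adversarial,
#' contrastive+consistency, and landmark terms respectively.
#' @param l1,l2,l3,l4 Non-negative reals.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(l1 = 0.2, l2 = 0.3, l3 = 0.4, l4 = 0.1) {
  stop_if(any(c(l1, l2, l3, l4) < 0), "loss weights must be non-negative")
  structure(list(l1 = l1, l2 = l2, l3 = l3, l4 = l4), class = "loss_weights")
}

#' Segmentation loss: BCE + Dice
#'
#' Mean binary cross-entropy (predictions clamped to `[eps, 1 - eps]`) plus
#' the Dice loss `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)`.
#'
#' @param y_pre Probability raster in `(0, 1)`.
#' @param y Binary raster of the same shape.
#' @param eps Stabiliser, default `1e-6`.
#' @return Scalar loss.
#' @export
seg_loss <- function(y_pre, y, eps = 1e-6) {
  stop_if(!identical(dim_hw(y_pre), dim_hw(y)),
          "prediction and target shapes differ")
  p <- pmin(pmax(as.numeric(y_pre), eps), 1 - eps)
  yv <- as.numeric(y)
  bce <- -mean(yv * log(p) + (1 - yv) * log(1 - p))
  dice <- (2 * sum(as.numeric(y_pre) * yv) + eps) /
    (sum(as.numeric(y_pre)) + sum(yv) + eps)
  bce + (1 - dice)
}

dim_hw <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d[1:2]
}

graph_seg_loss <- function(ypre, y, eps = 1e-6) {
  yv <- as.numeric(y)
  dim(yv) <- dim(ad_value(ypre))
  pc <- ad_clamp(ypre, eps, 1 - eps)
  qc <- ad_clamp(ad_shift(ad_scale(ypre, -1), 1), eps, 1 - eps)
  bce <- ad_scale(ad_add(ad_mul(ad_log(pc), ad_input(yv)),
                         ad_mul(ad_log(qc), ad_input(1 - yv))),
                  -1)
  bce <- ad_mean_all(bce)
  inter <- ad_sum_all(ad_mul(ypre, ad_input(yv)))
  dice <- ad_div(ad_shift(ad_scale(inter, 2), eps),
                 ad_shift(ad_sum_all(ypre), sum(yv) + eps))
  ad_add(bce, ad_shift(ad_scale(dice, -1), 1))
}

## Training-time variant fed with pre-sigmoid logits: the BCE part uses the
## softplus identity BCE = mean(softplus(z) - y * z), whose gradient
## sigmoid(z) - y never vanishes under saturation; the Dice part uses the
## sigmoid probabilities. Equal to graph_seg_loss(sigmoid(z), y) away from
## the clamp boundaries.
graph_seg_loss_logits <- function(zlog, ypre, y, eps = 1e-6) {
  yv <- as.numeric(y)
  dim(yv) <- dim(ad_value(zlog))
  bce <- ad_mean_all(ad_sub(ad_softplus(zlog), ad_mul(zlog, ad_input(yv))))
  inter <- ad_sum_all(ad_mul(ypre, ad_input(yv)))
  dice <- ad_div(ad_shift(ad_scale(inter, 2), eps),
                 ad_shift(ad_sum_all(ypre), sum(yv) + eps))
  ad_add(bce, ad_shift(ad_scale(dice, -1), 1))
}

#' Build the discriminator
#'
#' Four stride-2 3x3 convolutions with LeakyReLU, global average pooling and
#' a sigmoid scalar output; judges a segmentation map alone (not conditioned
#' on the image).
#'
#' @param channels Widths of the four conv blocks.
#' @param seed Integer seed for initialisation.
#' @return An object of class `vessel_disc`.
#' @export
discriminator <- function(channels = c(16L, 32L, 64L, 128L), seed = 1L) {
  stop_if(length(channels) != 4, "discriminator needs four conv widths")
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in 1:4) {
      p[[paste0("d", i)]] <- conv_init(3, 3, cin, channels[i])
      cin <- channels[i]
    }
    p$fc <- list(w = xavier_init(cin, 1L), b = numeric(1))
    structure(list(params = p, channels = as.integer(channels)),
              class = "vessel_disc")
  })
}

## x: [h, w, 1] node or array; dn: flat param-node list. Returns scalar node.
graph_disc_forward <- function(dn, x) {
  z <- as_adnode(x)
  for (i in 1:4) {
    z <- ad_leaky_relu(ad_conv2d(z, dn[[paste0("d", i, ".w")]],
                                 dn[[paste0("d", i, ".b")]],
                                 stride = 2L, pad = 1L), alpha = 0.2)
  }
  d <- dim(ad_value(z))
  flat <- ad_reshape(z, c(d[1] * d[2], d[3]))
  gap <- ad_matmul(ad_input(matrix(1 / (d[1] * d[2]), 1, d[1] * d[2])), flat)
  ad_sigmoid(ad_add_bias(ad_matmul(gap, dn[["fc.w"]]), dn[["fc.b"]]))
}

#' Score a segmentation map with the discriminator
#' @param d A [discriminator()].
#' @param x Raster `[h, w]` or `[h, w, 1]` of probabilities or labels.
#' @return Probability in `(0, 1)` that `x` is a real (ground-truth) map.
#' @export
disc_predict <- function(d, x) {
  stopifnot(inherits(d, "vessel_disc"))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  dn <- lapply(flatten_params(d$params), ad_param)
  as.numeric(ad_value(graph_disc_forward(dn, ad_input(x))))
}

#' Adversarial losses for discriminator and generator
#'
#' The discriminator minimises `-log D(Y) - log(1 - D(Ypre))` (the negated
#' maximisation objective); the generator term entering the total loss is
#' the non-saturating `-log D(Ypre)`.
#'
#' @param d A [discriminator()] or a function mapping a raster to a
#'   probability.
#' @param y Binary ground-truth raster.
#' @param y_pre Predicted probability raster.
#' @return List with scalars `L_D` and `L_G`.
#' @export
adversarial_losses <- function(d, y, y_pre) {
  score <- if (is.function(d)) d else function(x) disc_predict(d, x)
  eps <- 1e-12
  dr <- min(max(score(y), eps), 1 - eps)
  df <- min(max(score(y_pre), eps), 1 - eps)
  list(L_D = -(log(dr) + log(1 - df)), L_G = -log(df))
}

#' Landmark pseudo-label loss
#'
#' Mean squared Euclidean distance between predicted landmarks and the
#' pseudo-label landmarks extracted from the ground-truth mask.
#'
#' @param R,RY `[K, 2]` ordered landmark matrices.
#' @return Non-negative scalar.
#' @export
landmark_loss <- function(R, RY) {
  R <- matrix(as.numeric(R), ncol = 2)
  RY <- matrix(as.numeric(RY), ncol = 2)
  stop_if(nrow(R) != nrow(RY), "landmark sets differ in size (%d vs %d)",
          nrow(R), nrow(RY))
  mean(rowSums((R - RY)^2))
}

#' Combine loss components into the weighted total
#'
#' `total = l1*seg + l2*adv + l3*(ctr + cst) + l4*lmd`.
#'
#' @param seg,adv,ctr,cst,lmd Finite scalar components.
#' @param weights A [loss_weights()].
#' @return An object of class `loss_bundle`: the five components plus
#'   `total`.
#' @export
total_loss <- function(seg, adv = 0, ctr = 0, cst = 0, lmd = 0,
                       weights = loss_weights()) {
  comps <- c(seg = seg, adv = adv, ctr = ctr, cst = cst, lmd = lmd)
  bad <- names(comps)[!is.finite(comps)]
  stop_if(length(bad) > 0, "non-finite loss component: %s",
          paste(bad, collapse = ", "))
  total <- weights$l1 * seg + weights$l2 * adv + weights$l3 * (ctr + cst) +
    weights$l4 * lmd
  structure(list(seg = seg, adv = adv, ctr = ctr, cst = cst, lmd = lmd,
                 total = total), class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("loss bundle: seg %.4f  adv %.4f  ctr %.4f  cst %.4f  lmd %.4f  total %.4f\n",
              x$seg, x$adv, x$ctr, x$cst, x$lmd, x$total))
  invisible(x)
}
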