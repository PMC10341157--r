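## Training loop: one image per iteration (batch size 1), Adam with weight
## decay, alternating discriminator/generator updates, and the composite
## objective. Per iteration the self-supervised branch builds a style view
## and an affine view of the input, extracts landmarks from all views plus
## pseudo-label landmarks from the ground-truth mask, and renders the
## Gaussian landmark map fed to the decoder.

#' Training configuration
#'
#' @param epochs Number of passes over the training pairs.
#' @param seed Integer seed controlling initialisation and all per-iteration
#'   randomness (derived sub-seeds, so runs are reproducible).
#' @param net A [net_config()] describing the model variant.
#' @param lr Adam learning rate for the generator.
#' @param lr_d Adam learning rate for the discriminator; kept an order of
#'   magnitude below `lr` so the discriminator never saturates and the
#'   non-saturating generator gradient stays bounded.
#' @param weight_decay L2 weight decay added to gradients.
#' @param batch_size Images per iteration (the reference protocol uses 1).
#' @param image_size Training resolution `(H, W)`; pairs are resized to it.
#' @param weights A [loss_weights()].
#' @param sigma Gaussian-map standard deviation in feature-grid units.
#' @param temperature NT-Xent temperature for the contrastive term.
#' @param disc_channels Discriminator conv widths.
#' @param d_steps Discriminator updates per generator update.
#' @param affine_bounds Named list of sampling bounds for the consistency
#'   view: `max_rotation` (deg), `max_scale_dev`, `max_shear`,
#'   `max_translate` (px).
#' @param augment Apply foreground-maximising slice selection plus random
#'   flips/photometrics to each training pair.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, seed = 1L, net = net_config(),
                         lr = 0.001, lr_d = lr / 10, weight_decay = 0.0005,
                         batch_size = 1L,
                         image_size = NULL, weights = loss_weights(),
                         sigma = 0.7, temperature = 0.2,
                         disc_channels = c(16L, 32L, 64L, 128L), d_steps = 1L,
                         affine_bounds = list(max_rotation = 10, max_scale_dev = 0.1,
                                              max_shear = 0.05, max_translate = 4),
                         augment = FALSE) {
  stop_if(batch_size < 1, "batch_size must be >= 1")
  stop_if(epochs < 1, "epochs must be >= 1")
  if (is.null(image_size)) image_size <- net$image_size
  structure(list(epochs = as.integer(epochs), seed = as.integer(seed), net = net,
                 lr = lr, lr_d = lr_d, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size), weights = weights,
                 sigma = sigma, temperature = temperature,
                 disc_channels = as.integer(disc_channels),
                 d_steps = as.integer(d_steps), affine_bounds = affine_bounds,
                 augment = isTRUE(augment)),
            class = "train_config")
}

## Adam with decoupled-from-nothing classic L2 decay folded into the gradient.
adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_update <- function(flat, grads, st, lr, wd, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * flat[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    flat[[nm]] <- flat[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, st = st)
}

collect_grads <- function(pn) {
  lapply(pn, function(nd) nd$grad)
}

## One generator-side loss graph for a single (image, mask) pair.
## Returns list(total = node, comps = numeric components, pn = param nodes).
build_train_graph <- function(net, disc, x, y, cfg, iter_seed) {
  w <- cfg$weights
  vcfg <- net$cfg
  sld <- vcfg$variant == "transunet_sld"
  pn <- param_nodes(net)
  xn <- ad_input(x)
  feats <- graph_encode(pn, vcfg, xn)
  mt <- graph_bottleneck(pn, vcfg, feats$m3)
  d3 <- dim(ad_value(feats$m3))
  h4 <- d3[1]; w4 <- d3[2]

  comps <- c(seg = 0, adv = 0, ctr = 0, cst = 0, lmd = 0)
  R_node <- NULL
  Rval <- NULL
  mgm <- NULL
  heads <- NULL
  if (sld) {
    heads <- ad_scale(graph_project_heads(pn, feats$m3), vcfg$head_gain)
    pflat <- graph_spatial_softmax(heads)
    R_node <- graph_soft_argmax(pflat, h4, w4)
    Rval <- ad_value(R_node)
    ## Gaussian map from the predicted landmarks; constant w.r.t. the graph
    mgm <- ad_input(render_gaussian_map(Rval, c(h4, w4), cfg$sigma))
  }
  zlog <- graph_decode_logits(pn, vcfg, feats, mt, mgm)
  ypre <- ad_sigmoid(zlog)
  terms <- list()
  lseg <- graph_seg_loss_logits(zlog, ypre, y)
  comps["seg"] <- ad_value(lseg)
  terms$seg <- ad_scale(lseg, w$l1)

  if (w$l2 > 0) {
    dn <- lapply(flatten_params(disc$params), ad_input) # frozen for generator
    lg <- ad_scale(ad_log(ad_clamp(graph_disc_forward(dn, ypre), 1e-12, 1)), -1)
    comps["adv"] <- ad_value(lg)
    terms$adv <- ad_scale(lg, w$l2)
  }

  if (sld && w$l3 > 0) {
    ## consistency view: affine-warped image, landmarks mapped back
    A_img <- center_affine(
      sample_affine(derive_seed(iter_seed, 1L),
                    cfg$affine_bounds$max_rotation, cfg$affine_bounds$max_scale_dev,
                    cfg$affine_bounds$max_shear, cfg$affine_bounds$max_translate),
      dim(x))
    xw <- apply_affine_image(A_img, x)
    featsw <- graph_encode(pn, vcfg, ad_input(xw))
    pw <- graph_spatial_softmax(ad_scale(graph_project_heads(pn, featsw$m3),
                                         vcfg$head_gain))
    Rw <- graph_soft_argmax(pw, h4, w4)
    Agi <- invert_affine(grid_affine(A_img))
    Rback <- ad_add_bias(ad_matmul(Rw, t(Agi$matrix[, 1:2])), Agi$matrix[, 3])
    diffc <- ad_sub(R_node, Rback)
    lcst <- ad_scale(ad_sum_all(ad_mul(diffc, diffc)), 1 / nrow(Rval))
    comps["cst"] <- ad_value(lcst)

    ## contrastive view: photometric style jitter, same geometry
    ## the style view keeps the geometry, so both descriptor sets are
    ## sampled at the original view's landmark coordinates: landmark k is
    ## the same physical location in both views
    xs <- style_transform(x, derive_seed(iter_seed, 2L))
    featss <- graph_encode(pn, vcfg, ad_input(xs))
    headss <- ad_scale(graph_project_heads(pn, featss$m3), vcfg$head_gain)
    desc_a <- ad_sample_bilinear(heads, Rval)
    desc_b <- ad_sample_bilinear(headss, Rval)
    lctr <- graph_contrastive_loss(desc_a, desc_b, cfg$temperature)
    comps["ctr"] <- ad_value(lctr)
    terms$ctrcst <- ad_scale(ad_add(lctr, lcst), w$l3)
  }

  if (sld && w$l4 > 0) {
    RY <- extract_landmarks(net, y) # pseudo-labels; detached
    diffl <- ad_sub(R_node, ad_input(RY))
    llmd <- ad_scale(ad_sum_all(ad_mul(diffl, diffl)), 1 / nrow(Rval))
    comps["lmd"] <- ad_value(llmd)
    terms$lmd <- ad_scale(llmd, w$l4)
  }

  total <- Reduce(ad_add, terms)
  list(total = total, comps = comps, pn = pn, ypre_val = ad_value(ypre))
}

## Image-pixel affine expressed on the H/4 feature grid whose cell centres
## sit at image coordinates 4*i + 1.5.
grid_affine <- function(A) {
  L <- A$matrix[, 1:2]
  ctr <- c(1.5, 1.5)
  affine_transform(cbind(L, ((L - diag(2)) %*% ctr + A$matrix[, 3]) / 4))
}

disc_step <- function(disc, dst, y, ypre_val, cfg) {
  dn <- lapply(flatten_params(disc$params), ad_param)
  dr <- ad_clamp(graph_disc_forward(dn, ad_input(y)), 1e-12, 1 - 1e-12)
  df <- ad_clamp(graph_disc_forward(dn, ad_input(ypre_val)), 1e-12, 1 - 1e-12)
  ld <- ad_scale(ad_add(ad_log(dr), ad_log(ad_shift(ad_scale(df, -1), 1))), -1)
  ad_backward(ld)
  flat <- flatten_params(disc$params)
  up <- adam_update(flat, collect_grads(dn), dst, cfg$lr_d, cfg$weight_decay)
  disc$params <- unflatten_params(up$flat)
  list(disc = disc, dst = up$st, L_D = ad_value(ld))
}

prepare_pair_for_training <- function(pair, cfg, iter_seed) {
  if (cfg$augment) {
    pair <- select_best_slice(pair)
    pair <- augment(pair, derive_seed(iter_seed, 9L))
  }
  resize_pair(pair, cfg$image_size)
}

#' Train a segmentation network
#'
#' Runs the full composite-objective training: per iteration the generator
#' graph (segmentation + adversarial + landmark terms) is built and
#' back-propagated, preceded by `d_steps` discriminator updates on the
#' detached prediction. Loss components with zero weight (and all landmark
#' terms for non-SLD variants) are skipped entirely and logged as 0.
#'
#' @param pairs Non-empty list of `sample_pair` objects.
#' @param cfg A [train_config()].
#' @param log_csv Optional path; per-iteration loss components are written
#'   as CSV (`epoch, iter, seg, adv, ctr, cst, lmd, total`).
#' @param checkpoint Optional path; the trained model is saved there via
#'   [save_checkpoint()].
#' @return List with the trained `net`, the `disc`riminator, and `history`
#'   (the per-iteration loss data frame).
#' @export
train <- function(pairs, cfg, log_csv = NULL, checkpoint = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  stop_if(length(pairs) == 0, "training set is empty")
  net <- vessel_net(cfg$net, seed = cfg$seed)
  disc <- discriminator(cfg$disc_channels, seed = derive_seed(cfg$seed, 77L))
  flat <- flatten_params(net$params)
  gst <- adam_state(flat)
  dst <- adam_state(flatten_params(disc$params))
  w <- cfg$weights
  history <- vector("list", cfg$epochs * length(pairs))
  it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    for (pi in seq_along(pairs)) {
      it <- it + 1L
      iseed <- derive_seed(cfg$seed, it)
      pair <- prepare_pair_for_training(pairs[[pi]], cfg, iseed)
      x <- pair$image
      y <- pair$mask
      if (w$l2 > 0) {
        ## discriminator sees the current generator output, detached
        pre <- graph_forward_segment(param_nodes(net), net$cfg, ad_input(x),
                                     NULL)
        ypre_det <- ad_value(pre$ypre)
        for (s in seq_len(cfg$d_steps)) {
          ds <- disc_step(disc, dst, array(y, dim = c(dim(y), 1L)), ypre_det, cfg)
          disc <- ds$disc
          dst <- ds$dst
        }
      }
      gr <- build_train_graph(net, disc, x, y, cfg, iseed)
      tv <- ad_value(gr$total)
      if (!is.finite(tv)) {
        dump <- file.path(tempdir(), sprintf("lavs_diverged_ep%d_it%d.rds", ep, it))
        saveRDS(list(net = net, disc = disc, comps = gr$comps), dump)
        stop_if(TRUE, "training diverged (non-finite loss) at epoch %d iter %d; state dumped to %s",
                ep, it, dump)
      }
      ad_backward(gr$total)
      flat <- flatten_params(net$params)
      up <- adam_update(flat, collect_grads(gr$pn), gst, cfg$lr, cfg$weight_decay)
      net$params <- unflatten_params(up$flat)
      gst <- up$st
      history[[it]] <- data.frame(epoch = ep, iter = it,
                                  seg = gr$comps["seg"], adv = gr$comps["adv"],
                                  ctr = gr$comps["ctr"], cst = gr$comps["cst"],
                                  lmd = gr$comps["lmd"], total = tv,
                                  row.names = NULL)
    }
  }
  history <- do.call(rbind, history)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  res <- list(net = net, disc = disc, history = history)
  if (!is.null(checkpoint)) save_checkpoint(res, checkpoint)
  res
}

#' Save a trained model (with its configuration) to a checkpoint file
#' @param fit Result of [train()], or a list with at least `net`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(net = fit$net, disc = fit$disc, history = fit$history), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return List with `net`, `disc`, `history`.
#' @export
load_checkpoint <- function(path) {
  stop_if(!file.exists(path), "checkpoint not found: %s", path)
  readRDS(path)
}

#' Predict a vessel probability map for one image
#'
#' Resizes the image to the network's training resolution, runs the forward
#' pass (for SLD variants the Gaussian map is rendered from the image's own
#' landmarks), and resizes the probability map back to the native
#' resolution.
#'
#' @param net A trained [vessel_net()].
#' @param image RGB raster.
#' @param size Working resolution; defaults to the network's nominal size.
#' @return Probability matrix at the native image resolution.
#' @export
predict_vessels <- function(net, image, size = NULL) {
  if (is.null(size)) size <- net$cfg$image_size
  d0 <- dim(image)[1:2]
  xr <- resize_raster(image, size, method = "bilinear")
  mgm <- NULL
  if (net$cfg$variant == "transunet_sld") {
    R <- extract_landmarks(net, xr)
    mgm <- render_gaussian_map(R, size %/% 4L)
  }
  p <- forward_segment(net, xr, mgm)
  resize_raster(p[, , 1], d0, method = "bilinear")
}
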