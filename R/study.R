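## The package's reference synthetic study: a scaled-down end-to-end
## experiment (small network, 64 x 64 synthetic fundus images) that
## exercises generation, training with the full composite objective, and
## held-out evaluation on one CPU in a few minutes.

#' Compact network configuration for the synthetic study
#'
#' A reduced-width version of the full architecture (encoder widths 8/16/32,
#' two transformer layers of four heads on 2 px patches with a 64-wide
#' embedding, eight landmarks) sized so that training on 64 x 64 synthetic
#' images is practical on a single CPU while preserving every structural
#' element of the full model. The embedding width is kept at half the patch
#' content (2x2x32 = 128 values) so the bottleneck does not discard most of
#' the within-patch detail.
#'
#' @param variant Model variant, as in [net_config()].
#' @return A [net_config()].
#' @export
study_net_config <- function(variant = "transunet_sld") {
  net_config(variant = variant, channels = c(8L, 16L, 32L),
             transformer = transformer_config(n_layers = 2L, n_heads = 4L,
                                              patch_size = 2L, embed_dim = 64L,
                                              mlp_ratio = 2),
             landmark_channels = 8L, image_size = c(64L, 64L))
}

#' Run the synthetic end-to-end study
#'
#' Generates a synthetic dataset (16 training and 8 held-out pairs at
#' 64 x 64 by default), trains each requested variant for `epochs` epochs
#' with the composite objective, and evaluates on the held-out pairs.
#'
#' @param seed Integer seed controlling data generation and training.
#' @param variants Character vector of variants to train.
#' @param n_train,n_test Dataset sizes.
#' @param epochs Training epochs.
#' @param dir Directory for the generated dataset (a fresh temporary
#'   directory by default).
#' @return Named list per variant: `fit` (training result), `metrics`
#'   (pooled held-out [metrics()] report), `epoch_loss` (per-epoch mean
#'   total loss), `loss_ratio` (epoch `epochs` mean over epoch 1 mean).
#' @export
synthetic_study <- function(seed = 1L, variants = c("transunet_sld", "unet"),
                            n_train = 16L, n_test = 8L, epochs = 30L,
                            dir = NULL) {
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("lavs_study_%d", seed))
  unlink(dir, recursive = TRUE)
  write_synthetic_dataset(dir, n = n_train + n_test, size = c(64L, 64L),
                          seed = derive_seed(seed, 1000L))
  pairs <- load_dataset(dir, "synthetic")
  train_pairs <- pairs[seq_len(n_train)]
  test_pairs <- pairs[n_train + seq_len(n_test)]
  out <- list()
  for (variant in variants) {
    cfg <- train_config(epochs = epochs, seed = seed,
                        net = study_net_config(variant),
                        image_size = c(64L, 64L),
                        disc_channels = c(8L, 16L, 32L, 64L))
    fit <- train(train_pairs, cfg)
    ep_loss <- tapply(fit$history$total, fit$history$epoch, mean)
    ev <- evaluate_split(fit, test_pairs)
    out[[variant]] <- list(fit = fit, metrics = ev$pixel_pooled,
                           per_image = ev$per_image, epoch_loss = ep_loss,
                           loss_ratio = unname(ep_loss[length(ep_loss)] / ep_loss[1]))
  }
  out
}
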