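## Segmentation backbone: three-resolution convolutional encoder, transformer
## bottleneck on the H/4 grid, and a decoder whose middle stage takes a third
## skip input fd(Menc,1) in addition to the usual up-sampled path and Menc,2.
## The decoder's first stage consumes the bottleneck output concatenated with
## the K-channel Gaussian landmark map (a zero map when landmarks are off).

#' Transformer bottleneck configuration
#'
#' @param n_layers Number of transformer layers (pre-norm MHSA + MLP, each
#'   with a residual connection). 0 gives the degenerate embed-and-merge
#'   chain with no token mixing.
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param patch_size Patch edge length on the H/4 feature grid, in grid px.
#' @param embed_dim Token embedding width; defaults to the C3 channel count
#'   of the network it is attached to.
#' @param mlp_ratio Hidden width of the MLP block as a multiple of
#'   `embed_dim`.
#' @param ln_affine Whether layer norms carry learnable gain/offset.
#' @return An object of class `transformer_config`.
#' @export
transformer_config <- function(n_layers = 4L, n_heads = 8L, patch_size = 8L,
                               embed_dim = NULL, mlp_ratio = 4, ln_affine = TRUE) {
  stop_if(n_layers < 0, "n_layers must be >= 0")
  stop_if(n_heads < 1, "n_heads must be >= 1")
  stop_if(patch_size < 1, "patch_size must be >= 1")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 patch_size = as.integer(patch_size), embed_dim = embed_dim,
                 mlp_ratio = mlp_ratio, ln_affine = isTRUE(ln_affine)),
            class = "transformer_config")
}

#' Network configuration
#'
#' @param variant `"unet"` (conv bottleneck, no landmarks), `"transunet"`
#'   (transformer bottleneck, zero landmark map), or `"transunet_sld"`
#'   (transformer bottleneck plus self-supervised landmark detection).
#' @param channels Encoder widths `(C1, C2, C3)`, strictly increasing.
#' @param transformer A [transformer_config()].
#' @param landmark_channels Number of landmarks K (and Gaussian-map
#'   channels fed to the decoder).
#' @param head_gain Fixed gain applied to the landmark-head responses
#'   before the spatial softmax. Sharpens the per-channel spatial
#'   distributions so soft-argmax reads out localised landmarks instead of
#'   collapsing toward the grid centre (the centre bias of soft-argmax
#'   under near-uniform distributions).
#' @param image_size Nominal training resolution `(H, W)`; sizes the learned
#'   position-embedding grid, which is bilinearly resampled for other input
#'   sizes.
#' @return An object of class `net_config`.
#' @export
net_config <- function(variant = c("transunet_sld", "transunet", "unet"),
                       channels = c(64L, 128L, 256L),
                       transformer = transformer_config(),
                       landmark_channels = 32L,
                       head_gain = 8,
                       image_size = c(512L, 512L)) {
  variant <- match.arg(variant)
  stop_if(length(channels) != 3 || any(diff(channels) <= 0),
          "channels must be three strictly increasing widths (C1, C2, C3)")
  if (is.null(transformer$embed_dim)) transformer$embed_dim <- as.integer(channels[3])
  stop_if(transformer$embed_dim %% transformer$n_heads != 0,
          "embed_dim must be divisible by n_heads")
  stop_if(any(image_size %% (4L * transformer$patch_size) != 0),
          "image_size must be divisible by 4 * patch_size")
  structure(list(variant = variant, channels = as.integer(channels),
                 transformer = transformer,
                 landmark_channels = as.integer(landmark_channels),
                 head_gain = head_gain,
                 image_size = as.integer(image_size)),
            class = "net_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

xavier_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

conv_init <- function(kh, kw, cin, cout) {
  list(w = he_init(c(kh, kw, cin, cout), kh * kw * cin), b = numeric(cout))
}

#' Build a segmentation network
#'
#' Initialises all trainable parameters for the configured variant. The
#' encoder weights are shared between the segmentation branch and the
#' landmark detector (the 1x1 projection head lives in the same parameter
#' set).
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `vessel_net` with elements `cfg` and `params`.
#' @export
vessel_net <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  C <- cfg$channels
  tc <- cfg$transformer
  K <- cfg$landmark_channels
  with_seed(seed, {
    p <- list()
    ## encoder: two 3x3 conv + ReLU blocks per level, 2x2 maxpool between
    cin <- 3L
    for (lvl in 1:3) {
      p[[paste0("enc", lvl, "a")]] <- conv_init(3, 3, cin, C[lvl])
      p[[paste0("enc", lvl, "b")]] <- conv_init(3, 3, C[lvl], C[lvl])
      cin <- C[lvl]
    }
    if (cfg$variant == "unet") {
      p$bota <- conv_init(3, 3, C[3], C[3])
      p$botb <- conv_init(3, 3, C[3], C[3])
    } else {
      E <- tc$embed_dim
      ps <- tc$patch_size
      gh <- cfg$image_size[1] %/% 4L %/% ps
      gw <- cfg$image_size[2] %/% 4L %/% ps
      pc <- ps * ps * C[3]
      p$tr_embed <- list(w = xavier_init(pc, E), b = numeric(E))
      p$tr_pos <- array(stats::rnorm(gh * gw * E, 0, 0.02), dim = c(gh, gw, E))
      for (l in seq_len(tc$n_layers)) {
        lp <- list(
          q = list(w = xavier_init(E, E), b = numeric(E)),
          k = list(w = xavier_init(E, E), b = numeric(E)),
          v = list(w = xavier_init(E, E), b = numeric(E)),
          o = list(w = xavier_init(E, E), b = numeric(E)),
          fc1 = list(w = xavier_init(E, round(tc$mlp_ratio * E)),
                     b = numeric(round(tc$mlp_ratio * E))),
          fc2 = list(w = xavier_init(round(tc$mlp_ratio * E), E), b = numeric(E))
        )
        if (tc$ln_affine) {
          lp$ln1 <- list(g = rep(1, E), b = numeric(E))
          lp$ln2 <- list(g = rep(1, E), b = numeric(E))
        }
        p[[paste0("trl", l)]] <- lp
      }
      p$tr_merge <- list(w = xavier_init(E, pc), b = numeric(pc))
    }
    ## decoder; first stage always sees C3 + K channels (zero map if no SLD)
    p$dec1a <- conv_init(3, 3, C[3] + K, C[3])
    p$dec1b <- conv_init(3, 3, C[3], C[3])
    p$dec2a <- conv_init(3, 3, C[3] + C[2] + C[1], C[2])
    p$dec2b <- conv_init(3, 3, C[2], C[2])
    p$dec3a <- conv_init(3, 3, C[2] + C[1], C[1])
    p$dec3b <- conv_init(3, 3, C[1], C[1])
    p$out <- conv_init(1, 1, C[1], 1)
    ## start the output at the vessel-pixel base rate (~10% of the frame)
    ## instead of 50%, so early training is not spent learning the prior
    p$out$b[] <- stats::qlogis(0.1)
    if (cfg$variant == "transunet_sld") {
      p$head <- list(w = xavier_init(C[3], K), b = numeric(K))
    }
    structure(list(cfg = cfg, params = p), class = "vessel_net")
  })
}

## Flatten the nested parameter list to named arrays (for the optimiser) and
## rebuild nodes. Names are dotted paths, e.g. "enc1a.w", "trl2.q.b".
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    el <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(el)) out <- c(out, flatten_params(el, key)) else out[[key]] <- el
  }
  out
}

assign_path <- function(lst, path, value) {
  if (length(path) == 1L) {
    lst[[path]] <- value
    return(lst)
  }
  sub <- lst[[path[1]]]
  if (is.null(sub)) sub <- list()
  lst[[path[1]]] <- assign_path(sub, path[-1], value)
  lst
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    out <- assign_path(out, strsplit(key, ".", fixed = TRUE)[[1]], flat[[key]])
  }
  out
}

## Parameter nodes for one forward/backward pass.
param_nodes <- function(net) {
  lapply(flatten_params(net$params), ad_param)
}

## ---- graph builders (operate on ad nodes; pn = flat param-node list) ----

conv_block <- function(x, pn, name, stride = 1L, pad = 1L) {
  ad_relu(ad_conv2d(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
                    stride = stride, pad = pad))
}

graph_encode <- function(pn, cfg, x) {
  d <- dim(ad_value(x))
  stop_if(d[1] %% 4 != 0 || d[2] %% 4 != 0,
          "input height and width must be divisible by 4 (got %d x %d)", d[1], d[2])
  stop_if(length(d) != 3 || d[3] != 3, "input must be an H x W x 3 raster")
  m1 <- conv_block(conv_block(x, pn, "enc1a"), pn, "enc1b")
  m2 <- conv_block(conv_block(ad_maxpool2(m1), pn, "enc2a"), pn, "enc2b")
  m3 <- conv_block(conv_block(ad_maxpool2(m2), pn, "enc3a"), pn, "enc3b")
  list(m1 = m1, m2 = m2, m3 = m3)
}

## Cache of patchify index vectors keyed by (h, w, c, p).
patch_idx_cache <- new.env(parent = emptyenv())

patch_indices <- function(h, w, C, p) {
  key <- paste(h, w, C, p, sep = "_")
  hit <- patch_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  gh <- h %/% p
  gw <- w %/% p
  nt <- gh * gw
  lin <- array(seq_len(h * w * C), dim = c(h, w, C))
  idx <- matrix(0L, nt, p * p * C)
  for (pj in 0:(gw - 1)) {
    for (pi in 0:(gh - 1)) {
      t <- pi + gh * pj + 1L
      idx[t, ] <- as.integer(lin[pi * p + 1:p, pj * p + 1:p, , drop = FALSE])
    }
  }
  fwd <- as.integer(idx)
  inv <- integer(length(fwd))
  inv[fwd] <- seq_along(fwd)
  res <- list(fwd = fwd, inv = inv, nt = nt, gh = gh, gw = gw)
  patch_idx_cache[[key]] <- res
  res
}

mhsa <- function(z, lp, pn, prefix, n_heads) {
  E <- ncol(ad_value(z))
  dh <- E %/% n_heads
  Q <- ad_add_bias(ad_matmul(z, pn[[paste0(prefix, ".q.w")]]), pn[[paste0(prefix, ".q.b")]])
  K <- ad_add_bias(ad_matmul(z, pn[[paste0(prefix, ".k.w")]]), pn[[paste0(prefix, ".k.b")]])
  V <- ad_add_bias(ad_matmul(z, pn[[paste0(prefix, ".v.w")]]), pn[[paste0(prefix, ".v.b")]])
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    qh <- ad_cols(Q, cols)
    kh <- ad_cols(K, cols)
    vh <- ad_cols(V, cols)
    att <- ad_softmax_rows(ad_scale(ad_matmul(qh, ad_transpose(kh)), 1 / sqrt(dh)))
    heads[[h]] <- ad_matmul(att, vh)
  }
  cat_h <- if (n_heads == 1L) heads[[1]] else ad_cbind(heads)
  ad_add_bias(ad_matmul(cat_h, pn[[paste0(prefix, ".o.w")]]), pn[[paste0(prefix, ".o.b")]])
}

graph_transformer <- function(pn, cfg, m3) {
  tc <- cfg$transformer
  d <- dim(ad_value(m3))
  h <- d[1]; w <- d[2]; C3 <- d[3]
  ps <- tc$patch_size
  stop_if(h %% ps != 0 || w %% ps != 0,
          "feature grid %d x %d is not divisible by patch_size %d", h, w, ps)
  pidx <- patch_indices(h, w, C3, ps)
  tokens <- ad_permute(m3, pidx$fwd, c(pidx$nt, ps * ps * C3))
  z <- ad_add_bias(ad_matmul(tokens, pn[["tr_embed.w"]]), pn[["tr_embed.b"]])
  pos <- pn[["tr_pos"]]
  pd <- dim(ad_value(pos))
  if (pd[1] != pidx$gh || pd[2] != pidx$gw) {
    pos <- ad_resize_bilinear(pos, pidx$gh, pidx$gw)
  }
  z <- ad_add(z, ad_reshape(pos, c(pidx$nt, tc$embed_dim)))
  for (l in seq_len(tc$n_layers)) {
    prefix <- paste0("trl", l)
    ln1 <- if (tc$ln_affine) {
      ad_layernorm(z, pn[[paste0(prefix, ".ln1.g")]], pn[[paste0(prefix, ".ln1.b")]])
    } else ad_layernorm(z)
    z <- ad_add(mhsa(ln1, NULL, pn, prefix, tc$n_heads), z)
    ln2 <- if (tc$ln_affine) {
      ad_layernorm(z, pn[[paste0(prefix, ".ln2.g")]], pn[[paste0(prefix, ".ln2.b")]])
    } else ad_layernorm(z)
    mlp <- ad_add_bias(ad_matmul(ad_gelu(
      ad_add_bias(ad_matmul(ln2, pn[[paste0(prefix, ".fc1.w")]]),
                  pn[[paste0(prefix, ".fc1.b")]])),
      pn[[paste0(prefix, ".fc2.w")]]), pn[[paste0(prefix, ".fc2.b")]])
    z <- ad_add(mlp, z)
  }
  merged <- ad_add_bias(ad_matmul(z, pn[["tr_merge.w"]]), pn[["tr_merge.b"]])
  ad_permute(merged, pidx$inv, c(h, w, C3))
}

graph_bottleneck <- function(pn, cfg, m3) {
  if (cfg$variant == "unet") {
    conv_block(conv_block(m3, pn, "bota"), pn, "botb")
  } else {
    graph_transformer(pn, cfg, m3)
  }
}

## Pre-sigmoid decoder output (used by the stable training BCE).
graph_decode_logits <- function(pn, cfg, feats, mt, mgm = NULL) {
  C <- cfg$channels
  K <- cfg$landmark_channels
  dmt <- dim(ad_value(mt))
  dm1 <- dim(ad_value(feats$m1))
  stop_if(dmt[1] != dm1[1] %/% 4 || dmt[2] != dm1[2] %/% 4,
          "decoder stage 1: bottleneck grid %d x %d does not match encoder H/4 grid",
          dmt[1], dmt[2])
  if (is.null(mgm)) mgm <- array(0, dim = c(dmt[1], dmt[2], K))
  dgm <- dim(ad_value(mgm))
  stop_if(dgm[1] != dmt[1] || dgm[2] != dmt[2] || dgm[3] != K,
          "decoder stage 1: Gaussian map must be %d x %d x %d", dmt[1], dmt[2], K)
  d1 <- conv_block(conv_block(ad_concat_c(list(mt, mgm)), pn, "dec1a"), pn, "dec1b")
  up1 <- ad_resize_bilinear(d1, dm1[1] %/% 2, dm1[2] %/% 2)
  fd1 <- ad_maxpool2(feats$m1)
  d2 <- conv_block(conv_block(ad_concat_c(list(up1, feats$m2, fd1)), pn, "dec2a"),
                   pn, "dec2b")
  up2 <- ad_resize_bilinear(d2, dm1[1], dm1[2])
  d3 <- conv_block(conv_block(ad_concat_c(list(up2, feats$m1)), pn, "dec3a"),
                   pn, "dec3b")
  ad_conv2d(d3, pn[["out.w"]], pn[["out.b"]], stride = 1L, pad = 0L)
}

graph_decode <- function(pn, cfg, feats, mt, mgm = NULL) {
  ad_sigmoid(graph_decode_logits(pn, cfg, feats, mt, mgm))
}

graph_forward_segment <- function(pn, cfg, x, mgm = NULL) {
  feats <- graph_encode(pn, cfg, x)
  mt <- graph_bottleneck(pn, cfg, feats$m3)
  list(ypre = graph_decode(pn, cfg, feats, mt, mgm), feats = feats, mt = mt)
}

## ---- public (plain-array) surface ----

#' Run the convolutional encoder
#'
#' Two 3x3 conv + ReLU blocks per level with 2x2 max-pool down-sampling
#' between levels, producing feature maps at full, half and quarter
#' resolution.
#'
#' @param net A [vessel_net()].
#' @param x RGB raster `[H, W, 3]`; H and W must be divisible by 4.
#' @return List with arrays `m1` (`H x W x C1`), `m2` (`H/2 x W/2 x C2`),
#'   `m3` (`H/4 x W/4 x C3`).
#' @export
encode <- function(net, x) {
  stopifnot(inherits(net, "vessel_net"))
  feats <- graph_encode(param_nodes(net), net$cfg, ad_input(x))
  lapply(feats, ad_value)
}

#' Run the transformer bottleneck
#'
#' Patchifies the quarter-resolution feature map, adds learned position
#' embeddings, applies `n_layers` pre-norm transformer layers (MHSA then MLP,
#' each with a residual connection), and merges patches back to a spatial
#' map of the same shape.
#'
#' @param net A [vessel_net()] with a transformer variant.
#' @param m3 Feature map `[h, w, C3]` with h, w divisible by `patch_size`.
#' @return Array of the same shape as `m3`.
#' @export
transformer_forward <- function(net, m3) {
  stopifnot(inherits(net, "vessel_net"))
  stop_if(net$cfg$variant == "unet", "variant 'unet' has no transformer bottleneck")
  ad_value(graph_transformer(param_nodes(net), net$cfg, ad_input(m3)))
}

#' Run the decoder
#'
#' Stage 1 consumes the bottleneck output concatenated channel-wise with the
#' Gaussian landmark map; stage 2 consumes the up-sampled stage-1 output,
#' the half-resolution skip `m2`, and additionally the max-pooled
#' full-resolution skip `fd(m1)`; the final stage consumes the up-sampled
#' stage-2 output with `m1` and ends in a 1x1 conv + sigmoid.
#'
#' @param net A [vessel_net()].
#' @param feats Encoder features as returned by [encode()].
#' @param mt Bottleneck output `[H/4, W/4, C3]`.
#' @param mgm Optional Gaussian landmark map `[H/4, W/4, K]`; a zero map is
#'   substituted when omitted.
#' @return Probability raster `[H, W, 1]` with values in `[0, 1]`.
#' @export
decode <- function(net, feats, mt, mgm = NULL) {
  stopifnot(inherits(net, "vessel_net"))
  pn <- param_nodes(net)
  fn <- lapply(feats, ad_input)
  ad_value(graph_decode(pn, net$cfg, fn, ad_input(mt),
                        if (is.null(mgm)) NULL else ad_input(mgm)))
}

#' Full forward pass of the segmentation network
#'
#' @param net A [vessel_net()].
#' @param x RGB raster `[H, W, 3]`, H and W divisible by
#'   `4 * patch_size` for transformer variants.
#' @param mgm Optional Gaussian landmark map `[H/4, W/4, K]`.
#' @return Probability raster `[H, W, 1]`.
#' @export
forward_segment <- function(net, x, mgm = NULL) {
  stopifnot(inherits(net, "vessel_net"))
  pn <- param_nodes(net)
  out <- graph_forward_segment(pn, net$cfg, ad_input(x),
                               if (is.null(mgm)) NULL else ad_input(mgm))
  ad_value(out$ypre)
}

#' Summarise a network's parameters
#'
#' @param net A [vessel_net()].
#' @return Data frame with one row per parameter array (name, dimensions,
#'   element count); total count as attribute `"total"`.
#' @export
net_summary <- function(net) {
  flat <- flatten_params(net$params)
  df <- data.frame(
    param = names(flat),
    dims = vapply(flat, function(x) paste(if (is.null(dim(x))) length(x) else dim(x),
                                          collapse = "x"), character(1)),
    count = vapply(flat, length, numeric(1)),
    row.names = NULL
  )
  attr(df, "total") <- sum(df$count)
  df
}
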