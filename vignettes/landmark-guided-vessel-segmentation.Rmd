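---
title: "Landmark-guided retinal vessel segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-guided retinal vessel segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Retinal fundus photographs show the vascular tree at low contrast against a
textured background; the thin terminal vessels that matter most clinically
(for hypertension, arteriosclerosis and retinopathy screening) are the first
casualties of pixel-wise segmentation. `lavs` implements a segmentation
framework built around two ideas:

1. a **hybrid convolutional/transformer encoder–decoder** so that local
   texture (convolutions) and long-range vessel continuity (self-attention)
   are modelled jointly, and
2. **self-supervised anatomical landmarks** — sparse, ordered 2-D points
   discovered without annotation — that are fed back into the decoder as
   Gaussian heatmaps and trained with consistency, contrastive and
   pseudo-label objectives.

## Architecture

The encoder is a standard three-level U-Net encoder: two 3×3
convolution + ReLU blocks per level with 2×2 max-pooling between levels,
producing feature maps $M_{enc,1}, M_{enc,2}, M_{enc,3}$ at full, half and
quarter resolution with widths $C_1 < C_2 < C_3$. Only two down-sampling
steps are used: deeper pyramids discard exactly the thin-vessel detail the
model is meant to keep.

The bottleneck is a transformer over the $H/4 \times W/4$ grid. The map is
cut into $p \times p$ patches, each flattened and linearly embedded; learned
position embeddings are added once at the input; then $N_t$ pre-norm
transformer layers apply multi-head self-attention and an MLP, each with a
residual connection:

$$Z' = \mathrm{MHSA}(\mathrm{LN}(Z)) + Z,\qquad
  Z'' = \mathrm{MLP}(\mathrm{LN}(Z')) + Z'.$$

A patch-merging linear layer restores the spatial map $M_t$. Because both
sub-blocks sit behind residual connections, zeroing their output projections
(with layer norms set non-affine) turns every layer into the identity — the
test suite uses this to pin down the residual structure.

The decoder mirrors the encoder with two deliberate modifications:

* stage 1 consumes `concat(Mt, Mgm)`, the bottleneck output joined
  channel-wise with the $K$-channel Gaussian landmark map;
* stage 2 consumes **three** inputs — the up-sampled stage-1 output, the
  usual half-resolution skip $M_{enc,2}$, and additionally the max-pooled
  full-resolution skip $f_d(M_{enc,1})$, which re-injects texture detail that
  global attention tends to smear.

The final stage joins the up-sampled stage-2 output with $M_{enc,1}$ and
ends in a 1×1 convolution + sigmoid. Three variants share this code path:
`unet` (two conv blocks replace the transformer; landmark map forced to
zero), `transunet` (transformer, zero landmark map) and `transunet_sld`
(transformer plus the landmark branch), so ablations are pure module swaps.

## Self-supervised landmarks

Landmarks are read out of the deepest encoder features: a 1×1 projection to
$K$ channels, **spatial softmax** per channel (a distribution over all grid
sites), and **soft-argmax** (the probability-weighted mean of site
coordinates) — a differentiable replacement for the argmax. Landmarks live
on the $H/4 \times W/4$ grid in 0-based `(row, col)` units.

Soft-argmax has a centre bias: under a near-uniform spatial distribution the
expected coordinate is the grid centre regardless of the features, and with
freshly initialised projections every channel's distribution *is* near
uniform — all K landmarks then collapse to the centre, the descriptors
become indistinguishable, and the contrastive loss freezes at its
uniform-similarity value $\ln(2K-1)$. The detector therefore applies a
fixed response gain (`head_gain`, default 8) to the projection output
before the spatial softmax, sharpening the per-channel distributions enough
that each channel reads out a localised landmark from the start. The gain
is the spatial-softmax inverse temperature; 8 was chosen from pilot runs as
the smallest value that reliably de-collapses the landmark set (larger
values make the readout argmax-like and the auxiliary losses jumpy).

Three objectives make the landmarks meaningful:

* **Consistency** (`cst`): landmarks of an affine-warped view, mapped back
  through the inverse transform, must coincide with the landmarks of the
  original view (mean squared distance). The affine is expressed on the
  feature grid by conjugating with the image-to-grid scaling.
* **Contrastive** (`ctr`): NT-Xent over L2-normalised descriptors obtained
  by bilinearly sampling the projection-head features of the original and a
  photometrically jittered ("style") view; the positive is the same
  landmark index in the other view, the negatives all remaining $2K-2$
  descriptors. Because the style view leaves geometry untouched, **both**
  descriptor sets are sampled at the original view's landmark coordinates —
  landmark $k$ is then the same physical location in both views. (Sampling
  each view at its own predicted landmarks lets the style view's landmark
  drift turn positives into comparisons of different locations; in pilot
  runs that noise kept the contrastive term from learning at all.)
* **Pseudo-labels** (`lmd`): landmarks extracted from the ground-truth mask
  (replicated to three channels and passed through the shared encoder)
  serve as regression targets for the image landmarks, as mean squared
  coordinate distance.

The Gaussian map fed to the decoder renders one isotropic Gaussian of unit
peak per landmark, $\exp(-d^2/2\sigma^2)$ with $\sigma = 0.7$ grid units —
sharp, near-one-hot bumps. We render the map at the *predicted* landmarks
and treat it as a constant input within each iteration (no gradient through
the rendering into the coordinates); pseudo-label landmarks are likewise
detached. Both are deliberate simplifications of an ambiguous construction:
a scalar reading of the map (one value per landmark) cannot be concatenated
with a spatial feature map, so the spatial-heatmap reading is the only one
consistent with the decoder interface.

## The training objective

$$L_{total} = \lambda_1 L_{seg} + \lambda_2 L_{adv}
  + \lambda_3 (L_{ctr} + L_{cst}) + \lambda_4 L_{lmd},
  \qquad \lambda = (0.2,\, 0.3,\, 0.4,\, 0.1).$$

$L_{seg}$ is mean binary cross-entropy plus Dice loss
$1 - (2\sum p y + \varepsilon)/(\sum p + \sum y + \varepsilon)$,
$\varepsilon = 10^{-6}$. Inside the training graph the BCE part is computed
from pre-sigmoid logits via the softplus identity
$\mathrm{BCE} = \overline{\mathrm{softplus}(z) - yz}$, whose gradient
$\sigma(z) - y$ survives saturation; the public `seg_loss()` takes
probabilities and matches the graph value away from the clamp boundaries.

$L_{adv}$ comes from a small discriminator (four stride-2 3×3 convolutions,
LeakyReLU, global average pooling, sigmoid scalar) that judges a
segmentation map alone. The discriminator minimises
$-\log D(Y) - \log(1 - D(\hat Y))$; the generator term is the
non-saturating $-\log D(\hat Y)$, substituted for the minimax form for
trainability. Training alternates one discriminator step with one
generator step. The discriminator's learning rate defaults to one tenth of
the generator's: with a shared rate the discriminator wins within a few
epochs, the $1/D$ factor in the non-saturating gradient then dwarfs the
segmentation gradient, and the segmentation output collapses toward the
empty map (which a pooled discriminator scores as realistic, since real
vessel masks are >90% background). The slow-discriminator setting keeps
$D \approx 0.5$ and the adversarial gradient bounded throughout.

Optimisation is Adam ($\beta = (0.9, 0.999)$), learning rate $10^{-3}$,
weight decay $5\times 10^{-4}$, one image per iteration, no schedule. The
output layer's bias is initialised to $\mathrm{logit}(0.1)$, the typical
vessel-pixel base rate, so the earliest epochs are not spent learning the
class prior.
Loss components with zero weight are skipped entirely (not computed and
logged as 0), which makes the composite objective cleanly modular — with
$\lambda_{2..4} = 0$ the parameter updates are bit-identical to plain
Dice+BCE training, and the suite asserts exactly that.

## Synthetic data: what it emulates, and what it does not

The generator draws `n_roots` recursively branching vessels from an
optic-disc point: midpoint-displaced polylines, per-level width
`root_width * width_decay^level`, anti-aliased and thresholded, clipped to a
circular field of view of radius $0.48\,\min(H, W)$ and pruned to the
8-connected component reachable from each root (so every tree is guaranteed
connected — the property the architecture is meant to preserve). A fraction
`thin_fraction` of terminal branches is rendered at ~1 px to reproduce the
thin-vessel regime. Rendering places the vessels on a warm-tinted disc with
low-frequency luminance variation and vignetting, darkening vessel pixels
multiplicatively by $1 - 0.6\,c$ (Weber-type contrast $c$) and adding
Gaussian pixel noise.

Default study conditions, chosen once as a plausible mid-difficulty regime:
`contrast = 0.6` (a clearly visible but not binary-separable vessel tree;
real fundus contrast varies widely around this) and `noise_sd = 0.03`
(mild sensor noise). Default geometry yields 5–15% vessel pixels per frame,
matching the foreground fractions of standard fundus benchmarks.

What the generator does **not** emulate: pathology (lesions, exudates),
central light reflexes inside wide vessels, arteriole/venule intensity
differences, inter-image colour shifts beyond the parametric style jitter,
and annotation noise. Passing the synthetic study therefore demonstrates
that the pipeline is implemented correctly and can learn vascular topology
from realistic-looking inputs — not that it reaches benchmark accuracy on
real fundus datasets, which requires the external DRIVE/CHASE-DB1/STARE
images and a GPU-scale budget.

The photometric "style" view is parametric by design: seeded per-channel
gamma in [0.7, 1.4], contrast scaling in [0.8, 1.25] about 0.5, brightness
offsets within ±0.15 and ±0.1 channel mixing. It is pixelwise (commutes
with cropping) and near-monotone per channel, which is all the contrastive
objective requires of a "same content, different style" view.

## Data handling choices

* The foreground-maximising augmentation places a 0.6-scale window at a
  3×3 grid of positions (the normalized offsets {0, ½, 1} in each axis —
  the only placement rule that yields exactly nine slices) and keeps the
  slice with the highest mask-foreground fraction, ties resolved in
  row-major order.
* Rotations are exact index permutations at multiples of 90° and centred
  bilinear/nearest warps within ±15° otherwise; scale augmentation spans
  [0.8, 1.2]. Geometric operations are applied identically to image, mask
  and field of view, with nearest-neighbour resampling for the masks.
* Readers cover PNG, TIFF and PPM/PGM; masks are binarised at 50% of their
  maximum. GIF is not decodable with the available codecs and raises an
  error naming the file. The fixed-split reader follows the convention of
  training on the *last* block of images and testing on the first, with a
  `swap` flag for the reverse.
* Fixed training resolution (512×512 by default, 256×256 and the study's
  64×64 as configuration switches); predictions are made at the training
  resolution and resized back to the native mask resolution before
  counting.

## Evaluation choices

Pixel counts use the standard orientation — TP = vessel pixels predicted as
vessel, FP = background predicted as vessel, FN = missed vessel — which is
the reading consistent with the blue-FN/red-FP error-overlay convention.
Metrics with zero denominators are reported as `NA`, never as 0. Both
pooling conventions are always computed: `pixel_pooled` (counts summed
before metrics; the default for benchmark-style comparisons) and
`per_image_mean`. Counting runs inside the field of view when one is
supplied, over the full frame otherwise. The binarisation threshold is
fixed at 0.5.

## Numerical core

No deep-learning runtime is available to R here, and the architecture *is*
the contribution, so the package carries its own reverse-mode autodiff
tape: eager ad_* operations over plain arrays, with the heavy kernels (3×3
convolution, 2×2 max-pooling, bilinear resizing) in C++. Every operation is
validated against central-difference numerical gradients in the test suite,
and a whole transformer layer is gradient-checked end-to-end. All
randomness flows through derived integer seeds, so initialisation, data
generation, augmentation and the affine/style views are exactly
reproducible; forward passes are deterministic.

## Problem sizes

The reference synthetic study — `synthetic_study()`, also what
`scripts/acceptance.R` runs — uses 16 training and 8 held-out 64×64 images,
30 epochs, batch size 1, and a reduced-width model (encoder widths 8/16/32,
two transformer layers of four heads on 2-px patches with a 64-wide
embedding, K = 8 landmarks, discriminator widths 8/16/32/64). The embedding
is kept at half the patch content (2×2×32 = 128 values) so the bottleneck
does not discard most within-patch detail; K stays small because each
landmark contributes one pseudo-label regression target, and at this
training budget more targets mean more auxiliary-gradient noise (K = 16
measurably degraded both the loss trajectory and held-out F1). The study
trains without the slice/flip augmentation of the full protocol: at 64×64
the 0.6-window crop followed by the resize back to the working resolution
shifts vessel widths far from the evaluation distribution, and 480
iterations are too few to absorb that shift. These sizes exercise the full
composite objective end-to-end in a few CPU-minutes; the full-width
defaults (64/128/256, four layers, eight heads on 8-px patches, K = 32,
512×512) remain the configuration for real-data training.

## Known limitations

* Batch size is fixed at one image per iteration (the reference protocol);
  there is no gradient accumulation.
* The landmark count K is a free parameter with no self-tuning; collapsed
  landmark sets (several landmarks at the same location) are not penalised
  beyond what the contrastive term discourages.
* The Sinkhorn/optimal-transport variant of the landmark loss is not
  implemented; the coordinate loss is plain squared distance, which is the
  closed form actually specified for it.
* The adversarial pair (GAP discriminator + non-saturating loss) is the
  simplest stable reading; image-conditioned discriminators were out of
  scope.
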