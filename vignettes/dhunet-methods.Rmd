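---
title: "DHuNeT: model, training objectives, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DHuNeT: model, training objectives, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Chronic-wound photographs (diabetic foot ulcers, pressure ulcers, venous
ulcers) are segmented into wound versus background pixels. The difficulty is
the enormous variation in lesion size, colour, contrast, and framing: many
clinical photographs additionally carry black border bands from the capture
device that a segmentation network would otherwise have to learn to ignore.

`dhunet` implements a dual-phase stacked UNet. A UNet is a symmetric
encoder–decoder: the encoder $\phi : X \to F$ contracts the image through
blocks of two $3\times3$ convolutions followed by $2\times2$ max pooling;
the decoder $\psi : F \to X$ expands the bottleneck features back to full
resolution, with skip connections forwarding each encoder level's features
to the same-resolution decoder level.

Two such UNets are stacked:

* **UNet-1** maps the standardized RGB image to a soft wound mask through a
  $1\times1$ convolution with sigmoid activation.
* **UNet-2** receives the channel concatenation of the image and UNet-1's
  *soft* mask (4 channels), and additionally receives UNet-1's features at
  every level: after each of its encoder blocks, its bottleneck block, and
  each of its decoder blocks, its feature map is replaced by the elementwise
  mean of UNet-1's corresponding map and its own,
  $$F_i^e = \tfrac{1}{2}\left(E_i^1 + E_i^2\right), \qquad
    F_i^d = \tfrac{1}{2}\left(D_i^1 + D_i^2\right),$$
  and the fused encoder maps also feed UNet-2's skip connections. This
  per-level averaging — "hyperactive" feature transfer — is the model's
  defining ingredient; both mask heads are supervised during training
  (deep supervision).

Feeding UNet-2 the *soft* rather than binarized UNet-1 mask keeps the whole
graph differentiable, so both UNets train jointly end to end.

## The default schedule and the parameter budget

The published description of this architecture fixes its trainable-parameter
budget (1,081,942) but not its depth, filter counts, normalization, or
upsampling mode. The committed search (`scripts/search_config.R`) therefore
enumerates standard dual-UNet schedules — depth 2–5, base filters 4–32,
batchnorm on/off, and upsampling by either $2\times2$ stride-2 transposed
convolution or parameter-free nearest-neighbour upsampling followed by a
$3\times3$ convolution — and counts each candidate's parameters in closed
form. No candidate reaches the published budget exactly; the closest is
depth 4, 8 base filters, batchnorm after every convolution, and
nearest+convolution upsampling, at **1,082,218** trainable parameters
(0.026% above the budget). That schedule is frozen as the package default
(`dhunet_config()`, mirrored in `inst/extdata/dhunet-default.yaml`), and the
tests assert the builder agrees with an independent closed-form count rather
than with the unreachable printed figure.

Counting conventions worth stating once: each block applies two biased
$3\times3$ same-padding convolutions (ReLU activations); the bottleneck
doubles the deepest level's channel count; a convolution followed by
batchnorm carries no bias, since the normalization's mean subtraction would
cancel it and leave a parameter with identically zero gradient; each head
is a biased $1\times1$ convolution.

## Preprocessing: contour-based region-of-interest cropping

`preprocess_sample()` composes, identically for image and mask:

1. ITU-R 601 luminance conversion, then a blur — median with a $5\times5$
   window by default (robust to speckle), or a Gaussian whose kernel is the
   normalized discretization of
   $A e^{-\frac{(x-\mu_x)^2}{2\sigma_x^2} - \frac{(y-\mu_y)^2}{2\sigma_y^2}}$
   on the kernel support.
2. Thresholding at 10 of 255 (strictly greater maps to 255). The target
   artifact is near-black framing bands, so a low fixed threshold separates
   content from border; it is configurable.
3. 8-connected labelling, Moore-neighbour boundary tracing of every region,
   and selection of the contour with the largest shoelace area. The contour
   is simplified by Ramer–Douglas–Peucker with tolerance 1% of the
   perimeter, and annotated with the vertex farthest from the centroid and
   the maximal x/y coordinates, which are exposed for inspection.
4. Cropping to the contour's axis-aligned bounding box. The box is the
   minimal faithful reading of "crop to the detected content": it removes
   black bands exactly and keeps all bright content. Coordinates are
   0-based, x = column, and boxes are half-open, stated once and tested.
5. Resizing to the standard input size (128 px default): bilinear for the
   image (then scaled to $[0,1]$), nearest-neighbour for the mask (then
   re-binarized at 0.5).

When no contour exists (an all-black frame), the identity crop is used so no
sample is ever silently dropped. The pipeline is idempotent up to resize
rounding: reapplying it to its own output leaves the mask unchanged and
moves image pixels by at most 2/255.

## Objectives and metrics

With ground truth $y_i \in \{0,1\}$ and predictions $\hat y_i \in [0,1]$
over $N$ pixels:

$$\mathrm{BCE}(y,\hat y) = -\frac{1}{N}\sum_{i=1}^N
  \left[y_i\log\hat y_i + (1-y_i)\log(1-\hat y_i)\right]$$

with $\hat y$ clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-7}$; and the soft Dice index in its
squared-denominator form

$$\mathrm{Dice}(y,\hat y) =
  \frac{2\sum_i y_i \hat y_i + s}{\sum_i y_i^2 + \sum_i \hat y_i^2 + s},$$

with smoothing $s = 10^{-6}$, so two empty masks score 1. Training
minimizes either BCE or $1-\mathrm{Dice}$, summed over both heads with
equal weight. Evaluation binarizes at 0.5 ($\ge$ convention) and reports
precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, their harmonic mean F1, and
Dice, under two aggregations: pooled pixel counts over the whole set
(micro, the default reported as `global`) and per-image metric means
(macro), since published segmentation tables rarely state which is used.
Degenerate $0/0$ ratios are reported as 0 for precision/recall/F1.

## Training protocol

Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) with the published defaults:
learning rate 0.005, batch size 32. Epoch count is not published; the
default is 50 with no early stopping. Shuffling is driven by the training
seed, weights are He-uniform initialized from the build seed, and runs are
bit-reproducible given both seeds. When validation data is supplied, the
epoch with the best head-2 Dice is checkpointed and restored.

## The synthetic generator and what the tests show

No clinical images ship with the package. `generate_sample()` renders
reproducible wound-like pairs: a skin-toned background (default RGB
224/172/138) with Gaussian texture noise (σ = 6 of 255), one to three
reddish lesions, and optional all-black border bands. Lesion outlines are
ellipses whose radius at polar angle φ is modulated by
$1 + j\sum_{k=1}^4 a_k \sin(k\varphi + \theta_k)$ with $\sum a_k = 1$ and
jitter $j = 0.3$ by default — irregular but simply connected, with an exact
mask by construction. All lesion geometry is drawn in fractional units
before any size-dependent randomness, so a seed renders the same scene at
any raster scale and foreground fractions are scale-free. Defaults were
chosen once for test coverage (lesions clearly separated from skin in the
green channel, foreground fractions around 0.1–0.2) since the clinical
benchmark's image statistics are not published.

What the generator deliberately does **not** emulate: lighting gradients
and shadows, specular highlights, tissue-type heterogeneity inside wounds,
ambiguous wound boundaries, and camera noise correlated across channels.
Passing desk-scale tests therefore demonstrates that the architecture,
gradients, objectives, and pipeline are correct and trainable — not that
the model reaches clinical-grade accuracy on real photographs.

## Desk-scale problem sizes

The test suite trains reduced models on generated data, with sizes chosen
as the package's own compromise between statistical meaning and a quick
suite:

* **Overfit sanity**: one fixed batch of 8 samples at 32×32, 50 Adam steps
  at learning rate 0.005; the combined two-head loss must fall below half
  its initial value (observed: ≈0.09 of initial).
* **End-to-end**: 64 training / 16 held-out samples at 64×64, a depth-2,
  8-filter model (65,402 parameters), 18 epochs, batch 16, both
  strategies; held-out head-2 Dice must reach 0.70 (observed: ≈0.99 for
  both strategies).
* **Strategy comparison**: 10 seeded replicate pairs at 32×32 (24 train /
  8 test, depth 2, 4 filters, 25 epochs), asking whether the Dice-strategy
  model attains at least the BCE-strategy model's precision in most runs —
  the direction of the published precision trade-off between the two
  objectives. The 25-epoch budget places models in the imperfect-fit
  regime (mean held-out Dice ≈ 0.90), the desk-scale analogue of the
  published operating point (Dice ≈ 0.83–0.85); at full saturation on the
  synthetic task both strategies exceed 0.97 precision and the comparison
  degenerates to noise. A caveat this package reports plainly: on the
  synthetic lesions, where colour alone nearly determines the answer, the
  per-seed precision difference between strategies is small and
  seed-dependent, and the directional claim does not reproduce reliably —
  the corresponding test documents this as a failing expectation rather
  than hiding it. Wound photographs, where foreground/background ambiguity
  is real, are where the trade-off has substance.

Full-scale results on the clinical benchmark (hundreds of real images,
GPU-scale training) are outside what this package's tests claim or check.

## Known limitations

* Pure-CPU training: the conv kernels are im2col + BLAS; practical up to
  roughly 128×128 images and a few hundred samples, not for the full
  clinical corpus.
* The default schedule is the nearest standard schedule to the published
  parameter budget, not a byte-exact reconstruction of the original
  (unpublished) one; the 276-parameter gap is documented above.
* Batch statistics are always used for normalization during training;
  very small batches (< 4) make batchnorm configs noisy — the desk-scale
  test models therefore run with batchnorm off.
* The region-of-interest crop assumes the wound sits inside the bright
  content region; it removes dark framing, it does not localize wounds.
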