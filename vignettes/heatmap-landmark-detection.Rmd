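---
title: "Heatmap landmark detection for cardiac MR: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap landmark detection for cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative cardiac MR reporting needs a handful of anatomical key
points per image: the two mitral-valve-plane points and the apex on
long-axis views (two-, three- and four-chamber), and the anterior and
posterior right-ventricular insertion points (A-RVI, P-RVI) plus the
LV centre (C-LV) on short-axis views. From these, clinically useful
quantities follow directly — the LV length (apex to the midpoint of the
valve points), the A-RVI angle that anchors the AHA sector model, and
the global longitudinal shortening curve over a cine series. cardiomark
implements an automatic detector for these landmarks together with the
derived measurements, plus a synthetic phantom generator so the entire
pipeline can be exercised, trained and validated with no clinical data.

## Detection as segmentation

Direct coordinate regression is brittle for sparse landmarks and cannot
express "this landmark is not in the image", which genuinely happens:
short-axis sections beyond the apical cap show no insertion points.
Instead, each landmark is encoded as a *heatmap*: the point is spread
by a Gaussian kernel, $h(x) = \exp(-\lVert x - x_0\rVert^2 / 2\sigma^2)$
with $\sigma = 4$ px by default, giving a per-pixel spatial-probability
map. With three landmarks per view, the target is a per-pixel
distribution over four classes (background + one class per landmark),
and detection becomes semantic segmentation. Absent landmarks are
naturally represented by an all-background target, and decoded outputs
with no sufficiently confident peak are reported absent.

Construction details that the formulation leaves open were fixed as
follows:

* **Finite kernel support.** As with discrete convolution by a finite
  Gaussian kernel, the blob is truncated at a radius of $4\sigma$, so
  landmark channels are exactly zero far from the point. Besides
  matching the discrete-convolution picture, this makes the
  Kullback–Leibler self-divergence *exactly* zero (no sub-floor tails
  interacting with the numerical floor on predictions).
* **Background and normalisation.** The background channel takes
  $\max(0, 1 - \sum_k h_k)$ and each pixel is renormalised to sum to 1,
  so the target is a valid class distribution wherever blobs overlap;
  the peak stays at the landmark.
* **Decoding.** Per landmark channel the peak is located (ties broken
  towards the smallest row-major index), the landmark is declared
  present iff the peak probability reaches $\tau = 0.5$ — the natural
  majority rule — and the coordinate is refined to the
  probability-weighted centroid within a box of half-width $2\sigma$
  around the peak, which recovers sub-pixel positions that a bare
  argmax cannot. A caveat follows from the distribution normalisation:
  if two landmarks approached within about one kernel width, their
  normalised peaks would drop below $\tau$. The cardiac roles are
  centimetres apart, so this regime does not occur in the intended use.

## The network and the loss

The backbone is a small U-Net: resolution levels connected by 2×2 max
pooling on the way down and nearest-neighbour upsampling plus skip
concatenation on the way up, with a convolution block = 3×3 convolution
→ instance normalisation → ReLU. The default has four levels with
two encoder blocks and one decoder block per level (three blocks per
resolution layer), 16 base channels doubling per level, and a final 1×1
convolution emitting the four raw score channels. On the default 96×96
grid this is ~440k parameters. Instance normalisation was chosen over
batch normalisation so that inference is independent of batch
composition and training is stable at small batch sizes.

Training minimises the sum of two terms computed on the per-pixel
softmax:

* the **Kullback–Leibler divergence** between the target heatmap
  distribution and the prediction, averaged over pixels (with
  $0\log 0 = 0$ and the prediction floored at $10^{-12}$); and
* a **soft-Dice term**: for each landmark channel the soft Dice ratio
  $2\sum pq / (\sum p + \sum q + \varepsilon)$, $\varepsilon = 10^{-8}$,
  averaged over landmark channels and subtracted from one.

Two readings of the Dice contribution were possible; adding the
similarity ratio itself would *reward* mismatch, so the term enters as
$1 - \text{Dice}$, making the total a proper loss that is zero exactly
for a perfect one-hot match. The background channel is excluded from
the Dice average so the dominant background cannot wash out the
landmark gradients; the per-channel mean (rather than pooling overlaps
across channels) keeps each landmark's contribution balanced.

The forward, loss and backward passes are implemented in compiled code
(im2col + BLAS GEMM in single precision) with an R reference
implementation of every loss quantity; the two routes are
cross-checked against each other and against central finite differences
in the test suite. Saliency maps are the magnitude of the loss gradient
with respect to the input pixels, obtained from the same backward pass.

## Training schedule

Adam with learning rate 0.001, $\beta = (0.9, 0.999)$,
$\varepsilon = 10^{-8}$; the learning rate is divided by 2 when the
validation loss fails to improve by a relative $10^{-3}$ for 5
consecutive epochs (the plateau rule's patience and threshold are
package choices; only "reduce by 2 on plateau" is prescribed by the
method). Samples are split *patient-wise* 90/10 into training and
validation so no patient leaks across sets, the checkpoint with the
lowest validation loss is returned, and long-axis views are pooled into
one multitask model: each epoch visits every pooled sample exactly once
in random order with no per-view rebalancing, so minibatches mix views
at the pool proportions. Batch size defaults to 8. One master seed
covers the split, weight initialisation and batch shuffling, making a
training run bit-reproducible.

Transfer learning to a new image contrast re-uses the pretrained
weights and runs the same loop at learning rate 0.0005 for 10 epochs
with all layers trainable (no freezing — the method prescribes only a
reduced rate). In the package's experiments the new domain is the
contrast-inverted phantom (bright background, dark blood pool), an
analogue of moving from cine to late-gadolinium-enhancement appearance.

## Preprocessing

Images are brought to the detector grid by bilinear resampling to a
fixed spacing (default 1 mm; output size rounded half-to-even for
platform stability) and centred padding/cropping to a fixed size.
Every grid operation returns a companion affine coordinate map, and
landmark coordinates ride through exactly the same transform — the
package convention is 0-based (row, col) with pixel centres at integer
coordinates, converted to millimetres by the spacing.

Surface-coil shading is corrected by estimating a multiplicative bias
field. The field is modelled as a smooth parametric surface: a
low-order polynomial (order tied to the `scale` parameter; the default
1/8 gives order 4) fitted to the log-intensities by iteratively
reweighted least squares with an asymmetric bisquare weight that clips
bright outliers (the anatomy) much harder than dim ones. Because the
converged fit is a projection in the log domain, correcting and
re-estimating yields a constant field — the correction is idempotent —
while the robustness keeps the bright blood pool from bending the
estimate. A plain heavy-smoothing surrogate was tried first and
rejected: at desk scale the anatomy dominates the smoothed image, the
"field" absorbs it, and iterating the correction keeps changing the
image by ~20%. Noise is not touched by the correction; its
contribution to intensity variation is irreducible, which is why the
correction-quality checks measure shading-only phantoms.

During training, the corrected image is substituted for the original
with probability 0.5 as an augmentation; at inference the correction
is always applied (the deterministic choice closest to the training
distribution). Further augmentation applies rotation (±30°), isotropic
scaling (±10%), translation (±5% of the extent, i.e. ±20 px at 400 px)
and intensity gamma (0.8–1.2) jointly to image and landmarks —
deliberately *no* mirror flips, which would silently swap
anterior/posterior landmark semantics. Intensities are normalised to
[0, 1] by the 1st–99th percentile window before entering the network.

## The phantom generator

The generator emulates the statistical structure the detector relies
on, not MR physics:

* **Long-axis views**: a bright blood-pool silhouette — an ellipse
  truncated at the base plane (at 0.8 of the semi-major axis, giving a
  bullet shape) — at random position and orientation; valve points
  flank the base, the apex sits at the opposite pole, and the
  apex-to-midbase distance *is* the sampled LV length.
* **Short-axis views**: a bright blood pool inside a darker myocardial
  annulus with an attached RV crescent built from two intersecting
  circles; the insertion points are the exact circle-intersection
  junctions and C-LV is the annulus centre. With probability
  `prob_no_landmark_frame` (default 0.1) the frame is landmark-free
  background texture, as happens beyond the apical cap of a real
  short-axis stack.
* **Cine series**: one long-axis geometry rendered over a smooth
  cycle, $L(t) = L_{ED}(1 - f\,s(t))$ with
  $s(t) = (1 - \cos 2\pi (t-1)/n)/2$, so phase 1 is end-diastole and
  the mid-series phase reaches $(1-f) L_{ED}$; 30 phases and $f = 0.2$
  by default.
* **Appearance**: Gaussian-smoothed edges, multiplicative low-frequency
  shading (a smoothed random field spanning $[1-a, 1]$, default
  $a = 0.3$), Rician-style magnitude noise (default SD 3% of the
  dynamic range), and annotation jitter of SD 0.5 px added to the
  emitted landmark coordinates to emulate interreader variability.

Default geometry is 96×96 px at 1 mm with LV lengths of 45–65 mm and
epicardial radii of 10–16 mm — proportionally realistic anatomy scaled
to a desk-size field of view. (Adult LV lengths run larger, but must
fit the 96 mm grid with margin at any orientation; the 400×400 grid of
a scanner-scale deployment remains fully configurable.) What the
phantoms deliberately do **not** model: true MR contrast mechanisms,
pathology (scar, amyloid), 3D geometry, motion artefacts, or the
long-tailed difficulty of clinical images (off-centre planning, unusual
shapes). Passing the phantom checks therefore demonstrates that the
pipeline's machinery — encoding, optimisation, decoding, measurement —
recovers known ground truth under controlled variation; it does not
certify clinical accuracy.

## Reference experiments and problem sizes

The package's reference runs, used by the acceptance checks and
`scripts/acceptance.R`, are sized for a single CPU:

* **Parameter recovery**: train the default detector (4 levels, base
  16) on 300 short-axis phantoms for 20 epochs; on 100 held-out
  phantoms the detection rate must be ≥ 95% with mean landmark error
  ≤ 3 px (the kernel width). The observed reference run reaches 100%
  with sub-pixel mean error.
* **Kernel-width sensitivity**: retraining with $\sigma = 2$ and
  $\sigma = 6$ must keep the held-out mean error within 1 px of the
  $\sigma = 4$ run.
* **Transfer**: fine-tuning the pretrained detector for 10 epochs at
  lr 0.0005 on 100 contrast-inverted phantoms must match or beat a
  scratch model given the same 10-epoch budget and data. The
  new-domain corpus is a third the pretraining size, mirroring the
  usual situation that the new contrast has far less data.
* **Reproducibility**: two end-to-end simulate → train → detect →
  evaluate runs from one master seed produce byte-identical tables
  (BLAS is pinned to one thread partly for this reason).

## Numerical choices and degenerate inputs

* Resampled output sizes round half-to-even; padding splits evenly with
  the extra pixel on the high-index side, cropping removes the extra
  pixel from the high-index side.
* Decode ties (equal peaks) go to the smallest row-major index;
  centroid windows are clipped at image borders.
* An all-zero image yields a flat bias field of ones; a landmark moved
  out of bounds by augmentation is marked absent rather than clamped;
  measurements with missing landmarks return NA ("undefined") rather
  than a value; a zero LV length at the cine baseline is an error.
* The A-RVI angle frame — counterclockwise from the +col axis with the
  row axis pointing down — is a package convention recorded in the
  function documentation; any fixed frame supports comparisons between
  label sources, and the choice is deliberately explicit because the
  measurement itself does not define a zero direction.
* Single-precision arithmetic in the network engine is deliberate
  (heatmap targets and losses are smooth; tests compare the engine
  against double-precision references at commensurate tolerances).

## Known limitations

* The decoder's presence rule breaks down for landmarks closer than
  about one kernel width (see above); real cardiac landmarks never are.
* The bias-field model is a global polynomial surface; localised coil
  artefacts sharper than its order are not captured.
* The phantom generator's simplicity means detector scores on phantoms
  overstate clinical performance by construction; the package's claims
  are about pipeline correctness, not clinical validation.
* Only 2D images are handled; series are processed frame by frame.
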