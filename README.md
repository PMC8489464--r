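# cardiomark

Automatic anatomical landmark detection for 2D cardiac MR images, with
the derived clinical measurements and a synthetic phantom generator.

Quantitative cardiac MR reporting hinges on a few key points per image:
the two mitral-valve-plane points and the apex on long-axis views
(CH2/CH3/CH4), and the anterior/posterior right-ventricular insertion
points (A-RVI, P-RVI) plus the LV centre (C-LV) on short-axis views.
From these follow the LV length (apex to the valve-point midpoint), the
A-RVI angle that anchors the AHA sector model, and the global
longitudinal shortening curve across a cine series. cardiomark is for
researchers building automated cardiac image analysis who need a
trainable, fully reproducible landmark detector and its measurement
chain in R.

## Method

Detection is cast as semantic segmentation. Each landmark is encoded as
a Gaussian spatial-probability heatmap,

    h_k(x) = exp(-||x - x_k||^2 / (2 sigma^2)),   sigma = 4 px,

and, with a background class, the per-pixel channels form a class
distribution over 4 classes. A compact U-Net (four resolution levels,
instance-norm conv blocks, ~440k parameters at the default size) maps
the image to per-pixel scores; training minimises

    L = KL(p || softmax(s)) + (1 - mean_k Dice_soft(p_k, q_k))

— the Kullback–Leibler divergence between target and predicted
distributions plus a soft-Dice shape term over the landmark channels —
with Adam (lr 0.001), patient-wise 90/10 splitting, plateau-halved
learning rate, and best-validation checkpointing. Decoding finds each
channel's peak, declares the landmark present iff the peak reaches 0.5,
and refines the coordinate to a probability-weighted centroid
(sub-pixel). Absent landmarks — e.g. short-axis frames beyond the
apical cap — are handled natively. Transfer to a new image contrast is
a 10-epoch fine-tune at lr 0.0005. The network engine (forward, loss,
backward, saliency) is implemented in the package in C++ over BLAS;
everything is seeded and bit-reproducible.

A synthetic cardiac phantom generator (ventricle silhouettes, annulus +
RV crescent geometry with exact ground truth, coil shading, Rician-like
noise, contracting cine series, landmark-free frames) makes the whole
pipeline trainable and verifiable without clinical data.

## Worked example

Train a small detector on simulated short-axis images and evaluate it
on held-out phantoms:

```r
library(cardiomark)

train_set <- phantom_dataset(120, phantom_config(), seed = 7)
test_set  <- phantom_dataset(30, phantom_config(), seed = 8)

det <- landmark_detector(train_set, sigma = 4,
                         train = train_config(n_epochs = 12, seed = 1))
det
#> Heatmap landmark detector
#>   views: SAX  sigma: 4 px
#> U-Net: 4 levels (2 enc + 1 dec blocks/level), base 16 channels
#>   input 96x96x1 -> scores 96x96x4, 439,748 parameters
#>   trained 12 epochs; best epoch 12 (val loss 0.69584)

evaluate_detector(det, test_set)
#> Detection rate: 100.0% (30 of 30 images); 2 false positive(s)
#> Distances over successful detections (mm, mean +- SD):
#>   SAX  A-RVI           0.92 +- 0.53  (n = 26)
#>   SAX  C-LV            0.83 +- 0.51  (n = 26)
#>   SAX  P-RVI           0.93 +- 0.57  (n = 26)
```

Four of the 30 held-out frames are landmark-free by design; they count
as successes when nothing must be found, and the two false positives
are spurious peaks on such frames (the reference-scale run below drives
these to zero).

The detection rate is the percentage of images on which every
truth-present landmark was found; distances are Euclidean errors to the
ground truth in mm over successfully detected images. (This is a
two-minute toy run; the reference run in `scripts/acceptance.R` uses
300 training phantoms and 20 epochs and reaches 100% detection with no
false positives and sub-millimetre mean error.) Individual images:

```r
pred <- predict(det, test_set[[1]])    # decoded landmarks + peaks
sal  <- saliency_map(det, test_set[[1]])  # |d loss / d pixel|
```

Derived measurements work on any landmark source:

```r
series <- generate_cine_series(phantom_config(view = "CH2", seed = 3),
                               n_phases = 30, contraction_fraction = 0.2)
curve <- shortening_curve(lapply(series, function(s) s$landmarks))
round(max(curve), 3)
#> [1] 0.209
```

A command-line front end (`inst/cli/cardiomark.R`) exposes the same
pipeline as `simulate`, `train`, `detect` and `evaluate` subcommands
driven by JSON configs, with manifests making a full run reproducible
from one master seed.

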