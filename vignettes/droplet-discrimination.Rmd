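---
title: "Discriminating dried blood droplet images by their angular log power spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating dried blood droplet images by their angular log power spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropspec)
```

## The problem

A droplet of whole blood left to dry on a glass slide deposits a circular
stain with a characteristic anatomy: a darker ring at the pinned contact
line, a corona crossed by radial cracks, and a paler centre with short,
disordered cracks.  The morphology of this pattern depends on the physical
state of the blood, which in turn tracks physiology — vigorous exercise,
for instance, changes blood chemistry profoundly within minutes.  The
question this package addresses is whether such physiological state changes
can be read out *quantitatively* from droplet photographs, without a human
deciding which features matter.

The package implements a complete, testable pipeline for that question:

1. a **synthetic study generator** that renders droplet images with known
   ground truth, standing in for a photographic dataset;
2. an **image pre-processing chain** that removes cracks and noise and
   distils each image to a texture map;
3. **rotation-invariant spectral features**: the angular log power spectrum
   on a polar grid about the droplet centre;
4. a **PCA–LDA discriminator** with a centroid distance-ratio decision rule;
5. a **two-stage greedy optimiser** that selects which participants' data
   train the discriminator;
6. a **blood chemistry module** for the accompanying acid–base panel.

## The feature model

Each image is reduced to a vector as follows.  Only the red channel is
used — on a backlit slide the haemoglobin-dominated deposit absorbs mostly
in the blue/green, so red carries the structural contrast.  Cracks transmit
the backlight and appear near-white; a pixel is declared *crack* where both
blue and green exceed a threshold $\alpha$ (default 200 of 255).  Crack
pixels are replaced by the discrete harmonic interpolant of their unmasked
surroundings (a sparse Laplace solve), which reproduces affine intensity
fields exactly and is idempotent; cracks are removed because they form
inconsistently between replicate droplets of the same blood and would
otherwise dominate the texture statistics.

The filled channel is low-pass filtered in the Fourier domain with the
transfer function $G(u,v) = \exp(-(u^2+v^2)/\sigma^2)$, $u,v$ in cycles per
pixel.  Note the unconventional normalisation (no factor 2): $\sigma$ is
the $e^{-1}$ half-width of the squared-frequency roll-off.  The default
$\sigma = 0.01$ cycles/pixel is appropriate for droplets of roughly 300 px
radius; because cycles-per-pixel is a resolution-dependent unit,
`scaled_sigma()` converts a resolution-independent cutoff (3 cycles per
droplet radius, which reproduces 0.01 at 300 px) to the rendering scale in
use.  The synthetic studies in this package render 64 px-radius droplets
and therefore use $\sigma \approx 0.047$.

Texture is extracted as the magnitude of the image Laplacian,
$\sqrt{f_{xx}^2 + f_{yy}^2}$, computed by central second differences with
replicate padding.  This form (the root-sum-square of the two *unmixed*
second derivatives, not $|f_{xx}+f_{yy}|$) responds strongly to thin lines
and weak edges.  It is worth noting that it is **anisotropic**: its response
to a one-dimensional feature varies with the feature's orientation by up to
$1/\sqrt{2}$.  The consequences for rotation invariance are discussed below.

The texture map is resampled on a polar grid about the droplet centre
(found by Otsu thresholding of the lightly smoothed channel, largest
connected component, holes filled; centroid and equivalent-area radius).
The grid has 48 radii spanning $(0, R]$ and 103 uniform angles.  Per radial
row the pipeline computes $\log(\cdot + \varepsilon)$, the discrete Fourier
transform along the angle, its magnitude, and a second
$\log(\cdot + \varepsilon)$, with $\varepsilon = 10^{-6}$ guarding both
logarithms against exact zeros.  Natural logarithms are used throughout
(the choice only rescales the features monotonically).  Because the
magnitude discards all phase, the result is unchanged by circular shifts
along the angle — rotations of the droplet about its centre.  The first
radial row (a ring of ~1 px radius) is discarded and only the first 52 of
103 frequency columns kept (the magnitude spectrum of a real signal is
symmetric), leaving a $47 \times 52$ block flattened row-major into a
2444-long feature vector, in cycles per revolution.

Replicate droplets from the same blood sample dry into visibly different
patterns, so per-cell feature vectors are averaged over the first $k$
replicates (manifest order) and the averaged vector min–max rescaled to
$[0,1]$.  Averaging depth is a first-class experimental variable
(`averaging_sweep()`).

## The discriminator and its optimiser

For a pair of conditions, each with one averaged column per participant,
the discriminator is: PCA on the training samples (SVD of the centred
matrix), retaining half of the non-trivial scores
($\lfloor n_\mathrm{nonzero}/2\rfloor$); then a two-axis LDA in score
space.  Two-class LDA has a rank-one between-class scatter, so only one
canonical axis exists; the second axis here is the second eigenvector of
the same ridge-regularised generalised eigenproblem
($\lambda = 10^{-6}\,\mathrm{tr}(S_w)/p$, needed because the retained
score count can approach the sample count), i.e. the leading direction of
residual within-class structure.  This construction is a documented design
choice — with two classes any "second discriminant" is a convention.  Both
axes are unit-norm with deterministic sign.  A sample is classified by the
ratio of its Euclidean distances to the two training centroids in the
$(LD_{S1}, LD_{S2})$ plane: class A iff $d_A/d_B < 1$, numerically
equidistant samples to class A by convention.

The training-subset optimiser addresses a practical observation: some
participants' droplets train the discriminator better than others, and the
exhaustive search over, say, all 20-of-30 subsets is combinatorially
hopeless (30 045 015 subsets per condition).  The greedy two-stage
procedure instead: **stage A** grows a training subset of condition A
participants — starting from the best pair containing anchor participant 1,
then the best pair containing anchor 2, each extended by the single
participant whose inclusion most lowers the error over *all* samples of
both conditions (with the full B cohort as the B training set), stopping
when no addition strictly improves; **stage B** repeats the search on the B
side with the stage-A choice fixed.  Both stages let the train-on-everyone
incumbent compete, so the final error can never exceed the unoptimised one,
and stage B can only keep or improve stage A.  Ties resolve to the smaller,
then lexicographically smallest subset, making the whole search
deterministic.  The cost is $O(n^2)$ error evaluations per anchor.  An
exhaustive enumerator (`exhaustive_oracle()`) is included purely as a test
oracle for tiny cohorts, guarded by a subset-count budget.

**A statistical caveat that matters.**  The error that both the optimiser
and the reported headline figure minimise is computed over *all*
participants, *including* the training subset.  This convention is part of
the procedure's definition and is reproduced here faithfully — but it means
the optimised error is a biased (optimistic) estimate of generalisation
error.  The bias is not hypothetical: on synthetic null studies with zero
class effect, the optimised all-sample error comes out far below the 50%
chance level (around 15–25% in this package's acceptance runs), because the
subset search has several hundred chances to find a split whose
partially-memorised discriminant looks good on the validation pool.  A
fixed, non-selected training split on label-shuffled data does hover at
chance (unit-tested).  Any use of this pipeline for real claims should add
an outer held-out validation; that is deliberately out of scope here, as it
is not part of the procedure being reproduced.

## What the synthetic generator emulates — and what it does not

`generate_study()` renders a full (participant × condition × replicate)
design with a single master seed and documented per-cell seed derivation,
so every image is individually reproducible.  Each droplet is a
red-dominated disc (radius 64 px in a 160 px frame by default) on a uniform
pale background, with: a darker rim annulus; an angular cosine texture in
the corona at a phenotype-controlled mode (cycles per revolution); radial
near-white cracks in the corona; short disordered central cracks; additive
Gaussian pixel noise; and a uniformly random orientation per image.  The
class signal of a study is injected as per-condition offsets to the
phenotype (by default on the angular texture mode and the crack count);
participants get stable random offsets shared across their conditions, and
every replicate droplet is additionally jittered, emulating the large
image-to-image variability that makes replicate averaging worthwhile.

The defaults encode the reference study conditions: 30 participants, five
conditions (baseline, peak exertion, and 2, 4, 6 minutes of recovery),
10–12 images per cell.  The chemistry generator draws the 11 measured
analytes per (participant, condition) from independent normals with the
per-condition reference means and SDs (`chemistry_reference()`; glucose and
PO~2~ are marked as invented defaults), truncates at zero, and derives pH
from [H^+^], the strong ion difference
$\mathrm{[SID]} = (\mathrm{[Na^+]} + \mathrm{[K^+]} + \mathrm{[Ca^{2+}]}) -
(\mathrm{[Cl^-]} + \mathrm{[La^-]})$, and the blood volume change
$\Delta BV = 100\,(\mathrm{Hb}_\mathrm{rest}/\mathrm{Hb}_t - 1)$ (the
Hb-ratio form; haematocrit-corrected variants need a variable the panel
does not carry).

The generator does **not** simulate the physics of evaporation, capillary
flow or crack mechanics, does not model correlations between analytes
(each is drawn independently, so e.g. the pH–PCO~2~ coupling of real blood
is absent), and makes no claim that angular texture frequency is the
feature that differs between physiological conditions in real droplets —
it is a controllable stand-in that lets every downstream stage be tested
against ground truth.  Passing tests therefore demonstrate that the
pipeline recovers a known class signal of this kind at realistic noise
levels, not that real blood droplets carry their signal in this particular
form.

## Numerical choices and degenerate inputs

* **Crack filling** solves the discrete Laplace equation on the masked set
  with Dirichlet data from unmasked neighbours (sparse Cholesky/LU via the
  Matrix package).  Interior masks reproduce affine fields to solver
  precision; masked pixels at the image border (where hull-based scattered
  interpolation would be undefined) are covered naturally by the same
  equations; a masked region sealed off from all unmasked pixels falls back
  to the unmasked mean.
* **Polar sampling** is bilinear with border clamping; radii are
  $r_i = iR/48$, $i = 1..48$, so the innermost ring is ~1 px — one reason
  its spectral row is discarded.  `to_polar(theta0 = )` rotates the
  sampling frame; for multiples of the angular step $2\pi/103$ this
  reproduces the sample set of a rotated droplet *exactly*, with no
  interpolation loss.
* **Rotation invariance in practice.**  Feature vectors are invariant to
  sampling-frame rotations by grid multiples at machine precision
  (~10^-10^ relative).  For a *re-rendered* droplet at an arbitrary new
  orientation, per-bin agreement of the double-log spectrum is much
  weaker (tens of percent on the worst bins): the Laplacian-magnitude
  operator is anisotropic, and bins beyond the local low-pass cutoff at
  each radius hold no true signal, so their logarithms sit on an
  interpolation-noise floor that does not reproduce.  What *is* stable
  under arbitrary rotation — and what the discriminator actually uses — is
  the location and strength of the true spectral lines; the test suite
  checks the leading line directly.  A related quirk: the magnitude
  operator rectifies a cosine texture of mode $m$, so its strongest
  spectral line appears at $2m$.
* **Optimiser determinism**: every tie in the greedy search and the oracle
  breaks by (error, subset size, lexicographic order).
* **Degenerate inputs** are rejected with informative errors: blank images
  in `find_centre()`, all-masked images in `fill_cracks()`, single-class or
  sub-2-sample classes in `fit_lda()`, identical samples in `fit_pca()`,
  zero-variance analytes in the chemistry PCA.  Constant feature vectors
  min–max normalise to zero with a warning.  $\Delta BV$ is identically
  zero at baseline by construction, so baseline correlation matrices carry
  an `NA` row for it (with a warning).

## Problem sizes used by the tests

The packaged acceptance runs use 30 participants × 2 conditions × 10
replicates at the 160 px/64 px rendering scale, three master seeds for the
strong-effect recovery and three for the null calibration; unit tests use
4–8 participant studies at the same scale.  These sizes were chosen so the
whole suite completes on a single CPU in minutes while keeping the cohort
geometry of the reference design.

## Known limitations

* The optimised all-sample error is an optimistic estimator (see the
  caveat above); the package reports it as defined and quantifies the bias
  on null studies rather than hiding it.
* Per-bin rotation invariance of the final features holds exactly only for
  polar-frame rotations; arbitrary-angle invariance is qualitative (stable
  spectral lines), for the reasons given.
* The synthetic class effect is one concrete texture mechanism; real
  droplet datasets may carry their signal elsewhere (e.g. crack
  morphology, radial banding), and the chemistry panel is drawn without
  cross-analyte correlation.
* Real-image studies are supported through `read_droplet_png()` plus the
  standard chain, but no real dataset ships with the package.
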