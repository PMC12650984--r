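---
title: "Dual-branch attention networks for hyperspectral SSC prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch attention networks for hyperspectral SSC prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Soluble solids content (SSC, °Brix) is the main internal quality index of
dessert fruit. Refractometry measures it destructively; hyperspectral
imaging in the visible/NIR range (roughly 400–1000 nm) offers a
non-destructive alternative, because dissolved sugars and the water matrix
shift the depth of absorption features in fruit reflectance. The modelling
task is a scalar regression from a hyperspectral cube — two spatial axes by
one spectral axis of reflectance — to a per-fruit SSC value.

`hyperbrix` implements a dual-branch convolutional network for this task:

* a **spectral branch** consumes small 3 × 3 × B pixel neighbourhoods and
  applies *channel attention*, learning which spectral bands matter;
* a **spatial branch** consumes larger 31 × 31 × B neighbourhoods and
  applies *spatial attention*, learning which neighbouring pixels matter;
* the two global-average-pooled feature vectors are concatenated and fed
  to a two-layer fully connected head with a linear output neuron.

Both attention operators carry their state across layers. The channel
weights of layer \(l\) are

\[
M^l_c=\sigma\!\big(\lambda_1\,\mathrm{MLP}(\mathrm{AvgPool}(F^l_c))+
\lambda_2\,\mathrm{MLP}(\mathrm{MaxPool}(F^l_c))+
\lambda_3\,\mathrm{MLP}(W_0\,M^{l-1}_c)\big),
\]

with a shared two-layer perceptron (bottleneck \(C \to C/r \to C\), ReLU
inside), learnable fusion scalars \(\lambda_{1..3}\) initialised at 1, and
\(W_0\) a learnable linear map from the previous layer's weights followed
by batch normalisation and ReLU. The spatial map is

\[
M^l_s=\sigma\!\big(W_s\,[\,\mathrm{AvgPool}(F^l_s),\ \mathrm{MaxPool}(F^l_s),\
W_l\,M^{l-1}_s\,]\big),
\]

where pooling is along the channel axis, \(W_l\) is a 3 × 3 transfer
convolution and \(W_s\) a 7 × 7 fusion convolution over the concatenated
maps. Attention rescales features by element-wise multiplication
(broadcast along the missing axis). At the first layer no previous
attention exists and the cross-layer term is dropped; we prefer this over
feeding a fake all-ones state because it keeps layer 1 parameter-free on
that path.

## Design choices on open points

Several details of this architecture family admit more than one reading;
the package fixes them as follows.

* **Global versus regional max pooling.** The channel-attention squeeze
  uses *global* max pooling along the spatial axes, consistent with its
  closed form and with the average-pool branch; a regional variant would
  introduce an undeclared window size.
* **Shared MLP for the cross-layer term.** The perceptron applied to the
  transferred shallow weights is the same shared MLP used for the two
  pooled vectors. Reusing it keeps the operator's parameter count at one
  MLP per block and matches the "shared weights" description of the
  pooled branches.
* **Fusion scalars are per layer.** Each block owns its
  \(\lambda_{1..3}\); sharing them across layers would couple blocks of
  different widths for no clear benefit.
* **MLP bottleneck ratio** defaults to \(r = 8\) (the CBAM convention;
  desk-scale models use \(r = 4\) so the bottleneck never collapses below
  2 units). **\(W_s\) is 7 × 7** with same-padding, also the CBAM
  convention.
* **Resolution mismatch across layers.** Max pooling shrinks feature maps
  between blocks, so the previous spatial attention map is max-pooled with
  the branch's own pooling geometry (window 3, stride 2) before \(W_l\).
* **Batch-norm placement** is conv → BN → activation → attention → pool in
  every block.

## From cube to patches

The preprocessing chain is: calibrate → mask → normalise → crop → extract
patch pairs.

* **Reflectance calibration** is the two-point correction
  \((I_{raw}-I_{black})/(I_{white}-I_{black})\); white-equal-black pixels
  are zeroed and counted in a warning rather than propagating NaN.
* **ROI masking** thresholds the 715.16 nm / 525.54 nm band ratio at 1.6.
  The comparison is inclusive (a "minimum threshold" admits its boundary);
  wavelengths are resolved to the nearest band so the rule survives band
  count changes; and only the largest connected component is kept, since
  one stray background pixel above threshold would otherwise corrupt the
  ROI mean spectrum.
* **Augmentation** expands a cube to exactly five: the original, three
  rotations drawn uniformly from 0–30°, 150–180° and 180–210°, and one
  left–right mirror of the original. We read "mirroring in both left–right
  directions" as a single horizontal flip, which is what makes the
  printed total of five come out. Rotation is bilinear per band around the
  raster centre with the band's background median as fill; mirroring is an
  exact column reversal. Augmentation is applied inside training folds
  only, so validation identities never change.
* **Normalisation** min–max scales each cube to [0, 1]; **cropping** takes
  a square window centred on the ROI centroid (224 px at sensor scale; at
  desk scale the cube is already the window), mirror-reflecting at the
  borders when the raster is smaller than the window. We crop after
  masking and before patch extraction.
* **Patch pairs**: labels exist per fruit, predictions per pixel. We
  sample `k_centers` ROI pixels per fruit without replacement, cut a
  3 × 3 × B and a 31 × 31 × B patch around each (mirror-reflect padding at
  borders), train on patches with the fruit's label, and predict a fruit
  as the mean of its per-patch predictions. `k_centers` trades compute for
  averaging; 8 per fruit for training and 16 for evaluation are the
  package defaults.

Labels are min–max scaled to [0, 1] on the calibration set before
training; metrics are reported on both the °Brix and the scaled axis,
because both conventions appear in the chemometric literature and they
differ exactly by the calibration span.

## Training core

No deep-learning framework is part of this package's stack; the network —
forward pass, backpropagation through the attention operators (including
the cross-layer pathways), batch normalisation, pooling and the
optimisers — is implemented in compiled C++ (im2col + BLAS convolutions).
Correctness rests on two pillars in the test suite: finite-difference
gradient checks over every parameter class, and R reference
implementations of the attention operators that the compiled path must
reproduce to 10⁻¹².

* **Loss** is mean squared error on scaled labels — the natural choice
  when the headline metric is RMSE.
* **Optimisers**: SGD, Adam, RMSProp and AdaBound (Adam whose per-element
  step size is clipped into a band that tightens towards a final
  SGD-like rate; final rate 0.1, gamma 10⁻³).
* **Batch-norm statistics.** Exponential running averages (momentum 0.1)
  lag the weights when optimisation moves quickly; on the desk-scale
  problems this lag showed up as a uniform prediction bias whenever
  inference followed a fast-moving epoch. After the final epoch (and
  before any recorded validation score) the running statistics are
  therefore recomputed exactly, as cumulative averages of the batch
  statistics under the final weights — the "precise BN" recalibration.
* **Degenerate inputs**: a non-finite loss aborts training with an error
  naming the learning rate; constant-label training sets are rejected for
  min–max scaling unless the caller supplies a scaler; batches of size 1
  at the epoch tail contribute no batch-norm statistics.
* **Weight decay** (decoupled L2 on every trainable tensor) is off for
  the reference configurations and set to 10⁻⁴ in the desk
  configurations, where the small fruit count makes memorisation of
  per-fruit baseline fingerprints the main failure mode.

## Bayesian hyperparameter optimisation

Hyperparameters (filter counts, FC sizes, learning rate, batch size,
activation, optimiser — the search spaces of the three model kinds are
built in) are tuned by sequential Bayesian optimisation:

* **Surrogate**: a zero-mean Gaussian process on standardised objectives
  with a Matérn 5/2 kernel, unit signal variance, jitter 10⁻⁶, and an
  isotropic lengthscale picked from {0.1, 0.2, 0.3, 0.5, 1.0} by marginal
  likelihood. Integer dimensions are scaled to [0, 1], learning rates in
  log₁₀, categoricals one-hot (relaxed to continuous coordinates inside
  the kernel).
* **Acquisition**: probability of improvement
  \(\Phi((\mu - f_{best} - \xi)/\sigma)\) with \(\xi = 0.01\), maximised
  over a pool of 512 random admissible candidates per iteration.
* **Initialisation**: 5 Latin-hypercube points before the first GP fit; a
  degenerate history (all objectives equal) falls back to random sampling
  with a notice.
* **Objective**: mean validation R² over five fruit-level
  cross-validation folds; fold-level values are logged with every
  iteration. Ties at the best objective are broken by the lowest fold
  variance ("stability"), then by earliest iteration.
* **Protocol**: 30 iterations × 30 epochs at reference scale; the
  pipeline's `tune_iters` lets desk runs use fewer.

## The synthetic scene generator

No public dataset accompanies this architecture, so the package ships a
generator that emulates the statistical structure the pipeline assumes,
with every default fixed up front:

* **Geometry**: a centred disk of fruit (radius 0.35 of the raster side)
  on a dark background, 64 × 64 px at 32 bands over 400–1000 nm — the
  arithmetic of every stage is unchanged from sensor scale (2048 px, 478
  bands), only cheaper.
* **SSC distribution**: Normal(11.76, 1.92²) °Brix rejection-clipped to
  [7.2, 18.1], the reference statistics of a 570-apple 'Fuji' survey.
* **Spectra**: a smooth baseline (offset plus three broad Gaussians at
  560, 760 and 950 nm with per-fruit random amplitudes, plus a smooth
  perturbation with a 4-band correlation length), minus Gaussian
  absorption dips (FWHM 30 nm) at 680, 880 and 960 nm whose depth is
  linear in SSC at 0.02 reflectance units per °Brix. The linear link
  makes attention-relevance and monotonicity checks exact. The baseline
  keeps the 715/525 nm ratio above 2 on fruit and at 1 on background, so
  the masking rule separates them with margin.
* **Digitisation**: counts = dark + reflectance × illumination × gain,
  with a smooth multiplicative illumination field (CV 0.05, spectrally
  flat — which is why the band-ratio mask is illumination-invariant), and
  additive Gaussian sensor noise (SD 0.01 in reflectance units). The
  white reference is a flat 0.999 reflector under nominal illumination
  and the black reference is the dark level, both frame-averaged, making
  the calibration identities exact and non-trivial.
* **What it does not model**: radiative transfer, specular highlights,
  curvature shading, variety-specific spectral libraries, wavelength
  calibration error, dead pixels. Passing the recovery test therefore
  shows the pipeline recovers a known monotone spectral signal through
  the full preprocessing/attention/training stack — not that it would
  reach the same accuracy on any particular instrument's data.

## Desk-scale problem sizes

The package's own experiments (tests and the acceptance script) run at
desk scale, chosen as the smallest sizes that still exercise every code
path meaningfully: 200 fruit at 64 × 64 × 32, 8 training and 16 evaluation
patch pairs per fruit, the down-scaled architecture of `desk_spec()`
(filters 8/16/24 spectral, 6/12/16 spatial, FC 32/16, Adam, learning rate
3 × 10⁻³, weight decay 10⁻⁴), 15 training epochs for the recovery run and
12 for the three-way ablation, and a 1-D toy objective for the
optimiser's convergence check. The five-fold CV objective and the
30 × 30 reference protocol remain available through `cv_objective()` and
the `"paper"` budget.

## Known limitations

* Fruit-level variance that mimics SSC (baseline amplitude fingerprints)
  is the dominant failure mode at small fruit counts; weight decay and
  patch averaging mitigate but do not remove it.
* The GP surrogate treats one-hot categoricals as continuous coordinates;
  with many categories a dedicated categorical kernel would be better.
* Single-CPU double-precision training: minutes per desk-scale model,
  hours at full sensor scale — the reference 30 × 30 BOA protocol is
  provided for completeness, not speed.
* ENVI I/O covers BSQ interleave with float samples, the variant the
  generator writes.
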