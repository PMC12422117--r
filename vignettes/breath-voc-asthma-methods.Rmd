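---
title: "Methods: simulating and classifying exhaled-breath profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying exhaled-breath profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The diagnostic problem

Airway inflammation in asthma leaves measurable traces in exhaled breath:
volatile organic compounds (VOCs) such as isoprene, acetone and ethanol
shift in concentration; the CO2 capnogram loses its healthy square shape
and takes on the obstructive "shark-fin" profile (a continuously rising
expiratory limb with no flat alveolar plateau); airway temperature rises
slightly and exhaled humidity falls; peak expiratory flow drops. `breathdx`
implements a complete analysis pipeline for multichannel breath records
built on these signals: simulation, preprocessing, Gaussian deconvolution
of VOC profiles, and a neural classifier (ADENA) trained to separate
asthmatic from non-asthmatic records.

Because real device recordings of this kind are proprietary, the package
ships a first-class synthetic cohort generator whose class-conditional
structure follows the published quantitative deconvolution results for
adult and pediatric groups. Every downstream stage is testable against
that generator's known ground truth.

## The synthetic cohort generator

One record is one exhalation session: 13 named channels (`co2`,
`voc_total`, `isoprene`, `acetone`, `ethanol`, `nox_proxy`, `flow`,
`temperature`, `humidity`, `pressure`, and three auxiliary VOC channels),
a binary label, an age-group tag, and a replicate index — every subject
contributes three sessions, mirroring triplicate testing. The canonical
13-channel list is a simulator convention: only some channels are named in
the source material, so the remainder are generic VOC sensors.

The total-VOC channel is a sum of three Gaussian components
("orders" 0-2) on a retention-time axis,

$$y(t) = \sum_{o=0}^{2} A_o \exp\!\left(-\frac{(t-\mu_o)^2}{2\sigma_o^2}\right) + b + \varepsilon,$$

whose class-conditional parameters $(A_o, \mu_o, \sigma_o)$ equal the
published adult or pediatric deconvolution statistics, retrievable with
`table_profile()`. The named VOC channels are
fixed scalings of the same mixture with independent noise. The baseline
$b$ defaults to 0 (the source is silent on it) and is configurable.

Choices the data do not pin down, fixed once with physiological defaults:

* **Capnogram parameterization.** Only the *shapes* are documented
  (square vs shark-fin), not equations. Controls get a trapezoid: a linear
  upstroke over the first 20% of expiration, then a flat plateau at the
  end-tidal level (5% CO2). Asthmatics get a monotone blend of a saturating
  exponential (rise constant 0.35 of the expiration) with a 15% linear
  admixture, which keeps the expiratory slope strictly positive — no flat
  plateau ever forms — while still ending exactly at the end-tidal level.
  Default timing: one 4 s breath sampled at 25 Hz.
* **Temperature/humidity offsets.** The literature gives a direction
  (warmer, drier in asthma), not a magnitude; the generator uses
  +0.5 degC and -3 %RH for asthmatics.
* **Noise model.** Additive i.i.d. Gaussian per channel, the simplest
  model consistent with unspecified sensor noise. The level is a fraction
  (`noise_frac`, default 0.05) of each channel's dynamic range.
* **Between-subject variation.** Parameters are jittered per subject by a
  lognormal multiplier with SD 0.1, so class means match the published
  tables while subjects remain distinguishable. Replicates share the
  subject's parameters and differ only in noise.
* **Effect-size dial.** `scale_effect(profile, f)` interpolates every
  class difference between 0 (classes identical — the null condition used
  to verify chance-level classification) and 1 (the full published
  effect).

What the generator does *not* emulate: sensor chemistry, drift,
cross-sensitivity between channels, or FeNO (not measured by this class of
device). Tests passing on synthetic cohorts therefore certify the
pipeline's statistical machinery, not clinical performance on real
patients.

## Preprocessing

`standardize()` maps each feature column to mean 0, SD 1; constant columns
become all-zeros with a warning rather than aborting (degenerate synthetic
edge cases should not kill a pipeline). `detect_end_tidal_plateau()`
smooths with a 5-sample centered moving average, takes first differences,
and returns the longest run with |slope| below tolerance — restricted to
the upper half of the signal range so the pre-upstroke baseline can never
masquerade as an alveolar plateau. `extract_features()` reduces a record
to 27 scalars: the VOC maximum and plateau width (time spent above half
maximum — for a single Gaussian this equals its FWHM), capnogram plateau
slope, end-tidal level and upstroke angle, and mean/max summaries of the
remaining channels. Replicates are aggregated by the per-subject median,
which tolerates one bad exhalation.

PCA (`fit_pca()`) eigendecomposes the feature covariance and keeps the
smallest number of components reaching a cumulative explained-variance
target (default 0.95; a fixed count can be forced). Whether the published
analysis ran PCA on raw waveform samples or on scalar features is
ambiguous; both paths work here, and the classifier default is scalar
features, which are better conditioned at cohort sizes of tens to
hundreds. The kept components are scaled by their explained-variance
ratios (`pca_weighted_scores()`) before entering the classifier — the
simplest reading of "assigning higher weights to the most informative
components".

## Gaussian deconvolution

`deconvolve()` fits a sum of `n_components` Gaussians plus a constant
baseline by Levenberg-Marquardt least squares (via minpack.lm, with the
analytic Jacobian). Initialisation is incremental: fit one component at
the residual maximum, refit jointly, add the next — dominant peaks are
absorbed first, so a component orders of magnitude smaller (the adult
order-0 amplitude is 0.00258 against siblings near 340) still surfaces
cleanly in the residual. Five seeded, jittered restarts run only when the
joint fit fails to converge or misfits grossly. Bounds (amplitudes
nonnegative, SDs between the sample spacing and the axis span) prevent
degenerate spikes. Components are reported in ascending-mean order, with
FWHM tied to SD by $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

`compare_groups()` averages per-order parameters over the subjects of
each class and reports percent differences $100(A - NA)/NA$; a zero
control mean flags the cell as undefined rather than silently zeroing it.
The FWHM row averages per-subject FWHMs and cross-checks against the FWHM
of the class-mean SD.

Two deliberate subtleties:

* **Component matching.** When a fitted component falls below the noise
  floor, pairing fitted to reference components by sorted mean scrambles
  the dominant pairs. `match_components()` instead minimizes the
  reference-amplitude-weighted sum of absolute mean differences over all
  assignments, so spurious components land on the least important slot.
* **Table audit.** `audit_fwhm_tables()` checks every published (SD,
  FWHM) pair against the Gaussian relation at 1% relative tolerance. The
  adult table is fully consistent. The pediatric table contains three
  violations: the order-0 control row (printed FWHM 3.17 vs expected
  3.08), and *both* order-"3" rows — the asthmatic row's printed 21.81
  matches the *control* SD (9.26), and the control row's printed 19.18
  matches nothing, i.e. the two FWHM cells appear swapped. (That block is
  also labelled "3" where "2" is meant.) The audit reports these; it
  corrects nothing, and the generator uses the printed amplitude, mean
  and SD columns, never the printed FWHM. The pediatric prose percentages
  for order 1 and the order-2 mean likewise contradict the printed table
  and are not used.

## The ADENA classifier

The network processes a feature vector as a one-channel 1-D signal:

1. Two convolution blocks, $X' = \sigma(w * X + b)$ with ReLU $\sigma$
   (16 then 32 filters, kernel 5, "same" padding).
2. Squeeze-and-excitation: per-channel means
   $z_c = \frac{1}{HW}\sum_{i,j} X_c(i,j)$ (here $H\times W = 1\times L$),
   then gates $E = \mathrm{sigmoid}(W_2\,\mathrm{relu}(W_1 z))$ with
   bottleneck ratio 4, multiplying their channels. The source assigns the
   activations in the opposite order (ReLU outermost); bounded gates
   require the sigmoid outermost, so that order is the default and the
   literal order remains available as `activation_order =
   "paper_literal"`. Both are tested.
3. Residual attention $RA = M(E)\cdot E$, with $M$ a learned sigmoid
   bottleneck over $E$. The multiplicative form is the default
   (`mask_product`); the residual-attention-literature form $(1+M(E))E$
   is kept as `residual_mask` since the intent is unresolvable.
4. Capsule dynamic routing: the feature map is cut into 8-dimensional
   input capsules (4 channel groups x position), linearly mapped to
   prediction vectors for 8 output capsules, and routed by agreement for
   3 iterations with the squash nonlinearity
   $v = \frac{\|s\|^2}{1+\|s\|^2}\frac{s}{\|s\|}$.
5. A stochastic-depth-wrapped dense residual block
   $x + g\,(W_2\,\mathrm{relu}(W_1 x + b_1) + b_2)$ on the 64-dim capsule
   read-out (bottleneck 32). Stochastic depth requires an identity path of
   matching width, which is why the "hidden layer of 32" lives inside a
   residual bottleneck; $g\sim\mathrm{Bernoulli}(0.8)$ during training and
   $g = 0.8$ at evaluation (survival rescaling).
6. Spatial dropout (rate 0.2) zeroes whole capsules during training,
   then spatial average pooling and a sigmoid head produce the asthma
   probability. Dropout precedes pooling (the composition order reads
   pooling outermost).

Forward and backward passes are hand-derived and vectorized over the
batch; the routing loop is unrolled in the backward pass so gradients flow
through the coupling coefficients. Analytic gradients are verified against
central differences at 1e-4 relative tolerance in the test suite.

The loss is the sum of focal loss and binary cross-entropy,
$L = -(1-p_t)^\gamma \log p_t - [y\log p + (1-y)\log(1-p)]$, averaged over
the batch, with probabilities clamped at $10^{-7}$. The focusing parameter
$\gamma$ is never stated in the source; the default is 2.0 (the standard
choice), exposed in the configuration. At $\gamma = 0$ the loss collapses
to exactly twice the cross-entropy, which the tests assert.

Architecture depth and widths are likewise unstated; the defaults above
are deliberately small (a few thousand parameters) because the intended
cohorts have tens to hundreds of subjects. The capsule read-out feeds a
dense sigmoid head (rather than capsule-norm classification) because the
final classification is described as fully connected.

## Training and evaluation protocol

Training uses Adam on shuffled minibatches (defaults: learning rate 5e-4,
200 epochs, batch size 4 — the tuned values; the grid-search default grids
are the tested learning rates plus that optimum, epochs 200/500/1000,
batches 2/4). All splitting is subject-level: the 60/30/10
train/validation/test split and the stratified 5-fold CV operate on
subjects, never on replicate records, so a subject's replicates can never
leak across partitions. How the 60/30/10 split interacts with 5-fold CV is
not spelled out in the source; here CV serves model selection on the 90%
train+validation pool and the untouched 10% yields the final report.

Metrics: MSE between labels and probabilities, F1 (0 when TP = 0),
accuracy, and AUC computed from the Mann-Whitney rank statistic with ties
counted one half — verified in tests against exhaustive pairwise
comparison. The confusion threshold is 0.5; AUC is threshold-free.
`reference_classifiers()` runs SVM, kNN, logistic regression, MLP, CART
and naive Bayes (library defaults, recorded per run) under the identical
fold protocol.

## Numerical and scale choices

The published headline numbers (98.7% accuracy, F1 0.98, MSE 0.065, AUC
0.98) come from a proprietary device cohort and cannot be reproduced from
public data. The package's stand-in, computed by `scripts/acceptance.R`
and asserted in the test suite, is property-based: on a 200-subject
synthetic adult cohort at 5% noise, 5-fold subject-level CV of ADENA must
reach mean accuracy and AUC of at least 0.95, and with the effect scaled
to zero the pooled held-out AUC must sit within 0.5 +/- 0.1. The null
calibration uses the AUC pooled over all held-out predictions (rather
than a mean of per-fold AUCs) because the pooled statistic has far lower
variance at 40 test subjects per fold. Deconvolution recovery is checked
on 100 mixtures drawn lognormally (SD 0.1) around the adult asthmatic
parameters with 1% noise: the median relative parameter error must stay
below 5%. The order-0 component lies far below that noise floor, so its
three parameters are unrecoverable by construction; the median over all
nine parameters absorbs this.

Problem sizes (200 subjects, 150 samples per channel, 400-sample
mixtures, 100 repetitions) are the package's test-scale defaults: large
enough for stable statistics, small enough to run a full verification in
minutes on one CPU.

Known limitations: the pediatric asthmatic profile contains an order-1
component with amplitude 6e-10 — twelve orders of magnitude below its
siblings — so exact round-trip recovery is only meaningful for the
dominant components there (the adult profiles round-trip to under 1%
relative error at zero noise, including the 0.00258-amplitude order-0
component); the simulator's independence assumptions (no channel
cross-correlation beyond shared mixtures) make the classification task
easier than real breath data; and eval-mode determinism holds on a single
thread.
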