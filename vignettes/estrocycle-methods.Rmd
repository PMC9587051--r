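---
title: "Cycle-aware estrous staging from vaginal cytology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-aware estrous staging from vaginal cytology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrocycle)
```

## The problem

The rodent estrous cycle runs through four canonical stages over roughly 4–5
days — diestrus (D), proestrus (P), estrus (E) and metestrus (M) — and the
standard way to stage an animal is vaginal cytology: the relative abundance
of three exfoliated cell classes (leukocytes, cornified epithelial cells,
nucleated epithelial cells) differs characteristically between stages.
Manual reading of these smears is slow and varies between examiners.
`estrocycle` implements an automated staging pipeline around a softmax image
classifier, and — because samples are usually collected daily — augments the
per-image prediction with the temporal structure of the cycle: sequential
classifications are fit to an archetypal periodic cycle, disagreements are
flagged, low-confidence disagreements yield a transition-stage suggestion,
and prolonged diestrus raises a pseudopregnancy warning.

## The archetypal cycle and phase fitting

Stages are encoded numerically in cycle order in increments of 1.0 starting
from 0.5: D = 0.5, P = 1.5, E = 2.5, M = 3.5, with 0.0 ≡ 4.0 naming the
metestrus→diestrus boundary. The archetypal cycle is a periodic waveform
$w(t)$ with period $T$ = 4.8 days mapping time to stage number. Each stage
occupies a fixed fraction of the period; the waveform is anchored at the
temporal midpoint of each stage (where it equals the stage's number) and at
the wrap boundary (0 at $t = 0$, 4 at $t = T$).

Two waveform modes are provided, because the anchor-fitting functional form
is a genuinely open design choice:

* `"interpolation"` (default): periodic piecewise-linear monotone
  interpolation through the five anchors. It passes through every anchor
  exactly and is monotone within a period, which is what the stage ordering
  implies.
* `"sinusoid"`: a least-squares fit of $a\sin(2\pi t/T) + b\cos(2\pi t/T) +
  c$ through the same anchors, for users who prefer a smooth two-term
  harmonic; it does not interpolate the anchors exactly.

Given classifications $s_1,\dots,s_n$ at times $t_1,\dots,t_n$ (strictly
increasing, more than four days of data: $n > 4x$ with $x$ samples/day), the
fitter computes the Pearson correlation $r(\varphi)$ between the encoded
stage numbers and $w(t_i + \varphi T)$ for $\varphi \in \{0, 0.1, \dots,
0.9\}$ cycle units, and reports the grid argmax (ties toward the smaller
phase) together with the whole $r(\varphi)$ profile. Residuals for outlier
flagging are computed on the stage-number circle — distance modulo 4 — so a
metestrus/diestrus discrepancy counts as adjacent (distance 1), not maximal;
samples with circular residual above 1.0 are flagged.

The stage-duration fractions default to D = 0.35, P = 0.15, E = 0.30,
M = 0.20. These are plausible placeholder values respecting the usual
ordering of stage lengths (diestrus longest, proestrus shortest); they are
**not** literature point estimates, and they are overridable in the
`cyclefit` config section.

## Confidence Index and prediction resolution

For a softmax output $p$, the Confidence Index is the normalized top-two
margin
$$\mathrm{CI} = \frac{P_{\max} - P_{\max-1}}{P_{\max} + P_{\max-1}},$$
which is 1 when all mass sits in one stage and 0 when the top two are tied.
`resolve_prediction()` combines the network stage with the fitted cycle's
stage at the sample time: agreement passes through untouched; disagreement
with CI ≥ 0.30 raises an outlier flag (the library, being non-interactive,
keeps the network stage as the default and reports both candidates);
disagreement with CI < 0.30 yields a transition suggestion — the boundary
label joining the two canonical stages nearest the fitted waveform position.

## Pseudopregnancy and anestrus rules

A pseudopregnancy warning fires when the current consecutive diestrus run
lasts more than 1.5 times the mean diestrus-run duration of previous
completed cycles (at least one completed prior run is required; "mean" is
our choice of baseline statistic, as a robust default over "max"). A run's
duration is the time spanned by its samples plus one median sampling
interval, so $k$ consecutive daily samples count as $k$ days. An anestrus
flag fires when the leukocyte fraction exceeds 0.9 on a consecutive span
strictly longer than 2 days. Both thresholds sit in the `cyclefit` config
section.

## Image preprocessing

* **Luminance peak alignment.** Images are normalized by shifting the
  luminance histogram's maximum peak to a fixed reference (0.8). The peak is
  located as the maximal bin of a 64-bin histogram and estimated as the mean
  pixel value inside that bin; shifts smaller than half a bin width are
  suppressed. This makes the operation exactly idempotent on
  background-dominated images and invariant to additive offsets, while a
  pure bin-centre mapping would not be (0.8 is not a bin centre of a 64-bin
  grid). The target level and bin count are design constants of this
  implementation.
* **Grayscale, three channels.** RGB is reduced with ITU-R BT.601 weights
  and replicated to three identical channels to meet standard backbone input
  conventions while removing stain hue.
* **Quadrisection.** Each image is split into four exactly tiling quadrants
  (odd dimensions give the extra row/column to top/left), quadrupling the
  data; quadrants inherit the parent's metadata and label. Quadrisection is
  applied **after** the train/validation/test split, so quadrants of one
  parent image can never leak across partitions.
* **Augmentation.** One random affine transform per call — reflection,
  rotation (±30° default), isotropic scale ([0.9, 1.1]), translation (±10%)
  — with bilinear resampling and edge-replication fill, all user-tunable.
  Every random draw in this package is seeded; reproducibility is a
  requirement of the test suite even where an interactive tool might not
  seed.
* **Resize.** Centre-aligned separable bilinear resize to 224 × 224 × 3.
* **Balancing and splitting.** Stages are downsampled without replacement to
  the minimum per-stage count; the 80/10/10 split is stratified on the joint
  (stain, species, lab, magnification) key with largest-remainder
  apportionment, so every stratum's fractions hold to within one record and
  the partitions are proportionally representative. Strata smaller than
  three records fall back to a pooled stratum with a logged warning.

## The classifier

The classifier is a pluggable backbone + softmax head. Deep pretrained
backbones (ResNet-50, VGG-19, Inception v3, MobileNet v2) are supported as
named plug-ins: their internals are deliberately not re-implemented, and a
feature extractor for them must be registered by the user
(`register_backbone()`); no pretrained weights ship with the package.

The bundled desk-scale backbone, `smallcnn`, is a small convolutional
network that can be trained in minutes on one CPU: a stride-2
average-pooling layer, a bank of eight seeded fixed zero-mean 9 × 9
convolution filters with ReLU, 4 × 4 spatial average pooling plus per-map
dispersion statistics, concatenated with a 16-bin intensity histogram. Only
the softmax head is trained — the same frozen-features/retrained-head
structure that transfer learning applies to the large backbones. The
discriminative signal in cytology (cell-type proportions and sizes) is
texture- and histogram-like, which is exactly what this feature stage
captures.

The training harness implements the transfer-learning schedule: minibatch
RMSprop (squared-gradient moving-average coefficient 0.99; Adam and SGD with
momentum are alternatives), three epochs with reshuffling every epoch, and a
piecewise step-decay learning rate
$$lr(e) = \max\bigl(lr_{\mathrm{floor}},\; lr_0 \cdot
\mathrm{drop}^{\lfloor e/\mathrm{epochs\_drop}\rfloor}\bigr),$$
with $e$ indexed from 0 so the first epoch trains at $lr_0$. Both readings
of the decay formula's "floor" are implemented: the floor function in the
exponent and an explicit minimum-learning-rate clamp (`lr_floor`, default
0). The deep-backbone defaults are the fine-tuning settings $lr_0 = 10^{-5}$,
minibatch 80. For `smallcnn`, which trains a fresh head from scratch rather
than nudging pretrained weights, those fine-tuning rates would move the head
negligibly in the ~60–120 optimizer steps a 3-epoch desk-scale run
provides; its backbone defaults are therefore $lr_0 = 0.1$ and minibatch 20
under the same schedule. At inference the four quadrant softmax vectors are
averaged and renormalized by default (a whole-image mode is available);
argmax ties break in canonical stage order.

## The synthetic cytology generator

Every downstream module is testable without any image download because the
package ships a seeded generator of stage-labelled synthetic cytology:

* **Cell geometry.** Leukocytes are small dark discs, nucleated epithelial
  cells mid-sized discs with a darker nucleus, cornified epithelial cells
  large irregular polygons without a nucleus; size ranges are ordered
  leukocyte < nucleated < cornified. Cornified cells cluster around clump
  centres with configurable strength, emulating the sheets typical of
  estrus.
* **Stage mixtures.** Default mean (leukocyte, cornified, nucleated)
  proportions are D = (0.85, 0.05, 0.10), P = (0.10, 0.10, 0.80),
  E = (0.05, 0.90, 0.05), M = (0.40, 0.30, 0.30), drawn with Dirichlet
  concentration 150; transition labels draw around the mean of their two
  flanking stages (interpolated, since no tabulated transition proportions
  exist to calibrate against). These means respect the qualitative cytology
  of each stage but are not measured values; they and the per-stage
  total-cell ranges (D 60–100, P 40–80, E 25–50, M 40–80, chosen so large
  estrus cells still place without overlap on a 448 px canvas) are
  config-overridable.
* **Exact countability.** Each cell type draws its darkest intensity from a
  disjoint band, cells are placed without overlap, and noise is optional, so
  a simple threshold-plus-connected-components counter
  (`count_cells_reference()`) recovers the generator's cell counts exactly
  on noise-free renderings. This is the generator's self-consistency oracle
  and the reason rendering favours separability over photorealism.
* **Sequences.** Multi-day series sample the archetypal cycle at a
  ground-truth phase; label noise corrupts only the stored benchmark label,
  never the rendered mixture; an optional pseudopregnancy onset forces
  diestrus with leukocyte fraction ≥ 0.9 thereafter, mirroring the >90%
  leukocyte signature of anestrus.

What the generator does **not** emulate: real stain chemistry and
illumination artefacts, mucus and debris, overlapping cell sheets, and the
13-substage fine structure of the cycle. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that its
statistical contracts hold — not that any particular accuracy transfers to
real cytology.

## Evaluation machinery

Confusion matrices (counts and row-stochastic), empirical one-vs-rest ROC
with trapezoidal auROC (verified in tests against the pairwise win-fraction
identity and against an independent ROC library), sensitivity/specificity
curves over the sorted unique scores plus endpoints — with the conventions
sens$(t) = P(s \ge t \mid +)$, spec$(t) = P(s \le t \mid -)$ so the endpoint
contracts sens(0) = spec(1) = 1 hold, a tie at an exact threshold counting
for both curves, and a zero-difference plateau resolved by its midpoint —
bootstrap accuracy distributions (5000 iterations by default, resampling
(truth, prediction) pairs jointly) with literal quartile-minus-IQR error
bars plus plain quartiles, Fisher's exact test on 2 × 2
correct/incorrect tables (exact two-sided hypergeometric p; sample odds
ratio with Woolf interval and Haldane–Anscombe correction, since no CI
method is canonical for this report), and grouped k-fold out-of-sample
evaluation that partitions group values — subjects, stains, species — never
records, with a leave-one-category-out mode that removes a whole stain or
species from training.

## Numerical choices and degenerate inputs

* Constant-zero images normalize to a constant 0.8 image (mode alignment is
  still defined).
* An all-constant stage sequence has zero variance and is rejected as
  degenerate by the phase fitter, as are sequences spanning four days or
  fewer.
* Phase-grid ties resolve to the smallest phase; argmax ties in the
  classifier resolve in canonical stage order; apportionment ties in the
  splitter favour train over validation over test.
* Dirichlet draws with infinite concentration return the mean exactly; a
  zero-cell request is an error (it would violate the minimum-cell curation
  filter by construction).
* Manifest records lacking dimensions or cell counts are retained by the
  exclusion filters (the rules only fire on recorded evidence), and the
  "excessive debris" criterion is not automated — a manual `exclude` column
  is honoured instead, since no quantitative debris definition exists.

## Problem sizes used by the test suite

The bundled checks run the full pipeline at desk scale: the end-to-end
training check uses 200 synthetic images per stage (448 px, two stains) with
the `smallcnn` backbone for 3 epochs and asserts held-out accuracy ≥ 0.8;
phase-recovery properties use 100 seeded 10-day sequences; oracle-equivalence
suites use 200 random sequences, 100 random ROC instances, and exhaustive
enumeration for the Fisher test (row totals to 15) and the anestrus rule
(all 256 binary 8-day patterns). These sizes are the package's own choice of
a configuration that a laptop CPU handles comfortably while still exercising
every module end to end; they are deliberately far below the scale of a real
multi-lab image bank, and accuracy numbers at this scale characterise the
synthetic benchmark only.

## Known limitations

* No pretrained deep backbone ships with the package; reproducing
  large-bank accuracy requires registering a real feature extractor and
  supplying real data.
* The archetypal cycle assumes a stationary period; drifting or irregular
  cycles are fit only as well as a fixed-period waveform allows.
* The Pearson correlation is computed on the linear stage encoding (the
  circular treatment applies to residuals only), matching the original
  formulation at the cost of some sensitivity near the wrap point.
* The 0.1-cycle phase grid bounds the fit's resolution. With noise-free
  daily sampling the grid argmax recovers a continuous ground-truth phase to
  within one grid increment almost always, but under ~10% label noise a
  flipped label can push the argmax to the adjacent grid cell on the far
  side of the truth in roughly one seeded series in ten — a boundary effect
  of a coarse grid argmax, not a defect of the correlation itself (the same
  seeds fit exactly without noise). Applications needing finer phase
  estimates should sample longer series rather than trust sub-grid
  precision.
* Transition-stage mixtures are interpolations, not calibrated measurements.
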