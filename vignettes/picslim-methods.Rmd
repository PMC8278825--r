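---
title: "picslim: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{picslim: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picslim)
```

## The measurement model

Spatial light interference microscopy (SLIM) decomposes the image field
into an incident (unscattered) component $U_i$ and a scattered component
$U_s$, and records four intensity frames while the relative phase delay
between them is stepped in increments of $\pi/2$:

$$ I(\phi_m) \;=\; |U_i|^2 + |U_s|^2 + 2\,|U_i||U_s|\cos(\Delta\phi - \phi_m),
   \qquad \phi_m \in \{0, \tfrac{\pi}{2}, \pi, \tfrac{3\pi}{2}\}, $$

with $\Delta\phi$ the phase difference between the scattered and incident
field. `simulate_interferograms()` implements exactly this law per pixel,
optionally with additive Gaussian camera noise clamped at zero intensity.

The inversion uses the two quadrature differences
$I(0)-I(\pi) = 4ab\cos\Delta\phi$ and
$I(\pi/2)-I(3\pi/2) = 4ab\sin\Delta\phi$ (writing $a=|U_i|$, $b=|U_s|$),
so `reconstruct_delta_phi()` is a single quadrant-aware arctangent. The
amplitude ratio $\beta = b/a$ follows from the frame sum
$S = 4(a^2+b^2)$ and the modulation amplitude $C = 4ab$:
$a^2$ and $b^2$ are the roots of $t^2 - (S/4)t + (C/4)^2$
(`estimate_beta()`). The quantitative phase of the total field is then

$$ \phi \;=\; \arg\!\left(1 + \beta e^{i\Delta\phi}\right)
   \;=\; \operatorname{atan2}\!\big(\beta\sin\Delta\phi,\;
         1 + \beta\cos\Delta\phi\big), $$

returned by `reconstruct_phase()`. With zero noise the round trip is exact
to better than $10^{-9}$ rad per pixel, which the test suite enforces
against an independent complex-arithmetic oracle.

Conventions that were genuinely open, and how they were fixed:

* **Sign convention.** The modulation is subtracted from $\Delta\phi$,
  i.e. $\cos(\Delta\phi - \phi_m)$. Any self-consistent convention passes
  the round trip; one had to be fixed and documented.
* **Branch choice.** Amplitude recovery takes $a \ge b$: SLIM assumes the
  unscattered field dominates. Pixels violating consistency (negative
  quadratic discriminant beyond numerical tolerance, possible under heavy
  noise) are clamped to the repeated root and flagged in a validity mask.
* **Degenerate pixels.** Where all modulation vanishes (no scattered
  light), $\Delta\phi$, $\beta$ and $\phi$ are defined as 0 and flagged,
  rather than returned as `NaN`; downstream statistics stay total.
* **Angles** are radians wrapped to $(-\pi, \pi]$ throughout, matching
  `atan2()`.
* **Noise model.** Additive Gaussian with a clamp at zero intensity.
  Camera shot noise is arguably Poisson; the noise standard deviation is
  a free parameter so a Poisson-like scaling can be emulated per
  intensity level, but a dedicated shot-noise model was deliberately
  deferred.

## Scan geometry and stitching

The scanner acquires frames of $1624 \times 1224$ px
($255 \times 170\ \mu m^2$, pixel pitch $255/1624 \approx 0.157\ \mu m$)
on a regular lattice. The printed lateral steps, 1580 and 1180, are
**read as pixels, not micrometres**: a micrometre reading would exceed
the frame size six-fold and leave no overlap, whereas the pixel reading
leaves a 44 px overlap strip on each axis — consistent with stitched
mosaics being possible at all. Steps remain configurable in case a
different instrument geometry is wanted. A $25 \times 25$ plan therefore
contains 625 tiles.

Autofocus uses the four corner focus values of the scanned area and
blends them bilinearly (`interpolate_focus()`); corner reproduction and
edge monotonicity are tested properties. The "four edges" phrasing of
focus-point selection is ambiguous (edges vs corners); corner-based
bilinear interpolation was implemented as the simplest surface agreeing
with four support values.

`stitch()` offers three overlap policies: `feather` (default; weights
ramp linearly to the tile border, the usual choice for seam-free
mosaics), `average`, and `overwrite`. Whether the original instrument
blended or overwrote is unknown; all three coincide — exactly — whenever
overlapping tiles agree, which makes `stitch(tile_image(img, plan),
plan)` an identity on the covered region for every mode, a property the
tests rely on. No correlation-based registration is attempted: tiles are
assumed mechanically placed on the planned lattice.

## Dry mass, stain normalization, histograms

Phase converts to dry-mass surface density as
$\rho = \lambda \phi / (2\pi\gamma)$. Neither $\lambda$ nor $\gamma$ is
printed for this instrument, so the package defaults are
$\lambda = 0.55\ \mu m$ (central wavelength of broadband white-light
illumination) and $\gamma = 0.2\ \mu m^3/pg$, the standard protein/lipid
refractive increment of the QPI literature; both are arguments, never
constants.

Stain normalization — removing the refractive contribution of the Luxol
Fast Blue myelin stain — is implemented as a global affine map
$\phi' = g\phi + c$ with user-supplied coefficients recorded in the map
metadata. The original calibration compared the same sections before and
after staining; those coefficients are not public, so the functional
form is kept minimal and explicit.

Myelin masks default to Otsu's between-class-variance threshold on the
phase histogram (`myelin_mask()`); on a plateau of equally optimal cuts
(e.g. a perfect two-level image) the midpoint is returned. Pooled phase
histograms default to 256 uniform bins over $[-0.5, 3.0]$ rad; bins are
half-open with the last closed, and out-of-range pixels are excluded
from the counts. Pooling is per class (not per image). Group overlap is
summarized by the histogram intersection coefficient
$\sum_i \min(p_i, q_i)$ — symmetric, in $[0,1]$, 1 iff the normalized
histograms coincide — computed for all six pairings of the four classes.
Hypothesis testing between groups is intentionally out of scope.

## The synthetic tissue world

No deposited image set exists, so every downstream stage is exercised on
a generative stand-in (`generate_fiber_phase_map()`): a Poisson number
of straight fiber segments with von Mises orientations (Best–Fisher
sampler), uniform centers, gamma-distributed lengths and per-fiber
amplitudes, rasterized as Gaussian cross-sections with additive phase
accumulation over a constant background plus Gaussian noise. The two
binary factors act as multipliers on the expected fiber count, encoding
the biological direction "appropriate-for-gestational-age and
hydrolyzed-fat-diet tissue carries more myelin".

Defaults, chosen once as a realistic desk-scale white-matter field and
not revisited: $192 \times 256$ px frames (the 4:3 aspect of the
full-size $1624 \times 1224$ frames), 80 fibers of mean length 60 px and
width 3 px, orientation concentration $\kappa = 4$ (a coherent tract),
peak phase 0.4 rad per fiber, background 0.1 rad, noise 0.02 rad, and
effect multipliers 1.5 (size) and 1.3 (diet). With these settings the
class-pooled pixel histograms overlap heavily while the classes differ
in spatial fiber density — the regime in which classification carries
information that pixel histograms alone do not.

Determinism is a contract: every map's seed derives from
`derive_seed(master, class_index, map_index)` (a fixed integer-mixing
rule that stays within 32-bit range), and identical `(params, label,
seed)` reproduce bit-identical maps. Maps are assigned round-robin to a
configurable number of synthetic source slides per class so that
held-out-slide evaluation has a meaningful unit.

What the generator does **not** emulate: biophysically realistic axon
packing, fiber curvature and crossing statistics, stain chromatics,
halo/shade-off artifacts, or the absolute phase values of piglet tissue.
A green classifier test on this world therefore establishes that the
pipeline recovers a planted, parameterized effect — not that any
particular accuracy is attainable on real tissue.

## The classification stage

The production-scale system fine-tuned a 71-layer pretrained network on
thousands of full-size images; that is out of desk-scale reach and out
of scope. The package keeps the surrounding machinery faithful and makes
the backbone pluggable:

* **Backbone:** any function `image -> feature vector`. The default
  (`backbone_pool()`) block-average-pools the frame to a $6 \times 8$
  grid and appends mean, standard deviation and mean absolute gradients
  — 52 features capturing exactly the density-and-texture contrast the
  generator plants.
* **Head (kept faithful):** two dense layers, each followed by dropout
  at rate 0.75, then a softmax of 2 units (diet or size task) or 4 units
  (joint task). Inverted dropout makes evaluation a deterministic pass.
* **Training:** minibatch Adam on cross-entropy. Optimizer, learning
  rate ($10^{-3}$), epochs (10) and batch size (32) are defaults of this
  package — the original values are unstated — and are all logged in the
  returned history. All weights are trained (no frozen backbone in the
  default, since the default backbone has no weights); a custom backbone
  is used as-is, which corresponds to the frozen-feature reading of
  transfer learning.

Dataset handling follows the published protocol where it is stated: of
10 000 images, 8016 train and 992 each validate and test. (The printed
per-category phrasing of the 992 reservation is arithmetically
inconsistent with the total; the 8016/992/992 overall reading is adopted
because it sums to 10 000.) `split_dataset()` reproduces those counts
reproducibly and can stratify by class, rotating remainder assignment
across classes so no class is over-drawn. Augmentation is restricted to
the shape-preserving symmetries of a rectangular frame — 180° rotation
and the two axis flips, each applied with probability 1/2; since
`rot180 = flip_x ∘ flip_y`, an asymmetric frame has exactly four
distinct variants. 90° rotations are offered to square inputs only.

Evaluation reports accuracy, mean cross-entropy and a confusion matrix
with row-normalized percentages. `evaluate_holdout_slide()` verifies the
requested slide reached neither training nor validation (a leak raises
an error) and reports three true-positive rates from the joint
predictions — both factors, diet alone, size alone — which necessarily
satisfy $\text{joint} \le \min(\text{diet}, \text{size})$.

## Numerical and testing choices

* Acceptance-level classifier checks run on $48 \times 64$ px maps with
  the fiber count scaled with area (12 instead of 80) purely to fit a
  one-CPU time budget; the effect sizes under test (diet multiplier 3
  for the strong task, 1.0 for the null control) are the stated
  benchmark conditions, not tuned values.
* The null-control test asserts test accuracy inside the binomial 95%
  chance band at the test-set size; with a fixed seed this is a single
  draw and carries the usual 5% false-alarm risk by construction.
* The TIFF layer is a hand-written baseline codec (uncompressed,
  single-channel, float32/uint16, multi-page) because the target R
  environment ships no TIFF package; interoperability with an
  independent implementation is part of the test suite. Acquisition
  metadata travels in a JSON sidecar rather than vendor tags, for
  portability. Phase is stored as float32 (lossless for practical
  purposes at $10^{-7}$ relative precision); 16-bit intensity storage
  records its linear scale factor.
* Feather weights are strictly positive (ramp minimum 1 at the border),
  so the weighted average is always well defined.
* Histogram edge equality for overlap computation is checked to
  $10^{-12}$; bin counts use `findInterval` semantics with an explicit
  last-edge closure.

## Known limitations

Halo and shade-off artifacts of phase contrast are not modeled or
corrected; illumination is treated as monochromatic at the central
wavelength; stage jitter and tile registration are ignored; the
classifier's default backbone is deliberately small and will saturate
far below what a deep pretrained model achieves on real data; and the
synthetic effect sizes are free parameters, so recovery tests
parameterize rather than reproduce the original study's class
differences.
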