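---
title: "Arch-height morphometry of plantar footprints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arch-height morphometry of plantar footprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The problem

A toeless plantar ink print carries enough shape information to grade the
medial longitudinal arch: a flat foot contacts the ground across the
midfoot, a high-arched foot barely does. The classical Cavanagh–Rodgers
Arch Index (AI) quantifies this as the midfoot share of the total contact
area, but the manual protocol (drawing a heel-to-second-toe line, trisecting
it, planimetering three regions) is slow and operator-dependent. This
package automates the AI and adds a landmark-free alternative built from
contour shape descriptors, with a synthetic-print generator that makes every
step verifiable against analytic ground truth.

## Pipeline and models

### Binarization and boundary

Input images (PNG/TIFF/PGM, 8-bit gray or RGB) are thresholded into a
foreground mask (`binarize()`, configurable threshold and polarity).
Interior dropouts are filled by default — ink prints have pressure
dropouts, and both the area and the arch-index model assume solid regions —
and components below 1% of the foreground are discarded as specks
(`min_component_frac`); genuinely split prints (a severe cavus foot whose
heel and forefoot disconnect) keep all large components and are analysed as
a union.

Boundary pixels are foreground pixels with at least one background
4-neighbor. `extract_contour()` orders them into closed cycles by
Moore-neighbor tracing (consecutive pixels 8-adjacent), oriented
counterclockwise with the foreground on the left. The test suite pins the
traced pixel set to a brute-force 4-neighbor scan on every fixture class.

### Geometric features

Area is the foreground pixel count. The default perimeter estimator is the
boundary-pixel count multiplied by pi/4 — the convention under which the
arch-height model's coefficients were fitted, kept as the scoring default
for fidelity even though it underestimates the geometric length (on a disk
of radius 50 it gives ~220 versus the true 314). The alternative
`chain_code` estimator sums the traced steps (1 axial, sqrt(2) diagonal)
scaled by Kulpa's constant pi(1+sqrt(2))/8 ≈ 0.9481: the raw step sum
overestimates smooth digitized contours by (8/pi)(sqrt(2)-1) ≈ 5.5% on
average over edge orientations, and the corrected form is the estimator
consistent with continuum length — it is the one under which measured disk
circularity approaches the analytic 4*pi and is scale-invariant (both
properties are asserted in the tests). Circularity is P^2/A: 4*pi for a
disk, 16 for a square, larger for elongated or indented prints; it rises as
the medial outline straightens in flat feet.

### Gabor-wavelet features

The oriented filter is a complex exponential under an anisotropic Gaussian,
psi(x) = exp(i k0 . x) exp(-0.5 |A x|^2) with A = diag(eps^-1/2, 1): the
envelope has standard deviation sqrt(eps) along the filter orientation and 1
across it, and the carrier k0 runs across the orientation, so the filter at
angle theta responds maximally to bar-like structure oriented at theta.
Kernels are mean-corrected, so constant regions give zero response. A bank
of K orientations theta_k = k pi/K yields per pixel the maximal response
magnitude and its orientation; from these come the second wavelet moment
(mean squared magnitude over the foreground) and the orientation-histogram
entropy E = -sum p_i ln p_i, which is 0 for a fully oriented pattern and
ln K for complete orientation disorder (a disk scores within 5% of ln K).

Defaults: K = 18 (10-degree bins), eps = 4, |k0| = pi/4 rad/px (8 px
wavelength), kernel support covering 3 envelope standard deviations, and a
magnitude floor of 0.1 x peak below which pixels are excluded from the
histogram so that near-zero interior responses do not contribute arbitrary
orientations. These are conventional oriented-filter-bank settings for
binary shape analysis at the package's 2 px/mm reference scale. Filtering
is frequency-domain with replicate (edge-extension) boundary handling —
chosen over zero padding so that constant images give zero response
everywhere including the frame edge — and is tested to agree with direct
spatial convolution to 1e-8.

### Curvature and mean bending energy

Local curvature uses the level-set form on a Gaussian-smoothed copy f of
the mask,

k = (2 f_x f_y f_xy - f_xx f_y^2 - f_yy f_x^2) / (f_x^2 + f_y^2)^(3/2),

with partials from Gaussian-derivative filters at scale `sigma_px` and the
sign fixed so convex boundary is positive (a disk of radius r scores +1/r;
the concave medial indentation of an arched print scores negative). Mean
bending energy is MBE = (1/N) sum k(n)^2 along the traced contour — the
energy needed to bend the outline into a circle of the same perimeter,
which is the minimizer at 1/r^2.

`sigma_px` defaults to **4**. This was a genuinely open numerical choice:
at sigma = 2 the second derivatives amplify the staircase ripple that
survives smoothing of a binary raster, the per-pixel curvature on a
radius-50 disk has a standard deviation comparable to the signal itself,
and its squared mean lands more than double the analytic 1/r^2; at sigma =
4 the disk oracles hold (mean curvature within 10% of 1/r, MBE within 15%
of 1/r^2, and the 1/s^2 scale law within 10%) while the medial-arch
concavity, tens of pixels wide at 2 px/mm, is still fully resolved. Pixels
with a vanishing smoothed gradient (< 1e-6) are set to zero rather than
left as 0/0.

MBE is by construction hypersensitive to boundary roughness: displacement
ripple of amplitude a and wavenumber q contributes curvature ripple of
order q^2 a. Smoothing at sigma attenuates wavelengths below ~2 pi sigma,
but roughness at 10-30 px wavelengths passes through and can multiply MBE
severalfold. This matters in practice: prints should be traced/scanned
smoothly, and the same is emulated (and measured) with the generator's
boundary-noise parameter below.

### Arch index

The longitudinal line of a toeless print cannot be the anatomical
heel-to-second-toe line, so `foot_axis()` uses the major principal axis of
the foreground pixel distribution — a reproducible surrogate that makes the
index rotation-invariant (tested at 37 degrees to within 0.01). The
projected extent is split into three equal intervals (forefoot A, midfoot
B, heel C; pixels exactly on a cut go to the heel-adjacent section, a
deterministic tie-break), and AI = B/(A+B+C). The partition is exact by
construction: every foreground pixel lands in exactly one section. Heel
orientation uses a width heuristic — the heel is the narrower end, the ball
of the forefoot the wider — which only affects which end is labelled A
versus C, never the index. Near-isotropic masks (principal eigenvalue ratio
< 1.05) have no meaningful axis and are rejected.

Cut-offs follow the clinical convention, boundaries inclusive:
AI >= 0.26 low arch, AI <= 0.21 high arch.

### The arch-height score

The landmark-free score is a linear model on the two most informative
contour features,

AHI = -7.351e-05 * P - 1050.964 * MBE + 0.4597,

with P the boundary-count perimeter in px and MBE in 1/px^2, both at the
2 px/mm reference scale. Both coefficients are negative: longer outlines
and more tightly curved outlines (both signatures of a high arch) push the
score down, and the intercept anchors the score near the AI range. Scores
are classified with inclusive cut-offs 0.23 (high) / 0.27 (low) by default.
Because the coefficients are resolution-specific, two calibration utilities
ship alongside: `derive_quartile_cutoffs()` re-derives the cut-offs as the
first and third quartiles of a score sample (linear-interpolation quantile
rule; reported rounded to 2 decimals with the unrounded values retained),
and `fit_ahi_model()` refits the coefficients by OLS against a reference
index, erroring on collinear designs. Quartiles of 10,000 draws from
Normal(0.25, 0.025) — the score distribution regime the default cut-offs
summarize — reproduce 0.23/0.27, as the acceptance tests verify.

## The synthetic-print generator

`generate_footprint()` rasterizes a three-part template in physical units
(mm): a heel disk (radius 0.40 x width), a forefoot ellipse (semi-axes
width/2 by 0.22 x length), and a midfoot band spanning 90% of the width,
with a medial indentation ellipse whose horizontal semi-axis grows linearly
with `arch_depth` in [0, 1]. Depth 0 gives a fully filled flat print;
depth near 1 narrows the midfoot strip below 10% of the width or
disconnects it. Defaults are a 180 x 90 mm adult print at 2 px/mm.

Two post-processing steps make the template behave like an ink print:

- **Outline rounding** (`smooth_mm`, default 6 mm): the raw template union
  has sharp corners where the primitives meet; real pedograph outlines do
  not. Without rounding, those few corner pixels dominate sum k^2, hold MBE
  an order of magnitude above the regime the fitted score expects, and even
  break MBE's monotonicity in arch depth. With 6 mm rounding, noise-free
  defaults sweep MBE from ~1.2e-4 (flat) to ~2.7e-4 (deep arch) and AI from
  0.36 to 0.12 — spanning both classification ranges.
- **Boundary noise** (`boundary_noise_px`, default 0): near-independent
  radial jitter of the traced outline (3-point averaged, re-rasterized by
  scanline fill, then hole-filled and de-specked). The outline polygon is
  offset +0.5 px from the boundary-pixel centers so that sub-pixel jitter
  perturbs the rasterization continuously. Sub-pixel noise (0.25 px) leaves
  MBE essentially unchanged; 1 px roughness inflates it 2-3x — the
  quantitative face of MBE's boundary sensitivity noted above. Fixture sets
  (`make_fixtures()`) default to 0.5 px, emulating carefully traced,
  scanned outlines.

Prints are deterministic given the seed, and left/right sides of the same
seed are exact mirror images.

### What the generator does and does not establish

Passing the synthetic suite shows the measurement chain is correct: features
match analytic oracles on disks/rectangles, obey the right scale laws, and
respond monotonically to a controlled arch-depth dial. It does not show
clinical validity on real feet: the template has no toes (by design), no
pressure gradation, one global outline-roughness scale, and an arch-depth
parameter that sweeps a family of shapes real cohorts sample only narrowly.
Absolute AHI values on synthetic prints agree with the fitted model's range
but not its cohort calibration — on a new scanner or print preparation the
quartile workflow (score the batch, derive Q1/Q3, classify) is the intended
use, which is also how the default 0.23/0.27 cut-offs were obtained.

## Validation problem sizes

The shipped tests run the full pipeline on disks of radius 25-80, gratings
at three orientations, and a few dozen synthetic prints (~380 x 200 px);
the trisection-exactness property uses 100 random prints and the
quartile-separation property 30 prints across three arch-depth strata.
These sizes keep the whole suite around a minute on one core while leaving
every estimator's bias visible well below the asserted tolerances.

## Known limitations

- The pi/4 perimeter convention is kept for score fidelity but is not a
  consistent length estimator; cross-study comparisons of P should state
  the estimator explicitly.
- The heel/forefoot orientation heuristic can flip the A/C labels on
  atypical shapes (never affecting AI).
- Gabor features are computed on the binary mask; grayscale pressure
  images are thresholded first, discarding intensity texture.
- The Moore trace assumes hole-filled regions; with `fill_holes = FALSE`
  interior cavities contribute no contour.
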