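---
title: "Shape-aware SSC mapping and the imaging reliability index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-aware SSC mapping and the imaging reliability index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sscmap)
```

This vignette is the package's own account of the science it implements:
the radiometric model and its assumptions, the statistics behind the
reliability index, what the synthetic phantoms do and do not emulate, and
the numerical and design choices made where the method description left
the design open. It states no empirical claim that the test suite or the
acceptance script does not itself compute.

## 1. Radiometric model

A push-broom NIR system records intensity counts $I_\lambda(i,j)$ per scan
row $i$, detector column $j$ and band $\lambda$. With a dark frame
$D_\lambda(j)$ (closed shutter) and a white reference $W_\lambda(j)$
(reflectance standard in the panel plane), relative reflectance is

$$R_\lambda(i,j) = \frac{I_\lambda(i,j) - D_\lambda(j)}{W_\lambda(j) - D_\lambda(j)}.$$

The dark reference is indexed per detector column and band only: dark
current is a property of the detector element, not the scan position.

Curved samples violate the implicit assumption that the sample sits in the
panel plane facing the camera. Two corrections act on the dark-subtracted
intensity before the division:

**Height.** A pixel at height $H_s$ (mm above the panel plane, from a
co-registered laser height map) is closer to both the source (distance
$H_1$, default 100 mm) and the lens (distance $H_2$, default 200 mm).
A simplified inverse-square model refers its intensity back to the panel
plane:

$$I'_h = (I - D)\left(\frac{H_1 + H_s}{H_1}\right)^2\left(\frac{H_2 + H_s}{H_2}\right)^2.$$

The factor is applied exactly as written, and the phantom forward model
divides by the same factor, so the pair is self-consistent regardless of
the physical sign convention of a particular instrument; a `height_sign`
flag negates $H_s$ for instruments with the opposite convention. An
empirical variant replaces the closed form with a white reference measured
at a ladder of panel heights (0–30 mm in 2 mm steps) and linearly
interpolated to each pixel's height; interpolation is clamped at the
measured range because the panel was not measured beyond it.

**Angle.** For a Lambertian surface the detected radiance falls with the
cosine of the angle $\theta$ between the surface normal and the vertical
viewing direction, so $I'_a = (I - D)/\cos\theta$. $\theta$ is computed
from the height map by central differences with edge replication, by
default along the width (detector) axis only — the convention of the
line-scan instrument — with a full-gradient mode available. Division by
$\cos\theta$ diverges at grazing angles; pixels with
$\cos\theta < $ `cos_floor` (default 0.2, i.e. $\theta > 78.5^\circ$) are
masked and counted rather than amplified. The combined correction is the
composition: $I'_{ha} = I'_h / \cos\theta$.

Assumptions worth stating: diffuse (Lambertian) reflection, vertically
downward illumination for the distance model, no subsurface scattering or
bidirectional effects, and a height map that is aligned (the package
resamples it bilinearly onto the cube grid when needed).

## 2. ROI, preprocessing, calibration

Flesh segmentation is a three-stage pipeline: (i) background removal by
thresholding a single band (two instrument presets: reflectance at
1204 nm > 0.2, or raw intensity at 1123 nm > 12 000 — the source
description ambiguously attributes both settings, and both PCA windows
1160–2168 nm and 1476–1917 nm, to the same dataset, so they are exposed as
named presets without asserting which belongs to which system); (ii) PC1
scores of the mean-centered masked spectra over the preset's wavelength
window (no variance scaling — standard for spectra); (iii) Otsu
binarization of the 256-bin histogram of min–max-scaled scores, keeping
the class that contains the median score (flesh is the majority class;
achenes, modeled as spectrally flat and bright, fall on the other side).
The flesh mask is split at its row centroid into apex (top) and base
(bottom) halves, whose mean spectra are the calibration observations.

Preprocessing is an eight-pattern battery: `none`, SG `smooth`, SG `d1`,
SG `d2` (window 9, polyorder 2), `snv`, and `snv_*` combinations with SNV
applied first — the order implied by the conventional label
"SNV-1st derivative", configurable in principle but fixed here. Savitzky–
Golay edges are handled by refitting the polynomial on the truncated
window instead of trimming bands, keeping the full band axis intact so
pixel spectra remain projectable with the calibration $W^*$. Derivatives
are in per-band units (no division by the nm spacing): PLSR is
scale-equivariant, so a global scale on a band-wise derivative changes
nothing downstream. SNV uses the $n-1$ denominator; a constant spectrum
has no SNV image and the pixel is masked and counted rather than patched.

PLSR is NIPALS with mean-centering only, exposing $W$, $P$, $q$, the
direct projection $W^* = W(P^\top W)^{-1}$ and the regression vector
$b = W^* q$. Fruits — not sections — are the sampling unit everywhere:
the 7:3 split is stratified on per-fruit mean Brix (quantile bins, default
5, seeded shuffle within bins, leftover fruits round-robin under the
global 70% target), and cross-validation folds are fruit-level, so the two
sections of a fruit never straddle a split. The latent-variable count is
chosen by the one-standard-error rule: the smallest $A$ whose RMSECV lies
within $\mathrm{SE}(A_{\min})$ of the minimum, SE being the per-fold RMSE
standard deviation over $\sqrt{\text{folds}}$. Sections are pooled as two
observations per fruit in a single model (the alternative — separate
section models — is not reported by the source tables, which list one
model per configuration). $A_{\max}$ defaults to 10; reported models use
far fewer.

## 3. The reliability index

The model is calibrated on ROI-averaged spectra but applied to pixels. To
ask whether a pixel spectrum is statistically consistent with calibration,
it is projected into the latent space with the calibration centering,
$t_j = (x_j - \bar{x})W^*$ (centering is the default; an uncentered mode
exists because the source leaves this implicit, but the latent space is
defined on centered data). With $\mu$ and $\Sigma$ the mean and sample
covariance of the calibration scores, each pixel's squared Mahalanobis
distance $D_j^2 = (t_j-\mu)^\top\Sigma^{-1}(t_j-\mu)$ follows
$\chi^2(A)$ under multivariate normality of scores. The threshold is
parameterized by a k-sigma rule through the two-sided normal coverage
$\alpha = \mathrm{erf}(k/\sqrt{2})$ — at $k=3$, $\alpha = 0.9973$ — and
$\tau = \chi^2_A(\alpha)$. (A one-sided reading of the same formula would
give 0.9987 at $k=3$ and not reproduce the quoted 0.997; the two-sided
form is therefore implemented. A direct-$\alpha$ mode covers the
alternative 99% boundary mentioned alongside.) The reliability of a map is
the fraction of pixels with $D^2 \le \tau$ (boundary inclusive; pixels
whose preprocessing failed count as outliers), and the model-level metric
is the unweighted mean over test fruit, so small fruit count as much as
large ones. $D^2$ is computed by a Cholesky solve, never an explicit
inverse; a covariance condition number above $10^{10}$ triggers a warning,
and a singular covariance is an error advising fewer latent variables.

The point of the index is that it can disagree with R²: a derivative
pattern that removes a multiplicative scatter confound from the averaged
calibration spectra (raising R²p) can simultaneously amplify white pixel
noise (inflating pixel $D^2$ and collapsing reliability). The test suite
constructs exactly this scenario and asserts the dissociation; the sweep
on noisy phantoms shows the same structure, and
`threshold_sensitivity()` verifies that the reliability ranking is stable
across $k \in \{2,3,4\}$ when one configuration dominates.

## 4. The phantom world

The generator emulates, with known ground truth, the features the method
must cope with:

- ellipsoidal fruit (default semi-axes 25 × 20 × 15 mm, ±10% between
  fruits) on a dark belt (background reflectance 0.05), 64 × 64 px at
  1 mm pitch, 913–2166 nm in 200 bands;
- a flesh reflectance continuum (0.85 sloping to 0.75) times
  $e^{-A(\lambda)}$ with Gaussian absorbance features at 970, 1165, 1420,
  1780, 1900 nm (water at 970/1420/1900, sugar at 1165/1780). The sugar
  feature strengths scale linearly with local SSC: ±8% per Brix about a
  10 Brix reference. This linear coupling is a stand-in that gives the
  regression a real signal, not a claim about strawberry optics — no
  quantitative SSC–absorbance relation is available to copy;
- a linear apex-to-base SSC gradient (defaults 12 → 8 Brix; fleet
  generation draws apex ~ N(11.5, 1.5) and a drop ~ N(3, 0.75), apices
  sweeter, matching the qualitative field observation);
- achene speckles (3% of fruit pixels) as flat high-reflectance (0.70)
  spots — no achene optical model exists, only the requirement that PC1 +
  Otsu can remove them;
- forward distortion $I = D + (W-D)\,R\,\cos\theta / g(H_s) + \varepsilon$
  with $\varepsilon \sim N(0, \sigma^2)$ additive on *intensity* (detector
  noise precedes calibration), $\sigma = 20$ counts by default against a
  white–dark span of ~7000 counts (≈0.3% reflectance noise). The forward
  model uses the same width-only finite-difference $\theta$ as the
  correction chain, so zero-noise phantoms are corrected back to truth to
  machine precision — the round-trip is exact by construction, which is
  what makes it a useful oracle.

What the phantoms do **not** emulate: subsurface scattering, specular
highlights, calyx/peduncle structures, spatially correlated noise,
wavelength miscalibration, or rotation-scan motion blur. A green test
therefore establishes that the chain of algorithms is implemented
correctly and behaves as the theory predicts on data obeying its
assumptions — not that any particular accuracy will be achieved on real
fruit. Reference SSC tables are derived by averaging the true SSC field
over the apex/base halves of the flesh mask (split at the row centroid),
standing in for destructive juice measurements.

## 5. Numerical choices and degenerate inputs

- Otsu runs on a 256-bin histogram of min–max-scaled scores (classic
  formulation); the threshold equals an exhaustive search by construction
  and is asserted against one in the tests.
- Bilinear height-map resampling aligns cell centers of the two grids and
  clamps at edges.
- `cos_floor` masking (not unbounded division) bounds the angle
  correction; masked pixels propagate as NA and are excluded from maps and
  reliability denominators only where stated (failed preprocessing counts
  as outliers, masked geometry pixels never enter the flesh matrix as
  complete cases).
- PLS components stop at the attained rank; strict mode errors, CV mode
  truncates. RMSECV at smaller $A$ reuses the nested structure of a single
  $A_{\max}$ fit per fold.
- One-SE ties break toward smaller $A$; a constant CV curve yields
  $A = 1$.
- All randomness (phantom noise, achene placement, fleet draws, splits,
  folds) descends from explicit integer seeds through a scoped RNG helper
  that restores the caller's RNG state; identical seeds give bit-identical
  scenes, splits and sweep tables.

## 6. Known limitations

The cylindrical rotation-scan reconstruction (azimuth from frame index ×
turn-rate/frame-rate, laser radius per row) is a documented approximation;
how the original rotation maps were draped onto the 3D surface is not
described anywhere, and no attempt is made at mesh reconstruction. The
interpolated-white and closed-form height corrections agree exactly only
at stack knot heights. Reported reliability is a consistency statistic,
not an accuracy guarantee: a biased but precise model can be perfectly
"reliable". Mask export uses CSV (and ENVI for cubes, PLY for clouds);
PNG export was dropped because no PNG writer is available in the target
environment.
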