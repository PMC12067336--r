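---
title: "Dose-limited bone micro-CT with self-supervised denoising: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-limited bone micro-CT with self-supervised denoising: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OsteoN2I)
```

## The problem

In situ synchrotron micro-CT of bone is dose-limited: above a cumulative
absorbed dose of roughly 35 kGy, collagen degrades and the measured
mechanical properties stop being representative. Reducing the number of
projections per scan reduces the dose proportionally, but the resulting
reconstructions are noisy and streaked, and the micrometre-scale features
bone researchers care about — osteocyte lacunae (volume, shape) and the
mineral density of the matrix — are distorted or lost.

`OsteoN2I` implements the full simulated-dose study around this problem:
a synthetic cortical-bone phantom with known lacunae, a parallel-beam
forward model with photon-counting noise, dose reduction by angular
subsampling, filtered back projection, self-supervised Noise2Inverse
denoising, morphometric and mineral quantification, and the radiation dose
budget. Because the phantom is synthetic, every downstream estimate can be
compared against analytic ground truth.

## Noise2Inverse

Noise2Inverse needs no clean reference image. The projection set is split
into $K$ interleaved subsets (every $K$-th angle); each subset is
reconstructed by FBP. The $K$ sub-reconstructions share the underlying
signal but carry *independent* noise, because measurement noise is
independent across projections. A network trained to map one
sub-reconstruction to another therefore cannot predict the noise and, at
the optimum of the mean-squared-error loss, converges toward the noise-free
reconstruction. At inference the network is applied to each
sub-reconstruction (for $K > 2$, to each leave-one-out mean) and the $K$
outputs are averaged.

This package uses $K = 2$ by default, the published choice for
low-projection data: larger $K$ leaves too few angles per split and the
sub-reconstructions become dominated by streak artefacts rather than noise.
For $K = 2$ both orderings (A→B and B→A) are used as training pairs; a
single-ordering mode is a flag. Whether the original protocol used one or
both orderings is not documented; both-orderings doubles the training set
at no acquisition cost, which is why it is the default here.

## The network

The denoiser is a mixed-scale dense (MSD) style convolutional network:
every layer adds a single channel computed from *all* previous channels by
3×3 convolutions whose dilation cycles through 1..10, followed by a bias
and ReLU; the output is a 1×1 linear combination of every channel. This
architecture is compact (a depth-20 network has ~3,000 parameters), which
matters on CPU and also regularizes strongly. The implementation (forward,
backward, Adam) is in C++ with a self-contained deterministic RNG, so
training is bit-reproducible for a fixed seed.

Training settings follow the published recipe where one exists: learning
rate $10^{-3}$, input slab of 5 adjacent slices, batch size 12, 80/20
train–validation split. Settings the protocol leaves open are package
defaults, documented here:

* **Depth 20** (not the published 100): the published depth targets
  1024×1024×800 volumes on GPU hardware; at the desk scale of this package
  the smaller network trains in minutes on one CPU and still denoises
  clearly. Depth is a hyper-parameter (`n2iHyperparams(depth = ...)`).
* **Optimizer Adam**, the de-facto standard for this regime; none is named
  in the protocol.
* **100 epochs default, best-validation weights kept**; no epoch count is
  published.
* **Global input normalization** by training-set mean/sd, stored in the
  model so inference is self-contained.
* **Validation split by contiguous slice blocks** (the last 20% of slice
  indices), not random slices: adjacent slices are nearly identical, and a
  random split would leak training content into validation.
* **Slab edges reflect** without repeating the boundary slice
  (slab 5 at the first slice reads slices 3, 2, 1, 2, 3).

## Forward model and reconstruction

Projection is a discrete Radon transform (unit-pixel ray stepping with
bilinear sampling) over equally spaced angles on the half turn $[0, \pi)$;
line integrals are in $\mu \cdot \mathrm{mm}$. Noise is photon counting:
transmitted counts $N \sim \mathrm{Poisson}(I_0 e^{-p})$ per bin, post-log
data $-\ln(\max(N,1)/I_0)$. Counts are clamped at one before the log —
standard transmission-CT practice — and clamping is reported. Dose
reduction keeps every $n$-th projection at unchanged per-projection
exposure, exactly the mechanism of the simulated-dose datasets
(`ceiling(N/n)` projections for a $1/n$ dose); an exposure-scaling mode is
deliberately not the default.

The experiment drivers acquire with a detector wide enough to cover the
square reconstruction window at every angle (the bath is continued beyond
the window before projection, as it would be at a beamline, and the
reconstruction is cropped back). Without this, oblique views truncate the
square field of view and the reconstruction grows a bright rim — up to
+30% of the water gray level near the edges — which contaminates any
reference region placed in the bath. `projectVolume`/`fbp` themselves
stay window-sized, so users simulating truncation can still do so
deliberately.

FBP uses the band-limited Ram-Lak kernel realized in real space (the
$h[0]=1/4$, odd-tap $-1/(\pi n)^2$ form) and applied by FFT, then linear
detector interpolation and $\pi/N_\theta$ scaling; a Shepp-Logan window is
available by option. The reconstruction circle is not masked, since the
phantom's water bath fills the field of view. Gray values stay in linear
attenuation units (1/mm) end to end; a noiseless disk round-trips with
under 1% RMS error, which the test suite asserts at a 5% bound.

Two conventional baselines ship for comparison: a sliding-window median
filter and Paganin single-distance phase retrieval (low-pass kernel
$1/(1 + \lambda z \delta / (4\pi\beta) |k|^2)$ with the hydroxyapatite
$\delta = 1.1378\times10^{-6}$, $\beta = 4.8945\times10^{-9}$ at 24 keV).
No propagation distance is documented for the original retrieval, so
`distanceMm` is a required user parameter.

## The phantom

`defaultBoneSpec()` encodes the study conditions at desk scale: 1.6 µm
voxels; a centred rectangular bone prism with a 1:2 cross-section
(mimicking the machined 1 mm × 2 mm sample) in a water bath; one alumina
reference cylinder in the bath; ellipsoidal lacunae with log-normal true
volumes (mode 393 µm³, truncated to 100–1600 µm³), aspect ratios
(shortest/longest axis) normal around 0.46, and uniformly random
orientation, placed without overlap by rejection sampling. The matrix
attenuation is chosen so that the default calibration maps it to
1226 mgHA/cm³, the typical bovine value. The lacuna number density is not
reported for the original samples; the default count (60 in the
64×192×192 grid) gives ~1% lacunar porosity, typical of cortical bone.
Thin grids accept only orientations whose axial extent fits, so very thin
test volumes carry a mild in-plane orientation bias; the default grid does
not.

What the phantom does *not* model: Haversian canals, canaliculi,
microcracks, the machined notch, beam hardening, scatter, detector
point-spread and ring artefacts. Passing tests therefore demonstrate the
pipeline's internal correctness and the direction of dose-driven feature
distortion, not beamline-specific artefact behaviour.

The per-projection photon budget of the real scans is not published. The
default $I_0 = 10^5$ expected photons per bin is a synthetic operating
point chosen once so that the one-sixth-dose FBP of the default phantom is
visibly non-segmentable (the Yen threshold finds no lacunae) while the
denoised volumes segment cleanly — the qualitative regime of the study
this package emulates.

## Quantification

Lacunae are segmented by automatic histogram thresholding (Yen by default,
Otsu available), computed by exhaustive scan over a 256-bin histogram of
the image range, mirroring the common ImageJ implementations. Connected
components use 26-connectivity in 3D; volumes are voxel counts times
voxel volume (4.096 µm³ at 1.6 µm) and the conventional inclusive
50–2000 µm³ filter is applied in physical units. The aspect ratio is
$\sqrt{\lambda_{\min}/\lambda_{\max}}$ of the voxel-coordinate covariance
eigenvalues — the shortest-to-longest principal *axis* ratio, which gives
0.5 for a 2:1 ellipsoid and matches the rod-vs-sphere language of the
field; the raw eigenvalue ratio is available by flag. The population
covariance of voxel centres is used without a grouping correction: on
digital ellipsoids at the relevant sizes it is essentially unbiased
(adding the $h^2/12$ correction biases ratios toward 1 by ~0.02).

Summary statistics are distribution *modes*, reported to µm³ precision in
the field — finer than any reasonable histogram bin — so the mode is taken
from a Gaussian KDE (Silverman bandwidth by default) on a fixed grid; this
is an interpretation, since the original binning is not documented.

Mineralization calibration converts each reference region's mean gray to
an apparent density through the material's mass attenuation coefficient,
fits known vs apparent density linearly (exact through two points), and
maps bone gray values through the hydroxyapatite coefficient to mgHA/cm³.
Packaged (µ/ρ) values at 24 keV (water 0.573, alumina 1.374,
hydroxyapatite 2.195, cortical bone 2.438 cm²/g) are log-log
interpolations of the NIST tables and are user-overridable; the alumina
density (3.95 g/cm³) is the handbook value, as none is documented in the
original protocol.

The paired experiment always runs Shapiro–Wilk (on paired differences) and
Levene (across groups) as *reported diagnostics* and then the paired
t-test; whether the original analysis gated the t-test on those
diagnostics is not documented, so they do not gate here. Zero-variance
differences yield a flagged degenerate result rather than an error.

## Dose budgeting

The absorbed dose model is the standard energy-fluence estimate
$D = N_\gamma E_\gamma (1 - e^{-\mu t}) / m$ with every factor exposed in
`BeamlineParams` (the original study's exact equations live in an
unavailable supplement). The packaged `paperGeometryPreset()` (24 keV,
100 ms, 3937 projections, 3.28 mm², cortical-bone absorber over a 1 mm
path) calibrates the effective flux density so one full scan deposits
exactly 8.0 kGy — the documented full-dose operating point — and the
calibrated flux (~2.7×10⁴ photons s⁻¹ µm⁻²) falls inside the plausible
25300–137000 range for such beamlines, a consistency check rather than an
input. Scan budgets are computed from *unrounded* fractional doses
(35/(8/3) = 13.125 → 13 scans; the rounded 2.7 kGy would give 12), which
reproduces the whole published budget row; doses are rounded to one
decimal for display only.

```{r dose-table}
doseTable()
```

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problem sizes chosen as the
package's own defaults for CPU execution: quantification phantoms of
64×192×192 voxels; training runs on a 24×128×128 phantom with 35 lacunae
and 400 projections (quantification sweep) and a 16×64×64 phantom with
240 projections (efficacy check), both with a depth-20 network and 30
epochs. At these sizes one training run takes one to two minutes on one
CPU. Mode estimates from a few dozen lacunae are still noisy, which is
why the dose-sweep acceptance asserts the *direction* of the recovered
volume shift, never its magnitude.

Other numerical choices: angles are half-open $[0,\pi)$, 0-based split
indexing, the extra angle of an odd split goes to split 0; FFT padding to
the next power of two ≥ 2× detector width; thresholds return bin
boundaries of a 256-bin histogram; PSNR records its data-range convention
in every report because published PSNR values are not interpretable
without one; TIFF output rescales to the [0,1] sample domain of the TIFF
backend and stores the original range in a JSON sidecar that the reader
undoes.

## Limitations

* The forward model is 2D slice-wise parallel-beam; no cone/fan geometry,
  no centre-of-rotation error.
* Training at the published scale (depth 100, thousands of 1024² slices)
  is out of scope; conclusions at desk scale are qualitative twins, not
  quantitative reproductions, of real-beamline results.
* Real-data image-quality values (e.g. published MSE/PSNR/SSIM tables)
  depend on undeposited beamline data and are not reproduction targets;
  only their percent-change arithmetic is.
* The dose model omits scintillator/detector efficiency and depth-dose
  structure; it is a budgeting tool, not dosimetry.
* At one-sixth dose with K = 2, each sub-reconstruction is built from
  ~33 angles and is dominated by angular-undersampling streaks. Streaks
  are deterministic given the angle set — *structured artefact, not
  independent noise* — so the Noise2Inverse premise is only partially
  satisfied there, and the calibrated mineralization mode of this
  emulation shifts *up* at one-sixth dose (full-dose values land at
  ~1200 mgHA/cm³, matching the expected bovine operating point, while
  one-sixth-dose values read ~6–8% high, consistently across noise
  realizations). Real-beamline studies report the opposite sign for
  mineralization, driven by attenuation noise in large samples; the
  recovered *lacunar volume* mode does shift down here, as it does on
  real data. The acceptance suite asserts the volume direction and keeps
  the mineralization direction as a deliberately failing check so the
  discrepancy stays visible.
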