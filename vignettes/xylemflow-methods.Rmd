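---
title: "Methods: quantifying stem water flow from tracer, label and MRI images"
author: "xylemflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stem water flow from tracer, label and MRI images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemflow)
```

# The problem

Water moves from root to leaf through the xylem: dead, lignified conduits a
few to a few tens of micrometres wide. Three imaging modalities see this
transport at complementary scales, and this package implements the
quantitative analysis behind each of them plus the dimensional bridge that
ties them together:

1. **micro-PIV** on a microfluidic Y-junction ("two vessels merge into
   one"), which resolves velocity fields at micron resolution from pairs of
   tracer-particle images;
2. **label-image morphometry** of stem cross sections, which turns an
   expert segmentation of vessel lumina into areas, perimeters, hydraulic
   diameters, ellipse fits and ring positions;
3. **contrast-enhanced MRI** of the stem, where a gadolinium chelate fed to
   the roots accumulates in nodal plexuses but washes through internodes,
   and the slice-by-slice signal build-up maps which stem regions filter
   the flow.

The bridge is Reynolds similarity. With mean xylem velocity
$U_0 = Q/S$ (volumetric flow over total conducting cross-section) and the
hydraulic diameter $D_h = 4S/P$ as the characteristic conduit size, the
Reynolds number $Re = U_0 D_h/\nu$ of a vessel can be matched by a
microchannel operated at the corresponding mean velocity — which is what
`matchChipOperatingPoint()` computes. With the defaults shipped here
($U_0 = 221.5\ \mu m\,s^{-1}$, $\nu = 8.74\times10^{-7}\ m^2 s^{-1}$,
lumen $D_h$ from 3.8 to 46 µm), vessel Reynolds numbers span roughly 0.001
to 0.012: overwhelmingly viscous, fully laminar flow.

Because no public dataset accompanies this problem, every stage has a
seeded synthetic generator with exact ground truth; the test suite and the
acceptance script run the full pipeline against those generators.

# The PIV engine

## Model

A velocity vector is estimated per interrogation window by zero-normalized
cross-correlation (ZNCC) between the window in frame A and the
corresponding window in frame B. Windows are mean-subtracted and scaled to
unit norm, which makes the estimator insensitive to uniform illumination
differences; the correlation plane is evaluated over integer lags within
the half-window search range by zero-padded FFT (a linear, not circular,
correlation).

The integer peak is refined per axis with the **three-point log-Gaussian
estimator**

$$\delta = \frac{\ln R_{-1} - \ln R_{+1}}
           {2\ln R_{-1} + 2\ln R_{+1} - 4\ln R_{0}},$$

which is exact when the sampled peak is Gaussian — the natural model when
particle images are themselves near-Gaussian blobs. Correlation values are
floor-shifted to $10^{-6}$ before taking logs; if a triple still contains
non-positive values the axis falls back to a three-point parabola and the
vector is flagged. The residual estimator bias over fractional shifts
("pixel locking") is measured by the suite and stays an order of magnitude
below the 0.1 px accuracy target.

## Multipass refinement and window deformation

`pivConfig()` defaults to three passes, 128×32 → 64×16 → 32×8 px windows
(w×h) at 50 % overlap. The elongated windows lie with their long axis along
the flow, trading streamwise resolution for dynamic range — appropriate for
quasi-unidirectional channel flow. Only the two endpoint window sizes are
externally meaningful; the intermediate pass is geometric interpolation.

After each pass the field is validated (below), invalid vectors replaced by
neighborhood medians, the grid lightly smoothed (3×3 box), densified to
pixel resolution by bilinear interpolation, and frame B is warped backward
through the dense predictor with bicubic (Catmull-Rom) resampling. The next
pass then measures only the residual displacement, so the final 32×8
windows operate in the sub-pixel regime even when the true shift is several
pixels. Total displacement at a node is the window-mean of the predictor
plus the residual correlation lag.

## Vector validation

Two stages, applied in order; the pair is idempotent (applying it twice
changes nothing), which the suite asserts:

* **SNR test** — primary/secondary correlation peak ratio, secondary
  searched outside a 3×3 exclusion zone around the primary; threshold 2.
  Independent-noise windows fail this test in ≈100 % of Monte-Carlo trials.
* **Normalized median test** (the field-standard reading of "adaptive
  median filtering") over a 7×7 node region: residual against the
  valid-neighbor median, normalized by the median neighbor residual plus a
  0.1 px stabilizer, threshold 2. Flagged vectors are replaced by the
  neighbor median and remain marked invalid/replaced.

Instantaneous fields are combined by `ensembleAverage()`: per-node mean
over valid vectors, with a 50 % validity quorum. The RMS error of the
ensemble mean shrinks as $1/\sqrt{N}$, which the suite verifies at
$N = 10, 40, 160$ constructed noisy fields; production micro-PIV uses
thousands of image pairs per regime, while the in-package suites use
ensembles of 5–200 pairs, the size at which the measured errors are already
two orders below the acceptance bounds.

## What the particle generator emulates — and what it does not

`makeParticleImagePair()` renders tracers as pixel-integrated Gaussians
(erf differences), default $e^{-2}$ diameter 3 px — a 2 µm fluorescent
tracer imaged at ~1 µm/px is diffraction-broadened to about that size —
with density 0.02 particles/px² (5–10 per final window), peak intensity
200/255, additive Gaussian noise of 2 counts, and 8-bit quantization.
Frame-B positions are frame-A positions displaced by the truth field
evaluated at the particle (first-order in the displacement), and particles
are seeded on a domain padded by the maximum displacement so density stays
stationary while tracers leave and enter the frame.

Not modeled: Brownian motion, out-of-plane loss of correlation (the depth
dimension of real micro-PIV), optical aberrations, and non-uniform
illumination. Passing tests therefore demonstrate algorithmic correctness
and precision of the estimator chain on ideal-optics images, not robustness
to every experimental pathology.

The Y-junction truth field (`yMergeField()`) is an **analytic blend, not a
Navier–Stokes solution**: two half-channel parabolas carrying flux shares
$1/(1+R)$ and $R/(1+R)$ relax exponentially (development length 800 px by
default, the relaxation scale reported for such junctions) into the single
duct parabola, with the transverse component derived from continuity so the
field is exactly divergence-free and station flux is conserved to rounding.
It reproduces the qualitative signatures — symmetry at $R=1$, near-inlet
peak shifted toward the higher-flux wall at $R=0.25$, downstream
re-symmetrization — but deliberately not the 3-D developing-flow velocity
maxima of $2.5\!-\!3\,U/U_0$ seen experimentally in merging junctions;
those require CFD or measurement and are excluded by design. The suite
holds the generator to the conservation/symmetry properties instead.

# Vessel morphometry

`measureLabels()` consumes an integer label raster (0.692 µm/px by default,
the optical-section pixel size of the source microscopy). Per label:

* **Area** — pixel count × pixel size². Lumen holes are filled first
  (`EBImage::fillHull`): the lumen is the hydraulic cross-section.
* **Perimeter** — Crofton 4-direction estimator,
  $P = \tfrac{\pi}{4}(R_0 + R_{90} + (R_{45}+R_{135})/\sqrt2)$ with $R_\theta$
  the number of intercept runs along direction $\theta$. This choice is
  pinned deliberately: naive boundary-pixel counting overestimates disk
  perimeters by up to ~27 %, which would bias $D_h = 4S/P$ low by the same
  factor and propagate straight into every Reynolds number.
* **Ellipse** — moment-based fit (semi-axes $2\sqrt{\lambda_i}$ of the
  second central moment matrix, with the 1/12 per-pixel correction), since
  vessel lumina are close to elliptical.
* **Ring assignment** — vessel centroids are recast into polar coordinates
  about the stem center. The "nominal center" is not defined by any
  measurement convention, so the package uses the centroid of vessel
  centroids with an explicit override. Ring edges are explicit radii when
  known; otherwise radius quartiles (with ties collapsing to ring I —
  documented, deterministic).

Every region is checked against the isoperimetric bound
$D_h \le 2\sqrt{S/\pi}\,(1+\varepsilon)$ with raster tolerance
$\varepsilon = 0.05$: a circle maximizes $D_h$ at fixed area, so violations
would flag a broken perimeter estimator.

On the built-in four-ring phantom (ellipses at radii 100/200/300/400 px),
areas are recovered within 3 %, semi-axes within 2 %, and ring assignment
exactly — the raster-discretization floor of these estimators at vessel
sizes of 8–28 px.

# MRI flow signal

For each slice $i$ and timepoint $t$ the normalized flow signal is

$$F_{it} = \frac{S(\mathrm{stem}_{it}) - S(\mathrm{stem}_{i0})}
                {S(\mathrm{air}_{it})},$$

with $S(\cdot)$ the mean pixel intensity under the region mask. Two
readings were possible and are fixed as: the **baseline is the first
timepoint** (not a pre-contrast average), and the **air mean of the same
timepoint** divides (no temporal smoothing) — both exactly as the defining
formula is written. The first column of the matrix is therefore identically
zero, and adding a constant offset to all frames of a slice changes the
signal only through the air normalization. Masks are fixed per slice across
time (the alternative, re-drawn masks per image, is not supported; nothing
in the source conventions requires it and fixed masks are the reproducible
choice).

Slices are classified node vs internode by the least-squares slope of
$F_{i\cdot}$ against acquisition time; the default threshold is half the
median slope of the phantom's node class, derivable whenever annotated
truth exists (`defaultSlopeThreshold()`), while real data require an
explicit threshold. The default phantom (18 slices × 19 timepoints, 23 min
steps; saturating-exponential accumulation
$S_0 + A(1-e^{-t/\tau})$ with $A = 50$, $\tau = 100$ min on a baseline of
100, noise sd 2 — the simplest monotone saturating form consistent with
contrast accumulation) is classified with 100 % accuracy noiseless and
≥ 95 % over 200 seeded noisy replicates. The phantom does not model MR
physics (T1/T2 relaxation, partial volume, coil shading); it emulates the
*statistical* structure the normalization must handle.

# Hydraulic scaling and the duct oracle

All hydraulics are computed in SI internally, with µm and mL/h converters
at the boundary — the quantities mix µm/s, mL/h and m²/s and Reynolds
targets at $10^{-3}$ are unforgiving of silent unit slips, so suspicious
magnitudes (velocities above 10 m/s, diameters above 0.1 m) raise warnings.

The PIV oracle is the classical Fourier-series solution for fully developed
laminar flow in a rectangular duct,

$$u(y,z) \propto \sum_{n\ \mathrm{odd}} \frac{(-1)^{(n-1)/2}}{n^3}
  \left[1 - \frac{\cosh(n\pi z/2a)}{\cosh(n\pi b/2a)}\right]
  \cos\!\frac{n\pi y}{2a},$$

evaluated with the cosh ratio in exponential form (stable at any aspect
ratio), truncated at 101 odd terms by default with a tail-bound convergence
check, and normalized so the quadrature mean equals $U_0$. Its
centerline-maximum to mean ratio is 2.0963 for a square duct, 1.5 in the
parallel-plate limit, and **1.9919 for the 1:2 duct** of the 120×240 µm
chip outlet — the analytic content of the observation that ultra-slow duct
flows peak "close to $2U_0$".

One further numerical note: the chip-scale correspondence quoted for such
junctions (e.g. $Re = 3$ at 0.1 mm/s) is not consistent with
$Re = U D_h/\nu$ at $D_h = 160\ \mu m$, which gives $Re \approx 0.018$ at
that speed; the characteristic length behind such chip figures is
unstated. The package therefore uses the hydraulic diameter uniformly for
vessels and chip alike, and surfaces the discrepancy as something to warn
about, never to assert.

# Problem sizes and determinism

All generators are bit-reproducible under `(seed, params)`; a single global
seed fans out to per-stage seeds through `deriveSeed()` (a 32-bit-safe
hash of seed and stage tag). The suites run PIV ensembles of 5–50 pairs
per condition on 192×64 px frames, 12-pair Poiseuille ensembles, one
four-ring phantom per property, and 20–200 MRI replicates; these sizes
put Monte-Carlo noise well below every asserted tolerance while keeping the
full suite in the low minutes. The acceptance script uses 50 pairs per
sub-pixel displacement and 100 pairs at the 2 px and 8 px operating points.

# Known limitations

* The PIV engine is strictly 2-D, single-camera, double-frame; no
  out-of-plane correlation loss, Hart correction, or ensemble-correlation
  variants.
* The merge-field model conserves flux and symmetry but not developing-flow
  inertia; do not read its near-inlet magnitudes as physics.
* Morphometry consumes label images; segmentation of raw fluorescence
  stacks (done by an expert upstream) is out of scope, as is
  metaxylem/protoxylem discrimination.
* The MRI stage assumes fixed per-slice masks and supplied segmentation;
  there is no DICOM reader — series arrive as TIFF stacks.
* The printed total-lumen area convention of the source material (lumen
  vs lumen+wall) is unstated; results here are lumen-only by construction.
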