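---
title: "Models and methods behind fluidmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluidmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidmorph)
```

fluidmorph is the computational layer of a microfluidic
epithelial-morphogenesis workflow: hydrostatic-head-driven interstitial flow
and morphogen transport in a collagen-filled tissue chamber, FRAP-based
velocimetry of that flow, collagen fiber-alignment quantification, and cyst
morphometrics under a morphogen gradient. This vignette explains the models
each stage implements, the assumptions they rest on, the parameters that
matter, and the choices made where the underlying procedures are usually
left unstated.

## The device model: Darcy flow in a homogenized 2-D chamber

The tissue chamber is a shallow rectangular channel (height 100 um, much
smaller than its width) filled with collagen-I hydrogel and flanked by two
fluidic lines connected through a row of micropores. We model the chamber
in 2-D plan view, depth-averaged: at 100 um height with widths of 250 um
and more, vertical variation is secondary, and all quantities of interest
(velocities, gradients, image-plane morphometrics) are plan-view.

Flow in the gel obeys Darcy's law, `v = -(k/mu) grad p`, with collagen
permeability `k = 2e-13 m^2`, porosity 0.99, and water viscosity and
density. At this permeability the Brinkman screening length `sqrt(k mu'/mu)`
is below a micrometre — far below any resolvable grid scale — so the Darcy
limit of the Brinkman equation is the model; no effective-viscosity term is
carried. Pressure obeys `div((k/mu) grad p) = 0` with no-flux chamber end
walls. Driving heads are liquid-column heights in the reservoirs,
converted with `rho g h` at standard gravity `g = 9.80665 m/s^2` exactly
(1 mm H2O = 9.80665 Pa).

The micropore row is not resolved. Each line-chamber interface carries a
single homogenized conductance `G` (m^2 s/kg): interface flux
`= G (p_line - p_chamber)`. `G` is a configuration parameter, and
`calibrate_pore_conductance()` chooses it in closed form so a reference
working point is hit — the shipped demo calibrates to a 20 um/s Darcy speed
at a 20 mm H2O head, the ceiling of the device's physiological working
range; heads of 2-20 mm H2O then span 2-20 um/s exactly, by linearity.
`G = Inf` recovers the open-interface slab, for which the solver agrees
with `v = k dP/(mu L)` to machine precision — the discrete scheme is exact
for 1-D linear pressure fields.

Discretization is finite volume on a uniform grid with staggered face
fluxes, so discrete mass conservation holds cell by cell to linear-solver
roundoff (the `flow_divergence()` diagnostic). The default grid spacing
resolves the chamber width with at least 10 cells (25 um on the 250 um
aligned preset). The "random" control device is only specified as 1:1
length-to-width; the preset uses a 1 mm square with the side length
exposed as a parameter, never hard-coded.

## Morphogen transport

The morphogen proxy (70 kDa dextran, `D = 7e-11 m^2/s`) obeys
depth-averaged advection-diffusion in the gel:
`phi dc/dt + v . grad c = phi D lap c`, i.e. transport at the seepage
velocity `v/phi`. Normalized concentrations are held at 1 on the dosed
line and 0 on the plain line (the lines act as reservoirs), with no-flux
end walls. Time stepping splits explicit first-order upwind advection from
implicit (backward Euler) diffusion; the step is auto-capped at 0.4x the
explicit advective CFL bound and a user step above the bound is refused
with the bound printed. Both half-steps respect the maximum principle, so
concentrations never leave the interval spanned by the boundary values.

The solver is verified against the closed-form eigenfunction series for
transient diffusion across a slab (`diffusion_series_profile()`), to
better than 1% relative L2 over three diffusive time scales at the
aligned-chamber geometry; the same series is the oracle for the
gradient-formation time.

"Gradient formed" has no standard quantitative criterion, so it is
operationalized: the cross-chamber profile (averaged along the length) is
formed at the first output time at which it is everywhere within a
tolerance — default 10% of the boundary concentration difference — of the
steady profile, and maintained through 24 h if it stays within tolerance
from formation to that horizon. The tolerance is a parameter of
`gradient_metrics()`, not a constant. With the fluidic lines held at fixed
concentration immediately adjacent to the chamber, formation across 250 um
takes minutes (`L^2/D ~ 15 min`); longer times in a physical device
reflect transport through the feed lines and reservoirs, which this
homogenized model deliberately excludes. Steady profiles under flow use
the 1-D advective-diffusive exponential with the mean cross-velocity.

## FRAP velocimetry

A 30 um circular spot is photobleached in the dextran-flooded chamber and
imaged every 0.5 s for 15 s; under flow the dark spot drifts with the
fluid while recovering by diffusion. Each frame is inverted, lightly
Gaussian-smoothed (default sigma of one fifteenth of the spot diameter)
against shot noise, cropped to a window around the darkest point,
thresholded with Otsu's method inside the crop, despeckled with a 3x3
median filter, and reduced to its largest connected component. Cropping
first matters: Otsu assumes the two classes occupy comparable histogram
mass, which fails on a full frame once recovery has shrunk the spot's
contrast. A component smaller than a quarter or larger than four times the
nominal spot area flags the frame invalid rather than failing the run.

The spot position is the intensity-deficit-weighted centroid of the mask
(binary centroid available as an option), and the velocity estimate is the
least-squares slope of x(t) and y(t) over all valid frames — regression
over the track rather than a first-to-last displacement, because frame
segmentation errors then average out; the pooled R^2 of the two fits is
the quality score. Internally images are row-down; all reported positions
and directions use mathematical convention (y up, degrees
counter-clockwise from +x), converted at the reporting boundary only. On
synthetic sequences with shot noise and diffusive recovery, median speed
error is well under 10% across the 2-20 um/s working range and recovered
directions are within a few degrees; pure recovery with zero flow yields
velocity components statistically indistinguishable from zero.

## Fiber orientation and the alignment coefficient

Local fiber orientation comes from the image structure tensor: Gaussian
pre-smoothing (sigma 1.5 px), central-difference gradients, tensor
smoothing at the fiber scale (sigma 4 px). At fiber pixels the gradient is
perpendicular to the fiber, so the fiber angle is the minor-eigenvector
direction. Pixels with gradient energy above the image mean contribute one
angle weighted by the tensor coherence `(l1-l2)/(l1+l2)`; a featureless
image yields an empty, flagged sample. A curvelet-based tool is the field's
usual instrument for this; at the level of angle histograms and a scalar
alignment coefficient, structure-tensor orientation measures the same
quantity without the exotic dependency.

The alignment coefficient is the resultant length of the doubled angles,

`coefficient = | sum_j w_j exp(2 i theta_j) | / sum_j w_j`,

the standard axial-concentration statistic: 1 iff all weighted angles are
equal mod 180 degrees, 0 for a balanced distribution, invariant to adding
180 degrees and equivariant under rotation. The mean orientation is half
the resultant's argument. For angles drawn from a doubled-angle von Mises
distribution with concentration kappa the population value is the Bessel
ratio `I1(kappa)/I0(kappa)`, which the implementation reproduces by Monte
Carlo within 0.01 at n = 1e5 and increases strictly with kappa.

Histograms use half-open 10-degree bins over [0, 180), with exactly 180
wrapping to 0; directional fractions (e.g. the 70-110 degree band used to
quantify cross-chamber alignment) are weighted fractions of the same
sample.

## Cyst morphometrics

Binary z-projection masks are reduced to their largest hole-filled
component; the boundary is traced and converted to micrometres in
mathematical coordinates. Metric definitions, stated because the names
alone are ambiguous:

* best-fit ellipse from second central mask moments (semi-axes
  `2 sqrt(eigenvalues)`, exact for a true ellipse);
* `aspect_ratio` = major/minor; `orientation_angle` = major-axis angle in
  [0, 180);
* `roundness` = `4 A / (pi major^2)` — the inverse aspect ratio for an
  ellipse;
* `shape_factor` = circularity `4 pi A / P^2`, 1 for a circle, decreasing
  with boundary complexity (a spreading, ruffled cluster);
* perimeter from a smoothed resampling of the boundary, since a raw pixel
  chain overestimates the length of smooth curves.

Protrusion detection automates the interactive click-the-tip procedure
while preserving it: user-supplied tip coordinates pass through verbatim.
The automatic path builds the radial profile r(phi) around the centroid
(the outer envelope per angular bin when the contour is not star-shaped —
flagged), fits a robust low-order Fourier baseline (harmonics 0-2, an
off-centre ellipse, iteratively trimmed so bumps cannot inflate their own
baseline), and takes peaks of the
residual — smoothed at a 4-degree scale, the low-pass that separates
protrusion-width features from finer ruffle texture — with prominence
above a threshold (default 5 um) and minimum angular separation (20
degrees, about twice the default bump width).
Protrusion angles are measured from the centroid against the horizontal
axis and folded into [0, 180], matching the 0-180 histogram convention; a
tip exactly on the centroid's horizontal line counts as "top" by a
deterministic tie rule.

Contour curvature uses Gaussian kernel smoothing of x(s), y(s) at uniform
arc length (periodic for closed contours, edge-reflected for open halves)
followed by central differences and the plane-curve formula
`kappa = (x'y'' - y'x'') / (x'^2+y'^2)^(3/2)`. Kernel smoothing was chosen
over a fitted spline because it is deterministic, exactly periodic on
closed contours, and attenuates a circle's radius by a known closed-form
factor — under 0.2% at the default scale — keeping the 1/r sanity check
honest. The default smoothing scale is 4 um with the sample spacing tied
to a quarter of that scale, which keeps rectified pixel-staircase noise
uniform across object sizes: a 50 um circle returns `kappa = 0.02 /um`
within 3%, and scaling a shape by 2 scales mean curvature by 0.5 within
2%. "Overall curvature" of a half is the unweighted mean of |kappa| over
its uniform arc-length samples (runs shorter than 7 points are dropped);
the curvature ratio is the top-half mean over the bottom-half mean, with
the top half defined as the side facing the dosed line. The split line is
the horizontal through the centroid, with crossing points interpolated
exactly onto it; ruffled boundaries may produce several runs per half and
all are used. A degenerate bottom half (mean |kappa| ~ 0) reports the
ratio as undefined rather than infinite.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of (seed, parameters) — bit-identical
on repeat, never touching the caller's RNG stream — and returns its ground
truth beside the data.

* **Fiber images**: anti-aliased line segments with orientations from the
  doubled-angle von Mises model (sampled with the Best-Fisher rejection
  algorithm, written in-package), lengths 30-80 px, on a uniform
  background. The default 700 segments on a 384 px field emulate the
  density of a 2 mg/mL collagen gel at confocal-reflectance resolution;
  sparser fields raise the finite-sample floor of the alignment
  coefficient.
* **FRAP sequences**: a Gaussian bleach profile on a uniform fluorophore
  field has a closed-form evolution under 2-D diffusion (variance
  `sigma0^2 + 2 D t`, depth shrinking by the same factor) and is advected
  at the true velocity; 31 frames at 0.5 s, 30 um spot, 2 um pixels on a
  192 x 448 um field so a 20 um/s track stays in frame.
* **Cyst masks**: a polar boundary — ellipse radius plus Gaussian bumps at
  specified protrusion angles plus band-limited random ruffles (harmonics
  8-16) whose RMS amplitude differs smoothly between the top and bottom
  half — rasterized to a binary mask. Ruffling is thus a controllable,
  measurable quantity.
* **Gradient scenes**: solver concentration fields rendered to noisy
  intensity frames for profile-extraction tests, with the solver itself as
  oracle.

The shared noise model is Poisson shot noise (a photon budget per unit
intensity) plus additive Gaussian read noise. What the generators do *not*
emulate: optical point-spread functions, depth attenuation, fiber
crossings in 3-D, cell texture inside the cyst mask, photobleaching of the
background during FRAP, or drift of the imaging stage. Passing the
recovery tests therefore shows the analysis chain is correct at realistic
noise levels and geometries — not that it is robust to every artifact of
real microscopy.

## Problem sizes and numerical defaults

The verification studies use: a 50-cell cross-chamber grid and 2 s
implicit steps for the series-oracle comparison; 200 seeded FRAP sequences
per speed in {2, 5, 10, 20} um/s for the recovery study (the acceptance
script reports the same quantities from 40 per speed); 200 seeded cysts
with 1-4 planted protrusions for detection scoring, plus 100 top-ruffled
and 50 symmetric-ruffled populations for the curvature-ratio contrast.
These sizes give stable medians and population means for the properties
asserted while keeping a full run comfortably on a laptop.

Degenerate inputs are contracts, not crashes: constant frames, featureless
fiber images, all-dark projections, contours entirely on one side of the
split line, sub-minimum track lengths, and zero-gradient boundary
conditions each produce a flagged result or a specific refusal message,
exercised in the test suite.

## Known limitations

The 2-D homogenized device model does not capture micropore-scale flow
structure or feed-line transport dynamics, so absolute gradient-formation
times are faster than in a physical device with long feed lines. The
structure-tensor estimator reports per-pixel orientation, not per-fiber
tracing; its coefficient has a finite-sample floor on sparse images. The
curvature pipeline measures |kappa| — it does not distinguish convex
protrusions from concave invaginations unless the signed option is used.
Group-comparison statistics beyond mean ± SEM are intentionally left to
standard tools on the exported tables.
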