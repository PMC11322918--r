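# fluidmorph

Computational toolkit for microfluidic epithelial-morphogenesis
experiments: interstitial flow and morphogen gradients in collagen-filled
tissue chambers, FRAP velocimetry, collagen fiber-alignment
quantification, and cyst/organoid morphometrics.

## Who this is for

Labs running (or modeling) microphysiological devices in which a hydrogel
tissue chamber sits between two fluidic lines: hydrostatic head
differences drive slow interstitial flow through the gel, a dosed line
sets up a morphogen gradient across the chamber, and the readouts are
collagen fiber orientation, interstitial fluid velocity, and the shape,
protrusions, and boundary ruffling of epithelial cysts cultured inside.
The package reproduces that entire computational chain on plain matrices
and tibbles, with seeded synthetic-data generators so every stage is
verifiable without raw images.

## The models at the core

* **Device transport** — Darcy flow `v = -(k/mu) grad p` in a homogenized
  2-D chamber (collagen permeability `k = 2e-13 m^2`, porosity 0.99),
  driven by reservoir heads (`p = rho g h`, 1 mm H2O = 9.80665 Pa), the
  micropore row homogenized into an interface conductance; morphogen
  transport `phi dc/dt + v.grad c = phi D lap c` with `D = 7e-11 m^2/s`
  (70 kDa dextran), finite-volume with implicit diffusion and upwind
  advection. Verified against `v = k dP/(mu L)` and the eigenfunction
  series for transient slab diffusion.
* **FRAP velocimetry** — a bleached 30 um spot is segmented per frame
  (invert, smooth, crop, Otsu, despeckle, largest component) and the
  convective velocity is the regression slope of its intensity-weighted
  centroid against time.
* **Fiber alignment** — structure-tensor orientation with coherence
  weights; the alignment coefficient is the resultant length of doubled
  angles `|sum w exp(2 i theta)| / sum w` in [0, 1], with 10-degree
  histograms and directional fractions.
* **Cyst morphometrics** — ellipse-fit aspect ratio, roundness
  `4A/(pi major^2)`, shape factor `4 pi A/P^2`, protrusion angles from the
  centroid folded to [0, 180], and the top/bottom contour-curvature ratio
  (`mean |kappa|` of the gradient-facing half over the opposite half).

See `vignettes/fluidmorph-methods.Rmd` for assumptions, parameter
defaults, and numerical choices.

## Worked example

```r
library(fluidmorph)

run <- run_pipeline(demo_config(seed = 1))
demo_summary(run)
```

```
   metric                          value
 1 transport.v_max_um_s.head2      2.00
 2 transport.re_max.head2          0.0005
 5 transport.v_max_um_s.head20    20.0
 6 transport.re_max.head20         0.005
 7 transport.formation_time_s   1800
 8 fibers.coefficient.aligned      0.968
 9 fibers.coefficient.random       0.0496
10 frap.speed_um_s.true2           1.99
11 frap.speed_um_s.true10          9.97
12 cysts.curvature_ratio.control   0.964
15 cysts.curvature_ratio.gradient  2.96
```

Reading it: with the pore conductance calibrated to the device's
physiological ceiling (20 um/s at 20 mm H2O), heads of 2-20 mm H2O produce
2-20 um/s by linearity, all at Reynolds numbers around 1e-3 — firmly
laminar. The pure-diffusion gradient is formed by the first 30-minute
snapshot and maintained through 24 h. Synthetic aligned-device fiber
images give an alignment coefficient of 0.97 versus 0.05 for the random
control; FRAP recovers 2 and 10 um/s ground truth within a few percent;
and cyst populations ruffled only on the gradient-facing side show a
curvature ratio of ~3 versus ~1 for symmetric controls.

Individual stages compose with the pipe:

```r
g <- gen_frap_sequence(seed = 42, velocity = c(10, 0))
g$sequence |> track_centroid() |> estimate_velocity() |> tidy()
#>   speed direction    vx    vy fit_r2 n_frames_used
#> 1  9.95     0.914  9.95 0.159  0.999            18
```

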