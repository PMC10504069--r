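---
title: "Models and methods behind endoshear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind endoshear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoshear)
```

endoshear couples two things that are usually kept apart: a physical model
of the laminar flow a 96-well fluidic plate applies to endothelial
monolayers, and the image-based statistics used to read out how the cells
respond (orientation, front–rear polarity, nuclear marker intensity,
relative mRNA expression). This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## 1. The duct-flow model

Each flow channel is treated as a single rectangular duct, 6.0 mm wide
(w), 0.5 mm high (h) and 125.77 mm long (L), carrying fully developed,
steady, incompressible laminar flow. Entrance effects and the short
inlet/outlet narrowings are deliberately outside the model: at the
operating Reynolds number (~96) the entrance length is a few millimetres,
small against L, and the quantity of interest — the shear stress over the
cell-covered bottom wall — is set by the developed profile.

Three layers of fidelity are provided:

* **Plate formula.** For w/h = 12 the flow is locally plane-Poiseuille and
  the bottom-wall shear is `tau = 6 mu Q / (w h^2)`. This is the standard
  design equation of parallel-plate flow chambers and the package's
  headline conversion: 14 mL/min ↔ 0.70 Pa = 7 dyn/cm² at the default
  viscosity.
* **Fourier series.** The exact solution of `laplacian(u) = -G/mu` with
  no-slip on all four walls, as a sine series across the channel height
  with cosh corrections toward the side walls. Flow rate follows as
  `Q = (G w h^3 / 12 mu) F(w/h)`; F(12) ≈ 0.947, i.e. the side walls cost
  about 5% of the plate-formula flow, equivalently raise the centreline
  shear about 5% above `6 mu Q/(w h^2)` at fixed Q.
* **Finite differences.** A 5-point discretisation of the same Poisson
  problem, solved directly as a sparse system. It shares nothing with the
  series solution beyond the problem statement, so the two act as mutual
  oracles in the test suite.

**Default viscosity (0.75 mPa·s).** The working fluid is culture medium at
37 °C, slightly less viscous than room-temperature water. This default is
also the value under which the plate formula reproduces the device's
printed operating point (14 mL/min at 0.7 Pa) exactly; both viscosity and
density are overridable in `fluid_props()`.

**Numerical choices.** The series uses 51 odd terms by default; against
201 terms the relative change is below 1e-6 at the device geometry (the
series converges like 1/n³). `cosh` ratios are evaluated in log space so
high aspect ratios do not overflow. The FD grid defaults to 241 × 21
(width × height). The FD wall shear uses a one-sided derivative upgraded
to third order with the curvature known exactly at the wall (u = 0 along
the wall forces `u_zz(0) = -G/mu`). Cross-validation between series and FD
is asserted over the central 80% of the cross-section: within the
side-wall boundary layer both solutions tend to zero and the second-order
FD error, measured relative to a vanishing local value, is no longer a
meaningful discrepancy metric. On that region the two routes agree to
0.02% (velocity) and 0.4% (wall shear) at the device aspect ratio.

**Shear evaluation height.** The headline output is the wall value
`mu du/dz` at z = 0. Because flow-chamber characterisations often plot the
shear on a plane slightly above the bottom (e.g. 10 µm, roughly the height
of the cell monolayer), `wall_shear_profile(..., z_eval_m = 10e-6)`
evaluates `mu du/dz` on that plane instead; at 10 µm it is ~3% below the
wall value.

## 2. Circular statistics of orientation and polarity

A cell's long axis is *axial* data: alpha and alpha + 180° are the same
axis, so angles live in [0°, 180°). The analysis doubles all angles,
`theta = 2 alpha`, making the data unimodal on the full circle, and then
uses ordinary circular statistics:

* polarity index `PI = |mean resultant vector|` of the doubled angles,
  `PI = sqrt((mean cos theta)^2 + (mean sin theta)^2)` — 0 for random
  orientation, 1 when all cells share one axis;
* mean direction `alpha_bar = theta_bar / 2`, mapped back to [0°, 180°);
* Rayleigh uniformity test on the doubled angles, `Z = N R²`, with the
  standard finite-N series correction for the p-value.

Front–rear polarity is *vectorial*: the angle of the nucleus→Golgi vector
relative to the flow vector, in (−180°, 180°]. No doubling is applied. Two
summaries are reported side by side: the unsigned resultant length R (a
length in [0, 1], as PI is defined) and the signed flow-polarity index
`FPI = mean(cos theta)`, which is negative when the population points
against the flow vector — the canonical endothelial response. Reporting
both avoids the ambiguity of a "signed PI": |FPI| ≤ R always, and the two
coincide in magnitude only when the distribution is symmetric about the
flow axis.

Orientation of a segmented object is the major principal axis of its pixel
distribution (second central moments, with the 1/12 per-pixel patch
correction): `alpha = 0.5 atan2(2 mu11, mu20 - mu02)`. Angles use the
mathematical convention (counter-clockwise from +x, y up), so image rows
are flipped internally; the flow axis defaults to (−1, 0), flow right to
left, and axial statistics are insensitive to that left/right choice.
Near-circular objects (eccentricity < 0.05) have no meaningful axis and
are excluded from summaries; the threshold is configurable. Degrees at
every interface, radians internally, wrap-around by modular arithmetic.

## 3. The synthetic monolayer generator

No raw images accompany the experiments this package models, so a seeded
generator stands in for the microscope. It emulates, per condition:

* a confluent monolayer of a few hundred elongated cells tiling the frame
  as a seeded **anisotropic Voronoi mosaic**: seed points on a jittered
  lattice (jitter ±35% of the spacing; equal lattice spacing in both axes,
  since unequal spacings would imprint a spurious global orientation on an
  isotropic mosaic); each seed's metric is contracted along its sampled
  orientation axis by the elongation factor and expanded across it by the
  same factor. The area-preserving form was chosen over contraction alone
  because it makes each region's fitted long axis track its own sampled
  angle even under neighbour competition (circular MAE ~2–5° at
  elongations ≥ 2) instead of being dragged toward the neighbourhood
  average; the fitted aspect ratio of rendered cells comes out roughly
  twice the elongation parameter.
* cell orientations drawn so that the *doubled* angles are von Mises with
  concentration kappa_axial — the exact inverse of the doubling transform,
  so the population PI is the Bessel ratio `I1(kappa)/I0(kappa)` in closed
  form;
* nuclei as filled ellipses at region centres, orientation = cell axis +
  wrapped-normal jitter (sd 15°), emulating correlated but distinct
  nuclear alignment; nuclei are clipped to their cell region so junctions
  keep neighbours separate (with shrink-and-recentre retries for narrow or
  truncated cells, and a hard error when cells are genuinely too dense to
  carry distinct nuclei);
* a Golgi blob displaced ~6 µm from the nucleus centroid along a polarity
  angle drawn von Mises about 180° (against flow) with concentration
  kappa_pol, pulled inward if the displacement would leave the cell — the
  truth table stores the *realised* angle recomputed from the stored
  centroids, so truth is self-consistent by construction;
* a nuclear marker channel at a per-cell Normal(condition mean, sd) level,
  emulating condition-dependent transcription-factor intensity;
* Poisson shot noise plus Gaussian read noise, applied last, 16-bit
  output.

Default condition presets mirror a static-versus-flow experiment:
kappa_axial 0 vs 3, kappa_pol 0 vs 2, elongation 1.4 vs 2.5, marker mean
4000 vs 8000 counts. The flow-side concentrations are chosen to give an
unambiguous alignment signal for validating the machinery; they are
stronger than the modest alignment real monolayers reach after 4 h of
0.7 Pa flow, which sits much closer to the static end of the scale.

**What passing tests do and do not show.** The generator produces crisp
junctions, complete staining, no debris, no out-of-focus light, no
mitotic or dying cells, and cells whose shape statistics follow the
programmed distributions exactly. Passing the recovery tests therefore
shows that the *analysis machinery* is unbiased and correctly implemented
— it does not certify the classical segmenter on real, messier microscopy.
For real data the interface accepts externally produced label maps
directly (`region_shapes()`, `nuclear_marker_intensity()`), so a dedicated
segmenter can be dropped in without touching the statistics.

## 4. Segmentation

A classical pipeline stands in for learned segmentation: Otsu threshold +
hole filling + minimum-area filter + distance-transform watershed for
nuclei; seeded propagation on the junction channel for cells (bright
ridges masked out, every remaining pixel assigned to the geodesically
nearest nucleus seed, so regions partition the non-ridge foreground one
region per seed); threshold + connected components + intensity-weighted
centroids for Golgi blobs. Defaults: minimum nucleus area 30 px², minimum
Golgi area 5 px², 8-connectivity, border-touching cells excluded from
orientation and polarity statistics to avoid truncated-shape bias. Cell
labels inherit the nucleus seed ids so per-cell and per-nucleus tables
join directly.

## 5. Organelle pairing

"Assign each Golgi to a nucleus minimising distance over all possible
pairs" is implemented as a globally optimal linear sum assignment
(Hungarian method) on the Euclidean distance matrix, not greedy
nearest-neighbour; the greedy variant is available behind a flag for
comparison, and the test suite proves optimality against brute-force
enumeration on small instances. Matched pairs farther apart than a gate —
1.5× the median nucleus major axis by default — are discarded to prevent
cross-cell mispairing; unmatched objects are reported, never silently
dropped.

## 6. Expression quantification

Nuclear marker intensity is the mean marker value over each
DNA-stain-segmented nucleus, the standard ROI-transfer recipe. Relative
mRNA expression uses the 2^−ΔΔCq method: replicate Cq values are averaged
(mean by default, median optional) before differencing, each gene is
normalised to the reference gene within sample, then to the control
condition. Standard curves fit Cq against log10(dilution); the efficiency
is `10^(-1/slope) - 1`, 100% for perfect doubling chemistry
(slope −3.3219 cycles/decade), and non-negative slopes are flagged invalid
rather than producing a nonsense efficiency. Group comparisons (rank-sum,
Welch t, one-way ANOVA with Tukey correction) are thin wrappers over the
stats package, present only so pipeline reports carry a uniform table.

## 7. Reproducibility and problem sizes

Every stochastic step runs under an explicit seed, and the pipeline is
deterministic end to end: identical configuration + seed gives
byte-identical images, truth tables and reports. Image intensities are
integer counts, so the 16-bit TIFF round trip is exact and analysing
re-read images reproduces the in-memory analysis identically.

The validation suite runs at deliberately moderate problem sizes chosen to
make sampling noise negligible relative to the tolerances: 10⁵ draws for
sampler-vs-Bessel calibration (2-standard-error bands plus the O(1/√n)
null bias), ~500-cell monolayers for pipeline-vs-truth recovery (±0.05 on
PI), 2000 cells for the isotropic null (where E[PI] under uniformity is
~0.02), 200 random instances for assignment optimality, and the 241 × 21
FD grid for the duct cross-check.

## 8. Known limitations

* The duct model is fully developed and steady: no entrance regions, no
  pulsatility, no compliance, Newtonian fluid only.
* The classical segmenter assumes clean junctional staining; it is a
  stand-in whose errors on real data would propagate to all shape
  statistics (the label-map interface is the escape hatch).
* The generator's cells are convex-ish mosaic regions; real endothelial
  shapes (curved, interdigitated junctions) are not emulated, nor are
  imaging artefacts.
* Polarity reporting deliberately exposes both R and FPI instead of a
  single signed "PI"; consumers must pick the quantity that matches their
  convention.
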