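---
title: "Fan-line reconstruction of megavoltage dose planes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fan-line reconstruction of megavoltage dose planes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodose)
```

## The model

A clinical linac beam diverges from an effectively point-like source.
`isodose` reconstructs the relative dose everywhere in a 2-D water-phantom
plane from two 1-D curves measured (or simulated) during commissioning:

* the central-axis percentage depth dose `PDD(d)`, normalised to 100% at
  the depth of maximum dose `d_ref` (the build-up maximum; 3.25 cm for the
  18 MV beam the bundled fixture emulates), and
* one off-axis ratio profile `OAR(x)` at `d_ref`, normalised to 100% on
  the axis.

The reconstruction assumes the dose factorises along fan lines:

$$PD(x, d) = \frac{PDD(d) \cdot OAR\!\big(x_{ref}\big)}{100},
\qquad x_{ref} = x\,\frac{SSD + d_{ref}}{SSD + d}.$$

`x_ref` is where the straight ray from the source through `(x, d)` crosses
the reference depth — similar triangles with the source `SSD` above the
surface. The depth factor is evaluated at the point's *vertical* depth, not
along the slanted ray: the divergence enters only through the lateral
rescaling. This matches how the profile anchors the lateral shape while the
PDD anchors the depth behaviour, and at `d = d_ref` the mapping is the
identity, so the reference row of the reconstructed plane reproduces the
input profile exactly.

Physically, the factorisation captures the inverse-square-plus-attenuation
depth behaviour and the collimator-defined lateral shape. What it cannot
capture is any *depth dependence of the lateral shape*: penumbra blurring
by secondary-electron transport and the growth of the scattered-photon
halo with depth both violate separability. The validation tooling exists
to measure exactly that error.

## Interpolation and edge rules

Both curves are piecewise-linear interpolants ("lineal interpolation"), and
the plane is the product evaluated at every pixel centre — a single
interpolation per factor, so a brute-force per-pixel evaluation of the
formula reproduces the implementation to machine precision, and
`dose_at_point()` is pixel-for-pixel consistent with `reconstruct_plane()`
without needing a grid.

Extrapolation is deliberately asymmetric:

* **PDD**: clamped to its endpoint values. Queries above the first sample
  (half a voxel of build-up) or below the last stay finite and
  non-negative.
* **Profile**: decays linearly to zero over one pixel spacing beyond the
  last sample, then is zero. Clamping here would smear the shoulder value
  across the rest of the phantom; a finite support avoids phantom-edge
  artifacts.

Ties in the PDD maximum resolve to the shallowest depth, which is the
physically meaningful end of the build-up plateau and makes `d_ref`
deterministic. If the profile's stated reference depth and the PDD's
maximum disagree by more than one pixel, the profile's depth wins (it is
the geometric anchor of the fan mapping) and a warning is raised.

All doses are percentages (0–100) throughout; the unit interval appears
only inside the rendering transforms.

## Coordinates and containers

Depth is positive downward with 0 at the phantom surface; lateral 0 is the
beam axis; all positions are pixel/voxel centres. A `dose_plane` is a tidy
tibble (`lateral`, `depth`, `dose`) carrying its `grid_spec`, with
`as.matrix()` recovering the depth × lateral matrix. Planes serialise to a
plain-text format with a three-line header at 17 significant digits, so a
write/read cycle is bit-exact.

## The synthetic beam fixture

No measured beam data ship with the package; `beam_model_params()` defines
an analytic 18 MV-like beam instead:

* `PDD(d) ∝ (1 − e^{−αd}) e^{−μd}` — exponential build-up times
  attenuation. `μ = 0.045 cm⁻¹` gives a realistic 18 MV tail slope, and
  `α` is solved by root-finding so the continuous maximum
  `d* = ln(1 + α/μ)/α` lands exactly at `d_max_target` (3.25 cm). The form
  vanishes at the surface, which overstates the real ~15–20% surface dose
  of an 18 MV beam but keeps the build-up shape qualitatively right.
* `OAR(x) ∝ erf((a−x)/σ) + erf((a+x)/σ)` — a flat top with sigmoid
  penumbra, shoulder `a` at the fan-line projection of the surface field
  edge (5.1625 cm at 3.25 cm depth for a 10 × 10 cm field at 100 cm SSD),
  `σ = 0.3` cm.
* The default scoring layout mirrors the reference simulation: 0.5 cm
  cubic voxels (0.125 cm³), 56 depth rows at 0.25–27.75 cm, 60 lateral
  columns spanning 30 cm — 3360 voxels, one profile per row. 0.25–27.75 cm
  is the unique 0.5 cm lattice consistent with 56 rows, the standard
  comparison depths (all on x.25/x.75), and the 30 cm phantom; it is an
  inference, overridable in the configuration.

Two ground-truth planes are generated from this model:

* `separable_truth()` evaluates the product form analytically — it lies in
  the algorithm's exact model class, so reconstructing it from its own
  axis PDD and `d_ref` profile must fail only by interpolation error. This
  *closure* error shrinks with pixel size (the tests check strict decrease
  over 0.2 → 0.1 → 0.05 cm pixels).
* `nonseparable_truth()` widens the penumbra with depth,
  `σ(d) = σ₀ + g·d` with `g = 0.04` cm/cm, and adds a 2% exponential
  scatter tail (5 cm decay length) outside the field — the two dominant
  non-separable features of a polyenergetic beam. With `g = 0` and zero
  tail it reduces exactly to the separable plane.

Everything is deterministic given parameters; there is no stochastic noise
in the generator, so repeated runs are byte-identical.

The fixture reproduces the qualitative shape of published 18 MV
commissioning curves only; it is not a digitisation of any measured
dataset, and passing closure tests on it demonstrates correctness of the
*algorithm*, not fidelity to any particular machine.

## Validation metric and regions

`agreement()` renormalises both planes to 100% at their own maxima and
reports the absolute difference per pixel in *percentage points of the
maximum*. A local relative difference would explode in the low-dose tail
where neither plane carries clinically relevant dose; percentage points
weight errors by their clinical meaning. Regions follow the standard
dosimetric convention on the fan-mapped reference profile: in-field at
off-axis ratio ≥ 80%, penumbra 20–80%, out-of-field < 20%. The configured
default bounds are 2 percentage points in-field and 5 in the penumbra.

Under the default non-separable parameters the single-profile algorithm
carries the narrow 3.25 cm penumbra to all depths while the truth's
penumbra widens substantially by 28 cm, and the resulting penumbra-region
deviation *exceeds* the 5-point bound (run `scripts/acceptance.R` to see
the measured value, ~9 points). This is a faithful depiction of the
method's limitation: a separable reconstruction cannot track a
depth-dependent penumbra, and the error lives exactly where the region
masks look for it. The in-field deviation for the separable closure, by
contrast, is far inside its 2-point bound at the default 0.1 cm pixels.

## Rendering

* **Gray**: `round(dose/100·255)` half-away-from-zero, clamped to 0–255.
* **Bands**: decile edges `1, 10, 20, …, 100`; the lowest band is closed
  (`[1, 10]`), later bands upper-inclusive (`(10, 20]` …), doses below 1%
  are background. Band borders — pixels whose 4-neighbourhood contains a
  different label — are the isodose curves.
* **HSI colour**: the triangle-model branch formulas convert RGB to hue,
  saturation and intensity, branching on the smallest channel in the fixed
  order blue, red, green (non-strict comparisons) so ties are
  deterministic; raw hue spans three sectors `[0, 3)` and is stored
  divided by 3. Achromatic pixels pin `S = 0, H = 0`. The palette paints
  80–100% red-orange, 70–80% yellow, 25–70% green and 0–25% blue, with
  intensity scaling linearly with dose inside each band (each band runs
  dark to light as dose rises; 0% is black) and the result rescaled to the
  brightest in-gamut shade of the band's hue.
* Two documented transform variants exist behind flags: the matrix-form
  opponent-axis transform (`hsi_matrix_transform()`) is provided for
  completeness with the signed standard matrix, since the commonly printed
  unsigned form is not invertible as published; and the green-smallest
  hue branch offers an `as_printed` toggle for a published variant whose
  denominator (`3I − 3R`) breaks the pattern of the other two branches —
  the pattern-consistent `3I − 3G` is the default. The branch-formula path
  is authoritative for rendering.

Images are written with the surface at the top and the axis centred;
`autoplot()` methods give the same views as ggplot objects.

## Problem sizes

The test suite and acceptance script run the closure experiments at 0.1 cm
pixels (301 × 280 ≈ 84k pixels), with the refinement check spanning 0.2 to
0.05 cm; brute-force oracle comparisons use 50 × 50 grids. These sizes
resolve the 0.3 cm penumbra with several pixels while keeping the full
suite fast on a single core.

## Known limitations

* Separability is the model: depth-dependent penumbra and scatter-halo
  growth are exactly the errors it cannot represent (quantified above).
* Square fields, normal incidence, homogeneous water only; no wedges,
  blocks, heterogeneity corrections, or multi-field summation.
* Relative dose only — absolute calibration (Gy per monitor unit or per
  source particle) is out of scope and treated as metadata.
* The surface-dose behaviour of the analytic fixture is schematic; real
  build-up regions carry electron contamination the generator omits.
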