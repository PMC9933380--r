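---
title: "Methods: LA volumetry, phasic strain and the foreshortening phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LA volumetry, phasic strain and the foreshortening phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laquant)
```

# The problem

Left-atrial (LA) volumes measured on *standard* long-axis cine views are
systematically smaller than those measured on *LA-focused* views or on a
short-axis reference stack. The mechanism is geometric: standard 2- and
4-chamber planes are prescribed on the **left-ventricular** long axis, which
deviates from the LA long axis; the resulting oblique sections foreshorten
the atrium, shrinking both the cross-sectional areas and the annulus-to-roof
length that enter the biplane area–length formula. This package provides the
clinical measurement chain and a synthetic 3D phantom in which the mechanism
can be switched on and off and measured against exact ground truth.

# The phantom

## Geometry

The cavity is a prolate ellipsoid with semi-axes $a, b$ (short) and $c$
(long), in millimetres, in a right-handed frame with the LA long axis along
$+z$, the mitral annulus center at the origin and the roof apex at
$(0, 0, 2c)$ in the reference state. The interatrial septum normal is $+x$.
The LV long axis deviates from the LA axis by a tilt $\theta$ (degrees,
$0 \le \theta < 90$), realized by rotating $+z$ about an axis in the annulus
plane.

**Tilt azimuth.** The rotation axis sits at 45° between the septum normal
and its in-plane orthogonal. This is a design choice: had the tilt axis been
the 4-chamber plane normal itself, the standard 4-chamber plane would still
contain the LA axis and would not foreshorten at all; the diagonal azimuth
makes both standard views oblique, which is the clinically relevant
situation. The azimuth is fixed (not sampled) so that cohort effects are
attributable to the tilt magnitude alone.

## Deformation through the cycle

Frames are indexed 1..`n_phases` (25 by default, within the 25–30 typical of
clinical cine protocols). The reference state — all scale factors equal to
1 — is the **mitral-closure** frame (frame 1), the cycle's volume minimum.
The per-phase target volume follows a piecewise-cosine curve through
(mitral closure, LAVmin) → (mitral opening, LAVmax) → (pre-A, pre-A volume)
→ (cycle wrap, LAVmin). Cosine segments have zero slope at the nodes, giving
the smooth two-lobed shape of a physiologic LA volume curve with its
pre-atrial-contraction shoulder; the curve's extrema therefore fall exactly
on the event frames, which is what lets tests assert that argmax/argmin
frame selection recovers the event frames. Default event frames are 1
(closure), `round(0.4 n)` (opening) and `round(0.85 n)` (pre-A).

Volume change is distributed **anisotropically**: the relative long-axis
change is 1.5× the relative short-axis change
($s_x = s_y = 1 + d$, $s_z = 1 + 1.5d$, with $d$ solved per phase from
$(1+d)^2(1+1.5d) = V(t)/V_{\min}$ by `uniroot` at $10^{-12}$ tolerance).
Long-axis shortening dominating over radial motion is the standard
description of atrial mechanics, and it means a foreshortened section
under-samples precisely the most deformable direction.

## Roof blunting

Atrial deformation is reduced near the posterior roof where the pulmonary
veins insert. The phantom encodes this by attenuating the *displacement*
field (not the coordinates): a surface point at normalized long-axis
position $z' \in [0,1]$ (annulus to roof) moves by
$w(z') \cdot u$, where $u$ is the affine displacement and

$$w(z') = 1 - \lambda \max\!\left(0, \frac{z' - 0.5}{0.5}\right),$$

i.e. full motion over the annular half, a linear ramp above, and $1-\lambda$
at the roof apex. $\lambda = 0$ keeps the phantom an exact affine ellipsoid
at every phase (all closed forms apply); $\lambda = 1$ freezes the apex.
Because LA-focused planes contain the roof while tilted standard planes cut
through the freely-moving body of the atrium, $\lambda > 0$ combined with
$\theta > 0$ makes standard-view perimeter strain read *higher* than
focused-view strain — the direction observed clinically — while
foreshortening simultaneously biases the standard volumes *down*.

Note one consequence: with $\lambda > 0$ the realized (mesh) LAVmax is
smaller than the LAVmax prescribed to the affine part of the deformation;
prescribed curve values are exact for $\lambda = 0$ and for the
mitral-closure frame (where all scales are 1) in general. Ground truth for
accuracy statements is always `phantom_volume()`, never the prescription.

## Mesh representation

The surface is a subdivided icosphere mapped to the ellipsoid (subdivision
level 4, 5120 triangles, by default), chosen for uniform triangle quality
under plane sectioning. Volumes use the divergence theorem on the
triangulated surface; at level 4 the inscribed mesh underestimates the
closed-form ellipsoid volume by about 0.2%, comfortably inside the 0.5%
cross-validation tolerance asserted in the tests. Plane–mesh sections are
assembled from per-triangle intersection segments oriented by the triangle
winding; area and perimeter come straight from the oriented segment set
(shoelace over segments), while ordered polygons (for export or plotting)
are chained through shared mesh edges. Vertices falling exactly in a cutting
plane are nudged by $10^{-9}$ mm to keep crossings transversal — relevant
because long-axis planes pass exactly through the annulus pole.

# Measurement chain

* **Sectioning.** Analytic path for $\lambda = 0$: the plane–ellipsoid
  intersection ellipse is computed in the unit-sphere frame and sampled at
  512 uniformly spaced parameter vertices (polygonization error < 0.1% in
  area). Mesh path otherwise. An empty intersection (a distal slice beyond
  the roof) returns an explicit sentinel that contributes zero area, so disk
  sums skip such slices deterministically rather than erroring.
* **Long-axis length.** Measured from the in-plane projection of the annulus
  center to the farthest contour vertex — the annulus-to-roof length a
  reader draws. The biplane formula then uses the shorter of the 2ch/4ch
  lengths (`L_min`), exactly as printed clinically; the constant is 0.85 as
  printed, not 8/(3π).
* **Short-axis stack.** Slices of thickness 6 mm (default) with normal along
  the LA axis, covering the full extent over all phases
  (`ceil(extent/thickness)` slices); each slice's area is evaluated at its
  slab mid-plane (midpoint rule), which integrates the quadratic area
  profile of an ellipsoid nearly exactly and makes disk sums
  bit-reproducible.
* **Phases.** LAVmax/LAVmin frames are argmax/argmin of each method's own
  volume series, ties broken toward the earlier frame. Severity uses
  half-open intervals [0,53), [53,63), [63,73], (73,∞) ml/m² so the printed
  clinical ranges become a gap-free partition; categories are computed on
  unrounded values.
* **Strain.** Feature tracking is replaced by perimeter (endocardial global
  longitudinal) strain, $100 (P(t)-P_{ref})/P_{ref}$, referenced to mitral
  closure, averaged over the 2ch/4ch curves, then decomposed as reservoir =
  cycle maximum, booster = value at the pre-A frame, conduit = difference
  (so $\varepsilon_s = \varepsilon_e + \varepsilon_a$ identically). The
  pre-A frame comes from the phantom's event table, standing in for ECG
  gating. Both view sets use the same surrogate, so between-view comparisons
  are unaffected by the surrogate choice.
* **Agreement.** Bland–Altman with the 1.96 multiplier (no small-sample t
  correction, matching standard practice for "95% limits of agreement");
  Pearson r is `NA` when either margin is constant. ICC is the two-way
  mixed, absolute-agreement, *single-measures* form ICC(A,1) — the
  single/average choice is a documented decision, as clinical reports often
  omit it.

# The cohort generator

`cohort_config()` defaults describe the emulated population:
108 subjects; tilt ~ truncated-normal(15°, 5°, ≥0) — a modelling choice, as
the angular deviation between LV-focused planes and the true LA axis is not
reported in the clinical literature; indexed LAVmax log-normal with median
42 ml/m² and sdlog 0.30, spanning all four severity categories at this
cohort size; LAEF ~ N(52, 9)% truncated to [25, 72]; BSA ~ N(1.88, 0.21) m²
truncated at 1.2; long/short aspect ratio ~ N(1.6, 0.15) truncated at 1.15;
pre-A volume at fraction N(0.40, 0.05) of the LAVmin→LAVmax span (chosen so
the booster share of reservoir strain is roughly the clinical ~45%);
roof blunting λ = 0.5 for every subject. Truncated normals are sampled by
inverse-CDF on a restricted uniform, so cohorts are bit-for-bit reproducible
from (config, seed).

What the generator does *not* emulate: the appendage and pulmonary-vein
ostia (excluded from clinical tracing anyway), myocardium (so the distal
slice rule based on surrounding myocardium is out of scope — the stack
simply covers the phantom), through-plane motion, partial-volume and
tracing-error noise, and any correlation between LA size, tilt and
deformation. Passing tests therefore demonstrate the *geometric mechanism*
and the correctness of the measurement chain, not patient-level magnitudes:
bias magnitudes, LOA widths and reclassification rates in the simulated
cohort depend on the assumed distributions and are expected to differ from
any particular patient cohort, while the bias *directions* (standard LAVmax
and LAVmin under-read, LAEF over-read, strain over-read; focused close to
the reference) are structural consequences of the geometry.

# Numerical and scale choices

Default problem sizes keep the full pipeline quick: level-4 meshes, 512
polygon vertices, 25 phases and n = 108 run the complete study in well under
a minute; the unit-test suite uses level-3 meshes and smaller cohorts where
only structure (not accuracy) is being checked, and the accuracy assertions
(0.5% mesh/closed-form agreement, 3%/0.5% disk-sum error at 6/1 mm) run at
the full default resolution. Degenerate inputs fail loudly: non-prolate
axes, tilt outside [0°, 90°), LAVmin > LAVmax, out-of-range phases,
non-positive thickness, missing ICC cells and zero-variance ratings all
raise errors rather than returning silently wrong numbers; the one deliberate
non-error is the empty-section sentinel described above. A failed subject
aborts a cohort run with its id — no silent skipping.

# Known limitations

* Perimeter strain is a global surrogate; regional/segmental strain and
  strain rate are out of scope.
* The analytic path exists only for λ = 0; blunted phantoms are mesh-only,
  so their "truth" carries the ~0.2% mesh discretization, which is why
  accuracy tolerances include it.
* Severity edges at exactly 53, 63 and 73 ml/m² follow this package's
  documented half-open convention; other software may bin edge values
  differently.
* The biplane formula's 0.85 is used as printed; replacing it by 8/(3π)
  would scale all biplane volumes by 0.9986 and changes no direction.
```{r example}
ph <- make_phantom(20, 20, 40, theta_deg = 15, lambda = 0.5,
                   volume_curve_params = list(lavmax = 82000, lavmin = 38000))
measure_phantom(ph)$standard
```
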