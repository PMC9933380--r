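# laquant

Quantification of left-atrial (LA) size and function as performed on cardiac
magnetic resonance (CMR) cine images, together with a synthetic 3D atrial
phantom that reproduces the geometric mechanism — *foreshortening* — by which
standard (LV-focused) long-axis views underestimate LA volumes relative to
LA-focused views and a short-axis reference stack.

## Who this is for

Cardiac imagers and methodologists who want a transparent, fully scriptable
test bed for LA volumetry and phasic strain: which measurement chain is
biased, in which direction, and by how much, as a function of acquisition
geometry. Real measurements (traced contours) can also be fed in as CSV.

## The measurements

* **Biplane area–length volume** from orthogonal 2- and 4-chamber views:

  `V = 0.85 · A_4ch · A_2ch / L_min`

  with `L_min` the shorter of the two annulus-to-roof lengths. The constant
  0.85 approximates the exact prolate-ellipsoid factor 8/(3π) ≈ 0.8488, so on
  a perfect ellipsoid the estimate is 0.85·3π/8 ≈ 1.00138 × the true volume.
* **Simpson's method of disks** on a short-axis stack (6 mm slices, no gap):
  `V = t · Σ A_k`, the reference method.
* **Emptying fraction** `LAEF = 100 · (LAVmax − LAVmin)/LAVmax`, with LAVmax
  on the frame before mitral-valve opening and LAVmin at mitral-valve
  closure; volumes also indexed to body surface area (ml/m²) and mapped to
  dilation-severity categories (<53 normal, 53–62 mild, 63–73 moderate,
  >73 severe ml/m²).
* **Phasic strain** (reservoir εs, conduit εe, booster-pump εa, with
  εs = εe + εa) as endocardial perimeter strain of the traced border — a
  transparent surrogate for commercial feature tracking, applied identically
  to both view sets.
* **Method agreement**: Bland–Altman bias and 95% limits of agreement,
  Pearson r/r², two-way mixed absolute-agreement ICC(A,1), and severity
  reclassification cross-tabs.

The phantom is a time-varying prolate ellipsoid (long axis = LA axis) whose
volume curve passes through LAVmin, LAVmax and a pre-atrial-contraction
shoulder, whose LV long axis is tilted against the LA axis (standard views
are prescribed on the LV axis and therefore cut the atrium obliquely), and
whose displacement is regionally blunted toward the pulmonary-vein roof.

## Worked example

```r
library(laquant)

ph <- make_phantom(20, 20, 40, theta_deg = 15, lambda = 0.5,
                   volume_curve_params = list(lavmax = 82000, lavmin = 38000))
m <- measure_phantom(ph, thickness = 6)
m$reference; m$standard; m$focused; m$strain_standard
```

```
reference volume series: LAVmax 70.1 ml (frame 10), LAVmin 38.1 ml (frame 1)
  LAEF 45.7%; indexed 37.3 / 20.3 ml/m2; severity: normal
standard volume series: LAVmax 55.7 ml (frame 10), LAVmin 29.8 ml (frame 1)
  LAEF 46.6%; indexed 29.6 / 15.8 ml/m2; severity: normal
focused volume series: LAVmax 69.9 ml (frame 10), LAVmin 38.0 ml (frame 1)
  LAEF 45.7%; indexed 37.2 / 20.2 ml/m2; severity: normal
LA phasic strain: reservoir 22.6%, conduit 12.2%, booster 10.3%
```

The standard (LV-focused) biplane measurement underestimates LAVmax
(55.7 vs 70.1 ml) and LAVmin and overestimates LAEF, while the LA-focused
biplane tracks the short-axis reference closely — the roof-blunted
deformation also makes standard-view strain read higher (22.6% reservoir)
than LA-focused strain (20.5%).

A full simulated comparison study on a seeded cohort:

```r
res <- run_study(study_config(cohort = cohort_config(n_subjects = 108, seed = 1)))
res$agreement        # bias / 95% LOA / r^2 per method and metric
res$reclassification # severity category changes vs the reference
write_study_outputs(res, "study_out")
```

A thin command-line wrapper is installed at `inst/cli/la_study.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/la_study.R", package="laquant"))')" \
  --seed 1 --n 108 --outdir study_out
```

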