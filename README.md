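# cervelast

Quantitative analysis of cervical ripening from shear-wave elastography
(SWE) and second-harmonic-generation (SHG) microscopy, with the
longitudinal and reproducibility statistics of a two-group monitoring
study, and a synthetic-data generator that makes every stage testable
with known ground truth.

## Who this is for

Researchers quantifying tissue softening with SWE (obstetrics,
biomechanics) and collagen organisation with nonlinear microscopy, and
anyone who needs a reference implementation of:

* **ROI stiffness quantification** — per-pixel shear-wave speeds `c` in a
  5-mm region of interest are converted to Young's modulus by
  `E = 3 ρ c²` (kPa, default ρ = 1000 kg/m³); the ROI estimate is the
  median with the sample SD as error bar, and acquisitions whose
  within-ROI SD exceeds 30% of the median are rejected as artefacts.
* **Fibre directionality R** — the ratio of minor to major axes of the
  moment ellipse of the 2D Fourier magnitude of a ~60 µm image window,
  thresholded at 80% of the central (DC) value and restricted to the
  DC-connected component. Small R ⇒ parallel fibres; R near 1 ⇒ disorder.
* **The study statistics** — rank-based ANOVA-type statistic for the
  group × repeated-time layout, per-hour Wilcoxon rank-sum tests with
  Benjamini–Hochberg step-up correction, Bland–Altman 95% limits of
  agreement (bias ± 1.96·SD of differences), Kruskal–Wallis, and
  quadratic stiffness-trajectory fits with R².
* **Synthetic study data** — exam tables following configurable quadratic
  stiffness trajectories with exactly dialled within-ROI dispersion
  (including designed QC violations), SHG-like fibre textures of
  controllable alignment built from fascicle chains, and prostaglandin
  assay tables.

## Worked example

A single ROI acquisition:

```r
library(cervelast)
summarize_roi(c(1.45, 1.52, 1.48, 1.50, 1.55))
#> ROI stiffness: 6.75 kPa (SWS 1.500 m/s), SD 0.34 kPa (5.1% of median), QC pass, n = 5
```

The five speeds (m/s) convert pixel-wise to moduli; the median 1.50 m/s
corresponds to 6.75 kPa, the dispersion is 5.1% of the median — far below
the 30% rejection threshold, so the acquisition passes QC.

The full synthetic study — 4 control + 5 treated animals, 7 examinations
over 24 h, 2 operators × 3 replicates (378 ROIs), one treated animal
losing its last examination and 2 designed artefacts:

```r
run_study(verbose = FALSE)
#> Synthetic ripening study report
#>   ROIs: 378 (missing 1.6%, QC-rejected 0.53%)
#>   ANOVA-type statistics:
#>     group      ATS = 715.39, df1 = 1.00, p = 3.11e-07
#>     time       ATS =  21.80, df1 = 1.86, p = 1.19e-09
#>     group:time ATS =   2.46, df1 = 1.86, p = 0.0894
#>   control trajectory: 0.0009 t^2 -0.0468 t +10.5318 (R^2 = 76%)
#>   treated trajectory: 0.0099 t^2 -0.3846 t +9.3221 (R^2 = 100%)
#>   SHG R: aligned 0.453 vs disordered 1.000 (ANOVA p = 0.000245)
#>   PGE2 Kruskal-Wallis: H = 6.82, p = 0.00902
```

Reading the report: the accounting matches the designed data losses; the
group effect dominates (treated animals soften, controls do not); the
fitted treated trajectory recovers the generating quadratic
(0.0103 t² − 0.3844 t + 9.2147 kPa) from noisy exams; aligned fibre
textures score much lower R than disordered ones; and the simulated
prostaglandin surge is detected. Pass `out_dir =` to write every
figure-ready table as CSV plus a `report.json`.

A command-line wrapper with subcommands `simulate-swe`, `simulate-shg`,
`analyze-swe`, `analyze-shg`, `stats` and `run-study` is installed at
`system.file("scripts/cervelast", package = "cervelast")`.

See the vignette (`vignettes/cervical-stiffness-pipeline.Rmd`) for the
models, numerical conventions and design choices.

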