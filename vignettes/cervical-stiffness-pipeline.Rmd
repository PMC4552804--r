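---
title: "Quantifying cervical ripening: stiffness, fibre directionality and the study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cervical ripening: stiffness, fibre directionality and the study statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervelast)
```

## The problem

Cervical ripening — the softening of the uterine cervix before delivery —
can be monitored *in vivo* with shear-wave elastography (SWE): an
ultrasound scanner measures the speed `c` of remotely induced shear waves,
and under local homogeneity, isotropy and pure elasticity the Young's
modulus follows

$$E = 3\,\rho\,c^2,$$

with tissue density $\rho$. At the microscopic scale the same remodelling
appears as a loss of collagen fibre organisation, visible in second
harmonic generation (SHG) microscopy and quantifiable through the Fourier
anisotropy of image windows.

`cervelast` implements the full quantitative chain of such a two-group
(control vs softening-induced), seven-examination, two-operator,
three-replicate monitoring study — and, because no imaging data are
deposited with studies of this kind, a synthetic-data generator that
emulates the design with known ground truth, so that every stage of the
chain is testable.

## Stiffness quantification

Each acquisition yields per-pixel shear-wave speeds inside a 5-mm circular
region of interest (ROI). `summarize_roi()` converts every pixel to the
modulus scale and reports the ROI **median** and sample (n−1) **SD** in
kPa. Working on the modulus scale and back-converting the median to a
summary speed is self-consistent, because the median commutes with the
monotone conversion; the scanner-style printed pairs
(1.291 m/s ↔ 5.00 kPa, 1.826 m/s ↔ 10.00 kPa, 1.779 m/s ↔ 9.5 kPa) are all
reproduced with the default $\rho = 1000$ kg/m³, which is why that default
was chosen; it is exposed as a parameter.

Quality control follows the dispersion rule: an acquisition is rejected
when the within-ROI SD exceeds 30% of the median ("higher than" — equality
passes, a deliberate boundary convention tested explicitly). Replicates
are aggregated per operator and exam by the median, with the SD as error
bar; a single surviving replicate reports an undefined (`NA`) SD rather
than zero, and an exam with no survivors is marked missing, never imputed.
`account_dataset()` reports totals and percentages at 2 significant
figures (378 records, 6 missing = 1.6%, 2 rejected = 0.53% under the
default design).

```{r}
summarize_roi(c(1.45, 1.52, 1.48, 1.50, 1.55))
```

## Fibre directionality from the Fourier spectrum

For an SHG image window (default 60 um, i.e. 180 px at 1/3 um/px, rounded
to an even side) the pipeline computes the centred 2D Fourier magnitude
(`compute_ft()`), thresholds it at 80% of the central (DC) value
(`threshold_ft()`), keeps the 8-connected component containing the centre,
and fits the ellipse with the same normalised second central moments as
the surviving region (`ellipse_from_mask()`; axis length =
4·sqrt(eigenvalue), with the 1/12 pixel-area correction, the convention of
standard region-properties tools). The directionality statistic is

$$R = \frac{\text{minor axis}}{\text{major axis}} \in (0, 1],$$

small when fibres are parallel (spectral energy concentrated
perpendicular to the fibre axis) and near 1 for disordered textures.

Numerical choices worth knowing:

* **No apodization window** is applied before the transform; an optional
  pre-window was considered and rejected because the threshold is defined
  relative to the DC bin and any taper changes both consistently.
* The threshold applies to the **magnitude**, not the power; at 80% the
  two select visibly different regions.
* The mask is restricted to the **DC-connected component** because moments
  over disconnected harmonic peaks do not describe a single ellipse.
* A single-pixel mask is the degenerate isotropic case and reports R = 1.
* A blank window (zero DC) is an error, not a silent R.
* The DC-relative threshold makes R sensitive to a constant background
  *offset* (it inflates the DC bin and shrinks the mask): zero-mean
  detector noise at SNR ≥ 10 moves R by well under 0.05, but offsets
  should be subtracted upstream.

Mosaics are reassembled from tiles with a fixed 10% overlap by linear
feathering (`stitch_tiles()`); tiles cut from one image restitch to it
exactly, which is how the stitcher is tested. The per-window intensity
summary is the mean of the 10 brightest pixels (`max10_intensity()`),
robust to single-pixel outliers. Group comparisons of R and intensity use
a plain one-way ANOVA with pooled-variance pairwise t tests
(`compare_shg_groups()`); studentised-range post-hoc machinery was left
out deliberately.

## The synthetic generators

### SWE exam tables

`simulate_swe_dataset()` draws, for every animal × hour × operator ×
replicate cell, an exam-level stiffness from the group's quadratic
trajectory plus Gaussian exam noise (default SD 0.5 kPa, which reproduces
the order of per-time SDs such studies report, 0.5–1.4 kPa). The default
trajectories are the two printed quadratics (control
$0.0014t^2-0.0648t+10.7016$, treated $0.0103t^2-0.3844t+9.2147$ kPa).
Within-ROI pixel moduli are generated as bounded symmetric multiplicative
deviates around the exam value, rescaled so that the sample median equals
the exam stiffness and the sample SD/median equals the requested fraction
*exactly* (default 10%; 40% on designed QC-violation slots). The bounded
deviate (truncated normal, |z| ≤ 1.8 before standardisation) was chosen
over a lognormal because exact-SD rescaling of unbounded draws can cross
zero at violation-level dispersion; exactness is what lets the test suite
assert that the 30% rule fires on precisely the designed slots. Records
can also be marked missing, emulating acquisitions lost to animal
movement. The full default design is 4 + 5 animals × 7 hours × 2
operators × 3 replicates = 378 records with 200 pixels per ROI (a
plausible pixel count for a 5-mm circle on an elastography map; the value
only scales the dispersion estimate's stability).

### Fibre images

`simulate_fibre_image()` renders collagen-like texture as **bundles
(fascicles) built from chains of short fibre segments**. Bundle axes are
spaced ~55 um apart; each bundle grows from a centre point in both
directions, and every segment's direction is the mean orientation plus
independent Gaussian jitter of SD `dispersion_sd`. This makes the two
morphologies of interest emerge from one dial: with little jitter a chain
is a straight, narrow (~6 um) band crossing the field — the "well aligned,
parallel fibres" picture — while strong jitter curls it into a compact
clump tens of um across, the disorganised picture. Segments carry
`fibres_per_segment` parallel Gaussian-profile ridges (FWHM 1.5 um,
2.5 um apart) with sinusoidal waviness, lognormal bundle-to-bundle
brightness (SD(log) = 1.0) and mild per-segment jitter; the noise-free
render is normalised to `intensity_peak` and Gaussian background noise is
added and clipped at zero.

This structure is not incidental: the 80%-of-DC threshold only yields a
multi-pixel mask when the window has strong intensity structure at the
window scale (a band covering ≲ 1/3 of a 60-um window puts its first
Fourier harmonic above 0.8·DC). A texture of uniform, dense infinite
stripes — however perfectly aligned — leaves only the DC pixel and hence
an uninformative R of 1. Real SHG fields supply that structure through
fascicles and pores; the generator supplies it through the bundle
envelope. With the defaults, aligned textures score mean R ≈ 0.2–0.4 and
heavily dispersed ones approach 1, and mean R increases monotonically over
dispersions 0° < 30° < 60° (a property the test suite checks across
seeds).

What the generator does **not** emulate: detector shot noise and gain,
fibre diameter variability, true 3-D section geometry, pore-scale
porosity, and absolute SHG efficiency. Passing tests therefore demonstrate
that the analysis chain responds correctly to controlled orientation
disorder — not that any particular absolute R value observed on real
tissue would be reproduced.

### Prostaglandin tables

`simulate_pge2_table()` draws lognormal baseline concentrations (median
50 pg/mL, CV 25%) and scales the treated group's post-induction sample by
a configurable fold change (default 10, a sharp surge), feeding the
downstream Kruskal–Wallis comparison.

## The study statistics

* **ANOVA-type statistic (ATS)** for the two-factor longitudinal layout
  (whole-plot group, repeated time; `anova_type_statistic()`): all
  observations are mid-ranked jointly, relative effects are formed per
  group × time cell, and the quadratic form is referred to an F
  distribution with Box-type numerator degrees of freedom. Within-subject
  effects use F(df1, ∞); the group effect uses a Satterthwaite-type
  denominator df built from the per-group covariances of the ranked
  subject profiles. Missing cells are handled by available-case means and
  pairwise covariance estimates. Under a null with the study's dimensions
  (4 + 5 animals, 7 times) the group test's empirical size is 2–5% at the
  5% level — slightly conservative, which is characteristic of the Box
  approximation at whole-plot sample sizes this small.
* **Per-hour rank-sum tests** (`ranksum_by_time()`): exact enumeration for
  combined n ≤ 12 without ties, tie-corrected normal approximation
  otherwise; fully tied data report p = 1. The across-hours correction is
  Benjamini–Hochberg step-up — the conventional reading of
  "Bonferroni-Hochberg" — with plain Bonferroni available via `method`.
* **Bland–Altman agreement** (`bland_altman()`): bias = mean difference,
  95% limits of agreement = bias ± 1.96·SD of differences. The
  large-sample 1.96 factor is kept (no small-sample t correction),
  matching the classical method; with 1000 normal differences the limits
  cover ≈ 95% of points.
* **Kruskal–Wallis** (`kruskal_wallis()`) wraps the tie-corrected
  `stats::kruskal.test`, with the all-identical degenerate case defined as
  H = 0, p = 1.
* **Quadratic trajectory fits** (`fit_quadratic()`): OLS on {1, t, t²};
  R² = 1 − SS_res/SS_tot, defined as 0 with a warning when the response is
  constant. By default group trajectories are fitted on per-hour medians
  (7 points per group, the aggregation behind a single printed trajectory);
  fitting all raw exam values is available via `use_medians = FALSE` —
  which of the two a given published fit used is generally not stated, so
  both are provided and neither asserted.

## The orchestrated study

`run_study()` chains everything deterministically under one seed
(per-purpose substreams are derived from it): simulate the exam table
(with one treated animal losing its last examination — 6 records — and 2
designed QC violations, mirroring a realistic accounting), quantify and
aggregate stiffness, run the ATS, the per-hour tests and the per-group
fits, Bland–Altman intra-operator (replicate 1 vs 2) and inter-operator
(operator exam medians) agreement, the SHG branch (10 aligned and 10
disordered images by default, dispersion 3° vs 60°, waviness 1 vs 4 um;
per-window R and max-10 intensity; one-way ANOVA), and the prostaglandin
comparison. Every figure-ready table is written as CSV next to a
`report.json` echoing the full configuration.

```{r}
report <- run_study(validate_config(list(
  seed = 1, shg = list(n_images_per_group = 3L))), verbose = FALSE)
report
```

The inter-operator Bland–Altman on this synthetic run has a bias near zero
by construction — both operators share the exam-noise model — so agreement
statistics here validate the *machinery*, not any claim about real
operator behaviour.

## Problem sizes used by the checks

The packaged checks run the conversion identities on printed pairs; the
trajectory recovery on 200 seeded replicates of 5 animals × 2 operators ×
7 hours; the Fourier oracle on 16 × 16 windows against a brute-force
double-sum transform; the directionality properties on 20 seeds per
dispersion level and 20 replicate two-group comparisons at 10 windows per
group; and the ATS calibration on 200 null simulations at the study's
dimensions. These sizes give stable Monte-Carlo estimates for each
property while keeping a full run of the suite under a minute.

## Known limitations

* The $E = 3\rho c^2$ inversion assumes homogeneity, isotropy and pure
  elasticity; viscoelastic dispersion and anisotropy are out of scope.
* ROI membership is taken as given; anatomical ROI placement on B-mode
  images is not modelled.
* The R statistic reduces a whole window to one anisotropy number; it
  cannot distinguish waviness from orientation scatter, and its absolute
  value depends on window content structure (see above), so it should be
  compared within-protocol only.
* The ATS implementation covers the one whole-plot × one sub-plot layout
  only, without confidence intervals for the relative effects.
* The variance decomposition between animals, operators and replicates is
  exposed as generator parameters rather than asserted, since longitudinal
  stiffness studies rarely publish it.
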