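---
title: "Methods: quality-gated mIF analysis and the HID proximity statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality-gated mIF analysis and the HID proximity statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`hidpipe`. The package analyses multiplex immunofluorescence (mIF) regions
of interest (ROIs) — multichannel fields of view with a DAPI nuclear
counterstain, four immune markers (CD8, PD-1, PD-L1, CD68) and a tissue
autofluorescence channel — and relates cell–cell spatial proximity to
patient survival.

## The HID statistic

For two phenotype sets $C^i$ and $C^j$ and a proximity radius $d$, the
Hypothesised Interaction Distribution counts proximal pairs:

$$H(i,j) = \left|\left\{(k,l):\; x_k \in C^i,\; x_l \in C^j,\; k \neq l,\;
\lVert x_k - x_l \rVert_2 < d \right\}\right|, \qquad h(i,j) = \frac{H(i,j)}{N}$$

with $N$ the total number of cells in the sample regardless of phenotype.
Conventions, all of which are exercised by exact tests:

* **Unordered, distinct pairs.** Each qualifying pair is counted once, so
  $H(i,j) = H(j,i)$. A cell co-expressing both phenotypes belongs to both
  sets but never pairs with itself: a zero-distance self-pair carries no
  biological meaning. (`hid_count(..., method =)` does not change this —
  both code paths share the rule.)
* **Strict inequality at $d$.** A pair at exactly $d$ is not counted.
  Distances are computed in pixel space after an exact, unrounded
  conversion `d_um / pixel_size_um` (30 µm at 0.495 µm/px is 60.606... px),
  which avoids quantisation exactly at the boundary.
* **Normalisation by all cells.** $N$ includes cells of no analysis
  phenotype, so $h$ shrinks as $1/N$ when bystander cells are added.

The default implementation bins cells on a grid of cell size $d$ and
examines only neighbouring bins; it is contractually identical to the
all-pairs loop (`method = "loop"`), and the test suite verifies equality on
1,000 randomized instances including coincident centroids and
boundary-distance pairs.

Within a patient, per-ROI $h$ values are aggregated by the **median**
(default), paralleling the density convention below; `mean` and `pooled`
($\sum H / \sum N$) aggregators are available because the choice is not
canonical. The default radius $d = 30$ µm corresponds to a neighbourhood of
roughly 2–3 cell diameters, the scale at which contact-mediated or
short-range paracrine interaction between a T cell and a PD-L1⁺ cell is
plausible.

## Image preparation

**Spectral unmixing.** A raw multispectral stack is decomposed per pixel as
`raw ≈ library %*% abundances` with nonnegative abundances (abundances are
physical concentrations; negative values are artefactual). The
unconstrained least-squares solution is computed for all pixels in one
matrix operation and only pixels violating nonnegativity are re-solved with
the Lawson–Hanson active-set algorithm — on realistic noise levels that is
a small minority, so per-pixel cost stays low. A rank-deficient library is
rejected naming the collinear columns. Building a real spectral library
from single-stain slides is out of scope; `spectral_mix()` provides the
forward model for simulation.

**Quality classification.** Each pixel is labelled background, tissue or
artifact by a rule-based classifier: background where smoothed total signal
is low; artifact where smoothed autofluorescence is high (red blood cells,
bubbles) or where the local energy of a high-pass DAPI response is low
inside signalled regions (out-of-focus patches); tissue elsewhere, with
small speckle regions reabsorbed. The classifier is deliberately a plain
`image -> mask` function: a learned segmenter can be slotted in anywhere a
mask is accepted, and the downstream contract (the gate and the
centroid-in-tissue rule) is unchanged. Default thresholds
(`bg_threshold = 0.05`, `af_threshold = 0.4`, `blur_threshold = 1e-4`)
are calibrated against the synthetic renderer's noise floor (Gaussian read
noise, sd 0.02) and verified against planted truth masks.

**The inclusion gate.** An ROI is excluded when its useful-tissue fraction
is strictly below 30%; exactly 30% is included. The denominator is all
pixels of the ROI (the alternative — non-background pixels only — is a
plausible reading; the choice is explicit in `useful_tissue_fraction`).
Only cells whose centroid pixel (nearest pixel, rounded coordinates) is
labelled tissue are retained.

## Segmentation, measurement, scoring

* **Nuclear detection**: Gaussian smoothing (σ = 2 px), intensity
  threshold (fixed 0.15 by default; Otsu optional), Euclidean distance
  transform, watershed split of touching objects, area filter
  (10–500 px²). Deterministic by construction. Parameters live in config;
  the defaults were tuned on synthetic validation renders.
* **Cell expansion**: each nucleus is dilated by
  `round(radius_um / pixel_size_um)` px (2 µm at 0.495 µm/px gives 4 px).
  A pixel reachable from several nuclei goes to the nucleus whose nearest
  pixel is closest in Euclidean distance, with exact ties broken toward the
  lower label id — so expansion stops at equidistant boundaries and no
  pixel belongs to two cells. Cytoplasm is the expansion minus the nucleus.
* **Statistics**: per cell × channel × compartment mean, min, max and
  **population** standard deviation (divide by *n*; the natural convention
  for pixel populations). Cells with an empty compartment get `NA` and a
  flag.
* **Rescaling**: per marker, a linear map of the 1st and 99th percentiles
  (linear-interpolation empirical percentiles) of that marker's pixel
  intensities over the entire analysis set onto [0, 1], clipped outside.
  Fitting once per dataset makes equal intensities render and score
  equally everywhere.
* **Positivity**: one threshold per marker on the rescaled mean intensity
  of the marker's primary compartment — cytoplasm/membrane for all four
  markers here, configurable per marker. A value exactly at the threshold
  scores **positive**; a fixed documented convention beats ambiguity.
* **Phenotypes**: memberships are conjunctions of flags and overlap
  (every CD8⁺PD-1⁺ cell is also CD8⁺ and PD-1⁺).

## Survival analysis

Kaplan–Meier estimation is implemented directly (product-limit with
censored subjects at an event time remaining at risk at that time), with
Greenwood's variance
$\widehat{\mathrm{Var}}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t} d_i / (n_i(n_i-d_i))$;
the tests cross-check it against `survival::survfit` to 1e-10 and against a
hand-computed three-subject example. Group comparison uses the
Mantel–Haenszel log-rank test and univariate Cox regression (Efron tie
handling by default) via the `survival` package; distribution comparisons
between HPV⁺ and HPV⁻ patients use the one-sided Mann–Whitney U test
(exact for small untied samples). A Kolmogorov–Smirnov normality statistic
is reported as a diagnostic only and never gates which test runs. No
multiple-testing correction is applied — the design mirrors a
pre-specified-hypotheses analysis — and the report counts the tests it ran.
Stratification labels a patient *high* when the feature exceeds the median
(densities) or mean (HID features) of the analysis population, ties going
low; whether a subgroup analysis uses the subgroup's own cut or the
cohort-wide cut is configurable (`cut_population`), since both readings are
defensible — subgroup cuts are the default.

## The synthetic-data generator

The generator is the package's stand-in for a real cohort and defines the
conditions under which every claim is tested.

* **Geometry**: 1392 × 1040 px ROIs at 0.495 µm/px, 10–20 ROIs per
  patient, 72 patients — the scale of a mid-size head-and-neck mIF study.
* **Abundances**: expected cells per ROI by exclusive marker class
  (CD8 15, CD8_PD1 5, CD68 6, CD68_PDL1 3, PDL1 24, PD1 33, negative 214;
  ~300 cells/ROI), chosen to match reported median population fractions of
  the six analysis phenotypes (6.6 / 1.5 / 3.1 / 1.1 / 9.0 / 12.7 percent).
* **Spatial structure**: with `colocalization_strength = 0` all cells are
  uniform over the field (CSR); otherwise a parent–offspring
  (Thomas-like) process moves a fraction `1 − exp(−strength)` of CD8/PD-1
  cells into a 15 µm disc around a random PD-L1⁺ parent — the simplest
  construction with a tunable proximal-pair excess. Calibration tests
  compare the empirical mean $h$ under CSR with the closed-form
  expectation $\lambda_i \lambda_j \pi d^2 / (A\,N)$; no edge correction is
  applied (HID itself applies none), so the observed mean sits a few
  percent below the in-plane value and the tolerance is widened
  accordingly (the suite also checks against the exact in-rectangle pair
  probability by numerical integration).
* **Rendering**: nuclei are Gaussian blobs (σ 2.2 px, amplitude ~N(0.9,
  0.08)) on DAPI; each marker channel paints a 9 px cytoplasmic disc per
  cell with amplitude drawn from overlapping log-normals — positives
  LogN(log 0.55, 0.3), negatives LogN(log 0.02, 0.35) — so threshold
  scoring faces a realistic, imperfect separation; Gaussian read noise
  (sd 0.02) and an autofluorescence baseline (0.05) are added. The design
  positivity threshold is 0.15 on the raw amplitude scale, between the two
  distributions; its rescaled equivalent is obtained by pushing it through
  the fitted dataset bounds. Artifacts consume `artifact_fraction` of the
  area: ~50% bright AF discs, ~20% locally blurred patches, ~30% a
  zero-signal margin, all recorded in the ground-truth mask.
* **Survival**: exponential proportional hazards — the simplest model
  satisfying the Cox assumption. Log-hazard =
  log(baseline 0.004/month) + `planted_log_hr` (default log 3) for
  patients in the *high* half of the true HID feature (cohort-mean cut),
  applied only in the configured stratum (default HPV-negative), plus
  log 3.3 for HPV-negative disease. Independent exponential censoring is
  calibrated per subject so the expected censored fraction is 40%. With
  these defaults overall median survival lands near seven years, the
  scale reported for such cohorts.
* **Determinism**: all randomness flows from one integer master seed
  through order-independent sub-seeds per (patient, ROI), so any ROI can
  be regenerated in isolation and identical seeds give byte-identical
  cohorts, images and downstream results.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: true Opal fluorophore spectra and scanner
optics, stromal-vs-tumour compartments, nuclear morphology variation,
marker intensity gradients within a slide, spatially correlated staining
artifacts, and batch effects between slides. Results on synthetic data
validate the machinery (counting, gating, estimation, calibration), not
biological claims.

## Problem sizes used by the tests

Simulation-heavy checks run at reduced sizes chosen to keep the suite
compact while leaving the per-area study conditions intact: image-level
checks use 400 × 520 px fields with densities scaled by area; the CSR
calibration uses 500 full-size point patterns; log-rank calibration uses
200 replicate 40-patient cohorts (3–4 small ROIs each); Cox recovery uses
200 replicates of 60 subjects; the end-to-end directional check uses 50
cohorts at full study conditions. `scripts/acceptance.R` re-runs the same
measurements at slightly smaller sizes and reports the numbers as JSON.

## Numerical choices and degenerate inputs

* Ties at the positivity threshold: positive. Ties at a stratification
  cut: low. Nearest-nucleus ties in expansion: lower label.
* `hid_normalize` refuses $N = 0$: an ROI with no cells contributes no
  HID value; a patient with no included ROIs is flagged missing and
  excluded with a log entry.
* `fit_rescale` refuses constant intensities (low = high) and fewer than
  100 pixels per marker.
* Log-rank requires two non-empty groups and at least one event; Cox
  requires an event in each covariate level, and monotone-likelihood fits
  are flagged with an unbounded confidence interval rather than a
  spurious finite one.
* `stratify` refuses all-identical values.
* The pipeline refuses to write into a non-empty results directory unless
  told to overwrite, so reruns never silently mix outputs.

## Known limitations

* The rule-based quality classifier is calibrated to the synthetic
  renderer; on real images its thresholds would need recalibration, or a
  trained segmenter dropped in behind the same interface.
* Watershed under-segments heavily overlapping nuclei (two blobs closer
  than ~one nuclear radius are one object at rendering resolution), which
  bounds achievable recall at high density.
* Percentile rescaling saturates above the 99th percentile; markers whose
  positive cells occupy well under 1% of pixels compress near 1.0 on the
  rescaled scale, which is why the design threshold is defined on the raw
  scale and mapped through the fitted bounds.
* Survival generation is exponential PH; non-proportional or
  time-varying hazards are out of scope.
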