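---
title: "Basal-cell morphometry: model, measurement and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basal-cell morphometry: model, measurement and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Histological grading of oral epithelial dysplasia is subjective and poorly
reproducible between observers. Quantitative morphometry of the basal cell
layer — the proliferative compartment of stratified squamous epithelium —
offers an objective alternative: cell and nuclear profile size grow steadily
from normal buccal mucosa through leukoplakia (a potentially malignant white
patch) to well-differentiated squamous cell carcinoma, while boundary shape
and the nuclear–cytoplasmic balance change in characteristic ways.

This package implements that analysis end to end: per-object measurement of
area and perimeter in calibrated physical units from integer-labeled mask
images, the classical shape and nuclear–cytoplasmic descriptors, the group
comparison statistics used in diagnostic morphometry, and a seeded
synthetic-histology generator so the whole chain is testable without any
image download. A published 70-case reference dataset (10 normal buccal
mucosa, 30 leukoplakia, 30 well-differentiated SCC; per-case mean cell
area, cell perimeter, nuclear area, nuclear perimeter) ships as
`table2_fixture()` and anchors both the statistics and the generator.

## Morphometric descriptors

From the four measured quantities per case — cell area $CA$ (µm²), cell
perimeter $CP$ (µm), nuclear area $NA$ (µm²), nuclear perimeter $NP$ (µm) —
three derived descriptors are computed per compartment:

* **Form perimeter** (circularity): $\mathrm{PE} = 4 c \, A / P^2$, where
  $c$ is the circle constant. A circle scores exactly 1; indented or
  elongated outlines score lower.
* **Contour index**: $\mathrm{CI} = P / \sqrt{A}$; $2\sqrt{\pi} \approx
  3.545$ for a circle, rising with indentations. The two are linked by the
  algebraic identity $\mathrm{CI}^2 \cdot \mathrm{PE} = 4c$, which the
  package enforces as a tested invariant.
* **N:C ratio**: $NA / (CA - NA)$, nuclear over cytoplasmic area.

The circle constant defaults to exact $\pi$; the rational approximation
$22/7$, common in the older morphometry literature, is available via
`options(basalmorph.circle = "22/7")` or the `circle` argument. The choice
rescales the form perimeter globally by $22/(7\pi) \approx 1.0004$ and
therefore cannot change any ANOVA, t or rank statistic; $\pi$ is the
mathematically correct default.

Measured data can violate the isoperimetric bound $\mathrm{PE} \le 1$
because area and perimeter are estimated independently from digitized
outlines; the reference dataset itself contains such rows (e.g. the fourth
normal case's nucleus). `derive_descriptors()` keeps these values
unclipped and warns once, because clipping would bias every downstream
statistic. Records with $NA \ge CA$, by contrast, are physically
impossible (the nucleus lies inside the cell) and are rejected at load
with a per-row report.

## Measurement from label masks

Input is a pair of co-registered integer label masks (cell and nucleus,
label $k$ marking cell $k$ and its nucleus) plus an isotropic calibration
in µm/pixel, as produced by any segmentation tool or by the packaged
generator. The coordinate convention, used everywhere, is: pixel centers
at integer coordinates, x = column, y = row, origin top-left, contours at
the 0.5 iso-level.

The outline estimator matters. Counting boundary pixels — the method of
early interactive image analyzers — overestimates smooth perimeters by up
to ~27% for straight edges at unfavorable angles (~5% averaged over a
circle), which would destroy the circle anchors of the shape descriptors
(PE = 1, CI = 3.54). The package instead extracts a **sub-pixel iso-contour
of the Gaussian-smoothed object indicator** (default `smooth_sigma = 1.5`
px) with `grDevices::contourLines()`, and computes perimeter as polygon
arc length and area by the shoelace formula on the *same* polygon, keeping
the two mutually consistent. For disks the curvature bias of the smoothed
level set is of order $\sigma^2/(2r)$: measured error is below 0.7% in
area and 0.5% in perimeter for radii ≥ 20 px, and below 0.3% / 0.1% at
radius 50 px (tested invariants: area ≤ 1%, perimeter ≤ 2% at r ≥ 50).
The flip side is corner rounding: sharp rectangle corners lose ~5% of
perimeter, and objects below ~10 px radius are measured with percent-level
bias. The estimator targets smooth biological outlines at adequate
magnification; datasets should be rendered or imaged so nuclei are ≥ ~15
px in radius.

Field measurement applies the screening rules of interactive morphometry
in geometric form: objects touching the raster border (the stand-in for
overlapping or clipped cells) are excluded; labels whose pixel set is
disconnected or contains holes cannot be summarized by a single simple
outline and are skipped with a logged reason; cells without a nucleus
label are excluded. Every emitted row satisfies $NA < CA$. Per-case
aggregation keeps the `max_cells_per_field = 7` largest cells by area in
each field (the classical "5–7 largest cells with clear outline" rule) and
averages across all kept objects. The reference protocol does not state
the per-case aggregation statistic, so it is configurable
(`stat = "mean"` default, `"median"` available); the mean is assumed
because the reference tables store per-case means. No section-thickness or
Holmes-effect correction is applied, matching the reference protocol's
explicit choice to measure the image as seen.

## The synthetic generator

`default_synthetic_spec()` reproduces the reference study's design: 10/30/30
cases, 5–10 fields per case, 5–7 cells per field, with per-group generative
parameters equal to the empirical per-case means and standard deviations of
the reference dataset (cell area, nuclear area, nuclear area fraction).

Geometry is **star-convex radial perturbation**: a cell outline is
$r(\varphi) = R\,(1 + u(\varphi))$ with $u$ a sum of harmonics $k = 2..6$
with random phases, RMS amplitude = the per-group *irregularity* knob, and
the polygon rescaled analytically so its area hits the target exactly.
This guarantees simple polygons, exact area control, and a single knob on
the shape axis: to second order the expected form perimeter is
$1 - 17\,a^2$ for RMS amplitude $a$ (equal variance across the five
harmonics). The mapping is used to set each group's irregularity from its
observed mean form perimeter; it underestimates the realized form
perimeter by up to ~0.1 at the largest amplitudes (higher-order terms),
which is acceptable because no acceptance gate depends on absolute shape
levels — the normal group's observed form perimeter exceeds 1 and clamps
to a circular boundary anyway. The nucleus is a scaled copy of the cell
boundary with an independent mild perturbation, rescaled to the case's
nuclear area fraction and radially capped strictly inside the cell, so
containment holds by construction (and is verified point-in-polygon in
the tests).

Per-case sizes $(CA, NA)$ are drawn from the group normal distributions,
truncated to positivity and $NA < CA$; the rejected-draw fraction is
reported and is far below 1% under the default parameters (the group
means are ~6 SD apart). Within a case, per-cell areas vary with a 10%
coefficient of variation — a free parameter documented as such, because
the reference study reports only per-case means. Cells are placed by
rejection sampling without overlap (bounding-circle test) and without
border contact; rasters are written as 16-bit TIFF with a JSON sidecar
per field, and a `manifest.json` records the full spec including the
seed. `generate_tabular()` bypasses imaging for fast statistical tests,
deriving perimeters from truncated-normal form-perimeter draws via
$P = \sqrt{4\pi A/\mathrm{PE}}$. Default rendering calibration is 0.2
µm/px on a 448×448 raster — chosen so the largest cells fit with
placement slack while normal-group nuclei stay near ~15 px radius, inside
the estimator's accurate range; the vignette-scale problem sizes
(70 cases, ~500 fields, ~3000 cells) run in about a minute.

Because the generator draws 5–7 cells per field and the aggregation cap is
7, the "largest cells" selection rule introduces no truncation bias in the
synthetic pipeline: the generator emulates the already-selected cell
population, which is what the reference per-case means describe. What the
synthetic data do **not** emulate: staining and optical texture, real
segmentation error, spatial correlation within fields, non-normal
per-case distributions, and inter-observer tracing variability. Passing
parameter-recovery tests therefore validates the measurement and
statistics chain, not the behavior of the pipeline on real H&E
photomicrographs.

## Statistics

All inference operates on per-case records (the reference design: 70
experimental units, df 2/67/69 for three groups), never on per-cell
measurements.

* `one_way_anova()` — fixed-effects decomposition via `stats::lm`/`anova`,
  returning the full SS/df/MS/F table.
* `t_test_pooled()` — pooled-variance Student's t (`stats::t.test`,
  `var.equal = TRUE`), df $n_1 + n_2 - 2$. The pooled (not Welch) form is
  used because the reference tables print df 38 and 58, which force it.
  The cytoplasm comparisons are computed on whole-cell area, not
  $CA - NA$: recomputation shows the reference values are near the
  whole-cell statistics (within ~1%) and nowhere near the $CA - NA$ ones
  (off by a factor ~2).
* `mann_whitney()` — U with the tie-corrected normal approximation,
  computed directly (base R exposes no Z); no continuity correction by
  default, so the statistic matches the closed forms used as test oracles
  (`continuity = TRUE` available). Cross-checked in the tests against
  `wilcox.test(correct = FALSE)` p-values and against exhaustive
  enumeration of the exact U distribution for total $n \le 12$.
* `kruskal_wallis()` — tie-corrected H via `stats::kruskal.test`, referred
  to $\chi^2_{k-1}$.

Rank statistics are invariant under strictly monotone transforms, so form
perimeter and contour index — linked by $\mathrm{CI} =
\sqrt{4c/\mathrm{PE}}$, a strictly decreasing map — give identical |Z| and
identical Kruskal–Wallis $\chi^2$ per compartment. This is a tested
invariant and explains why the reference study reports identical rank
results for the two descriptors.

P-values are reported at full precision in JSON and additionally in the
classical display form (`<0.0001` below $10^{-4}$) in the CSV reports;
significance is flagged at $P \le 0.05$. No multiple-testing adjustment is
applied, matching the reference analysis.

## Reproduction of the reference tables, and its limits

The acceptance suite recomputes every printed inferential statistic from
the packaged per-case data. The comparisons use a relative tolerance of
$10^{-3}$, about twice the Monte-Carlo bound on the drift attainable by
the half-ULP rounding (±0.0005) of the printed per-case inputs. The
outcome splits cleanly:

* Every **nucleus-derived size statistic reproduces essentially exactly**
  (relative agreement ~$10^{-4}$ or better): the nuclear-area ANOVA
  decomposition and F ratio, and all three nuclear-area pooled t values at
  the printed dfs.
* The **cell-area statistics do not**: the recomputed cell-area ANOVA F and
  two of three cytoplasm t values differ from the printed ones by 0.3–1.3%,
  far beyond what input rounding can produce. The printed SCC cell-area
  column is internally inconsistent with the source's own cell-area
  statistics (the leukoplakia-vs-normal comparison, which does not involve
  that column's suspect entries, reproduces to $2.5\times10^{-4}$).
* The **descriptor statistics** (form perimeter, contour index, N:C; ANOVA
  F and Kruskal–Wallis $\chi^2$) differ by 0.2–6%. The pattern — size
  statistics exact, nonlinear-descriptor statistics off by roughly the
  within-case squared coefficient of variation — indicates the source
  derived descriptors per cell and averaged, whereas only per-case mean
  areas and perimeters are printed; a nonlinear descriptor of a mean is
  not the mean of the descriptors. Exact reproduction from the printed
  table is therefore impossible, and the corresponding acceptance
  expectations are left failing by design rather than loosened; the
  recomputed values (all within a few percent) are what
  `scripts/acceptance.R` reports.
* The pairwise Mann–Whitney |Z| values on nuclear form perimeter recompute
  to 4.467 / 4.560 / 1.331 against printed 4.46 / 4.56 / 1.36 — two of
  three at the printed precision.

One reference value is printed without a group label: an N:C ratio of
"0.941 ± 0.182". Recomputation identifies it as the leukoplakia group
(0.9412 ± 0.1819); the package exposes per-group N:C summaries rather
than hard-coding the match.

## Numerical choices and degenerate inputs

* Sample SD uses the $n-1$ denominator; 95% confidence intervals use the
  t quantile with $n-1$ df, matching the Student's-t machinery of the
  reference analysis.
* Zero within-group variance (ANOVA), zero pooled variance (t), and
  fully tied samples (rank tests) raise classed degenerate-data errors
  rather than returning NaN.
* Contour extraction of labels that are too small to survive smoothing,
  disconnected, or holed skips the object with a reason; empty masks
  yield empty results, not errors.
* All generator randomness flows from a single integer seed recorded in
  the spec and every manifest; rerunning any stage with the same seed is
  byte-identical. (R's RNG is global; the seed is set at entry of each
  top-level generator operation.)

## Worked example

```{r example}
library(basalmorph)

# reference data: derive descriptors and run the full comparison
rep <- run_full_comparison(table2_fixture())
print(rep)

# synthetic end-to-end: render -> measure -> aggregate -> statistics
res <- run_synthetic_pipeline(default_synthetic_spec(seed = 1))
summarize_groups(res$records, "nuclear_area")

# on-disk pipeline
cmd_simulate("dataset", spec = default_synthetic_spec(seed = 1))
cmd_measure("dataset", "measurements.csv")
cmd_analyze("measurements.csv", "report")
```

## Known limitations

* The measurement estimator is biased at low resolution (objects under
  ~10 px radius) and on sharp corners; it is designed for smooth cellular
  outlines at ≥ ~15 px radius.
* Only per-case inference is implemented; per-cell mixed-effects modeling
  (which the printed reference data cannot support) is out of scope.
* The generator's irregularity-to-shape mapping is second-order and
  heuristic above RMS amplitude ~0.15.
* No real-image segmentation: inputs are labeled masks, not H&E
  photomicrographs.
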