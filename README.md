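# basalmorph

Quantitative morphometry of the basal cell layer of oral epithelium, for
pathologists and image-analysis researchers who want an objective,
reproducible complement to histological dysplasia grading.

The package measures cell and nuclear profiles from integer-labeled mask
images in calibrated physical units, derives the classical morphometric
descriptors, and runs the group-comparison statistics of diagnostic
morphometry across three diagnostic groups (normal buccal mucosa, oral
leukoplakia, well-differentiated squamous cell carcinoma). A published
70-case reference dataset of per-case basal-cell measurements ships with
the package, and a seeded synthetic-histology generator makes the whole
pipeline testable end to end without any external data.

## The descriptors

From cell area *CA* (µm²), cell perimeter *CP* (µm), nuclear area *NA*
(µm²) and nuclear perimeter *NP* (µm), per compartment:

- **Form perimeter** (circularity): PE = 4·c·A / P², with circle constant
  c = π by default (22/7 available; the choice is a global scale and
  cannot affect any test statistic). A circle scores 1.
- **Contour index**: CI = P / √A; 2√π ≈ 3.545 for a circle, larger with
  boundary indentations. Identity: CI² · PE = 4c.
- **N:C ratio**: NA / (CA − NA).

Inference per variable: one-way ANOVA, pairwise pooled-variance Student's
t, pairwise Mann–Whitney U (tie-corrected normal approximation), and
Kruskal–Wallis, all on per-case records, with significance at P ≤ 0.05.

## Worked example

```r
library(basalmorph)
rep <- run_full_comparison(table2_fixture())
print(rep)
```

```
Morphometric group comparison (70 cases, alpha = 0.05)

ANOVA F ratios:
  nuclear_area       F(2,67) =  193.505  P = <0.0001 *
  cell_area          F(2,67) =  240.797  P = <0.0001 *
  nuclear_form_pe    F(2,67) =   27.746  P = <0.0001 *
  cellular_form_pe   F(2,67) =   31.802  P = <0.0001 *
  nuclear_ci         F(2,67) =    9.696  P = 0.0002 *
  cellular_ci        F(2,67) =   18.841  P = <0.0001 *
  nc_ratio           F(2,67) =   22.588  P = <0.0001 *

Kruskal-Wallis:
  nuclear_area       chi2(2) =  50.341  P = <0.0001 *
  cell_area          chi2(2) =  57.950  P = <0.0001 *
  nuclear_form_pe    chi2(2) =  24.875  P = <0.0001 *
  cellular_form_pe   chi2(2) =  24.424  P = <0.0001 *
  nuclear_ci         chi2(2) =  24.875  P = <0.0001 *
  cellular_ci        chi2(2) =  24.424  P = <0.0001 *
  nc_ratio           chi2(2) =  22.561  P = <0.0001 *
```

Reading the output: nuclear and cell area separate the three diagnostic
groups overwhelmingly (F ≈ 194 and 241 on 2/67 df) — size is the
discriminating parameter, increasing from normal mucosa through
leukoplakia to carcinoma. Shape (form perimeter, contour index) and the
N:C ratio also differ overall, but their pairwise tests separate normal
mucosa from the lesions while failing to separate leukoplakia from
carcinoma. Note the rank statistics are identical for form perimeter and
contour index per compartment: the two descriptors are monotone
transforms of each other.

Synthetic end-to-end run (render fields → measure masks → aggregate per
case → statistics):

```r
res <- run_synthetic_pipeline(default_synthetic_spec(seed = 1))
summarize_groups(res$records, "nuclear_area")
#>         group     variable  n     mean       sd      sem ci95_low ci95_high
#> 1      normal nuclear_area 10 26.22809 4.923524 1.556955 22.70602  29.75017
#> 2 leukoplakia nuclear_area 30 58.95339 6.224027 1.136347 56.62930  61.27748
#> 3         scc nuclear_area 30 74.53189 7.637134 1.394344 71.68014  77.38364
```

The recovered group means sit within sampling error of the generative
parameters (27.0 / 59.4 / 74.5 µm²). On-disk equivalents:
`cmd_simulate()`, `cmd_measure()`, `cmd_analyze()`, or the thin CLI at
`inst/cli/basalmorph.R` (`simulate | measure | analyze`).

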