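# petsync

Regional PET quantification, molecular connectivity, and desynchronization
scoring for longitudinal preclinical neuroimaging studies.

## What it is for

Longitudinal small-animal TSPO-PET studies track neuroinflammation across
genotypes (e.g. an amyloidosis knock-in model vs. wild-type), treatment
arms, and scan ages, often paired with amyloid PET and behavioral testing.
`petsync` implements the analysis chain such studies need, for researchers
who have regional uptake tables (or labeled image volumes) and want
reproducible, seed-controlled results:

* **%ID quantification** — `value = 100 · concentration / injected_dose`
  per volume of interest (VOI).
* **Data-driven pseudo-reference selection** — for each candidate region,
  Cohen's d between pooled genotype groups
  (`d = (x̄_KI − x̄_WT) / s_p`, pooled SD with divisor `n − 1`); the region
  with the smallest `|d|` becomes the reference.
* **SUVR** — each scan divided by its own reference uptake; per-scan
  exclusion reporting when the reference is unusable.
* **z-score profiles** — `z = (SUVR − μ_ctrl) / σ_ctrl` per region against
  a wild-type control cohort at a reference timepoint.
* **Molecular connectivity** — interregional Pearson `r` across subjects
  for all VOI pairs, with the Fisher transform `z = atanh(r)`, plus a
  bootstrap ensemble of pairwise OLS line fits on the control cohort
  (resampling subjects with replacement, `B` replicates).
* **Desynchronization index (DI / CDS)** — for subject *s* and pair
  `(i, j)`, the perpendicular distance from `(SUVR_i, SUVR_j)` to the
  control fit `y = b x + a`:

  `d_ij = |b·x − y + a| / √(b² + 1)`,  `DI_i = Σ_{j≠i} d_ij`

  with PC1 composites over cortex and the entorhinal–hippocampus–amygdala
  region (standardized constituents, sign-stabilized scores, explained
  variance reported).
* **Group statistics** — Shapiro–Wilk gating, Mann–Whitney U (exact for
  small untied samples), Kruskal–Wallis H, Benjamini–Hochberg FDR,
  baseline-vs-percent-change regression, pooled regional TSPO–amyloid
  z-score coupling, and per-arm behavior correlation.
* **Synthetic cohorts** — a seed-deterministic generator emulating the full
  study design (two genotypes, four arms, three timepoints, correlated
  regional uptake, treatment-attenuated progression, per-arm
  desynchronization, tracer coupling, a behavior link, and scan
  missingness), so every stage is testable by parameter recovery.

All user-facing functions take a long-format table
(`subject_id, genotype, arm, age_months, tracer, voi, value, unit`) first
and return tibbles, so calls chain with the pipe; fitted objects have
`tidy()` / `glance()` methods and plots come from `autoplot()` /
`plot_trajectories()`.

## Worked example

```r
library(petsync)
library(dplyr)

cohort <- generate_cohort(synth_config(seed = 1))
screen <- select_pseudo_reference(cohort$uptake)
screen
#> <effect_size_report>
#>   candidates: 22  tracer: TSPO
#>   timepoints: pooled
#>   selected:   periaqueductal_gray (d = -0.023)
```

The screen compared all 22 regions and picked the candidate whose pooled
genotype effect size is nearest zero — the region least touched by disease,
hence usable as a pseudo-reference (`|d| = 0.023`; truly affected regions
in this cohort run `d ≈ 1`).

```r
suvr <- compute_suvr(filter(cohort$uptake, tracer == "TSPO"),
                     screen$selected_reference)
controls <- unique(suvr$subject_id[suvr$genotype == "WT" &
                                     suvr$age_months == 10])
atlas <- default_atlas()
targets <- setdiff(atlas$target_vois, screen$selected_reference)

fits <- bootstrap_pair_fits(suvr, controls, B = 1000, seed = 1,
                            timepoint = 10, vois = targets)
di <- compute_di(suvr, fits, timepoint = 10)
pc <- composite_pc1(di, atlas$composites$cortex, "cortex")
pc
#> <composite_pc1> cortex
#>   72 subjects, 10 constituents, PC1 explains 97.4% of variance
```

Each subject's DI sums, per region, its perpendicular distances to the 190
control-cohort line fits; the cortical PC1 compresses the ten cortical DIs
into one score per subject (97.4% of their variance is shared — the DIs
move together).

```r
metric <- rename(tidy(pc)[c("subject_id", "score")], metric = score)
filter(behavior_correlation(metric, cohort$behavior), genotype == "KI")
#> # A tibble: 4 × 7
#>   genotype arm      slope r_squared   p_value     n degenerate
#>   <chr>    <chr>    <dbl>     <dbl>     <dbl> <int> <lgl>
#> 1 KI       Ab/PL  -2.09     0.761   0.0000470    14 FALSE
#> 2 KI       Ab/Pio -0.324    0.165   0.0678       21 FALSE
#> 3 KI       PL/PL   0.136    0.0355  0.602        10 FALSE
#> 4 KI       PL/Pio -0.0861   0.00512 0.834        11 FALSE
```

Time in the water-maze target quadrant falls with cortical
desynchronization only in the antibody arm (slope −2.09 s per score unit,
R² = 0.76); the other arms sit at noise level — exactly the arm-specific
link this cohort was generated with.

The same chain runs end to end with output files and a digest manifest:

```r
run_pipeline(run_config(seed = 1), "out/")   # writes uptake.csv, effect_sizes.csv,
                                             # connectivity_*.csv, desync.csv,
                                             # stats_*.csv, manifest.json, ...
```

or from a shell via the thin wrapper
`inst/scripts/petsync run --seed 1 --out out/`.

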