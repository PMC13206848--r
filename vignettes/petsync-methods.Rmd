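---
title: "Regional PET quantification and desynchronization scoring: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional PET quantification and desynchronization scoring: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsync)
library(dplyr)
```

## The problem

Longitudinal small-animal PET studies of neuroinflammation follow two
genotypes (an amyloidosis knock-in model, `KI`, and wild-type controls,
`WT`) across treatment arms and scan ages, with a TSPO tracer reporting
microglial activation and an amyloid tracer reporting plaque load. Beyond
mean regional uptake, microglial activation is regionally *synchronized* in
healthy brains: uptake across regions co-varies tightly across subjects.
Disease degrades this synchrony. `petsync` implements the full quantitative
chain needed to measure both phenomena:

1. **Quantification** — percent injected dose (`%ID`), a data-driven
   pseudo-reference screen, standardized uptake value ratios (`SUVR`), and
   control-referenced z-score profiles.
2. **Connectivity** — interregional Pearson correlation matrices with the
   Fisher r-to-z transform, and a bootstrap ensemble of pairwise line fits
   on a control cohort.
3. **Desynchronization** — a per-subject, per-region connectivity deviation
   score (the desynchronization index, DI) measured against the control
   ensemble, aggregated into composite scores by PCA.
4. **Group statistics** — rank-based contrasts with FDR control,
   baseline-versus-change regression, pooled regional tracer coupling, and
   per-arm behavior correlation.
5. **Synthetic cohorts** — a generative model of the whole design, so every
   stage is testable by parameter recovery without any animal data.

## Quantification

`%ID` is `100 * concentration / injected_dose` per region, a
normalization-free measure. Ratio measures need a reference region that the
disease does not touch; rather than assuming one, the screen
(`select_pseudo_reference()`) compares pooled `WT` and `KI` `%ID`
distributions in every candidate region by Cohen's d (pooled-SD form,
sample variances with divisor `n - 1`) and selects the region with the
smallest `|d|`. Ties break lexicographically by region name so results are
reproducible. Two open choices are resolved as follows and exposed as
arguments:

* The screen pools all timepoints by default (`timepoint =` restricts it):
  pooling uses all evidence about genotype insensitivity and is the default
  a screening step should have.
* The magnitude `|d|`, not the signed value, defines "smallest effect":
  a large negative genotype effect makes a region just as unusable as a
  large positive one.

`compute_suvr()` divides each scan by its own reference uptake; the
reference region maps to 1. A scan whose reference value is missing or
non-positive is excluded *per scan* (not per animal) and reported in an
`excluded_scans` attribute — silent dropping would bias longitudinal
analyses. `compute_zscores()` standardizes against a control cohort at a
reference timepoint (default: the latest, where controls are most numerous
in this design); earlier scans reuse the same control statistics so that
z-scores are comparable across ages. The control cohort must have at least
three subjects and nonzero SD in every region.

## Connectivity and the desynchronization index

The interregional correlation matrix is the Pearson correlation of two
regions' uptake across subjects (molecular connectivity, not intraclass
correlation). Subjects with incomplete profiles are dropped listwise.
`fisher_z()` is `atanh` with inputs at `|r| >= 1` clipped to magnitude
`1 - 1e-7` under a warning, so downstream arithmetic never sees infinities.

The DI asks: how far does one subject sit from the control cohort's
pairwise uptake relationships? For every region pair, `bootstrap_pair_fits()`
resamples the control subjects with replacement `B` times (default
`B = 1000`, seed exposed) and fits ordinary least squares of the
higher-indexed region on the lower-indexed one (atlas order fixes the
orientation; the perpendicular distance used afterwards makes the score
nearly orientation-insensitive, and the orientation rule is recorded in the
ensemble). Replicates that leave a predictor without variance are redrawn a
bounded number of times; fully degenerate control data is an error. The
consensus fit is the mean of the replicate coefficients (median by flag).

For each subject and pair `(i, j)`, the perpendicular distance from the
subject's `(SUVR_i, SUVR_j)` point to the consensus line is
`|b x - y + a| / sqrt(b^2 + 1)`; the DI of region `i` sums the distances of
its `V - 1` pairs. Whether distances should be taken against the consensus
fit or averaged across replicate fits is not determined by the method's
definition; both are implemented (`method = "consensus"` default,
`"replicate"` behind the flag) and coincide as `B` grows. DI is reported raw
and normalized by the pair count (`di_norm`), the latter comparable across
atlases. DI is computed at the final timepoint by default — the age at
which the control cohort is scanned in this design — and any timepoint can
be selected.

Composite regions (whole cortex; the entorhinal–hippocampus–amygdala
aggregate) are summarized by the first principal component of the
subject-by-constituent DI matrix. Constituent DIs are standardized before
the decomposition (correlation-matrix PCA) because DI scale varies with a
region's uptake range; raw-scale PCA is available via
`standardize = FALSE`. The eigenvector sign is arbitrary, so scores are
oriented to correlate positively with the mean constituent DI; flipping the
raw eigenvector can never change reported scores.

## Group statistics

Distributions are gated by Shapiro–Wilk at `alpha = 0.05`
(`shapiro_gate()`; a constant vector is reported `non_normal` with a flag,
since the test is undefined there). Contrasts use Mann–Whitney U
(exact enumeration when the smaller group has at most 8 observations and no
ties; otherwise the tie-corrected normal approximation) and Kruskal–Wallis
H with tie correction. Families of p-values are adjusted by
Benjamini–Hochberg FDR; family boundaries are configuration (one family per
result panel), not constants, because different analyses group their
contrasts differently. Degenerate regressions (zero variance in predictor
or response) return a flagged result rather than `NaN`.

Two analyses need care in interpretation and are flagged in their output:
percent change from baseline is regressed *on* baseline (denominator =
baseline), which is mathematically coupled to the predictor; and pooled
regional coupling fits one line through all subject-by-region z-score
points, which are not independent within subject. Both are labeled
descriptive, and no between-arm slope test is offered for the behavior
correlations.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. Its defaults mirror the structure of a two-genotype, four-arm
(placebo, antibody, pioglitazone, combination), three-timepoint (5, 7.5,
10 months) dual-tracer design with arm sizes 8/8 (WT) and 10/14/11/21 (KI),
twenty target regions and two reference candidates.

For subject `s`, region `v`, age `t` (TSPO tracer):

```
value = exp( lambda_v * ( sqrt(1 - delta_s) F_s + sqrt(delta_s) G_sv )
             - lambda_v^2 / 2 )
        * ( base_v + A_s [s is KI] (offset_v + slope_v m_arm (t - t0)) )
      + noise_v eps
```

* `F_s ~ N(0,1)` is a shared activation factor entering as a log-normal,
  mean-one multiplicative scan scale (`lambda_v = 0.25`). A multiplicative
  factor is what tracer delivery and global activation differences produce;
  it cancels exactly in reference ratios, and — unlike an additive factor of
  the magnitude the observed between-animal heterogeneity requires — it can
  never drive a reference region's uptake toward zero and blow up SUVR.
* `G_sv ~ N(0,1)` is idiosyncratic. The mixing weights
  `sqrt(1 - delta)` / `sqrt(delta)` preserve the log-scale variance for any
  `delta` in `[0, 1]`, so desynchronization degrades covariance without
  changing scale: `delta = 0` is full synchrony, `delta = 1` full
  independence. `delta` applies to target regions only — a region
  insensitive to the disease process is also spared its desynchronization,
  which is exactly why it can serve as a reference.
* `A_s` is a log-normal, mean-one per-subject pathology amplitude
  (`amp_sigma = 0.8`) scaling the genotype effect of *both* tracers. It
  produces the large interindividual spread of `%ID` genotype contrasts
  (Cohen's d near 1 alongside a ~70% mean difference requires an SD of the
  order of the effect) and carries subject-level coupling between the
  tracers.
* `offset_v` (baseline KI elevation) and `slope_v` (KI increase per month)
  give each region its disease profile; treatment multiplies the slope
  (`m_arm` = 1 / 0.45 / 0.70 / 0.50), emulating the attenuation of
  longitudinal progression by the three active arms. Reference regions have
  zero offset and slope.

Amyloid-tracer values share the regional genotype profile through a per-arm,
per-age coupling strength `kappa` (plus a regionally flat KI elevation, a
log-normal scan factor of its own, and noise); wild-type amyloid signal is
pure noise around its baseline. The behavior score (time in target
quadrant, seconds) is `intercept_arm + beta_arm * proxy + noise`, where the
proxy is the amplitude-scaled idiosyncratic displacement
`A_s (1 + sqrt(delta_s) RMS(G over cortex))` — the generative quantity the
realized cortical DI responds to. By default only the antibody arm has a
nonzero (negative) `beta`, with `beta = -4` and a residual SD of 2.5 s
chosen so the arm's DI–behavior coupling lands in the strong range reported
for this kind of design (R² around 0.6 at n = 14).

Scan missingness is completely at random per (subject, tracer, timepoint)
with per-timepoint rates; acquisition interruptions in practice are
logistics-driven, not outcome-driven. A subject never loses all scans at
baseline, and rates of 0.95 and above are rejected because the baseline
guarantee becomes vacuous. All randomness flows from one integer seed with
a fixed draw order, so equal configurations produce byte-identical cohorts;
missingness uses an offset seed so it is reproducible independently of the
generation draws.

**What the generator does not emulate.** Voxel-level images, scanner
physics, partial-volume effects, and decay correction are out of scope. The
generator reproduces treatment effects as attenuated longitudinal slopes;
it does not reproduce a globally elevated `%ID` level specific to the
antibody arm, which would require arm-specific offsets outside this model.
Real uptake distributions are skewed and bounded; the model's Gaussian
noise is clamped at a small positive floor (0.01 %ID) to respect
positivity, a truncation that matters only in extreme tails. Passing
recovery tests therefore demonstrates that the pipeline measures what the
model generates — not that real data satisfy the model.

## Numerical and interface choices

* Sample SDs and variances use divisor `n - 1` throughout.
* Correlations at `|r| >= 1` are clipped before `atanh` (warning attached).
* Effect-size ties break lexicographically; the bootstrap redraw budget is
  100 per replicate.
* Degenerate inputs fail loudly: zero pooled variance (Cohen's d), zero
  control SD (z-scores), zero-variance regions (connectivity, PC1),
  complete ties (Kruskal–Wallis), empty groups.
* Uptake CSVs are written with 12 significant digits — a fixed point of
  write–parse–write, so round trips are byte-stable while staying far below
  measurement precision.
* `run_pipeline()` computes stage dependencies in memory but writes only
  the requested stages; `manifest.json` records the configuration and an
  MD5 digest per output, and identical configurations reproduce identical
  digests. Stage failures abort with the failing stage named.

## Validation sizes

The test suite validates parameter recovery at the sizes the methods are
designed for: desynchronization recovery on cohorts of 20–30 subjects per
arm with 20 regions and `B = 200` bootstrap replicates across 10–20 seeds;
pseudo-reference recovery with 25 subjects per genotype across 40 seeds;
null calibration of the FDR-adjusted contrast family on 200 simulated
no-effect cohorts; and exact brute-force equivalence of the DI for small
atlases (up to 6 regions). The geometry of the perpendicular distance is
checked against numeric minimization on 1,000 random instances.

## Known limitations

DI is a covariance-based score: it responds to any displacement from the
control pattern, including overall pathology burden, and is not by itself
evidence about which cell population drives the signal. The pooled coupling
analysis mixes within- and between-subject variation and is reported as
descriptive. The pseudo-reference screen can select either reference
candidate (or, in unlucky small-sample draws, a weakly affected target
region); the effect-size report exists precisely so that this choice is
inspectable, and the pipeline records it in every manifest.
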