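---
title: "Models and methods in chromamyelin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chromamyelin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromamyelin)
```

## What the package models

Absolute pitch (AP) is the ability to name the chroma of a tone — its
octave-equivalent pitch class — without a reference. chromamyelin
implements the full computational chain of a study relating AP ability to
intracortical myelination measured by quantitative R1 (qR1 = 1/qT1, in
s^-1, higher with more myelin) sampled on the cortical surface:

1. behavioral scoring of an AP naming test with octave-error correction;
2. conversion and smoothing of surface-sampled qR1 maps;
3. vertex-wise general linear models (GLM) with nuisance covariates and
   random-field-theory (RFT) cluster-level inference;
4. a Monte-Carlo assessment of how reliably the group effect can be
   estimated under an ethnicity-confounded recruitment design;
5. synthetic-data generators for all of the above, so every stage can be
   exercised and validated end to end without acquired data.

Surface reconstruction, depth sampling and template registration are out
of scope: per-vertex maps are consumed already vertex-correspondent on a
template mesh.

## Behavioral scoring

Each trial presents one of 72 targets (36 pure tones spanning C3–B5, 36
piano tones spanning E3–D#6, twelve-tone equal temperament with A4 =
440 Hz) and records key presses within a 4 s window. The first press
later than 100 ms after onset is the trial's response; a first press at
or before 100 ms is treated as a late response to the *previous* trial
and discarded (it never overwrites that trial's already-recorded
response); trials with no usable press are timeouts. "Later than 100 ms"
is read strictly: a press at exactly 0.100 s is not valid.

Errors are measured in semitones. The absolute error AE is
`|target - response|` on the MIDI scale. The octave-corrected error
folds the difference of the two chromas (`midi mod 12`) into the range
-5..+6: differences up to 6 are kept, larger ones are wrapped by an
octave, and the tie at 6 maps to +6. Its absolute value, the absolute
corrected error (ACE), is the circular semitone distance between the two
chromas, with maximum 6. The AP score is

$$\mathrm{APS} = 1 - \bar m / 6,$$

where $\bar m$ is the mean ACE. A perfect responder scores 1; a
uniformly random responder scores exactly 0.5, because the mean circular
distance over all chroma differences is 3 (this is enumerable over the
144 ordered chroma pairs and is frozen into the tests).

Two measures need a convention the source material leaves open:

* **Hit rate.** "Errors up to one semitone count as a hit" is applied to
  the *corrected* error by default (`hit_on = "ace"`), because high hit
  rates coexist with large raw AE in AP musicians whose errors are
  mostly octave displacements. `hit_on = "ae"` gives the raw-error
  reading.
* **Octave-error rate.** A valid answer with correct chroma but a
  different key; the denominator is the valid answers of the given
  timbre.

Group comparisons use Welch's t by default (`var_equal = TRUE` for the
pooled Student variant; which variant the original analysis used is not
stated) and a pooled two-proportion z for binary variables.

## qT1 to qR1 and search masks

`qt1_to_qr1()` computes 1000/qT1 (ms to s^-1) and winsorizes to
[0.25, 10] s^-1, the physically plausible cortical range (qT1 between
100 and 4000 ms). Bounding rather than exclusion keeps the mesh intact;
bound events are counted and reported. Nonpositive qT1 is marked invalid
with a warning.

Statistics are computed over a search mask built from a vertex
parcellation (`build_search_mask()`), mirroring the exclusion of ventral
parcels and the medial wall in 7 T data where signal drops out. All
downstream quantities — GLM maps within the mask, cluster extents, resel
counts — ignore excluded vertices entirely, and the tests verify that
arbitrary values planted outside the mask cannot change any result.

## Smoothing to a target FWHM

Maps are smoothed by `n_iter` iterations of a Gaussian-weighted local
average. Each iteration uses kernel width
$\sigma_\mathrm{it} = \mathrm{FWHM} / (2\sqrt{2\ln 2}\,\sqrt{n_\mathrm{iter}})$,
so the composed kernel approximates the target FWHM (variances of
composed Gaussians add). Two numerical choices matter:

* **Kernel support.** The per-iteration kernel is supported on the
  geodesic ball of radius $3\sigma_\mathrm{it}$ (neighbourhoods found by
  bounded graph search, distances Euclidean at these scales). A kernel
  restricted to the immediate 1-ring cannot work here: on a mesh with
  0.77 mm edges the largest variance a single 1-ring averaging step can
  add is $h^2/2 \approx 0.3$ mm$^2$, so ten such iterations compose to at
  most ~4 mm FWHM regardless of the weights — an 8 mm target in 10
  iterations forces multi-ring support. The $3\sigma$ truncation retains
  98.9% of the kernel mass and ~95% of its variance; the realized FWHM,
  measured from the spatial autocorrelation of smoothed white noise, is
  ~7.8 mm for the 8 mm target, and the test suite requires [6.5, 9.5] mm.
* **Mass conservation.** The kernel matrix is Sinkhorn-balanced against
  the barycentric vertex areas (one third of incident triangle area per
  vertex): a diagonal scaling makes the symmetric kernel's row sums equal
  the vertex areas, after which one smoothing step preserves constants
  *and* area-weighted mass exactly (to floating point), on any mesh and
  under any mask. Masked vertices are excluded from the kernel support
  and the remaining weights renormalized — smoothing happens within the
  mask, which is one of the two defensible orderings of masking and
  smoothing; the alternative (smooth, then mask) leaks boundary values
  inward.

The empirical-FWHM estimator (`estimate_map_fwhm()`) pools pair
correlations over distance bins and fits the Gaussian autocorrelation
$\rho(d) = \exp(-d^2/4\sigma^2)$; pairs are centered per vertex across
realizations, not per map across space, because spatial mean-removal
biases long-range correlations downward. A residual-based smoothness
estimator (`estimate_smoothness_resid()`, from along-edge variances of
standardized residuals) is provided as the alternative input to the
resel computation.

## Vertex-wise GLM and RFT cluster inference

For each vertex, ordinary least squares with a shared design matrix:

* `ap`: qR1 ~ 1 + age + sex + ethnicity + AP (17 subjects, 5 columns,
  df 12);
* `aps`: the AP indicator replaced by the continuous, timbre-averaged
  APS (the two timbres' APS values are nearly collinear, so the average
  is used; a per-timbre analysis is a trivial variant);
* `ap_europeans`: the European subset with the constant ethnicity column
  dropped (12 subjects, df 8);
* `ap_fdt`: `ap` plus -log10(FDT), the log frequency-discrimination
  threshold (df 11).

Binary codings are sex female = 1, ethnicity Asian = 1, AP = 1 — these
affect only signs. The effect is the contrast of the coefficient vector;
the implementation is QR-based and the tests require agreement with
explicit normal equations to 1e-8 relative on a thousand random small
instances.

Cluster inference thresholds the t map at the upper 0.001 quantile of
t(df) (strictly greater; ties are subthreshold), takes connected
components under 1-ring adjacency within the mask, and measures extent
as summed barycentric vertex area. The RFT model standardizes the search
region by the smoothness: the 2D resel count is area/FWHM², the boundary
contributes perimeter/(2 FWHM), and the topology a constant term. With
the unified t-field EC densities $\rho_d(u)$, the expected cluster count
is $E[N] = \sum_d R_d\,\rho_d(u)$ and a cluster of extent $s$ resels
gets the family-wise corrected p-value

$$p = 1 - \exp\{-E[N]\, e^{-s/E[S]}\}, \qquad
  E[S] = R_2\,\rho_0(u)\,/\,E[N],$$

the standard exponential approximation to the cluster-extent
distribution in two dimensions. By default the smoothness entering the
resels is the nominal applied FWHM (8 mm); the residual-based estimate
can be substituted (`smoothness = "residual"` in `run_study()`). Whether
the original toolbox used residual-based estimation is unknown; the
nominal choice is reproducible and, on these synthetic data, the two
agree to well within the test tolerances.

Per-layer, per-hemisphere analyses are *not* corrected across the
layer-by-hemisphere families, matching per-family reporting;
`bonferroni_families = TRUE` provides the stricter alternative.
Contrasts are directional (the default reports the positive direction;
both directions can be run). Empirically, on 500 null simulations at the
study's own conditions the fraction of datasets with any significant
cluster is close to, and bounded by, the nominal 0.05 (the acceptance
suite recomputes this).

## Synthetic data: what it emulates, and what it does not

`simulate_subject_table()` reproduces the cohort structure: 9 non-AP and
8 AP musicians, all non-AP European, the AP group 3 European / 5 Asian
(so the Europeans-only model has n = 12 and df 8), sex balanced within
group, ages uniform on 20–32 years with the two groups' age
distributions matched by interleaving the sorted draws — the study
recruited matched groups, and unmatched random draws occasionally
produce covariate imbalance (and contrast-variance inflation) that a
matched cohort would never contain. APS is drawn high (~0.92) for AP and
near chance (~0.51) for non-AP; -log10(FDT) is Gaussian per group around
the printed group statistics.

`simulate_qr1_dataset()` builds per-subject maps as: a smooth low-order
polynomial baseline around 0.65 s^-1 (a statistical stand-in for the real
myelination pattern — deliberately not anatomically realistic), additive
covariate terms, a group effect confined to a geodesic disc, a subject
random intercept, and i.i.d. vertex noise, bounded to [0.25, 10] s^-1.
Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| effect size | 0.017 s^-1 | anchored to the reported peak group effects (0.0169/0.0171 s^-1) |
| disc radius | 9 mm | large enough that 8 mm smoothing attenuates the peak by < 6% |
| vertex noise SD | 0.033 s^-1 | calibrated so the realized peak t matches the reported peak t(12) ≈ 6.6 after smoothing |
| subject intercept SD | 0.003 s^-1 | global per-subject variation unreduced by smoothing |
| covariate effects | -5e-4 (age), 3e-3 (sex), 2e-3 (ethnicity) | small relative to baseline, same order as the group effect |

The smoothing-noise algebra behind the calibration: 8 mm smoothing
reduces i.i.d. vertex noise SD by the factor
$\sqrt{a_v / (4\pi\sigma_\mathrm{tot}^2)} \approx 0.063$
($a_v$ = vertex area), so the per-subject map SD at a vertex is
$\sqrt{(0.033\cdot0.063)^2 + 0.003^2} \approx 0.0037$ s^-1, and the
contrast SE with the ethnicity-confounded design is about
$0.7 \times 0.0037 \approx 0.0026$ s^-1, giving an expected peak
t ≈ 6.5.

`simulate_behavior()` generates key-press logs: timeouts, correct chroma
with stated probability, otherwise a wrapped-geometric error over the
nonzero offsets -5..+6 (one dispersion knob, matching the broad
near-octave scatter seen in non-AP responders), octave displacement with
a per-timbre probability (defaults 0.6 pure / 0.15 piano, mirroring the
reported imbalance), truncated-lognormal reaction times in (0.1, 4] s,
and occasional sub-100 ms echo presses to exercise the validation rules.

Passing tests on these data demonstrate the *statistical* machinery —
calibration, recovery, invariances — not robustness to anatomy,
registration error, B1 bias or any other MR-physics artifact, none of
which the generator attempts to emulate.

## Design-reliability simulation

The recruitment design confounds ethnicity with group (all Asians are in
the AP group). The simulation quantifies what that costs when estimating
the group effect. Per replicate it draws ages, sexes, an ethnicity
effect $\gamma \sim N(0, \sigma_\gamma)$, and noise; generates the
scalar response from the additive model; and refits by OLS, recording
the relative error of the group coefficient. Three scenarios at n = 17:

* **balanced** — ethnicity split as evenly as 9 + 8 allows (3 + 3
  Asian): baseline sampling error;
* **actual** — the study's composition: ethnicity stays estimable but
  collinear with group (variance inflation factor ≈ 1.9, so the SD of
  the relative error grows by ≈ 1.37);
* **worst** — ethnicity identical to group: the full model is singular,
  so the model is fit *without* the ethnicity regressor and the whole
  ethnicity effect lands in the group estimate.

Drawing the ethnicity effect per replicate (rather than fixing it) is
the modelling choice that makes "worst" costly in the right way: with a
fixed effect, omission shifts only the mean; with an uncertain effect,
the worst case inherits its full variance,
$\mathrm{SD}_\mathrm{worst} = \sqrt{\mathrm{SD}_\mathrm{bal}^2 +
(100\,\sigma_\gamma/\beta_\mathrm{AP})^2}$, while the balanced and
actual designs estimate it away. Defaults ($\beta_\mathrm{AP} = 0.0169$,
noise SD 0.0033, $\sigma_\gamma = 0.0032$ s^-1, chosen by this algebra
before any simulation was run) put the three SDs near 10%, 14% and 22% —
the ordering balanced < actual < worst is the validated property; exact
SD values are not, since the original simulation's procedure is
unpublished.

## Problem sizes and numerical conventions

The validation suite runs at sizes chosen to make the statistical
properties measurable while keeping a full run in tens of seconds per
component: a 40 x 40 mm equilateral patch at 0.77 mm edges (~3.2k
vertices) for smoothing, calibration and recovery; 500 null simulations
for the family-wise error rate; 100 seeds for planted-effect recovery;
5000 replicates per reliability scenario. Other conventions: corrected
errors tie-break to +6; suprathreshold means strictly greater than the
threshold; vertex areas are barycentric thirds; smoothing iterations
compose exactly (k then k' equals k + k' at matched per-iteration
width); all generators are pure functions of (parameters, seed).

## Known limitations

* Meshes are synthetic (icospheres, flat patches); no reader for binary
  surface formats is included — geometry interchange is plain-text OFF
  and per-vertex CSV.
* RFT p-values use the nominal smoothness by default; residual-based
  estimation is available but not the default.
* The extent-distribution approximation degrades below df 3 (flagged on
  the report).
* The reliability simulation is a declared reinterpretation of an
  unpublished procedure, validated by ordering and convergence
  properties only.
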