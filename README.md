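# chromamyelin

Absolute pitch (AP) is the rare ability to name the chroma of a tone — its
octave-equivalent pitch class — without any reference. chromamyelin is an R
package for studies that relate AP ability to intracortical myelination
measured with quantitative MRI: it scores AP naming tests with octave-error
correction, prepares surface-sampled quantitative R1 maps (qR1 = 1/qT1,
s⁻¹, increasing with myelin content), fits vertex-wise general linear
models over a cortical mesh, performs random-field-theory (RFT)
cluster-level inference, and quantifies by Monte Carlo how reliably a group
effect can be estimated under an ethnicity-confounded recruitment design.
Synthetic-data generators for meshes, cohorts, vertex maps and trial-level
key-press logs make the whole chain runnable and testable end to end
without any acquired data.

It is intended for auditory-neuroscience and surface-based-morphometry
researchers who want the scoring rules, the smoothing, and the cluster
inference as reusable, tested components rather than toolbox scripts.

## The statistics at the core

**Behavioral scoring.** For target and response chromas (MIDI index mod
12), the octave-corrected error folds their difference into −5..+6
semitones (differences ≤ 6 kept, larger ones wrapped by an octave; the tie
at 6 maps to +6). With mean absolute corrected error m̄, the AP score is

    APS = 1 − m̄ / 6,

which is 1 for perfect chroma naming and exactly 0.5 for uniformly random
responses. Sessions are validated with a 4 s response window and a strict
100 ms floor (earlier first presses are late responses to the previous
trial).

**Surface GLM + RFT.** At every vertex of a masked mesh, OLS of smoothed
qR1 on an intercept, age, sex, ethnicity and the AP term (group indicator,
continuous APS, or −log10 frequency-discrimination threshold). Maps are
smoothed by iterated mass-conserving Gaussian diffusion to a target FWHM
(default 8 mm in 10 iterations). The t map is thresholded at p = 0.001,
connected components become clusters, and each cluster of extent s resels
gets the family-wise corrected p-value

    p = 1 − exp(−E[N] · exp(−s / E[S])),

with E[N] the expected cluster count from the unified t-field
Euler-characteristic densities over the region's resels (area/FWHM² plus
boundary and topology terms) and E[S] the expected extent per cluster.

**Design reliability.** Replicated generate-and-refit of the group model
under three n = 17 designs — ethnicity balanced across groups, the actual
confounded composition, and ethnicity identical to group — reporting the
mean ± SD of the relative error of the group-effect estimate.

## Worked example

Score one simulated AP test session:

```r
library(chromamyelin)
prof <- behavior_profile(chroma_accuracy = 0.93, chroma_error_sd = 1.5,
                         octave_error_rate = c(pure = 0.6, piano = 0.15))
events  <- simulate_behavior(prof, subject = "S01", seed = 42)
session <- validate_session(events)
score_session(session)
#> AP performance for 'S01' (hit on ACE <= 1)
#>  timbre n_valid mean_ae mean_ace octave_error_measure octave_error_rate   aps
#>    pure      36    7.92   0.1389                 7.78             0.556 0.977
#>   piano      36    3.00   0.0000                 3.00             0.250 1.000
#>     all      72    5.46   0.0694                 5.39             0.403 0.988
#>  hit_rate mean_rt
#>     0.972    1.64
#>     1.000    1.76
#>     0.986    1.70
```

The raw error (`mean_ae`, 7.9 semitones for pure tones) is dominated by
octave displacements: after octave correction the error collapses to 0.14
semitones and the AP score is 0.98 — the signature of an AP musician who
names chroma nearly perfectly but frequently misses the octave, more so
for the unfamiliar pure-tone timbre (octave-error rate 0.56 vs 0.25).

Run the surface analysis on a synthetic study with a planted 0.017 s⁻¹
group effect, then the reliability simulation:

```r
subjects <- simulate_subject_table(seed = 1)
mesh     <- make_mesh("flat_patch", target_edge_mm = 0.77, size = 40)
dataset  <- simulate_qr1_dataset(mesh, subjects, seed = 2)
run_study(dataset, models = c("ap", "aps"))
#> study_result: 2 run(s), cluster-defining p 0.001, FWER 0.05
#>      run id n_vertices area_mm2 peak_t peak_vertex extent_resels    p_fwer
#>  data.ap  1        179    91.91  5.178        1195         1.436 1.152e-06
#>  peak_effect  peak_se
#>      0.01281 0.002474

reliability_summary(reps = 5000, seed = 3)
#>             label    mean_pct   sd_pct misspecified reps
#> balanced balanced  0.01594232 10.35170        FALSE 5000
#> actual     actual -0.10487488 14.20410        FALSE 5000
#> worst       worst -0.82907690 22.08381         TRUE 5000
```

The group contrast recovers the planted cluster (peak t(12) = 5.2,
corrected p ≈ 1e-06) overlapping the planted disc; at this seed the
continuous-APS contrast finds no surviving cluster, which is the expected
behavior near the detection margin. The reliability table shows the cost
of the confounded design: the spread of the relative error grows from
±10% (balanced) to ±14% (actual composition) to ±22% when ethnicity is
perfectly aligned with group and must be dropped from the model.

`run_demo(seed = 1)` chains all stages — behavior, scoring, confusion
matrices, GLM + RFT, reliability — and writes CSV tables plus a markdown
report to an output directory.

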