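# rsindex

Cohort-relative resilience-to-stress scoring from multichannel
psychophysiological recordings.

## The problem

During a phased stress test — a baseline (calibration) phase, alternating
stressor and recovery phases — five physiological channels are recorded
continuously: trapezius electromyography (EMG, µV), blood volume pulse
(BVP, relative %), rib-cage breathing (BR, relative %), skin conductance
(SC, µS) and fingertip peripheral temperature (PT, °C). Under stress
EMG, SC and BR rise, PT falls and BVP is altered. How far a subject's
physiology is pushed away from baseline, and how fully it returns after the
final stressor, carry information about that person's resilience to stress.

`rsindex` treats each phase as a cluster of points in a 15-dimensional
feature space (five preprocessed channels plus their lag-1 and lag-2
differences) and measures baseline-relative phase separation `D(i)` with
four methods:

| Method | Separation measure |
|---|---|
| `ED-PCA` | Euclidean centroid distance in full-rank PCA space (after a Yeo-Johnson power transform) |
| `MD` | mean Mahalanobis distance of phase-i samples to the baseline centroid, under the pooled-pair covariance |
| `CVID` | mean silhouette of the phase pair under a Mahalanobis metric |
| `ED-KPCA` | Euclidean centroid distance in RBF kernel-PCA space (1-Hz downsampled) |

Two cohort-normalized indices are derived per subject and method:

- **Resilience to Stress Index** — `RSI_k = ΔR_k / ΔS`, where
  `ΔR_k = D_k(4) − D_k(5)` is the signed recovery between the last stressor
  phase and the last recovery phase, and `ΔS = max_j ΔR_j` over the cohort.
  The cohort's best recoverer scores exactly 1; a negative RSI means the
  subject ended the test farther from baseline than during the last stressor.
- **Alteration Factor** — `AF_k = (SubMaxS_k − SamMinS) / ΔSamST`, the
  subject's maximum baseline-relative stretch `SubMaxS_k = max_i D_k(i)`
  rescaled to [0, 1] over the cohort.

A statistical validation workflow (Anderson-Darling normality gate,
Pearson/Spearman correlation against questionnaire resilience totals,
tie-corrected Friedman comparison across methods) and a synthetic cohort
simulator with ground-truth recovery parameters complete the toolkit. Both
indices are *relative to the analyzed cohort* by construction — they are not
absolute scores.

## Worked example

Simulate a six-subject cohort (10-minute protocol, reduced 64-Hz rate for a
quick run; real recordings are 256 Hz) and score it:

```r
library(rsindex)
protocol <- default_protocol()   # 5 x 120 s: baseline, stressor, recovery, stressor, recovery
cohort  <- simulate_cohort(6, master_seed = 42, protocol = protocol, fs = 64)
indices <- compute_cohort(cohort$recordings, protocol,
                          rsi_config(methods = c("MD", "ED-PCA")))
indices[, c("subject_id", "method", "D4", "D5", "delta_r", "rsi", "af")]
```

```
   subject_id method   D4    D5 delta_r     rsi    af
1        S001     MD 4.05 3.706  0.3467  0.8356 0.000
2        S001 ED-PCA 4.52 0.482  4.0378  0.9432 0.155
3        S002     MD 4.04 4.109 -0.0645 -0.1555 0.487
4        S002 ED-PCA 5.40 2.998  2.4041  0.5616 0.858
5        S003     MD 4.13 4.135 -0.0072 -0.0174 1.000
6        S003 ED-PCA 5.58 2.548  3.0287  0.7075 1.000
7        S004     MD 4.05 3.669  0.3789  0.9130 0.434
8        S004 ED-PCA 4.34 0.427  3.9138  0.9142 0.000
9        S005     MD 4.06 3.650  0.4150  1.0000 0.361
10       S005 ED-PCA 4.48 0.201  4.2811  1.0000 0.116
11       S006     MD 4.08 4.071  0.0102  0.0247 0.382
12       S006 ED-PCA 5.43 3.659  1.7679  0.4130 0.878
```

Subjects S001/S004/S005 were simulated with high recovery fractions
(ρ = 0.93/0.94/0.98) and score the highest RSI under both methods; S002 and
S006 (ρ = 0.26/0.12) fail to return to baseline — S002's RSI is negative.
The AF column tracks the simulated stress-shift magnitude instead (S003 and
S005 received the largest shifts). Checking parameter recovery:

```r
sel <- indices$method == "MD"
spearman_cor(indices$rsi[sel], cohort$truth$rho)$estimate
#> 0.829   (rises above 0.9 at the full 256-Hz rate and n = 20; see tests)
```

Validation against questionnaire totals uses `resim_validation()`, which
gates each method through an Anderson-Darling normality test and then
applies Pearson or Spearman correlation accordingly.

A command-line pipeline mirrors the R API:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rsindex.R", package = "rsindex"))')" \
    simulate --n 20 --seed 1 --output-dir sim/
# ... compute --input-dir sim/ --output-dir results/
# ... validate --indices results/indices.csv --resim scores.csv --output report/
```

## Documentation

The methods vignette (`vignettes/resilience-index.Rmd`) describes the model,
every tunable parameter, what the simulator does and does not emulate, and
the numerical conventions (kernel-size rule, edge handling, covariance
regularization, tie handling).
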