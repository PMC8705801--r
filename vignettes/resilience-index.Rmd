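---
title: "Methods: cohort-relative resilience scoring from phased biosignal recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-relative resilience scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsindex)
```

## The measurement model

A phased psychophysiological stress test records five channels —
electromyography (EMG, µV), blood volume pulse (BVP, %), breathing (BR, %),
skin conductance (SC, µS), peripheral temperature (PT, °C) — at a common
sampling rate (256 Hz for the reference instrument) across an ordered
protocol of phases: one baseline (calibration) phase and alternating
stressor / recovery phases, by default five phases of 120 s. The modelling
assumption throughout is that *within a phase* the preprocessed samples form
a cluster in feature space, and that the displacement of each phase's
cluster from the baseline cluster quantifies how strongly the subject's
physiology was perturbed at that point of the test.

The package computes, per subject, a baseline-relative separation
$D(i)$ for every non-baseline phase $i$, and reduces these to two
cohort-normalized indices:

$$\mathrm{RSI}_k = \frac{\Delta R_k}{\Delta S}, \qquad
  \Delta R_k = D_k(4) - D_k(5), \qquad \Delta S = \max_j \Delta R_j,$$

$$\mathrm{AF}_k = \frac{\mathrm{SubMaxS}_k - \mathrm{SamMinS}}{\Delta\mathrm{SamST}},
  \qquad \mathrm{SubMaxS}_k = \max_{i \ge 2} D_k(i),$$

with $\mathrm{SamMinS}$ and $\Delta\mathrm{SamST}$ the cohort minimum and
range of the stretches. Both indices are relative to the cohort: the best
recoverer has RSI = 1, the least/most altered subjects have AF = 0 and 1.

**Why the signed difference for $\Delta R$.** A literal distance between
the phase-4 and phase-5 centroids is non-negative and could never produce
the negative resilience scores that non-recovering subjects must receive.
We therefore define $\Delta R$ as the *baseline-referenced* signed
recovery $D(1\to4) - D(1\to5)$: positive exactly when the final recovery
phase sits closer to baseline than the final stressor phase did, negative
when the subject drifted further away. The raw inter-centroid distance
$d(c_4, c_5)$ remains available as a diagnostic but plays no role in the
index.

## Preprocessing

Processing order is fixed: **trim → median filter → standardize →
(PCA paths only) Yeo-Johnson → re-standardize**.

- **Start-up trim** (`trim_seconds`, default 0.5 s): biofeedback hardware
  shows an offset transient at acquisition start. The trim is bookkept in
  `t0_offset` and deducted from phase 1 only — the phase timeline stays
  anchored at the original $t = 0$, since the transient is an acquisition
  artifact, not a protocol shift.
- **Median filter**: kernel $w = \mathrm{round}(n / (4 f_s))$, incremented
  to odd ($w = 151$ for the canonical 10-min, 256-Hz recording). The
  formula is our reading of a garbled printed rule; it is pinned by the
  only numeric anchor available (151). Edges are handled by symmetric
  reflection, chosen over zero padding so no artificial level step leaks
  into baseline statistics. Even→odd correction rounds *up* (150 → 151).
- **Standardization**: $z = (x - a)/s$ with the population ($N$-divisor)
  standard deviation — the standard-scaler convention; immaterial at
  $n \approx 10^5$ but fixed for reproducibility. Fitted per subject over
  the *whole* recording (phases pooled), never per phase: all phases of a
  subject must share one coordinate system or inter-phase distances are
  meaningless.
- **Yeo-Johnson power transform** (PCA paths): $\lambda$ fitted per channel
  by profile maximum likelihood on $[-5, 5]$, then re-standardized. Applied
  to the five channels *before* differencing, over all phases pooled.
- **Downsampling** (CVID and kernel-PCA paths): per-second block medians,
  computed phase-by-phase so no block straddles a phase boundary; a
  trailing partial block is aggregated over the samples available. A mean
  aggregator is selectable (`aggregator = "mean"`) and is the default for
  the phase-1-vs-5 correlation analysis, which is specified on per-second
  means.

## Features

Each channel $x$ contributes three columns: $x(t)$, $x(t)-x(t-1)$ and
$x(t)-x(t-2)$ — 15 features in all. The lag differences add short-range
temporal dependence that per-sample clustering would otherwise discard. The
first two rows (undefined differences) are dropped rather than padded:
fabricating values would bias the baseline cluster, and the loss (2 of
~153k samples) is negligible. Phase windows are half-open,
$[\lfloor t_0 f_s \rfloor, \lfloor t_1 f_s \rfloor)$, with 0-based sample
indexing, so boundary samples are never double-counted.

## The four separation methods

- **ED-PCA** — full-rank (15-component) PCA fitted per subject on the
  pooled full-rate samples; $D(i)$ is the Euclidean distance from the
  baseline centroid to the phase-$i$ centroid in component space. With all
  components retained the PCA map is orthogonal, so these equal raw-space
  centroid distances (a tested identity); the PCA is kept for its
  decorrelation diagnostics (explained variance per component).
- **MD** — for the pair (baseline, phase $i$): covariance estimated from
  the pooled rows of the two phases; the mean Mahalanobis distance of each
  *phase-$i$* row to the baseline centroid. Averaging over phase-$i$ rows
  only (not the baseline rows as well) is a deliberate resolution of an
  ambiguity: the quantity of interest is phase $i$'s displacement, and
  pooling baseline rows would mix in baseline self-scatter; the pooled
  alternative stays available via `instances = "pooled"`. When the
  covariance condition number exceeds $10^{10}$ (differenced columns can be
  near-collinear) a ridge of $10^{-6}\,\mathrm{tr}(\Sigma)/p$ is added to
  the diagonal and flagged in the diagnostics.
- **CVID** — the mean silhouette $s = (b-a)/\max(a,b)$ of the two-cluster
  labelling, with distances Mahalanobis under the pooled-pair covariance.
  Computed on the 1-Hz block-median rows (120 points per phase by default):
  the silhouette is $O(n^2)$ in distances, and the per-second scale mirrors
  the compute-saving convention used by the kernel path. Scores live in
  $[-1, 1]$; 0 means overlapping phases.
- **ED-KPCA** — kernel PCA on the 1-Hz rows. The kernel is unspecified
  upstream, so the default is RBF with the median-heuristic bandwidth
  ($\gamma = 1/(2\,\mathrm{med}^2)$ over pairwise distances) and 15 retained
  components for parity with ED-PCA; both are configurable and recorded in
  the run manifest. With a linear kernel and all components the method
  reduces exactly to ED-PCA (a tested identity).

All model fits (PCA, kernel PCA, power transform) are per subject — cohort
quantities enter only through the index normalizers.

**A structural note on MD.** Because the pooled-pair covariance contains
the between-phase mean separation $\Delta$, the normalized separation
saturates: $m = d/\sqrt{1 + d^2/4} \le 2$, where $d$ is the separation
under the noise metric. MD is therefore sensitive in the
overlapping-cluster regime ($d \lesssim 2$) and deliberately
magnitude-compressing beyond it. This is also why the alteration factor —
a magnitude measure — is better read from ED-PCA distances, which are
linear in physical displacement; the package's parameter-recovery tests
pair RSI with MD and AF with ED-PCA accordingly.

## Statistical validation

- **Anderson-Darling** (case 3, parameters estimated): the unadjusted
  $A^2$ is reported as the statistic; the p-value uses the
  $(1 + 0.75/n + 2.25/n^2)$ adjustment with the D'Agostino–Stephens
  interpolation. This exact variant was pinned by reproducing published
  statistic/p pairs to all printed digits.
- **Coefficient gate**: per method, Pearson is used only when *both* the
  RSI vector and the questionnaire vector pass the AD gate at $\alpha$;
  otherwise Spearman (average ranks on ties; exact permutation p for
  $n \le 8$ tie-free, $t$ approximation otherwise). The gate is computable
  only from the data at hand — when reproducing a published table whose
  gate was decided on unrounded values, the per-method `coefficient`
  override forces the published assignment. With $n < 5$ the gate cannot
  run and Spearman is used with a warning.
- **Friedman test** across methods: within-subject average ranks (rank 1 =
  smallest), classic chi-square statistic with tie correction, plus a
  median / median-absolute-deviation / mean-rank summary per method. No
  multiple-testing correction is applied anywhere; p-values are reported
  raw.
- **Phase-1 vs phase-5 correlations**: per channel, Spearman between the
  per-second aggregated baseline and final-recovery series, paired by
  within-phase position (second $k$ against second $k$) — the only pairing
  under which a correlation is well defined. Unequal lengths (e.g. after
  trimming) are truncated to the shorter with a logged warning.

## The synthetic cohort

The simulator generates what the pipeline consumes, not physiology in
detail. Each channel is a phase-dependent mean trajectory plus Gaussian
noise; BVP and BR additionally carry sinusoidal oscillators (≈1.2 Hz
cardiac, ≈0.25 Hz respiratory); sparse single-sample spikes emulate the
movement artifacts the median filter exists to remove. Phase transitions
are 2-s linear ramps — peripheral temperature in particular cannot jump —
which also exercises boundary handling. Ground truth per subject is the
recovery fraction $\rho$ (recovery-phase mean = baseline +
$(1-\rho) \cdot$ shift) and a shift-scale multiplier.

Default parameters (channel-native units):

| channel | baseline | noise sd | stress shift |
|---|---|---|---|
| EMG (µV) | 4 | 1.5 | +1.0 |
| BVP (%) | 45 | 5 | −4.0 |
| BR (%) | 50 | 5 | +4.0 |
| SC (µS) | 2 | 0.5 | +0.4 |
| PT (°C) | 18 | 0.5 | −0.4 |

Baselines follow the instrument's typical relaxed measures. The shifts put
each channel's stress response at roughly 0.7–0.8 of its within-phase
spread (total multivariate separation $d \approx 1.5$). This is the
*overlap regime* that real recordings exhibit — real-cohort silhouette
medians are near zero and phase clusters overlap visibly in PCA plots — and
it is also the regime in which a pooled-covariance Mahalanobis metric
retains rank information (see the saturation note above). A separable-world
simulator (shifts of tens of noise sds) would look nothing like the
instrument's output and would make MD-based indices degenerate.

What the simulator does **not** emulate: pulse waveform morphology and
heart-rate variability spectra, respiratory sinus arrhythmia, electrodermal
drift and discrete SCR events, sensor quantization. A green
parameter-recovery test therefore establishes that the pipeline recovers
*mean-shift/recovery structure* under realistic noise, oscillations and
artifacts — not that it handles every property of field recordings.

## Numerical conventions and degenerate inputs

- Missing values are fatal everywhere, never imputed: the pipeline assumes
  complete uniform streams.
- Constant series cannot be standardized or power-transformed (error).
- `compute_rsi` requires at least one recovered subject (max $\Delta R > 0$);
  `compute_af` requires a non-degenerate spread of stretches. Ties at the
  cohort extremes all receive the extreme value (1, or 0/1 for AF) — the
  formulas are well defined under ties and need no tie-break.
- Normalizers are computed per method, never pooled across methods.
- Spike artifacts, ridge events and truncated pairings surface as
  diagnostics/warnings; seeds and fitted settings (kernel size, bandwidth)
  are recorded in the run manifest for bit-reproducible reruns.

## Known limitations

- Both indices are cohort-relative; scores are not comparable across
  cohorts with different normalizers.
- The silhouette path subsamples to 1 Hz by default; full-rate CVID is
  configurable but quadratic in cost.
- The baseline "self-distance is zero" identity holds for the centroid
  methods (ED-PCA, ED-KPCA) by construction; for MD the per-point mean
  necessarily includes self-scatter (≈ the mean of a $\chi_{15}$
  distribution for well-conditioned data), so MD profiles have a positive
  floor — differences, not levels, carry the signal.
- Test-retest properties, sensor placement effects and non-default
  protocols with multiple baselines are out of scope.
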