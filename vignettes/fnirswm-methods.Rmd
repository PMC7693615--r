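---
title: "Models and methods behind fnirswm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fnirswm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirswm)
```

`fnirswm` re-implements, as a tested pipeline, the complete analysis of an
acute-exercise / working-memory fNIRS experiment: a synthetic-data generator
whose ground truth is known, the channel-space preprocessing chain from raw
optical intensity to block-averaged haemoglobin difference, behavioral
scoring via the rate-correct score, region-of-interest pooling over a
fronto-parietal montage, and the inference stage. This vignette explains the
models, the defaults, and the design choices that were genuinely open.

## The experiment being modelled

Two groups of healthy older adults (experimental, n = 19; control, n = 23;
ages ~64–79, mean 69.18 ± 3.92 years) perform a letter n-back task at four
time points: before an intervention and 15, 30 and 45 minutes after it. One
session contains 6 task blocks of 45 s (two blocks per load condition:
0-back, 1-back, 2-back; 15 trials each, exactly 5 targets per block), with
27 s rests between consecutive blocks — 405 s (6:45 min) in total. A trial is
500 ms of stimulus, a 1500 ms response interval, and a uniform 800–1200 ms
onset jitter, i.e. 3000 ms on average. During the task, a 38-channel
dual-wavelength (760/850 nm) fNIRS montage samples at 3.47 Hz over the
fronto-parietal working-memory network; 6 channels fall outside the regions
of interest and are excluded, leaving 18 frontal (DLPFC + VLPFC) and
14 parietal (IPL + SPL) channels.

## The forward model of the simulator

The generator builds per-channel chromophore concentration time series and
maps them to raw intensities through the *forward* modified Beer–Lambert
relation, so that the analysis chain can be validated as the exact inverse:

* **Evoked component.** The block design (all six blocks, with relative load
  weights 0.4 / 0.7 / 1.0 for 0-/1-/2-back) is convolved with a canonical
  double-gamma HRF (6 s peak, 16 s undershoot, undershoot ratio 1/6 — the
  field's convention; the curve is normalised to peak 1 so an amplitude
  parameter is interpretable directly). Evoked ΔO2Hb peak amplitudes default
  to 1.1 (frontal) and 2.0 (parietal) in molar × 10⁻⁸, constant over groups
  and time points, reflecting the parietal-dominant activation and the
  absence of group/time effects in the haemodynamic results being emulated.
  Evoked ΔHHb is −1/3 of ΔO2Hb (canonical anticorrelation; configurable).
* **Amplitude structure.** Per-participant sub-ROI effects are log-normal
  (σ = 0.3 on the log scale) with a compound correlation of 0.8 between
  sub-ROIs, mirroring the strong between-region correlations that justify
  pooling. Per-channel log-normal gains (σ = 0.4) spread amplitude *within*
  a sub-ROI but are normalised to mean 1, so the sub-ROI mean amplitude
  carries the configured correlation. (Because the effects are log-normal,
  the recoverable Pearson correlation is the log-normal-attenuated value,
  ≈ 0.79 for ρ = 0.8 and σ = 0.3.)
* **Physiological noise**, injected in the concentration domain: cardiac
  (~1 Hz, amplitude 0.75), respiratory (~0.3 Hz, 0.3), Mayer waves (~0.1 Hz,
  0.4), very-low-frequency drift (~0.004 Hz, 1.0) and white noise (SD 0.2),
  all in molar × 10⁻⁸, with small random frequency jitter and random phases;
  HHb noise is scaled by 0.3. The cardiac term is what the channel quality
  check looks for.
* **Motion artifacts**, injected in the optical-density domain: one-sample
  spikes (rate 0.005 /s, amplitude ~0.01 OD) and baseline steps persisting
  to the end of the recording (rate 0.002 /s, ~0.005 OD) — the two artifact
  archetypes wavelet filtering targets.
* **Optics.** ΔOD(λ) = (ε_HbO2(λ)·ΔHbO + ε_HHb(λ)·ΔHHb) · d · DPF with
  d = 3 cm and the age-dependent differential pathlength factor
  DPF = 4.99 + 0.067·age^0.814 (807 nm formula, applied to both wavelengths;
  per-wavelength override possible). Extinction coefficients are the
  Gratzer/Prahl literature values. Intensity is I = I₀·exp(−ΔOD) about a
  constant per-channel baseline I₀ = 1 — OD is relative, so the scale is
  immaterial.

The behavioral generator draws, per trial, omissions, premature keypresses
(RT < 200 ms) and correctness from the cell's configured probabilities, and
response times from a log-normal (CV 0.25) truncated at the 2000 ms window.
The default accuracy/RT cells for 2-back reproduce the published group ×
time sample statistics; 0-/1-back cells are near-ceiling values typical of
those loads. A separate generator (`simulate_rcs_cohort`) draws rate-correct
scores directly from published cell means and standard errors with a
compound-symmetric within-subject correlation — see below.

## The preprocessing chain

Stage order is fixed and enforced: OD → quality check → wavelet motion
correction → band-pass → Beer–Lambert inversion → block averaging → channel
outlier filter → HBdiff.

* **Optical density** is −ln(I/Ī) with Ī the channel's temporal mean
  (HOMER convention; the log base is a documented package choice).
* **Cardiac quality check.** A channel passes if the Welch power spectrum of
  its 850 nm OD series has a peak in the 0.5–1.6 Hz band exceeding 3× the
  median broadband power. The published criterion ("a cardiac peak around
  1 Hz") is qualitative; the band and factor are this package's defaults and
  both are parameters. On clean simulated data with cardiac noise present
  the drop rate is 0.
* **Wavelet motion correction.** Per channel and wavelength a Daubechies-2
  DWT is taken; at each detail level, coefficients outside
  [Q1 − 0.1·IQR, Q3 + 0.1·IQR] are zeroed and the transform inverted. Two
  numerical choices are ours: (i) the transform uses *periodization*
  boundary handling — the even-length periodized db2 transform is
  orthonormal, so reconstruction is exact to machine precision and the
  inverse is simply the adjoint; output length always equals input length.
  (ii) The decomposition depth is chosen so that every detail level lies
  *above* the 0.01–0.08 Hz analysis band (approximation cut-off kept above
  0.1 Hz by default). Deeper decompositions put evoked energy into detail
  levels with very few coefficients, where the quartile rule degenerates and
  the evoked response itself gets clipped; with the default depth the
  correction is transparent to the haemodynamic band and acts on broadband
  transients, which is the artifact model it targets. A consequence worth
  stating plainly: one-sample spikes are removed very effectively (>80%
  deviation reduction in tests), while the low-frequency content of large
  baseline *steps* survives the correction and is only attenuated by the
  high-pass stage; catastrophically shifted channels are expected to be
  caught by the QC and z-outlier stages instead.
* **Band-pass.** Fifth-order high-pass at 0.01 Hz and third-order low-pass
  at 0.08 Hz, each applied forward–backward (zero phase — causal filtering
  would shift block-average latencies). Edge transients at such low
  normalised cut-offs are suppressed by mean removal and odd-reflection
  padding before filtering. The filters follow the closed-form Butterworth
  magnitude |H(f)|² = 1/(1 + (f/f_c)^{2n}) per pass.
* **Beer–Lambert inversion** solves the 2×2 system per sample with the same
  extinction table and DPF as the forward model; output in molar × 10⁻⁸.
  ΔHbT = ΔO2Hb + ΔHHb and ΔHBdiff = ΔO2Hb − ΔHHb hold exactly at every
  stage by construction.
* **Block averaging** extracts −2…45 s epochs around block onsets (closed on
  the left, open on the right, in samples), subtracts each epoch's −2…0 s
  baseline mean, and averages within condition. The scalar per-channel
  summary used downstream is the mean of the baseline-corrected average over
  0–45 s (the peak is available as an alternative); the summary statistic is
  a package decision — the source analysis never states one.
* **Channel outlier filter.** Summaries are z-standardised across channels
  within condition × time point; |z| > 3.29 (the two-sided 99.95% normal
  quantile) marks a channel as excluded from pooling.

A note on amplitude fidelity: the 0.01–0.08 Hz band-pass itself attenuates
the periodic block response (~8% at the block-average peak for this design) —
that is a property of the published filter, not an implementation error. The
package's recovery tests therefore compare pipeline output against the
ground-truth concentrations passed through the same band-pass; on that basis
the chain recovers evoked ΔO2Hb and ΔHHb peaks to well under 5% with noise
disabled, and block-average peaks correlate with true amplitudes at r > 0.9
under the default noise model.

## Behavioral scoring

The first two trials of every block are discarded (in 2-back they are
necessarily non-match trials), leaving 26 analysable trials per condition
and time point. Premature responses (RT < 200 ms) and omissions count as
errors. The rate-correct score is

RCS = n_correct / Σ RT over all responded trials (s),

i.e. correct responses per second of responding. Omissions contribute to
neither numerator nor denominator (they are non-responses); premature
keypresses are responses, so their RTs enter the denominator — both readings
follow the definition literally and are configurable. Participants whose
pretest 1-back correct count falls below the Binomial(26, 0.5) 99% quantile
(19 of 26, i.e. 73%) are excluded at the participant level; RCS values with
|z| > 3.29 within a condition × time point cell are excluded cell-wise.

## ROI pooling

Channels are pooled hierarchically: channel → sub-ROI (DLPFC/VLPFC/IPL/SPL ×
hemisphere, unweighted mean) → region × hemisphere (mean of the two sub-ROI
means) → hemisphere. Pooling sub-ROI *means* rather than a flat channel mean
matters when channel counts differ (5 vs 4 in frontal sub-ROIs); the flat
mean is available as a configuration switch. Dropped channels are omitted
from means, never imputed; empty cells propagate as missing.

## Inference

* **Mixed repeated-measures ANOVA** (`mixed_rm_anova`): one between-subjects
  factor, up to three within-subjects factors, balanced complete cases
  (incomplete subjects are listwise-deleted with a message). Sums of squares
  come from the classical univariate strata partition; with unequal group
  sizes this equals Type II sums of squares (and Type I/III coincide with it
  on balanced designs). For every within effect, the Greenhouse–Geisser ε is
  estimated from the pooled within-group covariance of orthonormal contrast
  scores; Mauchly's test is reported, and GG-corrected p-values are reported
  whenever ε < 1 rather than conditionally on Mauchly, with both p-values
  available. Effect sizes are generalized eta squared,
  η²_ges = SS_effect / (SS_effect + Σ SS_error over all strata). Under the
  null with true sphericity the GG-corrected test is mildly conservative —
  the known cost of the correction.
* **Planned contrasts**: within each group, paired t of each follow-up
  against pretest, Bonferroni over the per-group family of three
  (configurable). Zero-variance differences are flagged degenerate, not
  silently reported.
* **Welch pairwise comparisons** of cell means (subject replicates averaged
  first) with Satterthwaite degrees of freedom, Bonferroni over the pair
  family.
* **Forced-entry regression**: OLS with all predictors entered at once;
  unstandardized B, standardized β (from complete-case sample SDs), t, p per
  predictor, model F/df/p and adjusted R². The MMSE-like covariate enters
  raw (unstandardized), as nothing suggests otherwise.

## The published-statistics cohort and what it shows

`simulate_rcs_cohort()` draws per-subject RCS vectors from the published
2 × 4 cell means and standard errors (SD = SE·√n at the published group
sizes) with a compound-symmetric within-subject correlation ρ = 0.8. That
value was fixed a priori as typical for repeated cognitive performance
measures, and it is also the value implied by the published time-effect
F statistic together with the cell SDs (back-solving the within-subject
error variance gives ρ ≈ 0.80). Under these conditions, each element of the
published result pattern — a significant time main effect, significant
experimental-group pre→post15 and pre→post45 contrasts, no significant
control-group contrasts — reproduces in a clear majority of simulated
cohorts; their *conjunction* occurs in about half of cohorts, which is what
the printed effect sizes genuinely support.

Problem sizes in the test-suite and acceptance runs are the package's own
choices: 5-recording cohorts for amplitude recovery, 1000 replicates for the
type-I calibration, 100 cohorts for the pattern study, 200 participants for
correlation-recovery checks.

## What the simulator does not capture

Synthetic recordings have stationary sinusoidal physiology with random
phases, channel-independent noise, and idealised artifact archetypes. Real
fNIRS data have non-stationary physiology, spatially correlated superficial
contamination (no short-separation channels exist in this montage), scalp
coupling that drifts within a session, and motion artifacts of mixed shape.
Passing the recovery tests therefore demonstrates internal consistency of
the chain — the inverse model matches the forward model and the statistics
are calibrated — not field performance on arbitrary real recordings.
Likewise, the group-level fNIRS results of the emulated study (a region main
effect only) depend on undeposited raw data and are represented in the
generator's defaults rather than re-estimated.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(n_per_group = c(experimental = 6, control = 6), seed = 1)
report <- run_pipeline(cfg)
as.data.frame(report$rcs_anova)[, c("effect", "df_num", "df_den",
                                    "F", "p_gg", "ges")]
report$rcs_contrasts
```
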