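---
title: "Methods: synthetic ground truth and analysis models in cardiochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ground truth and analysis models in cardiochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiochron)
```

## Scope

`cardiochron` implements the computational core of a cross-sectional
cardiac-aging comparison between laboratory mice and naked mole-rats (NMR,
*Heterocephalus glaber*): ECG rhythm and interval analysis with
irregular-beat screening, systolic/diastolic function metrics, dobutamine
stress-response deltas, and cross-sectional age-trend statistics. Because
studies of this kind typically do not deposit raw recordings, every analysis
stage is exercised against a synthetic-data module with analytic ground
truth; the generators are first-class, tested code, not fixtures.

## The synthetic ECG model

Each beat is a sum of five Gaussians (P, Q, R, S, T), the standard
construction for synthetic ECG, chosen because wave landmarks are then
analytic. A wave with amplitude $a$ (mV), center $c$ (ms from the R peak)
and width $\sigma$ (ms) contributes $a\,e^{-(t-c)^2/2\sigma^2}$. Ground-truth
conventions:

* wave onset/offset $= c \mp 2\sigma$;
* QRS onset $=$ Q onset, QRS offset $=$ S offset, so the true QRS duration
  is well defined;
* PQ $=$ QRS onset $-$ P onset; PR $=$ R peak $-$ P onset. Both
  atrio-ventricular conventions are reported because published figures
  quote both without defining either.

Species defaults encode anesthetized physiology: mice at 550 bpm with a
~9.4 ms QRS, NMRs at 240 bpm with a ~12.6 ms complex, breathing rates of 65
and 45 breaths/min (the middle of the anesthesia maintenance ranges of
50–80 and 40–50), and a sinusoidal respiratory R-R modulation of 3% depth —
a plausible anesthetized value, not a measured one. Beat-to-beat white R-R
jitter defaults to 1%. The three limb leads are projections of three wave
groups (P, QRS, T) through a fixed $3\times3$ weight matrix with lead I
strongest, matching the convention that rodent rhythm strips display lead I.
A `qrs_ms` target rescales the whole ventricular group (Q, R, S and T)
proportionally — a slower complex slows repolarization timing with it —
and the default P-wave position tracks cycle length across heart rates so
that the pre-P baseline segment stays isoelectric.

One user seed drives three independent substreams (R-R process, event
placement, measurement noise), so raising the noise level never perturbs
beat placement, and equal seeds give bit-identical recordings.

**Premature beats.** The taxonomy is atrial (APB: preserved P, normal QRS),
ventricular (VPB: absent P, QRS widened by 2.5 by default) and junctional
(JPB: absent P, normal QRS). The coupling interval is drawn uniformly from
0.5–0.65 of the mean R-R — comfortably below the 0.70 screening threshold,
as real premature beats are — and the post-event pause is fully
compensatory for VPB (flanking intervals sum to twice the mean R-R) and
resetting for APB/JPB, the textbook electrophysiology defaults; source
studies do not describe event timing, so these kinetics are generator
conventions. Event probabilities must sum to at most 0.2 per beat: beyond
that the clean-template averaging assumption of the analysis breaks down.

**What the generator does not emulate.** Baseline wander, electrode motion
artifacts, T-wave alternans, rate-dependent morphology change within a
recording, and non-white noise. Passing tests therefore demonstrate
correctness of the algorithms under controlled morphology and calibrated
noise, not robustness to every artifact of bench recordings.

## ECG analysis

**R-peak detection** is an energy detector in the Pan–Tompkins family
scaled to rodent rates: zero-phase band-pass (2nd-order Butterworth,
20–250 Hz), squaring, 9-ms moving-average envelope, an adaptive threshold
at 25% of the median height of the strongest envelope peaks (the strongest
~2 per second are R peaks for any rodent rate), greedy acceptance under a
refractory period of 0.4 times the running median R-R, and refinement to
the band-passed extremum within ±10 ms. Sampling below 500 Hz is rejected:
a mouse QRS of ~9 ms cannot be timed at coarser grids (the generator
default is 2 kHz).

**Irregular-beat screening** flags R-R intervals below 70% or above 130% of
the moving average R-R interval. The moving-average construction is
deliberately pinned down (it is usually left unstated): a centered window
of 11 intervals, excluding the index interval, truncated at the series
edges. Centering avoids biased ratios during rate drift; excluding the
index interval prevents a premature interval from masking itself. Screening
is single-pass — flagged intervals are not removed from neighbours'
averages. A premature beat produces one short and usually one long
interval; consecutive suspect intervals sharing a beat are merged into one
event so each physical event is counted once. The thresholds (0.70/1.30)
and the 100-beat template count are configuration defaults kept bit-equal
to the conventional screening constants.

**Beat averaging** takes the first `n` (default 100) beats whose flanking
intervals are clean, extracts windows spanning $[-0.45, +0.55]$ of the
median R-R centered on R (asymmetric on purpose: more of diastole follows R
than precedes it), and returns the per-sample mean and SD. Residual noise
shrinks as $1/\sqrt{n}$, which the tests verify.

**Interval measurement** defines the isoelectric baseline as the median of
the segment $[-0.40, -0.30]$ of the median R-R before R. QRS onset/offset
are the nearest points flanking R where the baseline-corrected absolute
signal falls below 5% of the R amplitude and stays below for at least 1 ms;
the P peak is the largest absolute deflection between the baseline segment
and QRS onset, with P onset by the same 5% rule applied to the P amplitude.
A P deflection is only accepted above 3 times the baseline noise SD *and*
1% of the R amplitude (the absolute floor keeps wave tails from being
mistaken for atrial activity on noise-free beats); otherwise PR/PQ are
reported missing and QRS is still returned.

A numerical consistency note: the 5% threshold crossing of a Gaussian flank
sits at $\sigma\sqrt{2\ln 20}\approx 2.45\sigma$ from the center, while the
ground-truth onset convention is $2\sigma$, so the measured P onset leads
the defined one by $\approx 0.45\sigma_P$. With the default P widths
($\sigma_P = 2.6$–$2.8$ ms, i.e. P durations of ~10–11 ms, typical for
small rodents) the two conventions agree within 2 ms, which is the
tolerance the test suite enforces; much wider P waves would push the
conventions apart faster than the measurement noise does.

**Premature-beat classification** replaces the manual two-expert
adjudication step with explicit rules, applied to the beat terminating each
short flagged interval: (1) single-beat QRS width above 1.5 times the
template width → VPB; (2) otherwise a P-wave presence score — the maximum
normalized cross-correlation between the template P wave and the beat's
pre-QRS window, searched over 0.6–1.6 times the template PQ interval — of
at least 0.6 → APB, below → JPB. Two details matter in practice. A
premature beat's pre-QRS window rides on the previous beat's T wave, which
at rodent coupling intervals can mimic a P hump; the averaged-beat template
shifted to the previous R is therefore subtracted first (signal-averaged
residual analysis), and the window is quadratically detrended. Second,
segments whose residual amplitude is outside 0.35–3 times the template P
amplitude are not P candidates: shape-only correlation of near-flat noise
is meaningless. Events flagged only for a long pause remain unclassified,
as does everything when fewer than 20 clean beats were available for the
template. The screened heart rate uses non-flagged intervals only.

## Doppler inflow and E/A separability

Transmitral inflow is modelled per cycle as two Gaussian velocity pulses
(E then A) with fixed width $\sigma = 14$ ms; systole occupies a fixed
55 ms, and the pulses sit at 30% and 85% of the remaining diastole. Because
pulse widths are fixed while diastole shrinks with rate, E and A fuse at
high heart rates — the real failure mode of rodent diastolic measurement;
`doppler_fusion_hr()` returns the geometric bound (~527 bpm for the
defaults).

The analysis mirrors the reporting rule that E/A is only quantified when
the peaks are clearly separable, which is operationalized as: in at least
80% of cycles, two peaks each with topographic prominence at least 20% of
the larger and an inter-peak valley at most 80% of the smaller. Cycles are
segmented by autocorrelation period estimation with the cut phase placed at
minimal velocity — level-based gap detection cannot distinguish a deep E–A
valley from the systolic gap. Fused traces return no ratio, ever. In
practice the prominence/valley rule withdraws the ratio somewhat before the
geometric fusion bound (from ~450 bpm for the defaults), which is the
conservative side to err on.

## Function metrics and stress deltas

`function_metrics()` applies the standard identities SV = EDV − ESV,
EF = 100·SV/EDV, CO = SV·HR/1000, nCO = CO/BW; an ESV above EDV is rejected
as a segmentation-error signal rather than silently clamped. Atrial volume
uses the biplane area–length formula $V = \frac{8}{3\pi} A_{2ch} A_{4ch} / L$,
which reproduces the analytic ellipsoid volume exactly under the
area/length mapping; which long-axis length to use when views disagree is
unstated in typical reports, so the shorter of the two is the documented
default and the argument is explicit. LV volumes are accepted as inputs:
the package does not re-derive them from B-mode geometry. Stress deltas are
percent changes from the unstressed baseline per metric, with the rodent
dobutamine protocol constants (1.5 mg/kg intraperitoneal, ~6 min uptake)
carried as metadata. In the pipeline the stressed state is simulated as a
second parameter set (HR and ESV multipliers), not a pharmacokinetic model.

## Cohort generation and age-trend statistics

Outcomes are generated on a z-scored scale,
$y_z = \beta_{age} z + \beta_{age^2} \tilde q + \beta_{sex}\,\mathrm{male} + \varepsilon$,
then mapped to physical units by a configured mean and SD. The quadratic
uses the orthogonalized basis $\tilde q = (z^2-1)/\sqrt2$ (zero-mean,
near-unit variance): published standardized quadratic coefficients can be
large, and on the raw $z^2$ basis they would blow up the outcome range at
the age extremes. Sex is coded female = 0, male = 1. When the residual SD is
unspecified it defaults to $\sqrt{\max(0.04,\,1-\sum\beta^2)}$ so the
marginal variance stays near the configured physical variance. Packaged
default designs carry the study-scale group sizes (mouse 62♀ + 70♂ over
0.25–2.5 years, NMR 48♀ + 72♂ over 2–34 years), ages drawn uniformly over
the range (the real mouse study enrolled discrete age cohorts; uniform ages
are a deliberate simplification that leaves trend estimation harder, not
easier), a linear standardized age effect of 0.48 on mouse QRS duration
among other study-scale standardized effects, and a Poisson arrhythmia count model with
the NMR rate fixed at zero. How a per-recording event rate should scale
with recording length is not defined by the source material, so the count
model is exposed as configuration.

`fit_trend()` z-scores outcome and age and selects among the nested family
{age}, {age, age²}, each optionally + sex, + sex-specific age slopes.
"Smallest model that fits best" is operationalized as forward selection by
nested F-tests at $\alpha = 0.05$ with a fewest-parameters tie-break; AIC
is available as an alternative criterion. This choice is calibrated: under
null outcomes the age term is selected at the nominal 5% rate, and with a
generating $\beta_{age} = 0.48$ at $n = 132$ the mean recovered coefficient
is within ±0.05 and the generating form is selected in ~90% of replicates
(both recomputed by `scripts/acceptance.R`). Published per-panel $\beta$ values
are treated as standardized coefficients; multiple outcomes are fitted
independently with no multiplicity correction, mirroring per-panel
reporting.

`wilcoxon_test()` is exact (full enumeration distribution) for tie-free
samples when the smaller group has at most 10 observations, and otherwise
uses the normal approximation with tie and continuity corrections; the test
suite verifies exact agreement with an independent brute-force enumeration
over all group sizes up to 7. When every observation is tied the rank sum
carries no evidence and p = 1 is returned directly.

`detectable_change()` implements the two-sample normal-approximation bound
$(z_{1-\alpha/2} + z_{power})\,\mathrm{CV}\sqrt{2/n}$. All assumptions are
arguments: published detectable-change figures of this form (2.4% at
CV 2.9%, ~10/5/4.9% at CVs 12.1/6.1/5.9) are jointly consistent with
$\alpha = 0.05$, power 0.80 and $n \approx 23$, and that is the
configuration the acceptance script reproduces them under.

## Problem sizes and numerical choices

The test suite and acceptance script use 45–300 s recordings at 2 kHz,
500-replicate trend simulations, 1000 seeded R-R series for the screening
oracle, and 100-point parameter sweeps — sizes chosen so the full suite
completes in about a minute while keeping every Monte-Carlo bound
comfortably away from its threshold. Tolerances: detection matches truth
within ±2 ms (four samples at 2 kHz); interval recovery within ±1 ms (QRS)
and ±2 ms (PQ/PR) noise-free, ±2/±3 ms at 20 dB after 100-beat averaging;
E/A recovery within 2%; the biplane identity to 0.1%. Degenerate inputs
(flat signals, constant outcomes, empty samples, ESV > EDV, zero-variance
scales) are rejected with explicit errors rather than propagated.

## Known limitations

* The waveform generator is phenomenological; no ionic or propagation
  modelling, and no image synthesis anywhere.
* Classification thresholds (width ratio 1.5, P score 0.6) were chosen as
  round, defensible defaults and exposed as arguments; they are not fitted
  to expert labels, because none ship with the package.
* The cross-sectional trend machinery deliberately omits longitudinal and
  mixed-effects modelling, survival analysis, and any multiple-testing
  framework beyond documentation.
* QT/ST analysis, atrial-fibrillation detection and tissue-Doppler E′/A′
  are out of scope.
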