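---
title: "abrkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{abrkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrkit)
```

## What the package measures

The auditory brainstem response (ABR) is a scalp-recorded evoked potential
produced in the first few milliseconds after a sound. Its successive
positive deflections — waves I–IV in the mouse — index transmission through
successive brainstem nuclei, so their peak-to-trough amplitudes and
time-to-peak latencies quantify early auditory processing noninvasively.
Three derived measurements matter downstream:

* **Monaural wave metrics.** For a click presented to one ear at a fixed
  level (90 dB SPL by convention), each wave's amplitude is the voltage
  from its peak to the lowest point before the next wave, and its latency
  is the time of the peak. The two ears are measured separately and the
  per-wave metrics averaged per animal.
* **Hearing thresholds.** For tone bursts at 1–46 kHz (and broadband
  clicks), the threshold is the lowest stimulus level at which a response
  is still detectable while descending in 5–10 dB steps; per-frequency
  thresholds form the audiogram.
* **Binaural interaction component (BIC).** If the two ears were processed
  independently, the binaural ABR would equal the sum of the two monaural
  ABRs. It does not: the difference, `BIC = binaural − (left + right)`,
  shows a prominent negative deflection (DN1) aligned with wave IV whose
  amplitude and latency index binaural integration. Sweeping the
  interaural time difference (ITD) over ±2 ms in 0.5 ms steps yields
  DN1-versus-ITD series: in small rodents DN1 amplitude falls and latency
  grows with |ITD|.

The comparison layer mirrors the factorial design used in mouse models of
Fragile X syndrome: sex (female, male) crossed with genotype (wild-type
B6, homozygous/hemizygous Fmr1 mutants, heterozygous females), with litter
type as a nuisance factor and animal as the unit of repeated measurement.

## Recording and preprocessing model

Epochs are 12 ms windows sampled at 97656.25 Hz starting at stimulus
onset. `ceiling(0.012 × fs)` gives 1172 samples with time axis
`t = n / fs`; the count is fixed so tests can be exact. The preprocessing
order is fixed — artifact rejection, averaging, band-pass filtering,
baseline zeroing — and every stage records its settings in the trace's
provenance.

* **Artifact rejection** removes any epoch whose maximum absolute voltage
  strictly exceeds a threshold, the conventional defence against
  heartbeat-scale transients. The default threshold is 5× the median
  absolute deviation of the pooled epoch samples (configurable as an
  absolute voltage); a sample exactly at threshold is kept. If the MAD is
  degenerate (noise-free synthetic sets) nothing is rejected. Rejecting
  every epoch is a distinct, signalled failure rather than an empty
  average.
* **Averaging** is the pointwise mean of the accepted epochs; recordings
  conventionally average 500–1000 repetitions per condition.
* **Filtering** is a second-order 50–3000 Hz Butterworth band-pass applied
  forward–backward (zero phase), because a causal filter would bias the
  latencies that are the core measurement. Two numerical safeguards
  matter at this window length: the 12 ms epoch is shorter than the
  settling time of the 50 Hz edge, so the trace mean is removed before
  filtering (the band-pass's DC steady state is exactly zero), and the
  trace is mirror-padded before the two passes. Mirror padding keeps the
  pad at the signal's own level; an odd (point-reflected) pad would
  acquire a DC offset of twice the edge sample and bleed a slow transient
  into the window.
* **Baseline zeroing** subtracts the full-window mean. There is no
  pre-stimulus segment to prefer — the window starts at stimulus onset —
  and the operation is idempotent and shift-invariant.

Filtering and zeroing commute for this zero-phase filter, and the whole
chain moves noiseless peak latencies by at most one sample (the measured
shift at the defaults is exactly one sample early, from the asymmetric
biphasic waveshape interacting with the 3 kHz edge; quantitative checks
therefore compare detections against truth measured on the identically
filtered noiseless trace — "filter compensation").

## Wave quantification

`detect_peaks()` searches one latency window per wave (defaults: the
generator latencies ±0.6 ms, overlaps truncated at midpoints so windows
are ordered and disjoint) for the most prominent local maximum, with
prominence computed topographically within the window. Ties go to the
earliest candidate, favouring physiological ordering. Candidates below
`min_prominence` leave the wave explicitly missing — never zero-filled —
so missingness propagates honestly into the statistics. The default floor
is 6× the standard deviation of the pre-wave baseline (first 0.8 ms).

The trough for a wave is the minimum between its peak and the next
detected wave's peak; the last detected wave searches a configurable
1.5 ms post-window (there is no wave V bound in this scheme). Amplitude
is peak minus trough, hence non-negative by construction. Manual
overrides (`apply_manual_override()`) move or clear peaks, re-run the same
trough rule, flip `source` to `"manual"`, and refuse edits that break the
strict latency ordering.

`monaural_summary()` averages the per-wave metrics across ears
(metric-averaging, not trace-averaging: the recording convention is
ambiguous between the two, so the alternative — average the two ear
traces, then measure — remains available by summing traces upstream; with
symmetric ears and linear metrics the two agree at high SNR). A wave
present in only one ear falls back to that ear's value and is flagged.

## Threshold estimation

Human visual threshold judgement must be replaced by a stated criterion.
Two detectors share one interface:

* **RMS criterion** (the default surrogate): a response is present when
  the RMS of the trace in the 1–6 ms response window strictly exceeds
  `criterion_multiple` (default 2.0) × a noise floor estimated from the
  lowest-level (subthreshold) trace of the same series.
* **Template cross-correlation** (matched filter): the trace is projected
  onto the unit-normalised suprathreshold trace of the same series
  (default: the highest level). Because noise is integrated coherently
  over the whole window, sensitivity improves by roughly the square root
  of the window length (~22× here).

The distinction matters quantitatively: near threshold, the evoked signal
contributes RMS well below the noise floor of a realistic average, so the
window-RMS statistic cannot respond one 5 dB step above threshold (it
would need signal RMS ≈ 1.7× the noise SD). The matched filter detects
the same condition with a large margin at ordinary averaging depths. The
stochastic threshold-recovery studies in the test suite and acceptance
script therefore run the template detector; the RMS detector remains the
default for interface fidelity and is exact on noiseless data.

`estimate_threshold()` walks a strictly descending level series (steps
must lie in 5–10 dB) and reports the lowest tested level at which
detection succeeds *and* persists at every higher level — monotone
enforcement smooths isolated detector flips the way a human rater
implicitly would. Thresholds are reported as tested levels, never
interpolated. If the top level is undetected the series is "no response".

One consequence of the generative amplitude model (below) is worth
stating: the synthetic response is exactly zero *at* the generative
threshold level, so on noiseless data the estimate lands exactly one step
above the generative value. All recovery checks are therefore phrased as
"within one level step", and group differences (e.g. an injected high-
frequency threshold shift) are recovered exactly when the shift is a
multiple of the step.

## BIC and DN1 extraction

`compute_bic()` is the pointwise subtraction identity. The monaural
traces entering the sum are the monaural *components* of the same ITD
condition — each ear's stimulus delayed by ±itd/2 exactly as in the
binaural presentation — so that the summed and binaural traces align and
the subtraction isolates binaural interaction rather than shift residuals.

`find_dn1()` anchors its search at the wave IV peak of the summed trace,
in a window of ±(1.5 ms + |itd|/2); the widening tracks lateralised
shifts of the wave complex at nonzero ITDs. For the anchor detection on
lateralised summed traces the prominence floor derives from the quiet
tail of the trace (beyond 8 ms) because the early baseline then contains
the shifted wave I. DN1 latency is the argmin of the BIC inside the
window; amplitude is the magnitude of that minimum relative to the zero
baseline. The deflection is absent when the minimum is non-negative or
does not exceed 3× the RMS of the BIC outside the window (plus a 1e-12 aV
guard so an identically zero BIC is absent) — the quantification needs an
explicit absence criterion where a human would simply not mark a wave.

A known, documented bias: baseline-zeroing each parent trace forces every
trace to zero mean, so a one-sided deflection like DN1 acquires a small
positive offset in the subtraction (about 3% of DN1 amplitude at the
defaults). Group contrasts are unaffected (the offset is common to all
groups), latencies are unaffected, and noiseless recovery checks run on
raw traces where the identity is exact.

## The synthetic generator and its truth bookkeeping

Every stage above is validated against a generator whose parameters are
the package's statement of the study conditions:

* **Wave kernels.** Each wave is a Gaussian-windowed biphasic deflection —
  a positive lobe with a trough 2.5 widths later — normalised so its
  peak-to-trough extent equals the stated amplitude. Default latencies
  1.3/2.2/3.1/4.3 ms, widths 0.10/0.10/0.12/0.13 ms, and peak-to-trough
  amplitudes 1.2/0.9/0.7/1.0 aV at the 90 dB click reference. Real mouse
  ABRs constrain only the qualitative morphology (four
  waves inside ~6 ms); these conventions make peak/trough quantification
  well-posed and keep neighbouring-wave crosstalk below 1e-9 aV at the
  peaks (1e-6 aV at the troughs, which sit closer to the next wave).
  Voltage units are arbitrary ("aV") throughout: only ratios are
  meaningful, so the wave IV base of 1.0 aV makes multiplicative effects
  read directly in aV.
* **Level dependence.** Amplitude grows linearly above the condition's
  generative threshold, `A(level) = base × (level − thr)/60`, clipped to
  zero at and below threshold. Linear-above-threshold (rather than
  sigmoidal) growth keeps threshold recovery well-posed; the slope 1/60
  makes the gain exactly 1 at a 90 dB click against the 30 dB click
  threshold, so effect sizes expressed on wave amplitudes are in aV at
  the standard stimulus. Baseline audiogram thresholds are 65/55/45/35/
  30/30/35/45 dB SPL at 1/2/4/8/16/24/32/46 kHz — the mouse's best
  hearing sits at 8–46 kHz.
* **DN1.** A negative Gaussian (width 0.15 ms) at 4.5 ms, magnitude
  0.6 aV at 0 ITD, with amplitude ∝ exp(−|itd|/2 ms) and latency growing
  at 0.1 ms per ms of |ITD| — smooth monotone forms matching the
  qualitative rodent BIC behaviour.
* **Group effects.** A multiplicative wave IV amplitude factor, an
  additive DN1 latency shift applied at 0 ITD only, and an additive
  threshold shift at 32/46 kHz, each keyed by sex:genotype; plus a
  per-animal Gaussian amplitude intercept (default SD 0.1 aV). Defaults
  are null. Morphometrics are drawn per animal (pinna 9×12 mm,
  interpinna 18 mm, nose-to-pinna 22 mm, weight 22 g female / 27 g male,
  the only generative morphology difference being sex in weight).
* **Noise.** White Gaussian background at 1 aV SD per epoch — chosen so a
  500-sweep average has noise ≈ 0.045 aV and the smallest wave a
  single-trace SNR near 15, matching what practitioners see after
  standard averaging — plus heartbeat-like artifacts: with probability
  0.05 per epoch, a slow 20 aV biphasic transient at a random position
  kept fully inside the window (so an artifact always crosses a rejection
  threshold placed between the background and artifact scales, making the
  rejection bookkeeping exact).

`synth_cohort()` realises animals (profiles, litters, morphometrics) and
enumerates every trace with a deterministic per-trace seed, so cohorts of
any size are cheap to hold and byte-reproducible; epochs or averaged
traces are realised lazily. `"trace"` mode draws the averaged trace
directly with noise SD `background/√n_reps`, which is equal in
distribution to averaging artifact-free epochs and is used for
Monte-Carlo studies; `"epoch"` mode exercises the full rejection path.
Generative truth (per-wave latencies/amplitudes on the sample grid,
per-frequency thresholds, per-ITD DN1 latency/amplitude, artifact
indices) is emitted alongside and never altered by analysis.

What the generator does *not* emulate — and what passing tests therefore
do not certify for recorded data: level-dependent latency shifts,
asymmetric or multi-peaked wave shapes, non-Gaussian or correlated
(EEG-like) background noise, ear asymmetries, electrode drift, and any
nonlinearity of binaural summation beyond the single DN1 kernel. The
pipeline's contracts (identities, ordering, monotone enforcement,
missingness handling) hold regardless; its quantitative accuracies are
statements about this generative family.

## Statistics

`fit_mixed_model()` fits
`response ~ sex * genotype * condition + litter + (1 | animal)` by REML
(lme4), with Satterthwaite degrees of freedom for inference (lmerTest).
The observed design has no heterozygous males (the mutation is X-linked),
so the fixed-effect matrix is rank-deficient by construction; the aliased
columns are dropped and all contrasts among observed cells remain
estimable. Singular random-effect fits are flagged, not hidden; rows with
missing responses (absent waves) are dropped, never imputed.

`pairwise_emmeans()` produces estimated-marginal-mean pairwise genotype
contrasts within sex (or sex within genotype), optionally at a fixed
condition level, Tukey-adjusted within each family (matching the ANOVA
post hoc convention) with raw p-values retained alongside. Significance
tiers are `*` <0.05, `**` <0.01, `***` <0.0001. `anova_two_way()` handles
the morphology responses with sex × genotype ANOVA and Tukey HSD.

Simulation checks calibrate the layer: with 8 animals per group, a 30%
wave IV deficit (−0.3 aV) in one female genotype is recovered within 2 SE
with power ~1; under null effects the focal unadjusted contrast rejects
at ≈5%; and a +0.2 ms DN1 latency shift at 0 ITD is recovered within one
sample from the full pipeline.

## Problem sizes and numerical choices

The shipped studies use: 500 averaged traces for wave-assignment
fidelity, 200 level series (at 400-sweep averaging) for threshold
recovery, 200 pure-noise traces for the false-detection rate, 100
replicate cohorts of 8 animals per group for each statistical scenario,
and a demonstration cohort of 2 animals per group at 30 epochs per
condition for the end-to-end determinism check. These sizes give the
Monte-Carlo rates two-digit stability while keeping a full run in the
low minutes on one core.

Tie-breaks and degenerate inputs are all stated conventions: equal
prominence → earliest peak; sample exactly at rejection threshold →
accepted; detection statistic exactly at criterion → no response;
zero-MAD epoch sets → nothing rejected; all-flat traces → all waves
missing; empty cells in the factorial → explicit errors (morphology
ANOVA) or dropped aliased columns (mixed model).

## Known limitations

* DN1 amplitude carries the ~3% baseline-offset bias described above when
  measured through the zero-mean pipeline.
* The wave IV anchor on strongly lateralised (|ITD| ≥ 1.5 ms) summed
  traces can lock onto either shifted ear-component; the DN1 search
  window is wide enough that the measurement is unaffected on clean data,
  but anchor latencies themselves should not be interpreted at large
  ITDs.
* Threshold estimates are grid-valued and sit one step above the
  generative threshold by construction of the amplitude model; absolute
  thresholds are comparable only within a fixed level grid and detector.
* The template detector assumes the top-level trace is genuinely
  suprathreshold; a series that starts below threshold degrades to the
  RMS detector's behaviour.
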