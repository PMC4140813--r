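---
title: "cbopto: generative model and estimator conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cbopto: generative model and estimator conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the point-process
model behind the generator, the conventions behind every estimator, and
the reasoning behind defaults that were genuinely open choices. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The generative model

### Spontaneous Purkinje cell firing

Spontaneous simple-spike firing is modelled as a *jittered-regular
renewal process with pauses*:

* **Renewal core.** Interspike intervals are gamma distributed with mean
  `1 / baseline_modal_rate` and coefficient of variation
  `isi_jitter_cv`. The renewal rate *is* the modal (rhythmic) frequency:
  the autocorrelation of the train carries side peaks at multiples of
  the mean ISI, and the Fourier transform of the autocorrelation
  histogram (ACH) peaks there.
* **Pauses.** An independent Poisson process (rate λ, exponential
  durations with mean `pause_duration_mean` = 60 ms) deletes every spike
  it covers. By the M/G/∞ vacancy formula a spike survives with
  probability `exp(-λ·d)`, so the count rate is
  `modal_rate · exp(-λ·d)`. The pause rate is *solved*, not set: given
  `baseline_count_rate` and `baseline_modal_rate`, λ is chosen so the
  expected count rate is exact. This reproduces the characteristic
  discrepancy between the count rate of a PC and its modal frequency
  (e.g. 35 spikes/s against 68 Hz, a pause time fraction of ~0.49), and
  it makes "count rate < modal frequency whenever pauses are present" a
  theorem of the generator rather than an accident.
* **Complex spikes.** Overlaid as a Poisson process (0.23 Hz default)
  with a dead time equal to the climbing-fiber pause; every simple spike
  within `(cs, cs + 15 ms]` is deleted. The pause identifies simple and
  complex spikes as one cell's output, and the generated minimum
  complex-to-simple gap is therefore ≥ 15 ms by construction.

The gamma/exponential distributional choices are ours; recordings
constrain the first two moments (rates, regularity) and the pause
accounting, not the law. Within-run analyses only consume those moments.

### Between-unit heterogeneity

Real cohorts show large rate scatter between cells. Putting a common
lognormal multiplier on *both* count and modal rate would spread the
modal frequency by the same ~20–35%, which contradicts how tightly the
cohort modal frequency is reproduced; the heterogeneity must therefore
live mostly in the pause process. Each unit draws:

* a **pause burden** multiplier on λ — gamma with shape 4 (SD 0.5),
  truncated to [0.4, 1.5] so every unit's spontaneous rate stays inside
  the 20–150 Hz identification gate. The pause rate is re-solved
  numerically under the truncated mixture so the expected cohort count
  rate remains exact;
* a small lognormal **modal jitter** (CV 1.5%);
* for the gc and thermal modes, where no modal-frequency statistic is
  reproduced, an additional lognormal **rate scale** (CV 0.2) on the
  whole unit profile. The printed cohort dispersions imply a between-cell
  CV nearer 0.3; 0.2 is a deliberate compromise that keeps the mean of a
  20–25-unit cohort close to the population value it is validated
  against while preserving a realistic SEM order.

All randomness is seeded: cohort-level assignments (which units carry an
onset transient, fire sparsely, or are excited) come from the cohort
stream, and each unit's spike trains come from a unit stream whose seed
is drawn from the cohort stream. (An earlier arithmetic seed derivation
left unit effects of nearby cohort seeds correlated; drawing the unit
seeds from the cohort stream removes that while keeping each unit
reproducible from the cohort seed.)

### The four perturbation modes

Time-varying rates are generated by time-rescaling the renewal process
(the intensity follows the target count profile divided by the pause
survival), with pauses applied at the stationary solved rate. The
deterministic transition events of each mode are placed explicitly and
are exempt from pause thinning — they model the synaptic transition, not
the spontaneous gap process — but not from complex-spike deletion.

* **pc** — direct ChR2 drive. At `onset_latency` (3.9 ms, trial jitter
  SD 0.45 ms) after light onset the first driven spike is placed;
  firing then continues as a renewal process at the driven modal rate
  (116.6 Hz; driven count rate 97 spikes/s via the driven pause solve)
  with reduced jitter (CV 0.10). A configurable fraction of units (4/14)
  carries a decaying onset transient. The drive persists for a per-unit
  offset latency (16.4 ms, between-unit SD 5.3 ms) beyond light offset,
  then baseline resumes. The printed "±" dispersions on the latencies
  are read as between-unit SDs: reading them as SEMs would imply
  between-unit spreads (e.g. 5.3·√14 ≈ 20 ms) under which the cohort
  means themselves would not be stable at the printed precision.
  An optional `intensity_block` reproduces the high-intensity phenotype:
  above a tip-power threshold the driven rate is scaled down and a
  silent pause follows light offset. Its threshold is arbitrary (the
  underlying report is qualitative) and it is off by default.
* **mli** — interneuron-mediated suppression. Baseline firing stops at
  light onset except for one transmitted *last spike* at 3.6 ms
  (between-unit SD 0.4 ms); 4/21 units resume sparse (3 Hz) firing after
  500 ms of light. After light offset the first spike reappears at
  123.5 ms (between-unit SD 22.7 ms) and the rate relaxes to baseline
  with `recovery_tau` = 0.8 s, reaching baseline ~2.5 s after offset.
* **gc** — granule-cell drive. Each unit is excited or inhibited; the
  split is a stratified draw (exactly `round(13/25 · n)` excited,
  randomly assigned), reproducing the reported 13/12 split at n = 25.
  The count rate approaches baseline ± 15 spikes/s with
  `gc_onset_tau` = 1.5 s (no onset time constant is reported; this value
  is free) and returns with `gc_offset_tau` = 0.55 s. The baseline rate
  (47.5 spikes/s) is borrowed from the opsin-free cohort of the same
  mouse line; the modal rate (55 Hz) gives the mild pause burden of
  "occasional pauses". The ISI jitter CVs (0.385 spontaneous, 0.452
  driven) were calibrated once by simulation so the cohort CV2 measured
  by the package's own epoch estimator lands at the published 0.48
  (light off) and 0.54 (light on), then frozen; they are not re-fitted.
* **thermal** — opsin-free warming. The count rate follows
  `base + Δ·(1 − exp(−t/τ_on))` during light and decays with `τ_off`
  after, never below baseline by construction. With τ_on = 2.30 s the
  asymptotic increment Δ that makes the 5-s light-epoch *mean* rate rise
  from 47.5 to 54.4 Hz is `6.9 / (1 − (τ/T)(1 − e^{−T/τ}))` = 11.65
  spikes/s, which is the default. This cohort is modelled pause-free
  (modal = count rate) and regular: no rhythmicity statistics are
  reported for it, published average traces of the condition are smooth,
  and pause-induced counting noise would otherwise dominate the slow
  time constants at a 20-unit, 20-trial cohort (the per-bin SD of the
  grand-average time course scales with the pause cluster size; with a
  32% pause fraction the onset τ is unidentifiable to ±10% at this
  cohort size, pause-free it is comfortably identifiable).

### What the generator does and does not emulate

It reproduces: labeled event-time structure, the count/modal
discrepancy, the climbing-fiber pause, the four modes' rate time courses
and latencies, epoch regularity, and cohort-level heterogeneity of rates
and latencies. It does not emulate: waveforms or sorting errors
(inputs are labeled event times by construction), complex-spike rate
modulation (none was observed in the underlying experiments), bursting
or adaptation within the light epoch, correlations between units, or
light-propagation physics (the spatial profile is a phenomenological
attenuation table). Passing tests therefore validate the *analysis
chain* against a known ground truth with realistic first- and
second-order statistics — they do not certify behaviour on waveform-level
artifacts real recordings can contain.

## Estimator conventions

* **Epochs.** Light-on is `[on, off)` (closed left: a spike exactly at
  onset belongs to the light epoch); the spontaneous epoch is the
  pre-onset window minus its first 100 ms. Post-light data are never
  used for baselines because every mode has structured recovery there.
* **PSTH.** `rate[i] = count_i / (n_trials · bin_width)`; mass
  conservation (`sum(rate·bin·n_trials)` = spike count in window) is a
  tested invariant. 1 ms bins for latency work, 100 ms for kinetics.
* **Onset peak latency.** First post-onset 1 ms bin that (i) exceeds the
  baseline mean + 2 SD of baseline bins, (ii) exceeds every baseline
  bin — this keeps flat traces from reporting chance peaks — and
  (iii) is a local maximum within a 5 ms lookahead; the position is
  refined by parabolic interpolation (shift clamped to one bin). With the
  generator's low first-spike jitter, the PSTH-peak reading and a
  first-spike reading of the latency nearly coincide, which is how the
  ambiguity between the two published phrasings is resolved.
* **Offset return latency.** The PSTH is smoothed with an 11 ms centered
  moving average; the baseline band is the smoothed-baseline mean ± 2 SD.
  The return is the first post-offset time inside the band whose
  following 10 ms *median* stays inside (a median dwell tolerates
  single-bin excursions of 20-trial PSTHs), refined to the crossing of
  the midpoint between the pre-return plateau and the baseline mean,
  which centres the estimate on the underlying rate step instead of the
  band edge.
* **Suppression latencies.** The last transmitted spike is the last
  simple spike before the first sustained (> 100 ms) light-on silence —
  robust to sparse late firing — with a per-unit median over trials
  (robust to the rare trial whose transmitted spike is deleted by a
  coincident climbing-fiber pause). A *complete block* for the recovery
  latency means no simple spike in `[on + 10 ms, off]`; trials without
  any post-offset spike are censored.
* **ACH and modal frequency.** Pair lags within trials only, zero-lag
  excluded, mirrored (symmetry is exact by construction). For the
  spectrum the positive-lag counts are divided by the per-trial lag
  coverage `max(T_i − lag, 0)` (triangular correction), mean-subtracted,
  end-tapered with a cosine roll-off over the last 25% of lags, zero
  padded to ≥ 4096 samples and Fourier transformed. The modal frequency
  is the dominant magnitude peak in 20–250 Hz, parabolic-refined, and is
  reported only when it exceeds 3.5× the band's median magnitude —
  flat (Poisson) trains stay below ~3.2 on this statistic while rhythmic
  trains exceed 4.5, so the criterion separates them with margin. A
  half-frequency peak replaces the reported peak only when it is an
  interior local maximum whose flanks dip below 60% of it (a genuine
  spectral line, not pedestal), guarding against pause-pedestal ripples
  halving the estimate. One bias is inherent to the definition and
  documented rather than corrected: damping by ISI jitter pulls the
  spectral peak slightly below the renewal rate (≈ 1% at CV 0.10,
  10–15% for the much less rhythmic spontaneous trains).
* **CV / CV2.** CV uses the sample (n−1) standard deviation. Epoch ISIs
  require both endpoints inside the same epoch of the same trial;
  intervals containing a complex spike are excluded, and CV2 adjacent
  pairs are formed within the surviving contiguous runs only, never
  across an exclusion or a trial boundary. The paired comparison is a
  two-sided Wilcoxon signed-rank test, exact for n ≤ 25 without ties.
* **Exponential kinetics.** `r(t) = r_inf + A·exp(−t/tau)` by
  Levenberg–Marquardt least squares; τ is initialized from the time to
  cover 63% of the window's endpoint gap, amplitudes from endpoint
  rates. The first 50 ms of each phase are excluded so fast transients
  do not contaminate slow fits. Non-convergence returns a flagged
  failure with diagnostics, never silently. A free three-parameter
  exponential is weakly identified when the window spans only ~2 time
  constants of noisy data, so the quantities a recording pins down
  precisely can be anchored (`intercept`, `asymptote`), and
  `fit_light_cycle()` fits the whole cycle jointly with a shared
  baseline and amplitude but free, independent τ_on/τ_off — on/off
  symmetry, the signature of thermal kinetics, remains a result rather
  than an assumption. The thermal report uses the joint fit; the gc
  offset fit removes the rectification noise floor of the averaged
  |modulation| trace in quadrature (`E[m²] = s² + σ²`, floor power
  measured > 4 τ after offset) before fitting the decay to zero.
  The thermal/synaptic discriminator calls a pair of fits thermal-like
  when both τ exceed 1 s and agree within 1.5×, synaptic-like when the
  offset τ is below 1 s; both thresholds are ours, chosen to separate
  the ~2.2–2.3 s thermal pair from the 0.55 s synaptic return with wide
  margin.
* **GC response labels.** A unit is excited/inhibited when its light-on
  rate differs from baseline by more than 2 standard errors of the
  per-trial baseline rates, else unmodulated.
* **Spatial profile.** Modulation multiples (`rate_on/rate_off`,
  undefined — not infinite — at zero baseline) are averaged in depth bins
  aligned to multiples of 200 µm, per lateral distance; dispersion is
  reported as SEM. The default attenuation table peaks for fiber tips
  250–500 µm above the cell at 330 µm lateral distance, is reduced at
  660 µm, zero at 990 µm and beyond 1500 µm of depth offset.

## Problem sizes

The validation suite and the acceptance script regenerate the four
cohorts at their study conditions: 14 PC-mode units × 20 one-second
light trials, 21 MLI-mode units × 30 trials, 25 GC-mode units × 15
five-second-light trials, and 20 thermal units × 20 trials; formula
oracles run on toy trains and property checks on batches of 300–1000 s
of generated spiking. Cohort-level checks compare recovered means at
2×SEM or the published tolerance of the quantity.

## Known limitations

* The spontaneous modal-frequency estimate of weakly rhythmic,
  pause-heavy trains sits visibly below the renewal rate (damping bias
  above); only driven-epoch modal frequencies are quantitatively
  validated.
* Offset-return and recovery latencies inherit the between-unit latency
  spread: a 14-unit cohort mean moves a few ms from seed to seed, as the
  published dispersions themselves suggest.
* The generator's trials are exchangeable — no drift, adaptation, or
  electrode instability across trials.
* `epoch_isis` pools pre-onset data only for the "off" epoch; protocols
  whose analysis requires post-light baselines need explicit windows.
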