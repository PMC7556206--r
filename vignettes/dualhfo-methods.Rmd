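---
title: "Interictal HFO asymmetry analysis for dual-pathology epilepsy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal HFO asymmetry analysis for dual-pathology epilepsy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

In dual-pathology epilepsy a patient carries two potentially epileptogenic
lesions — one hippocampal, one in the temporal neocortex — and the central
presurgical question is which of them generates the seizures. Ictal SEEG
(stereotactic EEG from implanted depth electrodes) answers this when enough
seizures are captured, but often leaves uncertainty. `dualhfo` implements an
interictal alternative: count brief pathological events between seizures —
epileptic spikes (IES), ripples (80–250 Hz), ripples co-occurring with
spikes (IES-ripples) and fast ripples (250–500 Hz) — in the contacts of each
lesion, and ask whether their spatial asymmetry points at the
seizure-generating lesion.

The core statistic is the asymmetry ratio of mean event rates,

$$R = \frac{\bar r_{\mathrm{hip}} - \bar r_{\mathrm{neo}}}
           {\bar r_{\mathrm{hip}} + \bar r_{\mathrm{neo}}} \in [-1, 1],$$

computed per patient and per event type over all contacts located in either
lesion. $R$ near $1$ means events concentrate in the hippocampal lesion,
near $-1$ in the neocortical one, near $0$ neither. Because hippocampal
tissue generates more spikes and HFOs than neocortex *regardless* of where
seizures arise, raw rates cannot identify the focus; the ratio is a
within-patient contrast that removes the common hippocampal excess.

Patients fall into three groups by their seizure-generating lesion
(1 hippocampal, 2 both, 3 neocortical). The pipeline's stages are:

1. **Detection** of the four event types per channel.
2. **Rates and ratios**: events → per-channel events/min → lesion contact
   means → per-patient $R$ per event type.
3. **Group statistics**: Mann-Whitney U comparisons of channelwise rates
   between lesions, and Spearman correlation of each $R$ with the group.
4. **Prediction**: rank patients by $R_{\mathrm{fast\ ripple}}$; with group
   sizes $(n_1, n_2, n_3)$, predict group 1 for the top $n_1$ ranks, group 3
   for the bottom $n_3$, group 2 in between; score the number of correct
   assignments.
5. **Permutation test**: hold the zone pattern fixed, shuffle the
   group-label multiset uniformly across rank positions, and report the
   one-sided probability of at least the observed number of matches —
   Monte-Carlo with 100,000 shuffles plus an exact enumeration oracle.

The packaged 16-patient cohort table (`load_fixture("table2")`, group sizes
5/7/4) lets every stage from 4 on be reproduced exactly:
11 of 16 correct assignments (69%), Spearman $\rho = -0.512$
($p = 0.043$), permutation $p \approx 0.007$.

## The permutation null, exactly

With the zone pattern fixed, the number of positionwise matches under a
uniformly shuffled label multiset depends only on the $3\times 3$
contingency table of zone versus label counts. `exact_match_distribution()`
sums multivariate-hypergeometric weights over all tables with the given
margins; for zone and label counts both $(5, 7, 4)$ this is exact over all
$16!/(5!\,7!\,4!) = 1{,}441{,}440$ distinct arrangements, and the
distribution's mean has the closed form $\sum_i n_i^2 / N = 90/16 = 5.625$.
The Monte-Carlo path (`permutation_test()`) exists because it mirrors the
published procedure; the exact path verifies it. Both are reported. The
test is one-sided ($\ge$ observed), matching the "better than chance"
question, and an add-one-smoothed $p$ accompanies the plain proportion.

Ties in $R_{\mathrm{fast\ ripple}}$ are broken by ascending patient id —
stable and reproducible — and `rank_and_predict()` reports a `tie_warning`
when tied values straddle a zone boundary, in which case accuracy depends
on tie order. In the packaged table all three ties (at 0.02, 0.01 and
−0.05) fall inside one zone, so its accuracy is tie-order invariant (a
property the test suite verifies by enumerating tie orders).

## Statistical choices

**Mann-Whitney U.** For $n_a + n_b \le 40$ the p-value is exact: the null
distribution of the rank sum over all $\binom{n_a+n_b}{n_a}$ midrank
subsets is built by a count recursion on doubled midranks, which handles
ties exactly; the two-sided p is $\min(1,\, 2\min(P_{\le}, P_{\ge}))$.
Larger samples (for example 60 hippocampal vs 124 neocortical channels) use
the tie-corrected normal approximation without continuity correction.
Different statistics packages disagree in the third decimal here; the exact
branch is the reference below $n = 40$.

**Spearman correlation.** Midranks for ties, $\rho$ = Pearson correlation
of ranks, two-sided p from the $t$ approximation with $n-2$ degrees of
freedom (an exact permutation p is available for $n \le 8$; beyond that the
$t$ approximation is standard and its type-I behaviour is verified by
simulation, see below). The group variable is ordinal with only three
levels; heavy ties in $x$ are intrinsic to the design and handled by
midranks.

**Channel pooling.** Channelwise lesion comparisons pool contacts across
patients and treat them as independent — a simplification (within-patient
correlation is ignored) that mirrors how such channel counts are commonly
reported; the per-patient ratio analysis, which drives all conclusions, is
immune to it.

**Undefined ratios.** $R = 0/0$ (no events in either lesion) carries no
information: such patients are excluded from correlations and ranked last
for prediction, both with surfaced warnings.

**"Ripples" versus IES-ripples.** An IES-ripple *is* a ripple, so the
ripple rate counts all ripples with IES-ripples as a labelled subset;
`ripple_includes_ies_ripple = FALSE` gives the isolated-only convention.
Both conventions are one flag apart because the literature is not uniform.

**Lesion means.** "Mean rate" is the mean over contacts of per-contact
rates (each contact weighted equally); a pooled-count alternative
(total events / total contact-minutes) is available via
`patient_ratios(pooled = TRUE)`.

## The synthetic cohort generator

No public recording accompanies the study design this package implements,
so validation rests on a generative model with known ground truth,
emulating the study conditions: 16 patients split 5/7/4 across groups,
cohort totals of 60 hippocampal and 124 neocortical contacts (split across
patients uniformly at random above per-patient minima of 2 and 3), 1-hour
segments at 2 kHz with an 800 Hz acquisition low-pass.

The hierarchical rate model is standard in HFO-detector validation work:

- lesion-level baseline rates (events/min), hippocampal above neocortical
  for every event type (defaults: IES 4.0/1.5, ripples 2.0/0.8,
  IES-ripples 1.0/0.4, fast ripples 1.5/0.6 — magnitudes typical of
  published interictal SEEG rate distributions);
- per-channel rates are gamma draws (shape 2, i.e. channel-to-channel
  coefficient of variation $\approx 0.7$) around the lesion mean, rescaled
  so the lesion's contact mean hits its target exactly — consequently each
  patient's *true-rate* ratio equals the configured value exactly;
- for fast ripples the two lesion means are rescaled, preserving their
  sum, so that the expected $R_{\mathrm{fast\ ripple}}$ equals the group's
  configured asymmetry: defaults $(0.6, 0.1, -0.3)$ for groups 1/2/3 —
  strongly hippocampal when seizures are hippocampal, near zero when both
  lesions generate seizures (group-2 patients span the middle of any
  ranking), moderately neocortical for neocortical onset;
- observed event counts are Poisson(rate × duration).

The signal tier adds morphology: pink ($1/f$) Gaussian background low-pass
filtered at 800 Hz and scaled to 15 µV SD; HFOs as Gaussian-windowed
sinusoids (window SD = duration/4) of 6–10 cycles with frequency drawn
uniformly from 100–220 Hz (ripples) or 330–430 Hz (fast ripples). The
draw ranges sit deliberately inside the nominal bands: an `n`-cycle burst
has spectral width of order `f/n`, so a 6-cycle burst at the shared
250 Hz edge spreads a quarter of its energy into the neighbouring band
and is not attributable to either band by any detector; the defaults are
the measured region in which at least 99% of every injected burst's
energy stays in its own band. IES as biphasic transients of 50–100 ms
whose dominant raised-cosine lobe occupies 60% of the duration, followed
by a 40%-amplitude counter-phase; IES-ripples as a ripple summed onto a
spike at the same onset. Event peak amplitude is `snr` × background SD
(default 6). Same-type events never overlap (unambiguous ground truth);
different types may (an IES-ripple is exactly such an overlap).

What the generator does **not** emulate: sleep-stage structure, artifacts
(pulse, movement, electrode noise), ictal activity, spatial correlation
between neighbouring contacts, non-stationary background, or realistic
event-waveform variability. Passing recovery tests therefore demonstrates
internal consistency of detector and statistics under the stated model —
not detector performance on clinical recordings.

## The event detectors

The published analysis used a trained SVM detector whose specification
lives in its own publication; `dualhfo` instead implements a fully
specified classical detector family so that every result here is
reproducible from this package alone.

**HFO bands** (Staba-style RMS threshold): zero-phase (forward–backward)
FIR band-pass, so event timing is phase-neutral; rectified-RMS envelope
(10 ms window for ripples, 5 ms for fast ripples); baseline as
median + $k \times 1.4826\,\mathrm{MAD}$ of the envelope — median/MAD
rather than mean/SD because the events themselves would inflate a moment
estimate; supra-threshold intervals closer than 10 ms merged; an interval
is an event if it contains at least `min_cycles = 4` oscillation cycles
(pairs of rectified-signal peaks above half threshold), the common
operational definition of an HFO. When detections in the two HFO bands
overlap in time, the band with the larger peak envelope wins: a burst near
the 250 Hz edge leaks into the neighbouring band through its spectral
skirt, and keeping both would double-count one physiological event.

**Spikes**: band-pass 10–60 Hz, candidate local extrema above
`spike_amp_k` robust SDs, half-amplitude width of the 10-ms RMS envelope
within 15–200 ms (the band-pass differentiates a 50–100 ms transient into
an envelope roughly a third as wide, hence the 15 ms floor), interval =
envelope half-amplitude crossings, and a 150 ms refractory so the
counter-phase of one biphasic transient is not a second spike.

**Co-occurrence**: a ripple is an IES-ripple iff its interval overlaps a
spike interval dilated by ±50 ms (a typical spike–HFO coupling window;
configurable), with strict boundaries — a ripple starting exactly at
spike end + 50 ms stays isolated.

**Calibration.** The defaults `threshold_k = 3.75` and `spike_amp_k = 5`
were set by simulation so that false detections on pure pink-noise
background stay below 1 event/min in every band while events at the study
signal-to-noise (6 × background SD) are detected with sensitivity ≥ 0.85
and precision ≥ 0.8 per type. These thresholds are properties of the
stand-in detector against this synthetic background, not of any clinical
recording; all of them live in `detection_params()` for recalibration.

## Numerical and interface choices

- All intervals are half-open `[start, end)` in seconds from segment
  start; durations are minutes only where rates are involved.
- Signals are microvolts throughout; EDF scaling is symmetric per channel
  with 16-bit quantization (worst-case error one digitization step).
- EDF is the signal container (the clinical de-facto standard); the
  package carries its own minimal reader/writer for standard 16-bit EDF
  with uniform sampling rate, round-trip tested and cross-checked against
  an independent EDF implementation in the test suite.
- Every stochastic step is seeded through a single integer
  (`sim_config(seed=)`, `permutation_test(seed=)`), and reports embed the
  seed; identical seed and configuration reproduce every number
  bit-for-bit.
- Degenerate inputs fail loudly and early: negative rates, group counts
  that do not sum, bands incompatible with the sampling rate, events on
  unknown channels, missing metadata rows (named), cohorts missing one of
  the three groups.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the test suite choose sizes
that keep a full run in minutes while leaving every statistical check
well-powered: the rate-table tier runs the full 16-patient, 184-contact,
1-hour cohort (milliseconds per cohort; 100-cohort power and 1000-cohort
type-I calibrations use it directly); the signal tier runs reduced cohorts
(60–300 s segments, 8–32 contacts) for detector validation, since
synthesizing and filtering the full 184 × 1-h cohort at 2 kHz adds nothing
statistically to the recovery estimates beyond narrower confidence
intervals.

## Known limitations

- The detector is a transparent stand-in, not a reimplementation of the
  trained classifier used in the original analysis; absolute rates from
  clinical data will differ (systematically, by detector operating point),
  though the ratio $R$ is insensitive to any detector bias that is common
  to both lesions.
- The per-patient prediction is retrospective and in-sample by
  construction; zone sizes are taken from the cohort's own group counts.
  No out-of-sample claim is made or testable here.
- Channel pooling ignores within-patient correlation (see above).
- The generator's independence assumptions (channels, events) make
  synthetic recovery estimates optimistic relative to clinical SEEG.
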