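---
title: "Methods: scalp-EEG HFO energy analysis for infantile spasms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scalp-EEG HFO energy analysis for infantile spasms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-frequency oscillations (HFOs, 40–500 Hz) on scalp EEG are a candidate
biomarker of epileptic network activity in infantile spasms (IS). The
analysis pipeline implemented here quantifies them the way the clinical
literature does on 1000-Hz scalp recordings: events are *marked* (at least
four consecutive, regular oscillations standing out from the surrounding
background, appearing at least twice per 5 minutes), and band activity is
*quantified* as average Morlet-wavelet energy in three bands — gamma
(40–80 Hz), ripple (80–200 Hz) and fast ripple (FR, 200–300 Hz; 300 Hz is
the analysis filter ceiling at this sampling rate, not the textbook 500 Hz
upper limit of FR). Group/state/band contrasts are tested with the aligned
rank transform (ART), a non-parametric factorial procedure, with
Holm-corrected post hoc comparisons. EEG severity in IS is graded on the
BASED scale (Burden of Amplitudes and Epileptiform Discharges, scores 2–5)
and treatment efficacy combines a clinical response with a post-treatment
BASED score of at most 3.

Because no clinical recordings are available, the package ships a
first-class synthetic-data module whose cohorts carry the statistical
structure every downstream stage assumes, with full ground truth. All
quantitative claims in the test suite are claims about this stated synthetic
world, not about patients.

## The synthetic world

`generate_background()` produces Gaussian noise with power ∝ 1/f above 1 Hz
(flat below), scaled to an exact per-channel RMS. Defaults:
19 channels of the 10–20 system, 1000 Hz, 15 µV RMS. The 15 µV figure is
the broadband background against which bursts must be visible after the slow
(< 4 Hz) rhythms that dominate infant EEG are ignored; HFO-band content of
this background is a few µV RMS, in line with scalp HFO literature.

`inject_burst()` adds a Hann-windowed sinusoid of `n_cycles` cycles; the
band label follows the analysis bands. `inject_discharges()` adds biphasic
spikes (20–70 ms) each followed by a 200–500 ms slow half-wave at Poisson
times — the amplitude/density material the BASED criteria look at.
Sleep segments receive 11–14 Hz spindle bursts; IS sleep segments receive
discharges. Real EEG features *not* emulated: topographic correlation
between channels, REM/NREM structure, muscle artifact, non-stationary
background. A green test therefore establishes algorithmic correctness and
statistical calibration, not clinical validity.

Energy effects are specified per (group, state, band) as multiplicative
factors on *energy*; burst amplitudes are scaled by `sqrt(factor)` because
energy is quadratic in amplitude. The measured band energy is
`background + burst` energy, so the recovered ratio between two cells is
compressed toward 1 by the background floor; with the default burst
amplitude (60 µV) and event rates that give a few bursts per second of
segment, a factor of 2 is recovered as ≈ 1.7–1.9, inside the ±20%
recovery band the tests assert.

Randomness: one master seed; each (group, subject, state) cell draws from a
deterministic substream, so cohorts are bit-reproducible and subjects are
independent.

### Compute-budget scaling

Interictal segments are 300 s in the protocol (spasm stages 2 s). Tests
that need hundreds of segments shorten them (4–10 s) while holding the
*per-segment* injected-event count at what a realistic 5-minute recording
would contain, by raising `event_rate` (defined per 5 minutes)
proportionally — e.g. `event_rate = 600` on a 6-s segment equals 12 events
per 5-minute-equivalent segment. Wavelet frequency grids are coarsened
(4/10/10 Hz steps) in the replicate experiments. Thresholds and acceptance
tolerances are never scaled.

## The detector

The clinical marking definition is visual; this implementation fixes it as
an explicit rule set (all parameters live in `detector_params()`):

1. zero-phase 4th-order Butterworth band-pass (forward–backward, so no
   group delay even on 2-s spasm segments);
2. Hilbert analytic envelope;
3. background level = envelope mean + `amp_factor` (3) SDs, re-estimated
   once with provisional candidate regions excluded;
4. a candidate is an excursion above that level lasting at least
   `min_high_cycles` (1.5) *band coherence times* (`1/(high − low)`), widened
   to the surrounding region above mean + `boundary_sd` (0.5) SDs;
5. one peak per cycle is counted on the band-passed signal (positive local
   maxima, sub-sample refined by parabolic interpolation); the longest run
   of inter-peak intervals inside `[1/high, 1/low]` must contain ≥ 4 peaks
   with max/min interval ≤ `regularity_max` (1.5);
6. events closer than `merge_gap` (10 ms) merge; the per-channel rate rule
   (≥ `min_rate` = 2 events per 5 minutes, applied as a rate) drops sparse
   channels. For the 2-s pre-spasm/spasm/post-spasm segments `min_rate = 0`.

Two details came out of an explicit calibration on 1/f background (seeds
disjoint from every test seed) and are worth recording:

* On Gaussian narrowband noise the envelope exceeds mean + 3 SD hundreds of
  times per 5 minutes; what separates noise excursions from genuine bursts
  is *duration*. Measured excursion durations scale with the band's
  coherence time in every band, hence the duration floor is expressed in
  those units. At 1.5 coherence times the false-event rate at default
  settings is ≈ 0.25 (gamma), 0.13 (ripple) and 1.0 (FR) events per
  5 minutes per channel.
* At 1000 Hz an FR cycle spans 3–5 samples, so integer-sample inter-peak
  intervals make any FR noise look "regular" (the FR band edge ratio
  300/200 = 1.5 equals the regularity limit, so the regularity rule alone
  cannot reject in-band noise there). Parabolic sub-sample peak timing
  restores the test's power. FR detection at this sampling rate remains the
  weakest of the three bands; bursts shorter than ~8 cycles sit close to
  the noise-excursion duration distribution.

Detection-performance statements ("bursts at 5× the background envelope SD")
use the SD of the *broadband* background envelope, i.e. bursts that visibly
stand out of the raw trace (~49 µV over a 15 µV RMS background). Relative
to the band-filtered envelope such bursts are 10–14 in-band SDs. The
alternative reading (5× the *band-filtered* envelope SD) would place burst
peaks essentially at the detection threshold; a matched-filter calculation
shows no detector could then reach 90% sensitivity at ~1 false event per
5 minutes, so that reading was discarded as internally inconsistent.

## Morlet energy

`morlet_tfr()` uses complex Morlet atoms with `omega0 = 6` cycles
(σ_t = 6/(2πf)), evaluated by FFT convolution with reflect-padding; each
frequency's response is calibrated so a sinusoid of amplitude *a* yields its
mean-square power a²/2 at its own frequency, independent of frequency —
power is in µV². Frequency grids: 2 Hz steps in gamma, 5 Hz in
ripple/FR (≥ 4 bins per band; a 60-Hz tone leaks < 2% of its gamma energy
into the ripple grid). Band averages exclude samples within one wavelet
half-length (3 σ_t, per frequency) of the segment edges. Average energy is
a single scalar per (subject, channel, state, band): the mean over the
band's time–frequency cells.

Energies are computed on average-referenced signals (all 19 electrodes in
the average, midline included — the protocol does not say otherwise);
BASED amplitude reading uses the longitudinal bipolar montage. The
responsible lead is the channel with the largest pooled average energy per
subject, ties broken by canonical 10–20 order and flagged. F7/F8 count as
temporal (anterior temporal convention); this moves counts between the
frontal and temporal lobes and is deliberately exposed in `lobe_of()`.
Because it is unstated whether cohort summaries should average over channels
or use only the responsible lead, both tables are available
(`channel_band_energies()` and `lead_restricted_energies()`).

## ART statistics

For each effect, responses are aligned — every estimated marginal effect
except the one of interest removed via the cell-means decomposition
(inclusion–exclusion over the effect's factor subsets) — then mid-ranked,
and a repeated-measures ANOVA with the subject error stratum
(`aov` with `Error(subject/(within...))`) is run on the ranks; only that
effect's F is read per fit. Correct alignment leaves F ≈ 0 for every other
effect on the aligned (unranked) column; `art_diagnostics()` checks this.
Under the null the three-way interaction rejects at ≈ 5% (the acceptance
suite measures it over 500 simulated mixed designs).

Post hoc contrasts collapse the factors of interest into one composite
factor and align for *it* (removing all other effects but keeping the
involved main effects and interactions — without this, a sleep-vs-wake
contrast within a band would be blind to a uniform sleep/wake main effect).
Within-subject pairs use a paired t on per-subject mean ranks; pairs
crossing a between factor use Welch's t. Holm's step-down correction is
applied within the requested contrast family (and to the omnibus family in
`art_anova()`).

Numerical conventions: quartiles by linear interpolation (type 7);
`paired_compare()` gates on Shapiro–Wilk at p > 0.05 between the paired t
and the Wilcoxon signed-rank; a zero-variance difference vector returns
p = 1 with statistic 0 rather than an error; α = 0.05 two-sided throughout.
Rank invariance of the ART F under strictly monotone response transforms
holds exactly for single-factor designs (where alignment is a shift); for
multi-factor alignment it is approximate, and the test asserts the exact
single-factor case only. Unbalanced between-group designs are accepted with
a warning; with a single between factor the sequential and marginal tests
coincide, which covers the designs in scope.

## BASED and efficacy

Scoring operates on *annotated* inputs (discharge annotations plus
slow-wave peak-to-peak amplitudes per bipolar derivation, 0.5–3 Hz
filtered) — spike detection is not re-invented, matching how the scale is
used by readers. The ladder: 5 if more than half the 1-s windows of the
worst 5 minutes contain a discharge, or slow waves exceed 300 µV on more
than half the derivations; 4 if density ≤ 50% and slow waves reach 200 µV;
3 for multifocal spikes under 200 µV; 2 for a single focus; no epileptiform
activity (scores 0–1) is outside the scale and raises an error. A discharge
spanning a 1-s window boundary counts in every window it touches
(conservative toward higher density). The 200 µV boundary is not defined by
the source criteria (">200" vs "<200"); exactly 200 µV scores 4 and emits a
warning. Efficacy: `effective` requires a clinical response (controlled or
improved) *and* BASED ≤ 3; `efficiency = (controlled + improved)/total ×
100%`.

## Known limitations

* EDF support is 16-bit single-rate EDF with a sidecar TSV for annotations
  (no EDF+ TAL encoding); files from other software load if single-rate.
* The FR band at 1000 Hz is at the edge of detectability (see above).
* The cohort-level "all effects equal" null is validated at the design-table
  level (500 reps); a full cohort-synthesis null at that replicate count
  would dominate the test budget and adds no inferential path not already
  exercised.
* Absolute energy values are arbitrary (they depend on simulation
  amplitudes); only ratios and directions are meaningful, which is also why
  no absolute value is an acceptance surface.
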