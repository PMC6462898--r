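---
title: "Pulse arrival time and blood pressure: models, simulator, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse arrival time and blood pressure: models, simulator, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Arterial wave propagation theory links blood pressure to the speed at which
the pressure pulse travels the arterial tree: higher pressure stiffens the
wall and shortens the travel time. Two beat-by-beat surrogates of that
travel time can be read from standard ICU monitoring channels:

* **Pulse arrival time (PAT)** — from the ECG R peak (ventricular
  depolarization) to a landmark on a distal pulse. PAT contains the
  pre-ejection period plus the true transit time; the pre-ejection period
  is not separated here.
* **Pulse transit time (PTT)** — between the same pulse's arrival at two
  arterial sites; here, from the ABP systolic peak (S\*) to the PPG
  systolic peak (S).

Because distal PPG landmarks differ in how sharply they are defined, five
PPG-family end points are measured for each beat: the pulse foot **O** and
systolic peak **S** on the filtered PPG, the maximum-slope point **w** on
its first derivative (VPG), and the **a** (early-systolic maximum) and
**b** (subsequent minimum) waves on its second derivative (APG). Together
with the ECG-to-ABP interval PAT\_RS\*, the transit interval PTT\_S\*S, and
the R-R interval, eight propagation features are extracted per beat, and
their linear association with per-beat SBP, MAP, and DBP is quantified
with the sample Pearson coefficient.

Three analysis modes answer different questions:

1. **Subject by subject** — one coefficient per subject and feature;
   within-subject coupling, free of between-subject offsets. Summarized as
   an unweighted mean ± SD and binned by strength of |r|
   (very strong ≥ 0.8; strong 0.6–0.8; moderate 0.4–0.6; weak 0.2–0.4;
   very weak < 0.2, half-open below the upper edge so every value lands in
   exactly one bin).
2. **Collective beats** — all subjects' beats pooled with no centering.
   Between-subject differences in baseline PAT and pressure contribute
   fully, so the pooled coefficient can be much weaker than every
   within-subject coefficient (or even flip sign); the test suite contains
   a constructed two-subject example of the flip.
3. **One excellent beat per subject** — one best-quality beat per subject,
   selected automatically by a per-beat signal-quality score (mean
   correlation of the beat's segment with the record's median beat
   template, averaged over the three channels; ties go to the earliest
   beat).

## Signal model and preprocessing

ECG is band-passed at 0.5–40 Hz (4th-order Butterworth) and PPG at
0.5–10 Hz (4th-order Chebyshev type II, 20 dB stopband; the band edges are
the stopband corners in the usual Chebyshev-II convention). Both filters
are applied forward and backward, so the net phase shift is zero —
essential, since any group delay would bias intervals measured *between*
channels. ABP is deliberately left unfiltered: SBP and DBP are amplitude
readings, and filtering would bias them.

Numerically, each filter is factored into second-order sections before
use; the direct 8th-order band-pass polynomial has poles crowded near
_z_ = 1 and loses several digits in recursion. The forward–backward pass
uses a 3 s odd-reflect extension at both ends plus steady-state
initialization of each biquad, so start-up transients decay in the padding
and a constant input maps to its (near-zero) steady-state response
everywhere. With this arrangement filtering is linear to ~1e−13 relative
and DC suppression is limited only by the Chebyshev-II stopband floor
(20 dB per pass, 1 % amplitude after two passes for the PPG filter;
the Butterworth ECG filter leaves < 1e−15).

VPG and APG are forward differences scaled by the sampling rate (so units
are signal-units/s and /s²; amplitudes are rate-invariant), with the last
sample replicated to preserve length.

## Fiducial detection

R peaks are detected with a two-event moving-average scheme on the
squared, positively rectified filtered ECG (event window 97 ms, cycle
window 611 ms, 250 ms refractory period); every reported peak is a local
maximum of the input signal. Any detector meeting the ±1-sample
localization property below would be conforming.

Within each beat window the remaining landmarks are windowed extrema:
S\* is the ABP maximum in (R_i, R_{i+1}) and D\* the minimum after it;
in the PPG window (R_i, R_i + 0.9·RRI) — the 0.9 factor excludes the next
beat's upstroke — S is the PPG maximum, w the VPG maximum before S, a the
APG maximum before w, b the APG minimum between a and S, and O the PPG
minimum between R and a (the pulse foot, found after the peak as is
conventional). Ties break to the earliest sample, times are reported at
sample resolution (no sub-sample interpolation), and any beat violating
the ordering O ≤ a ≤ w ≤ b ≤ S, lacking an interior ABP peak, or missing
its following R is dropped and excluded from pairing. Only beats with the
complete eight-landmark set enter the feature table, with `beat_index`
kept for traceability.

Two readout conventions were genuinely open and are fixed as follows:
**SBP/DBP** are the unfiltered ABP values at the detected S\*/D\* samples;
**MAP** is the time average of ABP over the cardiac cycle (the standard
monitor convention), with the DBP + PP/3 estimate available behind
`map_rule = "dbp_pp3"`. The maximum-slope landmark is implemented as the
VPG systolic maximum and labeled `w`.

## The synthetic cohort

Real ICU waveforms come with no ground truth, so validation uses a
generator whose records carry exact per-beat annotations:

* **Beat timing** — per-beat heart rate ~ N(`hr_mean`, `hr_sd`), default
  75 ± 3 bpm; 150 beats at 125 Hz by default, i.e. roughly two minutes of
  signal per record, matching the scale of the archived study records.
* **Pressure process** — beat-to-beat SBP follows a bounded AR(1) walk
  (persistence 0.9; innovation SD chosen so the stationary SD equals
  `sbp_sd`, default 8 mmHg around 120 mmHg; clipped to
  [`dbp_offset` + 30, 250] mmHg). DBP is SBP minus a jittered 40 mmHg
  pulse pressure. The AR(1) choice induces realistic slow within-record BP
  drift without modeling physiology; its persistence inflates the
  standard error of the record mean by √((1+φ)/(1−φ)) ≈ 4.4, which the
  tests account for.
* **The programmed coupling** — the quantity under test:
  PAT\_RS(i) = `pat_rs_mean` + `coupling_slope` · (SBP(i) − `sbp_mean`) +
  N(0, `pat_noise_sd`), default 350 ms − 2 ms/mmHg with 10 ms jitter. The
  ABP systolic peak sits at `pat_rsstar_fraction` (default 0.6) of PAT_RS
  after R. The implied population coefficient is analytic:
  r = slope·σ_SBP / √(slope²σ_SBP² + σ_noise²), which gives the simulator
  an exact oracle — e.g. slope −0.002 s/mmHg, σ_SBP 8 mmHg, jitter 12 ms
  programs r = −0.80.
* **Morphology** — each channel is a train of Gaussian two-bump kernels: a
  dominant systolic wave plus a smaller, later diastolic wave (widths
  90/160 ms for PPG, 80/120 ms for ABP), so O, a, w, b, S all exist and
  are separable; the ECG beat is a narrow R spike with small P and T
  bumps. The diastolic bump's tail shifts the summed kernel's maximum
  slightly off the systolic center; that constant offset is computed once
  and pre-subtracted, so the rendered peak lands on the programmed time,
  and the ABP kernel is rescaled so the rendered peak equals the
  programmed SBP. A phantom lead-in pulse (pulse channels only) gives the
  first beat a preceding diastolic tail.
* **Ground truth** — derived from the clean rendering by the same
  windowed-extremum definitions the detectors use, before noise is added;
  truth and waveform therefore agree to within one sample by
  construction, and the localization tests measure what filtering and
  detection add on top.
* **Corruption modes** — for screening tests: `missing_*` replaces a
  channel with a flat line; `abnormal_*` destroys one channel's
  morphology with heavy broadband noise (for ABP, wide enough to leave
  the plausible 20–300 mmHg range). Magnitudes are chosen so clean and
  corrupted records are separated by a wide margin — screening thresholds
  are validated against the simulator, not tuned to it.

What the simulator does **not** emulate: baseline wander and motion
artifact, respiratory modulation, arrhythmia and ectopic beats, pulse
morphology change with vascular ageing, measurement asynchrony between
channels, and any causal hemodynamics (the PAT–BP link is imposed, not
derived). Passing tests therefore demonstrate that the pipeline measures
a known coupling correctly on well-formed signals — not that real
monitoring data satisfies the model.

## Screening

The seven categories (missing/abnormal × ABP/ECG/PPG, plus good) are
assigned by reproducible proxies for what is usually a visual judgement:
a channel absent or flat over the whole record is *missing*; a present
channel is *abnormal* if its own peak detector cannot find beats at a
plausible rate (≥ 80 % of inter-beat intervals inside 30–200 bpm), if its
mean beat-template correlation falls below 0.8, or — ABP only — if more
than 10 % of samples leave 20–300 mmHg. Missing takes precedence over
abnormal and channels are checked ABP → ECG → PPG, mirroring the
category structure of the packaged screening ledger. All thresholds are
exposed in `quality_thresholds()`.

The packaged bookkeeping fixture (`inst/extdata/screening_fixture.csv`)
transcribes a published 578-record screening into this format; its
provenance file documents the three typographic normalizations made so
the per-category counts match the printed totals.

## Numerical and statistical choices

* The Pearson engine uses the centered-sums form
  Σdxdy / √(Σdx²Σdy²) — numerically stable and exactly symmetric;
  expanded one-pass sum formulas (which appear with typographical sign
  errors in parts of the applied literature) are avoided. Zero variance
  is an explicit error, never a silent 0. Raw coefficients are reported
  without p-values or multiplicity correction.
* Validation problem sizes, chosen as the package's own study conditions:
  localization on a noise-free 100-beat record; coupling recovery on
  2000-beat records over 20 fixed seeds (mean estimate within ±0.05 of
  the programmed −0.80; with the coupling removed, the mean estimate
  within two standard errors of zero); screening separation on 50 clean +
  50 corrupted records (exact agreement required); Pearson agreement with
  a definition-level brute-force oracle to 1e−12 on 1000 random arrays.
* Determinism: every stochastic step runs under an explicitly scoped seed;
  identical configurations give bit-identical waveforms, feature tables,
  and reports, and each pipeline output is stamped with a hash of the
  scientific configuration (output paths excluded).

## Known limitations

* PAT here includes the pre-ejection period; without separating it, PAT
  cannot be a pure transit-time measure.
* The screening proxies judge whole records; a record abnormal only in a
  short segment is either accepted or rejected wholesale.
* Sample-resolution timing quantizes intervals to 8 ms at 125 Hz; with
  per-beat jitter of comparable size this attenuates recovered
  correlations by a percent or two, visible in the recovery tests.
* The WFDB adapter reads single-segment, format-16 records only; it is a
  convenience for pre-downloaded data and nothing downstream depends on
  it.
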