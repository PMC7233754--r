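---
title: "Methods: emulated EEG sessions and cohort parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulated EEG sessions and cohort parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cogstream)
```

`cogstream` is a headless pipeline for cognitive-neuropsychological EEG
studies built on consumer-grade wireless headsets. This vignette is the
package's account of its models and the choices behind them: what the
synthetic data generator emulates, what the analysis assumes, which knobs
matter, and what passing tests do and do not establish about real
recordings.

## The task model

The core paradigm is a word n-Back. Each trial shows a series of word
pairs ("displays", the potential targets) at a fixed cadence — one
display or probe every `stimulus_interval_s` (default 2 s) — then a
single probe word. The participant presses a key if the probe matches a
word from the pair shown `n` displays earlier. Trials come in four types
showing `n`, `n+1`, `n+2`, `n+3` displays before the probe, mixed in
fractions 1/3, 1/4, 1/4, 1/6 of the block; exactly half of all probes
are matched. A white-screen rest (default 30 s) follows every twelfth
trial, and a practice block (default 7 trials) precedes the main block.

Design decisions worth stating:

- **The two middle type fractions** are fixed only in their sum (the
  outer fractions 1/3 and 1/6 are part of the paradigm); we split the
  remaining 1/2 symmetrically, 1/4 each, and expose it as configuration.
- **Totals must divide the fractions.** `total_trials` must make every
  `fraction x total` an integer (a multiple of 12 under the defaults);
  composition refuses otherwise and names the smallest valid total
  rather than silently rounding.
- **Lure policy.** An unmatched probe is, with probability 0.5, a word
  from another display of the same trial (an interference lure), else a
  fresh word not shown in the trial. Words never repeat within a trial;
  they may recur across trials so small pools stay usable.
- **Fractions apply to the main block only**; practice trials draw their
  type uniformly and are flagged `practice = TRUE` so analysis excludes
  them everywhere.
- **Rests** are placed after every `rest_every`-th main trial, including
  after the final one when the total is a multiple of the cadence.
- Probe response windows equal the stimulus interval.

Eyes-open/closed schedules (alternating cues at fixed intervals) and
affective-valence picture tasks (seeded-shuffled placeholder image ids,
three response labels: unpleasant / neutral / pleasant) use the same
timeline representation. All composition is a pure function of its spec,
including the seed.

## The device emulator

The emulated headset mirrors a 14-channel consumer device: electrodes
AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4 (10-10
placement, references P3/P4), 2048 Hz internal sampling decimated to a
128 Hz stream, 14-bit quantization at 0.51 µV per LSB, 0.16–43 Hz
bandwidth, 50/60 Hz notches, 8400 µVpp dynamic range. Note the printed
range and `0.51 x 2^14 = 8355.84` µV disagree by ~0.5%; the profile
stores both as printed and the validity check tolerates 2% rather than
forcing consistency.

Each channel is synthesized as

> pink noise (1/f power, scale `noise_scale_uV`) +
> one sinusoid per band, amplitude `band_gain x state_modulation(state(t))`,

where `state(t)` is derived from the timeline: **onset** during displays
and probes of non-practice trials, **offset** during rests, **other**
elsewhere. Oscillator frequency and phase are redrawn per state segment,
uniformly within the band but keeping a margin (default 1 Hz) from the
band edges so that, at the analysis resolution of 0.5 Hz, a band's
energy stays attributable to that band. Sinusoidal oscillators are a
deliberate idealization: they make Parseval's theorem an exact oracle
(a tone of amplitude A carries band power A²/2).

Numerical choices in the signal chain:

- **Filtering is zero-phase and applied in the frequency domain**: the
  spectrum is multiplied by the squared-magnitude responses of a
  2nd-order Butterworth high-pass at 0.16 Hz and 2nd-order band-stops at
  50/60 Hz (exact zeros at the notch frequencies). This is what
  forward-backward filtering does to a stationary signal, at a fraction
  of the cost, and it preserves event alignment exactly for epoching.
- **The 43 Hz "bandwidth" is read as a flat passband edge**, with a
  raised-cosine rolloff reaching zero at the output Nyquist (64 Hz)
  before decimation. A conventional low-pass with its −3 dB point at
  43 Hz would attenuate upper-gamma tones by tens of percent, which
  would make in-band spectral fidelity unattainable; the flat-passband
  reading preserves fidelity for all four bands while keeping decimation
  alias-free by construction.
- **Quantization** rounds to the LSB grid and clips on the code grid
  (±⌊4200/0.51⌋ codes, i.e. within one LSB of the range edge), which
  makes it exactly idempotent.
- Pink noise is shaped in the frequency domain from white Gaussian
  noise and normalized to its target standard deviation.

Contact quality is emulated as a bounded random walk over the standard
five color levels (black/red/orange/yellow/green = 0–4); the numeric
thresholds behind real wizards are proprietary, so the mapping is an
emulator convention, not a claim about any vendor's internals.

## Sessions and the behavioral responder

A session binds one participant and one task run. Since such headsets
have no hardware trigger input, stimulus-to-sample locking is arithmetic
on the shared clock: `index = floor((onset − start) × fs)`, 0-based,
with half-open event intervals; reconstruction errs by under one sample
period.

The responder presses on matched probes with probability
`plogis(qlogis(hit_rate_base) + engagement_acc_slope × engagement)` and
on unmatched probes with `false_alarm_rate`. Reaction times are
lognormal — the standard positively skewed RT model — with median
`rt_median_s + engagement_rt_slope × engagement` and log-scale sigma
`rt_sigma`, truncated to the response window via the inverse CDF (so
truncation stays deterministic under the seed). Presses outside probes
are not modeled; keypresses on display events would be ignored and
excluded from metrics. Windows below a 50 ms floor are refused.

## Analysis

- **Cleaning**: fixed windows (default 1 s) are masked per channel when
  peak amplitude exceeds 100 µV or variance is zero (flatline). This is
  the simplest defensible artifact rule; the package ships a transient
  injector purely to test it against known ground truth.
- **Epochs**: onset epochs span each non-practice trial from first
  display onset to probe offset (so the shortest 2-Back onset epoch is
  6 s); offset epochs span rests. Epochs overlapping any masked window
  are dropped.
- **Welch PSD**: periodic Hann window, 2 s segments, 50% overlap,
  mean-detrended, one-sided density normalized so its integral equals
  mean squared amplitude. 2 s windows give 0.5 Hz resolution — enough to
  resolve the 4 Hz theta floor — and always fit the shortest epoch.
- **Band power** is the trapezoidal integral of the density over the
  half-open band `[low, high)`, in µV² (not mean density; the integral
  makes the Parseval oracle exact). Bands tile 4–43 Hz: theta [4,8),
  alpha [8,12), beta [12,30), gamma [30,43) — the conventional edges,
  with gamma clipped at the device bandwidth; half-open intervals make
  binning at 8 and 12 Hz unambiguous. Relative (total-power-normalized)
  powers are available behind a flag; absolute is the default.
- **Behavioral scoring** is standard signal detection: hits, misses,
  false alarms, correct rejections, accuracy = (hits + CR)/probes, and
  mean RT over hits only. Participants without hits lose their RT metric
  and are excluded pairwise, not listwise.
- **Cohort statistics**: Spearman's ρ from average ranks with a
  two-sided exact permutation p-value for n ≤ 9 and the t approximation
  with n−2 df above; Pearson's r with the t reference. Cohort rows
  report the n actually used after the pairwise join; combinations with
  fewer than 3 complete pairs are skipped with a warning. Raw p-values
  are reported by default (as is conventional for these small cohorts);
  a Benjamini–Hochberg column is available behind a flag.

## Ground-truth coupling and parameter recovery

The generator's purpose is to let the pipeline be validated by
recovering a planted brain–behavior association. Two correlated
standard-normal latents drive a participant: an EEG engagement trait *e*
multiplying the coupled band amplitude by `exp(coefficient × e)` in the
coupled state (default: theta at P7 during onset, coefficient 0.4), and
a behavioral latent *b* shifting the median RT linearly (default slope
0.15 s per unit). For bivariate normal latents with Pearson correlation
*r*, any monotone transforms have population Spearman correlation
`(6/π) asin(r/2)`; the generator inverts this — `r = 2 sin(π ρ*/6)` — so
the planted population rank correlation is exactly the requested ρ*.
Both measured quantities are kept high signal-to-noise (the oscillator
dominates the in-band pink noise; ~12 expected hits average the RT
noise), so measurement attenuation of the recovered correlation stays
small.

The replicate study simulates 200 cohorts of 15 participants, each a
24-trial 2-Back session (no practice, 20 s rests), synthesizing only the
coupled electrode, on a profile identical to the standard one except for
a 256 Hz internal rate. Problem sizes are the package's choice: no
synthesized content lies above 43 Hz, so the reduced internal rate is
spectrally equivalent while hundreds of replicate cohorts stay
desk-scale; 24 trials keep per-participant behavioral estimates stable
without inflating session length. Under these conditions the mean
recovered ρ sits near 0.57 — the planted 0.6 minus small measurement
attenuation and the finite-n bias of rank correlations — with the
correct sign recovered in effectively all replicates, and null-coupling
cohorts center on zero.

## Storage

The two-store design — a schema-less time-indexed point store for
signal/event points and a relational store for participants, groups and
task specs — is honored as two contracts inside one directory, not as
external services: points persist as JSON-lines with last-writer-wins
upsert on (measurement, microsecond timestamp, tags) and half-open range
queries; metadata persists as JSON with referential integrity (a
participant referenced by a group cannot be deleted); whole recordings
are stored as EDF blocks (one signal per channel, µV, 1 s records)
rather than as millions of points. Microsecond timestamp resolution
leaves headroom over the 7.8 ms sample spacing. Exports are EDF + JSON +
CSV throughout; byte-identical reruns under fixed seeds are a tested
contract, which is why session start times are explicit inputs rather
than wall-clock reads.

## What the tests show — and what they cannot

The suite validates the pipeline against ground truth the generator
knows: exact composition arithmetic, Parseval-level spectral fidelity,
statistic oracles, masked-artifact localization, and recovery of planted
cohort correlations. Passing all of it shows the *pipeline* is correct
and unbiased under its own generative model. It does not show that real
recordings satisfy that model: real EEG rhythms are broadband and
nonstationary rather than segment-wise sinusoidal, artifacts are richer
than amplitude transients (ocular, muscular, electrode pops), channels
are volume-conduction correlated rather than independent, and real
brain–behavior couplings need not be monotone in any latent trait.
Cohort-level inferences from real data also inherit the usual caveats of
n ≈ 15 designs and raw p-values. The emulator is a validation
instrument, not a head model.

## Known limitations

- No reference re-montaging, channel interpolation, ERP averaging,
  time-frequency analysis or source localization.
- The point store is single-process and in-memory-backed; it targets
  session-scale workloads, not service-scale ones.
- EDF support covers the subset this package writes (equal rates per
  signal, 1 s records); it is not a general EDF+ implementation.
- Valence and eyes tasks generate signals and timelines but no
  behavioral model beyond placeholders.
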