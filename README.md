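# cogstream

Headless R pipeline for EEG-driven cognitive-neuropsychological
experiments with consumer-grade headsets — from task design to cohort
statistics, with no hardware in the loop.

Studies of working memory in clinical populations (e.g. elderly
participants at risk of executive decline) increasingly use wireless
consumer EEG devices: a 14-channel, 128 Hz headset with saline electrodes
placed on the 10-10 system, paired with computerized tasks such as the
word n-Back. The analysis asks how band-limited oscillatory power —
theta (4–8 Hz), alpha (8–12 Hz), beta (12–30 Hz), gamma (30–43 Hz) —
during task-engaged ("WM onset") versus resting ("WM offset") brain
states relates to behavior (reaction time of hits, response accuracy)
across a cohort.

`cogstream` implements that entire pipeline headlessly and adds the piece
a methods paper cannot ship: a **device emulator with known ground
truth**, so the pipeline's statistics can be validated by parameter
recovery instead of trusting them on faith.

## What is in the box

- **Task engine** — composes word n-Back blocks (trial types `n … n+3`
  in fractions 1/3, 1/4, 1/4, 1/6; exactly half the probes matched;
  2 s stimulus cadence; rest every 12 trials; practice trials flagged),
  eyes-open/closed schedules, and affective-valence image sequences, all
  as absolute-time event timelines, deterministic under seeds.
- **Headset emulator** — renders a timeline into a microvolt signal:
  1/f (pink) background plus one oscillator per band whose amplitude
  follows the task state, generated at the device's internal rate
  (2048 Hz), band-limited to 0.16–43 Hz, notch-filtered at 50/60 Hz,
  decimated to 128 Hz and quantized at 0.51 µV/LSB over an 8400 µVpp
  range. A latent engagement trait couples one chosen band's amplitude to
  simulated behavior.
- **Session runtime** — binds timeline, recording and a parameterized
  responder (logistic hit/false-alarm model, truncated-lognormal RTs)
  into sessions; aligns events to samples (`floor((t - t0) * fs)`, since
  such headsets have no hardware trigger input).
- **Stores** — a schema-less time-indexed point store (tagged points,
  half-open range queries, last-writer-wins upsert) plus relational
  participant/group/task metadata with referential integrity, persisted
  as JSON/JSON-lines and EDF blocks in one directory.
- **Analysis** — amplitude/flatline artifact masking, state epoching,
  Welch PSD (2 s Hann windows, 50% overlap, density normalized so the
  integral equals mean squared amplitude), per-band integrated power
  ⌠[low,high) PSD(f) df in µV², signal-detection behavioral scoring, and
  cohort correlations: Spearman's ρ with an exact permutation p-value for
  n ≤ 9 (t approximation above), and Pearson's r with the t reference.

## Worked example

```r
library(cogstream)

profile <- epoc_default_profile()
spec    <- nback_spec(n = 2, total_trials = 36, seed = 7)

sequence <- compose_nback(spec)
sequence
#> <trial_sequence> 2-Back, 36 trials (18 matched)
#> displays
#>  2  3  4  5
#> 12  9  9  6

timeline <- build_timeline(sequence, spec)
timeline
#> <event_timeline> 183 events over 450.0 s
#> kind
#> display   probe    rest
#>     137      43       3

truth <- participant_truth(profile, engagement = 0.8,
  coupling = list(electrode = "P7", band = "theta",
                  state = "onset", coefficient = 0.4),
  seed = 7)
session <- run_session(participant("p01", age = 72), spec, profile, truth,
                       responder = responder_model(seed = 7),
                       channels = c("P7", "F7"))

behavioral_metrics(session)
#>   participant_id hits misses false_alarms correct_rejections  accuracy mean_rt_hits_s
#> 1            p01   14      4            2                 16 0.8333333      0.7421735

subset(session_band_power(session, electrodes = "P7"), band == "theta")
#>   participant_id session_id  state electrode  band mean_power_uV2 n_epochs
#> 1            p01  p01-nback  onset        P7 theta      15.290941       36
#> 5            p01  p01-nback offset        P7 theta       8.241723        3
```

The 36 trials split exactly into the configured type fractions with 18
matched probes; the 450 s timeline holds 137 display and 43 probe slots
(7 practice trials included) and 3 rests. The responder produced 14 hits
and 16 correct rejections (accuracy 30/36). Theta power at P7 is ~15.3 µV²
during task engagement versus ~8.2 µV² at rest: the participant's
engagement (+0.8) multiplied the coupled onset theta amplitude by
`exp(0.4 × 0.8) ≈ 1.38`, i.e. power by ~1.9 over the 8 µV² baseline.

At cohort level, with a planted population rank correlation of 0.6
between onset theta-P7 power and mean hit RT:

```r
cohort <- simulate_cohort(n_participants = 15, rho = 0.6, seed = 11)
recover_cohort_correlation(cohort)
#>   electrode  band state         metric statistic  estimate   p_value  n
#> 1        P7 theta onset mean_rt_hits_s  spearman 0.5607143 0.0296765 15
```

A command-line interface wrapping the same functions lives at
`inst/cli/cogstream.R` (`compose`, `run`, `simulate-cohort`, `analyze`,
`export`).

## Layout

```
R/                  implementation
inst/cli/           command-line entry point
inst/extdata/       canonical device profile (epoc.json)
tests/testthat/     unit, property and acceptance tests
scripts/            acceptance script
vignettes/          methods vignette (model, parameters, design choices)
```
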