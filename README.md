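# gazefix

Velocity-based fixation detection for low- *and* high-quality eye-tracking
data.

## The problem

Fixation durations are a workhorse measure of attention and information
processing, but detecting fixations automatically is only easy when the
recording is clean. Data from infants, clinical groups, or low-cost
eye trackers routinely combines low spatial precision (sample-to-sample
jitter that inflates apparent gaze velocity), frequent missing samples, and
episodes where only one eye is detected. A fixed-parameter event detector
fed such data either shreds true fixations into artifactual fragments or
welds neighbouring fixations together.

`gazefix` implements an adaptive velocity-threshold (I-VT-family) pipeline
built for exactly this regime, for researchers who need per-participant
parsing of variable-quality recordings:

1. **Combine & smooth** — average the two eyes (configurable one-eye
   policy) and suppress jitter with a *bilateral filter*: each sample
   becomes a weighted mean of its neighbours with weight
   `G(Δt; σ_t) · G(‖Δx‖ in deg; σ_r)`, so averaging never crosses a
   saccade-sized displacement and saccades stay sharp.
2. **Interpolate** — fill missing-data gaps, but only those short enough
   (gap ≤ interpolation latency) *and* safely inside a fixation (flanking
   fixation centroids closer than the maximum interpolation displacement).
3. **Segment** — per-sample velocity `v_i = ‖x_{i+1} − x_i‖ · dpp · f_s`
   (deg/s); samples with `v > v_thr` are saccadic, maximal runs of missing
   samples are gaps, the data segments in between are fixations.
4. **Validate post hoc**, in this order: (i) merge adjacent fixations
   closer than Δt_merge in time and d_merge in space, (ii) delete fixations
   whose intersample RMS exceeds a bound, (iii) delete fixations shorter
   than a minimum duration. Rejected fixations are kept in an audit list
   with flags, supporting later manual moderation.

Two shipped presets carry the published parameter sets
(`detection_preset("high_precision")`: v_thr 9°/s, min duration 99 ms;
`"low_precision"`: 20°/s, 120 ms, wider merge distance). The package also
computes the data-quality metrics used to stratify participants (RMS
intersample precision, dispersion SD, data loss), per-fixation pupil means,
and ships a synthetic gaze simulator with ground-truth events so every
stage is testable without real recordings.

## Worked example

The package ships a small synthetic recording (simulator output: four
fixations, RMS ≈ 0.12°, two injected missing-data gaps):

```r
library(gazefix)
path   <- system.file("extdata", "example_gaze.csv",     package = "gazefix")
schema <- system.file("extdata", "schema_default.json",  package = "gazefix")
rec <- read_gaze(path, schema, sampling_rate = 120)
quality_report(rec)
#> <quality_report>
#>   RMS precision (all): 0.3716 deg
#>   dispersion SD: x 2.3712 deg, y 0.7668 deg
#>   data loss: 4.3% (left 4.3%, right 4.3%)
#>   single-eye samples: 0.0%

det <- detect_fixations(rec, detection_preset("high_precision"), verbose = TRUE)
#> detect_fixations: interpolated 2 gap(s); merged: 0, rms-rejected: 0, duration-rejected: 0
det$fixations$surviving[, c("id", "onset", "offset", "duration", "rms", "n_samples")]
#>   id    onset   offset duration         rms n_samples
#> 1  1    0.000  583.333 583.3330 0.009731160        70
#> 2  2  608.333 1133.333 525.0000 0.011698456        63
#> 3  3 1158.333 1516.667 358.3340 0.009859882        43
#> 4  4 1541.667 1958.333 416.6663 0.011880767        50
```

Reading: the all-samples RMS (0.37°) is inflated by saccadic displacements —
within fixations the smoothed trace sits near 0.01° RMS. Both 40 ms data
gaps fell inside fixations and passed the displacement gate, so they were
interpolated instead of splitting their fixations; four fixations survive
with onsets/offsets in ms, centroids in pixels, and per-fixation pupil
means.

Simulation with ground truth, and recovery scoring:

```r
sim <- simulate_gaze(simulation_params(n_fixations = 20, noise_rms = 0.30, seed = 7))
det <- detect_fixations(sim$recording, detection_preset("low_precision"))
score_recovery(det, sim$truth)
#> <recovery_report> hit rate 1.000 (20/20), false detections 0.000 (0 extra)
#>   mean |onset error| 2.8 ms, |offset error| 3.0 ms, duration ratio 1.014
```

## Command line

An Rscript wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gazefix.R", package = "gazefix"))')
Rscript "$CLI" simulate --seed 7 -o raw.csv --truth truth.csv
Rscript "$CLI" detect raw.csv --params high_precision -o fixations.csv \
    --segments segments.csv --rejected rejected.csv --run-record run.json
Rscript "$CLI" quality raw.csv -o quality.json
Rscript "$CLI" score --detected fixations.csv --truth truth.csv -o score.json
```

`--params` takes a preset name or a JSON config (see
`inst/extdata/params_*.json`); `--schema` a JSON column mapping for
arbitrary vendor exports. Every `detect` run can emit a run record (fully
resolved parameters, input digest, per-criterion counts) so detection
settings are always reportable.

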