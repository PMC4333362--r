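---
title: "Fixation detection in variable-quality gaze data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation detection in variable-quality gaze data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefix)
```

## The model

An eye tracker emits a stream of samples: timestamp, per-eye x/y screen
coordinates, per-eye validity. During a **fixation** the eyes are
stationary up to measurement jitter; during a **saccade** the gaze
position changes rapidly. Velocity-threshold (I-VT-family) detection
exploits that separation: with per-sample velocity

$$v_i = \lVert \mathbf{x}_{i+1} - \mathbf{x}_i \rVert \cdot
  \mathrm{dpp} \cdot f_s \quad [\text{deg/s}],$$

samples with $v_i > v_{thr}$ are flagged saccadic and the data segments
between two saccades are fixations. The assumption that breaks down in
low-quality data is that jitter velocity stays below $v_{thr}$: with RMS
spatial precision $r$ (deg) the jitter alone contributes velocities of
order $r \cdot f_s$ — at 120 Hz, a 0.30° precision recording jitters at
~36 deg/s, far above any sensible threshold. The pipeline therefore
(1) suppresses jitter before thresholding, (2) repairs missing-data gaps
that would masquerade as events, and (3) cleans the segmentation with
ordered post-hoc filters whose thresholds are adapted to each recording's
quality.

### Eye combination

Both eyes valid → arithmetic mean; exactly one valid → that eye's
coordinates (flagged `single_eye`) when `include_single_eye = TRUE`, else
missing; neither → missing. Keeping one-eye samples is recommended for
infant data, where a hand over one eye is common and the remaining eye is
usually fine; the per-fixation `single_eye_fraction` lets a user audit the
consequence. Pupil values combine under the same rule.

### Bilateral smoothing

Each available sample is replaced by a weighted mean of available
neighbours within ±`window` ms:

$$w_{ij} = \exp\!\left(-\frac{\Delta t_{ij}^2}{2\sigma_t^2}\right)
           \exp\!\left(-\frac{d_{ij}^2}{2\sigma_r^2}\right),$$

with $\Delta t$ the time difference and $d$ the positional distance in
degrees. The *range* kernel is what distinguishes this from a low-pass
filter: across a saccade of amplitude $A$, cross-plateau weights scale as
$e^{-(A/\sigma_r)^2/2}$ (≈ $e^{-50}$ for a 5° saccade at
$\sigma_r = 0.5°$), so plateaus are denoised without being dragged toward
each other — jitter is eliminated while saccades are preserved.

The kernel widths are tunable (`smoothing_params()`), with defaults
`window = 100` ms, `temporal_sigma = 20` ms, `range_sigma = 0.5°`. These
are this package's own choices: the window is kept shorter than the
shipped minimum fixation durations (99/120 ms) so the filter cannot bridge
whole events, and the range sigma sits above plausible jitter (≤ ~0.4°)
but below typical saccade amplitudes. They are not claimed to match any
other implementation.

### Velocity

The forward intersample difference, assigned to the leading sample of
each pair ($v_i$ from samples $i, i+1$); the last sample copies its
predecessor, and $v$ is undefined where either endpoint is missing. An
available sample with undefined velocity cannot be shown to be saccadic
and falls to the fixation class. No acceleration is computed and no
higher-order derivative filter is used: the detected quantity is exactly
the rate of change from one gaze point to the next.

### Gated interpolation

Only gaps that can safely be assumed to lie *within* a fixation are
filled, under two gates:

* **latency**: the span of missing samples is ≤ `interpolation_latency`
  (default 60 ms — chosen because genuinely codable fixations shorter
  than this do not occur in the target data; users wanting the
  saccade-programming argument can raise it toward 150 ms);
* **displacement**: both flanking segments are fixations and their
  centroids (over available samples) lie closer than
  `max_interpolation_displacement` (0.25°) — the eyes came back to where
  they were, so no saccade hid inside the gap.

Decisions are taken on the pre-interpolation segmentation in a single
pass, then the gap is filled by linear interpolation between the last
available sample before and the first after; velocity and segmentation
are recomputed once from scratch. Edge gaps have only one flank and are
never filled. Two readings were open here and are resolved as follows:
the latency gate is *fill iff gap ≤ latency* (the alternative reading —
fill longer gaps — contradicts the gate's stated purpose), and the
displacement gate compares the two flanking centroids (the simplest
operationalisation of a "maximum displacement between the two ends"; the
decision is logged via `interpolated` flags so users can audit every
filled sample). Gap duration is measured as the span of the missing
samples themselves.

### Post-hoc validation, in this order

1. **Merge** adjacent fixations with an inter-fixation interval strictly
   under `merge_max_gap` (50 ms) *and* centroid distance at most
   `merge_max_distance` (0.24°/0.35°). Greedy left-to-right scan iterated
   to a fixed point, so a merged fixation can merge again; the scan order
   makes the result deterministic. The merged record spans onset-to-offset
   (bridged interval counts toward duration — the duration should reflect
   the inferred single fixation) but pools centroid/RMS/pupil over member
   samples only, so statistics are not polluted by the bridged saccadic
   samples. Distances above 0.45° are warned against: that scale starts
   swallowing genuine small saccades.
2. **RMS rejection**: fixations whose intersample RMS (both axes
   together, consecutive available pairs, in degrees) is strictly above
   `max_rms_per_fixation` are rejected.
3. **Duration rejection**: fixations strictly shorter than
   `min_fixation_duration` are rejected.

The order matters: merging first lets several short fragments of one true
fixation survive the duration filter as a single merged fixation that
none would survive alone (the package's acceptance tests pin this
behaviour). Rejected fixations are never discarded — they move to an
audit list with `rejected_rms`/`rejected_duration` flags, because the
intended workflow is automatic parsing followed by manual moderation.

Boundary conventions follow the thresholds' verbal definitions literally:
merge gap strict (`<`), merge distance inclusive (`≤`), RMS rejection
strict (`>`), duration rejection strict (`<`). A fixation exactly at a
bound is therefore kept.

**Merging never bridges missing data.** A design point that was genuinely
open: should two fixations separated by a short *data gap* (rather than by
spurious saccade flags) merge? This package says no — the separator must
be free of missing samples. Bridging data gaps is exactly the job of the
interpolation stage, which has a displacement gate to rule out a hidden
saccade; letting the merge filter bridge any ≤ 50 ms gap regardless of
displacement would silently bypass that gate and make the effect of
interpolation unobservable. Hand-built fixation tables passed directly to
`merge_adjacent()` carry no separator information and are treated as
mergeable.

## Parameters at a glance

| parameter | unit | high preset | low preset | role |
|---|---|---|---|---|
| `interpolation_latency` | ms | 60 | 60 | longest fillable gap (0 disables) |
| `velocity_threshold` | deg/s | 9 | 20 | saccade flagging |
| `max_interpolation_displacement` | deg | 0.25 | 0.25 | gap displacement gate |
| `degrees_per_pixel` | deg/px | 0.0177 | 0.0177 | isotropic unit conversion |
| `merge_max_distance` | deg | 0.24 | 0.35 | merge spatial gate (≤) |
| `merge_max_gap` | ms | 50 | 50 | merge temporal gate (<) |
| `max_rms_per_fixation` | deg | 0.24 | 0.21 | precision rejection (>) |
| `min_fixation_duration` | ms | 99 | 120 | duration rejection (<) |

The presets mirror the published high-/low-spatial-precision parameter
sets for 120 Hz infant recordings; they are starting points, meant to be
adapted per participant as data quality varies. Noisier data wants a
higher velocity threshold (fewer false saccades), a wider merge distance,
and a longer minimum duration; high-precision, high-rate data wants the
opposite, and post-hoc merging should be avoided altogether when
microsaccades are of interest.

## The synthetic-data generator

`simulate_gaze()` emulates the regimes the detector must survive:
alternating fixations (durations uniform on a configurable range, default
200–800 ms) and saccades (default 5°, 30 ms) with a minimum-jerk position
profile $s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$, so peak saccade
velocity scales realistically as $1.875\,A/D$ (≈ 312 deg/s for the
default); optional constant-velocity pursuit ramps (excluded from
fixation ground truth, matching coding guidelines that delete pursuit);
per-eye i.i.d. Gaussian jitter; both-eye gaps injected mid-fixation;
single-eye episodes; optional vergence offset.

**Noise calibration.** The dial is the intersample RMS precision of the
*combined* trace. With independent per-eye, per-axis jitter of sigma
$\sigma_e$, the two-eye average has per-axis sigma $\sigma_e/\sqrt{2}$,
an intersample difference doubles that variance, and two axes add:
$\mathrm{RMS} = 2 \cdot \sigma_e/\sqrt{2} = \sigma_e\sqrt{2}$. The
generator therefore uses $\sigma_e = \texttt{noise\_rms}/\sqrt{2}$
(equivalently: the combined trace has per-axis sigma `noise_rms`/2), and
the calibration is verified by Monte-Carlo in the acceptance suite
(measured within 10% of target at 0.10° and 0.30°).

**What a green test does and does not establish.** The simulator's jitter
is white and Gaussian; real oculomotor and tracker noise is temporally
autocorrelated, heteroscedastic across the screen, and punctuated by
drift, head motion, and blink artefacts. The bilateral filter is more
effective against white jitter than against correlated noise, so the
near-perfect hit rates on simulated 0.30° data should be read as "the
pipeline's operators behave as specified", not as a performance claim for
real infant recordings — on real data the published expectation is that
automatic parsing still needs manual moderation. Saccade amplitude is
fixed per simulation (no main-sequence variability) and gaps are placed
mid-fixation (the easiest case for the displacement gate, and the
intended one).

## Numerical choices and degenerate inputs

* Time in ms, positions in pixels internally; every threshold in
  deg/deg s⁻¹/ms; conversion only through the single isotropic
  `degrees_per_pixel`.
* Event intervals are half-open `[onset, offset)`; segments tile the
  recording gap-free, and `duration = offset − onset`; the final segment
  closes one sample period after its last sample.
* Missing data is `NA`, never a sentinel; `read_gaze()` can map vendor
  sentinels (e.g. −1) to missing, and a validity flag of 0 overrides
  stored coordinates.
* `interpolation_latency = 0` is the documented "interpolation off"
  switch; all other thresholds must be strictly positive.
* A trace with no available samples segments to an empty table with a
  warning (not an error); precision metrics on fewer than two available
  samples raise a typed error; a fixation with fewer than two samples has
  RMS 0.
* The whole pipeline is deterministic: identical inputs and parameters
  give bit-identical fixation tables; the simulator is deterministic
  under its mandatory seed.
* Recording-level RMS precision defaults to all-pairs mode on the raw
  combined trace; `quality_report()` switches to within-fixation mode
  (manufacturer convention — precision during stable gaze) when detection
  parameters are supplied.

## Known limitations

* No adaptive (data-driven) velocity threshold; adaptation is manual,
  via presets or per-participant configs.
* No automatic smooth-pursuit or glissade/microsaccade classification;
  pursuit is simulated for robustness testing but detection labels it
  like any other sample run.
* A single isotropic degrees-per-pixel factor; recordings with strongly
  anisotropic geometry need their own conversion upstream.
* No calibration-drift or offset correction; precision metrics are
  offset-invariant by construction, but accuracy is out of scope.
* The graphical hand-moderation step of the intended two-step workflow is
  out of scope; the audit list and flags exist to feed such a tool.
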