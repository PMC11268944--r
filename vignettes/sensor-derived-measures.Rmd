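---
title: "From raw structured-test recordings to sensor-derived measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw structured-test recordings to sensor-derived measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmkit)
```

`sdmkit` extracts sensor-derived measures (SDMs) from structured tests
recorded with smartphones and wearables. This vignette explains the data
model, the extraction algorithms and their assumptions, the quality-flag
system, the numerical choices made where the design was genuinely open,
and what the synthetic-data generators do and do not emulate.

## The data model

A **reading** is one subject's session of one test. Tests are composed of
sub-tasks: a drawing session asks for four shapes, twice, with both
hands. Each attempt is a **level**, and the dimensions that distinguish
levels — shape, hand, attempt — are **modalities**. Levels carry raw
columnar **datasets** (first column a non-decreasing timestamp in seconds
relative to reading start), protocol **context** (e.g. the reference
polyline of the shape to draw, the expected test duration), analysis
**epochs**, extracted **measures** and **flags**.

Timestamps are 64-bit floats in seconds, relative to the reading start.
This is vendor-neutral and sidesteps epoch and timezone conventions; a
recording's absolute start time, if known, belongs in the metadata bag.

Measure ids are generated, never hand-written:
`{task}-{modality values joined by "_"}-{abbr}[-{agg}]`. The mapping is
deterministic and injective provided modality values avoid the two
reserved separators; the id alone identifies the test, the level and the
quantity. Flag ids follow `{task}-{domain}-{severity}-{name}`. Two
domains (technical, behavioral) separate device problems from user
behaviour; two severities separate "annotate" (deviation) from
"distrust" (invalidation). Flags always annotate: no operation in the
package deletes a measure or a sample because of a flag, so post-hoc
filtering remains entirely in the analyst's hands.

## The processing graph and the data trace

A pipeline is an ordered list of declared steps. Each step names its kind
(transform, extract, flag), its input and output ids, an optional level
filter, and parameters that are frozen at declaration and recorded
verbatim in the trace. Execution is declaration order, independently per
level: levels are independent sub-task attempts, so a flag that stops
processing (``stopped_processing = TRUE``) aborts downstream steps on the
flagged level only, never the whole reading. A step whose inputs are
absent on a level is recorded as `skipped_missing_input` and does not
raise — incomplete recordings are the rule, not the exception, in
unsupervised data collection.

Every run emits a trace: nodes for the reading, levels, datasets, epochs,
measures and step instances; dotted containment edges and directed
input/output flow edges. The trace is checked to be acyclic
(`trace_is_acyclic()`), and every measure is reachable from a raw dataset
through flow edges (`trace_measures_reachable()`). Cyclic step
declarations are rejected before any execution.

## Extraction algorithms

### Step detection and cadence (`sixmwt`)

The six-minute walk uses a belt-worn device on the lower back, gravity
expected on +z. Gravity is estimated as the per-axis median — robust
against activity bursts and much simpler to reason about than a low-pass
split. The step detector band-passes its input with a zero-phase
(forward–backward) Butterworth filter, 0.5–5 Hz by default, covering
physiological step frequencies while removing drift and impact
harmonics; peaks must have a topographic prominence of at least
0.3 m/s² and be separated by at least 0.25 s (a 240 steps/min ceiling).
Cadence is `60 · count / span`; minute-wise cadence aggregates use
half-open windows `[k·60, (k+1)·60)` seconds.

One composition choice matters: the detector is fed the *signed
projection* of the gravity-subtracted acceleration onto the gravity
axis, not the Euclidean norm of the dynamic acceleration. The norm
rectifies the vertical oscillation — every swing through zero creates a
second peak per cycle — and doubles the apparent step rate; the signed
projection keeps one peak per step.

The zero-phase filter is symmetrized: the forward–backward pass is
averaged with its time-reversed counterpart, which makes the
time-reversal symmetry of the filter exact rather than approximate at
the record edges. The 0.5 Hz high-pass edge has a transient of several
seconds; extraction windows of a minute or more make this negligible.

### Turns (`utt`)

Turns are intervals where the yaw-rate magnitude stays at or above
15 °/s with constant sign; the angle is the trapezoidal integral of the
rate over the interval, and intervals reaching 160° absolute become turn
epochs (angle, duration, peak rate as payload). The integration interval
is extended by the half-sample trapezoids to the adjacent sub-threshold
samples: a sampled constant-rate block then integrates to its exact
rectangle area instead of losing one sample period of area (0.9° at
100 Hz for a 90 °/s turn). Sign is preserved throughout: playing a
recording backwards in time negates the rate samples and therefore the
detected angles.

### Postural sway (`sbt`)

With the device on the belt, anteroposterior sway is the x axis and
mediolateral the y axis after median gravity removal. Means are removed,
then: RMS per axis; the 95% confidence ellipse area
`π · χ²₀.₉₅,₂ · √(λ₁λ₂)` with `χ²₀.₉₅,₂ = 5.991` and `λᵢ` the
eigenvalues of the 2×2 covariance — a rotation invariant of the AP/ML
plane; and a jerk RMS pooling the first differences of both axes divided
by the sampling period. For isotropic Gaussian sway of standard
deviation σ the expected ellipse area is `π·5.991·σ²`, which the test
suite and acceptance script verify on generated recordings.

### Drawing similarity (`draw`)

Both the finger trace and the reference polyline are resampled to 100
points equally spaced in arc length. The primary measure `sim` is the
mean Euclidean distance between index-coupled points: zero for a perfect
trace, exactly the offset magnitude for a rigid translation. `dtw_sim`
relaxes the index coupling with full (unconstrained) dynamic time
warping, Euclidean local cost, normalized by the optimal path length.
Because the identity alignment is one admissible path of length 100,
`dtw_sim ≤ sim` always; the gap between the two quantifies how much of
the error is timing rather than shape. Arc-length resampling first also
caps the DTW cost matrix regardless of trace length.

### Pinching, event streams, cognition

A pinch attempt is a maximal interval with two simultaneous screen
contacts; it succeeds when the inter-contact distance drops below the
protocol's target distance. Contacts that never overlap raise the
`single_finger` behavioural flag. Tapping, typing, grip and sit-to-stand
variants share one event-stream backend: count, rate over the
first-to-last span, inter-event interval mean and CV.

Symbol–digit substitution scores a response correct when it equals the
key map of its stimulus. Reaction times are summarized over correct
trials; drift is the mean RT of the last third minus the first third of
trials — positive drift indicates slowing across the test.

### Questionnaires

Scoring rules are data, not code: an instrument is its item count, item
range and subscale definitions. MSIS-29 keeps the original 1–5 item
scale, physical = items 1–20 and psychological = items 21–29, each
transformed to 0–100 as `100·(sum − n)/(4n)`. ALSFRS-R sums 12 items
scored 0–4 (total 0–48). PDQ-39 scores its 8 published dimensions as
`100·sum/(4n)` and the summary index as their mean. The remaining three
registry slots (`mood`, `fatigue`, `qol`) are generic placeholder
instruments wired through the same engine — they demonstrate that new
instruments are configuration, not code, and carry no clinical claim.
All transforms are monotone non-decreasing in every answer, which the
suite checks property-style. Out-of-range answers are a validation
error, not a flag: a corrupted questionnaire payload is a data defect,
not a user behaviour.

## Quality flags and thresholds

Three automatic checks guard the inertial pipelines, with thresholds
collected in `sdm_config()` and overridable by YAML or a named list:

| check | default rule | rationale |
|---|---|---|
| sampling stability | `sd(Δt)/mean(Δt) > 0.10` or a gap `> 1.5` nominal periods | 10% timing jitter visibly biases band-pass output; 1.5 periods is the smallest gap distinguishable from jitter |
| device orientation | median of the expected gravity component has the wrong sign or magnitude `< 0.5 g` | half a g on the wrong axis means the device cannot be in the instructed pose |
| protocol duration | recording spans `< 80%` of the expected duration | shorter tests change the construct (fatigue effects); 80% tolerates late starts without invalidating usable walks |

The expected duration comes from the level context, which the
generators record; absent a stated expectation, no duration flag is
raised. Non-monotone timestamps are flagged at load time
(`{task}-technical-deviation-ts_nonmonotone`) rather than rejected, and
the reading remains available for inspection.

## Synthetic recordings: what they do and do not show

The generators exist so the whole pipeline — IO, processing, extraction,
flags, export — is testable end to end without any device data, with
ground truth known by construction:

- `gen_walk()` uses a single-harmonic model: gravity on +z plus
  `1 m/s² · sin(2π · cadence/60 · t)` and white noise. One sine peak is
  one step. This exercises detection, cadence and aggregation logic; it
  is **not** a biomechanical gait model — no double support, no asymmetry,
  no harmonics, no pathological patterns. Passing the cadence-recovery
  suite shows the detector is correct on its stated model, not that it
  is clinically valid on patient data.
- `gen_sway()` draws iid Gaussian AP/ML acceleration, for which the
  ellipse area has the closed form `π·5.991·σ²`; real sway is
  autocorrelated.
- `gen_turns()` emits piecewise-constant yaw rate, exact by
  construction.
- `gen_drawing()` jitters the reference polyline; `gen_cps()` fixes the
  number of correct responses at `round(p·n)` so accuracy is exact.
- `corrupt()` injects dropped samples, a flipped vertical axis,
  truncation, or shuffled timestamps — one operator per flag path.

All randomness flows through one explicit seed per generator call
(`with_seed` saves and restores the caller's RNG state); identical seeds
give byte-identical readings.

Problem sizes in the test and acceptance suites — 60 s walks at 100 Hz,
ten seeds per condition, 6 000-sample sway records, 100-point drawing
resampling — were chosen as the smallest sizes at which the statistical
checks are stable (the sway closed form, for instance, needs a few
thousand samples for the sample covariance to settle within its 10%
band).

## Known limitations

- Walked distance is not estimated: a step-length model requires
  anthropometrics the data model does not carry.
- No sensor fusion or quaternion orientation handling; orientation
  checks are gravity-axis heuristics.
- Vendor file formats are out of scope; the canonical JSON dialect
  (schema in `inst/schema/reading.schema.json`) is the package's native
  format and vendor adapters are expected to target it.
- Questionnaire placeholders (`mood`, `fatigue`, `qol`) are synthetic
  instruments; replace their configurations before any real use.
- Scores and measures carry no normative reference values; analytical
  validity on the synthetic models does not imply clinical validity.
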