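---
title: "Quantifying motor-unit assays: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-unit assays: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(motorunit)
library(dplyr)
```

`motorunit` quantifies the readouts of compartmental motor-unit cultures —
spinal-cord explants innervating primary myofibers across a microfluidic
barrier — together with two related in vivo readouts (muscle-fiber
diameter and NMJ innervation). This vignette explains the models behind
each pipeline stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the design choices
made where the underlying protocols leave the definition open.

## Track kinematics

### The substrate

A *track* is the per-frame position of one tracked cargo (e.g.
quantum-dot-labelled BDNF) along the axon axis, in micrometers, sampled
uniformly in time. Axons in microfluidic grooves are quasi-one-dimensional,
and every statistic used here is a speed or displacement, so tracks are
one-dimensional by construction: position `x_um` along the axis, with
**retrograde motion (towards the soma) negative** and anterograde positive.
That sign convention is stated once and used everywhere. A second
coordinate column (`y_um`) in input files is accepted and carried through
but ignored by the kinematics.

Tracks must be uniformly sampled: frame intervals are checked against the
track mean with a relative tolerance of 1e-6, and a track with a dropped
frame is *rejected, not interpolated* — interpolating across a gap would
fabricate slow steps and silently alter the stop statistics.

### Statistics

For a track of $n$ frames with positions $x_i$ and frame interval
$\Delta t$:

* **Step speeds** $s_i = |x_{i+1} - x_i| / \Delta t$, one per inter-frame
  step ($n - 1$ in total).
* **Stops**: maximal runs of at least 3 consecutive steps with
  $s_i < 0.1\ \mu m/s$. The inequality is strict — a step at exactly
  0.1 um/s is not part of a stop — and runs of 1–2 sub-threshold steps
  are not stops. Both thresholds are arguments (`stop_speed_um_s`,
  `min_frames`).
* **Average velocity** $V_{avg} = |x_n - x_1| / (t_n - t_1)$: net
  displacement over elapsed time. This is the processive-transport rate
  used by the inclusion filter; a total-path-length variant is available
  via `average_velocity(path_length = TRUE)` for cases where the
  back-and-forth distance is of interest.
* **Instantaneous velocity** $V_{inst}$: the mean step speed, *excluding*
  steps inside detected stops by default. Speed-while-moving and pausing
  are reported as separate axes of change (a cargo can slow down without
  pausing more, and vice versa), which requires decoupling the two;
  `include_paused = TRUE` switches to the plain mean over all steps. A
  track whose every step lies in a stop gets $V_{inst} = 0$ and a
  `stationary` flag.
* **Run lengths**: the absolute net displacement of each maximal
  stop-free stretch of steps.
* **MSD**: the time-averaged mean squared displacement with overlapping
  windows, $\mathrm{MSD}(k) = \mathrm{mean}_i\,(x_{i+k} - x_i)^2$, for
  lags $k \ge 1$ (lag 0 omitted). Overlapping time-averaging is the
  standard single-particle-tracking estimator; the ensemble curve
  averages per-track MSDs at each lag, with tracks shorter than a lag
  simply not contributing to it. For a pure run at speed $v$,
  $\mathrm{MSD}(k) = (v k \Delta t)^2$ exactly; for a static particle
  observed with localization noise $\sigma$, the ensemble MSD converges
  to $2\sigma^2$ at every lag. Both limits are verified in the test
  suite.
* **Directionality**: retrograde / anterograde / stationary by the sign
  of the net displacement, with a +/- 1 um dead band (`min_net_um`) so
  that jitter around zero is not classified as transport.
* **Co-transport**: two tracks on the same frame grid are co-transported
  over maximal windows of at least `min_frames` frames in which their
  positions differ by less than `dist_um`.

### The inclusion filter

A track enters analysis when its duration is **strictly greater than 10
frames** and its average velocity is **at least 0.2 um/s** (inclusive).
These are the tracking protocol's printed criteria, implemented with
exactly the printed strictness on each side; both thresholds are exposed
as arguments. Filtering is idempotent, and `summarize_tracks()` keeps
excluded tracks in its per-track table with `passed_filter = FALSE` so
exclusions are auditable.

One consequence worth knowing: for tracks passing the velocity criterion,
$V_{inst} \ge V_{avg}$ always (pausing and backtracking can only lower
the net rate relative to the moving-step mean). For very slow unfiltered
tracks the default $V_{inst}$ (which excludes stop steps) can drop below
$V_{avg}$, because the excluded steps are not the slowest in a track
whose every step is slow. The invariant is therefore asserted on filtered
cohorts.

### Velocity distributions

`velocity_distribution()` histograms per-track average velocities
(default bin width 0.1 um/s), normalizes occupied-bin fractions to sum
to 1, and overlays an ordinary least-squares polynomial of the fractions
on bin centers. The source protocol draws a polynomial fitting curve
without stating its degree; the default here is cubic (degree 3), low
enough not to chase bin noise while still able to follow a skewed,
single-peaked velocity distribution, and the degree is an argument. When
there are fewer occupied bins than coefficients the degree is reduced
with a warning rather than fitting an underdetermined model.

## Contraction calling

Innervated myofibers twitch; denervated ones mostly do not. Contraction
movies (1000 frames at 30 fps) are reduced upstream to one
intensity-over-time trace per fiber ROI, and the pipeline classifies each
trace as contracting or non-contracting:

1. **Normalize** (`normalize_trace()`): deviation = (value − baseline) /
   baseline, with the **median** of the trace as baseline. The median is
   robust to the bursts themselves — bursts occupy a minority of frames,
   so they leave the baseline untouched.
2. **Detect bursts** (`detect_bursts()`): a burst is a maximal run of at
   least `min_frames = 2` consecutive frames whose absolute deviation
   exceeds `k_mad = 5` robust standard deviations (1.4826 x MAD of the
   fiber's deviation series). Five robust SDs puts the per-frame false
   positive rate near $5 \times 10^{-7}$ for Gaussian noise, so a
   1000-frame movie of a quiet fiber essentially never yields a false
   event (verified by simulation); requiring two consecutive frames
   suppresses single-frame outliers. If the MAD is zero while deviations
   exist (an artificially noiseless trace), an absolute threshold of 0.1
   relative deviation is used, with a warning.
3. **Call** (`classify_contracting()`): contracting iff the fiber shows
   **at least 2 burst events**. The underlying categorization is binary
   with no printed numeric rule; repeated bursting is what distinguishes
   a contracting myotube from a one-off artefact, so the default demands
   it, the threshold is an argument (`min_events`), and the event count
   is reported per fiber so single-event fibers remain auditable.
4. **Aggregate** (`percent_contracting()`): 100 x contracting / analyzed
   per chamber.

The roster of analyzable fibers (fibers overlapped by at least one axon)
is determined upstream at image acquisition; the pipeline scores every
fiber present in its input.

## NMJ scoring, aggregates, fiber diameters

* **In vitro NMJ health** (`healthy_nmj_fraction()`): among
  *colocalization events* (presynaptic axon co-localized with a
  postsynaptic AChR patch), the percentage whose axon is intact.
  Non-colocalized events are ignored entirely — they are not NMJs — and
  units with no colocalized events are dropped with a warning rather
  than scored 0/0.
* **In vivo innervation** (`innervation_percent()`): among postsynaptic
  (AChR) sites, the percentage with the presynaptic marker present.
  Whether partial overlap should count as innervation is not quantified
  in the source protocol; the event table carries a boolean
  `pre_present` decided upstream, keeping that judgement at the
  segmentation boundary.
* **Aggregate density** (`aggregate_density()`): per-section density =
  count / area; the group statistic is the mean over sections with SEM,
  and percent change is $100(1 - \text{group}/\text{reference})$ within
  each compartment (gray/white matter). Group ns are stated
  inconsistently across such experiments (sometimes sections, sometimes
  animals), so section-level pooling is the default and an
  `animal_col` argument averages within animal first; both modes are
  reportable.
* **Fiber diameters** (`fiber_diameter_summary()`): mean, SD, SEM and n
  per group plus all pairwise mean differences with standard errors.
* **Blinding**: `blind_groups()` / `unblind_groups()` let scoring run
  with opaque group codes; the label-equivariance test verifies the
  round trip changes no numbers.

## Survival and group statistics

`percent_surviving()` divides each explant's motor-neuron count at every
observation day by the count first detected in *that* explant, so the
baseline maps to exactly 100% and the statistic is scale-invariant.
`group_timecourse()` reports mean +/- SEM over explants per condition
and day; explant-level (rather than experiment-level) SEM is the
default, matching the per-explant definition of the statistic.

Two comparison methods cover the designs used in this field:

* `student_t()`: classical pooled-variance two-sample t (Welch behind a
  flag, `welch = TRUE`), two-sided by default.
* `anova_fisher_lsd()`: one-way ANOVA omnibus F followed by Fisher's
  least-significant-difference pairwise tests — t statistics built on
  the pooled ANOVA MSE with $N - k$ degrees of freedom, pairwise p
  unadjusted (the LSD convention). The post hocs are *protected* by
  default: pairwise p values are withheld unless the omnibus F is
  significant at $\alpha = 0.05$, the classical protected-LSD protocol;
  `gate_on_omnibus = FALSE` gives the ungated variant, and the
  unprotected p values are always present in the `p_unprotected` column.
  With two groups the ANOVA reproduces the pooled t exactly
  ($F = t^2$), which the tests assert.

SEM throughout uses the $n - 1$ sample SD; all group results are
reported as mean +/- SEM.

## The synthetic-data generators

Every assay has a seeded generator that emulates its statistical
structure, so each pipeline stage can be exercised end to end against
known ground truth. All randomness flows from one user seed through
`derive_seeds()`, identical (parameters, seed) pairs give bit-identical
outputs, and the caller's RNG state is never disturbed.

* **Transport** (`simulate_track()`): two-state run/pause Markov
  dynamics with per-frame Bernoulli switching (geometric dwell times,
  the simplest process producing stop statistics of the observed kind).
  The true position advances by direction x speed x $\Delta t$ during
  runs and stays put during pauses; iid Gaussian *localization noise*
  is added to every measured position. Per-track direction is drawn
  from `retrograde_fraction`; the per-track run speed comes from a
  truncated normal. Defaults follow the imaging protocol — 3 s frame
  interval (20 frames/min), 100 frames (5-minute movies).
* **Contraction** (`simulate_intensity_traces()`): baseline 1.0 plus
  Gaussian noise; contractors add a Poisson number of rectangular burst
  deflections (count ~ Poisson(rate x duration)) at uniform onsets.
  Defaults: 30 fps, 1000 frames.
* **NMJ events** (`simulate_nmj_events()`): iid Bernoulli intactness
  (in vitro) or innervation (in vivo).
* **Survival** (`simulate_explant_counts()`): sequential binomial
  thinning of the baseline count, so counts are non-increasing by
  construction and the expected count at day $d$ is baseline x
  fraction($d$); exact rounding with noise off.
* **Aggregates / fibers**: Poisson counts over section areas; Gaussian
  diameters truncated at zero.

### Presets and free parameters

Named presets (`condition_presets()`) pin the group-level observables
reported for each experimental condition: 10% contracting without motor
neurons versus 74% in healthy co-cultures; 75% intact NMJs in wild-type
co-cultures; 50% motor-neuron loss at day 16 in mutant-SOD1 co-cultures
(observed at days 7, 10, 12, 14, 16); 40% versus 80% in vivo innervation
(untreated versus 30 mg/kg pridopidine-treated disease, against a fully
innervated wild-type reference); a treated aggregate density of half the
vehicle density; and a treated fiber-diameter mean 4 um above vehicle.

Everything else is a free parameter of the simulator, chosen once at
values a practitioner would call realistic and not revisited:

| parameter | default | rationale |
|---|---|---|
| run speed mean / SD | 0.8 / 0.2 um/s | typical dynein-driven retrograde cargo speeds (order 1 um/s) |
| pause entry / exit per frame | 0.05 / 0.5 | a few pauses per 5-min movie, pauses lasting seconds |
| localization noise | 0.05 um | sub-pixel centroid accuracy of spot tracking |
| retrograde fraction | 0.9 | signalling endosomes are predominantly retrograde |
| burst rate / amplitude / duration | 0.3 Hz / 0.5 rel / 5 frames | several clear twitches per 33-s movie |
| trace noise | 0.02 rel | bright-field intensity jitter well below burst amplitude |
| survival at days 10/12/14 (mutant) | 0.95 / 0.80 / 0.65 | death beginning at day 10, progressing to 50% by day 16 |
| aggregate density (vehicle) | 50 / mm2 | dense pathology in end-stage mutant cord |
| fiber diameter mean / SD | 32 (vehicle), 36 (treated), 40 (WT) / 8 um | atrophied versus healthy gastrocnemius fibers |

Kinematic magnitudes are deliberately *not* claimed to match any
published velocity values — none are printed for this system — so the
transport presets support property and recovery testing, not
quantitative comparison.

### What the generators do not emulate

The generators reproduce each assay's sampling distribution, not its
imaging physics. They do not render movies or model spot-detection
failures (mislinked tracks, dropped detections), photobleaching,
fiber-to-fiber amplitude variation, correlated twitching of neighboring
fibers, within-chamber correlation of NMJ outcomes, or section-to-section
density heterogeneity beyond Poisson. Passing recovery tests therefore
demonstrates that the pipelines are unbiased estimators under the assays'
idealized statistical structure — it does not validate robustness to
upstream segmentation artefacts, which must be assessed on real data.

## Numerical choices and degenerate inputs

* Frame-grid checks use a relative tolerance of 1e-6; co-transport
  requires both tracks on one grid to the same tolerance.
* Stop/burst runs use strict inequalities at the threshold; ties are
  not events.
* Step indices and event start frames are 1-based in R outputs; the CSV
  `frame` column is 0-based on disk, converted at the reader boundary.
* Degenerate inputs fail loudly and specifically: zero baselines name
  the explant or fiber, schema errors list the missing columns, gappy
  tracks name the track. Empty cohorts summarize to empty tables
  without error.
* Result CSVs are written with 6 significant digits, UTF-8 and `\n`
  newlines, so re-runs are byte-identical.

## Problem sizes used in the checks

The automated checks run each oracle comparison on 1000+ randomized
instances (tracks up to 200 frames), calibrate both tests' type-I error
on 10^4 null simulations, and run the recovery studies at the assays'
native sizes: 40 chambers x 30 fibers (contraction), 30 chambers x 50
events (in vitro NMJ), 200 explants x 40 neurons (survival), 5 muscles
x 100 NMJs (innervation), 50 sections per group (aggregates) and 500
fibers per group (diameters), each over 10 independent seeds. Recovered
means are required to land within 3 SEM of the preset's target.

## Known limitations

* Tracks are 1-D; genuinely 2-D behaviours (lateral excursions,
  crossing tracks) are out of scope.
* Contraction calling is binary; contraction magnitude and frequency
  content are not quantified (the event table is the hook if they ever
  are).
* The LSD post hocs are unadjusted by design; if many groups are
  compared and family-wise control matters, use the omnibus p plus an
  adjustment downstream.
* Survival analysis is fraction-based, matching the per-explant
  counting protocol; no censoring or Kaplan-Meier machinery is
  involved.
```{r example}
# one healthy-co-culture chamber, end to end
p <- get_preset("contraction", "WT_cocult")
sim <- simulate_intensity_traces(p, n_fibers = 30, seed = 1)
calls <- classify_contracting(sim$traces)
percent_contracting(calls)
# ground truth for the same chamber
mean(sim$labels$contracting) * 100
```
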