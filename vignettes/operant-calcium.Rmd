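---
title: "Classifying event-modulated and spatially tuned neurons in operant calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying event-modulated and spatially tuned neurons in operant calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opercal)
```

`opercal` analyzes extracted one-photon calcium traces recorded while an
animal performs operant tasks. This vignette is the package's account of
its models and methods: what is computed, why the defaults are what they
are, what the synthetic subsystem does and does not emulate, and where
the genuinely open design choices were made.

## 1. The peri-event modulation criterion

For each neuron and each event kind we build a peri-event time histogram
(PETH): activity is averaged into 100 ms bins over a −3 to +3 s window
around each event (60 bins per trial; bins are half-open `[start, end)`).
Events whose window is not fully covered by the trace are dropped, never
padded. The criterion is then:

* **Baseline**: all bin values in the −3 to −1 s period, pooled across
  trials (20 bins × trials values).
* **Threshold**: the empirical 99th percentile of the pooled baseline
  (linear interpolation between order statistics, `quantile` type 7 — the
  convention is fixed for bit-reproducibility; on a pooled baseline of
  1…100 it yields 99.01).
* **Decision**: the *trial-averaged* PETH must strictly exceed the
  threshold in at least three consecutive bins lying wholly inside the
  −0.5 to +0.5 s event window. Only increases are detected; there is no
  decrease criterion and no multiple-comparison correction across
  neurons.

Two readings of this procedure were open and are exposed as flags:
pooling baseline values across trials versus thresholding the averaged
baseline trace (`baseline = "pooled"` is the default — a percentile of 20
averaged values is a much coarser statistic), and whether the 3-bin run
may extend beyond the event window (`scan = "event"` restricts it; a
`"full"` scan is available). Runs must lie wholly inside the scanned
window.

### Calibration and power

On untuned neurons the criterion is conservative: the trial-averaged
trace rarely stays above the pooled 99th percentile for 300 ms, and the
measured false-positive fraction on 200 untuned synthetic neurons with
~30 events is well under 5% (typically 0–1%). Power, however, depends
sharply on what the baseline window contains. A calcium indicator
outlasts behavior: with a ~0.5 s decay constant a transient is visible
for ~2.5 s, so any same-kind event 3–5.5 s before the aligned event
parks its decay tail inside the −3…−1 s baseline and inflates the
threshold. Sessions with dense pressing therefore *cannot* show high
sensitivity under this criterion — an intrinsic property of
percentile-of-baseline tests on slow indicators, not an implementation
artifact. The package's standard alignment therefore uses **isolated
events** (`isolated_events()`, default ≥ 5.5 s of same-kind silence:
the 3 s pre-event window plus a 2.5 s indicator tail), generalizing the
practice of aligning to the first press of a ratio run. With isolated
alignment, sensitivity on 3-SD responders is 1.00 across 20 simulated
delay-task sessions; with all-event alignment in dense sessions it can
collapse to near zero.

For two-lever tasks, neurons significant for either lever are counted,
then *excluded* from the single-lever categories: `both` neurons never
appear in `left_only`/`right_only` (`attribute_lever_modulation()`).
Reward and extension modulation are independent flags.

## 2. The synthetic subsystem

The simulators exist so that every analysis stage can be checked by
ground-truth recovery. They emulate four session types: plain
fixed-ratio (FR-n) pressing, the FR5 switch task (after five rewards =
25 presses the lever exchanges sides), the two-lever FR1 delay task
(random lever; press → retract → pellet 1 s later → 2 s inter-trial
interval), and the non-contingent task (reward every 20 s, preceded by a
1 s cue). Event logs obey a fixed tie order at equal timestamps
(extension < press < retraction < cue < reward) and reinforcement
conservation (rewards = ⌊presses/ratio⌋). The lever-selection stream is
seeded independently of the press-timing stream, so changing the presser
policy never changes the lever sequence. The FR5-switch lever exchange
takes a small mechanical latency (0.1 s retract, 0.1 s extend), which
keeps the fifth reward strictly before the retraction in the log.

**Session geometry.** The arena is 30 × 30 cm so the 15 × 15 grid of
2 × 2 cm analysis bins tiles it exactly; levers sit on the y = 0 wall at
x = 7.5 and 22.5 cm with the food port centered between them. Imaging
sessions default to 600 s (the midpoint of typical 8–10 min runs) at
30 Hz (typical miniscope rate); every analysis is parameterized by rate.

**Virtual animal.** Positions follow a bounded-velocity random walk
(Ornstein–Uhlenbeck velocity, correlation time 0.5 s, stationary speed
scale 8 cm/s, 30 cm/s cap) with specular wall reflection — position
folds and velocity flips, which makes the unbiased walk's stationary
occupancy uniform (verified by a chi-square oracle on temporally thinned
samples; consecutive 30 Hz samples are autocorrelated, so the oracle
thins to ~1 sample/s). Task bias attracts the walk toward the extended
lever and, for `port_dwell` seconds after each reward, toward the food
port; the port attraction gets a 2× gain (pellet retrieval is a reliable
dash — larger gains overshoot the port and displace the apparent field).
With `bias = 0` the occupancy is uniform; with bias on, occupancy
concentrates at task locations, emulating the uneven coverage that makes
operant spatial analysis hard in the first place.

**Traces.** Each neuron's trace is a sum of transients convolved with a
double-exponential kernel (rise 0.05 s, decay 0.5 s — a generic
fast-GCaMP surrogate; truncated at 5 decay constants, unit peak) plus
i.i.d. Gaussian noise. Amplitudes are in multiples of the noise SD (when
`noise_sd = 0`, the unit falls back to 1 so noise-free constructions keep
their signal). Tuning kinds:

* *Event-locked* (`press_left/right/both`, `reward`, `extension`): one
  evoked response per matching event — the kernel driven for
  `response_duration` (default 0.25 s) from `event + response_latency`
  (default 0.05 s), peak scaled to the neuron's amplitude. Evoked
  responses are sustained bursts, not single-spike transients; this is
  what press-locked averages look like and what gives the criterion its
  three consecutive bins.
* *Spontaneous baseline*: homogeneous Poisson transients at
  `baseline_rate` (default 0.02 events/s — dentate granule cells are
  sparse) with peak `spont_amp_frac` (default 0.5) of the evoked
  amplitude; spontaneous single events are smaller than evoked bursts.
* *Place*: inhomogeneous Poisson transients, rate
  `baseline_rate · (1 + (gain − 1) · exp(−d²/2w²))` with `gain = 8`
  (peak rate = baseline × gain) and `d` the distance to the field
  center.
* *Active-lever*: the same field model, but centered on whichever lever
  is currently extended (baseline rate when none is) — the lever-locked
  population the switch analysis is designed to detect.

What the generator does **not** emulate: pixel-level movies, motion
artifacts, source-extraction crosstalk, slow drift (an optional AR(1)
flag exists but defaults off), spike inference, non-Gaussian noise, or
learning across sessions. Passing recovery tests therefore demonstrates
the *analysis logic* under known tuning, kinetics and noise — not
robustness to upstream extraction failures.

## 3. Spatial analysis

Occupancy maps count dwell per 2 × 2 cm bin (half-open edges, top edge
closed; Σ dwell equals the tracked duration exactly). Rate maps pair the
trace to track samples by nearest sample and reduce it to its
**transient component** first: rectified at zero and thresholded at 2
robust SDs (MAD). The spatial statistics are defined on calcium
transients; without the threshold the rectified noise floor (~0.4 SD per
sample) dominates sparse signals and flattens every map. Bin rates are
defined only where dwell ≥ `min_dwell` (0.5 s) — rates in barely-visited
bins are estimation noise. An optional Gaussian smoothing of the
activity-sum and dwell maps before their ratio (`smooth_sigma`, in bins)
is off by default for whole-session maps.

Spatial information is `SI = Σ p_i (λ_i/λ) log2 (λ_i/λ)`, zero-rate bins
contributing zero; it is nonnegative for nonnegative activity and
invariant to rescaling the trace. The null distribution comes from
circular time-shifts of the trace against the track — shifts uniform in
`[min_shift, duration − min_shift]` (default 20 s), preserving
autocorrelation while destroying spatial coupling. Defaults: 1000
shuffles, significance at the 95th shuffle percentile, eligibility ≥ 3
active bins (a bin is *active* at ≥ 20% of the neuron's peak bin rate).
The shuffle count, shift floor, percentile and activity definition are
conventional for this statistic and all config-exposed. Calibration on
position-independent neurons lands at the nominal 5% flag rate (measured
4.0–4.2% at 500 neurons × 1000 shuffles, inside the binomial 95% CI).

### Lever-switch center-of-mass shifts

`switch_com_shift()` splits an FR5-switch session into left-active and
right-active epochs and recomputes each neuron's field COM per epoch,
reporting `Δx = x_COM(right) − x_COM(left)` (the y-dimension is not
compared: levers and port share one wall, and x carries the variance).
Epoch maps differ from whole-session maps in three defaults, each forced
by the epoch restriction:

* **Transient onsets** (`activity_mode = "onsets"`, unit impulse at each
  3.5 SD upward crossing) instead of supra-threshold fluorescence: decay
  tails are carried along the stereotyped lever-to-port runs and drag a
  fluorescence-weighted COM toward the travel path. Onsets localize
  activity at its origin. The detector threshold is higher than the
  2 SD map threshold because an onset detector must keep noise
  upcrossings negligible (~2% of samples cross 2 SD upward).
* **Smoothing** (`smooth_sigma = 1` bin): epoch restriction thins
  per-bin dwell, and unsmoothed epoch maps peak at single-visit bins.
* **A shared noise scale**: the transient threshold is estimated once on
  the full session so both epochs are on the same scale.

The COM itself is the rate-weighted mean of bin centers over bins ≥
`field_threshold` × peak (default 0.2; the switch analysis uses 0.5 to
anchor the COM at the field core). On synthetic lever-locked neurons
(fields at the levers, 7.5 vs 22.5 cm) the recovered population mean Δx
is 15–16 cm; allocentric neurons with a field at the food port show a
population mean Δx within ±2 cm. Two caveats are themselves findings
about the design: allocentric fields must lie where *both* epochs sample
them (the port does; an off-wall field does not — operant occupancy does
not cover the arena), and per-neuron |Δx| contains zero-mean sampling
noise of a few cm that only population averaging removes, so the
per-neuron table is reported and any hypothesis test is left to the
user.

## 4. Pipeline, determinism and problem sizes

`run_pipeline()` composes the stages from a single config whose analysis
defaults are the task's stated parameters (−3…3 s window, 100 ms bins,
−3…−1 s baseline, ±0.5 s event window, 99th percentile, 3 consecutive
bins, 15 × 15 × 2 cm grid, ≥ 3 active bins) and whose simulation
defaults are the session conditions (600 s, 30 Hz). Sub-seeds for
policy, track, population, and traces derive from the master seed; the
same config and seed regenerate a bit-identical report
(`report_hash()`), and the report embeds a config hash, the seed and the
package version. A small utility (`colocalization_fraction()`) summarizes
retrograde-tracing colocalization count tables (per-row percentages,
zero-denominator rows flagged as 0% by convention, per-region
mean ± SEM); the packaged locus-coeruleus table ships in
`inst/extdata/`.

Validation problem sizes were chosen to finish in minutes on one core
while keeping binomial confidence intervals tight: 200 neurons × 5 seeds
for event recovery, 500 neurons × 1000 shuffles for calibration, two
sessions × 40 neurons for the switch analysis. The non-contingent
schedule's first reward is taken at t = 20 s (the interval, not a random
start), and plain-FR reward dispensing defaults to zero latency; both
are configurable.

## 5. Known limitations

* The criterion detects increases only; suppressed neurons are invisible.
* Sensitivity depends on event spacing (Section 1); reports state the
  alignment rule used.
* A press-locked neuron partially leaks into reward alignment when reward
  follows the press at a fixed 1 s lag — the residual decay can satisfy
  the criterion early in the reward window. The delay task's dissociation
  is imperfect for slow indicators.
* Spatial eligibility and the active-bin rule depend on the transient
  threshold; very-low-amplitude place fields (< ~2 noise SD) are below
  the design's detection floor.
* No cross-session cell registration: counts are per session.
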