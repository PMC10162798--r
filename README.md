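# opercal

Event-modulation and spatial analysis of one-photon calcium imaging
recorded during operant conditioning.

When a mouse presses a lever for food while a miniscope records
GCaMP fluorescence from (for example) dopamine-receptor-expressing
dentate-gyrus neurons, three questions recur:

1. **Which neurons are modulated by task events** — lever presses, reward
   delivery, lever extension?
2. **Which neurons are spatially tuned**, given that operant animals do
   not sample the arena uniformly but camp at task-relevant locations?
3. **Do spatial fields follow the task** (a field locked to whichever
   lever is active) **or the room** (an allocentric place field)?

`opercal` implements the full analysis path for these questions, plus a
seeded synthetic subsystem (task simulators, virtual-animal position
tracks, GCaMP-like traces with ground-truth tuning labels) so every stage
can be validated by ground-truth recovery. It consumes extracted
fluorescence traces (e.g. CNMF-E output), behavioral event logs, and
position tracks; it is downstream of motion correction, source
extraction, and pose tracking.

## The methods

**Peri-event modulation.** For each neuron and event kind, activity is
binned into 100 ms bins over a −3…+3 s peri-event window (60 bins per
trial). Baseline is the −3…−1 s period; a neuron is *significantly
modulated* when its trial-averaged activity exceeds the empirical 99th
percentile of the pooled baseline bin values for at least three
consecutive bins within the −0.5…+0.5 s event window. For two-lever
tasks, neurons significant for *both* levers are categorized `both` and
excluded from the single-lever categories.

**Spatial tuning.** The arena (30 × 30 cm) is divided into 15 × 15 bins
of 2 × 2 cm. With occupancy probability `p_i` and mean activity rate
`λ_i` in bin *i* (transient activity per second of dwell), and
`λ = Σ p_i λ_i`, the spatial information is

    SI = Σ_i p_i (λ_i / λ) log2(λ_i / λ)   [bits per activity unit]

scored against a null distribution of 1000 circular time-shifts of the
trace relative to the track (uniform shifts ≥ 20 s, preserving
autocorrelation). A neuron is spatially modulated when it is active in at
least three bins and its SI exceeds the 95th percentile of its shuffles.

**Lever-switch remapping.** FR5-switch sessions (lever exchanges sides
after every five rewards = 25 presses) are split into left-active and
right-active epochs; each eligible neuron's place-field center of mass
(COM) is recomputed per epoch from transient-onset rate maps, and the
x-dimension shift `Δx = x_COM(right) − x_COM(left)` distinguishes
lever-locked fields (Δx ≈ lever separation) from allocentric ones
(Δx ≈ 0).

## Worked example

Simulate a 10-minute two-lever delay session (random lever extends; a
press retracts it; pellet 1 s later; 2 s inter-trial interval) over a
50-neuron population with known tuning, then run the full analysis:

```r
library(opercal)

cfg <- pipeline_config(
  task = list(type = "two_lever_delay", duration = 600),
  population = list(n_neurons = 50,
                    kind_fractions = c(press_both = 0.2, reward = 0.06,
                                       place = 0.14, none = 0.6)),
  seed = 42, press_rate = 6, n_shuffles = 200)
rep <- run_pipeline(cfg)
rep
#> <session_report> two_lever_FR1_delay: 50 neurons
#>   press_left   3/50 modulated (6.0%)
#>   press_right  5/50 modulated (10.0%)
#>   press_any    5/50 modulated (10.0%)
#>   reward       4/50 modulated (8.0%)
#>   extension    0/50 modulated (0.0%)
#>   spatial: 4/50 flagged
rep$attribution_counts
#>        both   left_only  right_only      reward   extension unmodulated
#>           3           0           2           2           0          43
```

The seeded multinomial drew exactly 5 `press_both` neurons for this
population, and all 5 are recovered under `press_any` alignment (10% of
the population); the `both` / `right_only` split reflects the either-lever
exclusion rule applied to the noisier single-lever alignments. Reports are
bit-reproducible: `report_hash(rep)` is identical across reruns of the
same config and seed.

Lower-level entry points — `simulate_fr_session()`,
`simulate_fr5_switch_session()`, `simulate_position_track()`,
`generate_population()`, `synthesize_traces()`, `build_peth()`,
`classify_modulated()`, `shuffle_test()`, `switch_com_shift()` — are all
exported and documented; the methods vignette
(`vignettes/operant-calcium.Rmd`) explains the models and every tunable
parameter.

### File formats

Event logs (`time_s,kind` CSV + JSON sidecar), position tracks
(`t_s,x_cm,y_cm` CSV + sidecar), trace matrices (one CSV row per neuron +
sidecar), ground truth (JSON), modulation and spatial results (CSV):
every writer has a matching reader, and `run_pipeline(..., out_dir =)`
emits all of them.

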