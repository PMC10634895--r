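# stopcolumn

Biophysical cortical-column modeling of the frontocentral event-related
potential (P2/N2/P3 complex) in the Stop-Signal Task.

The package implements, end to end:

- **Column simulator** (`R/column-model.R`, `src/simulate.cpp`): a reduced
  two-layer (L2/3 + L5) neocortical column — 100 four-compartment pyramidal
  cells per layer with point basket interneurons at a 3:1 ratio — that
  converts timed proximal (thalamocortical-like) and distal
  (cortico-cortical-like) exogenous drives into a net current-dipole trace.
  Includes the eight medial-prefrontal local-connectivity modifications,
  dipole scaling (×150) and 30 ms Hamming smoothing, and 50-trial ensembles
  with per-trial Gaussian drive timing.
- **Hypothesis presets** (`R/presets.R`): named models of successful and
  failed stopping — the successful three-drive sequence (proximal 115 ms,
  distal 190 ms, two-spike proximal 306 ms), the failed-Stop timing-change
  model (late drive at 325 ms, weights unchanged), one-spike and
  strength-change alternatives, two somatic-inhibition variants, and the
  rejected distal-first ordering. Presets round-trip exactly through JSON.
- **Model fitting** (`R/fitting.R`): RMSE objective on a 2 ms grid,
  bound-constrained derivative-free optimization (pattern search;
  golden-section for single parameters) with frozen-parameter masks, weight
  changes capped at 300% of the starting value, stage-wise fits with warm
  starts, preset comparison, and the two-source summation analysis.
- **ERP statistics** (`R/erp-analysis.R`): epoch container, mean-subtraction
  baseline correction over −100…0 ms, P2/N2/P3 peak quantification
  (100–200 / 150–250 / post-signal windows), per-timepoint resampling
  t-tests (label permutation by default, 1000 resamples, add-one-smoothed
  p-values), Benjamini–Hochberg correction, and the P3 onset statistic
  (earliest point of the significant run reaching the P3 peak; the
  alternative "first significant" reading is exposed via a parameter).
- **Component selection** (`R/ic-selection.R`): the two-criterion rule —
  maximal absolute channel weight at one of the nine frontocentral
  electrodes (Fz, F1, F2, FCz, FC1, FC2, Cz, C1, C2), then the strongest
  Pearson correlation (200–500 ms) between the component's
  failed-minus-successful difference and the full-data difference — plus
  single-component reconstruction.
- **Synthetic data** (`R/synthetic-data.R`): a 62-channel sensor-level SST
  epoch generator with a planted frontocentral source (P2 at 150 ms, N2 at
  200 ms, P3 peaking at 300 ms with an explicit onset at 224 ms), condition
  effects (delayed P3 onset and larger P2 on failed Stops, no P3 on Go),
  nuisance sources, and full ground truth for recovery testing.
- **Pipeline** (`R/pipeline.R`): `run_pipeline()` chains synthesis →
  component selection → ERP statistics → preset fitting/comparison and
  writes a reproducible run manifest.

## Quick start

```r
library(stopcolumn)

# simulate the successful-Stop frontocentral ERP (50 trials)
ens <- simulate_preset(load_preset("successful"), sim_config(seed = 1))
plot(ens$time_ms, ens$mean$net, type = "l")

# ERP statistics on synthetic sensor data
ds <- generate_sensor_dataset(synthetic_config(seed = 1))
sel <- select_p3_component(ds$decomp, ds$epochs)
bc <- baseline_correct(ds$epochs)

# run the demo pipeline end to end
man <- run_pipeline(default_pipeline_config(seed = 1))
```

## Analysis workflow

Numbered scripts under `analysis/` reproduce the main results; outputs go
to `results/`:

```sh
Rscript analysis/01_simulate_fcerp.R --seed 1     # P2/N2/P3 waveforms
Rscript analysis/02_hypothesis_comparison.R       # timing vs alternatives
Rscript analysis/03_erp_statistics.R              # P3 onset statistics
Rscript analysis/04_two_source.R                  # two-source summation
```

## Acceptance measurements

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes `t11` (trial-mean P2 latency, ms, under the successful preset) and
`t12` (synthetic grand-average Stop-trial post-signal peak latency, ms).

## Tests

```r
testthat::test_dir("tests/testthat", package = "stopcolumn",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds one block per acceptance
criterion; the remaining files unit-test each module.

## Notes

- Cell-level kinetic constants (compartment coupling, synapse time
  constants, backpropagation and regenerative-current parameters, default
  drive weights) are documented package defaults, hand-tuned once so the
  default column reproduces the qualitative waveform; they are not
  literature-transcribed values.
- The somatic-inhibition sign convention follows the layer geometry: an
  inhibitory conductance at the soma pulls current downward along the
  apical dendrite, producing a negative-going deflection.
- Dipole units are scaled model units; no conversion to µV is attempted —
  the multiplicative scaling factor absorbs the unit bridge.
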