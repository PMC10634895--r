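---
title: "Modeling the frontocentral stop-signal ERP with a reduced cortical column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the frontocentral stop-signal ERP with a reduced cortical column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
```

```{r setup}
library(stopcolumn)
```

## The model

During the Stop-Signal Task, frontocentral EEG electrodes show a
stereotyped sequence after the Stop-Signal: a positive P2 near 150 ms, a
negative N2 near 200 ms, and a broad positive P3 peaking near 300 ms whose
onset is delayed on failed stops. `stopcolumn` models this waveform as the
net current dipole of a reduced two-layer neocortical column receiving a
sequence of timed exogenous drives.

The column holds 100 four-compartment pyramidal cells per layer (L2/3 and
L5; basal, soma, apical trunk, apical tuft) plus point-neuron basket
interneurons at a 3:1 pyramidal-to-basket ratio. The L5 apical dendrites
are longer, so L5 dominates the net dipole. Membrane dynamics use
exponential-Euler integration (dt = 0.025 ms) with double-exponential
AMPA/NMDA/GABAa/GABAb conductances; NMDA carries a sigmoidal voltage
dependence. Somatic spikes are threshold-reset events that trigger a
staggered depolarizing backpropagation pulse up the apical compartments
(upward current flow), and the L5 tuft carries a regenerative
calcium-like current (downward current flow). The dipole is the summed
axial current along the apical axis, smoothed with a 30 ms Hamming window
and scaled by 150. Eight local weights are increased relative to the
default column to represent medial-prefrontal connectivity
(`mpfc_factors()`).

Exogenous inputs arrive over two pathways: *proximal* drives contact the
basal compartments and both basket populations and push current upward
(positive deflections); *distal* drives contact the apical tufts and L2/3
baskets and push current downward (negative deflections). Each drive's
spike times are drawn per trial from a Gaussian with configurable mean and
SD.

## Simulating the successful-Stop waveform

The successful-Stop preset carries three drives: proximal at 115 ms,
distal at 190 ms, and a two-spike proximal drive at 306 ms.

```{r simulate}
ens <- simulate_preset(load_preset("successful"),
                       sim_config(seed = 1, n_trials = 10))
plot(ens$time_ms, ens$mean$net, type = "l", xlab = "time (ms)",
     ylab = "dipole (scaled model units)")
abline(v = c(150, 200, 300), lty = 3)
quantify_peaks(ens$mean$net, ens$time_ms)
```

(The vignette uses 10 trials for speed; analyses use the default 50.)

## Competing hypotheses for failed stops

Failed-Stop presets alter the successful model in one specific way each:
`failed_timing` delays the late proximal drive to 325 ms with identical
weights; `failed_onespike` reduces it to one spike; `failed_strength`
keeps the timing and frees only the synaptic weights; the two
somatic-inhibition variants raise the first proximal drive's weights onto
L5 baskets (AMPA 0.000561 → 0.001, NMDA 0.1 → 0.2). `compare_models()`
fits each preset's free parameters to a common target by RMSE (pattern
search under bounds, weight changes capped at 300% of the start) and
ranks them:

```{r compare, eval = FALSE}
truth <- set_preset_parameters(load_preset("successful"), c(P2.mu = 325))
tgt <- generate_simulator_target(truth, sim_config(seed = 901, n_trials = 5),
                                 n_pyramidal = 25)
compare_models(tgt$time_ms, tgt$target,
               c("failed_timing", "failed_strength"),
               config = sim_config(seed = 1, n_trials = 5),
               n_pyramidal = 25, budget = 20)
```

On such self-generated targets the timing-change preset reliably
out-ranks the strength-change alternative (see
`tests/testthat/test-acceptance.R`).

## P3 onset statistics

The P3 onset is defined statistically: per-timepoint two-sample t
statistics between Stop and matched-Go trial pools, a permutation null
(1000 resamples, add-one-smoothed p-values), Benjamini–Hochberg
correction at 0.05, and the onset is the earliest timepoint of the
contiguous significant run reaching the P3 peak.

```{r onset}
ds <- generate_sensor_dataset(synthetic_config(seed = 2))
bc <- baseline_correct(ds$epochs)
fc <- match("FCz", bc$channels)
stop_trials <- bc$data[bc$condition == "successful_stop", , fc]
go_trials <- bc$data[bc$condition == "go_successful", , fc]
pk <- quantify_peaks(colMeans(stop_trials), bc$times)
p3_onset(stop_trials, go_trials, bc$times, pk$p3$latency,
         n_resamples = 300, seed = 1)
```

The synthetic generator plants the onset at 224 ms (243 ms for failed
stops), so recovery can be verified against ground truth.

## Component selection

Sensor-space data are reduced to a single spatial component by the
two-criterion rule: the component's maximum absolute channel weight must
sit on a frontocentral electrode, and among such candidates the one whose
reconstructed condition difference best correlates (200–500 ms) with the
full-data difference wins.

```{r ic}
sel <- select_p3_component(ds$decomp, ds$epochs)
c(selected = sel$index, planted = ds$truth$planted_index)
```

## Design notes

- Cell-level kinetic constants are documented package defaults, hand-tuned
  once to reproduce the qualitative waveform (positive P2 near 150 ms,
  negative N2 near 200 ms, late positive P3), then frozen; they are not
  literature-transcribed values.
- The resampling scheme behind the onset test is exposed as label
  permutation (default) or a with-replacement bootstrap; both are
  reproducible by seed.
- Benjamini–Hochberg controls the false discovery rate; the onset
  procedure uses the standard step-up rule.
- The optimizer is a bounded pattern search (Hooke–Jeeves;
  golden-section for one-parameter fits) with a fixed ensemble seed per
  run so the stochastic simulator presents a deterministic objective.
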