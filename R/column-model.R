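#' @useDynLib stopcolumn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif convolve approx sd var
NULL

POP_INDEX <- c(L2Pyr = 0L, L5Pyr = 1L, L2Basket = 2L, L5Basket = 3L)
COMP_INDEX <- c(basal = 0L, soma = 1L, trunk = 2L, tuft = 3L)
REC_INDEX <- c(AMPA = 0L, NMDA = 1L, GABAa = 2L, GABAb = 3L)

#' Simulation configuration
#'
#' Sets the numerical grid and trial structure for column simulations. The
#' epoch spans -100 to +500 ms around the Stop-Signal by default, matching the
#' analysis epochs, and the dipole post-processing defaults (multiplicative
#' scaling 150, 30 ms Hamming smoothing, 50 trials per condition) follow the
#' study conditions.
#'
#' @param dt integration step (ms); must be <= 0.05.
#' @param tmin,tmax epoch bounds (ms relative to the Stop-Signal).
#' @param seed master seed for the trial ensemble.
#' @param scaling multiplicative dipole scaling factor.
#' @param smooth_window_ms duration of the Hamming smoothing window (ms).
#' @param n_trials trials per simulated condition.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, tmin = -100, tmax = 500, seed = 42L,
                       scaling = 150, smooth_window_ms = 30, n_trials = 50L) {
  stopifnot(dt > 0, dt <= 0.05, tmax > tmin, scaling > 0,
            smooth_window_ms >= 0, n_trials >= 1)
  structure(list(dt = dt, tmin = tmin, tmax = tmax, seed = as.integer(seed),
                 scaling = scaling, smooth_window_ms = smooth_window_ms,
                 n_trials = as.integer(n_trials)),
            class = "sim_config")
}

# default biophysical constants of the reduced cells; these are package
# defaults (the source publications of the upstream column model carry the
# detailed kinetics, which are deliberately not reproduced here)
default_biophysics <- function() {
  list(
    e_leak = -65, g_leak = 0.1, capacitance = 1,
    spike_threshold = -52, spike_reset = -70,
    refractory_pyr = 5, refractory_basket = 2,
    basket_threshold = -52,
    # axial conductance and signed segment length (um, relative) for the
    # pairs (basal,soma), (soma,trunk), (trunk,tuft); L5 apical dendrites are
    # longer, so L5 dominates the net dipole
    axial_g = matrix(c(0.3, 0.3, 0.3,
                       0.3, 0.3, 0.3), nrow = 2, byrow = TRUE),
    seg_len = matrix(c(150, 200, 200,
                       150, 400, 400), nrow = 2, byrow = TRUE),
    # backpropagation pulse delivered to (soma, trunk, tuft) after each
    # somatic spike; staggered rise times make the depolarization travel
    # upward, producing upward (positive) dipole current
    bp_amp = c(60, 45, 18),
    bp_tau_rise = c(0.3, 0.8, 1.5),
    bp_tau_decay = c(1.5, 3, 5),
    # L5-only tuft regenerative (calcium-like) current: triggered above a
    # tuft-voltage threshold, sustained, produces downward current flow
    ca_threshold = -30, ca_amp = 5,
    ca_tau_rise = 3, ca_tau_decay = 30, ca_refractory = 40,
    # double-exponential receptor kinetics (rise, decay, reversal);
    # NMDA additionally carries a sigmoidal voltage dependence
    rec_tau_rise = c(AMPA = 0.5, NMDA = 8, GABAa = 0.5, GABAb = 5),
    rec_tau_decay = c(AMPA = 5, NMDA = 50, GABAa = 7, GABAb = 50),
    rec_erev = c(AMPA = 0, NMDA = 0, GABAa = -80, GABAb = -90)
  )
}

# default local (within-column) connectivity; weights are per presynaptic
# spike and summed over the all-to-all projection inside the C++ core
default_connectivity <- function() {
  con <- rbind(
    data.frame(src = "L2Pyr", target = "L2Pyr", receptor = "AMPA", compartment = "basal", weight = 5e-5),
    data.frame(src = "L2Pyr", target = "L2Pyr", receptor = "NMDA", compartment = "basal", weight = 2e-5),
    data.frame(src = "L2Pyr", target = "L5Pyr", receptor = "AMPA", compartment = "trunk", weight = 5e-5),
    data.frame(src = "L5Pyr", target = "L5Pyr", receptor = "AMPA", compartment = "basal", weight = 5e-5),
    data.frame(src = "L5Pyr", target = "L5Pyr", receptor = "NMDA", compartment = "basal", weight = 2e-5),
    data.frame(src = "L2Pyr", target = "L2Basket", receptor = "AMPA", compartment = "soma", weight = 1e-3),
    data.frame(src = "L5Pyr", target = "L5Basket", receptor = "AMPA", compartment = "soma", weight = 1e-3),
    data.frame(src = "L2Pyr", target = "L5Basket", receptor = "AMPA", compartment = "soma", weight = 5e-4),
    data.frame(src = "L2Basket", target = "L2Pyr", receptor = "GABAa", compartment = "soma", weight = 0.01),
    data.frame(src = "L2Basket", target = "L2Pyr", receptor = "GABAb", compartment = "soma", weight = 1e-3),
    data.frame(src = "L5Basket", target = "L5Pyr", receptor = "GABAa", compartment = "soma", weight = 0.01),
    data.frame(src = "L5Basket", target = "L5Pyr", receptor = "GABAb", compartment = "soma", weight = 1e-3),
    data.frame(src = "L2Basket", target = "L2Basket", receptor = "GABAa", compartment = "soma", weight = 1e-3),
    data.frame(src = "L5Basket", target = "L5Basket", receptor = "GABAa", compartment = "soma", weight = 1e-3)
  )
  con$delay <- 1
  con
}

#' Build the default cortical column network
#'
#' Constructs the reduced two-layer column: 100 four-compartment pyramidal
#' cells per layer with point-neuron basket interneurons at a 3:1
#' pyramidal-to-interneuron ratio, plus the default local connectivity.
#' All cells start at resting potential.
#'
#' @param config a [sim_config()].
#' @param n_pyramidal pyramidal cells per layer (default 100).
#' @return an object of class `stop_network`.
#' @export
build_default_network <- function(config = sim_config(), n_pyramidal = 100L) {
  if (n_pyramidal <= 0) stop("n_pyramidal must be positive")
  n_basket <- max(1L, as.integer(round(n_pyramidal / 3)))
  net <- c(
    list(n_l2pyr = as.integer(n_pyramidal), n_l5pyr = as.integer(n_pyramidal),
         n_l2basket = n_basket, n_l5basket = n_basket,
         connectivity = default_connectivity(),
         mpfc_applied = FALSE),
    default_biophysics()
  )
  class(net) <- "stop_network"
  net
}

#' Medial-prefrontal connectivity factors
#'
#' The eight local-connectivity weights that distinguish the medial frontal
#' column from the default (sensory-cortex) column, expressed as
#' multiplicative factors over the default weights.
#'
#' @return data.frame with columns src, target, receptor, factor.
#' @export
mpfc_factors <- function() {
  data.frame(
    src = c("L2Pyr", "L5Pyr", "L2Pyr", "L2Pyr", "L5Pyr",
            "L2Basket", "L2Basket", "L5Basket"),
    target = c("L2Pyr", "L5Pyr", "L2Pyr", "L5Pyr", "L5Pyr",
               "L2Pyr", "L2Pyr", "L5Pyr"),
    receptor = c("NMDA", "NMDA", "AMPA", "AMPA", "AMPA",
                 "GABAa", "GABAb", "GABAb"),
    factor = c(1.5, 1.5, 1.5, 2.0, 1.5, 2.0, 2.0, 3.0)
  )
}

#' Apply the medial-prefrontal connectivity modifications
#'
#' Scales exactly eight local synaptic weights (NMDA +50% within-layer
#' pyramidal-pyramidal in both layers; AMPA +50% L2/3->L2/3 and L5->L5 and
#' +100% L2/3->L5; GABAa +100% and GABAb +100% from L2/3 baskets; GABAb
#' +200% from L5 baskets) over the default column. Applying twice is an
#' error, preventing compounded factors.
#'
#' @param network a `stop_network` from [build_default_network()].
#' @return the modified network, flagged as modified.
#' @export
apply_mpfc_modifications <- function(network) {
  stopifnot(inherits(network, "stop_network"))
  if (isTRUE(network$mpfc_applied))
    stop("medial-prefrontal modifications already applied to this network")
  fac <- mpfc_factors()
  con <- network$connectivity
  for (i in seq_len(nrow(fac))) {
    j <- which(con$src == fac$src[i] & con$target == fac$target[i] &
                 con$receptor == fac$receptor[i])
    if (length(j) != 1)
      stop("default connectivity lacks ", fac$src[i], "->", fac$target[i],
           " ", fac$receptor[i])
    con$weight[j] <- con$weight[j] * fac$factor[i]
  }
  network$connectivity <- con
  network$mpfc_applied <- TRUE
  network
}

#' Define an exogenous drive
#'
#' A proximal drive contacts the basal-proximal compartments of pyramidal
#' cells in both layers and both basket populations (feedforward,
#' thalamocortical-like, pushing current upward); a distal drive contacts the
#' apical tufts of both pyramidal populations and the L2/3 baskets (feedback,
#' cortico-cortical-like, pushing current downward). Spike times are drawn
#' per trial from Normal(mu, sigma^2); each of `n_spikes` times is an
#' independent draw.
#'
#' @param name drive label.
#' @param pathway "proximal" or "distal".
#' @param mu mean spike time (ms post-Stop-Signal).
#' @param sigma across-trial SD of the spike time (ms).
#' @param n_spikes spikes per trial (>= 1).
#' @param weights named list: for each target population, c(AMPA=, NMDA=).
#'   Defaults are package hand-tuned values.
#' @param delay conduction delay (ms) applied to every target.
#' @return an object of class `drive_spec`.
#' @export
drive_spec <- function(name, pathway = c("proximal", "distal"), mu, sigma = 0,
                       n_spikes = 1L, weights = NULL, delay = 10) {
  pathway <- match.arg(pathway)
  stopifnot(sigma >= 0, n_spikes >= 1, delay >= 0)
  if (is.null(weights)) weights <- default_drive_weights(pathway)
  targets <- if (pathway == "proximal")
    c("L2Pyr", "L5Pyr", "L2Basket", "L5Basket")
  else c("L2Pyr", "L5Pyr", "L2Basket")
  if (!all(names(weights) %in% targets))
    stop("weights name targets outside the ", pathway, " pathway")
  for (w in weights) stopifnot(all(w >= 0))
  structure(list(name = name, pathway = pathway, mu = mu, sigma = sigma,
                 n_spikes = as.integer(n_spikes), weights = weights,
                 delay = delay),
            class = "drive_spec")
}

# hand-tuned default synaptic weights per pathway (model conductance units)
default_drive_weights <- function(pathway) {
  if (pathway == "proximal") {
    list(L2Pyr = c(AMPA = 0.10, NMDA = 0.40),
         L5Pyr = c(AMPA = 0.10, NMDA = 0.40),
         L2Basket = c(AMPA = 0.02, NMDA = 0.01),
         L5Basket = c(AMPA = 0.000561, NMDA = 0.1))
  } else {
    list(L2Pyr = c(AMPA = 0.08, NMDA = 0.03),
         L5Pyr = c(AMPA = 0.08, NMDA = 0.03),
         L2Basket = c(AMPA = 0.05, NMDA = 0.01))
  }
}

#' Realize per-trial drive spike times
#'
#' Draws `n_spikes` times from Normal(mu, sigma^2); draws falling before the
#' simulation start are clipped to `tmin + dt`.
#'
#' @param drive a [drive_spec()].
#' @param config a [sim_config()].
#' @param trial_seed integer seed; the draw is reproducible per seed.
#' @return numeric vector of spike times (ms).
#' @export
realize_drive_times <- function(drive, config, trial_seed = NULL) {
  stopifnot(inherits(drive, "drive_spec"))
  draw <- function() {
    t <- rnorm(drive$n_spikes, mean = drive$mu, sd = drive$sigma)
    pmin(pmax(t, config$tmin + config$dt), config$tmax)
  }
  if (is.null(trial_seed)) draw() else with_preserved_seed(trial_seed, draw())
}

# evaluate expr under a given seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# map drive targets to the C++ channel indexing
drive_target_channels <- function(drive) {
  comp <- if (drive$pathway == "proximal") "basal" else "tuft"
  out <- list()
  for (tgt in names(drive$weights)) {
    w <- drive$weights[[tgt]]
    # baskets are point neurons: their single compartment is channel slot 0
    cmp <- if (grepl("Basket", tgt)) "basal" else comp
    for (rec in names(w)) {
      if (w[[rec]] <= 0) next
      out[[length(out) + 1L]] <- list(
        chan = POP_INDEX[[tgt]] * 16L + COMP_INDEX[[cmp]] * 4L + REC_INDEX[[rec]],
        w = w[[rec]])
    }
  }
  out
}

# lower the connectivity data.frame to the flat vectors the C++ core expects;
# basket targets are point neurons and live in channel slot 0
flatten_connectivity <- function(con) {
  comp_idx <- ifelse(grepl("Basket", con$target), 0L,
                     COMP_INDEX[con$compartment])
  chan <- POP_INDEX[con$target] * 16L + comp_idx * 4L +
    REC_INDEX[con$receptor]
  list(con_src = unname(POP_INDEX[con$src]), con_chan = unname(as.integer(chan)),
       con_w = con$weight, con_delay = con$delay)
}

#' Simulate one trial
#'
#' Integrates the column under the given drives with a fixed-step
#' exponential-Euler scheme, recording the raw (unscaled, unsmoothed) net
#' current dipole, per-layer contributions, compartment-mean voltages, and the
#' spike raster. Deterministic given `trial_seed`.
#'
#' @param network a `stop_network`.
#' @param drives list of [drive_spec()] (possibly empty).
#' @param config a [sim_config()].
#' @param trial_seed integer seed controlling drive-time draws and initial
#'   voltage jitter.
#' @return list with elements `dipole` (data.frame time_ms, net, L23, L5),
#'   `spikes` (data.frame cell_id, population, t_ms), `comp_mean`
#'   (time x 8 matrix of compartment-mean voltages), and `drive_times`.
#' @export
simulate_trial <- function(network, drives, config, trial_seed = 1L) {
  stopifnot(inherits(network, "stop_network"), inherits(config, "sim_config"))
  n_steps <- as.integer(round((config$tmax - config$tmin) / config$dt))
  n_state <- (network$n_l2pyr + network$n_l5pyr) * 4L +
    network$n_l2basket + network$n_l5basket

  realized <- with_preserved_seed(trial_seed, {
    init_v <- network$e_leak + runif(n_state, -1, 1)
    times <- lapply(drives, function(d) realize_drive_times(d, config))
    list(init_v = init_v, times = times)
  })

  ev_step <- integer(0); ev_chan <- integer(0); ev_w <- numeric(0)
  for (i in seq_along(drives)) {
    d <- drives[[i]]
    tch <- drive_target_channels(d)
    for (t in realized$times[[i]]) {
      s <- as.integer(floor((t + d$delay - config$tmin) / config$dt))
      for (tc in tch) {
        ev_step <- c(ev_step, s)
        ev_chan <- c(ev_chan, as.integer(tc$chan))
        ev_w <- c(ev_w, tc$w)
      }
    }
  }

  cpp_net <- c(network[c("n_l2pyr", "n_l5pyr", "n_l2basket", "n_l5basket",
                         "e_leak", "g_leak", "capacitance", "spike_threshold",
                         "spike_reset", "refractory_pyr", "refractory_basket",
                         "basket_threshold", "axial_g", "seg_len", "bp_amp",
                         "bp_tau_rise", "bp_tau_decay", "ca_threshold",
                         "ca_amp", "ca_tau_rise", "ca_tau_decay",
                         "ca_refractory", "rec_tau_rise", "rec_tau_decay",
                         "rec_erev")],
               flatten_connectivity(network$connectivity))

  out <- .simulate_trial_cpp(cpp_net, list(step = ev_step, chan = ev_chan,
                                           w = ev_w),
                             realized$init_v, config$dt, config$tmin, n_steps)

  pops <- c("L2Pyr", "L5Pyr", "L2Basket", "L5Basket")
  list(
    dipole = data.frame(time_ms = out$time_ms,
                        net = out$dip_l2 + out$dip_l5,
                        L23 = out$dip_l2, L5 = out$dip_l5),
    spikes = data.frame(cell_id = out$spike_cell,
                        population = pops[out$spike_pop + 1L],
                        t_ms = out$spike_t),
    comp_mean = out$comp_mean,
    drive_times = realized$times
  )
}

#' Net dipole from compartment potentials
#'
#' Sums, over adjacent compartment pairs, axial current times the signed
#' length of the segment along the apical axis; upward current flow (lower
#' compartment more depolarized than the one above it) is positive.
#'
#' @param v matrix (cells x 4) or vector (length 4) of compartment potentials
#'   ordered basal, soma, trunk, tuft.
#' @param axial_g axial conductances for the pairs (basal,soma), (soma,trunk),
#'   (trunk,tuft).
#' @param seg_len signed segment lengths for the same pairs.
#' @return scalar net dipole sample (model units).
#' @export
compute_dipole <- function(v, axial_g, seg_len) {
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  stopifnot(ncol(v) == 4, length(axial_g) == 3, length(seg_len) == 3)
  s <- 0
  for (p in 1:3) s <- s + axial_g[p] * seg_len[p] * sum(v[, p] - v[, p + 1])
  s
}

#' Post-process a raw dipole trace
#'
#' Convolves with a unit-sum Hamming kernel of the requested duration
#' (same-length output, zero-padded edges) and applies the multiplicative
#' scaling factor. A zero-length window skips smoothing.
#'
#' @param trace data.frame from [simulate_trial()]'s `dipole`, or a numeric
#'   vector.
#' @param scaling multiplicative factor (> 0).
#' @param window_ms Hamming window duration (ms).
#' @param dt sample spacing (ms); taken from the trace's time axis when a
#'   data.frame is given.
#' @return object of the same shape with net/L23/L5 (or the vector) smoothed
#'   and scaled.
#' @export
postprocess_dipole <- function(trace, scaling = 150, window_ms = 30, dt = NULL) {
  stopifnot(scaling > 0, window_ms >= 0)
  if (is.data.frame(trace)) {
    dt <- diff(trace$time_ms[1:2])
    for (col in c("net", "L23", "L5"))
      trace[[col]] <- smooth_scale(trace[[col]], scaling, window_ms, dt)
    return(trace)
  }
  if (is.null(dt)) stop("dt required for a bare numeric trace")
  smooth_scale(trace, scaling, window_ms, dt)
}

smooth_scale <- function(x, scaling, window_ms, dt) {
  if (window_ms > 0) {
    n <- as.integer(round(window_ms / dt)) + 1L
    if (n > length(x)) stop("smoothing window longer than the trace")
    if (n >= 2) {
      k <- as.numeric(signal::hamming(n))
      k <- k / sum(k)
      # pad with edge values so the unit-sum kernel preserves constants at
      # the boundaries instead of decaying toward zero
      pad <- n - 1L
      xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
      full <- convolve(xp, rev(k), type = "open")
      lead <- (n - 1L) %/% 2L
      x <- full[(pad + lead + 1L):(pad + lead + length(x))]
    }
  }
  x * scaling
}

#' Simulate a trial ensemble
#'
#' Runs `config$n_trials` independent trials with per-trial seeds derived from
#' the master seed, post-processes each trial (scaling + smoothing), and
#' averages.
#'
#' @param network a `stop_network`.
#' @param drives list of [drive_spec()].
#' @param config a [sim_config()].
#' @param keep_spikes keep per-trial rasters (memory).
#' @return list with `time_ms`, `mean` (data.frame time_ms, net, L23, L5),
#'   `trials` (n_trials x time matrix of processed net dipoles), `rasters`
#'   (list or NULL), `trial_seeds`.
#' @export
simulate_ensemble <- function(network, drives, config, keep_spikes = FALSE) {
  seeds <- derive_seeds(config$seed, config$n_trials)
  trials <- NULL; l23 <- NULL; l5 <- NULL
  rasters <- if (keep_spikes) vector("list", config$n_trials) else NULL
  time_ms <- NULL
  for (i in seq_len(config$n_trials)) {
    tr <- simulate_trial(network, drives, config, trial_seed = seeds[i])
    proc <- postprocess_dipole(tr$dipole, config$scaling, config$smooth_window_ms)
    if (is.null(trials)) {
      time_ms <- proc$time_ms
      trials <- matrix(0, config$n_trials, length(time_ms))
      l23 <- numeric(length(time_ms)); l5 <- numeric(length(time_ms))
    }
    trials[i, ] <- proc$net
    l23 <- l23 + proc$L23; l5 <- l5 + proc$L5
    if (keep_spikes) rasters[[i]] <- tr$spikes
  }
  list(time_ms = time_ms,
       mean = data.frame(time_ms = time_ms, net = colMeans(trials),
                         L23 = l23 / config$n_trials, L5 = l5 / config$n_trials),
       trials = trials, rasters = rasters, trial_seeds = seeds)
}

#' Derive independent sub-seeds from a master seed
#'
#' Deterministic counter scheme: the master seed seeds R's RNG once and `n`
#' integer seeds below 2^31 are drawn.
#'
#' @param master integer master seed.
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  with_preserved_seed(master, sample.int(.Machine$integer.max, n))
}
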