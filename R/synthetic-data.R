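#' Standard 62-channel 10-10 montage labels
#'
#' @return character vector of 62 channel labels.
#' @export
montage_62 <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz")
}

# approximate planar coordinates for the montage: row (anterior-posterior)
# and lateral index parsed from the label; used only to draw smooth
# synthetic scalp maps, not as a head model
montage_positions <- function(channels = montage_62()) {
  rowy <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
            TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -5)
  latx <- c(z = 0, "1" = -1, "2" = 1, "3" = -2, "4" = 2,
            "5" = -3, "6" = 3, "7" = -4, "8" = 4)
  pos <- t(vapply(channels, function(ch) {
    m <- regmatches(ch, regexec("^([A-Za-z]+)(z|[0-9]+)$", ch))[[1]]
    c(x = unname(latx[m[3]]), y = unname(rowy[m[2]]))
  }, c(x = 0, y = 0)))
  rownames(pos) <- channels
  pos
}

# Gaussian scalp map peaked at one channel
topography <- function(peak_channel, channels = montage_62(), width = 1.5) {
  pos <- montage_positions(channels)
  d2 <- (pos[, "x"] - pos[peak_channel, "x"])^2 +
        (pos[, "y"] - pos[peak_channel, "y"])^2
  exp(-d2 / (2 * width^2))
}

#' Synthetic sensor-level Stop-Signal EEG configuration
#'
#' Component templates emulate the frontocentral ERP: a positive P2 at
#' 150 ms, a negative N2 at 200 ms, and a broad positive P3 peaking at
#' 300 ms with an explicit onset (the divergence time from Go trials, which
#' carry no P3). Condition effects: on failed Stops the P3 onset is delayed
#' by `failed_p3_delay` ms, the P2 amplitude is multiplied by
#' `failed_p2_mult`, and the N2 is `failed_n2_delay` ms later.
#'
#' @param n_channels number of channels (uses the first of [montage_62()]).
#' @param n_trials trials per condition.
#' @param srate sampling rate, Hz.
#' @param p2_amp,p2_lat,p2_sd P2 Gaussian amplitude, latency, width (ms).
#' @param n2_amp,n2_lat,n2_sd N2 Gaussian (amplitude negative).
#' @param p3_amp,p3_lat,p3_onset,p3_rise,p3_fall P3 shape: zero before
#'   `p3_onset`, saturating rise (time constant `p3_rise`), maximum exactly
#'   at `p3_lat`, half-Gaussian decay (`p3_fall` ms) after.
#' @param failed_p3_delay ms (default 19), `failed_p2_mult` (> 1),
#'   `failed_n2_delay` ms.
#' @param n_nuisance nuisance sources; `nuisance_amp` their amplitude.
#' @param amp_jitter trial-wise multiplicative amplitude SD.
#' @param lat_jitter trial-wise latency shift SD (ms).
#' @param noise_sd sensor noise SD.
#' @param fc_channel designated frontocentral channel for the planted source.
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 62L, n_trials = 50L, srate = 500,
                             p2_amp = 5, p2_lat = 150, p2_sd = 12,
                             n2_amp = -4, n2_lat = 200, n2_sd = 15,
                             p3_amp = 8, p3_lat = 300, p3_onset = 224,
                             p3_rise = 5, p3_fall = 60,
                             failed_p3_delay = 19, failed_p2_mult = 1.3,
                             failed_n2_delay = 10,
                             n_nuisance = 5L, nuisance_amp = 5,
                             amp_jitter = 0.1, lat_jitter = 2, noise_sd = 2,
                             fc_channel = "FCz", seed = 1L) {
  stopifnot(n_channels >= 10, n_channels <= 62, n_trials >= 2,
            amp_jitter >= 0, lat_jitter >= 0, noise_sd >= 0,
            failed_p3_delay >= 0, p3_onset < p3_lat)
  channels <- montage_62()[seq_len(n_channels)]
  if (!fc_channel %in% channels)
    stop("fc_channel must be one of the montage channels")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Noiseless single-channel target ERP for one condition
#'
#' @param config a [synthetic_config()].
#' @param condition one of "successful_stop", "failed_stop",
#'   "go_successful", "go_failed". Go conditions carry no P3; failed
#'   conditions carry the P2/N2/P3 condition effects.
#' @return data.frame(time_ms, amplitude) on the -100..500 ms grid at the
#'   configured sampling rate; the baseline window is exactly zero.
#' @export
generate_target_erp <- function(config, condition) {
  known <- c("successful_stop", "failed_stop", "go_successful", "go_failed")
  if (!condition %in% known)
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(known, collapse = ", "))
  t <- seq(-100, 500, by = 1000 / config$srate)
  failed <- condition %in% c("failed_stop", "go_failed")
  p2a <- config$p2_amp * if (failed) config$failed_p2_mult else 1
  n2l <- config$n2_lat + if (failed) config$failed_n2_delay else 0
  amp <- p2a * exp(-(t - config$p2_lat)^2 / (2 * config$p2_sd^2)) +
         config$n2_amp * exp(-(t - n2l)^2 / (2 * config$n2_sd^2))
  if (condition %in% c("successful_stop", "failed_stop")) {
    # the failed-Stop effect is a delayed P3 ONSET; the peak latency is
    # shared, so the grand-average Stop ERP peaks at p3_lat
    onset <- config$p3_onset + if (failed) config$failed_p3_delay else 0
    amp <- amp + p3_template(t, config$p3_amp, onset, config$p3_lat,
                             config$p3_rise, config$p3_fall)
  }
  amp[t <= 0] <- 0
  data.frame(time_ms = t, amplitude = amp)
}

# P3 shape: zero before onset, then an equal mix of a fast saturating
# exponential (sharp statistical divergence at the onset) and a linear ramp
# (strictly increasing to the peak, so the maximum sits exactly at `peak`),
# with a half-Gaussian decay after the peak
p3_template <- function(t, amp, onset, peak, rise, fall) {
  u <- ifelse(t > onset,
              0.5 * (1 - exp(-(t - onset) / rise)) +
              0.5 * pmin(1, (t - onset) / (peak - onset)), 0)
  v <- ifelse(t > peak, exp(-(t - peak)^2 / (2 * fall^2)), 1)
  amp * u * v
}

#' Generate a synthetic sensor-level SST dataset with ground truth
#'
#' Builds trials = sum over sources of (scalp map x jittered source
#' waveform) + sensor noise, for the four conditions. One designated
#' frontocentral source (scalp map peaked at `fc_channel`) carries the
#' ERP templates and all condition effects; the nuisance sources carry
#' condition-independent smooth oscillations with scalp maps peaked at
#' non-frontocentral channels.
#'
#' @param config a [synthetic_config()].
#' @return list with `epochs` (an [epoch_set()], trials x time x channels),
#'   `decomp` (ground-truth [decomposition()]: true mixing + true source
#'   activations), and `truth` (planted component index, per-condition P3
#'   onsets, condition effects, seed).
#' @export
generate_sensor_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  channels <- config$channels
  t <- seq(-100, 500, by = 1000 / config$srate)
  nt <- length(t)
  conds <- rep(c("successful_stop", "failed_stop", "go_successful",
                 "go_failed"), each = config$n_trials)
  n_all <- length(conds)
  k <- config$n_nuisance
  with_preserved_seed(config$seed, {
    # scalp maps: planted frontocentral source at a random component slot
    non_fc <- setdiff(channels, frontocentral_channels())
    nuisance_peaks <- sample(non_fc, k)
    planted <- sample.int(k + 1L, 1L)
    order_maps <- append(as.list(nuisance_peaks), config$fc_channel,
                         after = planted - 1L)
    mixing <- vapply(order_maps, topography, numeric(length(channels)),
                     channels = channels)
    templates <- lapply(stats::setNames(nm = unique(conds)), function(cn)
      generate_target_erp(config, cn)$amplitude)
    acts <- array(0, c(n_all, nt, k + 1L))
    nuis_freq <- matrix(runif(k * 3, 2, 15), k)
    data <- array(0, c(n_all, nt, length(channels)))
    for (i in seq_len(n_all)) {
      a <- 1 + rnorm(1, 0, config$amp_jitter)
      shift <- rnorm(1, 0, config$lat_jitter)
      w <- a * approx(t + shift, templates[[conds[i]]], xout = t,
                      rule = 2)$y
      acts[i, , planted] <- w
      ki <- 0L
      for (j in seq_len(k + 1L)[-planted]) {
        ki <- ki + 1L
        ph <- runif(3, 0, 2 * pi)
        acts[i, , j] <- config$nuisance_amp / 3 *
          (sin(2 * pi * nuis_freq[ki, 1] * t / 1000 + ph[1]) +
           sin(2 * pi * nuis_freq[ki, 2] * t / 1000 + ph[2]) +
           sin(2 * pi * nuis_freq[ki, 3] * t / 1000 + ph[3]))
      }
      for (ch in seq_along(channels))
        data[i, , ch] <- acts[i, , ] %*% mixing[ch, ] +
          rnorm(nt, 0, config$noise_sd)
    }
    list(
      epochs = epoch_set(data, t, conds, config$srate, channels),
      decomp = decomposition(mixing, acts, channels),
      truth = list(
        planted_index = planted,
        p3_onset = c(successful_stop = config$p3_onset,
                     failed_stop = config$p3_onset + config$failed_p3_delay),
        failed_p3_delay = config$failed_p3_delay,
        failed_p2_mult = config$failed_p2_mult,
        failed_n2_delay = config$failed_n2_delay,
        fc_channel = config$fc_channel,
        seed = config$seed))
  })
}

#' Simulator-generated fitting target with recorded ground truth
#'
#' Runs the column simulator under a preset and returns the trial-mean
#' dipole plus the generating parameter values, for parameter-recovery
#' (self-consistency) fitting experiments.
#'
#' @param preset a [model_preset()].
#' @param config a [sim_config()].
#' @param n_pyramidal pyramidal cells per layer.
#' @return list(time_ms, target, truth) where truth is the full
#'   [preset_parameters()] value table of the generating preset.
#' @export
generate_simulator_target <- function(preset, config = sim_config(),
                                      n_pyramidal = 100L) {
  ens <- simulate_preset(preset, config, n_pyramidal = n_pyramidal)
  truth <- preset_parameters(preset, free = character(0))[, c("name", "value")]
  list(time_ms = ens$time_ms, target = ens$mean$net, truth = truth,
       preset = preset$name, seed = config$seed)
}
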