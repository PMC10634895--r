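#' Frontocentral channels used for component selection
#'
#' @return the nine 10-10 channel labels defining the frontocentral region.
#' @export
frontocentral_channels <- function() {
  c("Fz", "F1", "F2", "FCz", "FC1", "FC2", "Cz", "C1", "C2")
}

#' ICA decomposition container
#'
#' Wraps a spatial decomposition for consumption: a channels x components
#' mixing matrix plus per-trial component activations. The decomposition is
#' consumed, not computed, here.
#'
#' @param mixing channels x components mixing matrix.
#' @param activations trials x time x components array (or a components x
#'   time matrix for a single trial, which is promoted).
#' @param channels channel labels (10-10 names), length = rows of `mixing`.
#' @return an object of class `decomposition`.
#' @export
decomposition <- function(mixing, activations, channels) {
  mixing <- as.matrix(mixing)
  if (length(dim(activations)) == 2)
    activations <- array(t(activations), c(1L, ncol(activations), nrow(activations)))
  stopifnot(nrow(mixing) == length(channels),
            ncol(mixing) <= nrow(mixing),
            dim(activations)[3] == ncol(mixing))
  structure(list(mixing = mixing, activations = activations,
                 channels = as.character(channels)),
            class = "decomposition")
}

#' Select the component carrying the frontocentral P3 effect
#'
#' Two-criterion rule: (1) keep components whose maximum absolute mixing
#' weight falls on one of the nine frontocentral channels (Fz, F1, F2, FCz,
#' FC1, FC2, Cz, C1, C2); (2) among those, return the component whose
#' reconstructed failed-minus-successful ERP difference at the reference
#' channel correlates most strongly (Pearson, over 200-500 ms post-signal)
#' with the same difference in the full data.
#'
#' @param decomp a [decomposition()].
#' @param epochs an [epoch_set()] with channels matching the decomposition
#'   and conditions including "successful_stop" and "failed_stop".
#' @param ref_channel reference channel for the correlation (default "FCz").
#' @param window correlation window, ms (default c(200, 500)).
#' @return list(index, candidates, correlations).
#' @export
select_p3_component <- function(decomp, epochs, ref_channel = "FCz",
                                window = c(200, 500)) {
  stopifnot(inherits(decomp, "decomposition"), inherits(epochs, "epoch_set"))
  if (!identical(as.character(epochs$channels), decomp$channels))
    stop("epoch channels do not match the decomposition channels")
  peak_ch <- decomp$channels[apply(abs(decomp$mixing), 2, which.max)]
  candidates <- which(peak_ch %in% frontocentral_channels())
  if (!length(candidates))
    stop("no frontocentral component: no component has its maximal ",
         "absolute weight at ", paste(frontocentral_channels(), collapse = "/"))
  widx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  ref <- match(ref_channel, decomp$channels)
  if (is.na(ref)) stop("reference channel ", ref_channel, " not present")
  cond_diff <- function(x) {
    # x: trials x time; failed-minus-successful mean difference
    colMeans(x[epochs$condition == "failed_stop", , drop = FALSE]) -
      colMeans(x[epochs$condition == "successful_stop", , drop = FALSE])
  }
  full_diff <- cond_diff(epochs$data[, widx, ref])
  correlations <- rep(NA_real_, ncol(decomp$mixing))
  for (k in candidates) {
    ic_ref <- decomp$mixing[ref, k] * decomp$activations[, widx, k]
    ic_diff <- cond_diff(ic_ref)
    correlations[k] <- if (sd(ic_diff) == 0 || sd(full_diff) == 0) -Inf else
      cor(ic_diff, full_diff)
  }
  index <- candidates[which.max(correlations[candidates])]
  list(index = index, candidates = candidates, correlations = correlations)
}

#' Reconstruct channel data from a single component
#'
#' Channel data = mixing column (outer) activation row, with every other
#' component zeroed. Reconstruction is linear in the activations, and
#' summing the reconstructions of all components returns the mixed data.
#'
#' @param decomp a [decomposition()].
#' @param index component index.
#' @param times time axis for the returned [epoch_set()].
#' @param condition condition labels for the returned epochs.
#' @param srate sampling rate (Hz).
#' @return an [epoch_set()] (trials x time x channels).
#' @export
reconstruct_single_ic <- function(decomp, index, times, condition,
                                  srate = 500) {
  stopifnot(inherits(decomp, "decomposition"))
  if (index < 1 || index > ncol(decomp$mixing))
    stop("component index ", index, " out of range 1..", ncol(decomp$mixing))
  dims <- dim(decomp$activations)
  out <- array(0, c(dims[1], dims[2], nrow(decomp$mixing)))
  for (ch in seq_len(nrow(decomp$mixing)))
    out[, , ch] <- decomp$mixing[ch, index] * decomp$activations[, , index]
  epoch_set(out, times, condition, srate, decomp$channels)
}

#' Mix a full decomposition back to channel space
#'
#' @param decomp a [decomposition()].
#' @return trials x time x channels array equal to the sum of all
#'   single-component reconstructions.
#' @export
mix_decomposition <- function(decomp) {
  dims <- dim(decomp$activations)
  out <- array(0, c(dims[1], dims[2], nrow(decomp$mixing)))
  for (k in seq_len(ncol(decomp$mixing)))
    for (ch in seq_len(nrow(decomp$mixing)))
      out[, , ch] <- out[, , ch] +
        decomp$mixing[ch, k] * decomp$activations[, , k]
  out
}
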