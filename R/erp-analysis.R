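#' @importFrom stats p.adjust median quantile cor complete.cases
NULL

#' Trial-by-time epoch container
#'
#' Holds Stop-Signal-locked single-trial ERP epochs: a trials x time (or
#' trials x time x channels) amplitude array sampled uniformly, with 0 ms at
#' the Stop-Signal and a condition label per trial.
#'
#' @param data matrix (trials x time) or 3-d array (trials x time x channels).
#' @param times time axis in ms (0 = Stop-Signal).
#' @param condition character vector, one label per trial (e.g.
#'   "successful_stop", "failed_stop", "go_successful", "go_failed").
#' @param srate sampling rate in Hz.
#' @param channels optional channel labels (10-10 names) for 3-d data.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, condition, srate = 500, channels = NULL) {
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(times),
            dim(data)[1] == length(condition))
  if (!is.null(channels)) stopifnot(length(channels) == dim(data)[3])
  structure(list(data = data, times = times, condition = as.character(condition),
                 srate = srate, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " samples x ", dim(x$data)[3], " channel(s), ",
      min(x$times), "..", max(x$times), " ms @ ", x$srate, " Hz\n", sep = "")
  print(table(x$condition))
  invisible(x)
}

#' Subset an epoch_set by condition
#'
#' @param epochs an [epoch_set()].
#' @param condition label(s) to keep.
#' @return an `epoch_set` with the matching trials.
#' @export
epochs_by_condition <- function(epochs, condition) {
  keep <- epochs$condition %in% condition
  if (!any(keep)) stop("no trials with condition ", paste(condition, collapse = "/"))
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$times,
            epochs$condition[keep], epochs$srate, epochs$channels)
}

#' Baseline-correct epochs
#'
#' Mean-subtraction using the 100 ms preceding the Stop-Signal: per trial
#' (and channel) the mean over the baseline window is subtracted.
#'
#' @param epochs an [epoch_set()].
#' @param baseline c(start, end) in ms; default c(-100, 0).
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- epochs$times >= baseline[1] & epochs$times <= baseline[2]
  if (sum(idx) < 2L) stop("epochs do not cover the baseline window")
  for (ch in seq_len(dim(epochs$data)[3])) {
    mu <- rowMeans(epochs$data[, idx, ch, drop = FALSE])
    epochs$data[, , ch] <- epochs$data[, , ch] - mu
  }
  epochs
}

#' Quantify P2/N2/P3 peaks on an average trace
#'
#' P2 is the maximum of the average ERP 100-200 ms post-Stop-Signal, N2 the
#' minimum 150-250 ms, and P3 the maximum over the whole post-signal window
#' (0-500 ms here). Ties resolve to the earliest sample.
#'
#' @param trace numeric average ERP.
#' @param times time axis in ms matching `trace`.
#' @param windows list with elements p2, n2, p3, each c(start, end) ms.
#' @return list with p2/n2/p3, each holding `amplitude` and `latency` (ms).
#' @export
quantify_peaks <- function(trace, times,
                           windows = list(p2 = c(100, 200), n2 = c(150, 250),
                                          p3 = c(0, 500))) {
  stopifnot(length(trace) == length(times))
  pick <- function(win, fun) {
    idx <- which(times >= win[1] & times <= win[2])
    if (!length(idx)) stop("peak window outside the trace")
    v <- trace[idx]
    j <- if (identical(fun, max)) which(v == max(v))[1] else which(v == min(v))[1]
    list(amplitude = v[j], latency = times[idx][j])
  }
  list(p2 = pick(windows$p2, max), n2 = pick(windows$n2, min),
       p3 = pick(windows$p3, max))
}

#' Per-timepoint resampling t-test p-values
#'
#' For each timepoint, computes the two-sample t statistic between the Stop
#' and matched-Go trial pools and builds a null distribution by resampling
#' (default: label permutation of the pooled trials; optionally a
#' with-replacement bootstrap). The p-value is the add-one-smoothed
#' proportion of null |t| at least as large as the observed |t|. Timepoints
#' where both pools have zero variance get p = 1.
#'
#' @param stop_trials matrix trials x time.
#' @param go_trials matrix trials x time (same time axis).
#' @param n_resamples resampling draws (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param method "permutation" (default) or "bootstrap".
#' @return numeric vector of p-values, one per timepoint.
#' @export
bootstrap_t_pvalues <- function(stop_trials, go_trials, n_resamples = 1000L,
                                seed = 1L, method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  stopifnot(nrow(stop_trials) >= 2, nrow(go_trials) >= 2,
            ncol(stop_trials) == ncol(go_trials), n_resamples >= 1)
  n1 <- nrow(stop_trials); n2 <- nrow(go_trials)
  pooled <- rbind(stop_trials, go_trials)
  tstat <- function(a, b) {
    m <- colMeans(a) - colMeans(b)
    se2 <- apply(a, 2, var) / nrow(a) + apply(b, 2, var) / nrow(b)
    t <- ifelse(se2 > 0, m / sqrt(se2), 0)
    t
  }
  obs <- abs(tstat(stop_trials, go_trials))
  exceed <- with_preserved_seed(seed, {
    ex <- numeric(ncol(pooled))
    for (r in seq_len(n_resamples)) {
      if (method == "permutation") {
        idx <- sample.int(n1 + n2)
        a <- pooled[idx[seq_len(n1)], , drop = FALSE]
        b <- pooled[idx[-seq_len(n1)], , drop = FALSE]
      } else {
        a <- pooled[sample.int(n1 + n2, n1, replace = TRUE), , drop = FALSE]
        b <- pooled[sample.int(n1 + n2, n2, replace = TRUE), , drop = FALSE]
      }
      ex <- ex + (abs(tstat(a, b)) >= obs)
    }
    ex
  })
  p <- (exceed + 1) / (n_resamples + 1)
  # degenerate timepoints: identical constant pools carry no evidence
  zerovar <- apply(pooled, 2, var) == 0
  p[zerovar] <- 1
  p
}

#' Benjamini-Hochberg significance mask
#'
#' Standard BH step-up rule at level alpha. (BH controls the false discovery
#' rate, not the family-wise error rate.)
#'
#' @param p numeric vector of p-values.
#' @param alpha level (default 0.05).
#' @return logical mask, TRUE where significant after correction.
#' @export
bh_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  if (!length(p)) return(logical(0))
  p.adjust(p, method = "BH") <= alpha
}

#' P3 onset latency from timepoint-wise resampling statistics
#'
#' Runs [bootstrap_t_pvalues()] on the post-signal timepoints, corrects with
#' [bh_correct()], and returns the onset of the significant divergence
#' before the P3 peak. Under the default rule ("run-to-peak") the onset is
#' the earliest timepoint of the contiguous significant run containing (or
#' ending at) the P3 peak sample; under "first-significant" it is the first
#' significant timepoint at or before the peak regardless of contiguity.
#' Returns NA when no timepoint at or before the peak is significant.
#'
#' @param stop_trials matrix trials x time (baseline-corrected).
#' @param go_trials matrix trials x time.
#' @param times time axis (ms).
#' @param p3_peak_latency peak latency (ms) from [quantify_peaks()].
#' @param n_resamples,seed,method passed to [bootstrap_t_pvalues()].
#' @param alpha BH level.
#' @param rule "run-to-peak" (default) or "first-significant".
#' @return onset latency in ms, or NA.
#' @export
p3_onset <- function(stop_trials, go_trials, times, p3_peak_latency,
                     n_resamples = 1000L, seed = 1L,
                     method = c("permutation", "bootstrap"), alpha = 0.05,
                     rule = c("run-to-peak", "first-significant")) {
  rule <- match.arg(rule)
  post <- which(times >= 0)
  p <- bootstrap_t_pvalues(stop_trials[, post, drop = FALSE],
                           go_trials[, post, drop = FALSE],
                           n_resamples = n_resamples, seed = seed,
                           method = match.arg(method))
  sig <- bh_correct(p, alpha)
  tpost <- times[post]
  peak_i <- which.min(abs(tpost - p3_peak_latency))
  upto <- which(sig[seq_len(peak_i)])
  if (!length(upto)) return(NA_real_)
  if (rule == "first-significant") return(tpost[upto[1]])
  # walk back from the peak through the contiguous significant run
  if (!sig[peak_i]) {
    # peak itself not significant: use the run ending nearest before it
    last_sig <- max(upto)
    i <- last_sig
  } else i <- peak_i
  while (i > 1 && sig[i - 1]) i <- i - 1
  tpost[i]
}
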