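#' Enumerate a preset's parameters as a bounded vector
#'
#' Flattens every drive parameter into a named table. Naming scheme:
#' `<drive>.mu` (timing), `<drive>.sigma` (SD), and
#' `<drive>.<target>.<receptor>` (synaptic weight). Bounds: timing within
#' +/- 50 ms of the preset value, SD in [0, 3*value + 5], and each weight in
#' [0, 4*w0] — a change of at most 300% of the starting value, keeping
#' weights biologically plausible.
#'
#' @param preset a [model_preset()].
#' @param free character vector of free names; defaults to the preset's own
#'   mask. Names not matching any parameter raise an error.
#' @return data.frame with columns name, value, lower, upper, frozen, kind.
#' @export
preset_parameters <- function(preset, free = preset$free) {
  rows <- list()
  for (d in preset$drives) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(d$name, ".mu"), value = d$mu,
      lower = d$mu - 50, upper = d$mu + 50, kind = "timing")
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(d$name, ".sigma"), value = d$sigma,
      lower = 0, upper = 3 * d$sigma + 5, kind = "SD")
    for (tgt in names(d$weights)) for (rec in names(d$weights[[tgt]])) {
      w0 <- d$weights[[tgt]][[rec]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(d$name, tgt, rec, sep = "."), value = w0,
        lower = 0, upper = 4 * w0, kind = "weight")
    }
  }
  out <- do.call(rbind, rows)
  bad <- setdiff(free, out$name)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  out$frozen <- !(out$name %in% free)
  out
}

#' Write parameter values back into a preset
#'
#' @param preset a [model_preset()].
#' @param values named numeric vector using the [preset_parameters()] naming
#'   scheme.
#' @return the preset with updated drives.
#' @export
set_preset_parameters <- function(preset, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    di <- which(vapply(preset$drives, function(d) d$name, "") == parts[1])
    if (!length(di)) stop("no drive named ", parts[1])
    d <- unclass(preset$drives[[di]])
    if (length(parts) == 2) {
      if (!parts[2] %in% c("mu", "sigma")) stop("unknown parameter ", nm)
      d[[parts[2]]] <- unname(values[[nm]])
    } else if (length(parts) == 3) {
      if (is.null(d$weights[[parts[2]]]) ||
          !parts[3] %in% names(d$weights[[parts[2]]]))
        stop("unknown parameter ", nm)
      d$weights[[parts[2]]][[parts[3]]] <- unname(values[[nm]])
    } else stop("unknown parameter ", nm)
    preset$drives[[di]] <- do.call(drive_spec, d)
  }
  preset
}

#' Root-mean-square error between two traces on a 2 ms grid
#'
#' Both traces are linearly resampled to the target's 2 ms grid restricted
#' to `window`, then RMSE is computed in target units.
#'
#' @param sim_time,sim simulated time axis (ms) and trace.
#' @param target_time,target target time axis (ms) and trace.
#' @param window c(start, end) ms; default full epoch -100..500.
#' @return scalar RMSE.
#' @export
rmse <- function(sim_time, sim, target_time, target, window = c(-100, 500)) {
  lo <- max(min(sim_time), min(target_time), window[1])
  hi <- min(max(sim_time), max(target_time), window[2])
  if (hi <= lo) stop("simulated and target time axes do not overlap the window")
  grid <- seq(ceiling(lo / 2) * 2, floor(hi / 2) * 2, by = 2)
  s <- approx(sim_time, sim, xout = grid)$y
  t <- approx(target_time, target, xout = grid)$y
  sqrt(mean((s - t)^2))
}

#' Bound-constrained derivative-free minimization of a parameter table
#'
#' Pattern search (Hooke-Jeeves) over the free entries of a
#' [preset_parameters()] table. Frozen entries are never touched; the search
#' never evaluates outside the bounds; objective failures are recorded as
#' +Inf evaluations and the search continues. Deterministic given the start
#' point and budget.
#'
#' @param objective function(named numeric vector of ALL parameter values)
#'   -> scalar loss.
#' @param params parameter table from [preset_parameters()].
#' @param budget maximum objective evaluations (default 100).
#' @param seed recorded in the result (the search itself is deterministic;
#'   the seed is for objectives that internally fix an ensemble seed).
#' @return a `fit_result`: `params` (updated table), `value` (best loss),
#'   `n_eval`, `trace` (best-so-far loss per evaluation, non-increasing),
#'   `seed`.
#' @export
optimize_params <- function(objective, params, budget = 100L, seed = 1L) {
  free <- which(!params$frozen)
  state <- new.env(parent = emptyenv())
  state$n <- 0L; state$trace <- numeric(0)
  state$best <- Inf; state$best_x <- params$value[free]
  full_values <- function(xf) {
    v <- params$value; v[free] <- xf
    stats::setNames(v, params$name)
  }
  eval_obj <- function(xf) {
    if (state$n >= budget)
      stop(structure(class = c("budget_exhausted", "error", "condition"),
                     list(message = "budget exhausted", call = NULL)))
    xf <- pmin(pmax(xf, params$lower[free]), params$upper[free])
    val <- tryCatch(objective(full_values(xf)),
                    error = function(e) Inf)
    if (!is.finite(val)) val <- Inf
    state$n <- state$n + 1L
    if (val < state$best) { state$best <- val; state$best_x <- xf }
    state$trace <- c(state$trace, state$best)
    # hand the search a large finite penalty instead of Inf: pattern search
    # stops immediately when the start point evaluates to Inf
    min(val, 1e12)
  }
  run_search <- function() {
    x0 <- params$value[free]
    # evaluate the start point so the trace always includes it
    eval_obj(x0)
    if (length(free) == 1) {
      # golden-section search; pattern search needs >= 2 dimensions
      stats::optimize(function(x) eval_obj(x),
                      lower = params$lower[free], upper = params$upper[free],
                      tol = 1e-4)
    } else {
      pracma::hooke_jeeves(x0, eval_obj,
                           lb = params$lower[free],
                           ub = params$upper[free],
                           maxfeval = budget)
    }
  }
  if (length(free)) {
    tryCatch(run_search(), budget_exhausted = function(e) NULL,
             error = function(e) NULL)
  } else {
    eval_obj(numeric(0))
  }
  params$value[free] <- state$best_x
  structure(list(params = params, value = state$best, n_eval = state$n,
                 trace = state$trace, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> loss ", format(x$value), " after ", x$n_eval,
      " evaluations\n", sep = "")
  fr <- x$params[!x$params$frozen, c("name", "value")]
  if (nrow(fr)) print(fr, row.names = FALSE)
  invisible(x)
}

#' Build the RMSE objective for a preset against a target ERP
#'
#' The returned closure writes candidate values into the preset, simulates a
#' trial ensemble with a FIXED ensemble seed (so the objective is
#' deterministic for the optimizer), and returns the RMSE of the trial mean
#' against the target.
#'
#' @param preset a [model_preset()].
#' @param target_time,target target time axis (ms) and trace.
#' @param config a [sim_config()]; its `seed` fixes the ensemble.
#' @param n_pyramidal pyramidal cells per layer (reduce for speed).
#' @param window RMSE window, see [rmse()].
#' @return function(named values) -> RMSE.
#' @export
preset_objective <- function(preset, target_time, target,
                             config = sim_config(), n_pyramidal = 100L,
                             window = c(-100, 500)) {
  force(preset); force(config)
  function(values) {
    p <- set_preset_parameters(preset, values)
    ens <- simulate_preset(p, config, n_pyramidal = n_pyramidal)
    rmse(ens$time_ms, ens$mean$net, target_time, target, window)
  }
}

#' Fit a preset's free parameters to a target ERP
#'
#' @inheritParams preset_objective
#' @param budget objective-evaluation budget.
#' @param free free-parameter names; defaults to the preset's mask.
#' @return a `fit_result` (see [optimize_params()]) with the fitted preset
#'   attached as `$preset`.
#' @export
fit_preset <- function(preset, target_time, target, config = sim_config(),
                       n_pyramidal = 100L, budget = 100L,
                       free = preset$free, window = c(-100, 500)) {
  params <- preset_parameters(preset, free)
  obj <- preset_objective(preset, target_time, target, config, n_pyramidal,
                          window)
  fit <- optimize_params(obj, params, budget = budget, seed = config$seed)
  fit$preset <- set_preset_parameters(
    preset, stats::setNames(fit$params$value, fit$params$name))
  fit
}

#' Stage-wise fitting with warm starts
#'
#' Executes fitting stages in order; each stage frees a stated subset of
#' parameters and warm-starts from the previous stage's best preset, so a
#' later stage's initial loss equals the earlier stage's final loss when the
#' objective is shared.
#'
#' @param preset starting [model_preset()].
#' @param target_time,target target ERP.
#' @param stages list; each element is either a character vector of free
#'   names (possibly empty = all frozen) or a list(free =, budget =).
#' @param config,n_pyramidal,window see [fit_preset()].
#' @param budget default per-stage budget.
#' @return list of `fit_result`, one per stage (last element = final fit).
#' @export
staged_fit <- function(preset, target_time, target, stages,
                       config = sim_config(), n_pyramidal = 100L,
                       budget = 100L, window = c(-100, 500)) {
  if (length(stages) == 0) stop("stages must name at least one stage")
  out <- vector("list", length(stages))
  cur <- preset
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.list(st)) { fr <- st$free %||% character(0); bu <- st$budget %||% budget }
    else { fr <- st; bu <- budget }
    out[[i]] <- fit_preset(cur, target_time, target, config, n_pyramidal,
                           budget = bu, free = fr, window = window)
    cur <- out[[i]]$preset
  }
  out
}

#' Fit and rank competing presets against one target
#'
#' Each preset is fit (one stage, its own free mask) against the common
#' target; presets are ranked by final RMSE ascending. A preset whose fit
#' errors is reported with RMSE = Inf rather than aborting the others.
#'
#' @param target_time,target common target ERP.
#' @param presets list of [model_preset()] or character vector of shipped
#'   preset names.
#' @param config,n_pyramidal,budget,window see [fit_preset()].
#' @return a `comparison_report`: data.frame (preset, rmse, rank, n_free,
#'   free) sorted by rank, with the fits in `attr(, "fits")`.
#' @export
compare_models <- function(target_time, target, presets,
                           config = sim_config(), n_pyramidal = 100L,
                           budget = 100L, window = c(-100, 500)) {
  if (is.character(presets)) presets <- lapply(presets, load_preset)
  fits <- lapply(presets, function(p)
    tryCatch(fit_preset(p, target_time, target, config, n_pyramidal,
                        budget = budget, window = window),
             error = function(e) structure(list(value = Inf, error =
               conditionMessage(e)), class = "fit_result")))
  rep <- data.frame(
    preset = vapply(presets, function(p) p$name, ""),
    rmse = vapply(fits, function(f) f$value, 0),
    n_free = vapply(presets, function(p) length(p$free), 0L),
    free = vapply(presets, function(p) paste(p$free, collapse = ","), ""))
  rep <- rep[order(rep$rmse), ]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  attr(rep, "fits") <- fits
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' Two-source summation fit
#'
#' Splits the target ERP at a latency between the N2 and P3 peaks: the early
#' copy is set to zero after the split and fit by a model carrying only the
#' first proximal and the distal drive; the late copy is set to zero before
#' the split and fit by a model carrying only the late proximal drive (by
#' default only its timing parameters are free). The predicted waveform is
#' the elementwise sum of the two fitted trial means.
#'
#' @param target_time,target the target ERP.
#' @param split split latency (ms); default the zero crossing between the
#'   N2 and P3 peaks of the target. Must lie inside the epoch.
#' @param preset base [model_preset()]; defaults to the successful preset.
#' @param config,n_pyramidal,budget,window see [fit_preset()].
#' @param early_free,late_free free-parameter names for the two fits.
#' @return list(sum, time_ms, early_fit, late_fit, split).
#' @export
two_source_fit <- function(target_time, target, split = NULL,
                           preset = load_preset("successful"),
                           config = sim_config(), n_pyramidal = 100L,
                           budget = 50L, window = c(-100, 500),
                           early_free = c("P1.mu", "D1.mu"),
                           late_free = c("P2.mu", "P2.sigma")) {
  pk <- quantify_peaks(target, target_time)
  if (is.null(split)) {
    idx <- which(target_time > pk$n2$latency & target_time < pk$p3$latency &
                 target >= 0)
    split <- if (length(idx)) target_time[idx[1]] else
      (pk$n2$latency + pk$p3$latency) / 2
  }
  if (split <= min(target_time) || split >= max(target_time))
    stop("split latency lies outside the epoch")
  early_target <- ifelse(target_time <= split, target, 0)
  late_target <- ifelse(target_time > split, target, 0)
  dn <- vapply(preset$drives, function(d) d$name, "")
  early_preset <- preset; early_preset$drives <- preset$drives[dn != "P2"]
  late_preset <- preset; late_preset$drives <- preset$drives[dn == "P2"]
  early_fit <- fit_preset(early_preset, target_time, early_target, config,
                          n_pyramidal, budget, free = early_free, window = window)
  late_fit <- fit_preset(late_preset, target_time, late_target, config,
                         n_pyramidal, budget, free = late_free, window = window)
  e <- simulate_preset(early_fit$preset, config, n_pyramidal)
  l <- simulate_preset(late_fit$preset, config, n_pyramidal)
  list(sum = e$mean$net + l$mean$net, time_ms = e$time_ms,
       early = e$mean$net, late = l$mean$net,
       early_fit = early_fit, late_fit = late_fit, split = split)
}
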