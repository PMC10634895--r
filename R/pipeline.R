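#' Default demo pipeline configuration
#'
#' Small-scale settings so the full pipeline (synthesize -> select IC ->
#' extract ERP features -> fit presets -> compare) completes in seconds.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own seed from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("stopcolumn-run-"),
                                    seed = 1L) {
  list(
    seed = seed,
    out_dir = out_dir,
    synth = list(n_trials = 30L, n_nuisance = 3L),
    ic = list(ref_channel = "FCz"),
    erp = list(n_resamples = 200L, alpha = 0.05),
    fit = list(presets = c("failed_timing", "failed_strength"),
               n_pyramidal = 12L, n_trials = 3L, budget = 6L))
}

pipeline_required_blocks <- c("seed", "out_dir", "synth", "ic", "erp", "fit")

#' Run the end-to-end pipeline
#'
#' Stages: (1) synthesize a sensor dataset with ground truth; (2) select
#' the frontocentral P3 component and reconstruct from it; (3) epoch-level
#' ERP analysis (baseline correction, peak quantification, P3 onsets for
#' successful and failed Stops); (4) fit the configured presets to the
#' failed-Stop target (rescaled to simulator units) and rank them. All
#' reports are written under `config$out_dir`; the returned manifest lists
#' every output path, the per-stage seeds, and timings. Identical config
#' and seed give identical reports.
#'
#' @param config nested list (see [default_pipeline_config()]) or a path to
#'   a JSON file holding one.
#' @return a `run_manifest` list: config hash, seeds, package version,
#'   per-stage output paths, and per-stage elapsed seconds.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  missing <- setdiff(pipeline_required_blocks, names(config))
  if (length(missing))
    stop("pipeline config is missing required block(s): ",
         paste(missing, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  paths <- list(); timing <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timing[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  # 1. synthesize
  ds <- stage("synth", {
    scfg <- do.call(synthetic_config,
                    c(config$synth, list(seed = seeds[1])))
    generate_sensor_dataset(scfg)
  })

  # 2. component selection + single-IC reconstruction
  sel <- stage("ic", {
    s <- select_p3_component(ds$decomp, ds$epochs,
                             ref_channel = config$ic$ref_channel %||% "FCz")
    paths$selected_ic <- file.path(config$out_dir, "selected_ic.json")
    jsonlite::write_json(
      list(index = s$index, candidates = s$candidates,
           correlations = s$correlations,
           planted_index = ds$truth$planted_index),
      paths$selected_ic, auto_unbox = TRUE, digits = NA, na = "null")
    s
  })
  recon <- reconstruct_single_ic(ds$decomp, sel$index, ds$epochs$times,
                                 ds$epochs$condition, ds$epochs$srate)

  # 3. ERP analysis on the reconstructed frontocentral channel
  erp <- stage("erp", {
    bc <- baseline_correct(recon)
    fc <- match(ds$truth$fc_channel, bc$channels)
    pull <- function(cond) bc$data[bc$condition == cond, , fc]
    feats <- list(); onsets <- list()
    for (cond in c("successful_stop", "failed_stop")) {
      avg <- colMeans(pull(cond))
      pk <- quantify_peaks(avg, bc$times)
      feats[[cond]] <- pk
      go <- pull(if (cond == "successful_stop") "go_successful" else "go_failed")
      onsets[[cond]] <- p3_onset(pull(cond), go, bc$times, pk$p3$latency,
                                 n_resamples = config$erp$n_resamples %||% 1000L,
                                 seed = seeds[2],
                                 alpha = config$erp$alpha %||% 0.05)
    }
    paths$features <- file.path(config$out_dir, "erp_features.csv")
    ftab <- do.call(rbind, lapply(names(feats), function(cn) data.frame(
      condition = cn,
      p2_amp = feats[[cn]]$p2$amplitude, p2_lat = feats[[cn]]$p2$latency,
      n2_amp = feats[[cn]]$n2$amplitude, n2_lat = feats[[cn]]$n2$latency,
      p3_amp = feats[[cn]]$p3$amplitude, p3_lat = feats[[cn]]$p3$latency,
      p3_onset = onsets[[cn]])))
    utils::write.csv(ftab, paths$features, row.names = FALSE)
    list(features = ftab, onsets = onsets)
  })

  # 4. preset fitting + comparison against the failed-Stop clean target,
  # rescaled into simulator dipole units via the successful-preset baseline
  cmp <- stage("fit", {
    fcfg <- config$fit
    simc <- sim_config(seed = seeds[3],
                       n_trials = fcfg$n_trials %||% 3L)
    scfg <- do.call(synthetic_config, c(config$synth, list(seed = seeds[1])))
    tgt <- generate_target_erp(scfg, "failed_stop")
    base <- simulate_preset(load_preset("successful"), simc,
                            n_pyramidal = fcfg$n_pyramidal %||% 12L)
    scale <- max(abs(base$mean$net)) / max(abs(tgt$amplitude))
    rep <- compare_models(tgt$time_ms, tgt$amplitude * scale,
                          fcfg$presets %||% c("failed_timing", "failed_strength"),
                          config = simc,
                          n_pyramidal = fcfg$n_pyramidal %||% 12L,
                          budget = fcfg$budget %||% 6L)
    paths$comparison <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(as.data.frame(rep), paths$comparison, row.names = FALSE)
    rep
  })

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  paths$config <- cfg_path
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed, stage_seeds = seeds,
    package_version = as.character(utils::packageVersion("stopcolumn")),
    outputs = paths, timing = timing,
    selected_ic = sel$index, comparison = as.data.frame(cmp),
    erp_features = erp$features)
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    manifest[c("config_hash", "seed", "stage_seeds", "package_version",
               "outputs", "timing")],
    man_path, auto_unbox = TRUE, digits = NA)
  manifest$outputs$manifest <- man_path
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, ", package ", x$package_version, "\n",
      "  selected IC: ", x$selected_ic, "\n  outputs:\n", sep = "")
  for (nm in names(x$outputs)) cat("    ", nm, ": ", x$outputs[[nm]], "\n",
                                   sep = "")
  invisible(x)
}
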