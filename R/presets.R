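#' Construct a named model preset
#'
#' A preset bundles a network variant, an ordered list of exogenous drives,
#' and a free/frozen parameter mask, representing one hypothesis about the
#' drive sequence generating the frontocentral ERP.
#'
#' @param name preset name.
#' @param network "mpfc" (default column with the medial-prefrontal
#'   connectivity modifications) or "default".
#' @param drives ordered list of [drive_spec()] objects.
#' @param free character vector of free parameter names (see
#'   [preset_parameters()] for the naming scheme); all other parameters are
#'   frozen.
#' @param notes provenance/hypothesis notes (free text).
#' @return an object of class `model_preset`.
#' @export
model_preset <- function(name, network = c("mpfc", "default"), drives,
                         free = character(0), notes = "") {
  network <- match.arg(network)
  stopifnot(length(drives) >= 1,
            all(vapply(drives, inherits, logical(1), "drive_spec")))
  structure(list(name = name, network = network, drives = drives,
                 free = as.character(free), notes = notes),
            class = "model_preset")
}

#' @export
print.model_preset <- function(x, ...) {
  cat("<model_preset> ", x$name, " (", x$network, " network)\n", sep = "")
  for (d in x$drives)
    cat(sprintf("  %-4s %-8s mu=%g sigma=%g n_spikes=%d\n",
                d$name, d$pathway, d$mu, d$sigma, d$n_spikes))
  if (length(x$free)) cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

# the hand-tuned drive set reproducing the successful-Stop frontocentral
# waveform (positive P2 ~150 ms, negative N2 ~200 ms, late positive P3);
# the three drives are a thalamocortical (proximal) input at 115 ms, a
# cortico-cortical (distal) input at 190 ms, and a re-emergent
# thalamocortical (proximal) input at 306 ms carried by two spikes
successful_drives <- function() {
  list(
    drive_spec("P1", "proximal", mu = 115, sigma = 10),
    drive_spec("D1", "distal", mu = 190, sigma = 8),
    drive_spec("P2", "proximal", mu = 306, sigma = 12, n_spikes = 2,
               weights = list(
                 L2Pyr = c(AMPA = 0.15, NMDA = 0.55),
                 L5Pyr = c(AMPA = 0.15, NMDA = 0.55),
                 L2Basket = c(AMPA = 0.02, NMDA = 0.01),
                 L5Basket = c(AMPA = 0.000561, NMDA = 0.1))))
}

# replace named fields of one drive inside a drive list
modify_drive <- function(drives, name, ...) {
  mods <- list(...)
  for (i in seq_along(drives)) {
    if (drives[[i]]$name == name) {
      d <- unclass(drives[[i]])
      for (f in names(mods)) d[[f]] <- mods[[f]]
      drives[[i]] <- do.call(drive_spec, d)
      return(drives)
    }
  }
  stop("no drive named ", name)
}

#' Load a shipped model preset
#'
#' Available presets:
#' \describe{
#'   \item{successful}{Successful-Stop model: proximal drive at 115 ms,
#'     distal at 190 ms, two-spike proximal at 306 ms.}
#'   \item{failed_timing}{Failed-Stop timing-change hypothesis: the late
#'     proximal drive is delayed to 325 ms with synaptic weights identical
#'     to the successful preset; only its timing parameters are free.}
#'   \item{failed_onespike}{Alternative: the late proximal drive carries one
#'     spike instead of two.}
#'   \item{failed_strength}{Alternative: the late proximal drive keeps the
#'     successful timing (306 ms) and only its synaptic weights are free.}
#'   \item{failed_inhibition}{Alternative: somatic inhibition — the first
#'     proximal drive's weights onto L5 basket cells are raised (AMPA
#'     0.000561 to 0.001, NMDA 0.1 to 0.2); all parameters frozen.}
#'   \item{failed_inhibition_opt}{As `failed_inhibition` but with the first
#'     proximal drive's timing, SD, and weights free for optimization.}
#'   \item{distal_first}{Rejected alternative: the initial drive is distal
#'     (at 115 ms) followed by proximal at 190 ms; predicts an initial
#'     negative deflection, contrary to the observed positive P2.}
#' }
#'
#' @param name preset name.
#' @return a [model_preset()].
#' @export
load_preset <- function(name) {
  known <- c("successful", "failed_timing", "failed_onespike",
             "failed_strength", "failed_inhibition", "failed_inhibition_opt",
             "distal_first")
  if (!name %in% known)
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  drv <- successful_drives()
  switch(name,
    successful = model_preset(
      "successful", "mpfc", drv,
      notes = "hand-tuned three-drive sequence for the successful-Stop FC-ERP"),
    failed_timing = model_preset(
      "failed_timing", "mpfc", modify_drive(drv, "P2", mu = 325),
      free = c("P2.mu", "P2.sigma"),
      notes = "late proximal drive delayed to 325 ms, weights unchanged"),
    failed_onespike = model_preset(
      "failed_onespike", "mpfc", modify_drive(drv, "P2", n_spikes = 1L),
      free = c("P2.mu", "P2.sigma"),
      notes = "late proximal drive reduced from two spikes to one"),
    failed_strength = model_preset(
      "failed_strength", "mpfc", drv,
      free = c("P2.L2Pyr.AMPA", "P2.L2Pyr.NMDA",
               "P2.L5Pyr.AMPA", "P2.L5Pyr.NMDA"),
      notes = "late proximal timing fixed at 306 ms; weights free"),
    failed_inhibition = model_preset(
      "failed_inhibition", "mpfc",
      modify_drive(drv, "P1", weights = list(
        L2Pyr = c(AMPA = 0.10, NMDA = 0.40),
        L5Pyr = c(AMPA = 0.10, NMDA = 0.40),
        L2Basket = c(AMPA = 0.02, NMDA = 0.01),
        L5Basket = c(AMPA = 0.001, NMDA = 0.2))),
      notes = "first proximal drive onto L5 baskets raised (AMPA 0.001, NMDA 0.2)"),
    failed_inhibition_opt = model_preset(
      "failed_inhibition_opt", "mpfc",
      modify_drive(drv, "P1", weights = list(
        L2Pyr = c(AMPA = 0.10, NMDA = 0.40),
        L5Pyr = c(AMPA = 0.10, NMDA = 0.40),
        L2Basket = c(AMPA = 0.02, NMDA = 0.01),
        L5Basket = c(AMPA = 0.001, NMDA = 0.2))),
      free = c("P1.mu", "P1.sigma",
               "P1.L2Pyr.AMPA", "P1.L2Pyr.NMDA",
               "P1.L5Pyr.AMPA", "P1.L5Pyr.NMDA",
               "P1.L2Basket.AMPA", "P1.L2Basket.NMDA",
               "P1.L5Basket.AMPA", "P1.L5Basket.NMDA"),
      notes = "somatic-inhibition start with first proximal drive fully free"),
    distal_first = model_preset(
      "distal_first", "mpfc",
      list(drive_spec("D0", "distal", mu = 115, sigma = 10),
           drive_spec("P1", "proximal", mu = 190, sigma = 8),
           drive_spec("P2", "proximal", mu = 306, sigma = 12, n_spikes = 2,
                      weights = list(
                        L2Pyr = c(AMPA = 0.15, NMDA = 0.55),
                        L5Pyr = c(AMPA = 0.15, NMDA = 0.55),
                        L2Basket = c(AMPA = 0.02, NMDA = 0.01),
                        L5Basket = c(AMPA = 0.000561, NMDA = 0.1)))),
      notes = "initial drive distal instead of proximal; rejected qualitatively"))
}

#' Build the network a preset specifies
#'
#' @param preset a [model_preset()].
#' @param config a [sim_config()].
#' @param n_pyramidal pyramidal cells per layer.
#' @return a `stop_network`, with the medial-prefrontal modifications
#'   applied when the preset requests the "mpfc" variant.
#' @export
build_preset_network <- function(preset, config = sim_config(),
                                 n_pyramidal = 100L) {
  net <- build_default_network(config, n_pyramidal)
  if (preset$network == "mpfc") net <- apply_mpfc_modifications(net)
  net
}

#' Simulate a preset's trial ensemble
#'
#' @param preset a [model_preset()].
#' @param config a [sim_config()].
#' @param n_pyramidal pyramidal cells per layer (reduce for fast fits).
#' @param keep_spikes keep per-trial spike rasters.
#' @return the [simulate_ensemble()] result.
#' @export
simulate_preset <- function(preset, config = sim_config(),
                            n_pyramidal = 100L, keep_spikes = FALSE) {
  net <- build_preset_network(preset, config, n_pyramidal)
  simulate_ensemble(net, preset$drives, config, keep_spikes = keep_spikes)
}

#' Serialize a preset to JSON
#'
#' @param preset a [model_preset()].
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
preset_to_json <- function(preset, path = NULL) {
  obj <- list(
    name = preset$name, network = preset$network, free = preset$free,
    notes = preset$notes,
    drives = lapply(preset$drives, function(d)
      list(name = d$name, pathway = d$pathway, mu = d$mu, sigma = d$sigma,
           n_spikes = d$n_spikes, delay = d$delay,
           weights = lapply(d$weights, as.list))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Load a preset from JSON
#'
#' Inverse of [preset_to_json()]: every field round-trips exactly.
#'
#' @param json JSON string or path to a JSON file.
#' @return a [model_preset()].
#' @export
preset_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  drives <- lapply(obj$drives, function(d)
    drive_spec(d$name, d$pathway, mu = d$mu, sigma = d$sigma,
               n_spikes = d$n_spikes, delay = d$delay,
               weights = lapply(d$weights, function(w)
                 unlist(lapply(w, as.numeric)))))
  model_preset(obj$name, obj$network, drives,
               free = unlist(obj$free) %||% character(0),
               notes = obj$notes %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
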