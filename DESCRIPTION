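Package: stopcolumn
Title: Biophysical Cortical-Column Modeling of Frontocentral ERPs in the Stop-Signal Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the frontocentral event-related potential (P2/N2/P3 complex)
    observed after Stop-Signals in the Stop-Signal task with a reduced laminar
    neocortical-column model driven by timed proximal (thalamocortical) and distal
    (cortico-cortical) exogenous inputs. Provides the net current-dipole forward
    simulation, RMSE-based model fitting with bound-constrained derivative-free
    optimization and stage-wise parameter freezing, named presets for competing
    hypotheses about successful versus failed stopping, resampling-based P3 onset
    statistics with Benjamini-Hochberg correction, frontocentral independent-component
    selection, and a synthetic sensor-level EEG generator with ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
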