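# shared small-scale fixtures so unit tests stay fast; acceptance-scale
# runs live in test-acceptance.R

small_cfg <- function(seed = 1L, n_trials = 1L, ...)
  sim_config(seed = seed, n_trials = n_trials, ...)

small_net <- function(cfg = small_cfg(), n_pyramidal = 6L, mpfc = TRUE) {
  net <- build_default_network(cfg, n_pyramidal = n_pyramidal)
  if (mpfc) net <- apply_mpfc_modifications(net)
  net
}

# network with all inhibition removed, for sign-convention checks
no_inhib <- function(net) {
  net$connectivity$weight[net$connectivity$receptor %in%
                            c("GABAa", "GABAb")] <- 0
  net
}

extremum <- function(x) x[which.max(abs(x))]
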