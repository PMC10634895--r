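test_that("sim_config validates its fields", {
  cfg <- sim_config()
  expect_equal(cfg$dt, 0.025)
  expect_equal(cfg$scaling, 150)
  expect_equal(cfg$smooth_window_ms, 30)
  expect_equal(cfg$n_trials, 50L)
  expect_error(sim_config(dt = 0.1), "dt")
})

test_that("default network has 100 pyramidal cells per layer at a 3:1 ratio", {
  net <- build_default_network(sim_config())
  expect_equal(net$n_l2pyr, 100L)
  expect_equal(net$n_l5pyr, 100L)
  expect_equal(round(net$n_l2pyr / net$n_l2basket), 3)
  expect_equal(round(net$n_l5pyr / net$n_l5basket), 3)
  expect_error(build_default_network(sim_config(), n_pyramidal = 0),
               "positive")
})

test_that("L5 apical dendrites are longer than L2/3", {
  net <- build_default_network(sim_config())
  expect_gt(sum(net$seg_len[2, 2:3]), sum(net$seg_len[1, 2:3]))
})

test_that("mpfc factor table lists exactly the eight modified connections", {
  f <- mpfc_factors()
  expect_equal(nrow(f), 8L)
  expect_true(all(f$factor != 1))
  key <- paste(f$src, f$target, f$receptor)
  expect_setequal(key, c(
    "L2Pyr L2Pyr NMDA", "L5Pyr L5Pyr NMDA", "L2Pyr L2Pyr AMPA",
    "L2Pyr L5Pyr AMPA", "L5Pyr L5Pyr AMPA", "L2Basket L2Pyr GABAa",
    "L2Basket L2Pyr GABAb", "L5Basket L5Pyr GABAb"))
  expect_equal(f$factor[key == "L2Pyr L2Pyr NMDA"], 1.5)
  expect_equal(f$factor[key == "L2Pyr L5Pyr AMPA"], 2.0)
  expect_equal(f$factor[key == "L2Basket L2Pyr GABAa"], 2.0)
  expect_equal(f$factor[key == "L5Basket L5Pyr GABAb"], 3.0)
})

test_that("apply_mpfc_modifications scales listed weights and nothing else", {
  base <- build_default_network(sim_config())
  mod <- apply_mpfc_modifications(base)
  pick <- function(net, src, tgt, rec) {
    con <- net$connectivity
    con$weight[con$src == src & con$target == tgt & con$receptor == rec]
  }
  expect_equal(pick(mod, "L2Pyr", "L2Pyr", "NMDA"),
               1.5 * pick(base, "L2Pyr", "L2Pyr", "NMDA"))
  expect_equal(pick(mod, "L5Basket", "L5Pyr", "GABAb"),
               3 * pick(base, "L5Basket", "L5Pyr", "GABAb"))
  # an unlisted connection is unchanged
  expect_equal(pick(mod, "L2Pyr", "L2Basket", "AMPA"),
               pick(base, "L2Pyr", "L2Basket", "AMPA"))
  expect_true(mod$mpfc_applied)
  expect_error(apply_mpfc_modifications(mod), "twice|already")
})

test_that("realize_drive_times draws clipped Gaussian spike times", {
  cfg <- small_cfg()
  d0 <- drive_spec("P", "proximal", mu = 115, sigma = 0)
  expect_equal(realize_drive_times(d0, cfg, trial_seed = 1), 115)
  expect_equal(realize_drive_times(d0, cfg, trial_seed = 99), 115)
  d <- drive_spec("P", "proximal", mu = 306, sigma = 12, n_spikes = 2)
  t1 <- realize_drive_times(d, cfg, trial_seed = 5)
  expect_length(t1, 2)
  expect_identical(t1, realize_drive_times(d, cfg, trial_seed = 5))
  # law of large numbers on the mean of many draws
  dm <- drive_spec("P", "proximal", mu = 115, sigma = 10, n_spikes = 1)
  many <- vapply(seq_len(10000), function(s)
    realize_drive_times(dm, cfg, trial_seed = s), 0)
  expect_lt(abs(mean(many) - 115), 3 * 10 / sqrt(10000) + 0.1)
  # early draws are clipped to the simulation start
  dl <- drive_spec("P", "proximal", mu = -500, sigma = 1)
  expect_equal(realize_drive_times(dl, cfg, trial_seed = 1),
               cfg$tmin + cfg$dt)
})

test_that("drive_spec validates pathway targets", {
  expect_error(drive_spec("D", "distal", mu = 100, weights = list(
    L5Basket = c(AMPA = 0.1))), "distal")
  expect_error(drive_spec("P", "proximal", mu = 100, sigma = -1))
})

test_that("compute_dipole follows the axial-current hand computation", {
  # equal potentials -> no axial current
  expect_equal(compute_dipole(c(-65, -65, -65, -65), rep(0.3, 3),
                              c(150, 200, 200)), 0)
  # toy two-compartment cell: soma -60, tuft -70, conductance g, length l
  g <- 0.3; l <- 200
  v <- c(-60, -60, -70, -70)
  expect_equal(compute_dipole(v, c(0, g, 0), c(0, l, 0)), g * 10 * l)
})

test_that("quiescent network produces a flat dipole", {
  cfg <- small_cfg()
  tr <- simulate_trial(small_net(cfg), list(), cfg, trial_seed = 3)
  settled <- tr$dipole$time_ms > cfg$tmin + 20
  # quiescence relative to a driven response scale
  drv <- drive_spec("P", "proximal", mu = 50, sigma = 0)
  trd <- simulate_trial(small_net(cfg), list(drv), cfg, trial_seed = 3)
  expect_lt(max(abs(tr$dipole$net[settled])),
            1e-3 * max(abs(trd$dipole$net)))
})

test_that("sign conventions: proximal positive, distal negative", {
  cfg <- small_cfg()
  net <- no_inhib(small_net(cfg))
  prox <- drive_spec("P", "proximal", mu = 50, sigma = 0)
  dist <- drive_spec("D", "distal", mu = 50, sigma = 0)
  win <- function(tr) tr$dipole$net[tr$dipole$time_ms >= 50 &
                                    tr$dipole$time_ms <= 100]
  expect_gt(extremum(win(simulate_trial(net, list(prox), cfg, 3))), 0)
  expect_lt(extremum(win(simulate_trial(net, list(dist), cfg, 3))), 0)
})

test_that("somatic inhibition produces a negative-going deflection", {
  # drive only the basket cells: their GABAa synapses at the pyramidal
  # somas pull current down the apical shaft
  cfg <- small_cfg()
  net <- small_net(cfg)
  binh <- drive_spec("B", "proximal", mu = 50, sigma = 0, weights = list(
    L2Basket = c(AMPA = 0.5, NMDA = 0.1),
    L5Basket = c(AMPA = 0.5, NMDA = 0.1)))
  tr <- simulate_trial(net, list(binh), cfg, trial_seed = 3)
  w <- tr$dipole$net[tr$dipole$time_ms >= 50 & tr$dipole$time_ms <= 110]
  expect_lt(extremum(w), 0)
})

test_that("net dipole equals the sum of the layer contributions", {
  cfg <- small_cfg()
  drv <- drive_spec("P", "proximal", mu = 50, sigma = 0)
  tr <- simulate_trial(small_net(cfg), list(drv), cfg, trial_seed = 3)
  expect_equal(tr$dipole$net, tr$dipole$L23 + tr$dipole$L5)
})

test_that("identical seeds give bit-identical trials", {
  cfg <- small_cfg()
  drv <- drive_spec("P", "proximal", mu = 50, sigma = 5)
  a <- simulate_trial(small_net(cfg), list(drv), cfg, trial_seed = 11)
  b <- simulate_trial(small_net(cfg), list(drv), cfg, trial_seed = 11)
  expect_identical(a$dipole, b$dipole)
  expect_identical(a$spikes, b$spikes)
})

test_that("numerical divergence raises an error naming the cell", {
  cfg <- small_cfg()
  net <- small_net(cfg)
  # two coincident spikes at weight 1e308 overflow the conductance to Inf,
  # which makes the membrane update non-finite
  bomb <- drive_spec("P", "proximal", mu = 50, sigma = 0, n_spikes = 2,
                     weights = list(L2Pyr = c(AMPA = 1e308, NMDA = 0)))
  expect_error(simulate_trial(net, list(bomb), cfg, trial_seed = 1),
               "cell|L2|L5")
})

test_that("postprocess_dipole scales and smooths as specified", {
  # constant trace: unit-sum kernel preserves constants, then scaling
  x <- rep(2, 400)
  expect_equal(postprocess_dipole(x, scaling = 150, window_ms = 30,
                                  dt = 0.5), rep(300, 400))
  # window 0 -> scaling only
  y <- sin(seq_len(100))
  expect_equal(postprocess_dipole(y, scaling = 3, window_ms = 0, dt = 0.5),
               3 * y)
  # unit impulse -> the normalized Hamming kernel appears around the impulse
  z <- numeric(201); z[101] <- 1
  k <- postprocess_dipole(z, scaling = 1, window_ms = 30, dt = 1)
  h <- signal::hamming(31); h <- h / sum(h)
  expect_equal(k[86:116], as.numeric(h), tolerance = 1e-10)
  # scaling linearity
  expect_equal(postprocess_dipole(y, 5, 10, dt = 0.5),
               5 * postprocess_dipole(y, 1, 10, dt = 0.5))
  expect_error(postprocess_dipole(y[1:5], 1, 30, dt = 0.5), "window")
})

test_that("simulate_ensemble derives per-trial seeds from the master seed", {
  cfg <- small_cfg(seed = 4, n_trials = 3)
  drv <- drive_spec("P", "proximal", mu = 50, sigma = 5)
  net <- small_net(cfg)
  a <- simulate_ensemble(net, list(drv), cfg)
  b <- simulate_ensemble(net, list(drv), cfg)
  expect_identical(a, b)
  # n_trials = 1: mean equals the single trial
  cfg1 <- small_cfg(seed = 4, n_trials = 1)
  e1 <- simulate_ensemble(net, list(drv), cfg1)
  expect_equal(e1$mean$net, as.numeric(e1$trials[1, ]))
  # different master seed -> different draws
  cfg2 <- small_cfg(seed = 5, n_trials = 3)
  expect_false(identical(simulate_ensemble(net, list(drv), cfg2)$trials,
                         a$trials))
})

test_that("derive_seeds is a deterministic counter scheme", {
  expect_identical(derive_seeds(42, 5), derive_seeds(42, 5))
  expect_false(identical(derive_seeds(42, 5), derive_seeds(43, 5)))
  expect_length(derive_seeds(1, 10), 10)
  # does not disturb the caller's RNG stream
  set.seed(9); x <- runif(1)
  set.seed(9); invisible(derive_seeds(1, 3)); y <- runif(1)
  expect_identical(x, y)
})

test_that("halving dt changes a fixed-seed trial by less than 2% RMS", {
  cfg <- small_cfg()
  cfgh <- small_cfg(dt = 0.0125)
  net <- no_inhib(small_net(cfg))
  drv <- drive_spec("P", "proximal", mu = 50, sigma = 0)
  a <- postprocess_dipole(simulate_trial(net, list(drv), cfg, 7)$dipole)
  b <- postprocess_dipole(simulate_trial(net, list(drv), cfgh, 7)$dipole)
  bn <- approx(b$time_ms, b$net, xout = a$time_ms)$y
  expect_lt(sqrt(mean((a$net - bn)^2)) / sqrt(mean(a$net^2)), 0.02)
})
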