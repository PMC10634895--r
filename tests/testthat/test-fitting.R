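test_that("rmse closed-form identities hold", {
  t <- seq(-100, 500, 2)
  a <- sin(t / 40)
  expect_equal(rmse(t, a, t, a), 0)
  expect_equal(rmse(t, a, t, a + 3), 3)          # constant offset -> |c|
  expect_equal(rmse(t, a, t, a - 3), 3)
  expect_equal(rmse(t, a, t, a + 3), rmse(t, a + 3, t, a))  # symmetric
  # resampling onto the 2 ms grid: a finer simulated axis is accepted
  tf <- seq(-100, 500, 0.5)
  expect_lt(rmse(tf, sin(tf / 40), t, a), 1e-3)
  expect_error(rmse(t, a, t + 10000, a), "overlap")
})

test_that("parameter tables carry the bounded-change contract", {
  p <- load_preset("successful")
  tab <- preset_parameters(p, free = c("P2.mu", "P2.L5Pyr.AMPA"))
  expect_true(all(c("P1.mu", "P1.sigma", "P2.L5Pyr.AMPA") %in% tab$name))
  w <- tab[tab$name == "P2.L5Pyr.AMPA", ]
  expect_equal(w$lower, 0)
  expect_equal(w$upper, 4 * w$value)  # change bounded at 300% of start
  expect_false(w$frozen)
  expect_true(tab$frozen[tab$name == "P1.mu"])
  expect_error(preset_parameters(p, free = "bogus.name"), "unknown")
})

test_that("set_preset_parameters writes values back into drives", {
  p <- load_preset("successful")
  q <- set_preset_parameters(p, c(P2.mu = 325, P1.L5Basket.AMPA = 0.001))
  d <- q$drives[[which(vapply(q$drives, `[[`, "", "name") == "P2")]]
  expect_equal(d$mu, 325)
  d1 <- q$drives[[1]]
  expect_equal(unname(d1$weights$L5Basket[["AMPA"]]), 0.001)
  expect_error(set_preset_parameters(p, c(P9.mu = 1)), "no drive")
})

test_that("optimizer solves bounded toy problems and honors freezing", {
  # 1-D convex
  pars <- data.frame(name = "x", value = 0, lower = 0, upper = 4,
                     kind = "timing", frozen = FALSE)
  fit <- optimize_params(function(v) (v[["x"]] - 2)^2, pars, budget = 100)
  expect_lt(abs(fit$params$value - 2), 1e-2)
  # 2-D
  pars2 <- data.frame(name = c("x", "y"), value = c(0, 0),
                      lower = c(0, -5), upper = c(4, 5),
                      kind = "timing", frozen = c(FALSE, FALSE))
  fit2 <- optimize_params(function(v) (v[["x"]] - 2)^2 + (v[["y"]] + 1)^2,
                          pars2, budget = 300)
  expect_lt(max(abs(fit2$params$value - c(2, -1))), 1e-2)
  # frozen entries are identical in input and output, and never passed
  # outside their fixed value
  pars3 <- pars2; pars3$frozen <- c(TRUE, FALSE)
  seen <- new.env(); seen$x <- numeric(0)
  fit3 <- optimize_params(function(v) {
    seen$x <- c(seen$x, v[["x"]]); (v[["y"]] + 1)^2
  }, pars3, budget = 100)
  expect_equal(fit3$params$value[1], 0)
  expect_true(all(seen$x == 0))
  # best-so-far trace is non-increasing
  expect_true(all(diff(fit2$trace) <= 0))
  expect_lte(fit2$n_eval, 300)
})

test_that("optimizer never evaluates outside bounds (fuzz)", {
  for (s in 1:5) {
    set.seed(s)
    lo <- runif(3, -5, 0); hi <- lo + runif(3, 1, 5)
    pars <- data.frame(name = c("a", "b", "c"),
                       value = runif(3, lo, hi), lower = lo, upper = hi,
                       kind = "weight", frozen = FALSE)
    ok <- new.env(); ok$all <- TRUE
    tgt <- runif(3, lo, hi)
    invisible(optimize_params(function(v) {
      ok$all <- ok$all && all(v >= lo - 1e-12) && all(v <= hi + 1e-12)
      sum((v - tgt)^2)
    }, pars, budget = 150))
    expect_true(ok$all)
  }
})

test_that("objective failures are absorbed as +Inf evaluations", {
  pars <- data.frame(name = c("x", "y"), value = c(3.5, 0),
                     lower = c(0, -5), upper = c(4, 5),
                     kind = "timing", frozen = FALSE)
  fit <- optimize_params(function(v) {
    if (v[["x"]] > 3) stop("numerical failure")
    (v[["x"]] - 2)^2 + v[["y"]]^2
  }, pars, budget = 200)
  expect_true(is.finite(fit$value))
  expect_lt(abs(fit$params$value[1] - 2), 0.3)
})

test_that("staged_fit warm-starts stages and rejects empty stage lists", {
  p <- load_preset("successful")
  cfg <- small_cfg(seed = 31, n_trials = 1)
  tgt <- generate_simulator_target(p, cfg, n_pyramidal = 4)
  expect_error(staged_fit(p, tgt$time_ms, tgt$target, list(), cfg,
                          n_pyramidal = 4), "stage")
  fits <- staged_fit(p, tgt$time_ms, tgt$target,
                     stages = list(character(0),
                                   list(free = "P2.mu", budget = 5)),
                     config = cfg, n_pyramidal = 4)
  # all-frozen stage evaluates the preset once without changing it
  expect_equal(fits[[1]]$n_eval, 1L)
  expect_equal(fits[[1]]$params$value,
               preset_parameters(p, character(0))$value)
  # warm start: stage 2's first evaluation equals stage 1's final loss
  expect_equal(fits[[2]]$trace[1], fits[[1]]$value)
  # self-target at the generating seed: initial RMSE is exactly zero
  expect_equal(fits[[1]]$value, 0)
})
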