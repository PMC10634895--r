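tm <- seq(-100, 500, by = 2)

test_that("epoch_set validates and subsets by condition", {
  x <- matrix(0, 4, length(tm))
  ep <- epoch_set(x, tm, rep(c("successful_stop", "failed_stop"), 2))
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$data), c(4, length(tm), 1))
  sub <- epochs_by_condition(ep, "failed_stop")
  expect_equal(dim(sub$data)[1], 2)
  expect_error(epochs_by_condition(ep, "nope"), "condition")
  expect_error(epoch_set(x, tm[-1], rep("a", 4)))
})

test_that("baseline_correct subtracts the pre-signal mean per trial", {
  x <- matrix(0, 3, length(tm))
  x[1, ] <- 5                      # constant trial -> all zeros
  x[2, ] <- 0                      # already zero-mean baseline -> unchanged
  s <- sin(tm / 50)
  x[3, ] <- 2 + ifelse(tm > 0, s, 0)  # c on baseline, c + s(t) after
  bc <- baseline_correct(epoch_set(x, tm, rep("successful_stop", 3)))
  expect_equal(bc$data[1, , 1], rep(0, length(tm)))
  expect_equal(bc$data[2, , 1], rep(0, length(tm)))
  expect_equal(bc$data[3, tm > 0, 1], s[tm > 0])
  # missing baseline -> error
  late <- epoch_set(matrix(0, 2, sum(tm >= 0)), tm[tm >= 0], rep("a", 2))
  expect_error(baseline_correct(late), "baseline")
})

test_that("quantify_peaks finds the windowed extrema with earliest-tie rule", {
  trace <- 5 * exp(-(tm - 150)^2 / 200) - 4 * exp(-(tm - 200)^2 / 200) +
    8 * exp(-(tm - 300)^2 / 800)
  pk <- quantify_peaks(trace, tm)
  expect_equal(pk$p2$latency, 150)
  expect_equal(pk$n2$latency, 200)
  expect_equal(pk$p3$latency, 300)
  # flat zero trace: amplitudes 0, latencies at window starts
  pk0 <- quantify_peaks(rep(0, length(tm)), tm)
  expect_equal(pk0$p2$amplitude, 0)
  expect_equal(pk0$p2$latency, 100)
  expect_equal(pk0$n2$latency, 150)
  expect_equal(pk0$p3$latency, 0)
  # N2 search stays within 150-250 even if a deeper minimum lies outside
  tr2 <- -10 * exp(-(tm - 400)^2 / 200) - 4 * exp(-(tm - 200)^2 / 200)
  expect_equal(quantify_peaks(tr2, tm)$n2$latency, 200)
  expect_error(quantify_peaks(trace[1:3], tm[1:3]), "window")
  # invariance to baseline offsets after correction
  ep <- epoch_set(matrix(trace + 7, 2, length(tm), byrow = TRUE), tm,
                  rep("successful_stop", 2))
  avg <- colMeans(baseline_correct(ep)$data[, , 1])
  pk2 <- quantify_peaks(avg, tm)
  expect_equal(pk2$p2$latency, pk$p2$latency)
  expect_equal(pk2$p3$latency, pk$p3$latency)
})

test_that("bootstrap_t_pvalues behaves at the null and under separation", {
  set.seed(1)
  base <- matrix(rnorm(20 * length(tm)), 20)
  # stop pool identical to go pool -> p = 1 everywhere (t = 0 observed)
  p_null <- bootstrap_t_pvalues(base, base, n_resamples = 100, seed = 2)
  expect_true(all(p_null > 0.9))
  # large constant separation from 224 ms onward
  sep <- base; sep[, tm >= 224] <- sep[, tm >= 224] + 50
  p_sep <- bootstrap_t_pvalues(sep, base, n_resamples = 500, seed = 2)
  expect_true(all(p_sep[tm >= 226] < 0.005))
  expect_true(mean(p_sep[tm < 224] < 0.05) < 0.2)
  # p-values are add-one smoothed, never exactly zero
  expect_true(all(p_sep >= 1 / 501))
  # zero variance in both pools -> p = 1
  z <- matrix(1, 5, 3)
  expect_equal(bootstrap_t_pvalues(z, z, n_resamples = 50, seed = 1),
               rep(1, 3))
  # reproducible by seed
  expect_identical(p_sep, bootstrap_t_pvalues(sep, base, 500, seed = 2))
})

test_that("bh_correct implements the Benjamini-Hochberg step-up rule", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.20), 0.05),
               c(TRUE, TRUE, FALSE))
  expect_true(all(bh_correct(rep(0.001, 10), 0.05)))
  expect_false(any(bh_correct(rep(1, 10), 0.05)))
  expect_length(bh_correct(numeric(0)), 0)
  # order invariance
  p <- c(0.001, 0.04, 0.3, 0.012, 0.9)
  ord <- sample(length(p))
  expect_equal(bh_correct(p)[ord], bh_correct(p[ord]))
  # agrees with stats::p.adjust
  expect_equal(bh_correct(p, 0.05), p.adjust(p, "BH") <= 0.05)
})

test_that("p3_onset recovers an injected divergence and handles no-signal", {
  set.seed(3)
  go <- matrix(rnorm(40 * length(tm)), 40)
  stopm <- matrix(rnorm(40 * length(tm)), 40)
  stopm[, tm >= 224] <- stopm[, tm >= 224] + 6
  on <- p3_onset(stopm, go, tm, p3_peak_latency = 300,
                 n_resamples = 500, seed = 4)
  expect_lte(abs(on - 224), 2)
  expect_lt(on, 300)
  # no significant timepoints -> undefined
  expect_true(is.na(p3_onset(go, go, tm, 300, n_resamples = 100, seed = 4)))
  # the alternative first-significant reading is exposed
  on2 <- p3_onset(stopm, go, tm, 300, n_resamples = 500, seed = 4,
                  rule = "first-significant")
  expect_lte(on2, on)
})

test_that("p3_onset false-positive rate is controlled at the null", {
  hits <- vapply(1:12, function(s) {
    set.seed(s)
    a <- matrix(rnorm(20 * 100), 20)
    b <- matrix(rnorm(20 * 100), 20)
    !is.na(p3_onset(a, b, seq(0, 198, 2), 150, n_resamples = 200, seed = s))
  }, TRUE)
  expect_lte(mean(hits), 0.25)  # alpha = 0.05 + Monte-Carlo margin
})
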