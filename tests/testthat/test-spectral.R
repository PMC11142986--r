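test_that("epoch_power matches the direct-DFT oracle and basic spectra", {
  rate <- 1000; t <- (0:1999) / rate
  x <- sin(2 * pi * 10 * t)
  ps <- epoch_power(matrix(x, 1), rate)
  expect_equal(ps$freqs[which.max(ps$power)], 10)
  bp <- band_power(ps, c(8, 13))
  expect_equal(bp, oracle_band_power(x, rate, c(8, 13)), tolerance = 1e-9)
  # random epoch too
  set.seed(4)
  y <- rnorm(2000)
  expect_equal(band_power(epoch_power(matrix(y, 1), rate), c(4, 6)),
               oracle_band_power(y, rate, c(4, 6)), tolerance = 1e-9)
  # all-zero epoch -> all-zero spectrum
  expect_true(all(epoch_power(matrix(0, 1, 2000), rate)$power == 0))
  expect_error(epoch_power(matrix(0, 1, 300), rate), "longer than epoch")
})

test_that("white noise has equal expected power in equal-width bands", {
  set.seed(5)
  x <- rnorm(200000)
  ps <- epoch_power(matrix(x, 1), 1000)
  b1 <- band_power(ps, c(5, 10)); b2 <- band_power(ps, c(20, 25))
  expect_equal(b1 / b2, 1, tolerance = 0.05)
})

test_that("band_power is the inclusive-bin mean (loop oracle)", {
  ps <- structure(list(freqs = seq(2, 30, by = 0.125),
                       power = matrix(seq_len(225), 1), n_windows = 1),
                  class = "power_spectrum")
  expect_equal(band_power(ps, c(2, 30)), mean(seq_len(225)))
  # one-bin band
  expect_equal(band_power(ps, c(4, 4)), ps$power[1, which(ps$freqs == 4)])
  # loop oracle on theta
  sel <- which(ps$freqs >= 4 & ps$freqs <= 6)
  acc <- 0
  for (j in sel) acc <- acc + ps$power[1, j]
  expect_equal(band_power(ps, c(4, 6)), acc / length(sel))
  expect_error(band_power(ps, c(1, 5)), "outside")
})

test_that("the batch band-power path equals epoch_power + band_power exactly", {
  set.seed(6)
  ep <- array(rnorm(4 * 3 * 2000), dim = c(4, 3, 2000))
  es <- structure(list(epochs = ep, rate = 1000,
                       channel_labels = c("a", "b", "c")), class = "epoch_set")
  bands <- list(theta = c(4, 6), alpha = c(8, 13))
  got <- coregload:::epoch_set_band_power(es, bands)
  for (k in 1:4) for (ch in 1:3) for (bn in names(bands)) {
    ref <- band_power(epoch_power(ep[k, , ], 1000), bands[[bn]])[ch]
    expect_equal(got[k, ch, bn], ref, tolerance = 1e-12)
  }
})

test_that("erd_ers arithmetic, normalization and invariances", {
  # identity
  e <- erd_ers(matrix(rep(10, 8), ncol = 1), rep(c("A", "B", "C", "D"), 2))
  expect_true(all(e$values == 0))
  # two conditions: P = (8, 12) -> (-20, +20)
  e <- erd_ers(matrix(c(8, 12), ncol = 1), c("A", "B"))
  expect_equal(as.vector(e$values), c(-20, 20))
  # normalization identity: mean over conditions of (1 + v/100) = 1, exact
  set.seed(7)
  for (i in 1:25) {
    n_cond <- sample(2:5, 1)
    labels <- rep(letters[1:n_cond], times = sample(2:6, n_cond, replace = TRUE))
    bp <- matrix(rexp(length(labels) * 3), ncol = 3)
    e <- erd_ers(bp, labels)
    expect_equal(colMeans(1 + e$values / 100), rep(1, 3), tolerance = 1e-12)
    # scale invariance: percent change is scale-free
    e2 <- erd_ers(bp * 37.5, labels)
    expect_equal(e2$values, e$values, tolerance = 1e-9)
  }
  # a condition with zero kept epochs raises the dedicated condition class
  expect_error(erd_ers(matrix(1:4, ncol = 1), rep("A", 4),
                       conditions = c("A", "B")),
               class = "coregload_no_epochs")
})

test_that("pupil_summary: constants, load ordering, all-blink error", {
  ci <- data.frame(start = c(1, 501), end = c(500, 1000),
                   condition = c("low", "high"))
  es <- structure(list(keep = c(TRUE, TRUE), anchor_sample = c(1, 501),
                       condition = c("low", "high"), length_s = 2),
                  class = "epoch_set")
  p <- rep(4, 1000)
  out <- pupil_summary(p, 250, ci, epochs = es)
  expect_equal(unname(out), c(4, 4))
  # load-dependent offset shows up with the right sign
  p2 <- c(rep(4, 500), rep(4.3, 500))
  out2 <- pupil_summary(p2, 250, ci, epochs = es)
  expect_gt(out2[["high"]], out2[["low"]])
  # fixation-related route
  fx <- data.frame(onset = c(10, 600), offset = c(100, 700),
                   aoi = c("picture", "picture"))
  out3 <- pupil_summary(p2, 250, ci, fixations = fx)
  expect_equal(unname(out3), c(4, 4.3))
  # condition whose pupil is entirely dropout -> error
  p3 <- c(rep(0, 500), rep(4, 500))
  expect_error(pupil_summary(p3, 250, ci, epochs = es), "no valid pupil")
})

test_that("expected_band_power reflects multipliers and topographies", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("theta", "alpha")))
  m["A", "alpha"] <- 0.8
  cfg <- sim_config(seed = 1, conditions = c("A", "B"),
                    condition_power_multipliers = m)
  tbp <- expected_band_power(cfg)
  # theta at Fz near-identical across conditions (only window leakage from
  # the manipulated alpha carrier differs), alpha lower in A at Pz
  expect_equal(tbp["A", "theta", "Fz"], tbp["B", "theta", "Fz"],
               tolerance = 1e-3)
  expect_lt(tbp["A", "alpha", "Pz"], tbp["B", "alpha", "Pz"])
  # the implied ERD has the analytic two-condition structure
  erd <- expected_erd(cfg, "Pz", "alpha", avg_ref = FALSE)
  expect_equal(sum(1 + erd / 100), 2, tolerance = 1e-12)
  expect_lt(erd[["A"]], 0)
})
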