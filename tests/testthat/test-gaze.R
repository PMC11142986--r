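test_that("interpolate_blinks: identity, constant fill, padding, idempotence", {
  # no sentinel samples: identity, empty blink list
  p <- c(4, 4.1, 4.2, 4.1)
  out <- interpolate_blinks(p, 250)
  expect_identical(out$pupil, p)
  expect_equal(nrow(out$blinks), 0)
  # 100 ms sentinel run inside a constant 5.0 trace -> filled with 5.0
  p <- rep(5, 250)
  p[100:124] <- 0
  out <- interpolate_blinks(p, 250, pad_ms = 50)
  expect_true(all(out$pupil == 5))
  expect_equal(out$blinks$onset, 100)
  expect_equal(out$blinks$offset, 125)
  # all-sentinel channel errors
  expect_error(interpolate_blinks(rep(0, 10), 250), "entirely dropout")
  # samples outside the padded runs are bit-identical; idempotent
  set.seed(1)
  p <- 4 + cumsum(rnorm(1000, sd = 0.01))
  p[300:340] <- 0
  out <- interpolate_blinks(p, 250, pad_ms = 50)
  pad <- round(50 / 1000 * 250)
  untouched <- setdiff(seq_along(p), (300 - pad):(340 + pad))
  expect_identical(out$pupil[untouched], p[untouched])
  again <- interpolate_blinks(out$pupil, 250, pad_ms = 50)
  expect_identical(again$pupil, out$pupil)
  expect_equal(nrow(again$blinks), 0)
})

test_that("blink recovery matches simulator ground truth", {
  cfg <- quick_sim_config(seed = 5)
  sim <- simulate_session(cfg)
  out <- interpolate_blinks(sim$et$data["pupil_L", ], 250, pad_ms = 50)
  tb <- sim$truth$true_blinks
  expect_equal(nrow(out$blinks), nrow(tb))
  # onsets within pad_ms (50 ms = 12.5 ET samples)
  expect_true(all(abs(out$blinks$onset - tb$onset) <= 13))
})

test_that("detect_saccades: flat trace, constructed step, reference loop", {
  expect_equal(nrow(suppressMessages(
    detect_saccades(rep(1, 500), rep(1, 500), 250))), 0)
  # one 10-degree step with a smooth ramp inside 1 s of jittered fixation
  set.seed(8)
  rate <- 250
  x <- 100 + runif(250, -1.5, 1.5); y <- 100 + runif(250, -1.5, 1.5)
  ramp_idx <- 120:129  # 40 ms
  u <- seq(0, 1, length.out = 10)
  x[ramp_idx] <- 100 + 453 * (u - sin(2 * pi * u) / (2 * pi))
  x[130:250] <- x[130:250] + 453
  sac <- detect_saccades(x, y, rate)
  expect_equal(nrow(sac), 1)
  expect_true(sac$onset <= 121 && sac$offset >= 128)
  expect_gt(sac$amplitude, 400)
  # brute-force velocity thresholding agrees on the saccadic span
  vx <- coregload:::ek_velocity(x, rate, 5)
  vy <- coregload:::ek_velocity(y, rate, 5)
  sig <- function(v) sqrt(median(v[!is.na(v)]^2) - median(v[!is.na(v)])^2)
  over <- which((vx / (6 * sig(vx)))^2 + (vy / (6 * sig(vy)))^2 > 1)
  expect_equal(sac$onset, min(over))
  expect_equal(sac$offset, max(over) + 1)
})

test_that("detect_saccades is scale-equivariant (exact)", {
  cfg <- quick_sim_config(seed = 6)
  sim <- simulate_session(cfg)
  gx <- sim$et$data["gaze_x", ]; gy <- sim$et$data["gaze_y", ]
  mask <- gx == 0 & gy == 0
  s1 <- detect_saccades(gx, gy, 250, mask = mask)
  s2 <- detect_saccades(3.7 * gx, 3.7 * gy, 250, mask = mask)
  expect_identical(s1$onset, s2$onset)
  expect_identical(s1$offset, s2$offset)
})

test_that("simulated saccades >= 1 degree are recovered (>=95%, onset <= 8 ms)", {
  cfg <- quick_sim_config(seed = 7)
  sim <- simulate_session(cfg)
  gx <- sim$et$data["gaze_x", ]; gy <- sim$et$data["gaze_y", ]
  mask <- gx == 0 & gy == 0
  sac <- detect_saccades(gx, gy, 250, mask = mask)
  ts <- sim$truth$true_saccades
  big <- ts[ts$amplitude_deg >= 1, ]
  matched <- vapply(big$onset, function(o)
    any(abs(sac$onset - o) <= 2), logical(1))  # 2 ET samples = 8 ms
  expect_gte(mean(matched), 0.95)
})

test_that("derive_fixations covers the complement and validates overlap", {
  none <- data.frame(onset = numeric(0), offset = numeric(0))
  fx <- derive_fixations(none, none, 250, c(1, 251))
  expect_equal(nrow(fx), 1)
  expect_equal(c(fx$onset, fx$offset), c(1, 251))
  one <- data.frame(onset = 100, offset = 110)
  fx <- derive_fixations(one, none, 250, c(1, 251))
  expect_equal(nrow(fx), 2)
  expect_equal(fx$onset, c(1, 110))
  expect_equal(fx$offset, c(100, 251))
  overlapping <- data.frame(onset = c(10, 15), offset = c(20, 25))
  expect_error(derive_fixations(overlapping, none, 250, c(1, 251)),
               "overlapping")
})

test_that("fixation counts from detection are within 5% of ground truth", {
  cfg <- quick_sim_config(seed = 5)
  sim <- simulate_session(cfg)
  gx <- sim$et$data["gaze_x", ]; gy <- sim$et$data["gaze_y", ]
  pl <- interpolate_blinks(sim$et$data["pupil_L", ], 250)
  mask <- rep(FALSE, length(gx))
  for (i in seq_len(nrow(pl$blinks)))
    mask[pl$blinks$onset[i]:(pl$blinks$offset[i] - 1)] <- TRUE
  sac <- detect_saccades(gx, gy, 250, mask = mask)
  fx <- derive_fixations(sac, pl$blinks, 250, c(1, length(gx) + 1),
                         gaze_x = gx, gaze_y = gy)
  n_true <- nrow(sim$truth$true_fixations)
  expect_lte(abs(nrow(fx) - n_true) / n_true, 0.05)
})

test_that("assign_aoi uses half-open centroid containment", {
  aois <- list(aoi("text", c(0, 0, 100, 100)),
               aoi("picture", c(100, 0, 200, 100)))
  fx <- data.frame(onset = 1:3, offset = 2:4, duration_ms = 4,
                   x = c(150, 100, 300), y = c(50, 50, 50))
  out <- assign_aoi(fx, aois)
  expect_equal(out$aoi, c("picture", "picture", NA))
  # x = 100 is outside "text" (half-open max edge) but inside "picture"
  out1 <- assign_aoi(data.frame(x = 99.999, y = 50), list(aois[[1]]))
  expect_equal(out1$aoi, "text")
  expect_error(assign_aoi(fx, list(aoi("a", c(0, 0, 10, 10)),
                                   aoi("b", c(5, 5, 15, 15)))), "overlapping")
})

test_that("transition counting follows the direct-switch rule", {
  mk <- function(labs) data.frame(duration_ms = rep(100, length(labs)),
                                  aoi = labs)
  expect_equal(gaze_metrics(mk(c("text", "text", "text")))$n_transitions, 0L)
  expect_equal(gaze_metrics(mk(c("text", "picture", "text")))$n_transitions, 2L)
  expect_equal(gaze_metrics(mk(c("text", NA, "picture")))$n_transitions, 0L)
  # invariant: transitions <= labeled fixations - 1, random sequences
  set.seed(33)
  for (i in 1:50) {
    labs <- sample(c("text", "picture", NA), sample(1:30, 1), replace = TRUE)
    gm <- gaze_metrics(mk(labs))
    n_lab <- sum(!is.na(labs))
    if (n_lab >= 1) expect_lte(gm$n_transitions, max(0, n_lab - 1))
  }
})
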