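make_sine_rec <- function(f, n = 30000, rate = 1000) {
  t <- (seq_len(n) - 1) / rate
  recording(matrix(sin(2 * pi * f * t), 1), rate, "ch")
}

mid_gain <- function(rec_out, rec_in) {
  mid <- 10001:20000
  sd(rec_out$data[1, mid]) / sd(rec_in$data[1, mid])
}

test_that("fir_filter passband, stopbands and DC behave per design", {
  r10 <- make_sine_rec(10)
  expect_equal(mid_gain(fir_filter(r10), r10), 1, tolerance = 0.01)
  r60 <- make_sine_rec(60)
  expect_lt(20 * log10(mid_gain(fir_filter(r60), r60)), -40)
  r125m <- make_sine_rec(0.125)
  expect_lt(20 * log10(mid_gain(fir_filter(r125m), r125m)), -40)
  dc <- recording(matrix(100, 1, 30000), 1000, "ch")
  expect_lt(max(abs(fir_filter(dc)$data[1, 10001:20000])), 1e-9)
  expect_error(fir_filter(make_sine_rec(10), hp_hz = 0.25, lp_hz = 600),
               "Nyquist")
  expect_error(fir_filter(make_sine_rec(10), hp_hz = 50, lp_hz = 48), "hp_hz")
})

test_that("fir_filter preserves event latencies (zero phase)", {
  x <- numeric(30000); x[15000] <- 1
  out <- fir_filter(recording(matrix(x, 1), 1000, "ch"))
  expect_equal(which.max(out$data[1, ]), 15000)
})

test_that("rereference_average subtracts the mean and conserves zero sum", {
  rec <- recording(matrix(c(1, 3), 2, 10), 100, c("a", "b"))
  out <- rereference_average(rec)
  expect_equal(out$data[, 1], c(a = -1, b = 1))
  set.seed(2)
  rec <- recording(matrix(rnorm(5 * 100), 5), 100, letters[1:5])
  out <- rereference_average(rec, exclude_labels = "e")
  expect_lt(max(abs(colSums(out$data))), 1e-12)
  expect_equal(out$channel_labels, letters[1:4])
  expect_error(rereference_average(recording(matrix(0, 2, 5), 10,
                                             c("a", "b")), c("a", "b")),
               "every channel")
})

test_that("extract_epochs tiles condition intervals and respects boundaries", {
  rec <- recording(matrix(rnorm(2 * 20000), 2), 1000, c("Fz", "Pz"))
  ci <- data.frame(start = c(1, 10001), end = c(10000, 20000),
                   condition = c("A", "B"))
  # 10 s condition interval, contiguous tiling -> 5 epochs of 2 s
  anchors <- tile_anchors(ci[1, ], 1000, 2)
  expect_equal(nrow(anchors), 5)
  es <- extract_epochs(rec, anchors, ci)
  expect_equal(length(es$keep), 5)
  expect_true(all(es$condition == "A"))
  # an anchor 1 s before the condition boundary would cross into B: dropped
  es2 <- extract_epochs(rec, c(1, 9001), ci)
  expect_equal(length(es2$keep), 1)
  # but crossing into unlabeled tail (past the last interval) only drops
  # when truncated by the recording end
  es3 <- extract_epochs(rec, 19001, ci)
  expect_equal(length(es3$keep), 0)
  expect_error(extract_epochs(rec, 25000, ci), "outside recording")
  expect_error(extract_epochs(rec, 5, ci[2, ]), "unknown condition")
})

test_that("reject_artifacts uses a strict threshold and is monotone", {
  ep <- array(0, dim = c(3, 1, 100))
  ep[1, 1, 50] <- 101    # rejected
  ep[2, 1, 50] <- 100    # boundary: kept
  es <- structure(list(epochs = ep, condition = rep("A", 3),
                       keep = rep(TRUE, 3), anchor_sample = c(1, 101, 201),
                       lock = "stimulus", length_s = 0.1, rate = 1000,
                       channel_labels = "Fz"), class = "epoch_set")
  out <- reject_artifacts(es, 100)
  expect_equal(out$keep, c(FALSE, TRUE, TRUE))
  # monotone in the limit over random epoch sets
  set.seed(12)
  for (i in 1:20) {
    ep <- array(rnorm(10 * 2 * 50, sd = 60), dim = c(10, 2, 50))
    es <- structure(list(epochs = ep, condition = rep("A", 10),
                         keep = rep(TRUE, 10),
                         anchor_sample = seq(1, 500, by = 50),
                         lock = "stimulus", length_s = 0.05, rate = 1000,
                         channel_labels = c("a", "b")), class = "epoch_set")
    lims <- sort(runif(2, 50, 200))
    k_lo <- reject_artifacts(es, lims[1])$keep
    k_hi <- reject_artifacts(es, lims[2])$keep
    expect_true(all(k_hi[k_lo]))  # kept at L stays kept at L' > L
  }
})

test_that("remove_eog leaves uncorrelated data alone and honors thresholds", {
  set.seed(3)
  X <- matrix(rnorm(10 * 4000), 10)
  rec <- recording(X, 1000, paste0("ch", 1:10))
  ref <- rnorm(4000)  # independent of everything
  out <- remove_eog(rec, rbind(ref), corr_threshold = 0.7, seed = 1)
  expect_identical(out$recording$data, rec$data)
  # unreachable threshold removes nothing even with a perfect reference
  out2 <- remove_eog(rec, rbind(X[1, ]), corr_threshold = 1.01, seed = 1)
  expect_equal(length(out2$report$removed), 0)
  expect_error(remove_eog(recording(matrix(rnorm(4 * 100), 4), 100,
                                    paste0("c", 1:4)), rbind(rnorm(100))),
               ">= 8 channels")
})

test_that("ICA removes the simulated blink projection, sparing parietal alpha", {
  cfg <- sim_config(seed = 11, n_paragraphs = 5, paragraph_s = 8)
  sim <- simulate_session(cfg)
  eeg <- fir_filter(sim$eeg)
  cl <- remove_eog(eeg, "EOG", 0.7, seed = 11)
  expect_true(cl$report$converged)
  expect_gte(length(cl$report$removed), 1)
  bl <- sim$truth$true_blinks
  bl_eeg <- round((bl$onset - 1 - sim$truth$stream_offset_et) / 250 * 1000) + 1
  bl_eeg <- bl_eeg[bl_eeg > 0 & bl_eeg + 250 <= ncol(eeg$data)]
  blink_amp <- function(rec) mean(vapply(bl_eeg, function(s)
    max(abs(rec$data["Fp1", s:(s + 250)])), numeric(1)))
  expect_lt(blink_amp(cl$recording), 0.2 * blink_amp(eeg))
  pz_alpha <- function(rec) band_power(
    epoch_power(rec$data["Pz", 1:80000, drop = FALSE], 1000), c(8, 13))
  expect_lt(abs(pz_alpha(cl$recording) / pz_alpha(eeg) - 1), 0.1)
})
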