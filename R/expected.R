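# Analytic expectations for the synthetic generator.
#
# The band-power estimator (Hanning-tapered 500 ms windows, zero-padded to
# a 0.125 Hz grid) smears narrow-band power across neighbouring bins, so
# the expected *estimate* differs from the raw band variance. These
# closed-form expectations convolve the known synthesis spectra with the
# window's power kernel; they are independent of the estimation code path
# and serve as the oracle for parameter-recovery tests.

# |W(f)|^2 of the Hanning taper on the padded DFT grid, plus the PSD
# normalization constant used by epoch_power()
estimator_kernel <- function(rate, win_ms = 500, pad_to_spacing_hz = 0.125) {
  win_n <- round(win_ms / 1000 * rate)
  pad_n <- round(rate / pad_to_spacing_hz)
  w <- hann_taper(win_n)
  W2 <- Mod(fft(c(w, rep(0, pad_n - win_n))))^2
  list(W2 = W2, pad_n = pad_n, spacing = rate / pad_n,
       norm = 2 / (rate * sum(w^2)))
}

# expected band estimate (mean over inclusive band bins) for a
# unit-variance process whose normalized discrete PSD puts weight p[m] on
# grid frequency index m (0-based, 0..pad_n/2)
expected_band_estimate <- function(kern, p_idx, p_wt, band) {
  pad_n <- kern$pad_n
  k_band <- which_band_bins(band, kern$spacing, pad_n)
  acc <- 0
  for (j in seq_along(p_idx)) {
    m <- p_idx[j]
    dminus <- (k_band - m) %% pad_n
    dplus <- (k_band + m) %% pad_n
    acc <- acc + p_wt[j] * mean(0.5 * (kern$W2[dminus + 1] + kern$W2[dplus + 1]))
  }
  kern$norm * acc
}

which_band_bins <- function(band, spacing, pad_n) {
  k <- 0:(pad_n %/% 2)
  f <- k * spacing
  k[f >= band[1] - 1e-9 & f <= band[2] + 1e-9]
}

# normalized discrete PSD of the synthesis components on the kernel grid
component_psd <- function(kern, shape_fun) {
  m <- 1:(kern$pad_n %/% 2)
  f <- m * kern$spacing
  wt <- shape_fun(f)^2
  s <- sum(wt)
  keep <- wt > 0
  list(idx = m[keep], wt = wt[keep] / s)
}

#' Expected band-power estimates for a simulated session
#'
#' Closed-form expectation of the sliding Hanning-window band-power
#' estimate, per condition x band x channel, for the raw (unreferenced)
#' generated EEG. Ocular transients and the synthetic EOG channel's own
#' noise are not included (they are broadband, small at the analysis
#' channels, and the affected epochs are largely removed by amplitude
#' rejection).
#'
#' @param config a [sim_config()]
#' @param win_ms,pad_to_spacing_hz estimator parameters (must match the
#'   analysis settings)
#' @return numeric array `[condition, band, channel]`
#' @export
expected_band_power <- function(config, win_ms = 500, pad_to_spacing_hz = 0.125) {
  kern <- estimator_kernel(config$eeg_rate, win_ms, pad_to_spacing_hz)
  bands <- list(theta = config$theta_band, alpha = config$alpha_band)
  comps <- list(
    theta = component_psd(kern, band_shape_fun(config$theta_band)),
    alpha = component_psd(kern, band_shape_fun(config$alpha_band)),
    bg = component_psd(kern, bg_shape_fun(config$background_exponent)))
  # K[source, band]: expected estimate per unit source variance
  K <- sapply(bands, function(bd) sapply(comps, function(cp)
    expected_band_estimate(kern, cp$idx, cp$wt, bd)))
  nch <- length(config$channels)
  is_eog <- config$channels == "EOG"
  mult <- config$condition_power_multipliers
  out <- array(0, dim = c(length(config$conditions), 2, nch),
               dimnames = list(config$conditions, c("theta", "alpha"),
                               config$channels))
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    v_th <- (config$theta_topography * config$carrier_rms[["theta"]] *
             mult[cond, "theta"])^2
    v_al <- (config$alpha_topography * config$carrier_rms[["alpha"]] *
             mult[cond, "alpha"])^2
    v_bg <- ifelse(is_eog, 0, config$background_rms^2)
    for (bi in 1:2) {
      out[ci, bi, ] <- v_th * K["theta", bi] + v_al * K["alpha", bi] +
        v_bg * K["bg", bi]
    }
  }
  out
}

#' Expected ERD/ERS\% for a simulated session
#'
#' Analytic expectation of the ERD/ERS percent change at a given channel
#' and band under a generator configuration, optionally after average
#' re-referencing over the scalp channels (carrier topography weights
#' become `w - mean(w)`; independent backgrounds lose a factor
#' `1 - 1/C`).
#'
#' @param config a [sim_config()]
#' @param channel channel label
#' @param band `"theta"` or `"alpha"`
#' @param avg_ref expectation after average re-referencing?
#' @return named vector of expected ERD/ERS\% per condition
#' @export
expected_erd <- function(config, channel, band = c("alpha", "theta"),
                         avg_ref = TRUE) {
  band <- match.arg(band)
  kern <- estimator_kernel(config$eeg_rate)
  bd <- if (band == "alpha") config$alpha_band else config$theta_band
  comps <- list(
    theta = component_psd(kern, band_shape_fun(config$theta_band)),
    alpha = component_psd(kern, band_shape_fun(config$alpha_band)),
    bg = component_psd(kern, bg_shape_fun(config$background_exponent)))
  K <- sapply(comps, function(cp) expected_band_estimate(kern, cp$idx, cp$wt, bd))
  scalp <- config$channels != "EOG"
  i <- match(channel, config$channels)
  if (is.na(i)) stop("unknown channel ", channel)
  w_th <- config$theta_topography
  w_al <- config$alpha_topography
  if (avg_ref) {
    C <- sum(scalp)
    w_th_i <- w_th[i] - mean(w_th[scalp])
    w_al_i <- w_al[i] - mean(w_al[scalp])
    v_bg <- config$background_rms^2 * (1 - 1 / C)
  } else {
    w_th_i <- w_th[i]; w_al_i <- w_al[i]
    v_bg <- config$background_rms^2
  }
  mult <- config$condition_power_multipliers
  P <- vapply(config$conditions, function(cond) {
    (w_th_i * config$carrier_rms[["theta"]] * mult[cond, "theta"])^2 * K["theta"] +
    (w_al_i * config$carrier_rms[["alpha"]] * mult[cond, "alpha"])^2 * K["alpha"] +
    v_bg * K["bg"]
  }, numeric(1))
  B <- mean(P)
  (P - B) / B * 100
}
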