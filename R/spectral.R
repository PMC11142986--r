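# Band power and ERD/ERS% against global condition baselines.

# symmetric Hanning taper
hann_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Average power spectrum of one epoch (sliding Hanning-window FFT)
#'
#' Each 500 ms window is Hanning-tapered, zero-padded so the discrete
#' frequency spacing equals `pad_to_spacing_hz`, transformed, and converted
#' to one-sided power spectral density (uV^2/Hz); window spectra are
#' averaged over the epoch and the grid restricted to 2-30 Hz.
#'
#' @param epoch numeric matrix, channels x samples (a vector is treated as
#'   one channel)
#' @param rate sampling rate in Hz
#' @param win_ms window length in ms
#' @param step_ms window step (50\% overlap by default)
#' @param pad_to_spacing_hz target frequency spacing in Hz
#' @param fmin,fmax retained frequency range in Hz (inclusive)
#' @return object of class `"power_spectrum"`: list with `freqs`, `power`
#'   (channels x freqs), `n_windows`
#' @export
epoch_power <- function(epoch, rate, win_ms = 500, step_ms = 250,
                        pad_to_spacing_hz = 0.125, fmin = 2, fmax = 30) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  ns <- ncol(epoch); nch <- nrow(epoch)
  win_n <- round(win_ms / 1000 * rate)
  if (win_n > ns) stop("window (", win_ms, " ms) longer than epoch")
  step_n <- max(1L, round(step_ms / 1000 * rate))
  pad_n <- round(rate / pad_to_spacing_hz)
  if (pad_n < win_n) stop("pad_to_spacing_hz too coarse for the window")
  starts <- seq(1L, ns - win_n + 1L, by = step_n)
  w <- hann_taper(win_n)
  # stack all (channel, window) segments as columns and transform at once
  seg <- matrix(0, pad_n, nch * length(starts))
  k <- 0
  for (s in starts) {
    idx <- s:(s + win_n - 1L)
    seg[1:win_n, k + seq_len(nch)] <- t(epoch[, idx, drop = FALSE] * rep(w, each = nch))
    k <- k + nch
  }
  X <- mvfft(seg)
  norm <- 2 / (rate * sum(w^2))
  freqs_all <- (0:(pad_n %/% 2)) * pad_to_spacing_hz
  keep <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9)
  P2 <- Mod(X[keep, , drop = FALSE])^2 * norm
  pw <- matrix(0, nch, length(keep))
  for (j in seq_along(starts))
    pw <- pw + t(P2[, (j - 1) * nch + seq_len(nch), drop = FALSE])
  pw <- pw / length(starts)
  structure(list(freqs = freqs_all[keep], power = pw,
                 n_windows = length(starts)),
            class = "power_spectrum")
}

#' Mean power in a frequency band
#'
#' Mean of spectral power over all bins with `band[1] <= f <= band[2]`
#' (both edges inclusive; on the default 0.125 Hz grid the canonical edges
#' 4, 6, 8, 13 Hz fall exactly on bins).
#'
#' @param spectrum a `"power_spectrum"` from [epoch_power()]
#' @param band Hz pair
#' @return numeric vector, one value per channel
#' @export
band_power <- function(spectrum, band) {
  if (band[1] < min(spectrum$freqs) - 1e-9 || band[2] > max(spectrum$freqs) + 1e-9)
    stop("band [", band[1], ", ", band[2], "] outside the spectrum grid")
  sel <- spectrum$freqs >= band[1] - 1e-9 & spectrum$freqs <= band[2] + 1e-9
  rowMeans(spectrum$power[, sel, drop = FALSE])
}

# Batch band power over an epoch set, computed as an exact direct DFT at
# the band bins only (identical values to epoch_power + band_power, proved
# by tests; avoids full padded FFTs when thousands of epochs are scored).
# Returns array [epoch, channel, band].
epoch_set_band_power <- function(es, bands, channels = NULL, win_ms = 500,
                                 step_ms = 250, pad_to_spacing_hz = 0.125) {
  rate <- es$rate
  nch_all <- dim(es$epochs)[2]
  ch_idx <- if (is.null(channels)) seq_len(nch_all) else {
    if (is.character(channels)) match(channels, es$channel_labels) else channels
  }
  if (anyNA(ch_idx)) stop("unknown channel in 'channels'")
  ns <- dim(es$epochs)[3]
  win_n <- round(win_ms / 1000 * rate)
  step_n <- max(1L, round(step_ms / 1000 * rate))
  pad_n <- round(rate / pad_to_spacing_hz)
  starts <- seq(1L, ns - win_n + 1L, by = step_n)
  w <- hann_taper(win_n)
  norm <- 2 / (rate * sum(w^2))
  spacing <- rate / pad_n
  bin_sets <- lapply(bands, function(bd) which_band_bins(bd, spacing, pad_n))
  all_bins <- sort(unique(unlist(bin_sets)))
  tt <- 0:(win_n - 1)
  ang <- 2 * pi * outer(all_bins / pad_n, tt)
  Mc <- cos(ang) * rep(w, each = length(all_bins))
  Ms <- -sin(ang) * rep(w, each = length(all_bins))
  n_ep <- dim(es$epochs)[1]
  out <- array(NA_real_, dim = c(n_ep, length(ch_idx), length(bands)),
               dimnames = list(NULL, es$channel_labels[ch_idx], names(bands)))
  seg_cols <- length(starts)
  for (ci in seq_along(ch_idx)) {
    ch <- ch_idx[ci]
    # windows of all epochs for this channel, as columns
    segs <- matrix(0, win_n, n_ep * seg_cols)
    k <- 0
    for (e in seq_len(n_ep)) {
      xe <- es$epochs[e, ch, ]
      for (s in starts) {
        k <- k + 1
        segs[, k] <- xe[s:(s + win_n - 1L)]
      }
    }
    P <- ((Mc %*% segs)^2 + (Ms %*% segs)^2) * norm
    for (bi in seq_along(bands)) {
      rows <- match(bin_sets[[bi]], all_bins)
      bp <- colMeans(P[rows, , drop = FALSE])
      # columns of segs are grouped per epoch, so reshape epoch-major
      out[, ci, bi] <- colMeans(matrix(bp, nrow = seg_cols))
    }
  }
  out
}

#' ERD/ERS percent change against the global condition baseline
#'
#' For each condition c the mean band power over its kept epochs, P_c, is
#' referenced to the unweighted mean B of the P_c over all conditions of
#' the task: `value_c = (P_c - B) / B * 100`. Negative values indicate
#' desynchronization (power loss) relative to the task-global baseline.
#' By construction the unweighted mean over conditions of `1 + value/100`
#' is exactly 1.
#'
#' @param per_epoch_band_power numeric matrix, epochs x channels (a vector
#'   is treated as one channel)
#' @param condition_labels per-epoch condition labels
#' @param conditions optional condition ordering (default: unique labels)
#' @param epoch_weighted if `TRUE`, the baseline is the epoch-weighted
#'   grand mean instead of the unweighted condition-mean average
#' @return list of class `"erd_ers"` with `values` (condition x channel,
#'   percent), `cond_power`, `baseline` (per channel), `n_epochs`
#' @export
erd_ers <- function(per_epoch_band_power, condition_labels,
                    conditions = NULL, epoch_weighted = FALSE) {
  if (is.vector(per_epoch_band_power))
    per_epoch_band_power <- matrix(per_epoch_band_power, ncol = 1)
  if (nrow(per_epoch_band_power) != length(condition_labels))
    stop("one condition label per epoch required")
  conditions <- conditions %||% unique(condition_labels)
  n_by <- table(factor(condition_labels, levels = conditions))
  if (any(n_by == 0)) {
    missing <- names(n_by)[n_by == 0]
    stop(structure(class = c("coregload_no_epochs", "error", "condition"),
                   list(message = paste0("no kept epochs for condition(s): ",
                                         paste(missing, collapse = ", ")),
                        call = sys.call())))
  }
  P <- t(sapply(conditions, function(cc)
    colMeans(per_epoch_band_power[condition_labels == cc, , drop = FALSE])))
  if (ncol(per_epoch_band_power) == 1) P <- matrix(P, ncol = 1,
    dimnames = list(conditions, NULL))
  B <- if (epoch_weighted) colMeans(per_epoch_band_power) else colMeans(P)
  vals <- sweep(sweep(P, 2, B, `-`), 2, B, `/`) * 100
  structure(list(values = vals, cond_power = P, baseline = B,
                 n_epochs = as.vector(n_by), conditions = conditions),
            class = "erd_ers")
}

#' Per-condition mean pupil size
#'
#' Stimulus-locked (over kept 2 s epochs) or fixation-related (over
#' picture-AOI fixation spans) summaries of a blink-interpolated pupil
#' trace. Samples still at the dropout sentinel are treated as invalid; a
#' condition with no valid samples is an error.
#'
#' @param pupil numeric pupil trace
#' @param rate sampling rate of `pupil` in Hz
#' @param condition_intervals data.frame `start`, `end`, `condition`
#'   (sample indices on the `pupil` timeline)
#' @param epochs an epoch set (stimulus-locked mode), or `NULL`
#' @param fixations a fixation data.frame with `onset`, `offset`, `aoi`
#'   (fixation-related mode), or `NULL`
#' @param aoi AOI label selecting fixations in fixation-related mode
#' @return named numeric vector of per-condition means
#' @export
pupil_summary <- function(pupil, rate, condition_intervals, epochs = NULL,
                          fixations = NULL, aoi = "picture") {
  spans <- if (!is.null(epochs)) {
    keep <- which(epochs$keep)
    if (!length(keep)) stop("no kept epochs")
    data.frame(onset = epochs$anchor_sample[keep],
               offset = epochs$anchor_sample[keep] +
                 round(epochs$length_s * rate) - 1,
               condition = epochs$condition[keep])
  } else if (!is.null(fixations)) {
    fx <- fixations[!is.na(fixations$aoi) & fixations$aoi == aoi, , drop = FALSE]
    cond <- condition_at(fx$onset, condition_intervals)
    data.frame(onset = fx$onset, offset = fx$offset, condition = cond)
  } else stop("provide either epochs or fixations")
  spans <- spans[!is.na(spans$condition), , drop = FALSE]
  conds <- unique(condition_intervals$condition)
  out <- setNames(rep(NA_real_, length(conds)), conds)
  for (cc in conds) {
    idx <- unlist(lapply(which(spans$condition == cc), function(i)
      seq(max(1, spans$onset[i]), min(length(pupil), spans$offset[i]))))
    vals <- pupil[idx]
    vals <- vals[vals != DROPOUT_SENTINEL & is.finite(vals)]
    if (!length(vals))
      stop("no valid pupil samples in condition ", cc)
    out[cc] <- mean(vals)
  }
  out
}

# condition label of the interval containing each sample (NA outside)
condition_at <- function(samples, condition_intervals) {
  ci <- condition_intervals[order(condition_intervals$start), , drop = FALSE]
  idx <- findInterval(samples, ci$start)
  out <- rep(NA_character_, length(samples))
  ok <- idx >= 1 & idx <= nrow(ci)
  inb <- ok & samples <= ci$end[pmax(idx, 1)]
  out[inb] <- ci$condition[idx[inb]]
  out
}
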