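# Filtering, ocular-artifact removal, re-referencing, epoching and
# amplitude-based epoch rejection. Pipeline order is fixed:
# filter -> EOG removal -> average reference -> epoch -> reject.

# Windowed-sinc (Hamming) linear-phase low-pass kernel, odd length,
# -6 dB point at fc, transition width `trans` Hz
design_lowpass <- function(fc, trans, rate) {
  m <- ceiling(3.3 * rate / trans)
  if (m %% 2 == 0) m <- m + 1
  n <- seq_len(m) - (m + 1) / 2
  h <- 2 * fc / rate * sinc(2 * fc / rate * n)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# band-pass kernel: high-pass (spectral inversion of a low-pass at hp)
# convolved with a low-pass at lp. Transition widths: hp/2 below the
# high-pass edge and min(lp/4, 12 Hz) above the low-pass edge, giving
# >= 40 dB (Hamming: ~53 dB) one octave into each stopband.
design_bandpass <- function(hp, lp, rate) {
  h_lp <- design_lowpass(lp + min(lp / 4, 12) / 2, min(lp / 4, 12), rate)
  h_hp_lp <- design_lowpass(hp - hp / 4, hp / 2, rate)
  h_hp <- -h_hp_lp
  h_hp[(length(h_hp) + 1) / 2] <- h_hp[(length(h_hp) + 1) / 2] + 1
  convolve(h_hp, rev(h_lp), type = "open")
}

# zero-phase FFT convolution of all channels (rows of X) with a symmetric
# odd-length kernel, group delay compensated
fft_filtfilt <- function(X, h) {
  n <- ncol(X); L <- length(h)
  half <- (L - 1) / 2
  nf <- stats::nextn(n + L - 1, c(2, 3, 5))
  H <- fft(c(h, rep(0, nf - L)))
  out <- matrix(0, nrow(X), n)
  # chunk channels to bound the complex working-set size
  for (grp in split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / 6))) {
    pad <- matrix(0, nf, length(grp))
    pad[1:n, ] <- t(X[grp, , drop = FALSE])
    y <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / nf
    out[grp, ] <- t(y[(half + 1):(half + n), , drop = FALSE])
  }
  out
}

#' Linear-phase FIR band-pass filter (zero-phase application)
#'
#' Windowed-sinc Hamming design; the symmetric kernel is applied by FFT
#' convolution with exact group-delay compensation, so event latencies are
#' preserved. Stop-band attenuation is ~53 dB one octave beyond each edge.
#' The channel mean (DC) is removed before filtering.
#'
#' @param rec a [recording()]
#' @param hp_hz high-pass edge in Hz
#' @param lp_hz low-pass edge in Hz (`hp_hz < lp_hz < rate/2`)
#' @return filtered [recording()]
#' @export
fir_filter <- function(rec, hp_hz = 0.25, lp_hz = 48) {
  ny <- rec$rate / 2
  if (lp_hz >= ny) stop("lp_hz must be below Nyquist (", ny, " Hz)")
  if (hp_hz <= 0 || hp_hz >= lp_hz) stop("need 0 < hp_hz < lp_hz")
  h <- design_bandpass(hp_hz, lp_hz, rec$rate)
  if (length(h) > n_samples(rec))
    stop("recording (", n_samples(rec), " samples) shorter than the ",
         length(h), "-tap kernel; record longer or relax hp_hz")
  out <- fft_filtfilt(rec$data - rowMeans(rec$data), h)
  recording(out, rec$rate, rec$channel_labels, rec$units)
}

#' Remove ocular ICA components by correlation with an EOG reference
#'
#' An ICA decomposition (deterministic given `seed`) is computed over the
#' channels in `channels`; components whose absolute time-course
#' correlation with any EOG reference trace exceeds `corr_threshold` are
#' zeroed and the data re-mixed. Replaces the visual EOG-component
#' screening used in manual workflows with an auditable automatic rule.
#'
#' @param rec a [recording()] (>= 8 channels entering the decomposition)
#' @param eog_reference channel labels in `rec`, or a numeric matrix of
#'   reference traces (rows = references)
#' @param corr_threshold absolute correlation above which a component is
#'   removed
#' @param channels channels to decompose (default: all except the
#'   reference channels)
#' @param seed,max_iter ICA determinism and iteration controls
#' @return list: `recording` (cleaned), `report` (data.frame of components
#'   with correlations and removal flags, plus `converged`)
#' @export
remove_eog <- function(rec, eog_reference, corr_threshold = 0.7,
                       channels = NULL, seed = 1L, max_iter = 500) {
  if (is.character(eog_reference)) {
    ridx <- match(eog_reference, rec$channel_labels)
    if (anyNA(ridx)) stop("unknown EOG reference channel")
    refs <- rec$data[ridx, , drop = FALSE]
    if (is.null(channels))
      channels <- setdiff(rec$channel_labels, eog_reference)
  } else {
    refs <- matrix(eog_reference, ncol = n_samples(rec))
    if (is.null(channels)) channels <- rec$channel_labels
  }
  cidx <- match(channels, rec$channel_labels)
  if (anyNA(cidx)) stop("unknown channel in 'channels'")
  if (length(cidx) < 8) stop("need >= 8 channels for ICA-based EOG removal")
  X <- rec$data[cidx, , drop = FALSE]
  dec <- fastica_decompose(X, seed = seed, max_iter = max_iter)
  if (!dec$converged) {
    warning("ICA failed to converge; data passed through unchanged")
    return(list(recording = rec,
                report = list(converged = FALSE, removed = integer(0))))
  }
  # component/reference correlations on the ICA estimation subsample (the
  # correlation estimate converges long before the full record is used)
  Se <- dec$unmixing %*% (X[, dec$est_idx, drop = FALSE] - dec$center)
  cors <- matrix(0, nrow(Se), nrow(refs))
  for (r in seq_len(nrow(refs)))
    cors[, r] <- as.vector(stats::cor(t(Se), refs[r, dec$est_idx]))
  max_abs <- apply(abs(cors), 1, max)
  removed <- which(max_abs > corr_threshold)
  if (length(removed)) {
    U <- dec$unmixing[removed, , drop = FALSE]
    S_rem <- U %*% X - drop(U %*% dec$center)
    out <- rec$data
    out[cidx, ] <- X - dec$backproject[, removed, drop = FALSE] %*% S_rem
    rec <- recording(out, rec$rate, rec$channel_labels, rec$units)
  }
  report <- list(converged = TRUE, removed = removed,
                 correlations = max_abs, n_components = dec$n_comp,
                 iterations = dec$iterations)
  list(recording = rec, report = report)
}

#' Average re-reference
#'
#' Subtracts the instantaneous mean over the included scalp channels from
#' each included channel and drops the excluded channels, so the output
#' channels sum to zero at every sample.
#'
#' @param rec a [recording()]
#' @param exclude_labels channels to drop before averaging (mastoids, EOG,
#'   appended eye-tracking channels)
#' @return re-referenced [recording()] containing only included channels
#' @export
rereference_average <- function(rec, exclude_labels = character()) {
  bad <- setdiff(exclude_labels, rec$channel_labels)
  if (length(bad)) stop("exclude_labels not in recording: ",
                        paste(bad, collapse = ", "))
  keep <- !(rec$channel_labels %in% exclude_labels)
  if (!any(keep)) stop("exclusion removes every channel")
  X <- rec$data[keep, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  recording(X, rec$rate, rec$channel_labels[keep], rec$units[keep])
}

#' Contiguously tiled stimulus-locked anchors
#'
#' Anchors every `length_s` seconds from each condition interval's start
#' to its end (reading-task stimulus-locked convention: epochs tile the
#' recording from the first paragraph onset).
#'
#' @param condition_intervals data.frame `start`, `end`, `condition`
#' @param rate sampling rate in Hz
#' @param length_s epoch length in seconds
#' @return data.frame `sample`, `condition`
#' @export
tile_anchors <- function(condition_intervals, rate, length_s = 2) {
  L <- round(length_s * rate)
  out <- lapply(seq_len(nrow(condition_intervals)), function(i) {
    s <- seq(condition_intervals$start[i], condition_intervals$end[i] - L + 1,
             by = L)
    data.frame(sample = s, condition = condition_intervals$condition[i])
  })
  do.call(rbind, out)
}

#' Extract fixed-length epochs
#'
#' Epoch k spans `[anchor_k, anchor_k + length_s)`. Epochs truncated by the
#' recording end are dropped, as are epochs whose span crosses into a
#' *different* condition interval (they may extend into unlabeled gaps).
#' The condition label is inherited from the interval containing the
#' anchor; an anchor in no interval is an error.
#'
#' @param rec a [recording()]
#' @param anchors numeric anchor samples, or a data.frame with column
#'   `sample`
#' @param condition_intervals data.frame `start`, `end`, `condition`
#' @param lock `"stimulus"` or `"fixation"` (metadata)
#' @param length_s epoch length in seconds
#' @param channels optional channel subset to store
#' @param min_anchor_gap optional minimum anchor spacing in samples;
#'   anchors closer than this to the previously kept anchor are skipped
#' @return an `"epoch_set"`: list with `epochs` (n x channels x samples),
#'   `condition`, `keep`, `anchor_sample`, `lock`, `length_s`, `rate`,
#'   `channel_labels`
#' @export
extract_epochs <- function(rec, anchors, condition_intervals,
                           lock = c("stimulus", "fixation"), length_s = 2,
                           channels = NULL, min_anchor_gap = NULL) {
  lock <- match.arg(lock)
  if (is.data.frame(anchors)) anchors <- anchors$sample
  anchors <- as.numeric(anchors)
  L <- round(length_s * rec$rate)
  n <- n_samples(rec)
  if (any(anchors < 1 | anchors > n)) stop("anchor outside recording")
  cond <- condition_at(anchors, condition_intervals)
  if (anyNA(cond)) stop("unknown condition at anchor ",
                        anchors[which(is.na(cond))[1]])
  keep_a <- anchors + L - 1 <= n
  # no crossing into a different condition interval
  ci <- condition_intervals
  for (k in which(keep_a)) {
    own_end <- ci$end[ci$start <= anchors[k] & ci$end >= anchors[k]][1]
    if (anchors[k] + L - 1 > own_end) {
      others <- ci[ci$start > own_end, , drop = FALSE]
      if (nrow(others) && any(others$start <= anchors[k] + L - 1))
        keep_a[k] <- FALSE
    }
  }
  anchors <- anchors[keep_a]; cond <- cond[keep_a]
  if (!is.null(min_anchor_gap) && length(anchors) > 1) {
    sel <- rep(TRUE, length(anchors))
    last <- anchors[1]
    for (k in 2:length(anchors)) {
      if (anchors[k] - last < min_anchor_gap) sel[k] <- FALSE
      else last <- anchors[k]
    }
    anchors <- anchors[sel]; cond <- cond[sel]
  }
  ch_idx <- if (is.null(channels)) seq_len(nrow(rec$data)) else
    match(channels, rec$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channel in 'channels'")
  ne <- length(anchors)
  ep <- array(0, dim = c(ne, length(ch_idx), L))
  for (k in seq_len(ne))
    ep[k, , ] <- rec$data[ch_idx, anchors[k]:(anchors[k] + L - 1)]
  structure(list(epochs = ep, condition = cond, keep = rep(TRUE, ne),
                 anchor_sample = anchors, lock = lock, length_s = length_s,
                 rate = rec$rate, channel_labels = rec$channel_labels[ch_idx]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %.1f s, lock=%s\n",
              length(x$keep), sum(x$keep), dim(x$epochs)[2], x$length_s, x$lock))
  print(table(condition = x$condition, kept = x$keep))
  invisible(x)
}

#' Amplitude-based epoch rejection
#'
#' Marks `keep = FALSE` for every epoch with any sample strictly exceeding
#' `limit_uv` in absolute value on any inspected channel (an epoch whose
#' maximum absolute value equals the limit exactly is kept). Rejection is
#' monotone in the limit.
#'
#' @param epochs an `"epoch_set"` (data in microvolts)
#' @param limit_uv rejection threshold in microvolts
#' @param channels optional channel subset to inspect (e.g. exclude
#'   appended eye-tracking channels)
#' @return the epoch set with updated `keep` and a `rejection` summary
#'   (kept/total per condition)
#' @export
reject_artifacts <- function(epochs, limit_uv = 100, channels = NULL) {
  ch_idx <- if (is.null(channels)) seq_len(dim(epochs$epochs)[2]) else
    match(channels, epochs$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channel in 'channels'")
  ne <- dim(epochs$epochs)[1]
  bad <- vapply(seq_len(ne), function(k)
    max(abs(epochs$epochs[k, ch_idx, ])) > limit_uv, logical(1))
  epochs$keep <- epochs$keep & !bad
  epochs$rejection <- as.data.frame(table(
    condition = epochs$condition, kept = epochs$keep))
  epochs
}
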