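# Synchronization of the EEG and eye-tracking streams via shared trigger
# events, and merging onto the common (EEG) timeline.

#' Estimate the affine ET-to-EEG sample mapping from shared triggers
#'
#' Shared trigger labels (stimulus onsets sent to both systems) are matched
#' and a least-squares affine fit `eeg_sample = offset + scale * et_sample`
#' is computed. The affine form absorbs clock drift; with no drift the
#' fitted scale is `eeg_rate / et_rate`. Fails when any post-fit residual
#' exceeds `max_jitter` EEG samples.
#'
#' @param eeg_events,et_events [event_table()]s carrying the triggers
#' @param max_jitter maximum tolerated absolute residual, in EEG samples
#' @param offset_only force `scale` to `scale_hint` and fit the offset only
#' @param scale_hint known rate ratio (used by `offset_only`)
#' @return list of class `"coreg_mapping"`: `offset`, `scale`, `residuals`
#'   (per matched marker, EEG samples), `n_markers`
#' @export
estimate_offset <- function(eeg_events, et_events, max_jitter = 3,
                            offset_only = FALSE, scale_hint = NULL) {
  common <- intersect(eeg_events$label, et_events$label)
  if (length(common) < 2)
    stop("need at least 2 shared trigger labels (found ", length(common), ")")
  a <- eeg_events[match(common, eeg_events$label), ]
  b <- et_events[match(common, et_events$label), ]
  if (!identical(order(a$sample), order(b$sample)))
    stop("shared triggers occur in different orders in the two streams")
  x <- b$sample; y <- a$sample
  if (offset_only) {
    scale <- scale_hint %||% stop("offset_only requires scale_hint")
    offset <- mean(y - scale * x)
  } else {
    if (stats::var(x) == 0) stop("markers are not spread in time; cannot fit scale")
    scale <- stats::cov(x, y) / stats::var(x)
    offset <- mean(y) - scale * mean(x)
  }
  res <- y - (offset + scale * x)
  if (max(abs(res)) > max_jitter)
    stop("marker residual ", signif(max(abs(res)), 4),
         " exceeds max_jitter = ", max_jitter, " EEG samples")
  structure(list(offset = offset, scale = scale, residuals = res,
                 n_markers = length(common)),
            class = "coreg_mapping")
}

#' Map ET sample indices onto the EEG timeline
#'
#' Applies the affine mapping and rounds half away from zero (bit-exact,
#' platform-independent).
#'
#' @param mapping a `"coreg_mapping"` from [estimate_offset()]
#' @param et_sample numeric ET sample indices
#' @return numeric EEG sample indices
#' @export
map_to_eeg <- function(mapping, et_sample) {
  round_half_away(mapping$offset + mapping$scale * et_sample)
}

#' Upsample an eye-tracking recording by linear interpolation
#'
#' Piecewise-linear interpolation onto the target grid; source samples are
#' preserved exactly at their grid positions. Dropout-sentinel runs are
#' propagated, not interpolated across: any target sample whose bracketing
#' source interval touches a sentinel sample becomes sentinel, so run
#' boundaries keep their time positions (blink repair is the job of
#' [interpolate_blinks()], before or after upsampling).
#'
#' @param et a [recording()]
#' @param target_rate target rate in Hz (`>= et$rate`)
#' @param sentinel the dropout value (default 0)
#' @return a [recording()] at `target_rate`
#' @export
upsample_et <- function(et, target_rate, sentinel = DROPOUT_SENTINEL) {
  if (target_rate < et$rate)
    stop("target_rate (", target_rate, ") below source rate (", et$rate, ")")
  n <- n_samples(et)
  if (n < 2) stop("need at least 2 samples to interpolate")
  t_src <- (seq_len(n) - 1) / et$rate
  n_out <- floor(t_src[n] * target_rate) + 1
  t_out <- (seq_len(n_out) - 1) / target_rate
  lo <- pmin(pmax(findInterval(t_out, t_src), 1L), n - 1L)
  hi <- lo + 1L
  out <- matrix(0, nrow(et$data), n_out)
  for (ch in seq_len(nrow(et$data))) {
    x <- et$data[ch, ]
    y <- approx(t_src, x, xout = t_out, rule = 2)$y
    bad <- x == sentinel
    if (any(bad)) y[bad[lo] | bad[hi]] <- sentinel
    out[ch, ] <- y
  }
  recording(out, target_rate, et$channel_labels, et$units)
}

#' Merge eye-tracking channels into the EEG recording
#'
#' Upsamples the ET stream to the EEG rate, shifts it by the fitted
#' mapping, appends the ET channels to the EEG data (sentinel-padded where
#' the ET stream does not cover the EEG span), and expresses ET events on
#' the EEG timeline.
#'
#' @param eeg,et [recording()]s
#' @param mapping `"coreg_mapping"` from [estimate_offset()]
#' @param et_events optional [event_table()] on the ET timeline
#' @param sentinel dropout/padding value
#' @return list of class `"coreg_session"`: `eeg` (recording with appended
#'   channels), `events` (mapped ET events or `NULL`), `mapping`
#' @export
merge_streams <- function(eeg, et, mapping, et_events = NULL,
                          sentinel = DROPOUT_SENTINEL) {
  up <- upsample_et(et, eeg$rate, sentinel = sentinel)
  n <- n_samples(eeg)
  out <- matrix(sentinel, nrow(up$data), n)
  # ET upsampled sample u sits at EEG sample offset + scale*(u-1)/scale ...
  # equivalently: original ET sample s maps to offset + scale*s; upsampled
  # index u corresponds to ET sample 1 + (u-1)*et$rate/eeg$rate
  u_idx <- seq_len(n_samples(up))
  eeg_pos <- round_half_away(mapping$offset +
    mapping$scale * (1 + (u_idx - 1) * et$rate / eeg$rate))
  okk <- eeg_pos >= 1 & eeg_pos <= n
  out[, eeg_pos[okk]] <- up$data[, okk, drop = FALSE]
  merged <- recording(rbind(eeg$data, out), eeg$rate,
                      c(eeg$channel_labels, up$channel_labels),
                      c(eeg$units, up$units))
  ev <- NULL
  if (!is.null(et_events) && nrow(et_events)) {
    ms <- map_to_eeg(mapping, et_events$sample)
    if (any(ms < 1 | ms > n))
      stop("mapping sends ", sum(ms < 1 | ms > n),
           " event(s) outside the EEG span")
    o <- order(ms)
    ev <- event_table(ms[o], et_events$label[o], et_events$attributes[o])
  }
  structure(list(eeg = merged, events = ev, mapping = mapping),
            class = "coreg_session")
}
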