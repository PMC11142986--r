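# Blink interpolation, adaptive velocity-based saccade detection,
# fixation derivation, AOI assignment and gaze metrics.
#
# Event convention: spans are [onset, offset) in 1-based sample indices,
# so duration_ms = (offset - onset) / rate * 1000 and adjacent events may
# share a boundary without overlapping.

#' Area of interest
#'
#' A labelled screen rectangle (pixels, origin top-left). Containment is
#' half-open on the max edges: a point on `x1` or `y1` is outside.
#'
#' @param label AOI label (`"text"`, `"picture"`, ...)
#' @param rect numeric `c(x0, y0, x1, y1)` with `x0 < x1`, `y0 < y1`
#' @return list of class `"coreg_aoi"`
#' @export
aoi <- function(label, rect) {
  stopifnot(length(rect) == 4, rect[1] < rect[3], rect[2] < rect[4])
  structure(list(label = label, rect = as.numeric(rect)), class = "coreg_aoi")
}

#' Interpolate blink dropouts in a pupil trace
#'
#' Each maximal dropout-sentinel run, extended by `pad_ms` on both sides
#' (to cover the partial-occlusion shoulders around a blink), is replaced
#' by linear interpolation between the surrounding valid samples; runs
#' touching a recording edge are filled with the nearest valid value. All
#' samples outside the padded runs are returned bit-identical.
#'
#' @param pupil numeric pupil trace using `sentinel` for lost samples
#' @param rate sampling rate in Hz
#' @param pad_ms padding applied to each side of a dropout run
#' @param sentinel dropout value (default 0)
#' @return list: `pupil` (repaired trace), `blinks` (data.frame `onset`,
#'   `offset` of the unpadded sentinel runs)
#' @export
interpolate_blinks <- function(pupil, rate, pad_ms = 50,
                               sentinel = DROPOUT_SENTINEL) {
  n <- length(pupil)
  bad <- pupil == sentinel
  if (all(bad)) stop("pupil trace is entirely dropout sentinel")
  if (!any(bad))
    return(list(pupil = pupil,
                blinks = data.frame(onset = numeric(0), offset = numeric(0))))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(onset = starts[r$values], offset = ends[r$values] + 1)
  pad <- round(pad_ms / 1000 * rate)
  a <- pmax(1, runs$onset - pad)
  b <- pmin(n + 1, runs$offset + pad)
  # merge padded runs that touch
  keep_from <- c(TRUE, a[-1] > cummax(b[-length(b)]))
  grp <- cumsum(keep_from)
  a <- tapply(a, grp, min); b <- tapply(b, grp, max)
  out <- pupil
  for (i in seq_along(a)) {
    lo <- a[i]; hi <- b[i] - 1
    left <- lo - 1; right <- hi + 1
    if (left >= 1 && right <= n) {
      out[lo:hi] <- out[left] + (out[right] - out[left]) *
        (seq_len(hi - lo + 1)) / (hi - lo + 2)
    } else if (left >= 1) {
      out[lo:hi] <- out[left]
    } else if (right <= n) {
      out[lo:hi] <- out[right]
    }
  }
  list(pupil = out, blinks = runs)
}

# Engbert-style moving-window velocity estimator: for window w = 2m+1,
# v_t = (sum_{k=1..m} x_{t+k} - x_{t-k}) / (m (m+1) dt). Endpoints and
# samples within m of a masked sample are NA.
ek_velocity <- function(x, rate, smooth_window = 5, mask = NULL) {
  n <- length(x)
  m <- (smooth_window - 1) %/% 2
  if (n < smooth_window) stop("trace shorter than smooth_window")
  v <- rep(NA_real_, n)
  num <- numeric(n - 2 * m)
  core <- (m + 1):(n - m)
  for (k in 1:m) num <- num + x[core + k] - x[core - k]
  v[core] <- num / (m * (m + 1)) * rate
  if (!is.null(mask) && any(mask)) {
    spread <- mask
    for (k in 1:m) {
      spread <- spread | c(rep(FALSE, k), mask[1:(n - k)]) |
        c(mask[(k + 1):n], rep(FALSE, k))
    }
    v[spread] <- NA
  }
  v
}

#' Adaptive velocity-based saccade detection
#'
#' Velocities come from a centered moving-window differentiator
#' (`smooth_window` samples). Per-axis adaptive thresholds are
#' `eta = lambda_thresh * sigma` with the median-based scale
#' `sigma = sqrt(median(v^2) - median(v)^2)`; samples with
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` are saccadic. Maximal saccadic runs at
#' least `min_duration_ms` long become events; runs separated by less than
#' one `smooth_window` are merged. Thresholds scale with the data, so the
#' detector is equivariant under `gaze * c` for any `c > 0`.
#'
#' @param gaze_x,gaze_y gaze traces (px or degrees)
#' @param rate sampling rate in Hz
#' @param lambda_thresh threshold multiplier (canonical 6)
#' @param min_duration_ms minimum saccade duration
#' @param smooth_window velocity window length in samples (odd)
#' @param mask logical vector marking invalid samples (blinks/dropouts)
#' @return data.frame: `onset`, `offset` (`[onset, offset)` samples),
#'   `duration_ms`, `peak_velocity` (same spatial unit per second),
#'   `amplitude` (displacement onset to offset)
#' @export
detect_saccades <- function(gaze_x, gaze_y, rate, lambda_thresh = 6,
                            min_duration_ms = 12, smooth_window = 5,
                            mask = NULL) {
  stopifnot(length(gaze_x) == length(gaze_y), lambda_thresh > 0)
  vx <- ek_velocity(gaze_x, rate, smooth_window, mask)
  vy <- ek_velocity(gaze_y, rate, smooth_window, mask)
  ok <- !is.na(vx) & !is.na(vy)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration_ms = numeric(0), peak_velocity = numeric(0),
                      amplitude = numeric(0))
  if (!any(ok)) return(empty)
  sig <- function(v) sqrt(max(median(v[ok]^2) - median(v[ok])^2, 0))
  sx <- sig(vx); sy <- sig(vy)
  if (sx == 0 || sy == 0) {
    message("no gaze velocity variability; returning no saccades")
    return(empty)
  }
  crit <- rep(FALSE, length(gaze_x))
  crit[ok] <- (vx[ok] / (lambda_thresh * sx))^2 +
              (vy[ok] / (lambda_thresh * sy))^2 > 1
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values]; off <- ends[r$values] + 1
  if (!length(on)) return(empty)
  # merge runs separated by less than one smooth_window
  if (length(on) > 1) {
    gap <- on[-1] - off[-length(off)]
    keep_from <- c(TRUE, gap >= smooth_window)
    grp <- cumsum(keep_from)
    on <- as.numeric(tapply(on, grp, min))
    off <- as.numeric(tapply(off, grp, max))
  }
  dur_ms <- (off - on) / rate * 1000
  sel <- dur_ms >= min_duration_ms
  on <- on[sel]; off <- off[sel]; dur_ms <- dur_ms[sel]
  if (!length(on)) return(empty)
  pv <- amp <- numeric(length(on))
  spd <- sqrt(vx^2 + vy^2)
  for (i in seq_along(on)) {
    idx <- on[i]:(off[i] - 1)
    pv[i] <- max(spd[idx], na.rm = TRUE)
    amp[i] <- sqrt((gaze_x[off[i] - 1] - gaze_x[on[i]])^2 +
                   (gaze_y[off[i] - 1] - gaze_y[on[i]])^2)
  }
  data.frame(onset = on, offset = off, duration_ms = dur_ms,
             peak_velocity = pv, amplitude = amp)
}

#' Derive fixations as the complement of saccades and blinks
#'
#' Fixations are the intervals of the session span not covered by a
#' saccade or a blink, dropping pieces shorter than `min_fix_ms`.
#' Centroids are the mean gaze over the interval (dropout samples
#' excluded).
#'
#' @param saccades,blinks data.frames with `onset`, `offset` (may be empty)
#' @param rate sampling rate in Hz
#' @param session_span `c(first_sample, last_sample + 1)` of the span
#' @param min_fix_ms minimum fixation duration
#' @param gaze_x,gaze_y optional gaze traces for centroids
#' @param sentinel dropout value excluded from centroids
#' @return data.frame: `onset`, `offset`, `duration_ms`, `x`, `y`
#' @export
derive_fixations <- function(saccades, blinks, rate, session_span,
                             min_fix_ms = 50, gaze_x = NULL, gaze_y = NULL,
                             sentinel = DROPOUT_SENTINEL) {
  ev <- rbind(saccades[, c("onset", "offset")],
              blinks[, c("onset", "offset"), drop = FALSE])
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$onset[-1] < ev$offset[-nrow(ev)]))
    stop("overlapping input events")
  lo <- session_span[1]; hi <- session_span[2]
  bounds_on <- c(lo, ev$offset)
  bounds_off <- c(ev$onset, hi)
  keep <- bounds_off > bounds_on
  on <- bounds_on[keep]; off <- bounds_off[keep]
  dur <- (off - on) / rate * 1000
  sel <- dur >= min_fix_ms
  on <- on[sel]; off <- off[sel]; dur <- dur[sel]
  cx <- cy <- rep(NA_real_, length(on))
  if (!is.null(gaze_x)) {
    for (i in seq_along(on)) {
      idx <- on[i]:(off[i] - 1)
      good <- gaze_x[idx] != sentinel | gaze_y[idx] != sentinel
      if (any(good)) {
        cx[i] <- mean(gaze_x[idx][good])
        cy[i] <- mean(gaze_y[idx][good])
      }
    }
  }
  data.frame(onset = on, offset = off, duration_ms = dur, x = cx, y = cy)
}

#' Assign fixations to areas of interest by centroid containment
#'
#' @param fixations data.frame with centroid columns `x`, `y`
#' @param aois list of [aoi()] objects (must be pairwise non-overlapping)
#' @return `fixations` with an added `aoi` column (`NA` when the centroid
#'   is in no AOI)
#' @export
assign_aoi <- function(fixations, aois) {
  if (length(aois) > 1) {
    for (i in seq_along(aois)) for (j in seq_len(i - 1)) {
      a <- aois[[i]]$rect; b <- aois[[j]]$rect
      if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
        stop("overlapping AOIs: ", aois[[i]]$label, " and ", aois[[j]]$label)
    }
  }
  lab <- rep(NA_character_, nrow(fixations))
  for (a in aois) {
    r <- a$rect
    inr <- !is.na(fixations$x) &
      fixations$x >= r[1] & fixations$x < r[3] &
      fixations$y >= r[2] & fixations$y < r[4]
    lab[inr] <- a$label
  }
  fixations$aoi <- lab
  fixations
}

#' Gaze metrics: fixation counts, picture fixation duration, transitions
#'
#' Transitions are *direct switches* between a text fixation and a picture
#' fixation: an adjacent ordered pair in the full, time-ordered fixation
#' sequence whose AOI labels are \{text, picture\} in either order. Any
#' intervening fixation outside both AOIs breaks the switch.
#'
#' @param fixations time-ordered data.frame with `duration_ms` and `aoi`
#' @param text_label,picture_label AOI labels entering the transition rule
#' @return list: `n_fixations_per_aoi` (named counts, `none` for
#'   unassigned), `mean_fixation_duration` (ms, over picture-AOI
#'   fixations; `NaN` when there are none), `n_transitions`
#' @export
gaze_metrics <- function(fixations, text_label = "text",
                         picture_label = "picture") {
  lab <- ifelse(is.na(fixations$aoi), "none", fixations$aoi)
  counts <- table(lab)
  pic <- fixations$duration_ms[lab == picture_label]
  tr <- 0L
  if (length(lab) > 1) {
    a <- lab[-length(lab)]; b <- lab[-1]
    tr <- sum((a == text_label & b == picture_label) |
              (a == picture_label & b == text_label))
  }
  list(n_fixations_per_aoi = counts,
       mean_fixation_duration = mean(pic),
       n_transitions = as.integer(tr))
}
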