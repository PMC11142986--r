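# Synthetic co-registered EEG + eye-tracking sessions with ground truth.
#
# EEG model: independent 1/f^beta background per scalp channel, plus
# narrow-band-filtered Gaussian noise carriers in the theta and alpha bands
# (noise carriers, not sinusoids, so power rather than phase carries the
# condition effect), each projected across the montage by a fixed
# topography and amplitude-scaled per condition, plus ocular (blink /
# saccade) transients projected with frontal-maximal weights.
#
# ET model: piecewise-constant fixations with bounded uniform jitter,
# raised-cosine saccadic ramps, pupil = baseline + condition offset + slow
# drift, dropout sentinel 0 during blinks.

DROPOUT_SENTINEL <- 0

# --- frequency-domain noise synthesis ---------------------------------------

# Gaussian noise with spectral amplitude shape(f) on the DFT grid,
# analytically scaled to unit variance (so expected band power is exact).
synth_shaped_noise <- function(n, fs, shape_fun) {
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  amp <- shape_fun(f)
  amp[!is.finite(amp)] <- 0
  # analytic variance of the synthesized series: (2/n^2) * sum(amp^2)
  # (Nyquist bin treated as an ordinary bin; negligible for large n)
  s2 <- 2 * sum(amp^2) / n^2
  if (s2 <= 0) return(numeric(n))
  amp <- amp / sqrt(s2)
  re <- rnorm(kmax); im <- rnorm(kmax)
  X <- complex(real = amp * re / sqrt(2), imaginary = amp * im / sqrt(2))
  full <- complex(length.out = n)
  full[2:(kmax + 1)] <- X
  idx <- n:(n - kmax + 2)
  if (kmax >= 2) full[idx] <- Conj(X[1:(kmax - 1)])
  Re(fft(full, inverse = TRUE)) / n
}

bg_shape_fun <- function(beta, f_floor = 1) {
  # 1/f^(beta/2) amplitude, flat below f_floor (mimics high-passed hardware)
  function(f) pmax(f, f_floor)^(-beta / 2)
}

band_shape_fun <- function(band) {
  function(f) as.numeric(f >= band[1] & f <= band[2])
}

# variance fraction of the background spectrum falling inside a band
bg_band_fraction <- function(beta, band, fs, f_floor = 1, df = 0.01) {
  f <- seq(df, fs / 2, by = df)
  s <- bg_shape_fun(beta, f_floor)(f)^2
  sum(s[f >= band[1] & f <= band[2]]) / sum(s)
}

# --- schedule ----------------------------------------------------------------

# condition blocks tiling the session; times in seconds from session start
sim_schedule <- function(config) {
  if (config$task == "reading") {
    block_s <- config$n_paragraphs * config$paragraph_s
    labs <- config$conditions
    onsets_in_block <- (seq_len(config$n_paragraphs) - 1) * config$paragraph_s
    loads <- rep(NA_character_, length(labs))
  } else {
    block_s <- config$n_trials * 2
    grid <- expand.grid(load = config$loads, condition = config$conditions,
                        stringsAsFactors = FALSE)
    labs <- paste(grid$condition, grid$load, sep = "|")
    loads <- grid$load
    onsets_in_block <- (seq_len(config$n_trials) - 1) * 2
  }
  start_s <- (seq_along(labs) - 1) * block_s
  list(block_s = block_s, labels = labs, loads = loads,
       condition = sub("\\|.*$", "", labs),
       start_s = start_s, end_s = start_s + block_s,
       onsets_in_block = onsets_in_block,
       total_s = length(labs) * block_s)
}

# --- gaze process ------------------------------------------------------------

rect_point <- function(rect) c(runif(1, rect[1], rect[3]),
                               runif(1, rect[2], rect[4]))

# build the fixation/saccade event plan for the whole session
sim_gaze_plan <- function(config, sched) {
  fr <- config$et_rate
  total_s <- sched$total_s
  text <- config$aoi_layout$text
  pict <- config$aoi_layout$picture
  fix <- list(); sac <- list()
  t <- 0
  p <- c(mean(text[c(1, 3)]), mean(text[c(2, 4)]))
  i <- 0
  while (t < total_s) {
    i <- i + 1
    dur <- max(0.08, rgamma(1, shape = config$fixation_duration[["shape"]],
                            scale = config$fixation_duration[["scale"]]) / 1000)
    dur <- min(dur, total_s - t)
    fix[[i]] <- c(onset = t, offset = t + dur, x = p[1], y = p[2])
    t <- t + dur
    if (t >= total_s) break
    # which condition are we in? picture AOI only exists in picture blocks
    blk <- findInterval(t, sched$start_s)
    has_pic <- sched$condition[max(blk, 1)] != "NC"
    to_pic <- has_pic && runif(1) < config$p_picture_fixation
    if (to_pic && !point_in_rect(p, pict)) {
      q <- rect_point(pict)
    } else if (!to_pic && point_in_rect(p, pict)) {
      q <- rect_point(text)
    } else {
      amp_deg <- max(0.5, rgamma(1, shape = config$saccade_amplitude[["shape"]],
                                 scale = config$saccade_amplitude[["scale"]]))
      step <- amp_deg * config$px_per_deg
      home <- if (point_in_rect(p, pict)) pict else text
      ang <- runif(1, 0, 2 * pi)
      q <- p + step * c(cos(ang), sin(ang))
      q[1] <- min(max(q[1], home[1]), home[3] - 1e-9)
      q[2] <- min(max(q[2], home[2]), home[4] - 1e-9)
    }
    # enforce a minimum step so every saccade clears the fixational-jitter
    # velocity floor (AOI-edge clamping can otherwise collapse a step)
    min_px <- 0.5 * config$px_per_deg
    d <- q - p
    if (sqrt(sum(d^2)) < min_px) {
      dir <- if (sum(d^2) > 0) d / sqrt(sum(d^2)) else {
        ang <- runif(1, 0, 2 * pi); c(cos(ang), sin(ang))
      }
      q <- p + dir * min_px
    }
    amp_px <- sqrt(sum((q - p)^2))
    amp_deg <- amp_px / config$px_per_deg
    sdur <- min(0.080, max(0.020, (20 + 2.0 * amp_deg) / 1000))
    sdur <- min(sdur, total_s - t)
    sac[[length(sac) + 1]] <- c(onset = t, offset = t + sdur,
                                x0 = p[1], y0 = p[2], x1 = q[1], y1 = q[2],
                                amplitude_px = amp_px, amplitude_deg = amp_deg,
                                peak_velocity = if (sdur > 0) 2 * amp_px / sdur else 0)
    t <- t + sdur
    p <- q
  }
  list(fixations = do.call(rbind, fix), saccades = do.call(rbind, sac))
}

point_in_rect <- function(p, r) p[1] >= r[1] && p[1] < r[3] &&
  p[2] >= r[2] && p[2] < r[4]

# place blinks strictly inside sufficiently long fixations
sim_blinks <- function(config, plan, total_s) {
  n_target <- rbinom(1, size = round(total_s / 60 * config$blink_rate * 2),
                     prob = 0.5)
  fixd <- plan$fixations
  durs <- fixd[, "offset"] - fixd[, "onset"]
  margin <- 0.06
  out <- list()
  used <- rep(FALSE, nrow(fixd))
  for (b in seq_len(n_target)) {
    bd <- runif(1, config$blink_duration_ms[1], config$blink_duration_ms[2]) / 1000
    ok <- which(!used & durs > bd + 2 * margin)
    if (!length(ok)) break
    j <- if (length(ok) == 1) ok else sample(ok, 1)
    used[j] <- TRUE
    lo <- fixd[j, "onset"] + margin
    hi <- fixd[j, "offset"] - margin - bd
    on <- runif(1, lo, hi)
    out[[length(out) + 1]] <- c(onset = on, offset = on + bd)
  }
  if (!length(out)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("onset", "offset"))))
  m <- do.call(rbind, out)
  m[order(m[, "onset"]), , drop = FALSE]
}

# raised-cosine position ramp: x(u) = u - sin(2*pi*u)/(2*pi), u in [0,1]
raised_cosine_ramp <- function(u) u - sin(2 * pi * u) / (2 * pi)

# render gaze traces (no dropouts) on the ET session grid
render_gaze <- function(config, plan, n_et_sess) {
  fr <- config$et_rate
  gx <- numeric(n_et_sess); gy <- numeric(n_et_sess)
  fixd <- plan$fixations
  for (i in seq_len(nrow(fixd))) {
    a <- floor(fixd[i, "onset"] * fr) + 1
    b <- min(ceiling(fixd[i, "offset"] * fr), n_et_sess)
    if (a > b) next
    gx[a:b] <- fixd[i, "x"]; gy[a:b] <- fixd[i, "y"]
  }
  sacd <- plan$saccades
  for (i in seq_len(nrow(sacd))) {
    a <- floor(sacd[i, "onset"] * fr) + 1
    b <- min(ceiling(sacd[i, "offset"] * fr), n_et_sess)
    if (a > b) next
    tt <- ((a:b) - 1) / fr
    u <- (tt - sacd[i, "onset"]) / (sacd[i, "offset"] - sacd[i, "onset"])
    u <- pmin(pmax(u, 0), 1)
    r <- raised_cosine_ramp(u)
    gx[a:b] <- sacd[i, "x0"] + (sacd[i, "x1"] - sacd[i, "x0"]) * r
    gy[a:b] <- sacd[i, "y0"] + (sacd[i, "y1"] - sacd[i, "y0"]) * r
  }
  jit <- config$gaze_jitter_px
  gx <- gx + runif(n_et_sess, -jit, jit)
  gy <- gy + runif(n_et_sess, -jit, jit)
  list(x = gx, y = gy)
}

# --- EEG ocular trace --------------------------------------------------------

# EOG in microvolts at the frontal-maximum site: gaze-angle component plus
# blink bumps (raised cosine)
render_eog <- function(config, gaze_clean_x, blinks_s, n_eeg, eog_gain_uv_deg = 10,
                       blink_amp_uv = 150) {
  fe <- config$eeg_rate
  fr <- config$et_rate
  t_eeg <- (seq_len(n_eeg) - 1) / fe
  t_et <- (seq_along(gaze_clean_x) - 1) / fr
  gx <- approx(t_et, gaze_clean_x, xout = t_eeg, rule = 2)$y
  eog <- (gx - mean(gx)) / config$px_per_deg * eog_gain_uv_deg
  for (i in seq_len(nrow(blinks_s))) {
    a <- floor(blinks_s[i, "onset"] * fe) + 1
    b <- min(ceiling(blinks_s[i, "offset"] * fe), n_eeg)
    if (a > b) next
    u <- seq(0, 1, length.out = b - a + 1)
    eog[a:b] <- eog[a:b] + blink_amp_uv * 0.5 * (1 - cos(2 * pi * u))
  }
  eog
}

# --- main entry --------------------------------------------------------------

#' Simulate a co-registered EEG + eye-tracking session
#'
#' Generates one session under a [sim_config()]: the EEG recording, the
#' eye-tracking recording (channels `gaze_x`, `gaze_y`, `pupil_L`,
#' `pupil_R`), trigger event tables for both streams (same labels, matching
#' times up to a uniform jitter of at most `trigger_jitter_max` EEG samples
#' plus the imposed clock offset), and a ground-truth object for recovery
#' tests. Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [sim_config()]
#' @return list with elements `eeg`, `et` ([recording()]s), `eeg_events`,
#'   `et_events` ([event_table()]s) and `truth` (list: `true_fixations`,
#'   `true_saccades`, `true_blinks` in ET samples; `condition_intervals` in
#'   EEG samples; `true_band_power` condition x band x channel;
#'   `stream_offset_ms`, `stream_offset_et`)
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fe <- config$eeg_rate; fr <- config$et_rate
  sched <- sim_schedule(config)
  n_eeg <- round(sched$total_s * fe)
  n_et_sess <- round(sched$total_s * fr)
  off_et <- round(config$stream_offset_ms / 1000 * fr)
  off_ms <- off_et / fr * 1000

  # ---- eye tracking ----
  plan <- sim_gaze_plan(config, sched)
  blinks_s <- sim_blinks(config, plan, sched$total_s)
  g <- render_gaze(config, plan, n_et_sess)
  gx_clean <- g$x; gy_clean <- g$y

  # pupil: baseline + condition offset + slow drift + noise
  t_et <- (seq_len(n_et_sess) - 1) / fr
  cond_at <- sched$condition[pmin(pmax(findInterval(t_et, sched$start_s), 1),
                                  length(sched$labels))]
  drift <- 0.05 * sin(2 * pi * t_et / 61 + runif(1, 0, 2 * pi)) +
           0.03 * sin(2 * pi * t_et / 137 + runif(1, 0, 2 * pi))
  pupil <- config$pupil_baseline +
    as.numeric(config$pupil_load_gain[cond_at]) + drift
  pupil_l <- pupil + runif(n_et_sess, -0.01, 0.01)
  pupil_r <- pupil + runif(n_et_sess, -0.01, 0.01)

  # apply dropouts
  gx <- gx_clean; gy <- gy_clean
  blink_idx <- integer(0)
  for (i in seq_len(nrow(blinks_s))) {
    a <- floor(blinks_s[i, "onset"] * fr) + 1
    b <- min(ceiling(blinks_s[i, "offset"] * fr), n_et_sess)
    if (a <= b) blink_idx <- c(blink_idx, a:b)
  }
  gx[blink_idx] <- DROPOUT_SENTINEL; gy[blink_idx] <- DROPOUT_SENTINEL
  pupil_l[blink_idx] <- DROPOUT_SENTINEL; pupil_r[blink_idx] <- DROPOUT_SENTINEL

  # prepend the clock-offset padding (ET stream starts off_ms early)
  pad <- function(v) c(rep(v[1], off_et), v)
  et_data <- rbind(gaze_x = pad(gx), gaze_y = pad(gy),
                   pupil_L = pad(pupil_l), pupil_R = pad(pupil_r))
  et <- recording(et_data, fr, c("gaze_x", "gaze_y", "pupil_L", "pupil_R"),
                  units = c("px", "px", "au", "au"))

  # ---- EEG ----
  nch <- length(config$channels)
  is_eog_ch <- config$channels == "EOG"
  eeg_data <- matrix(0, nch, n_eeg)
  bg_fun <- bg_shape_fun(config$background_exponent)
  th_fun <- band_shape_fun(config$theta_band)
  al_fun <- band_shape_fun(config$alpha_band)
  mult <- config$condition_power_multipliers
  for (b in seq_along(sched$labels)) {
    a0 <- round(sched$start_s[b] * fe) + 1
    a1 <- round(sched$end_s[b] * fe)
    L <- a1 - a0 + 1
    cond <- sched$condition[b]
    th <- synth_shaped_noise(L, fe, th_fun) *
      config$carrier_rms[["theta"]] * mult[cond, "theta"]
    al <- synth_shaped_noise(L, fe, al_fun) *
      config$carrier_rms[["alpha"]] * mult[cond, "alpha"]
    blk <- outer(config$theta_topography, th) +
           outer(config$alpha_topography, al)
    for (ch in which(!is_eog_ch))
      blk[ch, ] <- blk[ch, ] + config$background_rms * synth_shaped_noise(L, fe, bg_fun)
    eeg_data[, a0:a1] <- blk
  }
  eog <- render_eog(config, gx_clean, blinks_s, n_eeg)
  eeg_data <- eeg_data + outer(config$eog_topography, eog)
  if (any(is_eog_ch))
    eeg_data[is_eog_ch, ] <- 1.25 * eog + rnorm(n_eeg, sd = 2)
  eeg <- recording(eeg_data, fe, config$channels, units = "uV")

  # ---- triggers ----
  onsets_s <- as.vector(outer(sched$onsets_in_block, sched$start_s, `+`))
  ord <- order(onsets_s)
  onsets_s <- onsets_s[ord]
  blk_of <- rep(seq_along(sched$labels), each = length(sched$onsets_in_block))[ord]
  # snap onsets to the ET grid so both streams can represent them exactly
  onsets_s <- round(onsets_s * fr) / fr
  labels <- paste0(sched$labels[blk_of], "_s",
                   ave(onsets_s, blk_of, FUN = seq_along))
  j <- config$trigger_jitter_max
  jit <- if (j > 0) sample(-j:j, length(onsets_s), replace = TRUE) else
    rep(0L, length(onsets_s))
  eeg_samp <- pmax(1, round(onsets_s * fe) + 1 + jit)
  et_samp <- round(onsets_s * fr) + 1 + off_et
  attrs <- lapply(seq_along(onsets_s), function(i) {
    a <- list(condition = sched$condition[blk_of[i]])
    if (!is.na(sched$loads[blk_of[i]])) a$load <- sched$loads[blk_of[i]]
    if (config$task == "nback") {
      a$target <- NA  # filled by simulate_nback_block when used standalone
    }
    a
  })
  o2 <- order(eeg_samp)
  eeg_events <- event_table(eeg_samp[o2], labels[o2], attrs[o2])
  eeg_events <- mark_nback_trials(eeg_events, config)
  et_events <- event_table(et_samp, labels, attrs)
  et_events <- mark_nback_trials(et_events, config)

  # ---- ground truth ----
  # event spans are [onset, offset) in 1-based ET-stream samples
  to_et <- function(x) round(x * fr) + 1 + off_et
  fixd <- split_fix_at_blinks(plan$fixations, blinks_s, min_piece_s = 0.05)
  true_fixations <- data.frame(
    onset = to_et(fixd[, "onset"]), offset = to_et(fixd[, "offset"]),
    x = fixd[, "x"], y = fixd[, "y"])
  sacd <- plan$saccades
  true_saccades <- data.frame(
    onset = to_et(sacd[, "onset"]), offset = to_et(sacd[, "offset"]),
    amplitude_px = sacd[, "amplitude_px"],
    amplitude_deg = sacd[, "amplitude_deg"],
    peak_velocity = sacd[, "peak_velocity"])
  true_blinks <- if (nrow(blinks_s)) data.frame(
    onset = to_et(blinks_s[, "onset"]),
    offset = to_et(blinks_s[, "offset"])) else
    data.frame(onset = numeric(0), offset = numeric(0))
  condition_intervals <- data.frame(
    start = round(sched$start_s * fe) + 1, end = round(sched$end_s * fe),
    condition = sched$condition, label = sched$labels,
    load = sched$loads, stringsAsFactors = FALSE)

  truth <- list(
    true_fixations = true_fixations, true_saccades = true_saccades,
    true_blinks = true_blinks, condition_intervals = condition_intervals,
    true_band_power = expected_band_power(config),
    stream_offset_ms = off_ms, stream_offset_et = off_et)

  list(eeg = eeg, et = et, eeg_events = eeg_events, et_events = et_events,
       truth = truth)
}

# split planned fixations at the blinks they host; drop tiny remnants
split_fix_at_blinks <- function(fixd, blinks_s, min_piece_s = 0.05) {
  if (!nrow(blinks_s)) return(fixd)
  out <- list()
  for (i in seq_len(nrow(fixd))) {
    a <- fixd[i, "onset"]; b <- fixd[i, "offset"]
    inside <- blinks_s[blinks_s[, "onset"] >= a & blinks_s[, "offset"] <= b, ,
                       drop = FALSE]
    cuts <- rbind(c(a, a), inside[order(inside[, 1]), , drop = FALSE], c(b, b))
    for (k in seq_len(nrow(cuts) - 1)) {
      lo <- cuts[k, 2]; hi <- cuts[k + 1, 1]
      if (hi - lo >= min_piece_s)
        out[[length(out) + 1]] <- c(onset = unname(lo), offset = unname(hi),
                                    x = unname(fixd[i, "x"]),
                                    y = unname(fixd[i, "y"]))
    }
  }
  do.call(rbind, out)
}

# flag one-third of n-back trials as targets and mark response correctness
mark_nback_trials <- function(events, config) {
  if (config$task != "nback" || !nrow(events)) return(events)
  blocks <- sub("_s[0-9]+$", "", events$label)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    n <- length(idx)
    n_t <- round(n / 3)
    tgt <- rep(FALSE, n)
    tgt[sample(n, n_t)] <- TRUE
    corr <- runif(n) < config$nback_accuracy
    for (k in seq_len(n)) {
      events$attributes[[idx[k]]]$target <- tgt[k]
      events$attributes[[idx[k]]]$correct <- corr[k]
    }
  }
  events
}

#' Simulate one n-back block event table
#'
#' 60 stimulus onsets (by default) spaced exactly 2000 ms apart (500 ms
#' word + 1500 ms fixation cross), exactly one-third of them targets in
#' pseudo-random order, each trial carrying a simulated correctness flag.
#'
#' @param config a [sim_config()] with `task = "nback"`
#' @param rate sample rate of the timeline the events live on (default
#'   `config$eeg_rate`)
#' @param start_s block start time in seconds
#' @return an [event_table()] with attributes `target` and `correct`
#' @export
simulate_nback_block <- function(config, rate = config$eeg_rate, start_s = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (config$task != "nback") stop("simulate_nback_block requires task = 'nback'")
  set.seed(config$seed)
  n <- config$n_trials
  onsets <- start_s + (seq_len(n) - 1) * 2
  n_t <- round(n / 3)
  tgt <- rep(FALSE, n)
  tgt[sample(n, n_t)] <- TRUE
  corr <- runif(n) < config$nback_accuracy
  attrs <- lapply(seq_len(n), function(k)
    list(target = tgt[k], correct = corr[k]))
  event_table(round(onsets * rate) + 1,
              sprintf("trial_%02d", seq_len(n)), attrs)
}
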