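#' Simulation configuration
#'
#' Parameters of the synthetic co-registered EEG + eye-tracking session
#' generator. Defaults reproduce the recording situation the analysis
#' targets: 31-channel EEG (30 scalp 10/20 electrodes + a synthetic ocular
#' reference) at 1000 Hz, binocular-style eye tracking at 250 Hz, four
#' decorative-picture conditions (CC, IC, DC, NC), theta 4-6 Hz
#' (frontal-midline-maximal) and alpha 8-13 Hz (parietal-maximal)
#' oscillations riding on 1/f background noise, ocular artifacts with
#' frontal topography, a fixation-saccade gaze process over text and
#' picture areas of interest, and a pupil trace with load-dependent offsets
#' and blink dropouts (dropout sentinel = 0).
#'
#' `condition_power_multipliers` is a conditions x bands (`theta`, `alpha`)
#' matrix of *amplitude* multipliers relative to 1.0; band power scales
#' with the square. All multipliers equal to 1 gives a null simulation.
#'
#' @param seed integer RNG seed
#' @param n_subjects number of subjects (used by the pipeline driver)
#' @param conditions condition labels
#' @param task `"reading"` or `"nback"`
#' @param eeg_rate,et_rate sampling rates in Hz; `et_rate <= eeg_rate`
#' @param channels montage channel labels (last may be `"EOG"`)
#' @param theta_band,alpha_band frequency band edges in Hz
#' @param theta_topography,alpha_topography,eog_topography nonnegative
#'   per-channel weights; defaults from [default_topographies()]
#' @param background_exponent spectral slope beta of the 1/f^beta background
#' @param background_rms background noise RMS per channel, microvolts
#' @param carrier_rms named amplitudes (microvolts RMS at the
#'   topography-maximum channel) of the theta and alpha carriers
#' @param condition_power_multipliers conditions x bands amplitude matrix
#' @param blink_rate blinks per minute
#' @param blink_duration_ms range of blink durations
#' @param fixation_duration gamma `shape`/`scale` (ms) of fixation durations
#' @param saccade_amplitude gamma `shape`/`scale` (degrees) of saccade steps
#' @param px_per_deg pixels per degree of visual angle
#' @param gaze_jitter_px half-width of the bounded uniform fixational jitter
#' @param aoi_layout list with `text` and `picture` rectangles
#'   (`c(x0, y0, x1, y1)` px, origin top-left, half-open max edges)
#' @param p_picture_fixation probability a fixation targets the picture AOI
#'   (picture conditions only)
#' @param pupil_baseline pupil size baseline, arbitrary units
#' @param pupil_load_gain named per-condition pupil offsets
#' @param trigger_jitter_max max |trigger jitter| in EEG samples
#' @param stream_offset_ms imposed EEG-to-ET clock lag (rounded to the ET
#'   sample grid)
#' @param n_paragraphs paragraphs per reading condition block
#' @param paragraph_s seconds per paragraph (self-paced reading dwell)
#' @param n_trials trials per n-back block (onsets every 2 s)
#' @param loads n-back load labels
#' @param nback_accuracy probability a trial is answered correctly
#' @return an object of class `"sim_config"`
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 1L,
                       conditions = c("CC", "IC", "DC", "NC"),
                       task = c("reading", "nback"),
                       eeg_rate = 1000,
                       et_rate = 250,
                       channels = default_montage()$label,
                       theta_band = c(4, 6),
                       alpha_band = c(8, 13),
                       theta_topography = NULL,
                       alpha_topography = NULL,
                       eog_topography = NULL,
                       background_exponent = 1,
                       background_rms = 10,
                       carrier_rms = c(theta = 3, alpha = 4),
                       condition_power_multipliers = NULL,
                       blink_rate = 15,
                       blink_duration_ms = c(100, 250),
                       fixation_duration = c(shape = 4, scale = 62.5),
                       saccade_amplitude = c(shape = 2, scale = 2),
                       px_per_deg = 45.3,
                       gaze_jitter_px = 1.5,
                       aoi_layout = NULL,
                       p_picture_fixation = 0.15,
                       pupil_baseline = 4,
                       pupil_load_gain = NULL,
                       trigger_jitter_max = 3L,
                       stream_offset_ms = 400,
                       n_paragraphs = 20L,
                       paragraph_s = 20,
                       n_trials = 60L,
                       loads = c("0back", "2back"),
                       nback_accuracy = 0.9) {
  task <- match.arg(task)
  if (eeg_rate <= 0 || et_rate <= 0) stop("sampling rates must be positive")
  if (et_rate > eeg_rate) stop("et_rate must not exceed eeg_rate")
  if (trigger_jitter_max < 0) stop("trigger_jitter_max must be >= 0")
  for (b in list(theta = theta_band, alpha = alpha_band)) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop("bands must be increasing positive Hz pairs")
    if (b[2] >= min(eeg_rate, et_rate) / 2)
      stop("band edge ", b[2], " Hz exceeds Nyquist at the lower rate (",
           min(eeg_rate, et_rate) / 2, " Hz)")
  }
  mont <- default_montage()
  mont <- mont[match(channels, mont$label), , drop = FALSE]
  if (anyNA(mont$x)) {
    # unknown labels: fall back to flat unit weights unless given explicitly
    mont$x[is.na(mont$x)] <- 0
    mont$y[is.na(mont$y)] <- 0
    mont$label <- channels
  }
  topo <- default_topographies(mont)
  theta_topography <- theta_topography %||% topo$theta
  alpha_topography <- alpha_topography %||% topo$alpha
  eog_topography <- eog_topography %||% topo$eog
  stopifnot(length(theta_topography) == length(channels),
            length(alpha_topography) == length(channels),
            length(eog_topography) == length(channels),
            all(theta_topography >= 0), all(alpha_topography >= 0))
  if (is.null(condition_power_multipliers)) {
    condition_power_multipliers <- matrix(
      1, length(conditions), 2,
      dimnames = list(conditions, c("theta", "alpha")))
  }
  condition_power_multipliers <- as.matrix(condition_power_multipliers)
  if (!all(condition_power_multipliers > 0))
    stop("condition_power_multipliers must be > 0")
  if (nrow(condition_power_multipliers) != length(conditions))
    stop("condition_power_multipliers needs one row per condition")
  if (is.null(rownames(condition_power_multipliers)))
    rownames(condition_power_multipliers) <- conditions
  if (is.null(colnames(condition_power_multipliers)))
    colnames(condition_power_multipliers) <- c("theta", "alpha")
  if (is.null(aoi_layout)) {
    # 1920 x 1200 screen; 580-px-wide centered text area, 400 x 300 picture
    # to the right of it
    aoi_layout <- list(text = c(670, 450, 1250, 750),
                       picture = c(1270, 450, 1670, 750))
  }
  if (is.null(pupil_load_gain))
    pupil_load_gain <- stats::setNames(rep(0, length(conditions)), conditions)
  cfg <- list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    conditions = conditions, task = task,
    eeg_rate = eeg_rate, et_rate = et_rate, channels = channels,
    montage = mont,
    theta_band = theta_band, alpha_band = alpha_band,
    theta_topography = theta_topography, alpha_topography = alpha_topography,
    eog_topography = eog_topography,
    background_exponent = background_exponent,
    background_rms = background_rms, carrier_rms = carrier_rms,
    condition_power_multipliers = condition_power_multipliers,
    blink_rate = blink_rate, blink_duration_ms = blink_duration_ms,
    fixation_duration = fixation_duration,
    saccade_amplitude = saccade_amplitude,
    px_per_deg = px_per_deg, gaze_jitter_px = gaze_jitter_px,
    aoi_layout = aoi_layout, p_picture_fixation = p_picture_fixation,
    pupil_baseline = pupil_baseline, pupil_load_gain = pupil_load_gain,
    trigger_jitter_max = as.integer(trigger_jitter_max),
    stream_offset_ms = stream_offset_ms,
    n_paragraphs = as.integer(n_paragraphs), paragraph_s = paragraph_s,
    n_trials = as.integer(n_trials), loads = loads,
    nback_accuracy = nback_accuracy)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> task=%s, %d channels @ %g Hz EEG / %g Hz ET, conditions: %s\n",
              x$task, length(x$channels), x$eeg_rate, x$et_rate,
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}
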