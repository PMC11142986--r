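# End-to-end orchestration: simulate -> sync -> gaze events -> EEG clean ->
# band power / ERD-ERS% -> statistics, with provenance logging and
# deterministic outputs.

#' Pipeline run configuration
#'
#' Every analysis parameter is surfaced with its canonical default: 2 s
#' epochs, +/-100 uV rejection, 500 ms Hanning windows on a 0.125 Hz grid,
#' theta 4-6 Hz at Fz, alpha 8-13 Hz at Pz, lambda = 6 saccade threshold,
#' alpha level 0.05.
#'
#' @param ... overrides of the defaults (unknown names are an error);
#'   `sim` is a list passed on to [sim_config()]
#' @return list of class `"run_config"`
#' @export
run_config <- function(...) {
  cfg <- list(
    n_subjects = 8L,
    seed = 1L,
    task = "reading",
    analysis = "both",            # stimulus | fixation | both
    sim = list(),                 # sim_config() overrides
    hp_hz = 0.25, lp_hz = 48,
    do_eog_removal = TRUE, eog_corr_threshold = 0.7,
    reject_uv = 100,
    epoch_length_s = 2,
    max_jitter = NULL,            # default: 2 * trigger jitter bound
    lambda_thresh = 6, min_saccade_ms = 12, smooth_window = 5,
    min_fix_ms = 50, blink_pad_ms = 50,
    channels_of_interest = c(theta = "Fz", alpha = "Pz"),
    alpha_level = 0.05,
    do_topo = TRUE, topo_pair = c("DC", "NC"), n_perm = 1999,
    do_rmcorr = TRUE, do_pupil = TRUE,
    min_anchor_gap = NULL,
    epoch_weighted_baseline = FALSE,
    out_dir = NULL, verbose = FALSE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' @param path file path (`.yaml`/`.yml` needs the yaml package)
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(lst$channels_of_interest))
    lst$channels_of_interest <- unlist(lst$channels_of_interest)
  do.call(run_config, lst)
}

# condition intervals from the stimulus trigger table: per contiguous
# condition run, [first onset, last onset + median spacing)
derive_condition_intervals <- function(events, rate) {
  cond <- vapply(events$attributes, function(a)
    a$condition %||% NA_character_, character(1))
  load <- vapply(events$attributes, function(a)
    a$load %||% NA_character_, character(1))
  lab <- ifelse(is.na(load), cond, paste(cond, load, sep = "|"))
  runs <- rle(lab)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  spacing <- median(diff(events$sample[starts[1]:ends[1]]))
  data.frame(start = events$sample[starts],
             end = events$sample[ends] + spacing - 1,
             condition = lab[starts],
             stringsAsFactors = FALSE)
}

# per-subject processing; returns tidy pieces
process_subject <- function(subj, cfg) {
  sim_args <- utils::modifyList(
    list(seed = cfg$seed + subj, task = cfg$task), cfg$sim)
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_session(scfg)
  fe <- scfg$eeg_rate; fr <- scfg$et_rate
  max_jitter <- cfg$max_jitter %||% (2 * scfg$trigger_jitter_max)
  mapping <- estimate_offset(sim$eeg_events, sim$et_events, max_jitter)

  # ---- gaze events (native ET timeline) ----
  pup <- interpolate_blinks(sim$et$data["pupil_L", ], fr,
                            pad_ms = cfg$blink_pad_ms)
  blinks <- pup$blinks
  mask <- rep(FALSE, n_samples(sim$et))
  for (i in seq_len(nrow(blinks)))
    mask[blinks$onset[i]:(blinks$offset[i] - 1)] <- TRUE
  gx <- sim$et$data["gaze_x", ]; gy <- sim$et$data["gaze_y", ]
  sacc <- detect_saccades(gx, gy, fr, lambda_thresh = cfg$lambda_thresh,
                          min_duration_ms = cfg$min_saccade_ms,
                          smooth_window = cfg$smooth_window, mask = mask)
  fix <- derive_fixations(sacc, blinks, fr, c(1, n_samples(sim$et) + 1),
                          min_fix_ms = cfg$min_fix_ms, gaze_x = gx, gaze_y = gy)
  aois <- list(aoi("text", scfg$aoi_layout$text),
               aoi("picture", scfg$aoi_layout$picture))
  fix <- assign_aoi(fix, aois)
  gm <- gaze_metrics(fix)

  # ---- EEG cleaning ----
  eeg <- fir_filter(sim$eeg, cfg$hp_hz, cfg$lp_hz)
  eog_report <- NULL
  if (cfg$do_eog_removal && "EOG" %in% eeg$channel_labels) {
    cleaned <- remove_eog(eeg, "EOG", cfg$eog_corr_threshold,
                          seed = cfg$seed + subj)
    eeg <- cleaned$recording
    eog_report <- cleaned$report
  }
  eeg <- rereference_average(eeg, exclude_labels = intersect(
    "EOG", eeg$channel_labels))
  intervals <- derive_condition_intervals(sim$eeg_events, fe)

  bands <- list(theta = scfg$theta_band, alpha = scfg$alpha_band)
  analyses <- if (cfg$analysis == "both") c("stimulus", "fixation") else cfg$analysis
  if (cfg$task == "nback") analyses <- "stimulus"
  erd_rows <- list(); pupil_rows <- list(); counts <- list()
  excluded <- character(0)

  for (an in analyses) {
    if (an == "stimulus") {
      if (cfg$task == "nback") {
        correct <- vapply(sim$eeg_events$attributes, function(a)
          isTRUE(a$correct), logical(1))
        anchors <- sim$eeg_events$sample[correct]
      } else {
        anchors <- tile_anchors(intervals, fe, cfg$epoch_length_s)$sample
      }
    } else {
      pic_fix <- fix[!is.na(fix$aoi) & fix$aoi == "picture", , drop = FALSE]
      if (!nrow(pic_fix)) { excluded <- c(excluded, an); next }
      anchors <- sort(map_to_eeg(mapping, pic_fix$onset))
      anchors <- anchors[anchors >= 1 & anchors <= n_samples(eeg)]
    }
    es <- extract_epochs(eeg, anchors, intervals, lock = an,
                         length_s = cfg$epoch_length_s,
                         min_anchor_gap = cfg$min_anchor_gap)
    es <- reject_artifacts(es, cfg$reject_uv)
    kept <- which(es$keep)
    tb <- table(factor(es$condition[kept], levels = unique(intervals$condition)))
    counts[[an]] <- setNames(as.integer(tb), names(tb))
    topo_channels <- if (cfg$do_topo) es$channel_labels else
      unique(unname(cfg$channels_of_interest))
    bp <- epoch_set_band_power(es, bands, channels = topo_channels)
    res <- tryCatch({
      lapply(names(bands), function(bn) {
        e <- erd_ers(bp[kept, , bn, drop = TRUE], es$condition[kept],
                     conditions = unique(intervals$condition),
                     epoch_weighted = cfg$epoch_weighted_baseline)
        data.frame(subject = subj, task = cfg$task, analysis = an, band = bn,
                   condition = rep(e$conditions, times = length(topo_channels)),
                   channel = rep(topo_channels, each = length(e$conditions)),
                   value_percent = as.vector(e$values),
                   baseline_power = rep(e$baseline, each = length(e$conditions)),
                   n_epochs = rep(e$n_epochs, times = length(topo_channels)),
                   stringsAsFactors = FALSE)
      })
    }, coregload_no_epochs = function(e) {
      excluded <<- c(excluded, an)
      NULL
    })
    if (is.null(res)) next
    erd_rows[[an]] <- do.call(rbind, res)

    # pupil summaries
    if (!cfg$do_pupil) {
      # skipped (config-gated; saves the ET upsampling pass)
    } else if (an == "stimulus") {
      merged <- merge_streams(eeg, sim$et, mapping)
      pe <- tryCatch(
        interpolate_blinks(merged$eeg$data["pupil_L", ], fe,
                           pad_ms = cfg$blink_pad_ms),
        error = function(e) NULL)
      if (!is.null(pe)) {
        ps <- tryCatch(pupil_summary(pe$pupil, fe, intervals, epochs = es),
                       error = function(e) NULL)
        if (!is.null(ps))
          pupil_rows[[an]] <- data.frame(
            subject = subj, analysis = an, condition = names(ps),
            pupil_mean = as.numeric(ps), stringsAsFactors = FALSE)
      }
    } else {
      et_intervals <- intervals
      et_intervals$start <- floor((intervals$start - mapping$offset) / mapping$scale)
      et_intervals$end <- floor((intervals$end - mapping$offset) / mapping$scale)
      ps <- tryCatch(
        pupil_summary(pup$pupil, fr, et_intervals, fixations = fix),
        error = function(e) NULL)
      if (!is.null(ps))
        pupil_rows[[an]] <- data.frame(
          subject = subj, analysis = an, condition = names(ps),
          pupil_mean = as.numeric(ps), stringsAsFactors = FALSE)
    }
  }

  list(erd = do.call(rbind, erd_rows),
       pupil = do.call(rbind, pupil_rows),
       gaze = data.frame(
         subject = subj,
         n_fix_text = as.integer(gm$n_fixations_per_aoi["text"] %||% 0L),
         n_fix_picture = if ("picture" %in% names(gm$n_fixations_per_aoi))
           as.integer(gm$n_fixations_per_aoi[["picture"]]) else 0L,
         mean_fix_duration_picture = gm$mean_fixation_duration,
         n_transitions = gm$n_transitions),
       counts = counts, excluded = excluded,
       mapping = list(offset = mapping$offset, scale = mapping$scale),
       eog = if (!is.null(eog_report))
         list(removed = length(eog_report$removed),
              converged = eog_report$converged) else NULL)
}

#' Run the full analysis pipeline on simulated subjects
#'
#' Simulates `n_subjects` sessions (seeds `seed + 1 ... seed + n`), runs
#' synchronization, gaze-event detection, EEG cleaning, band power and
#' ERD/ERS%, and the group statistics, and (optionally) writes the tidy
#' result tables plus a provenance log to `out_dir`. Fully deterministic
#' given the config.
#'
#' @param cfg a [run_config()]
#' @return list of class `"coreg_results"`: `erd`, `gaze`, `pupil`,
#'   `anova`, `posthoc`, `topo`, `rmcorr`, `sem`, `provenance`
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  subjects <- seq_len(cfg$n_subjects)
  per <- lapply(subjects, function(s) {
    if (cfg$verbose) message("subject ", s)
    tryCatch(process_subject(s, cfg),
             error = function(e) stop("pipeline failed at subject ", s, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  erd <- do.call(rbind, lapply(per, `[[`, "erd"))
  gaze <- do.call(rbind, lapply(per, `[[`, "gaze"))
  pupil <- do.call(rbind, lapply(per, `[[`, "pupil"))

  anova_rows <- list(); posthoc_rows <- list(); topo_rows <- list()
  sem_rows <- list()
  for (an in unique(erd$analysis)) for (bn in unique(erd$band)) {
    coi <- cfg$channels_of_interest[[bn]]
    sub <- erd[erd$analysis == an & erd$band == bn & erd$channel == coi, ]
    if (!nrow(sub)) next
    # only subjects present in every condition (exclusion rule)
    full <- names(which(table(sub$subject) == length(unique(sub$condition))))
    sub <- sub[sub$subject %in% full, ]
    if (length(unique(sub$subject)) < 3) next
    key <- paste(an, bn, sep = ".")
    if (cfg$task == "nback") {
      sub$DP <- sub("\\|.*$", "", sub$condition)
      sub$load <- sub("^.*\\|", "", sub$condition)
      av <- rm_anova(sub, dv = "value_percent", subject = "subject",
                     within = c("DP", "load"))
    } else {
      av <- rm_anova(sub, dv = "value_percent", subject = "subject",
                     within = "condition")
    }
    av <- cbind(analysis = an, band = bn, channel = coi, av)
    anova_rows[[key]] <- av
    ph <- posthoc_paired_t(sub, dv = "value_percent", subject = "subject",
                           within = "condition")
    posthoc_rows[[key]] <- cbind(analysis = an, band = bn, ph)
    sem <- within_subject_sem(sub, dv = "value_percent", subject = "subject",
                              within = "condition")
    sem_rows[[key]] <- data.frame(analysis = an, band = bn,
                                  condition = names(sem),
                                  sem = as.numeric(sem))
    if (cfg$do_topo && all(cfg$topo_pair %in% sub$condition)) {
      wide <- erd[erd$analysis == an & erd$band == bn &
                  erd$subject %in% full, ]
      chs <- unique(wide$channel)
      mk <- function(cc) {
        w <- wide[wide$condition == cc, ]
        m <- matrix(NA_real_, length(full), length(chs),
                    dimnames = list(full, chs))
        m[cbind(match(as.character(w$subject), full),
                match(w$channel, chs))] <- w$value_percent
        m
      }
      tt <- permutation_topo_test(mk(cfg$topo_pair[1]), mk(cfg$topo_pair[2]),
                                  n_perm = cfg$n_perm, seed = cfg$seed,
                                  alpha = cfg$alpha_level)
      topo_rows[[key]] <- cbind(analysis = an, band = bn, as.data.frame(tt))
    }
  }

  rmcorr_rows <- NULL
  if (cfg$do_rmcorr && !is.null(pupil) && nrow(pupil)) {
    for (bn in unique(erd$band)) {
      coi <- cfg$channels_of_interest[[bn]]
      sub <- erd[erd$analysis == "stimulus" & erd$band == bn &
                 erd$channel == coi, ]
      m <- merge(sub, pupil[pupil$analysis == "stimulus", ],
                 by = c("subject", "condition"))
      if (nrow(m) >= 4 && length(unique(m$subject)) >= 2) {
        rc <- tryCatch(rmcorr(m$subject, m$pupil_mean, m$value_percent),
                       error = function(e) NULL)
        if (!is.null(rc))
          rmcorr_rows <- rbind(rmcorr_rows, data.frame(
            measure_x = "pupil_mean", measure_y = paste0("erd_", bn),
            r = rc$r, df = rc$df, p = rc$p,
            ci_lo = rc$ci95[1], ci_hi = rc$ci95[2]))
      }
    }
    if (!is.null(rmcorr_rows))
      rmcorr_rows$p_bonferroni <- pmin(1, rmcorr_rows$p * nrow(rmcorr_rows))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("coregload")),
    seed = cfg$seed, n_subjects = cfg$n_subjects, task = cfg$task,
    parameters = cfg[c("hp_hz", "lp_hz", "reject_uv", "epoch_length_s",
                       "lambda_thresh", "min_fix_ms", "alpha_level",
                       "n_perm")],
    epoch_counts = lapply(per, `[[`, "counts"),
    excluded_analyses = lapply(per, `[[`, "excluded"),
    mappings = lapply(per, `[[`, "mapping"),
    eog = lapply(per, `[[`, "eog"))

  res <- structure(list(
    erd = erd, gaze = gaze, pupil = pupil,
    anova = do.call(rbind, anova_rows),
    posthoc = do.call(rbind, posthoc_rows),
    topo = do.call(rbind, topo_rows),
    sem = do.call(rbind, sem_rows),
    rmcorr = rmcorr_rows,
    provenance = provenance), class = "coreg_results")
  if (!is.null(cfg$out_dir)) write_results(res, cfg$out_dir)
  res
}

#' Write a results bundle as tidy TSV files plus a provenance JSON
#'
#' @param res a `"coreg_results"` from [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.12g", df[[j]])
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(res$erd, "erd.tsv"); wt(res$gaze, "gaze_metrics.tsv")
  wt(res$pupil, "pupil.tsv"); wt(res$anova, "anova.tsv")
  wt(res$posthoc, "posthoc.tsv"); wt(res$topo, "topo.tsv")
  wt(res$sem, "sem.tsv"); wt(res$rmcorr, "rmcorr.tsv")
  jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
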