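#' Multichannel uniformly sampled recording
#'
#' The basic container for EEG and eye-tracking streams: a channels-by-samples
#' numeric matrix plus sampling rate, channel labels and per-channel units
#' (e.g. `"uV"` for EEG, `"px"` for gaze, `"au"` for pupil size).
#'
#' @param data numeric matrix, channels x samples
#' @param rate sampling rate in Hz (> 0)
#' @param channel_labels character vector, one label per row of `data`
#' @param units character vector, one unit per channel (recycled if length 1)
#' @return an object of class `"coreg_recording"`
#' @export
recording <- function(data, rate, channel_labels, units = "uV") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  units <- rep_len(as.character(units), nrow(data))
  rownames(data) <- channel_labels
  structure(
    list(data = data, rate = as.numeric(rate),
         channel_labels = as.character(channel_labels), units = units),
    class = "coreg_recording")
}

#' @export
print.coreg_recording <- function(x, ...) {
  cat(sprintf("<coreg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Event/trigger table
#'
#' Ordered markers on a recording's sample grid. `sample` indices are
#' 1-based positions into the recording the table belongs to; `attributes`
#' is a list column of per-event metadata (condition, target flags, ...).
#'
#' @param sample numeric vector of 1-based sample indices (nondecreasing)
#' @param label character vector of event labels
#' @param attributes optional list of per-event attribute lists
#' @return data.frame of class `"coreg_events"` with columns `sample`,
#'   `label`, `attributes`
#' @export
event_table <- function(sample, label, attributes = NULL) {
  sample <- as.numeric(sample)
  label <- as.character(label)
  if (length(sample) != length(label))
    stop("sample and label must have equal length")
  if (is.unsorted(sample)) stop("event samples must be nondecreasing")
  if (any(!is.finite(sample)) || any(sample < 1))
    stop("event samples must be finite and >= 1")
  if (is.null(attributes)) attributes <- rep(list(list()), length(sample))
  if (length(attributes) != length(sample))
    stop("attributes must have one entry per event")
  df <- data.frame(sample = sample, label = label, stringsAsFactors = FALSE)
  df$attributes <- attributes
  class(df) <- c("coreg_events", "data.frame")
  df
}

check_events_against <- function(events, rec) {
  if (nrow(events) && max(events$sample) > n_samples(rec))
    stop("event sample ", max(events$sample),
         " beyond recording length ", n_samples(rec))
  invisible(TRUE)
}

#' Read / write recordings in the TSV interchange format
#'
#' One TSV per stream: three header lines `#rate`, `#labels`, `#units`
#' followed by one row per sample (columns = channels). The format is
#' lossless for finite doubles (written with 17 significant digits).
#'
#' @param path file path
#' @return `read_recording` returns a [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3)
    stop("format error at line 1: expected 3 header lines (#rate, #labels, #units)")
  hdr <- strsplit(lines[1:3], "\t", fixed = TRUE)
  if (hdr[[1]][1] != "#rate")
    stop("format error at line 1: expected '#rate'")
  if (hdr[[2]][1] != "#labels")
    stop("format error at line 2: expected '#labels'")
  if (hdr[[3]][1] != "#units")
    stop("format error at line 3: expected '#units'")
  rate <- suppressWarnings(as.numeric(hdr[[1]][2]))
  if (is.na(rate) || rate <= 0)
    stop("format error at line 1: rate must be a positive number")
  labels <- hdr[[2]][-1]
  units <- hdr[[3]][-1]
  if (length(units) != length(labels))
    stop("format error at line 3: ", length(units), " units for ",
         length(labels), " labels")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  nch <- length(labels)
  if (length(body) == 0) {
    dat <- matrix(numeric(0), nrow = nch, ncol = 0)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    widths <- lengths(parts)
    bad <- which(widths != nch)
    if (length(bad))
      stop("format error at line ", bad[1] + 3, ": row has ", widths[bad[1]],
           " fields, expected ", nch)
    vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
    nonnum <- which(is.na(vals))
    if (length(nonnum))
      stop("format error at line ", ceiling(nonnum[1] / nch) + 3,
           ": non-numeric field")
    dat <- matrix(vals, nrow = nch, ncol = length(body))
  }
  recording(dat, rate, labels, units)
}

#' @rdname read_recording
#' @param rec a [recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "coreg_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("#rate\t", format(rec$rate, digits = 17)),
    paste(c("#labels", rec$channel_labels), collapse = "\t"),
    paste(c("#units", rec$units), collapse = "\t")), con)
  if (ncol(rec$data)) {
    txt <- matrix(sprintf("%.17g", rec$data), nrow = nrow(rec$data))
    writeLines(apply(txt, 2, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write event tables as TSV
#'
#' Columns: `sample`, `label`, `attributes` (a JSON object per row).
#'
#' @param path file path
#' @return `read_events` returns an [event_table()].
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "character"))
  attrs <- lapply(df$attributes, function(s)
    if (is.na(s) || s == "" || s == "{}") list()
    else jsonlite::fromJSON(s, simplifyVector = TRUE))
  event_table(df$sample, df$label, attrs)
}

#' @rdname read_events
#' @param events an [event_table()]
#' @export
write_events <- function(events, path) {
  js <- vapply(events$attributes, function(a)
    as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)),
    character(1))
  df <- data.frame(sample = format(events$sample, digits = 17, trim = TRUE),
                   label = events$label, attributes = js,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
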