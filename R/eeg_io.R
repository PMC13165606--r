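#' Construct an EEG recording object
#'
#' A recording is a channels x samples matrix in microvolts plus subject
#' metadata. Rows are ordered as the montage orders its channels.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param subject_id Subject identifier.
#' @param group `"MDD"` (patient) or `"HC"` (healthy control).
#' @param condition `"EC"` (eyes closed) or `"EO"` (eyes open).
#' @param sampling_rate Hz.
#' @param montage An `eeg_montage`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, subject_id, group = c("MDD", "HC"),
                          condition = c("EC", "EO"),
                          sampling_rate = 256,
                          montage = standard_1020_montage(sampling_rate)) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (nrow(data) != length(montage$channel_names))
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$channel_names), " channels")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  rownames(data) <- montage$channel_names
  structure(list(data = data, subject_id = subject_id, group = group,
                 condition = condition, sampling_rate = sampling_rate,
                 montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s [%s/%s]: %d ch x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data),
              ncol(x$data) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

# Reorder a labelled channels x samples matrix into montage order,
# resolving aliases; errors name the missing channel.
.to_montage_order <- function(mat, labels, montage) {
  labels <- normalize_channels(labels)
  canon <- montage$channel_names
  idx <- match(canon, labels)
  if (anyNA(idx))
    stop("recording is missing montage channel(s): ",
         paste(canon[is.na(idx)], collapse = ", "))
  mat[idx, , drop = FALSE]
}

#' Read an EEG recording from disk
#'
#' Supports 16-bit EDF and delimited numeric text (header row of channel
#' labels, one sample per line). Channels are reordered into montage order;
#' modern temporal labels (T7/T8/P7/P8) are accepted as aliases.
#'
#' @param path File path.
#' @param format `"edf"` or `"delimited"`; default guessed from the extension.
#' @param subject_id,group,condition Metadata attached to the recording.
#' @param montage Target montage.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           subject_id = basename(path), group = "MDD",
                           condition = "EC",
                           montage = standard_1020_montage()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (format == "edf") {
    raw <- read_edf(path)
    fs <- raw$sampling_rate
  } else {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
    raw <- list(data = t(as.matrix(tab)), channel_names = colnames(tab))
    fs <- montage$sampling_rate
  }
  mat <- .to_montage_order(raw$data, raw$channel_names, montage)
  eeg_recording(mat, subject_id = subject_id, group = group,
                condition = condition, sampling_rate = fs, montage = montage)
}

#' Write a recording as delimited text
#'
#' Header row of channel labels, one sample per line, tab separated.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_delim <- function(rec, path) {
  tab <- as.data.frame(t(rec$data))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Band-pass and notch filtering
#'
#' Zero-phase filtering as used for resting-state EEG cleanup: a Butterworth
#' band-pass (default 0.5--70 Hz, order 4) followed by a biquad notch at the
#' power-line frequency (default 50 Hz, Q = 30), both applied forward and
#' backward (`signal::filtfilt`) so the output has no phase distortion and the
#' same length as the input.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz.
#' @param notch Notch centre frequency in Hz; `NA` disables the notch.
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 70, notch = 50,
                           notch_q = 30) {
  fs <- rec$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < sampling_rate/2")
  bp <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- rec$data
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bp, ch)))
  if (!is.na(notch) && !is.null(notch)) {
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    out <- t(apply(out, 1, function(ch) signal::filtfilt(b / a[1], a / a[1], ch)))
  }
  rec$data <- out
  rownames(rec$data) <- rec$montage$channel_names
  rec
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels. Provided as a simple
#' standardized reference; off by default in the pipeline.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Extract the centered segment of a recording
#'
#' Cuts the contiguous middle `duration` seconds, the standard way of picking
#' a stationary analysis stretch from a resting-state run.
#'
#' @param rec An `eeg_recording`.
#' @param duration Segment length in seconds (default 180).
#' @return An `eeg_recording` of exactly `duration` seconds.
#' @export
extract_middle_segment <- function(rec, duration = 180) {
  n <- round(duration * rec$sampling_rate)
  s <- ncol(rec$data)
  if (s < n)
    stop("recording is ", s / rec$sampling_rate,
         " s, shorter than requested segment of ", duration, " s")
  offset <- floor((s - n) / 2)
  rec$data <- rec$data[, (offset + 1):(offset + n), drop = FALSE]
  rec
}

#' Cut a recording into fixed-length windows
#'
#' Non-overlapping by default (2 s, the model's classification unit); a
#' trailing remainder shorter than one window is dropped. Windows inherit the
#' recording's subject/group/condition labels.
#'
#' @param rec An `eeg_recording`.
#' @param window_seconds Window length in seconds.
#' @param overlap Overlap between consecutive windows in seconds.
#' @return An object of class `eeg_windows`: list with `x` (channels x T x
#'   n_windows array), `info` (data frame of labels per window),
#'   `sampling_rate` and `montage`.
#' @export
make_windows <- function(rec, window_seconds = 2, overlap = 0) {
  fs <- rec$sampling_rate
  tl <- window_seconds * fs
  if (abs(tl - round(tl)) > 1e-9)
    stop("window_seconds x sampling_rate must be an integer number of samples")
  tl <- as.integer(round(tl))
  step <- as.integer(round((window_seconds - overlap) * fs))
  if (step < 1) stop("overlap must be smaller than the window length")
  s <- ncol(rec$data)
  starts <- seq.int(1L, by = step, length.out = max(0L, (s - tl) %/% step + 1L))
  n <- length(starts)
  x <- array(0, dim = c(nrow(rec$data), tl, n))
  for (i in seq_len(n))
    x[, , i] <- rec$data[, starts[i]:(starts[i] + tl - 1L)]
  info <- data.frame(subject_id = rep(rec$subject_id, n),
                     group = rep(rec$group, n),
                     condition = rep(rec$condition, n),
                     window_index = seq_len(n) - 1L,
                     stringsAsFactors = FALSE)
  structure(list(x = x, info = info, sampling_rate = fs,
                 montage = rec$montage),
            class = "eeg_windows")
}

#' Concatenate window sets
#'
#' @param ... `eeg_windows` objects (or a single list of them).
#' @return A combined `eeg_windows`.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1 && !inherits(ws[[1]], "eeg_windows")) ws <- ws[[1]]
  x <- array(unlist(lapply(ws, `[[`, "x")),
             dim = c(dim(ws[[1]]$x)[1:2], sum(vapply(ws, function(w) dim(w$x)[3], 0))))
  info <- do.call(rbind, lapply(ws, `[[`, "info"))
  rownames(info) <- NULL
  structure(list(x = x, info = info, sampling_rate = ws[[1]]$sampling_rate,
                 montage = ws[[1]]$montage),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("EEG windows: %d windows of %d ch x %d samples (%d subjects)\n",
              d[3], d[1], d[2], length(unique(x$info$subject_id))))
  invisible(x)
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with columns `subject_id`, `group`, `condition`,
#'   `path` (and optionally `format`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Relative recording paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load all recordings listed in a manifest
#'
#' @param manifest Data frame as returned by [read_manifest()].
#' @param montage Target montage.
#' @return List of `eeg_recording` objects.
#' @export
load_cohort <- function(manifest, montage = standard_1020_montage()) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(manifest$path[i],
                   format = if ("format" %in% names(manifest))
                     manifest$format[i] else "auto",
                   subject_id = manifest$subject_id[i],
                   group = manifest$group[i],
                   condition = manifest$condition[i],
                   montage = montage)
  })
}

#' Standard preprocessing: filter, segment, window
#'
#' Applies the band-pass/notch filter, optionally re-references to the common
#' average, extracts the centered analysis segment and cuts non-overlapping
#' windows, pooling all recordings into one window set.
#'
#' @param recordings List of `eeg_recording` objects.
#' @param filter Apply [bandpass_notch()] first.
#' @param reref Apply [average_reference()] (off by default).
#' @param segment_seconds Centered segment length (default 180 s).
#' @param window_seconds Window length (default 2 s).
#' @return An `eeg_windows` object.
#' @export
prepare_windows <- function(recordings, filter = TRUE, reref = FALSE,
                            segment_seconds = 180, window_seconds = 2) {
  ws <- lapply(recordings, function(rec) {
    if (filter) rec <- bandpass_notch(rec)
    if (reref) rec <- average_reference(rec)
    rec <- extract_middle_segment(rec, segment_seconds)
    make_windows(rec, window_seconds)
  })
  bind_windows(ws)
}
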