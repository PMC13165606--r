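# Minimal 16-bit EDF support (European Data Format): fixed-layout ASCII
# header + little-endian int16 data records. Enough for round-tripping
# multichannel recordings at a common sampling rate; annotations, per-signal
# rates and EDF+ extensions are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to a 16-bit EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range; one
#' data record per second (a trailing partial second is dropped).
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- as.integer(round(rec$sampling_rate))
  x <- rec$data
  n_rec <- ncol(x) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(x)
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad(paste(rec$group, rec$condition), 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * ns, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rownames(x), 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin, format = "g", digits = 7), 8)
  fld(formatC(pmax, format = "g", digits = 7), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    seg <- x[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((seg - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix, physical units),
#'   `channel_names`, `sampling_rate`, `patient` and `recording_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  readChar(con, 8, useBytes = TRUE)                # version
  patient <- rd(80); recording_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF files with per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    seg <- matrix(raw, nrow = spr[1], ncol = ns)   # samples x signals
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(seg)
  }
  phys <- (out - dmin) * (pmax - pmin) / (dmax - dmin) + pmin
  rownames(phys) <- labels
  list(data = phys, channel_names = labels, sampling_rate = fs,
       patient = patient, recording_id = recording_id)
}
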