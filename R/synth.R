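#' Specification for a synthetic resting-state EEG cohort
#'
#' Defines the generator for labeled synthetic cohorts: every channel is
#' spectrally shaped 1/f^beta background noise (partially shared across
#' channels, so functional-connectivity graphs are non-trivial) plus an
#' alpha-band oscillation with random phase. For the MDD class the alpha
#' amplitude is scaled up on right-hemisphere channels and down on
#' left-hemisphere channels so that the right/left alpha *power* ratio on
#' homologous channels equals `asymmetry_effect`; midline channels and the
#' HC class are unscaled. `asymmetry_effect = 1` makes the two classes
#' distributionally identical.
#'
#' @param n_pairs Number of MDD/HC subject pairs.
#' @param duration Recording length per condition, seconds (default 200 so the
#'   180 s centered-segment extraction is exercised).
#' @param sampling_rate Hz (default 256).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param alpha_band Alpha frequency interval in Hz; oscillation frequencies
#'   are drawn per subject from its central half.
#' @param asymmetry_effect Right/left alpha-power ratio planted for MDD
#'   (>= 1; 1 = no signal).
#' @param snr Oscillation-to-noise RMS amplitude ratio.
#' @param noise_rms Background RMS amplitude in microvolts.
#' @param channel_correlation Fraction of background variance shared across
#'   channels through common sources.
#' @param eo_alpha_factor Alpha attenuation in the eyes-open condition
#'   (alpha blocking; 1 = none).
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   cohort.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_pairs = 6, duration = 200, sampling_rate = 256,
                       noise_exponent = 1, alpha_band = c(8, 12),
                       asymmetry_effect = 1, snr = 1, noise_rms = 10,
                       channel_correlation = 0.3, eo_alpha_factor = 0.7,
                       seed = 1) {
  stopifnot(n_pairs >= 1, duration >= 2, sampling_rate > 0,
            length(alpha_band) == 2, alpha_band[1] < alpha_band[2],
            asymmetry_effect >= 1, snr >= 0, noise_rms > 0,
            channel_correlation >= 0, channel_correlation < 1)
  structure(list(n_pairs = n_pairs, duration = duration,
                 sampling_rate = sampling_rate,
                 noise_exponent = noise_exponent, alpha_band = alpha_band,
                 asymmetry_effect = asymmetry_effect, snr = snr,
                 noise_rms = noise_rms,
                 channel_correlation = channel_correlation,
                 eo_alpha_factor = eo_alpha_factor,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Unit-RMS 1/f^beta noise of length n (power spectrum ~ f^-beta).
.pink_noise <- function(n, beta, fs) {
  spec <- stats::fft(stats::rnorm(n))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]      # mirrored negative frequencies
  amp <- c(0, f[-1]^(-beta / 2))           # kill DC
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

.lateral_channels <- function() {
  list(left = setdiff(.hemi_left, .midline),
       right = setdiff(.hemi_right, .midline))
}

#' Generate one synthetic EEG recording
#'
#' @param spec A `synth_spec`.
#' @param subject_id Subject label.
#' @param group `"MDD"` or `"HC"`.
#' @param condition `"EC"` or `"EO"`.
#' @param stream Integer RNG stream offset; recordings with distinct streams
#'   are independent, the same (seed, stream) reproduces bit-identically.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(spec, subject_id, group = c("MDD", "HC"),
                               condition = c("EC", "EO"), stream = 0) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  montage <- standard_1020_montage(spec$sampling_rate)
  chans <- montage$channel_names
  C <- length(chans)
  n <- round(spec$duration * spec$sampling_rate)
  fs <- spec$sampling_rate

  set.seed((spec$seed + 104729L * stream) %% 2147483647L)
  n_src <- 4
  sources <- vapply(seq_len(n_src), function(i)
    .pink_noise(n, spec$noise_exponent, fs), numeric(n))
  mix <- matrix(stats::rnorm(C * n_src), C, n_src)
  mix <- mix / sqrt(rowSums(mix^2))
  rho <- spec$channel_correlation
  own <- vapply(seq_len(C), function(i)
    .pink_noise(n, spec$noise_exponent, fs), numeric(n))
  noise <- sqrt(1 - rho) * t(own) + sqrt(rho) * (mix %*% t(sources))
  noise <- noise * spec$noise_rms

  f_alpha <- stats::runif(1, mean(spec$alpha_band) - diff(spec$alpha_band) / 4,
                          mean(spec$alpha_band) + diff(spec$alpha_band) / 4)
  phase <- stats::runif(C, 0, 2 * pi)
  tt <- seq_len(n) / fs
  amp <- spec$snr * spec$noise_rms * sqrt(2)     # RMS ratio snr vs noise
  if (condition == "EO") amp <- amp * spec$eo_alpha_factor
  gain <- rep(1, C)
  if (group == "MDD" && spec$asymmetry_effect > 1) {
    lat <- .lateral_channels()
    gain[chans %in% lat$right] <- spec$asymmetry_effect^(1 / 4)
    gain[chans %in% lat$left]  <- spec$asymmetry_effect^(-1 / 4)
  }
  osc <- (amp * gain) * t(vapply(seq_len(C), function(c)
    sin(2 * pi * f_alpha * tt + phase[c]), numeric(n)))
  eeg_recording(noise + osc, subject_id = subject_id, group = group,
                condition = condition, sampling_rate = fs, montage = montage)
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_pairs` MDD and `n_pairs` HC subjects, each with one
#' eyes-closed and one eyes-open recording, plus a manifest compatible with
#' [load_cohort()]. With `dir` set, recordings are written to disk (delimited
#' text or EDF) and the manifest references the files; otherwise recordings
#' are returned in memory.
#'
#' @param spec A `synth_spec`.
#' @param dir Optional output directory.
#' @param format `"delimited"` or `"edf"` (used only when writing).
#' @return List with `recordings` (list of `eeg_recording`) and `manifest`
#'   (data frame: subject_id, group, condition, path).
#' @export
generate_cohort <- function(spec, dir = NULL, format = c("delimited", "edf")) {
  format <- match.arg(format)
  subjects <- data.frame(
    subject_id = c(sprintf("MDD%02d", seq_len(spec$n_pairs)),
                   sprintf("HC%02d", seq_len(spec$n_pairs))),
    group = rep(c("MDD", "HC"), each = spec$n_pairs),
    stringsAsFactors = FALSE)
  rows <- list(); recs <- list(); k <- 0L
  for (i in seq_len(nrow(subjects))) {
    for (cond in c("EC", "EO")) {
      k <- k + 1L
      rec <- generate_recording(spec, subjects$subject_id[i],
                                subjects$group[i], cond, stream = k)
      path <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        ext <- if (format == "edf") "edf" else "tsv"
        path <- file.path(dir, sprintf("%s_%s.%s", subjects$subject_id[i],
                                       cond, ext))
        if (format == "edf") write_edf(rec, path)
        else write_recording_delim(rec, path)
      }
      rows[[k]] <- data.frame(subject_id = subjects$subject_id[i],
                              group = subjects$group[i], condition = cond,
                              path = path, stringsAsFactors = FALSE)
      recs[[k]] <- rec
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(recordings = recs, manifest = manifest)
}
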