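#' Default 23-electrode montage
#'
#' The referential 10-20 electrode names used throughout the package: AF7,
#' AF3, AF4, AF8, FT9, FT7, FC3, FCz, FC4, FT8, FT10, T7, T8, TP7, CP3, CPz,
#' CP4, TP8, P8, PO7, PO3, PO4, PO8. These are the 23 channels the default
#' 4x7 grid layout places.
#'
#' @return Character vector of 23 electrode names.
#' @export
default_channel_names <- function() {
  c("AF7", "AF3", "AF4", "AF8", "FT9", "FT7", "FC3", "FCz", "FC4", "FT8",
    "FT10", "T7", "T8", "TP7", "CP3", "CPz", "CP4", "TP8", "P8", "PO7",
    "PO3", "PO4", "PO8")
}

#' Dynamics of one synthetic EEG regime
#'
#' A regime is a sinusoidal rhythm plus 1/f^alpha coloured noise. The
#' interictal default is noise-dominated (high complexity); the preictal
#' default is rhythm-dominated (low complexity), consistent with the use of
#' complexity features to separate the two classes. Amplitudes are in
#' microvolts.
#'
#' @param sine_freq_hz Rhythm frequency in Hz.
#' @param sine_amp Rhythm amplitude (uV).
#' @param noise_amp Broadband-noise amplitude (uV, standard deviation).
#' @param noise_color_exponent Spectral exponent alpha of the 1/f^alpha noise
#'   (0 = white).
#' @return A `synth_dynamics` list.
#' @export
synth_dynamics <- function(sine_freq_hz = 10, sine_amp = 10, noise_amp = 30,
                           noise_color_exponent = 1) {
  if (sine_amp < 0 || noise_amp < 0) {
    stopf("dynamics amplitudes must be non-negative (got sine_amp=%g, noise_amp=%g)",
          sine_amp, noise_amp)
  }
  if (sine_freq_hz <= 0) stopf("sine_freq_hz must be positive")
  structure(list(sine_freq_hz = sine_freq_hz, sine_amp = sine_amp,
                 noise_amp = noise_amp,
                 noise_color_exponent = noise_color_exponent),
            class = "synth_dynamics")
}

#' Configuration of the synthetic EEG generator
#'
#' Defines a multichannel recording with seizure-onset annotations and a
#' controllable complexity contrast between the interictal baseline and the
#' preictal (15-to-5-minutes-before-onset) regime. Identical configurations
#' (including `seed`) produce bit-identical recordings.
#'
#' @param n_channels Number of channels; must equal `length(channel_names)`.
#' @param channel_names Unique electrode labels; defaults to
#'   [default_channel_names()].
#' @param fs Sampling rate in Hz (default 256).
#' @param duration_s Recording length in seconds.
#' @param seizure_onsets_s Seizure onset times in seconds, within
#'   `[0, duration_s]`.
#' @param interictal_dynamics,preictal_dynamics [synth_dynamics()] for the two
#'   regimes. Defaults: interictal 10 Hz x 10 uV rhythm + 30 uV 1/f noise;
#'   preictal 8 Hz x 40 uV rhythm + 10 uV 1/f^0.5 noise.
#' @param crossfade_s Linear cross-fade between regimes, seconds (default 2).
#' @param seed Integer seed; the full output is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 23,
                         channel_names = default_channel_names(),
                         fs = 256,
                         duration_s = 600,
                         seizure_onsets_s = numeric(0),
                         interictal_dynamics = synth_dynamics(
                           sine_freq_hz = 10, sine_amp = 10, noise_amp = 30,
                           noise_color_exponent = 1),
                         preictal_dynamics = synth_dynamics(
                           sine_freq_hz = 8, sine_amp = 40, noise_amp = 10,
                           noise_color_exponent = 0.5),
                         crossfade_s = 2,
                         seed = 1L) {
  if (n_channels != length(channel_names)) {
    stopf("n_channels (%d) != length(channel_names) (%d)",
          n_channels, length(channel_names))
  }
  if (anyDuplicated(channel_names)) stopf("channel_names must be unique")
  if (fs <= 0) stopf("fs must be positive")
  if (duration_s < 0) stopf("duration_s must be >= 0")
  if (length(seizure_onsets_s) &&
      (min(seizure_onsets_s) < 0 || max(seizure_onsets_s) > duration_s)) {
    stopf("all seizure onsets must lie within [0, duration_s]")
  }
  structure(list(n_channels = n_channels, channel_names = channel_names,
                 fs = fs, duration_s = duration_s,
                 seizure_onsets_s = sort(seizure_onsets_s),
                 interictal_dynamics = interictal_dynamics,
                 preictal_dynamics = preictal_dynamics,
                 crossfade_s = crossfade_s, seed = as.integer(seed)),
            class = "synth_config")
}

#' Multichannel EEG recording container
#'
#' @param signal channels x samples numeric matrix (uV), all values finite.
#' @param channel_names Channel labels, one per row of `signal`.
#' @param fs Sampling rate in Hz.
#' @param onsets_s Seizure onset times (seconds), sorted ascending.
#' @param subject_id Subject identifier string.
#' @return A `recording` object.
#' @export
recording <- function(signal, channel_names, fs, onsets_s = numeric(0),
                      subject_id = "s01") {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_names)) {
    stopf("signal has %d rows but %d channel names",
          nrow(signal), length(channel_names))
  }
  if (!all(is.finite(signal))) stopf("signal contains non-finite values")
  rownames(signal) <- channel_names
  structure(list(signal = signal, channel_names = channel_names, fs = fs,
                 onsets_s = sort(onsets_s), subject_id = subject_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %d channels x %d samples @ %g Hz, %d seizure onset(s)>\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              length(x$onsets_s)))
  invisible(x)
}

# 1/f^alpha coloured noise by spectral shaping of white Gaussian noise.
# Returns a length-n series with standard deviation ~= amp.
colored_noise <- function(n, amp, alpha) {
  if (amp == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (alpha == 0) return(amp * w)
  f <- stats::fft(w)
  freq <- c(0, seq_len(n - 1))
  freq <- pmin(freq, n - freq)                      # two-sided frequency index
  shape <- c(1, (freq[-1])^(-alpha / 2))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  amp * x / stats::sd(x)
}

# Per-sample preictal weight in [0,1] for a recording: 1 inside any
# [onset-900, onset-300) span, 0 elsewhere, with linear cross-fades of
# `crossfade_s` straddling each span boundary.
preictal_weight <- function(t, onsets_s, pre_start_s = 900, pre_end_s = 300,
                            crossfade_s = 2) {
  w <- numeric(length(t))
  half <- crossfade_s / 2
  for (on in onsets_s) {
    a <- on - pre_start_s
    b <- on - pre_end_s
    if (b <= 0) next
    wi <- pmin(pmax((t - (a - half)) / max(crossfade_s, .Machine$double.eps), 0), 1) *
      pmin(pmax(((b + half) - t) / max(crossfade_s, .Machine$double.eps), 0), 1)
    w <- pmax(w, wi)
  }
  w
}

#' Generate one synthetic EEG recording
#'
#' Samples lying within the 15-to-5-minute span before any seizure onset are
#' drawn under the preictal dynamics, samples at least 15 minutes from every
#' onset under the interictal dynamics; a short linear cross-fade joins the
#' regimes. Each channel gets a seeded gain jitter in \[0.8, 1.2\] and its own
#' noise realisation and rhythm phase.
#'
#' @param config A [synth_config()].
#' @param subject_id Subject identifier (default "s01").
#' @return A [recording()].
#' @export
generate_recording <- function(config, subject_id = "s01") {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  for (on in config$seizure_onsets_s) {
    if (on < 900) {
      warnf("onset at %g s is closer than 900 s to recording start; preictal span truncated", on)
    }
  }
  w_pre <- preictal_weight(t, config$seizure_onsets_s,
                           crossfade_s = config$crossfade_s)
  sig <- with_seed(config$seed, {
    gains <- stats::runif(config$n_channels, 0.8, 1.2)
    out <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      di <- config$interictal_dynamics
      dp <- config$preictal_dynamics
      phase_i <- stats::runif(1, 0, 2 * pi)
      phase_p <- stats::runif(1, 0, 2 * pi)
      xi <- di$sine_amp * sin(2 * pi * di$sine_freq_hz * t + phase_i) +
        colored_noise(n, di$noise_amp, di$noise_color_exponent)
      xp <- dp$sine_amp * sin(2 * pi * dp$sine_freq_hz * t + phase_p) +
        colored_noise(n, dp$noise_amp, dp$noise_color_exponent)
      out[ch, ] <- gains[ch] * ((1 - w_pre) * xi + w_pre * xp)
    }
    out
  })
  recording(sig, config$channel_names, config$fs, config$seizure_onsets_s,
            subject_id)
}

#' Generate a set of independent synthetic recordings
#'
#' Recording `i` uses seed `config$seed + i - 1`; subject ids are unique.
#'
#' @param config A [synth_config()].
#' @param n_recordings Number of recordings (>= 1).
#' @return List of [recording()] objects.
#' @export
generate_dataset <- function(config, n_recordings) {
  if (n_recordings < 1) stopf("n_recordings must be >= 1")
  lapply(seq_len(n_recordings), function(i) {
    ci <- config
    ci$seed <- config$seed + i - 1L
    generate_recording(ci, subject_id = sprintf("synth%02d", i))
  })
}
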