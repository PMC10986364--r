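#' Zero-phase band-pass filter a recording
#'
#' Cascaded Butterworth high-pass and low-pass sections, each applied
#' forward-backward (zero phase) per channel, so window boundaries are not
#' shifted in time. An optional powerline notch can be enabled; the default
#' band (0.5-75 Hz) already excludes 50 Hz-region interference harmonics
#' above the cut-off.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order per edge (default 4).
#' @param notch_hz Optional powerline notch frequency (e.g. 50 or 60); `NULL`
#'   (default) applies no notch.
#' @return Filtered [recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 75, order = 4,
                            notch_hz = NULL) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (high_hz >= nyq) {
    stopf("high_hz (%g) must be below the Nyquist frequency %g Hz (fs = %g Hz)",
          high_hz, nyq, rec$fs)
  }
  if (low_hz <= 0 || low_hz >= high_hz) {
    stopf("need 0 < low_hz < high_hz (got %g, %g)", low_hz, high_hz)
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  out <- rec$signal
  for (ch in seq_len(nrow(out))) {
    y <- signal::filtfilt(lp, signal::filtfilt(hp, out[ch, ]))
    if (!is.null(notch_hz)) {
      bs <- signal::butter(2, c(notch_hz - 1, notch_hz + 1) / nyq,
                           type = "stop")
      y <- signal::filtfilt(bs, y)
    }
    out[ch, ] <- y
  }
  recording(out, rec$channel_names, rec$fs, rec$onsets_s, rec$subject_id)
}

#' Labelling specification for the seizure-prediction horizon
#'
#' Positives are windows lying entirely inside the span from
#' `sph_pre_start_s` down to `sph_pre_end_s` before a seizure onset (default
#' 15 to 5 minutes). Negatives are windows whose whole extent is at least
#' `negative_exclusion_s` from every onset. Everything else — the last five
#' minutes before onset, and ictal/post-ictal spans — is discarded.
#'
#' @param sph_pre_start_s Seconds before onset where positives begin (900).
#' @param sph_pre_end_s Seconds before onset where positives end (300).
#' @param negative_exclusion_s Minimum distance from any onset for negatives
#'   (900).
#' @param window_len_s Window length, seconds (6); must equal
#'   `2 * step_len_s`.
#' @param step_len_s Step length, seconds (3).
#' @return A `label_spec` list.
#' @export
label_spec <- function(sph_pre_start_s = 900, sph_pre_end_s = 300,
                       negative_exclusion_s = 900, window_len_s = 6,
                       step_len_s = 3) {
  if (!(sph_pre_start_s > sph_pre_end_s && sph_pre_end_s >= 0)) {
    stopf("need sph_pre_start_s > sph_pre_end_s >= 0")
  }
  if (window_len_s != 2 * step_len_s) {
    stopf("window_len_s must equal 2 * step_len_s")
  }
  structure(list(sph_pre_start_s = sph_pre_start_s,
                 sph_pre_end_s = sph_pre_end_s,
                 negative_exclusion_s = negative_exclusion_s,
                 window_len_s = window_len_s, step_len_s = step_len_s),
            class = "label_spec")
}

new_window_set <- function(windows, labels, start_times_s, subject_ids, fs,
                           window_len_s) {
  structure(list(windows = windows, labels = labels,
                 start_times_s = start_times_s, subject_ids = subject_ids,
                 fs = fs, window_len_s = window_len_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d windows (%d positive / %d negative), %d channels, %g s @ %g Hz>\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              dim(x$windows)[2], x$window_len_s, x$fs))
  invisible(x)
}

#' Cut a recording into labelled non-overlapping windows
#'
#' Windows tile the recording from t = 0 in steps of `window_len_s`. A window
#' is positive iff it lies entirely inside
#' `[onset - sph_pre_start_s, onset - sph_pre_end_s)` for some onset, negative
#' iff its whole extent is at least `negative_exclusion_s` from every onset;
#' windows in neither zone are discarded. A recording shorter than one window
#' yields an empty set.
#'
#' @param rec A (filtered) [recording()].
#' @param spec A [label_spec()].
#' @return A `window_set`: array `windows` (n x channels x samples), binary
#'   `labels` (1 = preictal), `start_times_s`, `subject_ids`, `fs`.
#' @export
label_windows <- function(rec, spec = label_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "label_spec"))
  wlen <- spec$window_len_s
  nsamp <- round(wlen * rec$fs)
  total_s <- ncol(rec$signal) / rec$fs
  starts <- if (total_s < wlen) numeric(0) else
    seq(0, total_s - wlen, by = wlen)
  keep <- logical(length(starts)); lab <- integer(length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- a + wlen
    pos <- any(vapply(rec$onsets_s, function(on) {
      a >= on - spec$sph_pre_start_s && b <= on - spec$sph_pre_end_s
    }, logical(1)))
    neg <- all(vapply(rec$onsets_s, function(on) {
      b <= on - spec$negative_exclusion_s || a >= on + spec$negative_exclusion_s
    }, logical(1)))
    if (pos) { keep[i] <- TRUE; lab[i] <- 1L }
    else if (neg) { keep[i] <- TRUE; lab[i] <- 0L }
  }
  starts <- starts[keep]; lab <- lab[keep]
  w <- array(0, c(length(starts), nrow(rec$signal), nsamp),
             dimnames = list(NULL, rec$channel_names, NULL))
  for (i in seq_along(starts)) {
    s0 <- round(starts[i] * rec$fs)
    w[i, , ] <- rec$signal[, (s0 + 1):(s0 + nsamp)]
  }
  new_window_set(w, lab, starts, rep(rec$subject_id, length(starts)), rec$fs,
                 wlen)
}

#' Merge window sets from several recordings
#'
#' @param sets List of `window_set` objects with identical channel count,
#'   sampling rate and window length.
#' @return One combined `window_set`.
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  fs <- sets[[1]]$fs; wl <- sets[[1]]$window_len_s
  for (s in sets) stopifnot(s$fs == fs, s$window_len_s == wl)
  n <- sum(vapply(sets, function(s) length(s$labels), 0L))
  d <- dim(sets[[1]]$windows)
  w <- array(0, c(n, d[2], d[3]),
             dimnames = list(NULL, dimnames(sets[[1]]$windows)[[2]], NULL))
  labels <- integer(n); starts <- numeric(n); subj <- character(n)
  at <- 0
  for (s in sets) {
    k <- length(s$labels)
    if (k) {
      w[at + seq_len(k), , ] <- s$windows
      labels[at + seq_len(k)] <- s$labels
      starts[at + seq_len(k)] <- s$start_times_s
      subj[at + seq_len(k)] <- s$subject_ids
      at <- at + k
    }
  }
  new_window_set(w, labels, starts, subj, fs, wl)
}

#' Balance classes 1:1 by seeded subsampling
#'
#' The majority class is subsampled uniformly without replacement to the
#' minority count. Per-subject balance is preserved when possible: the
#' majority-class quota is allocated across subjects proportionally to their
#' majority-class counts (largest-remainder rounding).
#'
#' @param ws A `window_set` containing both classes.
#' @param seed Integer seed for the subsample.
#' @return A balanced `window_set`.
#' @export
balance_classes <- function(ws, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  n1 <- sum(ws$labels == 1); n0 <- sum(ws$labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to balance")
  if (n1 == n0) return(ws)
  maj <- if (n1 > n0) 1L else 0L
  target <- min(n1, n0)
  maj_idx <- which(ws$labels == maj)
  subj <- ws$subject_ids[maj_idx]
  tab <- table(subj)
  quota <- as.numeric(tab) * target / length(maj_idx)
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  pick <- with_seed(seed, {
    unlist(lapply(seq_along(tab), function(i) {
      pool <- maj_idx[subj == names(tab)[i]]
      if (base[i] >= length(pool)) pool else sample(pool, base[i])
    }))
  })
  keep <- sort(c(which(ws$labels != maj), pick))
  new_window_set(ws$windows[keep, , , drop = FALSE], ws$labels[keep],
                 ws$start_times_s[keep], ws$subject_ids[keep], ws$fs,
                 ws$window_len_s)
}

#' Split each window into its two half-length steps
#'
#' Step 1 is the first half, step 2 the second; concatenating the steps
#' recovers the window exactly.
#'
#' @param ws A `window_set` whose per-window sample count is even.
#' @return Array of shape n x 2 x channels x step_samples.
#' @export
split_steps <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$windows)
  if (d[3] %% 2 != 0) stopf("window sample count (%d) must be even", d[3])
  half <- d[3] / 2
  out <- array(0, c(d[1], 2, d[2], half))
  out[, 1, , ] <- ws$windows[, , seq_len(half), drop = FALSE]
  out[, 2, , ] <- ws$windows[, , half + seq_len(half), drop = FALSE]
  dimnames(out) <- list(NULL, NULL, dimnames(ws$windows)[[2]], NULL)
  out
}
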