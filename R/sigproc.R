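#' Analysis frequency grid
#'
#' Eight frequencies geometrically spaced with endpoints exactly 3 and
#' 180 Hz (ratio `60^(1/7)`), the grid at which spectral power is measured.
#'
#' @param n number of frequencies.
#' @param fmin,fmax endpoints in Hz.
#' @return numeric vector of length `n`.
#' @examples
#' round(morlet_freqs(), 1)
#' @export
morlet_freqs <- function(n = 8L, fmin = 3, fmax = 180) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Band-stop filter line noise
#'
#' Applies a fourth-order Butterworth band-stop filter, 5 Hz wide and centred
#' on 60 Hz (edges 57.5-62.5 Hz), to every channel. The filter is run
#' forward-backward (zero phase), so no epoch-relative latency shift is
#' introduced; the effective order doubles.
#'
#' @param raw a `raw_signal`.
#' @param center,width stop-band centre and width in Hz.
#' @return the filtered `raw_signal`.
#' @export
notch_filter <- function(raw, center = 60, width = 5) {
  stopifnot(inherits(raw, "raw_signal"))
  nyq <- raw$sampling_rate / 2
  lo <- center - width / 2
  hi <- center + width / 2
  if (hi >= nyq)
    stop_memloop("stop band (%g-%g Hz) reaches Nyquist (%g Hz)", lo, hi, nyq,
                 class = "memloop_filter_error")
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "stop")  # 4th-order band-stop
  out <- raw
  for (ch in seq_len(nrow(raw$data)))
    out$data[ch, ] <- signal::filtfilt(bf, raw$data[ch, ])
  out
}

#' Bipolar re-referencing
#'
#' Differences immediately adjacent contact pairs to form virtual channels,
#' removing any signal common to all contacts (reference drift, common-mode
#' line noise).
#'
#' @param raw a monopolar `raw_signal`.
#' @param layout an `electrode_layout` (uses `layout$pairs`).
#' @return a `raw_signal` with one virtual channel per pair and montage
#'   `"bipolar-virtual"`.
#' @export
bipolar_rereference <- function(raw, layout) {
  stopifnot(inherits(raw, "raw_signal"))
  if (raw$montage != "monopolar")
    stop_memloop("input montage must be monopolar, got %s", raw$montage,
                 class = "memloop_montage_error")
  pairs <- layout$pairs
  ai <- match(pairs$anode, raw$labels)
  ci <- match(pairs$cathode, raw$labels)
  if (anyNA(ai) || anyNA(ci))
    stop_memloop("unknown contact label(s): %s",
                 paste(unique(c(pairs$anode[is.na(ai)], pairs$cathode[is.na(ci)])),
                       collapse = ", "),
                 class = "memloop_lookup_error")
  out <- raw
  out$data <- raw$data[ai, , drop = FALSE] - raw$data[ci, , drop = FALSE]
  out$labels <- paste0(pairs$anode, "-", pairs$cathode)
  out$montage <- "bipolar-virtual"
  out
}

# Complex Morlet wavelet (wave number w): Gaussian envelope SD = w / (2*pi*f).
# Returned amplitude-normalized so stationary sinusoid power is comparable
# across frequencies (L1-normalized envelope).
morlet_wavelet <- function(f, fs, wave_number = 5) {
  sd_t <- wave_number / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sd_t^2))
  (env / sum(env)) * exp(1i * 2 * pi * f * t)
}

#' Morlet wavelet power features for word-encoding epochs
#'
#' For every event, virtual channel and analysis frequency: extracts the
#' `[0, 1366)` ms epoch from word onset, mirror-pads it with 1,365 ms buffers
#' on both sides, convolves with a complex Morlet wavelet (wave number 5),
#' discards the buffers, squares the magnitude, takes the natural log and
#' averages over time. Output is un-normalized; see [normalize_features()].
#'
#' Feature columns are ordered pair-major, frequency-minor: all frequencies
#' of virtual channel 1, then all frequencies of channel 2, and so on.
#'
#' @param raw a bipolar-virtual `raw_signal` (monopolar accepted, each
#'   channel treated as one feature source).
#' @param events event table with `onset_ms`.
#' @param freqs analysis frequencies (default [morlet_freqs()]).
#' @param wave_number Morlet wave number.
#' @param epoch_ms epoch length from word onset (half-open, ms).
#' @param buffer_ms mirrored buffer length (ms).
#' @return a `power_features` object (un-normalized).
#' @export
wavelet_power <- function(raw, events, freqs = morlet_freqs(),
                          wave_number = 5, epoch_ms = 1366, buffer_ms = 1365) {
  stopifnot(inherits(raw, "raw_signal"))
  fs <- raw$sampling_rate
  n_ep <- floor(epoch_ms / 1000 * fs)
  n_buf <- floor(buffer_ms / 1000 * fs)
  ns <- ncol(raw$data)
  nch <- nrow(raw$data)
  wavelets <- lapply(freqs, morlet_wavelet, fs = fs, wave_number = wave_number)

  i0 <- floor(events$onset_ms / 1000 * fs) + 1L
  bad <- which(i0 < 1L | (i0 + n_ep - 1L) > ns)
  if (length(bad))
    stop_memloop("epoch for event %d ([%g, %g) ms) exceeds recording bounds",
                 bad[1], events$onset_ms[bad[1]], events$onset_ms[bad[1]] + epoch_ms,
                 class = "memloop_epoch_error")

  x <- matrix(NA_real_, nrow(events), nch * length(freqs))
  for (e in seq_len(nrow(events))) {
    idx <- i0[e]:(i0[e] + n_ep - 1L)
    for (ch in seq_len(nch)) {
      seg <- raw$data[ch, idx]
      nb <- min(n_buf, n_ep)
      padded <- c(rev(seg[seq_len(nb)]), seg, rev(seg[(n_ep - nb + 1L):n_ep]))
      for (k in seq_along(freqs)) {
        conv <- fft_convolve_same(padded, wavelets[[k]])
        core <- conv[(nb + 1L):(nb + n_ep)]
        x[e, (ch - 1L) * length(freqs) + k] <- mean(log(Mod(core)^2 + 1e-300))
      }
    }
  }
  labels <- raw$labels
  colnames(x) <- paste0(rep(labels, each = length(freqs)), "@",
                        rep(sprintf("%.1fHz", freqs), nch))
  structure(list(x = x,
                 pairs = data.frame(label = labels, stringsAsFactors = FALSE),
                 freqs = freqs,
                 feature_pair = rep(seq_len(nch), each = length(freqs)),
                 feature_freq = rep(seq_along(freqs), nch),
                 norm = NULL), class = "power_features")
}

# Linear "same"-mode convolution of x with kernel k (centred) via FFT.
fft_convolve_same <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- 2^ceiling(log2(n))
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                       stats::fft(c(k, rep(0, nfft - length(k)))),
                     inverse = TRUE) / nfft
  half <- (length(k) - 1L) %/% 2L
  full[(half + 1L):(half + length(x))]
}

#' Normalize power features
#'
#' `within_session` z-scores each (virtual channel x frequency) column across
#' the supplied events, so every column has mean 0 and SD 1 exactly.
#' `baseline_stats` applies externally supplied per-column means and SDs
#' without refitting (the closed-loop convention: statistics come from the
#' practice and baseline lists and are updated after each NoStim list).
#'
#' @param feats a `power_features` object.
#' @param mode `"within_session"` or `"baseline_stats"`.
#' @param stats_in for `baseline_stats`: list with `mean` and `sd` vectors
#'   (one entry per column), e.g. from [feature_stats()].
#' @return the normalized `power_features`, with a `norm` provenance block.
#' @export
normalize_features <- function(feats, mode = c("within_session", "baseline_stats"),
                               stats_in = NULL) {
  mode <- match.arg(mode)
  x <- feats$x
  if (mode == "within_session") {
    if (nrow(x) < 2L)
      stop_memloop("within_session normalization needs >= 2 events",
                   class = "memloop_norm_error")
    m <- colMeans(x)
    s <- apply(x, 2, stats::sd)
  } else {
    if (is.null(stats_in))
      stop_memloop("baseline_stats normalization needs supplied statistics",
                   class = "memloop_norm_error")
    m <- stats_in$mean
    s <- stats_in$sd
  }
  zero <- which(s == 0)
  if (length(zero))
    stop_memloop("degenerate feature column(s) with zero SD: %s",
                 paste(utils::head(colnames(x)[zero], 3), collapse = ", "),
                 class = "memloop_degenerate_error")
  feats$x <- sweep(sweep(x, 2, m), 2, s, "/")
  feats$norm <- list(mean = m, sd = s,
                     provenance = if (mode == "within_session")
                       "z-scored within session" else "z-scored to baseline statistics")
  feats
}

#' Per-column normalization statistics
#'
#' @param feats a `power_features` object.
#' @param rows optional row subset over which to compute the statistics.
#' @return list with `mean`, `sd`, `n`.
#' @export
feature_stats <- function(feats, rows = NULL) {
  x <- if (is.null(rows)) feats$x else feats$x[rows, , drop = FALSE]
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd), n = nrow(x))
}
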