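# The six sound variables measured on every plosive: duration, mean
# fundamental frequency, first three formants, average power, spectral
# Shannon entropy, and the voiced fraction of the plosive-to-plosive interval.

#' Frame-wise fundamental frequency track by normalized autocorrelation
#'
#' Frames of `window_ms` are analyzed every `frame_ms` (10 ms by convention).
#' A frame is voiced iff the normalized autocorrelation peak within the F0
#' band reaches `voicing_threshold`; F0 is the sample rate over the peak lag
#' with parabolic lag interpolation.
#'
#' @param x Numeric waveform of one plosive.
#' @param fs Sampling rate (Hz).
#' @param frame_ms Hop between estimates.
#' @param window_ms Analysis window length.
#' @param f0_band Admissible F0 range in Hz.
#' @param voicing_threshold Normalized autocorrelation needed to call a frame
#'   voiced.
#' @param prefilter_hz Zero-phase low-pass cutoff applied before
#'   autocorrelation; removing energy above the F0 band suppresses
#'   formant-ringing interference with the period estimate. `0` disables.
#' @return Data frame with `time_ms`, `f0_hz` (NA when unvoiced), `voiced`,
#'   `acf_peak`; zero rows (attribute `too_short`) if `x` is shorter than one
#'   window.
#' @export
f0_track <- function(x, fs, frame_ms = 10, window_ms = 30,
                     f0_band = c(75, 600), voicing_threshold = 0.4,
                     prefilter_hz = 1.2 * f0_band[2]) {
  win <- round(window_ms / 1000 * fs)
  hop <- round(frame_ms / 1000 * fs)
  empty <- data.frame(time_ms = numeric(), f0_hz = numeric(),
                      voiced = logical(), acf_peak = numeric())
  if (length(x) < win) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  x_raw <- x
  if (prefilter_hz > 0 && prefilter_hz < fs / 2 && length(x) > 30) {
    x <- fft_band(x, fs, lo = 0, hi = prefilter_hz, trans_hi = 100)
  }
  lag_min <- max(2L, floor(fs / f0_band[2]))
  lag_max <- min(win - 2L, ceiling(fs / f0_band[1]))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  nfft <- 2^ceiling(log2(2 * win))
  norm_acf <- function(w) {
    w <- w - mean(w)
    r0 <- sum(w^2)
    if (r0 <= 0) return(NULL)
    sp <- stats::fft(c(w, numeric(nfft - win)))
    r <- Re(stats::fft(Mod(sp)^2, inverse = TRUE)) / nfft
    r / r[1]
  }
  out <- lapply(starts, function(s) {
    idx <- s:(s + win - 1L)
    r <- norm_acf(x[idx])
    if (is.null(r)) {
      return(data.frame(time_ms = (s - 1) / fs * 1000, f0_hz = NA_real_,
                        voiced = FALSE, acf_peak = 0))
    }
    lags <- lag_min:lag_max
    rl <- r[lags + 1L]
    pk <- lags[which.max(rl)]
    # the period comes from the low-passed signal, but the voicing strength
    # from the raw frame: band-limited noise is autocorrelated at short lags
    # and would masquerade as voiced after the prefilter
    r_raw <- norm_acf(x_raw[idx])
    v <- if (is.null(r_raw)) 0 else r_raw[pk + 1L]
    # parabolic interpolation of the peak lag
    if (pk > lag_min && pk < lag_max) {
      y1 <- r[pk]; y2 <- r[pk + 1L]; y3 <- r[pk + 2L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) pk <- pk + 0.5 * (y1 - y3) / denom
    }
    voiced <- v >= voicing_threshold
    f0 <- min(f0_band[2], max(f0_band[1], fs / pk))
    data.frame(time_ms = (s - 1) / fs * 1000,
               f0_hz = if (voiced) f0 else NA_real_,
               voiced = voiced, acf_peak = v)
  })
  do.call(rbind, out)
}

#' Mean fundamental frequency over voiced frames
#'
#' @param track Output of [f0_track()].
#' @return Arithmetic mean of voiced-frame F0, or `NA` if no frame is voiced.
#' @export
f0_mean <- function(track) {
  v <- track$f0_hz[track$voiced]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' First three formants by linear prediction
#'
#' Autocorrelation-method LPC of order `2 + round(fs / 1000)` on the
#' pre-emphasized, Hamming-windowed segment. Formants are the pole angles of
#' roots inside the unit circle with frequency in `freq_range` and bandwidth
#' below `max_bw_hz`, sorted ascending; missing formants are returned as `NA`.
#'
#' @param x Numeric waveform (>= 25 ms recommended).
#' @param fs Sampling rate (Hz).
#' @param order LPC order; default `2 + round(fs / 1000)`.
#' @param freq_range Admissible formant frequency band (Hz).
#' @param max_bw_hz Maximum admissible formant bandwidth (Hz).
#' @return Named numeric vector `c(f1_hz, f2_hz, f3_hz)` (NA where missing),
#'   with matching bandwidths in attribute `bandwidths`.
#' @export
formants_lpc <- function(x, fs, order = NULL, freq_range = c(90, 5000),
                         max_bw_hz = 400) {
  if (is.null(order)) order <- 2L + as.integer(round(fs / 1000))
  res <- c(f1_hz = NA_real_, f2_hz = NA_real_, f3_hz = NA_real_)
  if (length(x) <= order + 1 || sum(x^2) == 0) return(res)
  y <- x - 0.97 * c(0, x[-length(x)])               # pre-emphasis
  n <- length(y)
  y <- y * (0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  a <- lpc_autocor(y, order)
  if (is.null(a)) return(res)
  # poles are reciprocals of the roots of A(q) = 1 - sum a_i q^i, q = z^-1
  q <- polyroot(c(1, -a))
  z <- 1 / q
  inside <- Mod(z) < 1 & Im(z) > 0
  freq <- Arg(z[inside]) / (2 * pi) * fs
  bw <- -fs / pi * log(Mod(z[inside]))
  ok <- freq >= freq_range[1] & freq <= freq_range[2] & bw < max_bw_hz
  freq <- freq[ok]; bw <- bw[ok]
  ord <- order(freq)
  freq <- freq[ord]; bw <- bw[ord]
  k <- min(3L, length(freq))
  if (k > 0) res[seq_len(k)] <- freq[seq_len(k)]
  bws <- c(NA_real_, NA_real_, NA_real_)
  if (k > 0) bws[seq_len(k)] <- bw[seq_len(k)]
  attr(res, "bandwidths") <- bws
  res
}

# Levinson-Durbin recursion for autocorrelation-method LPC coefficients.
# Levinson-Durbin recursion for autocorrelation-method LPC coefficients.
lpc_autocor <- function(y, order) {
  n <- length(y)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- stats::fft(c(y, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[1:(order + 1)] / nfft
  if (r[1] <= 0) return(NULL)
  a <- numeric(order)
  e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  a
}

#' Average power (energy per sample)
#'
#' @param x Numeric waveform of one plosive.
#' @return Mean of squared samples; scales as `c^2` under gain `c`.
#' @export
average_power <- function(x) {
  if (length(x) == 0) stop("empty segment")
  mean(x^2)
}

#' Spectral Shannon entropy of a plosive
#'
#' The power spectrum of the windowed segment, restricted to the analysis
#' band, is normalized to a probability vector p and summarized as
#' `H = -sum(p * log2(p))`. H lies in `[0, log2(n_bins)]` and is invariant to
#' overall gain. An all-zero segment yields 0 with attribute `silence = TRUE`.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param n_fft FFT length; default next power of two at or above `length(x)`.
#' @param window `"hann"` (default) or `"rectangular"`.
#' @param band Analysis band in Hz.
#' @return Entropy in bits, with attribute `n_bins`.
#' @export
spectral_entropy <- function(x, fs, n_fft = NULL, window = c("hann", "rectangular"),
                             band = c(50, 10000)) {
  if (length(x) == 0) stop("empty segment")
  window <- match.arg(window)
  n <- length(x)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(n))
  if (window == "hann" && n > 1) {
    x <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  sp <- stats::fft(c(x, numeric(max(0, n_fft - n))))
  half <- floor(n_fft / 2) + 1L
  freqs <- (seq_len(half) - 1) * fs / n_fft
  keep <- freqs >= band[1] & freqs <= min(band[2], fs / 2)
  p <- Mod(sp[seq_len(half)][keep])^2
  n_bins <- sum(keep)
  tot <- sum(p)
  if (tot <= 0) {
    h <- 0
    attr(h, "silence") <- TRUE
    attr(h, "n_bins") <- n_bins
    return(h)
  }
  p <- p / tot
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  attr(h, "n_bins") <- n_bins
  h
}

#' Voiced fraction of the plosive-to-next-plosive interval
#'
#' Time spent with vibrating vocal folds over a plosive, relative to the
#' interval from its onset to the next plosive's onset (or to its own end for
#' the last plosive); clamped to `[0, 1]`.
#'
#' @param track [f0_track()] of the plosive.
#' @param onset_ms Plosive onset.
#' @param end_ms Plosive end.
#' @param next_onset_ms Next plosive's onset, or `NA` for the last plosive.
#' @param frame_ms Frame hop used in the track.
#' @return Fraction in `[0, 1]`.
#' @export
voiced_fraction <- function(track, onset_ms, end_ms, next_onset_ms = NA,
                            frame_ms = 10) {
  interval <- if (is.na(next_onset_ms)) end_ms - onset_ms else next_onset_ms - onset_ms
  if (interval <= 0) return(0)
  voiced_ms <- sum(track$voiced) * frame_ms
  min(1, max(0, voiced_ms / interval))
}

#' Extract the six sound variables for one detected plosive
#'
#' @param record Band-filtered [audio_record()] of the whole laugh.
#' @param segment One row of the segment table from [detect_plosives()].
#' @param next_segment The following row, or `NULL` for the last plosive.
#' @param f0_band,voicing_threshold Passed to [f0_track()].
#' @return One-row data frame: `placement`, `onset_ms`, `duration_ms`,
#'   `f0_mean_hz`, `f1_hz`, `f2_hz`, `f3_hz`, `avg_power`, `entropy_bits`,
#'   `voiced_pct`. Undefined F0/formants are `NA`, never silent defaults.
#' @export
extract_plosive_features <- function(record, segment, next_segment = NULL,
                                     f0_band = c(75, 600), voicing_threshold = 0.4) {
  fs <- record$sample_rate_hz
  x <- record$samples[segment$start_sample:segment$end_sample]
  track <- f0_track(x, fs, f0_band = f0_band, voicing_threshold = voicing_threshold)
  # formants from the central portion of the burst: the attack and decay
  # transients bias the all-pole fit
  n <- length(x)
  mid <- x[max(1, round(0.15 * n)):max(1, round(0.75 * n))]
  fmts <- formants_lpc(if (length(mid) >= 64) mid else x, fs)
  next_onset <- if (is.null(next_segment)) NA else next_segment$start_ms
  data.frame(
    placement = segment$placement,
    onset_ms = segment$start_ms,
    duration_ms = segment$end_ms - segment$start_ms,
    f0_mean_hz = f0_mean(track),
    f1_hz = fmts[["f1_hz"]], f2_hz = fmts[["f2_hz"]], f3_hz = fmts[["f3_hz"]],
    avg_power = average_power(x),
    entropy_bits = as.numeric(spectral_entropy(x, fs)),
    voiced_pct = voiced_fraction(track, segment$start_ms, segment$end_ms, next_onset)
  )
}

#' Extract features for every accepted plosive of a laugh
#'
#' Runs [segment_laugh()] then [extract_plosive_features()] per plosive.
#'
#' @param record An [audio_record()].
#' @param config A [segmenter_config()].
#' @return Data frame (possibly zero rows) with the per-plosive variables plus
#'   `laugh_id` and `subject_id` copied from the record.
#' @export
extract_laugh_features <- function(record, config = segmenter_config()) {
  filtered <- band_filter(record, config$band_hz)
  detected <- detect_plosives(filtered, config, prefiltered = TRUE)
  seg <- clarity_filter(detected, filtered, config)
  segs <- seg$accepted
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    nxt <- if (i < nrow(segs)) segs[i + 1, ] else NULL
    extract_plosive_features(filtered, segs[i, ], nxt)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    extract_plosive_features(
      audio_record(1e-6, record$sample_rate_hz),
      data.frame(placement = 1, start_sample = 1, end_sample = 1,
                 start_ms = 0, end_ms = 0, peak_envelope = 0))[0, ]
  if (nrow(out)) {
    out$laugh_id <- record$laugh_id
    out$subject_id <- record$subject_id
  } else {
    out$laugh_id <- character(0)
    out$subject_id <- character(0)
  }
  out
}
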