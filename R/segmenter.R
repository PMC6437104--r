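# Plosive automatic detector: band filter, RMS amplitude envelope, and
# segmentation of the envelope into isolated energy peaks separated by silence.

#' Segmenter configuration
#'
#' @param band_hz Analysis band (Hz); audio is zero-phase band filtered first.
#' @param envelope_window_ms Sliding RMS window length.
#' @param onset_threshold_rel Detection threshold as a fraction of the
#'   per-recording envelope peak (recordings have unknown gain, so the
#'   threshold is relative, not absolute).
#' @param min_plosive_ms,max_plosive_ms Admissible plosive duration bounds.
#' @param min_silence_ms Minimum silent gap between consecutive plosives;
#'   closer bursts are merged.
#' @export
segmenter_config <- function(band_hz = c(50, 10000), envelope_window_ms = 5,
                             onset_threshold_rel = 0.1, min_plosive_ms = 30,
                             max_plosive_ms = 350, min_silence_ms = 20) {
  if (onset_threshold_rel <= 0 || onset_threshold_rel >= 1) {
    stop("onset_threshold_rel must lie in (0, 1)")
  }
  if (min_plosive_ms >= max_plosive_ms) stop("min_plosive_ms must be < max_plosive_ms")
  list(band_hz = band_hz, envelope_window_ms = envelope_window_ms,
       onset_threshold_rel = onset_threshold_rel, min_plosive_ms = min_plosive_ms,
       max_plosive_ms = max_plosive_ms, min_silence_ms = min_silence_ms)
}

# Zero-phase band limiting for simulator output, which is silence-padded by
# construction: FFT multiplication with raised-cosine band edges.
band_limit <- function(x, fs, band_hz) {
  nyq <- fs / 2
  if (band_hz[2] >= nyq) {
    stop("upper band edge (", band_hz[2], " Hz) must be below Nyquist (", nyq, " Hz)")
  }
  fft_band(x, fs, band_hz[1], band_hz[2])
}

#' Zero-phase band filter an audio record
#'
#' Out-of-band energy is attenuated by more than 40 dB; forward-backward
#' filtering keeps onsets in place.
#'
#' @param record An [audio_record()].
#' @param band_hz Length-2 pass band in Hz; upper edge must be below Nyquist.
#' @return A filtered [audio_record()].
#' @export
band_filter <- function(record, band_hz = c(50, 10000)) {
  fs <- record$sample_rate_hz
  nyq <- fs / 2
  if (band_hz[2] >= nyq) {
    stop("upper band edge (", band_hz[2], " Hz) must be below Nyquist (", nyq, " Hz)")
  }
  hp <- cached_butter(5, band_hz[1] / nyq, "high")
  lp <- cached_butter(5, band_hz[2] / nyq, "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, record$samples))
  out <- record
  out$samples <- pmax(pmin(y, 1), -1)
  out
}

#' Sliding-RMS amplitude envelope
#'
#' @param record An [audio_record()].
#' @param window_ms RMS window length in ms.
#' @return Nonnegative numeric vector, one value per sample.
#' @export
amplitude_envelope <- function(record, window_ms = 5) {
  if (window_ms <= 0) stop("window_ms must be positive")
  x2 <- record$samples^2
  w <- max(1L, round(window_ms / 1000 * record$sample_rate_hz))
  # centered moving average of the squared signal via cumulative sums
  cs <- cumsum(c(0, x2))
  n <- length(x2)
  half <- w %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect plosives as isolated energy peaks separated by silence
#'
#' Thresholds the RMS envelope at `onset_threshold_rel` times its peak, merges
#' bursts separated by less than `min_silence_ms`, extends boundaries to the
#' nearest envelope local minimum, and drops bursts shorter than
#' `min_plosive_ms`. Over-long segments are kept here and rejected by
#' [clarity_filter()] with a logged reason.
#'
#' @param record An [audio_record()] (band filtering is applied internally).
#' @param config A [segmenter_config()].
#' @param prefiltered Set `TRUE` if `record` is already band filtered.
#' @return Data frame with columns `placement`, `start_sample`, `end_sample`,
#'   `start_ms`, `end_ms`, `peak_envelope`. Zero rows is a valid outcome.
#' @export
detect_plosives <- function(record, config = segmenter_config(), prefiltered = FALSE) {
  if (length(record$samples) == 0) stop("record is empty")
  fs <- record$sample_rate_hz
  rec <- if (prefiltered) record else band_filter(record, config$band_hz)
  env <- amplitude_envelope(rec, config$envelope_window_ms)
  peak <- max(env)
  empty <- data.frame(placement = integer(), start_sample = integer(),
                      end_sample = integer(), start_ms = numeric(),
                      end_ms = numeric(), peak_envelope = numeric())
  if (peak <= 0) return(empty)
  thr <- config$onset_threshold_rel * peak
  above <- env >= thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(starts) == 0) return(empty)

  # merge runs separated by less than the minimum silence
  min_sil <- round(config$min_silence_ms / 1000 * fs)
  keep_s <- starts[1]; ks <- c(); ke <- c()
  for (i in seq_along(starts)) {
    if (i < length(starts) && (starts[i + 1] - ends[i]) < min_sil) next
    ks <- c(ks, keep_s); ke <- c(ke, ends[i])
    if (i < length(starts)) keep_s <- starts[i + 1]
  }
  starts <- ks; ends <- ke

  # extend each boundary to the nearest envelope local minimum
  n <- length(env)
  for (i in seq_along(starts)) {
    s <- starts[i]
    while (s > 1 && env[s - 1] < env[s]) s <- s - 1
    e <- ends[i]
    while (e < n && env[e + 1] < env[e]) e <- e + 1
    starts[i] <- s; ends[i] <- e
  }
  # resolve overlaps created by the extension: cut at the envelope minimum
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ends[i - 1]) {
      cut <- starts[i] - 1 + which.min(env[starts[i]:ends[i - 1]])
      ends[i - 1] <- cut
      starts[i] <- min(cut + 1L, ends[i])
    }
  }

  # sharpen each onset to the first crossing of 5% of the segment's own peak:
  # a low segment-relative threshold keeps onset timing independent of burst
  # amplitude, preserving inter-onset gaps
  for (i in seq_along(starts)) {
    seg_peak <- max(env[starts[i]:ends[i]])
    j <- which(env[starts[i]:ends[i]] >= 0.05 * seg_peak)[1]
    if (!is.na(j)) starts[i] <- starts[i] + j - 1L
  }

  dur_ms <- (ends - starts + 1) / fs * 1000
  keep <- dur_ms >= config$min_plosive_ms
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(empty)
  data.frame(
    placement = seq_along(starts),
    start_sample = starts, end_sample = ends,
    start_ms = (starts - 1) / fs * 1000, end_ms = ends / fs * 1000,
    peak_envelope = vapply(seq_along(starts),
                           function(i) max(env[starts[i]:ends[i]]), 0)
  )
}

#' Clarity filter: reject non-laugh segments with logged reasons
#'
#' Approximates the clinical audit that discarded exclamations, coughs and
#' humming: segments violating the plosive duration bounds, or whose envelope
#' stays near its peak for longer than `max_plosive_ms` (a sustained
#' vocalization rather than a burst), are rejected with a reason code.
#'
#' @param segments Data frame from [detect_plosives()].
#' @param record The [audio_record()] the segments came from.
#' @param config A [segmenter_config()].
#' @return List with `accepted` (segments, placements renumbered) and
#'   `rejections` (data frame: placement, reason).
#' @export
clarity_filter <- function(segments, record, config = segmenter_config()) {
  fs <- record$sample_rate_hz
  env <- amplitude_envelope(record, config$envelope_window_ms)
  reasons <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    dur <- (segments$end_sample[i] - segments$start_sample[i] + 1) / fs * 1000
    if (dur > config$max_plosive_ms) { reasons[i] <- "too_long"; next }
    if (dur < config$min_plosive_ms) { reasons[i] <- "too_short"; next }
    seg_env <- env[segments$start_sample[i]:segments$end_sample[i]]
    plateau <- max_run_length(seg_env >= 0.9 * max(seg_env)) / fs * 1000
    if (plateau > config$max_plosive_ms) reasons[i] <- "plateau"
  }
  accepted <- segments[reasons == "", , drop = FALSE]
  if (nrow(accepted)) accepted$placement <- seq_len(nrow(accepted))
  rejections <- data.frame(placement = segments$placement[reasons != ""],
                           reason = reasons[reasons != ""])
  list(accepted = accepted, rejections = rejections)
}

max_run_length <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Segment a laugh: detection followed by the clarity filter
#'
#' @inheritParams detect_plosives
#' @return As [clarity_filter()].
#' @export
segment_laugh <- function(record, config = segmenter_config()) {
  rec <- band_filter(record, config$band_hz)
  segs <- detect_plosives(rec, config, prefiltered = TRUE)
  clarity_filter(segs, rec, config)
}
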