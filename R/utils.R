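`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase FFT band filter with raised-cosine transition edges. Exact zero
# phase and fast, but assumes the signal decays toward its ends (circular
# convolution): used for simulator output (silence-padded by construction)
# and for the pitch prefilter on short segments.
fft_band <- function(x, fs, lo = 0, hi = fs / 2, trans_lo = 20, trans_hi = 500) {
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n, 8)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (0:(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f)                 # mirror for negative frequencies
  H <- rep(1, nfft)
  if (lo > 0) {
    H[f < lo - trans_lo / 2] <- 0
    tr <- f >= lo - trans_lo / 2 & f <= lo + trans_lo / 2
    H[tr] <- 0.5 * (1 - cos(pi * (f[tr] - (lo - trans_lo / 2)) / trans_lo))
  }
  if (hi < fs / 2) {
    H[f > hi + trans_hi / 2] <- 0
    tr <- f >= hi - trans_hi / 2 & f <= hi + trans_hi / 2
    H[tr] <- H[tr] * 0.5 * (1 + cos(pi * (f[tr] - (hi - trans_hi / 2)) / trans_hi))
  }
  Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
}

# Butterworth designs are cached: design cost dominates for short segments.
cached_butter <- function(order, W, type) {
  key <- paste0("butter_", order, "_", type, "_", paste(format(W), collapse = "_"))
  flt <- .laughdx_env[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order, W, type = type)
    .laughdx_env[[key]] <- flt
  }
  flt
}
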