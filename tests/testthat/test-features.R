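# The six sound variables: F0 track, formants, power, entropy, voicing.

test_that("F0 tracking nails a pure tone and refuses white noise", {
  x <- make_tone(220, 0.3)
  tr <- f0_track(x, FS)
  expect_true(all(tr$voiced))
  expect_true(all(abs(tr$f0_hz - 220) < 2))

  set.seed(8)
  noise <- stats::rnorm(round(0.3 * FS)) * 0.3
  tr <- f0_track(noise, FS)
  expect_lte(mean(tr$voiced), 0.1)

  short <- f0_track(make_tone(220, 0.01), FS)
  expect_equal(nrow(short), 0)
  expect_true(isTRUE(attr(short, "too_short")))
})

test_that("F0 of simulated plosives matches the annotated truth within 5%", {
  n_ok <- 0; n <- 0
  for (s in 1:16) {
    set.seed(s)
    f0 <- stats::runif(1, 180, 330)
    sp <- plosive_spec(0, 110, f0, formants_hz = c(900, 1400, 2800),
                       noise_mix = stats::runif(1, 0.1, 0.45))
    x <- synth_plosive(sp, FS)
    est <- f0_mean(f0_track(x, FS))
    n <- n + 1
    if (!is.na(est) && abs(est - f0) / f0 < 0.05) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("f0_mean averages voiced frames only and flags all-unvoiced tracks", {
  tr <- data.frame(time_ms = c(0, 10, 20), f0_hz = c(190, NA, 210),
                   voiced = c(TRUE, FALSE, TRUE), acf_peak = c(0.9, 0.2, 0.9))
  expect_equal(f0_mean(tr), 200)
  tr$voiced <- FALSE
  expect_true(is.na(f0_mean(tr)))
})

test_that("LPC recovers designed resonator frequencies within 10%", {
  set.seed(12)
  truth <- c(700, 1200, 2600)
  sp <- plosive_spec(0, 120, 140, formants_hz = truth,
                     formant_bw_hz = c(80, 100, 140), noise_mix = 0.4)
  x <- synth_plosive(sp, FS)
  est <- formants_lpc(x, FS)
  expect_true(all(abs(est - truth) / truth < 0.10))
})

test_that("white noise without resonators yields no stable formants", {
  set.seed(13)
  x <- stats::rnorm(3000) * 0.3
  est <- formants_lpc(x, FS, max_bw_hz = 80)
  expect_true(any(is.na(est)) || length(est) < 3)
})

test_that("reported poles are genuine roots of the prediction polynomial", {
  set.seed(14)
  sp <- plosive_spec(0, 100, 200, noise_mix = 0.3)
  x <- synth_plosive(sp, FS)
  y <- x - 0.97 * c(0, x[-length(x)])
  n <- length(y)
  y <- y * (0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  a <- laughdx:::lpc_autocor(y, 24)
  est <- formants_lpc(x, FS)
  # direct-evaluation oracle: A(1/z) = 0 at the reported pole frequencies
  bws <- attr(est, "bandwidths")
  for (i in which(!is.na(est))) {
    r <- exp(-pi * bws[i] / FS)
    z <- r * exp(1i * 2 * pi * est[i] / FS)
    val <- 1 - sum(a * (1 / z)^(seq_along(a)))
    expect_lt(Mod(val), 1e-6)
  }
})

test_that("average power follows its closed forms and scales quadratically", {
  expect_equal(average_power(numeric(100)), 0)
  expect_equal(average_power(rep(c(1, -1), 500)), 1)
  a <- 0.4
  x <- make_tone(441, 1, amp = a)   # integer number of periods
  expect_lt(abs(average_power(x) - a^2 / 2) / (a^2 / 2), 0.01)
  c_ <- 3.7
  expect_lt(abs(average_power(c_ * x) / average_power(x) - c_^2), 1e-9)
  expect_error(average_power(numeric(0)), "empty")
})

test_that("spectral entropy has exact single-bin, flat and brute-force values", {
  # sine at an exact bin with rectangular window concentrates in one bin
  n_fft <- 2048
  k <- 200
  x <- sin(2 * pi * k * (0:(n_fft - 1)) / n_fft)
  h <- spectral_entropy(x, FS, n_fft = n_fft, window = "rectangular")
  expect_lt(as.numeric(h), 1e-6)

  # an impulse has an exactly flat magnitude spectrum
  imp <- c(1, numeric(255))
  h <- spectral_entropy(imp, FS, window = "rectangular")
  expect_equal(as.numeric(h), log2(attr(h, "n_bins")), tolerance = 1e-9)

  # brute-force oracle on a fixed 64-sample vector
  set.seed(15)
  v <- stats::rnorm(64)
  h <- spectral_entropy(v, FS, window = "rectangular")
  sp <- stats::fft(v)
  half <- 33
  freqs <- (0:32) * FS / 64
  keep <- freqs >= 50 & freqs <= 10000
  p <- Mod(sp[1:half][keep])^2
  p <- p / sum(p)
  oracle <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_lt(abs(as.numeric(h) - oracle), 1e-9)
})

test_that("spectral entropy is gain-invariant and flags silence", {
  set.seed(16)
  x <- stats::rnorm(500)
  h1 <- as.numeric(spectral_entropy(x, FS))
  for (c_ in c(1e-3, 0.5, 40)) {
    expect_lt(abs(as.numeric(spectral_entropy(c_ * x, FS)) - h1), 1e-9)
  }
  hs <- spectral_entropy(numeric(128), FS)
  expect_equal(as.numeric(hs), 0)
  expect_true(isTRUE(attr(hs, "silence")))
})

test_that("voiced fraction relates voiced time to the inter-onset interval", {
  tr <- data.frame(time_ms = seq(0, 190, 10), f0_hz = 200,
                   voiced = TRUE, acf_peak = 0.9)
  expect_equal(voiced_fraction(tr, 0, 200, 200), 1.0)
  tr2 <- tr[1:10, ]   # 100 ms of voicing
  expect_equal(voiced_fraction(tr2, 0, 100, 200), 0.5)
  # a fully aperiodic plosive stays below 0.1 under the simulator's own
  # bandwidth coupling (narrow resonators on pure noise ring quasi-periodically,
  # which is why noisy plosives get wide bandwidths)
  set.seed(17)
  sp <- plosive_spec(0, 120, 200, noise_mix = 1,
                     formant_bw_hz = laughdx:::noise_bw(1))
  x <- synth_plosive(sp, FS)
  tr3 <- f0_track(x, FS)
  expect_lte(voiced_fraction(tr3, 0, 120, 210), 0.1)
})

test_that("feature extraction is deterministic and degrades gracefully", {
  lg <- seeded_laugh(seed = 55, n_plosives = 5)
  f1 <- extract_laugh_features(lg$record)
  f2 <- extract_laugh_features(lg$record)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 5)
  expect_true(all(!is.na(f1$avg_power)))

  seg <- data.frame(placement = 1, start_sample = 1, end_sample = 2205,
                    start_ms = 0, end_ms = 100, peak_envelope = 0)
  silent <- audio_record(numeric(2205), FS)
  row <- extract_plosive_features(silent, seg)
  expect_equal(row$avg_power, 0)
  expect_equal(row$entropy_bits, 0)
  expect_true(is.na(row$f0_mean_hz))
})

test_that("simulator annotations are recovered within tolerance end to end", {
  n_f0_ok <- 0; n_f0 <- 0; fm_ok <- 0; fm_n <- 0
  for (s in 1:20) {
    lg <- seeded_laugh(seed = 200 + s,
                       class_label = if (s %% 2) "control" else "depression")
    fe <- extract_laugh_features(lg$record)
    for (k in seq_along(lg$truth$plosives)) {
      tp <- lg$truth$plosives[[k]]
      j <- which.min(abs(fe$onset_ms - tp$onset_ms))
      if (!length(j) || abs(fe$onset_ms[j] - tp$onset_ms) > 30) next
      if (tp$noise_mix < 0.5) {
        n_f0 <- n_f0 + 1
        if (!is.na(fe$f0_mean_hz[j]) &&
            abs(fe$f0_mean_hz[j] - tp$f0_hz) / tp$f0_hz < 0.05) n_f0_ok <- n_f0_ok + 1
        est <- c(fe$f1_hz[j], fe$f2_hz[j], fe$f3_hz[j])
        err <- abs(est - tp$formants_hz) / tp$formants_hz
        fm_n <- fm_n + 3
        fm_ok <- fm_ok + sum(err < 0.10, na.rm = TRUE)
      }
    }
  }
  expect_gte(n_f0_ok / n_f0, 0.9)
  expect_gte(fm_ok / fm_n, 0.9)
})
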