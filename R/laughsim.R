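# Source-filter laughter simulator: glottal impulse train + white noise mixed
# per plosive, shaped by three formant resonators, band-limited 50-10,000 Hz.
# Stands in for clinical recordings and carries ground truth for every stage.

.laughdx_env <- new.env(parent = emptyenv())

#' Cohort simulation configuration
#'
#' Defines the study conditions emulated by the simulator: cohort composition
#' (30 patients, 20 controls), laugh counts per subject (Poisson with means 17
#' and 21), the inter-plosive repetition band (200-220 ms), and the acoustic
#' class effects. Patients differ from controls, in expectation, by a spectral
#' entropy shift (bits), an energy shift (dB) and a flattening of the
#' fundamental-frequency arch across successive plosives.
#'
#' @param n_patients,n_controls Subject counts per class.
#' @param laughs_per_patient_mean,laughs_per_control_mean Poisson means for the
#'   number of laughs recorded per subject.
#' @param entropy_shift_bits Expected patient-minus-control shift in spectral
#'   entropy (negative: patient laughter is less spectrally diverse).
#' @param energy_shift_db Expected patient energy shift in dB (negative:
#'   weaker laughter).
#' @param arch_flattening Fraction in `[0, 1]` by which the patient F0 arch
#'   gain is shrunk (1 = completely flat arch).
#' @param gap_ms_band Length-2 band (ms) for consecutive plosive onset gaps.
#' @param sample_rate_hz Sampling rate; must be at least twice the 10 kHz
#'   analysis band edge.
#' @param band_hz Analysis band applied to all emitted audio.
#' @param seed Integer seed making the whole cohort a pure function of this
#'   configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30, n_controls = 20,
                          laughs_per_patient_mean = 17,
                          laughs_per_control_mean = 21,
                          entropy_shift_bits = -1,
                          energy_shift_db = -6,
                          arch_flattening = 0.6,
                          gap_ms_band = c(200, 220),
                          sample_rate_hz = 22050,
                          band_hz = c(50, 10000),
                          seed = 1L) {
  if (n_patients < 0 || n_controls < 0) stop("subject counts must be >= 0")
  if (sample_rate_hz < 2 * band_hz[2]) {
    stop("sample_rate_hz must be at least twice the upper band edge (",
         2 * band_hz[2], " Hz)")
  }
  if (gap_ms_band[1] >= gap_ms_band[2]) stop("gap_ms_band must be an increasing pair")
  structure(list(
    n_patients = n_patients, n_controls = n_controls,
    laughs_per_patient_mean = laughs_per_patient_mean,
    laughs_per_control_mean = laughs_per_control_mean,
    entropy_shift_bits = entropy_shift_bits,
    energy_shift_db = energy_shift_db,
    arch_flattening = arch_flattening,
    gap_ms_band = gap_ms_band,
    sample_rate_hz = sample_rate_hz,
    band_hz = band_hz,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Per-plosive ground-truth specification
#'
#' @param onset_ms,duration_ms Burst placement and length in ms.
#' @param f0_hz Fundamental frequency of the glottal pulse train.
#' @param formants_hz Three strictly increasing resonance frequencies.
#' @param formant_bw_hz Three resonance bandwidths.
#' @param amplitude Linear peak level in `(0, 1]`.
#' @param noise_mix Fraction in `[0, 1]` of aperiodic source energy.
#' @param f0_jitter Relative cycle-to-cycle F0 perturbation (natural glottal
#'   jitter; set 0 for a strictly periodic source).
#' @param voiced Logical; by convention `noise_mix < 0.5`.
#' @export
plosive_spec <- function(onset_ms, duration_ms, f0_hz,
                         formants_hz = c(700, 1200, 2600),
                         formant_bw_hz = c(80, 120, 160),
                         amplitude = 0.5, noise_mix = 0.3,
                         f0_jitter = 0.01, voiced = noise_mix < 0.5) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (any(diff(formants_hz) <= 0)) stop("formants must be strictly increasing")
  if (noise_mix < 0 || noise_mix > 1) stop("noise_mix must lie in [0, 1]")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must lie in (0, 1]")
  list(onset_ms = onset_ms, duration_ms = duration_ms, f0_hz = f0_hz,
       formants_hz = formants_hz, formant_bw_hz = formant_bw_hz,
       amplitude = amplitude, noise_mix = noise_mix,
       f0_jitter = f0_jitter, voiced = voiced)
}

# Second-order all-pole resonator cascade (vocal-tract model).
resonate <- function(x, formants_hz, bw_hz, fs) {
  for (i in seq_along(formants_hz)) {
    r <- exp(-pi * bw_hz[i] / fs)
    theta <- 2 * pi * formants_hz[i] / fs
    x <- as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive"))
  }
  x
}

#' Synthesize a single plosive from its specification
#'
#' Source model: glottal impulse train at `f0_hz` (first-difference
#' approximation of the flow derivative) mixed with white noise so that
#' `noise_mix` is the aperiodic fraction of source energy, shaped by three
#' formant resonators and a raised-cosine burst envelope, peak-normalized to
#' `amplitude`.
#'
#' @param spec A [plosive_spec()].
#' @param fs Sampling rate in Hz.
#' @return Numeric waveform of `round(duration_ms / 1000 * fs)` samples.
#' @export
synth_plosive <- function(spec, fs) {
  if (max(spec$formants_hz) >= fs / 2) {
    stop("sample rate too low for requested formants (need fs > ",
         2 * max(spec$formants_hz), " Hz)")
  }
  n <- max(8L, round(spec$duration_ms / 1000 * fs))
  # impulse train by phase accumulation; two-pole smoothing imposes the
  # glottal-flow spectral tilt, the first difference models lip radiation
  jitter <- spec$f0_jitter %||% 0
  rel <- if (jitter > 0) {
    1 + jitter * as.numeric(stats::filter(stats::rnorm(n), rep(1, 40) / sqrt(40),
                                          sides = 1, circular = TRUE))
  } else rep(1, n)
  phase <- cumsum(spec$f0_hz / fs * rel)
  pulses <- c(0, diff(floor(phase)))
  g <- as.numeric(stats::filter(pulses, 0.97, method = "recursive"))
  g <- as.numeric(stats::filter(g, 0.97, method = "recursive"))
  voiced_src <- c(g[1], diff(g))
  noise_src <- stats::rnorm(n)
  unit_rms <- function(v) if (sum(v^2) > 0) v / sqrt(mean(v^2)) else v
  src <- sqrt(1 - spec$noise_mix) * unit_rms(voiced_src) +
         sqrt(spec$noise_mix) * unit_rms(noise_src)
  y <- resonate(src, spec$formants_hz, spec$formant_bw_hz, fs)
  # fast fixed attack (8 ms) then raised-cosine decay: laughter plosives have
  # sharp onsets, and a duration-independent attack keeps onset timing crisp
  na <- min(max(2L, round(0.008 * fs)), n %/% 3)
  nd <- n - na
  env <- c(sin(pi / 2 * seq_len(na) / na)^2, cos(pi / 2 * seq_len(nd) / nd)^2)
  y <- y * env
  peak <- max(abs(y))
  if (peak > 0) y <- y * (spec$amplitude / peak)
  y
}

# --- entropy calibration -----------------------------------------------------
# Spectral entropy is not an analytic function of the synthesis controls
# (noise mix, formant bandwidths), so a monotone lookup table is measured once
# per sample rate on a reference plosive and inverted by interpolation.

noise_bw <- function(noise_mix) c(50, 70, 90) * (1 + 3 * noise_mix)

entropy_noise_map <- function(fs) {
  key <- paste0("emap_", fs)
  if (!is.null(.laughdx_env[[key]])) return(.laughdx_env[[key]])
  grid <- seq(0.10, 0.95, length.out = 13)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(990017L)
  h <- vapply(grid, function(nm) {
    sp <- plosive_spec(0, 110, 200, formants_hz = c(900, 1400, 2800),
                       noise_mix = nm, formant_bw_hz = noise_bw(nm))
    mean(vapply(1:4, function(i) spectral_entropy(synth_plosive(sp, fs), fs), 0))
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else set.seed(NULL)
  h <- cummax(h)  # enforce monotone non-decreasing for invertibility
  map <- list(noise_mix = grid, entropy = h)
  .laughdx_env[[key]] <- map
  map
}

entropy_to_noise_mix <- function(target_bits, fs) {
  map <- entropy_noise_map(fs)
  out <- stats::approx(map$entropy, map$noise_mix, xout = target_bits,
                       yleft = map$noise_mix[1],
                       yright = map$noise_mix[length(map$noise_mix)],
                       ties = "ordered")$y
  pmin(pmax(out, 0.10), 0.95)
}

# --- subject profiles --------------------------------------------------------

# Rise-fall F0 arch template across successive plosives (max 8 supported).
ARCH_TEMPLATE <- c(0.00, 0.20, 0.30, 0.20, 0.00, -0.15, -0.30, -0.40)

#' Draw a subject profile for one simulated participant
#'
#' Control subjects are drawn from the baseline distributions; patients get the
#' configured class effects: spectral-entropy offset shifted by
#' `entropy_shift_bits`, energy scaled by `energy_shift_db`, and the F0 arch
#' gain shrunk by `arch_flattening`.
#'
#' @param class_label `"depression"` or `"control"`.
#' @param config A [cohort_config()].
#' @param seed Optional integer; when given, the draw is a pure function of it.
#' @return A list of class `subject_profile`.
#' @export
sample_subject_profile <- function(class_label, config = cohort_config(), seed = NULL) {
  if (!class_label %in% c("depression", "control")) {
    stop("class_label must be 'depression' or 'control', got: ", class_label)
  }
  if (!is.null(seed)) set.seed(seed)
  patient <- class_label == "depression"
  base_f0 <- min(600, max(75, stats::rnorm(1, 260, 35)))
  arch <- max(0, stats::rnorm(1, 0.25, 0.05))
  if (patient) arch <- arch * (1 - config$arch_flattening)
  energy <- exp(stats::rnorm(1, 0, 0.15))
  if (patient) energy <- energy * 10^(config$energy_shift_db / 20)
  entropy_offset <- stats::rnorm(1, if (patient) config$entropy_shift_bits else 0, 0.15)
  mean_laughs <- if (patient) config$laughs_per_patient_mean else config$laughs_per_control_mean
  structure(list(
    subject_id = sprintf("S%s_%06d", if (patient) "P" else "C",
                         sample.int(999999L, 1)),
    class_label = class_label,
    base_f0_hz = base_f0,
    f0_arch_gain = arch,
    energy_scale = energy,
    entropy_offset_bits = entropy_offset,
    n_laughs = stats::rpois(1, mean_laughs)
  ), class = "subject_profile")
}

#' Synthesize one laugh for a subject profile
#'
#' A laugh is a run of 4-7 plosives (5 or more with probability 0.8) repeated
#' at onset gaps drawn uniformly from the configured 200-220 ms band. Each
#' plosive's F0 follows the subject's rise-fall arch, its amplitude carries the
#' subject's energy scale, and its noise mix realizes the subject's entropy
#' target through the calibrated entropy lookup.
#'
#' @param profile A [sample_subject_profile()] result.
#' @param config A [cohort_config()].
#' @param laugh_id Identifier stamped on the returned record and truth.
#' @param n_plosives Optional override of the plosive count (0 gives silence).
#' @param seed Optional integer seed.
#' @return A list with elements `record` ([audio_record()]) and `truth`
#'   (list with `laugh_id` and `plosives`, a list of [plosive_spec()]s).
#' @export
synth_laugh <- function(profile, config = cohort_config(), laugh_id = "L1",
                        n_plosives = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  if (is.null(n_plosives)) {
    n_plosives <- sample(4:7, 1, prob = c(0.20, 0.45, 0.25, 0.10))
  }
  if (n_plosives == 0) {
    rec <- audio_record(numeric(round(0.5 * fs)) + 0, fs,
                        subject_id = profile$subject_id,
                        class_label = profile$class_label, laugh_id = laugh_id)
    return(list(record = rec, truth = list(laugh_id = laugh_id, plosives = list())))
  }
  map <- entropy_noise_map(fs)
  h_ref <- stats::approx(map$noise_mix, map$entropy, xout = 0.45)$y
  base_nm <- entropy_to_noise_mix(h_ref + profile$entropy_offset_bits, fs)

  gaps <- stats::runif(n_plosives - 1, config$gap_ms_band[1], config$gap_ms_band[2])
  onsets <- 60 + c(0, cumsum(gaps))
  durations <- stats::runif(n_plosives, 85, 140)
  arch <- ARCH_TEMPLATE[seq_len(n_plosives)]
  f0s <- profile$base_f0_hz * (1 + profile$f0_arch_gain * arch)
  amps <- pmin(1, pmax(0.02,
    0.55 * profile$energy_scale * (1 + 0.15 * arch) * exp(stats::rnorm(n_plosives, 0, 0.05))))
  nms <- pmin(0.95, pmax(0.10, base_nm + stats::rnorm(n_plosives, 0, 0.03)))

  plosives <- vector("list", n_plosives)
  total_ms <- onsets[n_plosives] + durations[n_plosives] + 120
  x <- numeric(round(total_ms / 1000 * fs))
  for (k in seq_len(n_plosives)) {
    f1 <- stats::rnorm(1, 900, 70)
    f2 <- max(f1 + 300, stats::rnorm(1, 1400, 100))
    f3 <- max(f2 + 600, stats::rnorm(1, 2800, 150))
    sp <- plosive_spec(onset_ms = onsets[k], duration_ms = durations[k],
                       f0_hz = f0s[k], formants_hz = c(f1, f2, f3),
                       formant_bw_hz = noise_bw(nms[k]),
                       amplitude = amps[k], noise_mix = nms[k])
    burst <- synth_plosive(sp, fs)
    i0 <- round(onsets[k] / 1000 * fs) + 1
    idx <- i0:(i0 + length(burst) - 1)
    x[idx] <- x[idx] + burst
    plosives[[k]] <- sp
  }
  x <- band_limit(x, fs, config$band_hz)
  x <- pmax(pmin(x, 1), -1)
  rec <- audio_record(x, fs, subject_id = profile$subject_id,
                      class_label = profile$class_label, laugh_id = laugh_id)
  list(record = rec, truth = list(laugh_id = laugh_id, plosives = plosives))
}

#' Simulate a full cohort in memory
#'
#' Draws subject profiles for the configured numbers of patients and controls,
#' synthesizes every laugh, and returns records plus ground-truth annotations.
#' The result is a pure function of `config` (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A list with `subjects` (data frame) and `laughs` (list of
#'   `list(record, truth)`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  entropy_noise_map(config$sample_rate_hz)  # build lookup outside subject RNG stream
  classes <- c(rep("depression", config$n_patients), rep("control", config$n_controls))
  subjects <- list()
  laughs <- list()
  for (i in seq_along(classes)) {
    prof <- sample_subject_profile(classes[i], config)
    prof$subject_id <- sprintf("S%03d_%s", i, if (classes[i] == "depression") "P" else "C")
    subjects[[i]] <- data.frame(
      subject_id = prof$subject_id, class_label = prof$class_label,
      base_f0_hz = prof$base_f0_hz, f0_arch_gain = prof$f0_arch_gain,
      energy_scale = prof$energy_scale,
      entropy_offset_bits = prof$entropy_offset_bits,
      n_laughs = prof$n_laughs, stringsAsFactors = FALSE
    )
    for (j in seq_len(prof$n_laughs)) {
      lid <- sprintf("%s_L%03d", prof$subject_id, j)
      laughs[[length(laughs) + 1]] <- synth_laugh(prof, config, laugh_id = lid)
    }
  }
  subjects <- if (length(subjects)) do.call(rbind, subjects) else
    data.frame(subject_id = character(), class_label = character(),
               base_f0_hz = numeric(), f0_arch_gain = numeric(),
               energy_scale = numeric(), entropy_offset_bits = numeric(),
               n_laughs = integer())
  list(subjects = subjects, laughs = laughs, config = config)
}

#' Generate a cohort on disk
#'
#' Writes one 16-bit PCM WAV per laugh, a per-plosive truth table, a subject
#' table and a manifest. Regenerating with the same configuration and seed is
#' byte-identical.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  dir.create(file.path(out_dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cohort <- simulate_cohort(config)
  utils::write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  manifest <- list(); truth_rows <- list()
  for (lg in cohort$laughs) {
    wav_path <- file.path("wav", paste0(lg$record$laugh_id, ".wav"))
    write_wav(lg$record, file.path(out_dir, wav_path))
    manifest[[length(manifest) + 1]] <- data.frame(
      laugh_id = lg$record$laugh_id, subject_id = lg$record$subject_id,
      class_label = lg$record$class_label, wav = wav_path,
      n_plosives = length(lg$truth$plosives), stringsAsFactors = FALSE
    )
    for (k in seq_along(lg$truth$plosives)) {
      sp <- lg$truth$plosives[[k]]
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        laugh_id = lg$record$laugh_id, index = k, onset_ms = sp$onset_ms,
        duration_ms = sp$duration_ms, f0_hz = sp$f0_hz,
        f1_hz = sp$formants_hz[1], f2_hz = sp$formants_hz[2],
        f3_hz = sp$formants_hz[3], amplitude = sp$amplitude,
        noise_mix = sp$noise_mix, stringsAsFactors = FALSE
      )
    }
  }
  empty_manifest <- data.frame(laugh_id = character(), subject_id = character(),
                               class_label = character(), wav = character(),
                               n_plosives = integer())
  manifest <- if (length(manifest)) do.call(rbind, manifest) else empty_manifest
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(laugh_id = character(), index = integer(), onset_ms = numeric(),
               duration_ms = numeric(), f0_hz = numeric(), f1_hz = numeric(),
               f2_hz = numeric(), f3_hz = numeric(), amplitude = numeric(),
               noise_mix = numeric())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
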