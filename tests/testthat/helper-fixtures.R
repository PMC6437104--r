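# Shared fixtures: all audio is generated in code at test time.

FS <- 22050

make_tone <- function(freq_hz, dur_s = 1, fs = FS, amp = 0.8) {
  amp * sin(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs)
}

tone_record <- function(freq_hz, dur_s = 1, fs = FS, amp = 0.8) {
  audio_record(make_tone(freq_hz, dur_s, fs, amp), fs)
}

# A small but fully structured cohort for pipeline tests.
tiny_cohort_config <- function(seed = 42L, ...) {
  cohort_config(n_patients = 3, n_controls = 3,
                laughs_per_patient_mean = 3, laughs_per_control_mean = 3,
                seed = seed, ...)
}

# Deterministic laugh + truth for segmentation/feature oracles.
seeded_laugh <- function(seed = 1L, class_label = "control",
                         config = cohort_config(), n_plosives = NULL) {
  prof <- sample_subject_profile(class_label, config, seed = seed)
  synth_laugh(prof, config, laugh_id = paste0("L", seed),
              n_plosives = n_plosives, seed = seed + 1000L)
}

# Match detected segments against truth onsets within a tolerance (ms).
segment_match_counts <- function(truth_onsets, detected_onsets, tol_ms = 30) {
  recalled <- sum(vapply(truth_onsets, function(o)
    any(abs(detected_onsets - o) < tol_ms), TRUE))
  precise <- sum(vapply(detected_onsets, function(o)
    any(abs(truth_onsets - o) < tol_ms), TRUE))
  list(recalled = recalled, n_truth = length(truth_onsets),
       precise = precise, n_detected = length(detected_onsets))
}

# Small labeled Gaussian-blob classification problem.
make_blobs <- function(n_per_class = 100, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * p, -sep / 2), ncol = p),
             matrix(stats::rnorm(n_per_class * p, sep / 2), ncol = p))
  list(X = X, y = c(rep(-1, n_per_class), rep(1, n_per_class)))
}

# Brute-force AUC: concordant-pair fraction with half credit for ties.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# A plosive data matrix built directly (no audio), n laughs x 5 plosives.
synthetic_data_matrix <- function(n_laughs = 4, plosives_per_laugh = 5,
                                  health = NULL, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_laughs)) {
    h <- if (is.null(health)) ((i - 1) %% 2) + 1L else health[i]
    for (k in seq_len(plosives_per_laugh)) {
      rows[[length(rows) + 1]] <- data.frame(
        laugh_id = sprintf("L%02d", i), subject_id = sprintf("S%02d", i),
        placement = k, onset_ms = 60 + 210 * (k - 1),
        duration_ms = stats::runif(1, 85, 140),
        f0_mean_hz = stats::rnorm(1, 250, 20),
        f1_hz = stats::rnorm(1, 900, 50), f2_hz = stats::rnorm(1, 1400, 60),
        f3_hz = stats::rnorm(1, 2800, 80),
        avg_power = stats::runif(1, 0.005, 0.03),
        entropy_bits = stats::rnorm(1, 4.5, 0.5),
        voiced_pct = stats::runif(1), health_status = h)
    }
  }
  do.call(rbind, rows)
}
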