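---
title: "Screening depression from laughter acoustics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening depression from laughter acoustics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Laughter is a structured vocal signal: a bout consists of a run of short
energy bursts — *plosives* — separated by near-silence and repeated roughly
every 200–220 ms. Clinical observations suggest that depression changes the
acoustics of these bursts: depressed laughter tends to be weaker (less
energy), less diverse in frequency content (lower spectral entropy), and
flatter in its fundamental-frequency contour across successive plosives.

`laughdx` implements the full software chain of a laughter-based screening
instrument: segment a recording into plosives, measure six acoustic
variables on each, assemble laugh-level exemplars, train small neural-network
classifiers, and evaluate them with a standard diagnostic battery. Because
clinical laughter recordings are not publicly available, the package also
contains a seeded simulator that generates laughter audio with controllable
class differences and per-plosive ground truth, so that every stage can be
tested end to end against known truth.

## The simulator

### Signal model

Each plosive is produced by a classic source–filter chain:

* **Voiced source**: an impulse train at the plosive's fundamental frequency
  F0, smoothed by two one-pole filters (coefficient 0.97) to impose the
  falling glottal-flow spectrum, then differentiated once to model lip
  radiation (net source tilt about −6 dB/octave). Cycle-to-cycle F0 jitter of
  1% (a low-pass random modulation) reproduces the natural aperiodicity of
  phonation; a strictly periodic source is available by setting
  `f0_jitter = 0`.
* **Noise source**: white Gaussian noise. The `noise_mix` parameter sets the
  fraction of source *energy* that is aperiodic; the two sources are mixed
  after unit-RMS normalization as `sqrt(1 - m) * voiced + sqrt(m) * noise`.
* **Vocal tract**: three cascaded two-pole resonators. Formant centers are
  drawn per plosive around 900, 1400 and 2800 Hz — laughter is usually an
  open-vowel vocalization, which puts F1 substantially higher than in neutral
  speech. Bandwidths are coupled to the noise mix
  (`(50, 70, 90) * (1 + 3 * noise_mix)` Hz): noisier plosives are also less
  sharply resonant, which is both phonetically reasonable and the second
  handle (besides the mix itself) on spectral entropy.
* **Burst envelope**: a fixed 8 ms raised-cosine attack followed by a
  raised-cosine decay over the rest of the burst. Laughter plosives have
  sharp onsets; a duration-independent attack also keeps onset timing crisp,
  so inter-onset intervals survive segmentation nearly unchanged.
* **Band limit**: every assembled laugh is zero-phase band-limited to
  50–10,000 Hz, the analysis band assumed throughout the package.

A laugh is 4–7 plosives (5 or more with probability 0.8, so that most laughs
support the five-plosive network schemas), onset gaps drawn uniformly from
200–220 ms, durations from 85–140 ms.

### Subjects and class effects

A simulated subject carries a base F0 (normal, mean 260 Hz, sd 35 — laughter
sits well above speaking pitch), an F0 *arch gain*, an energy scale, an
entropy offset, and a Poisson-distributed laugh count (means 17 for patients
and 21 for controls, matching the cohort the package emulates: 30 patients,
20 controls). The F0 of plosive *k* is `base_f0 * (1 + gain * a_k)` with a
fixed rise–fall template `a_k`; the arch rises over the first three plosives
and falls below baseline at the end.

Patients differ from controls, in expectation, by three configurable effects:

| effect | default | acts through |
|---|---|---|
| spectral entropy | −1 bit | noise mix + bandwidth coupling |
| energy | −6 dB | plosive peak amplitude |
| F0 arch | ×0.4 (60% flattening) | arch gain |

The published account of the phenomenon gives directions but no effect
sizes, so the defaults are one fixed, realistic choice: −1 bit is large
enough to be visible per plosive against the ~0.7-bit within-class spread
yet far from degenerate; −6 dB halves the amplitude, consistent with
"weaker" laughter; 60% flattening leaves a residual arch. With all three set
to zero the two classes are generated by identical code paths, which the
tests use as a null control.

Spectral entropy is not an analytic function of the synthesis controls, so
the mapping from a target entropy to a noise mix is a monotone lookup table,
measured once per sample rate on a reference plosive and inverted by linear
interpolation. Targets outside the table's range are clamped — an extreme
configured shift therefore partially saturates rather than extrapolating.

### What the simulator does not capture

Perceptual realism is a non-goal. Real recordings contain environmental
noise, room reverberation, speech–laugh overlaps, inhalation sounds and
recorder nonlinearities, none of which are simulated; voiced/unvoiced
phonetic categories are reduced to the single noise-mix axis; bouts and
episodes above the plosive level are not modeled because the classifiers
consume plosives only. Passing tests therefore demonstrate that the chain
recovers *planted* structure through realistic-but-clean audio, not that the
classifier transfers to clinical recordings.

## Plosive segmentation

The detector works on the 50–10,000 Hz band-filtered waveform (order-5
Butterworth high- and low-pass, applied forward–backward so onsets do not
shift). The amplitude envelope is a 5 ms sliding RMS — plosives are *energy*
peaks, and RMS is directly energy-based with a single parameter. Detection
then proceeds:

1. threshold the envelope at 10% of its per-recording peak (relative, because
   recordings have unknown gain);
2. merge bursts separated by less than 20 ms of silence;
3. extend each boundary to the nearest envelope local minimum, which makes
   durations robust to the threshold choice;
4. sharpen each onset to the first crossing of 5% of the segment's own peak —
   a low segment-relative threshold keeps onset timing independent of burst
   amplitude, so inter-onset gap statistics survive;
5. drop bursts shorter than 30 ms.

A separate *clarity filter* mimics the audit that discards non-laugh
vocalizations: segments longer than 350 ms, or whose envelope stays above
90% of its peak for longer than that (a sustained tone rather than a burst),
are rejected with a reason code. Duration rules are an intentionally crude
proxy — discriminating laughter from speech properly is out of scope.

The envelope window, thresholds and silence gap are configuration with the
defaults above; no published values exist for them.

## The six sound variables

* **Duration** (ms) — segment end minus onset.
* **Mean F0** (Hz) — frames of 30 ms every 10 ms; a frame's period is the
  peak of the normalized autocorrelation within 75–600 Hz, with parabolic
  lag interpolation. Two estimator details matter. First, the frame is
  zero-phase low-passed at 1.2× the upper F0 bound before autocorrelation:
  formant ringing otherwise injects spurious peaks into the lag range.
  Second, the *voicing decision* (normalized autocorrelation ≥ 0.4) is made
  on the raw, unfiltered frame: band-limited noise is autocorrelated at
  short lags and would masquerade as voiced after the prefilter. The
  plosive's F0 is the arithmetic mean over voiced frames; with no voiced
  frame it is `NA`, never a default.
* **F1–F3** (Hz) — autocorrelation-method LPC of order `2 + fs/1000`
  (Levinson–Durbin) on the pre-emphasized (0.97), Hamming-windowed central
  15–75% of the burst (attack and decay transients bias the all-pole fit).
  Formants are pole angles with frequency in 90–5,000 Hz and bandwidth
  below 400 Hz, sorted ascending; fewer than three qualifying poles yield
  `NA` flags.
* **Average power** — mean squared amplitude over the burst (normalized
  audio, dimensionless). Scales exactly as gain squared.
* **Spectral Shannon entropy** (bits) — the Hann-windowed power spectrum,
  restricted to 50–10,000 Hz, normalized to a probability vector `p`;
  `H = -sum(p log2 p)`. Gain-invariant by construction; an all-zero segment
  returns 0 with a silence flag. The estimator (window, band, FFT length =
  next power of two) is fixed and documented here because no canonical
  choice exists.
* **Voiced fraction** — voiced frames × 10 ms divided by the interval from
  this plosive's onset to the next one's (or to its own end for the last
  plosive), clamped to [0, 1].

## Network input schemas and the leakage decision

Classifiers consume laugh-level exemplars built from the first five plosives
of each laugh; laughs with fewer than five plosives are excluded rather than
padded (a pad value would dominate training at these sample sizes), as are
laughs with undefined F0/formants under the schemas that need them.

* `ANN40` (p = 40): eight acoustic columns per plosive — duration, F0 mean,
  F1, F2, F3, power, entropy, voiced fraction — for plosives 1–5.
* `EANN5` (p = 5): average power of plosives 1–5.
* `P5ANN6` (p = 6): duration, F0 mean, F1, F2, power and entropy of the
  fifth plosive.

The historical description of the 40-input layout counts "six variables plus
two" per plosive, where the two extras are the plosive's placement index and
the subject's *health status*. Feeding the class label to a classifier is
target leakage: it makes any reported validity meaningless. The default
`ANN40` therefore carries acoustic channels only — the three formants are
kept as separate columns, placement is implicit in the block position of
each plosive, and no label channel exists. A `legacy_layout = TRUE` layout
reproducing the literal composition (placement and label as input channels,
at the cost of the F3 and voiced-fraction columns) exists purely as a study
control; the acceptance suite shows it reaching ≥99% held-out accuracy on a
cohort with *zero* acoustic class differences, which is the whole argument
for excluding it.

Health status is stored as 1 = depression, 2 = healthy in every file, and
mapped to +1/−1 only at the network boundary. All features are z-scored
with parameters fit on the training split only; tanh units saturate on raw
hertz scales.

## The classifiers

All four networks are trained by batch ("static") backpropagation with
per-layer step sizes and momentum, implemented from scratch in the package:

* **MLP** (all three schemas): layers p–16–9–1, tanh throughout. Step sizes
  1.0 (first hidden), 0.1 (second hidden), 0.01 (output); momentum 0.7
  everywhere; at most 10,000 epochs with an MSE floor (default 1e-4) as the
  stop criterion. Weights start uniform in [−0.5, 0.5] from a seed;
  training is bit-reproducible.
* **RBFN** (ANN40 only, mirroring the historical finding that only the
  40-input variant was worth reporting): 40–8–4–1. Phase 1 places 8
  prototype centers by Lloyd's k-means under Euclidean distance (≤100
  epochs, empty clusters reseeded from the farthest point); widths are the
  mean distance to the two nearest fellow centers — a standard, scale-free
  overlap heuristic. Phase 2 freezes the prototypes and trains the Gaussian
  activations through a 4-unit tanh layer and tanh output with steps 1.0 and
  0.1, momentum 0.7, ≤10,000 epochs.

The update rule is `v(t) = mu*v(t-1) - eta_l * dMSE/dw; w <- w + v(t)`; with
momentum zero this reduces exactly to plain gradient descent, and the
analytic gradients match central finite differences to 1e-6 relative error
(both are tested). An online (per-exemplar) mode exists but is off by
default. Because the output unit is a tanh, the training MSE is bounded by
4; the divergence guard (abort above 1e6) exists for numerical pathology
only.

The decision rule is `label = +1 (depression) iff score > threshold`
(strict, threshold 0 by default); raw scores are kept for ROC analysis.

## Splitting and evaluation

The holdout split reserves 20% for evaluation, stratified by class. The
default split *unit is the subject*: all laughs of one participant stay on
one side, so reported performance reflects unseen individuals. Laugh-unit
splitting is available for comparison but lets a network recognize
individuals rather than the condition.

The evaluation battery reports, at both the laugh level and the subject
level (majority vote over a subject's laugh predictions, ties toward
depression — a screening instrument prefers a false alarm to a miss):

* the confusion matrix with a row-percent view (rows sum to 100);
* validity: accuracy, sensitivity (true-positive rate), *effectiveness* —
  implemented as the true-negative rate, i.e. specificity, which is the
  definition consistent with the confusion-matrix convention used here —
  and precision; undefined ratios are flagged, not propagated as NaN;
* performance: MSE, NMSE (MSE over target variance), Pearson r, %error,
  and the model-selection scores `AIC = n ln(MSE) + 2k` and
  `MDL = n ln(MSE) + (k/2) ln(n)` with `k` counting every trainable scalar
  (for the RBFN: centers and widths included);
* the ROC curve from a threshold sweep over the unique scores with infinite
  sentinels (ties collapse into one threshold), AUC by the trapezoid rule —
  equal by construction to the concordant-pair fraction with half credit
  for ties, which the tests verify exhaustively at small n;
* input sensitivity: each channel swept over its training mean ± 1 sd in 50
  steps with all other channels at their means; the dispersion (sd) of the
  network output is the channel's score, and channels are ranked by it.
  The ±1 sd range is a choice (nothing canonical exists); constant channels
  score 0 with a flag.

## Test design and problem sizes

The test suite generates all fixtures in code. Sizes were chosen to give
each statistical assertion adequate power while keeping a full run on one
CPU comfortable:

* segmentation fidelity: 200 simulated laughs (about 1,070 plosives);
  recall, precision and the fraction of inter-onset gaps inside the
  generative 200–220 ms band are all required ≥ 0.95;
* estimator recovery: F0 within ±5% and formants within ±10% of annotated
  truth for ≥90% of truth-voiced plosives over 20 laughs (the same check at
  lower n runs inside the feature tests);
* parameter recovery: one default 50-subject cohort; the ANN40 MLP must
  reach ≥85% held-out laugh-level sensitivity, and the aggregated
  sensitivity ranking must place entropy and energy as the top two variables
  in ≥8 of 10 training/split seeds;
* null-effect control: a *balanced* cohort of 80 + 80 subjects with
  Poisson(5) laughs each and all effects zero. Under subject-level splitting
  the held-out accuracy of a leakage-free pipeline is chance; because
  predictions are correlated within subject, the spread of the accuracy
  estimate is governed by the number of test *subjects*, so the null cohort
  trades laughs per subject for subject count (32 test subjects give an
  accuracy sd of about 0.045). Accuracy must fall in [40%, 60%] for ≥9 of
  10 split/training seeds, and the strict literal layout must reach ≥99% on
  the same null data.

## Known limitations

* The entropy control saturates at the edges of the calibration table, so
  configured shifts beyond roughly ±1.5 bits are compressed.
* LPC formant estimates on high-pitched voiced plosives are biased toward
  harmonics; the mid-burst analysis window and the estimator defaults keep
  ~95% of estimates within ±10% on simulator output, but individual
  estimates can be off by more.
* The clarity filter is duration-based only; it cannot reject speech or
  coughs that happen to be plosive-shaped.
* All performance figures in this package are measured on synthetic
  cohorts; nothing here validates clinical transfer.
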