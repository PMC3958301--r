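---
title: "Data-reduction strategies for wireless EEG seizure detection: models and methods"
author: "seizlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-reduction strategies for wireless EEG seizure detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizlink)
```

## The problem

A wireless EEG sensor node records multichannel scalp EEG and streams it to a
data server where seizure detection runs. The radio dominates the node's
power budget: a 32-electrode montage at 250 Hz and 16 bits produces
`data_rate_bps(32, 250, 16)` = 128000 bit/s (125 kbit/s with binary
prefixes), far too much to stream continuously from a battery-powered
device. seizlink models the three ways of spending that budget:

1. **raw** — transmit every sample; the server extracts features and
   classifies;
2. **compressed** — compress each epoch on the node with compressive sensing
   (CS), reconstruct on the server, then extract features and classify;
3. **features** — extract low-complexity features on the node and transmit
   only those (an `N:1` reduction for epochs of `N` samples).

Every stage between the electrode and the classifier is implemented and
simulated: epoch segmentation, feature extraction, CS encoding and
reconstruction, 16-bit uniform quantization, an i.i.d. bit-flip channel at a
configurable bit error rate (BER), SVM classification, and event-based
evaluation under leave-one-record-out (LORO) cross-validation.

## Features and their cost model

For an epoch `x_1..x_N` (default `N = 512`, i.e. 4 s at 128 Hz), computed
per channel and concatenated into a 23-element vector:

* **energy** `E = (1/N) sum x_i^2` — mean instantaneous power;
* **line length** `LL = (1/(N-1)) sum |x_{i+1} - x_i|` — mean absolute
  first difference, sensitive to amplitude and frequency increases;
* **nonlinear autocorrelation (NLACC)** — the epoch is cut into
  `N_S = floor(N/w)` sub-windows of `w = 15` samples; with per-sub-window
  extremes `max(S_i)`, `min(S_i)`,
  `HV_i = min(max(S_i), max(max(S_{i+1}), max(S_{i+2})))` and
  `LV_i = max(min(S_i), min(min(S_{i+1}), min(S_{i+2})))`, NLACC is
  `sum(HV_i - LV_i)`. It responds to repetitive spikes whose maxima and
  minima repeat across neighboring sub-windows — classic tonic-clonic
  morphology — while single transients contribute little.

Two definitional choices are deliberately resolved here. First, `HV_i` and
`LV_i` reference sub-windows `i+1` and `i+2`, so they are defined only for
`i <= N_S - 2`; `nlacc()` sums exactly those defined terms (an
alternating-spike epoch therefore scores `2A(N_S - 2)` for spike amplitude
`A`). Second, `N_S = floor(N/w)` and the trailing `N mod w` samples of each
epoch are discarded (for `N = 512`, `N_S = 34` and 2 samples are unused);
remainder handling is otherwise unspecified in the literature this package
follows.

`count_operations()` instruments canonical streaming-firmware realizations
of the three extractors and tallies additions, assignments, comparisons and
multiplications as they execute. The conventions — subtractions count as
additions, divisions as multiplications, `|.|` as a comparison plus a
worst-case negation, two-argument min/max as a comparison plus a
conditional-move assignment, worst-case branches always counted — are
documented in `R/opcount.R` and reproduce the published cost model exactly:

| feature | additions | assignments | comparisons | multiplications |
|---|---|---|---|---|
| energy | `N` | `N+1` | 0 | `N+1` |
| line length | `4N-3` | `N` | `N-1` | 1 |
| NLACC | `2N_S` | `2N+9N_S-4` | `2N+2N_S-4` | 0 |

One wrinkle is worth stating plainly: those NLACC closed forms are only
consistent with a firmware loop that accumulates `HV_i - LV_i` over **all**
`N_S` sub-windows, clamping the out-of-range neighbor indices of the last
two terms (the additions column is `2N_S`, not `2(N_S - 2)`). The
instrumented walk therefore models that variant, while `nlacc()` computes
the corrected `N_S - 2`-term value; the boundary terms do not involve the
signal's temporal structure and have no bearing on detection. Whether the
published assignment/comparison cells assume worst-case or average-case
branches is not stated anywhere; worst-case counting reproduces them under
the conventions above, and the test suite asserts the agreement for
`N` in 128..896 rather than hiding any residual.

## Synthetic EEG generator

The generator emulates the statistical structure the pipeline needs from
long-term pediatric scalp recordings, not their full physiology:

* **background**: per-channel stationary AR(2) noise,
  `x_t = 1.9 x_{t-1} - 0.905 x_{t-2} + e_t` with Gaussian innovations
  (`noise_sd = 10` signal units, stationary SD about 325 via
  `background_sd()`). The poles put the spectral mass in the delta band
  with a steep roll-off — the 1/f-like character that makes real EEG
  compressible in a DCT dictionary. A flatter AR(2) was rejected because it
  is incompressible at any ratio, which would make the compressed branch
  degenerate rather than degrade with compression as real EEG does.
* **seizures**: inside each annotated event a 3 Hz train of biphasic
  spikes with alternating polarity and ±10% per-spike amplitude jitter is
  added to all channels, scaled by `seizure_gain` (default 6) background
  SDs and a per-channel attenuation drawn once from U(0.5, 1). This is the
  repetitive similar-extremes morphology NLACC targets.
* **annotations**: integer-second onsets/offsets, non-overlapping, default
  durations 6-752 s (the clinical range), serialized in plain-text summary
  files; signals round-trip through 16-bit EDF.
* **determinism**: every consumer (per-channel background, attenuation,
  event placement, spike jitter, channel corruption, measurement matrices)
  draws from its own substream derived from one master seed
  (`substream_seed()`), so changing the channel count or sweep order never
  perturbs other draws.

What the generator does **not** model: artifacts (eye blinks, EMG,
electrode pops), realistic 10-20 spatial topography, inter-channel
correlation of the background, non-stationary sleep/wake cycles, or focal
low-amplitude seizures. Passing tests on this data therefore demonstrate
that the pipeline's machinery is correct and that its qualitative
BER/compression trends have the right direction — not that the absolute
detection numbers transfer to clinical recordings. A replication path for
archival data exists (`load_chbmit()` reads EDF directories with summary
annotations and decimates 256 to 128 Hz with an anti-alias FIR), but no
clinical data ships with the package.

The default `seizure_gain = 6` is a placeholder in the sense that no
quantitative seizure-to-background amplitude statistic is available for the
emulated archive; it was chosen so that the baseline (error-free,
uncompressed) detector is reliably strong, which is the regime in which
degradation under BER and compression is interpretable. It is exposed in
`gen_config()`.

## Compressive sensing

The node compresses each channel's epoch as `y = Phi x` where `Phi` is an
`M x N` sparse binary matrix with exactly `d = 4` ones per column, stored
as a `d x N` index table (as it would sit in node flash). Compression is a
series of accumulator additions — `cs_compress()` performs no
multiplications — and integer inputs stay integer. One matrix is shared by
all channels and epochs of a run.

Reconstruction is pluggable (`cs_params()`):

* **bsbl** — block-sparse Bayesian learning with EM hyperparameter updates
  over equal blocks (default 32 samples), intra-block correlation modeled
  by an AR(1) Toeplitz prior (`rho = 0.9`), noise floor `lambda`, blocks
  pruned at `1e-8` of the largest hyperparameter. Accurate on block-sparse
  signals (the CR 2:1 contract reconstructs two active blocks of 32 with
  NMSE well under 0.05) but costs an `M x M` solve per EM step per epoch.
* **fista_dct** — l1 minimization in an orthonormal DCT dictionary via
  FISTA, with the l1 weight set per epoch to `0.02 * max|A'y|` and the step
  from a power-iteration Lipschitz estimate. It is fully batched (all
  epochs and channels of a record reconstruct in a few dense matrix
  products), which is why it is the pipeline default for sweeps.
  Non-convergence within `max_iter` is flagged on the result, never raised.

With `M = N` and an invertible dense matrix the system is solved exactly —
the no-compression sanity case. Numerical tie-breaks worth noting: the DCT
basis is cached per `N`; FISTA's convergence test is the relative iterate
change against `tol = 1e-4`; BSBL adds `1e-10` to the diagonal if a solve
fails.

## Link model

Transmitted values pass through a 16-bit mid-rise uniform quantizer
(`encode_stream()`): `lo` maps to code 0, `hi` to 65535, out-of-range
values clip (counted on the stream), codes serialize MSB-first, and
decoding uses mid-rise reconstruction levels, so in-range values round-trip
within `(hi-lo)/2^17`. Full-scale conventions per data kind
(`quantizer_for()`): raw samples use the ADC full scale (±32768);
compressive measurements use ±`d`·32768 — the exact bound for a sum of `d`
samples, chosen over a data-calibrated range so the bitstream does not
depend on the cross-validation fold; feature values use ±1.2 times the
largest absolute value observed for the subject, treated as calibration
metadata transmitted error-free.

The channel flips each payload bit independently with probability BER
(`corrupt_stream()`); flips are seeded, reported, and involutive (the same
seed undoes itself). No forward error correction is modeled, and
medium-access overhead (13 bytes per packet of at most 114 payload bytes,
`packetize_account()`) is accounted for but not corrupted — the channel
model applies to the data payload.

## Detection and evaluation

Epochs are labeled SEIZURE only when wholly inside an annotated event,
NONSEIZURE when wholly outside, MIXED otherwise; MIXED epochs are excluded
from training and from every metric. The classifier is a soft-margin SVM
with a second-order polynomial kernel on z-scored features
(standardization statistics from the training split only). The kernel
degree is the one fixed modeling choice; `C = 1`, `coef0 = 1`,
`gamma = 1/p` and inverse-class-frequency weights are defaults exposed in
`classifier_spec()` — the class weighting matters because seizure epochs
are typically well under 10% of a record.

LORO cross-validation withholds each record once; training rows are
canonically ordered so results are invariant to the order records are
supplied; single-class training folds are skipped with a warning and NA
predictions. Metrics (`compute_metrics()`): seizure sensitivity (events
with at least one correctly labeled epoch), epoch sensitivity, specificity,
false positives per hour of **non-seizure recording time** (the
denominator is the non-seizure epoch count times the epoch duration — the
natural reading of "per hour" for records that are mostly non-seizure),
and mean detection latency over detected events (onset to the end of the
first correctly labeled epoch; undefined when nothing is detected). An
event too short to contain a whole epoch counts as undetectable in the
denominator — a conservative choice that can, for such events, push
seizure sensitivity below epoch sensitivity; at the study's epoch size and
event durations this does not arise.

## Study sizes and what the tests compute

The shipped end-to-end study uses desk-scale problem sizes, chosen once as
the package's own defaults: raw-vs-features equality on two seeds of a
4-record, 240-s-per-record subject; the BER sweep (0, 1e-5, 1e-3, 1e-2) on
ten seeds of the same subject layout; the compression sweep (1:1, 5:1,
10:1, 20:1) on ten seeds of a 3-record, 180-s subject; and a 10-record
separable-gain subject for the sensitivity ceiling. Trends are assessed on
medians across seeds and asserted as weak monotonicity (sensitivity
non-increasing, false positive rate non-decreasing, reconstruction error
non-decreasing in compression). At error-free, uncompressed settings the
raw and feature branches are asserted to produce equal metrics: the only
differences on that path are the half-LSB quantization of the transmitted
quantities, and NLACC's shift invariance absorbs the decoder's constant
mid-rise offset.

Nothing in this vignette states an empirical result that the test suite or
the acceptance script does not itself compute.

## Known limitations

* The synthetic background is spatially independent across channels; real
  bipolar montages are strongly correlated, which CS reconstruction and
  multivariate detectors could exploit.
* Only univariate time-domain features are implemented; spectral and
  cross-channel features are out of scope, as is any post-processing
  smoothing of predictions.
* The BSBL solver follows the block-sparse Bayesian framework but is not a
  numerical replica of any particular released implementation.
* Power consumption is represented only by the operation-count cost model
  and the transmission byte accounting; no hardware emulation is included.
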