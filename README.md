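# seizlink

Wireless EEG seizure-detection systems spend most of their battery on the
radio. **seizlink** simulates the three ways a sensor node can spend that
budget — streaming the raw EEG, streaming compressive-sensing measurements,
or streaming only low-complexity features — and measures what each costs in
transmitted bytes and sensor-side operations, and what each does to seizure
detection under imperfect channels.

It is aimed at biomedical-signal-processing researchers and embedded-EEG
engineers who want a tested, fully seeded desk-scale model of the whole
chain: synthetic annotated EEG (or archival EDF records), epoch features,
sparse-binary compressive sensing with Bayesian/l1 reconstruction, a 16-bit
quantizer with an i.i.d. bit-flip channel, an SVM detector, and event-based
metrics under leave-one-record-out cross-validation.

## The models at the core

For epochs of *N* samples (default *N* = 512, 4 s at 128 Hz), per channel:

* energy  E = (1/N) Σᵢ xᵢ²
* line length  LL = (1/(N−1)) Σᵢ |xᵢ₊₁ − xᵢ|
* nonlinear autocorrelation  NLACC = Σᵢ (HVᵢ − LVᵢ), with
  HVᵢ = min{max(Sᵢ), max(max(Sᵢ₊₁), max(Sᵢ₊₂))} and
  LVᵢ = max{min(Sᵢ), min(min(Sᵢ₊₁), min(Sᵢ₊₂))} over 15-sample
  sub-windows Sᵢ — a detector of repetitive spikes with similar extremes.

An instrumented cost model (`count_operations()`) tallies the additions,
assignments, comparisons and multiplications each extractor executes on a
small microcontroller; notably, line length needs exactly **1**
multiplication per epoch and NLACC **0**, which is why feature transmission
is the energy-efficient branch.

Compression uses **y = Φx** with a sparse random binary Φ (exactly *d* = 4
ones per column), so the node compresses with additions only;
reconstruction on the server uses block-sparse Bayesian learning or l1
minimization in a DCT dictionary (`cs_reconstruct()`). The channel is a
16-bit uniform mid-rise encoder plus independent bit flips at a given BER
(`encode_stream()`, `corrupt_stream()`), with 114-byte payloads carrying 13
bytes of MAC overhead each (`packetize_account()`).

## Worked example

```r
library(seizlink)

cfg <- gen_config(duration_s = 300, n_events = 1,
                  event_duration_s = c(40, 80), seed = 42)
rec <- generate_record(cfg)
rec
#> <eeg_record 'rec01': 23 ch x 38400 samples @ 128 Hz (300.0 s), 1 seizure event(s)>
rec$events[[1]]
#> <seizure_event 69-142 s (73 s)>

table(segment_and_label(rec, 512)$label)
#> NONSEIZURE    SEIZURE      MIXED
#>         56         17          2

count_operations("nlacc", 512)
#> <op_counts: 68 add, 1326 assign, 1088 compare, 0 multiply>
```

A 300-s record segments into 75 four-second epochs: 17 lie wholly inside
the annotated 73-s seizure, 2 straddle its boundaries (excluded from
training and scoring), and the NLACC cost model confirms the
multiplication-free extraction (68 = 2·N_S additions for N_S = 34
sub-windows).

Running two branches of the study end to end:

```r
gen <- gen_config(duration_s = 240, n_events = 1,
                  event_duration_s = c(40, 60), seed = 1)
ex <- run_experiment(experiment_config(
  approaches = c("raw", "features"), ber_sweep = c(0, 1e-2),
  generator = gen, n_records = 4, seed = 5))
ex
#>  approach   N cr  ber seizure_sensitivity specificity fpr_per_hour air_bytes_per_epoch
#>       raw 512  1 0.00                 100   100.00000      0.00000               26243
#>       raw 512  1 0.01                 100    96.25668     33.68984               26243
#>  features 512  1 0.00                 100   100.00000      0.00000                  59
#>  features 512  1 0.01                 100   100.00000      0.00000                  59
```

On an error-free channel the raw and feature branches detect identically —
the feature branch just does it in 59 bytes per epoch instead of 26,243
(the N:1 reduction plus packet overhead). At a bit error rate of 10⁻², the
raw branch's specificity drops and its false-positive rate jumps to ~34/h,
while the 46-byte feature payload barely exposes any surface to the
channel: the qualitative robustness ranking the package is built to study.

A thin CLI over the same functions ships in `inst/cli/seizlink.R`
(`simulate`, `features`, `compress`, `channel`, `detect`, `evaluate`,
`run`), and `vignettes/transmission-strategies.Rmd` documents the models,
parameter choices and limitations.

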