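---
title: "Two-lead ECG identification with sparse co-occurrence fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-lead ECG identification with sparse co-occurrence fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecg2id)
library(dplyr)
```

## The model

Two simultaneously recorded ECG leads are two projections of the same
cardiac electrical activity. At each sample time `t` the pair
`(x¹ₜ, x²ₜ)` is a point in the joint value plane; over a heartbeat these
points trace a closed curve whose shape is set by the relative amplitudes
and timing of the P, Q, R, S and T waves in the two leads — properties that
differ between people and are comparatively stable within a person. The
package's core representation is the *support* of that curve:

1. **Offset.** ADC values can be negative, so +500 is added to every
   sample. After the shift, 12-bit-range data fall in `[0, 1300)`; anything
   outside is clipped to the boundary with a warning that counts the
   clipped pairs (clipping rather than failing keeps pipelines total on
   real records whose baseline wanders beyond the nominal range).
2. **Co-occurrence matrix.** A segment of `L = 1280` samples marks cell
   `(x¹ₜ + 1, x²ₜ + 1)` of a 1300 × 1300 binary matrix. Duplicate pairs mark
   a cell once, so the matrix has at most `L` nonzeros (observed: a few
   hundred after reduction). The representation is *beat-phase invariant*:
   it does not matter where in the cardiac cycle a segment starts, which is
   why no R-peak detector is needed.
3. **Block binarization.** The matrix is tiled with `m × m` blocks and each
   block collapses to 1 iff it contains a nonzero (binary max-pooling;
   trailing blocks pool over their actual extent, so the reduced side is
   `⌈N/m⌉`). Pooling absorbs sample-level noise smaller than `m` ADC units
   and makes the support dense enough to compare.
4. **Sparse storage.** Only (row, column) pairs of nonzero cells are kept,
   1-based and column-major; the plain-text serialization is
   `d m` on a header line followed by one pair per line.

A probe is compared with an enrolled template by the Pearson correlation of
the flattened reduced matrices. For binary matrices this has a closed form
in the two nonzero counts and their overlap, which is what
`fp_correlation()` computes; the test suite verifies the closed form
against the term-by-term covariance definition to `1e-12`.

**Decision rules.** With per-subject thresholds `εᵢ = Rᵢᵐⁱⁿ − δ`
(minimum within-subject enrollment correlation minus a global margin), the
maximum-correlation rule accepts the best-scoring subject only if its
threshold is exceeded, otherwise rejects. Acceptance is strict (`r > ε`).
Ties on the maximum — possible in principle with identical templates — go
to the lexicographically smallest subject id, so decisions are
deterministic. The least-squares rule `argminᵢ (rᵢ − ε̄ᵢ)²` (with `ε̄ᵢ` the
mean training correlation) is closed-set: it always names a subject, so it
measures identification, not verification. An all-zero (or all-one)
fingerprint makes the correlation 0/0; it is scored 0 with a warning — a
degenerate fingerprint should match nothing rather than crash an
evaluation.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `offset` | 500 | ADC units | shifts signed samples non-negative |
| `N` | 1300 | cells | covers 12-bit data after the shift |
| `L` | 1280 | samples | 10 s at 128 Hz |
| `m` | 10 | cells | block size; divides 1300 exactly, reduces to 130 × 130 |
| `delta` | 0 | correlation | global threshold margin; swept 0–0.20 by 0.01 |
| `template_index` | 7 | — | enrollment segment used for probe comparison |
| `n_enroll`, `n_probe` | 8, 10 | segments | enrollment / probe split per subject |

The block size `m` is the one genuinely free parameter of the fingerprint.
`m = 10` keeps the reduced matrix sparse (a 1280-sample segment yields a
few hundred of 16 900 cells) yet tolerant of ±10 ADC units of noise;
`m = 1` disables reduction and is the identity. The operating point
`template_index = 7`, `delta = 0` is the package default: later enrollment
segments make better templates under the settling model described below,
and the δ sweep on the default cohort confirms 0 minimises `(FA + FR)/2`.

## Evaluation protocol

FR is the fraction of genuine probes *not* accepted as their true subject —
it counts outright rejections **and** misattributions, making
`success_rate = 1 − FR` its exact mirror. FA uses a verification-style
impostor protocol: every probe is paired with every other enrolled subject
as a claimed identity, and the claim counts as a false acceptance iff the
probe's correlation with the claimed subject's template exceeds *that
subject's* threshold. With 18 subjects and 10 probes each this gives 180
genuine and 180 × 17 = 3060 impostor trials. Under this construction FR is
non-increasing and FA non-decreasing in δ (thresholds only fall), which the
property tests assert along the whole grid. Rates are pooled over trials;
the per-subject breakdown is attached to every report (`tidy()` on an
evaluation).

## The synthetic cohort

The generator emulates the data regime of two-channel long-term Holter
recordings sampled at 128 Hz with 12-bit integer amplitudes: 18 subjects,
23 040 samples each (8 enrollment + 10 probe segments of 1280). Each
subject's beat is a sum of five Gaussian bumps (P, Q, R, S, T) with
lead-specific amplitudes; both leads share one jittered beat-time process,
reflecting simultaneous observation of the same activity. Between-subject
variation (log-sd 0.2 on amplitudes per wave and lead, 10 ms on wave
centres, log-sd 0.15 on widths, 70 ms on the heart period) exceeds
within-subject variation (15 ms beat jitter, white noise sd 3 ADC units),
which is what makes the cohort separable.

Records also carry two baseline components: a persistent low-amplitude
respiratory wander, and a **settling drift** (~45 ADC units, time constant
25 s) that is strongest at the start of the recording and decays away, as
electrode contact stabilises. The settling term matters for the threshold
model: enrollment segments are cut from the (early, drift-affected) start
of the record, so the within-subject training correlations include
dissimilar early/late pairs and the training *minimum* is a generous
threshold, while probes — cut after enrollment, in the settled regime —
correlate tightly with a late enrollment template. That is why template 7
with `δ = 0` rejects no genuine probe on the default cohort, and why later
templates outperform earlier ones.

Everything is a pure function of the master seed: per-subject seeds are
drawn once from it, parameters and record noise from those, and the cohort
manifest (seeds plus parameter hashes) allows bit-identical regeneration.

What passing on this cohort does **not** show: the generator has no
arrhythmia, ectopy, electrode artifacts, muscle noise or day-to-day
morphology change, and its noise is white. Real-data error rates will be
higher, and the published performance of the method on clinical recordings
cannot be reproduced from the generator — only the method's mechanics and
its qualitative behaviour (sparse-fingerprint correlation separating
subjects where single-lead and unaligned-PCA baselines struggle) carry
over.

## Comparison methods

*RBP* symbolises one lead into up/down bits (1 for a strict increase),
counts sliding 8-bit words (`m_bits = 8` gives 1272 words per segment,
enough for stable frequencies over 256 symbols) and compares rank-frequency
tables with a rank-weighted distance normalised to `[0, 1]`; ties in rank
go to the smaller word, words missing from either sequence are skipped, and
disjoint supports get distance 1. Scores enter the shared harness as
negated distances.

*Basic 2D* represents similarity through the half-difference matrix
`(A − B)/2`, correlating the probe's difference-to-template against a
within-subject difference baseline. On the synthetic cohort this statistic
carries almost no signal — within-subject differences are noise flicker,
essentially uncorrelated with anything — and the method performs near
chance; it is retained as the interface-complete baseline it is.

*PCA fusion* concatenates the two leads (length 2560), centres (the
covariance step includes mean removal — standard PCA), and keeps the top 19
eigenvectors of one projection trained on all enrollment segments; probes
are matched by correlating 19-dimensional feature vectors through the same
threshold machinery. Because raw time-domain segments are not beat-aligned,
the projection is phase-sensitive, and on phase-randomised synthetic
segments the method barely beats chance — the known weakness of unaligned
time-domain PCA for ECG.

Waveform-fiducial and wavelet baselines are out of scope: both require a
delineator/R-peak detector the method itself deliberately avoids. The
harness accepts any externally computed score matrix
(`evaluate_scores()`), so their scores could be tabulated for comparison if
produced elsewhere.

## Numerical and design notes

- Matrix orientation: row = lead-1 value, column = lead-2 value; WFDB
  channels map to leads in file order.
- Internal indices are 1-based throughout (natural in R); the text
  serialization is 1-based column-major and round-trip exact.
- The co-occurrence matrix lives in `Matrix` sparse storage end to end;
  nothing `N × N` is ever densified.
- Reduction when `m ∤ N`: trailing blocks pool over their real extent.
- `evaluate_scores()` requires thresholds to cover exactly the scored
  subjects and keeps `Acc ≡ 1 − (FA + FR)/2` to machine precision.
- Problem sizes in the shipped tests: the shared property-test cohort uses
  6 subjects at full record length; the end-to-end identification check
  runs the full 18-subject default cohort. Oracle suites use 20 × 20
  matrices (block pooling), 130 × 130 fingerprints (correlation), and
  1000 random round-trips (COO).

## Known limitations

- Closed-set least-squares never rejects; use the max-correlation rule when
  open-set rejection matters.
- The value-domain fingerprint discards all temporal ordering beyond
  co-occurrence; two signals tracing the same curve at different speeds are
  indistinguishable.
- Clipping (rather than rejecting) out-of-range samples can, in
  pathological records, pile mass onto boundary cells.
- Thresholds derive from only `C(8,2) = 28` training correlations per
  subject; `Rᵢᵐⁱⁿ` is a noisy order statistic, and small enrollment sets
  make `δ` sweeps correspondingly coarse.
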