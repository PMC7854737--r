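---
title: "Recursive dynamic functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive dynamic functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfc)
```

## The method

Classical dynamic functional connectivity (dFC) slides a fixed window along a
pair of neurophysiological signals and computes a Pearson correlation per
window, producing a connectivity time-series. Recursive dFC (rdFC) treats
that time-series as if it were activity data and slides the window again,
and again: order 1 is the windowed correlation of the raw signals, order
$n$ the windowed correlation of the order-$(n-1)$ series. Applied to a
*triplet* of EEG electrodes, every order carries exactly
$\binom{3}{2} = 3$ pairwise series, so the recursion neither grows nor
collapses — which is precisely why triplets are used: with four starting
nodes the pair count explodes combinatorially
(`count_static_measures(4, 5)` $\approx 1.49\times 10^7$ over five orders).

Each order is summarised by its three full-length *static* Pearson
coefficients, assigned to $(x, y, z)$ coordinates under a fixed pairing
convention: for an ordered sequence $(e_1, e_2, e_3)$,
$x \leftarrow \mathrm{corr}(e_1,e_2)$, $y \leftarrow \mathrm{corr}(e_1,e_3)$,
$z \leftarrow \mathrm{corr}(e_2,e_3)$, identically at every order. Five
orders give five points in $[-1,1]^3$ — the **5-point rdFC pattern**, a 3D
polyline whose segment slopes encode how connectivity at successive orders
co-varies. The convention is arbitrary but must stay fixed: permuting the
electrode sequence permutes pattern coordinates lawfully (the induced pair
permutation, iterated through the orders), which the test suite verifies to
$10^{-10}$.

Two patterns are compared by shape only. Each of the four segments is
normalised to a unit direction vector and the match score is
$\sum_{i=1}^{4}\langle a_i, b_i\rangle \in [-4, 4]$ — by construction
invariant to positive rescaling and translation of either pattern, since
correlation strengths vary widely while the slope structure is what recurs.
Significance is calibrated by Monte Carlo: 100,000 pseudo-patterns (15 iid
Uniform$(-1,1)$ values each) are matched best-of-three against the
reference set and the 95th percentile of their best scores is the cutoff;
for permutation-related reference triples this lands near 2.65.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| window | 1 | s | converted to `round(window * rate)` samples, reused at every order, so the method transfers across sampling rates |
| step | 1 | sample | the method's convention; exposed for exploration only |
| orders | 5 | – | beyond five the points shrink toward the origin in a repeating spiral and add no discriminative structure (verifiable with `orders = 20`) |
| epoch | 300 | s | long enough that static summaries average out artefacts of a few seconds |
| epoch index | 2 | – | the second 5-minute epoch skips the calibration sequence at the head of clinical recordings; flat-lined epochs advance to the next with a flagged substitution |
| band | 0.5–70 | Hz | clinical standard; 4th-order Butterworth, forward–backward (`filtfilt`) for zero phase |
| notch | 50 or 60 | Hz | mains frequency by region; RBJ biquad, Q = 30, also zero-phase |
| threshold | 2.65 | score | Monte-Carlo calibrated; recompute per reference set with `calibrate_threshold()` since it depends on the reference geometry |

## The synthetic generator

`coupling_spec()` / `generate_epoch()` build trivariate signals as a linear
mixture of band-limited (0.5–70 Hz) unit-variance Gaussian sources plus
independent channel noise. For constant mixing $M$ the channel correlations
have the closed form $\mathrm{cov} = MM^\top + \mathrm{diag}(\sigma^2)$, so
the whole forward pipeline is checked by parameter recovery: at 300 s /
256 Hz the first-order pattern coordinates land within 0.05 of the implied
correlations. Slow sinusoidal amplitude modulation of the sources
(0.05–0.17 Hz in `default_reference_spec()`) makes the pairwise correlations
drift so that all higher orders are nondegenerate; a `switch` replaces the
mixing matrix mid-record to drive temporal-course and seizure-transition
tests.

`default_reference_spec()` encodes the study condition used for reference
construction and calibration: one dominant shared source (gains 1.0 / 0.9 /
0.6 across channels, emulating the strong common signal of nearby scalp
electrodes), channel-dominant private sources, noise sd 0.3, implying
first-order correlations of about 0.71 / 0.59 / 0.43 — distinct, and of
realistic scalp-EEG magnitude. What the generator does **not** emulate:
oscillatory rhythms (an option exists but Gaussian sources keep the closed
form), volume conduction, non-stationary artefacts, electrode drift. Passing
tests therefore demonstrate correctness of the algorithms under controlled
coupling, not clinical performance.

## Reference sets and the permutation orbit

A triplet can be processed in $P(3,3) = 6$ orders; the six patterns of one
epoch are coordinate permutations of one underlying pattern, and the
position (x, y or z) of the *lowest first-order coordinate* splits them
into three classes of two. `generate_reference_set()` picks one pattern per
class as references 1 (lowest on z), 2 (on y) and 3 (on x), which fixes the
prediction mapping used by `predict_reference()`.

Which member of a class serves as the reference matters. The two members of
a class are related by coordinate permutations that iterate differently
through the orders: in two of the three classes the relation stays a
transposition at every order (the pair scores ≈ 3.7 mutually), but in the
third it passes through 3-cycles, and on many epochs that partner
best-matches a foreign reference. The original references were likewise not
arbitrary — representative patterns were searched for and found within the
six permutations of a single epoch. The constructor reproduces that
procedure: it screens epochs (reseeding with a logged message) until a
class-respecting selection exists under which all six permutations
best-match the reference of their own class. On unscreened generic epochs
the clean three-classes-of-two structure holds only in a minority of cases;
this screening is part of the construction, and a known limitation when
interpreting the orbit structure on arbitrary data.

## Numerical choices

* **Rolling sums in C++.** Step-1 windows over 76,800 samples demand O(N)
  per pair; running sums are rebuilt from scratch every $2^{16}$ windows to
  bound floating-point drift, and a window is declared degenerate when its
  variance is zero up to cancellation error. Correctness is guarded by a
  naive per-window recomputation oracle ($\le 10^{-8}$ on signals up to
  length 200).
* **Degenerate windows and segments.** A constant window cannot define a
  correlation; it contributes 0 and increments a counter rather than
  propagating NaN, which would poison every higher order. A zero-length
  pattern segment likewise has no direction and contributes 0 to a match
  score, so degenerate pseudo-patterns score low instead of erroring.
* **Correlations are clipped** to $[-1, 1]$ after computation to absorb
  rounding.
* **Resampling is Fourier-domain** (spectrum truncation / zero-padding):
  an ideal anti-alias filter with exactly zero group delay, which a
  polyphase FIR only approximates — the half-sample residual delay of the
  FIR route measurably degrades waveform correlation at 2500→250 Hz.
  The implicit periodicity assumption is harmless for long epochs.
* **Percentiles** use the linear-interpolation empirical definition
  (`quantile` type 7), stable at $n = 10^5$.
* **Mann–Whitney** uses the exact distribution when both groups are ≤ 20
  without ties and the tie-corrected normal approximation otherwise; the
  common-language effect size is $U_{\text{larger}}/(n_1 n_2)$. No Fisher
  transformation is applied — the rank test does not need Gaussian samples.
* **Ties** break deterministically: `best_match` to the lowest reference
  index; an exact tie of the two lowest first-order coordinates is reported
  as ambiguous with both candidate references rather than guessed.

## Design decisions where the design was open

* Filter realisations are stated only as band edges plus zero phase in
  clinical practice; the package fixes a 4th-order Butterworth band-pass
  and a Q = 30 biquad notch and records them in the preprocessing log.
* The flat-line detector flags a channel when any ≥ 1 s segment has zero
  peak-to-peak amplitude — catches disconnected electrodes without flagging
  low-amplitude sleep EEG.
* Bipolar montages convert to a common reference by telescoping channel
  chains along the montage graph; montages whose graph does not reach the
  target electrode fail with a montage error and are skipped, never
  silently guessed.
* Default triplet sets (near / intermediate / far, 32 / 32 / 10) are a
  deterministic, mirror-paired, distance-ranked selection on a schematic
  10–20 layout; the exact published compositions are not available, so the
  sets ship as editable configuration.
* Exclusivity of a match is operational — exactly one reference at or above
  threshold — and the first-order coordinate gap is reported separately,
  feeding the Mann–Whitney comparison of exclusive versus double matches.
* Noise-robustness powers are expressed relative to the epoch's mean
  channel power, making the "noise comparable to signal" regime a
  dimensionless sweep.

## Problem sizes used by the checks

Unit tests run at 64–128 Hz with 20–120 s epochs (a pattern costs
milliseconds); the end-to-end checks and the acceptance script exercise the
full 256 Hz / 300 s scale (76,800 samples; order-4 series of 75,780 values)
and the full 100,000-pattern calibration. The complete suite runs in well
under a minute on one CPU.

## Known limitations

* The calibrated threshold is a property of the reference set's segment
  geometry; 2.65 is the observed magnitude for permutation-related triples,
  not a universal constant.
* Pattern matching requires equal order counts; no partial or elastic
  matching (Procrustes, Fréchet) is attempted.
* Only Pearson correlation is supported as the connectivity measure, and
  only three starting nodes produce patterns (`count_static_measures()`
  generalises the counting, nothing else).
* Scalp-level correlation structure includes volume conduction; the package
  quantifies pattern prevalence and makes no physiological claims.
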