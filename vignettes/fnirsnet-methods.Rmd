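---
title: "Methods: thresholded fNIRS efficiency networks and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholded fNIRS efficiency networks and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fnirsnet)
```

## Scope

`fnirsnet` analyzes multichannel hemoglobin concentration time series as
thresholded binary correlation networks and relates their global and
local efficiency to age and to parent-rated autistic-behavior severity
(ABC totals). Because no raw clinical recordings are distributable, the
package pairs the analysis pipeline with a synthetic-cohort generator
that plants known ground truth; every claim the test suite makes about
the pipeline is a claim about recovering that ground truth.

## The analysis model

Each optode channel is a network node (44 in the reference montage, so
`choose(44, 2) = 946` candidate links). Per chromophore (oxy-, deoxy-,
total-Hb) the pipeline computes the Pearson correlation matrix of the
preprocessed series and binarizes it at each threshold
δ ∈ {0.2, 0.3, 0.4, 0.5, 0.6}: an edge requires `|r| > δ` (strictly;
`|r| = δ` gives no edge, and negative correlations count through their
magnitude). On every binary graph:

* **Global efficiency** is the mean inverse shortest-path length over
  ordered node pairs, with `1/L = 0` for disconnected pairs (the
  Latora–Marchiori convention, keeping the value in [0, 1] — 1 for a
  complete graph, 0 for an edgeless one). Path lengths come from a
  level-synchronous breadth-first search run from all sources at once.
* **Local efficiency** averages, over all N nodes, the global efficiency
  of the subgraph induced on each node's neighbors; nodes with fewer
  than two neighbors contribute 0 but still appear in the 1/N
  normalization.

Both metrics are cross-checked in the test suite against independent
oracles (Floyd–Warshall; an explicit double loop over neighbor
subgraphs) on hundreds of random graphs, and against closed forms
(path graph 5/6; triangle E_loc = 1; star E_loc = 0).

### Statistical stages

The covariate analysis is deliberately two-step: the bivariate age–ABC
correlation is tested first, and only if it is significant at α = 0.05
do the efficiency-vs-covariate associations switch to first-order
partial correlations (controlling the respective other covariate,
df = n − 3). Partial correlations use the closed form
`r_xy·z = (r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²))`, verified
against a residual-regression oracle to 1e−10. P-values are two-tailed
throughout; results are labeled significant (p < 0.05), marginal
(0.05 ≤ p < 0.1) or ns; no multiple-comparison correction is applied —
each (chromophore, δ, metric) cell is treated as its own topology, which
is the convention this analysis follows deliberately.

Subtyping applies K-means (k = 2) to z-scored (E_glob, E_loc) features
at a configurable cell (default oxy-Hb, δ = 0.4), with 50 seeded
restarts; z-scoring makes the clustering invariant to affine feature
rescaling, and the cluster with the higher raw mean E_glob is always
"Type I". A pooled-variance Student t-test compares ABC totals between
subtypes (reported as Type II minus Type I, so a positive t means the
lower-efficiency subtype is more severe).

## Preprocessing

1. **Beer–Lambert inversion** (optical input only): ΔOD at 780/805/830 nm
   is inverted per channel-sample by least squares against a fixed,
   documented extinction table (synthetic but qualitatively correct:
   deoxy-Hb dominates below the ~805 nm isosbestic point, oxy-Hb above),
   with source–detector distance 3 cm and differential pathlength factor
   6.0, all overridable. The forward model is also implemented, so the
   round trip is testable; it is exact to ~1e−15 on noiseless data.
2. **Sharp-change detection**: the recorded procedure this stands in for
   is manual video-assisted inspection, which is not algorithmic; the
   surrogate flags samples whose first difference is a robust z-score
   outlier (median/MAD, falling back to SD when MAD is 0) on at least
   two channel-series simultaneously — motion affects all channels at
   once, and the consensus rule suppresses single-channel noise flukes.
   Because a square-pulse artifact is sharp only at its onset and
   offset, runs of clean-looking samples between two flagged changes
   closer than 2 s are bridged (they are the displaced plateau), and the
   final flags are dilated by 0.5 s per side. Defaults: z = 5. An
   externally supplied mask can be used instead by setting
   `valid_mask` directly.
3. **Excision**: invalid samples are dropped and the retained segments
   concatenated in order. The pipeline removes each segment's linear
   trend before concatenation (`detrend_segments = TRUE`): splice
   discontinuities excite ~100 s of ringing at the 0.009 Hz filter
   corner, and their size is governed by the within-segment baseline
   trend. With realistic drift, de-meaning alone left edge correlations
   at about 0.28 on 11-minute recordings where detrending preserved
   0.64; both corrections are linear, so total = oxy + deoxy is
   preserved. The bare `excise()` default changes no retained value,
   so excision order/value invariants can be tested directly.
4. **Band-pass 0.009–0.08 Hz**: implemented as a zero-phase cascade of
   4th-order Butterworth low-pass and high-pass filters. A single
   band-pass transfer function of this band at 37 Hz sampling is
   numerically unstable (its poles move outside the unit circle in
   double precision), while the cascade is stable and has the measured
   response: 0.2% gain at 1.2 Hz (cardiac), 99% at 0.03 Hz (analysis
   band). Each pass runs forward and backward with steady-state initial
   conditions (the `lfilter_zi` construction) computed per series, which
   suppresses start-up transients that would otherwise decay over ~100 s
   into the data; the recursion itself is a small compiled
   direct-form-II-transposed kernel, verified bit-identical to a pure-R
   reference implementation.

Pipeline order is fixed — detection, excision, then filtering — and
correlations are computed on the concatenated retained series with no
interpolation.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package targets:

| quantity | default | rationale |
|---|---|---|
| subjects | 46 | reference cohort size |
| channels | 44 | reference montage |
| sampling interval | 27 ms (~37 Hz) | acquisition rate |
| raw duration | 660 s | 11 min raw so that ~6.9% exclusion leaves ≈10.24 retained minutes, matching both reported numbers |
| ages | uniform 2.0–8.9 y | reported range |
| ABC totals | mean 61.33, SD 21.79, clipped to 33–119 | reported distribution |
| age–ABC correlation | 0.51 | reported association (planted exactly, up to rounding/clipping) |
| connectivity band | 0.01–0.07 Hz | inside the analysis band |
| edge coupling | 0.7 | gives post-filter edge correlations ≈ 0.65–0.7, comfortably spanning the δ grid |
| severity → density slope | −0.12 per SD of ABC | strong planted effect so recovery is a sharp test |
| age → density slope | 0 | severity, not age, drives oxy-Hb efficiency in the planted truth |
| noise SD | 1 (≈ signal scale) | broadband sensor noise, mostly filtered out |
| cardiac / respiratory | 1.2 Hz / 0.3 Hz sinusoids, common phase, channel-scaled amplitude | physiological nuisance above the band |
| baseline drift | channel-independent sub-0.003 Hz wander, RMS = 0.01 units/s × duration (≈6.6 over 11 min) | slow wander is channel-specific in practice; a *shared* drift waveform would fabricate inter-channel correlation |
| artifacts | 1.4 events/min × 1.8 s, ±10 noise-SD square pulses on all channels | calibrated so the *excised* fraction ≈ 6.9% (the operational exclusion rate); true contamination is ~4.2% |

### How connectivity is planted

The generator mixes independent band-limited Gaussian latents (spectral
synthesis on the Fourier bins inside the connectivity band) with the
Cholesky factor of a target correlation matrix `R = I + c·A`, where `A`
is the ground-truth adjacency and `c` the edge coupling, so connected
channels share variance with correlation ≈ c. A per-edge latent scheme
was considered and rejected: summing one latent per incident edge caps
the correlation of a clique pair at 1/(degree), far below any useful
threshold.

`I + c·A` is only positive semi-definite for some graphs. For uniform
random graphs (`generate_graph(model = "gnm")`, the default, matching
the uniform-edge contract of that operation) the generator projects the
target onto the PSD cone by eigenvalue clipping — a best effort that
shrinks correlations at high density. Cohort simulation therefore uses
clique-union graphs (`model = "cliques"`): disjoint cliques chosen
greedily to hit the target edge count. Their target correlation is
exactly PSD for any c < 1, so edge correlations sit at c regardless of
density, and the binarized network's efficiency tracks planted density
tightly (for a union of cliques E_glob equals its density exactly at
perfect recovery). Edge-count granularity of the greedy partition is
below 2% of candidate links except within a few percent of density 1,
where disjoint cliques cannot realize every edge count.

Deoxy-Hb receives the shared component scaled by −0.5 plus its own
band-limited and white noise (channel-wise oxy/deoxy correlation
≈ −0.7), so deoxy-based networks are attenuated versions of oxy-based
ones rather than copies; total-Hb is the exact sample-wise sum.

### What the generator does *not* emulate

Spatial structure (channel geometry is metadata only), task-evoked
responses, systemic physiology coherence (Mayer waves), scalp/superficial
contamination, heteroscedastic noise, instrument-specific artifact
shapes, and item-level ABC psychometrics (the shipped per-item weight
table is a synthetic stand-in preserving the instrument's five areas,
item counts 9/12/12/13/11, weight range 1–4, maximum total 140 — the
true proprietary weights are not reproduced). Passing recovery tests
therefore demonstrates correctness of the pipeline's computations and
calibration of its statistics under a plausible signal model, not
robustness to every failure mode of real recordings.

## Numerical and design choices

* **Edge-count rounding** in graph generation is round-half-even (base R
  `round`), documented and asserted.
* **Disconnected pairs** contribute 0 to E_glob; subgraphs with < 2
  nodes contribute 0 to E_loc (standard conventions keeping both in
  [0, 1]).
* **Zero-variance channels** get correlation 0 (never an edge) with a
  warning rather than an abort, so degenerate inputs degrade gracefully.
* **Strict threshold**: `|r| > δ` exactly at the boundary is tested.
* **Determinism**: every stochastic operation takes a seed;
  K-means uses 50 restarts under a set seed; cohort generation derives
  per-subject sub-seeds from the cohort seed. Two runs with the same
  configuration are bit-identical, which the suite asserts.
* **Clipping**: ABC totals are rounded and clipped to the target range,
  which slightly biases the realized mean/SD and attenuates the planted
  age–ABC correlation; the Monte-Carlo tolerance (±0.15 over 20
  cohorts) accounts for this.
* **SNIRF input** is declined with an informative error; the CSV/TSV
  channel-column convention (`HbO_01…HbT_44`, `time` in seconds,
  optional `valid` flag, full-precision values) is the supported
  interchange format.

## Problem sizes used in validation

The test suite validates the graph metrics on exhaustive small cases
(n ≤ 12, oracle equivalence on 100 random graphs each), statistical
calibration at the study's n = 46 (1000 null replicates), and recovery
on ten replicate cohorts at full cohort size and channel count with
240 s recordings — at that length the efficiency estimates are noisier
than at the full 11 minutes, so the recovery assertions are conservative;
the end-to-end determinism and quality-report checks run at the full
default scale. `scripts/acceptance.R` reruns the full-scale cohort
analysis from scratch.

## Known limitations

* The clique-union planting model makes density → efficiency recovery
  nearly linear; graphs with richer mesoscale structure (overlapping
  communities, hubs) would loosen that link and are not exercised.
* The artifact detector is tuned to global square-pulse events; slow
  baseline shifts or channel-local artifacts will evade it (an external
  mask can be supplied instead).
* Efficiency values at δ = 0.2 on 44 channels sit near the dense-graph
  ceiling, compressing between-subject variance at the lowest threshold.
* P-values assume independent observations per subject pair; spatial
  autocorrelation between overlapping channel pairs is ignored, as is
  conventional for this analysis family.
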