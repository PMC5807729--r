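# fnirsnet

Functional near-infrared spectroscopy (fNIRS) records cortical
concentration changes of oxygenated, deoxygenated and total hemoglobin
through optode channels on the scalp. In resting-state studies of young
children with autism spectrum disorder (ASD), each channel is treated as
a node of a functional brain network: edges are declared wherever the
band-limited hemoglobin time series of two channels correlate strongly,
and the resulting binary graph is summarized by its global and local
efficiency. Those efficiency measures can then be related to age and to
parent-rated autistic-behavior severity (Autism Behavior Checklist, ABC),
and used to subtype participants.

`fnirsnet` implements that entire analysis as a tested, reusable R
pipeline, together with a synthetic-cohort generator that plants known
ground truth (connectivity density, covariate effects) so every stage can
be validated end to end without access to any clinical recordings.

## The model

For a recording with N channels (N = 44 in the reference montage, giving
C(44,2) = 946 candidate links), the pipeline computes the Pearson
correlation matrix r of the preprocessed series per chromophore, then
binarizes it at a threshold δ: an edge exists iff |r_ij| > δ, for each
δ ∈ {0.2, 0.3, 0.4, 0.5, 0.6}. On each binary graph G it evaluates

- global efficiency  E_glob = 1/(N(N−1)) · Σ_{i≠j} 1/L_ij, where L_ij is
  the shortest path length between nodes i and j (1/L = 0 for
  disconnected pairs);
- local efficiency   E_loc = 1/N · Σ_i E(G_i), where G_i is the subgraph
  induced on the neighbors of node i (nodes with fewer than two
  neighbors contribute 0).

Preprocessing follows the standard resting-state recipe: optional
modified Beer-Lambert inversion of optical densities (3 wavelengths →
HbO/HbR, least squares), automated sharp-change artifact detection with
excision of contaminated samples, and zero-phase Butterworth band-pass
filtering to 0.009–0.08 Hz.

Statistics: a bivariate age–ABC correlation decides (at p < 0.05)
whether subsequent efficiency-vs-covariate associations use first-order
partial correlations (df = n − 3) or stay bivariate; associations are
reported per (chromophore, δ, metric) cell with no multiple-comparison
correction; K-means (k = 2, z-scored E_glob/E_loc features at oxy-Hb,
δ = 0.4) splits the cohort into a higher-efficiency "Type I" and a
lower-efficiency "Type II" subtype, compared on ABC totals with a
pooled-variance t-test.

## Worked example

```r
library(fnirsnet)

# simulate a cohort of 46 children (44 channels, ~11 min at 37 Hz) with a
# planted negative severity -> connectivity effect and age-ABC r = 0.51
bundle <- generate_cohort(cohort_spec(seed = 1), signal_params())

res <- run_pipeline(bundle$recordings, bundle$cohort, run_config())
print(res)
```

which prints (seed 1):

```
<pipeline_result>
  pipeline started: 46 subjects, band 0.009-0.08 Hz, grid {0.2, 0.3, 0.4, 0.5, 0.6}
  preprocessing: mean excluded fraction 0.067, mean retained 10.26 min
  step 1: age-ABC r(46) = 0.507, p = 0.0003311 -> step 2 uses partial correlation
  clustering (oxy, delta = 0.4): Type I n = 21, Type II n = 25, ABC t = 7.862, p = 4.631e-10
```

Reading the output: about 6.7% of samples were excised as motion
artifacts (leaving ~10.3 min per subject); the planted age–ABC
correlation (0.51) is recovered and triggers the partial-correlation
branch; the K-means subtypes separate on ABC severity in the planted
direction (Type I, the higher-efficiency cluster, is less severe).
`res$associations` holds the 60-row association table (3 chromophores ×
5 thresholds × 2 metrics × 2 outcomes); for example the oxy-Hb
E_glob–ABC partial correlations are significantly negative at every
threshold, which is the planted effect.

A command-line wrapper with `simulate`, `preprocess`, `network`,
`analyze` and `run` subcommands is installed at
`inst/scripts/fnirsnet`; `fnirsnet run --config inst/extdata/demo_config.yaml
--out out/` runs a small demo end to end.

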