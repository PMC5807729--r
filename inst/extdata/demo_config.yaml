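# Demo configuration for `fnirsnet run --config demo_config.yaml --out <dir>`.
# Analysis settings mirror the package defaults; the simulate block keeps
# the demo cohort small so the smoke run finishes in seconds.
band: [0.009, 0.08]
delta_grid: [0.2, 0.3, 0.4, 0.5, 0.6]
z_threshold: 5.0
dilation_s: 0.5
dpf: 6.0
distance_cm: 3.0
cluster_chromophore: oxy
cluster_delta: 0.4
alpha: 0.05
demean_segments: true
detrend_segments: true
seed: 1
simulate:
  subjects: 8
  channels: 16
  duration: 120
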