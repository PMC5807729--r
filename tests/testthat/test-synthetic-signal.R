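# Signal generation tests work at full channel count but mostly reduced
# duration; the band-limited construction behaves identically at any
# length that contains Fourier bins inside the connectivity band.

test_that("total hemoglobin is exactly oxy + deoxy and output is seeded-deterministic", {
  g <- generate_graph(8, 0.4, seed = 3)
  p <- signal_params(duration = 60, seed = 11)
  rec1 <- generate_hemoglobin(g, p)
  rec2 <- generate_hemoglobin(g, p)
  expect_identical(rec1$oxy, rec2$oxy)
  expect_identical(rec1$total, rec1$oxy + rec1$deoxy)
  expect_equal(n_samples(rec1), round(60 / 0.027))
  expect_equal(n_channels(rec1), 8)
})

test_that("uncoupled channels are near-uncorrelated after band-pass at default duration", {
  g <- generate_graph(16, 0.5, seed = 4)  # edges exist but coupling is off
  mean_abs_r <- sapply(1:4, function(s) {
    p <- signal_params(edge_coupling = 0, seed = s)
    filt <- bandpass(generate_hemoglobin(g, p))
    r <- correlation_matrix(filt, "oxy")
    mean(abs(r[upper.tri(r)]))
  })
  expect_lt(mean(mean_abs_r), 0.1)
})

test_that("a fully coupled clique with low noise yields strong pairwise correlation", {
  g <- generate_graph(10, 1.0, seed = 5, model = "cliques")
  p <- signal_params(duration = 300, edge_coupling = 0.9, noise_sd = 0.2,
                     seed = 31)
  rec <- generate_hemoglobin(g, p)
  filt <- bandpass(rec)
  r <- correlation_matrix(filt, "oxy")
  expect_true(all(abs(r[upper.tri(r)]) > 0.6))
})

test_that("mean correlation over true edges does not decrease with edge coupling", {
  g <- generate_graph(12, 0.25, seed = 6)
  edge_mask <- g$adjacency[upper.tri(g$adjacency)]
  mean_r <- sapply(c(0, 0.3, 0.6), function(cpl) {
    p <- signal_params(duration = 300, edge_coupling = cpl, seed = 41)
    filt <- bandpass(generate_hemoglobin(g, p))
    r <- correlation_matrix(filt, "oxy")
    mean(abs(r[upper.tri(r)][edge_mask]))
  })
  expect_true(all(diff(mean_r) >= -0.02))
  expect_gt(mean_r[3], mean_r[1])
})

test_that("oxy and deoxy shared components are anti-correlated", {
  g <- generate_graph(6, 1.0, seed = 8, model = "cliques")
  p <- signal_params(duration = 300, edge_coupling = 0.8, noise_sd = 0.3,
                     seed = 51)
  filt <- bandpass(generate_hemoglobin(g, p))
  cors <- sapply(seq_len(6), function(ch) cor(filt$oxy[ch, ], filt$deoxy[ch, ]))
  expect_true(all(cors < -0.3))
})

test_that("parameter validation rejects impossible frequencies and couplings", {
  expect_error(signal_params(cardiac_freq = 30), "Nyquist")
  expect_error(signal_params(edge_coupling = 1), "edge_coupling")
  expect_error(signal_params(duration = 0.027), "2 samples")
  expect_error(signal_params(connectivity_band = c(0.07, 0.01)), "increasing")
})
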