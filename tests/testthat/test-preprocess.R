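test_that("a constant recording produces no sharp-change flags", {
  rec <- hb_recording(oxy = matrix(1, 3, 200), deoxy = matrix(2, 3, 200),
                      sampling_interval = 0.027)
  expect_true(all(detect_sharp_changes(rec)))
})

test_that("an injected step is flagged over a window around its onset", {
  set.seed(12)
  n_s <- 1000
  oxy <- matrix(rnorm(2 * n_s, sd = 0.5), 2)
  oxy[, 501:n_s] <- oxy[, 501:n_s] + 20 * 0.5  # 20 x noise_sd step, all channels
  deoxy <- matrix(rnorm(2 * n_s, sd = 0.5), 2)
  deoxy[, 501:n_s] <- deoxy[, 501:n_s] + 20 * 0.5
  rec <- hb_recording(oxy = oxy, deoxy = deoxy, sampling_interval = 0.027)
  dilation <- 10L
  mask <- detect_sharp_changes(rec, dilation = dilation, max_gap = 0L)
  expect_true(all(!mask[(501 - dilation):(501 + dilation)]))
  expect_true(all(mask[1:480]))
})

test_that("the detector recovers injected artifacts with high sensitivity and few false flags", {
  sens <- fpr <- numeric(10)
  for (s in 1:10) {
    rec <- noise_recording(8, round(300 / 0.027), seed = 300 + s)
    p <- signal_params(seed = 400 + s)
    art <- inject_artifacts(rec, p)
    mask <- detect_sharp_changes(art$recording)
    contaminated <- !art$truth_mask
    if (!any(contaminated)) { sens[s] <- 1; next }
    sens[s] <- mean(!mask[contaminated])
    fpr[s] <- mean(!mask[!contaminated])
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.05)
})

test_that("excision drops exactly the invalid samples without altering retained values", {
  rec <- noise_recording(3, 100, seed = 13)
  rec$valid_mask[c(10:13, 60:62)] <- FALSE
  out <- excise(rec)
  expect_equal(n_samples(out$recording), 93)
  expect_equal(out$report$excluded_fraction, 0.07)
  expect_identical(out$recording$oxy, rec$oxy[, rec$valid_mask])
  expect_equal(out$report$retained_duration_min, 93 * 0.027 / 60)

  rec$valid_mask[] <- FALSE
  rec$valid_mask[1] <- TRUE
  expect_error(excise(rec), "fewer than 2")
})

test_that("segment de-meaning centers each retained segment", {
  rec <- noise_recording(2, 50, seed = 14)
  rec$oxy <- rec$oxy + 5  # offset so de-meaning is observable
  rec$valid_mask[20:25] <- FALSE
  out <- excise(rec, demean_segments = TRUE)
  seg1 <- out$recording$oxy[, 1:19]
  expect_equal(rowMeans(seg1), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("excised fraction tracks the injected contamination at default settings", {
  diffs <- sapply(1:10, function(s) {
    rec <- noise_recording(8, round(660 / 0.027), seed = 500 + s)
    p <- signal_params(seed = 600 + s)
    art <- inject_artifacts(rec, p)
    art$recording$valid_mask <- detect_sharp_changes(art$recording)
    out <- excise(art$recording)
    out$report$excluded_fraction - mean(!art$truth_mask)
  })
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("band-pass attenuates cardiac frequencies and passes the analysis band", {
  dt <- 0.027
  tt <- seq(0, 614, by = dt)
  rms <- function(x) sqrt(mean(x^2))
  make <- function(f) {
    x <- matrix(sin(2 * pi * f * tt), 1)
    hb_recording(oxy = x, deoxy = x, sampling_interval = dt)
  }
  hi <- bandpass(make(1.2))
  expect_lt(rms(hi$oxy) / rms(sin(2 * pi * 1.2 * tt)), 0.01)
  lo <- bandpass(make(0.03))
  expect_gt(rms(lo$oxy) / rms(sin(2 * pi * 0.03 * tt)), 0.9)
  z <- bandpass(hb_recording(oxy = matrix(0, 1, length(tt)),
                             deoxy = matrix(0, 1, length(tt)),
                             sampling_interval = dt))
  expect_true(all(z$oxy == 0))
})

test_that("band-pass is linear and preserves the total hemoglobin identity", {
  rec1 <- noise_recording(2, 3000, seed = 15)
  rec2 <- noise_recording(2, 3000, seed = 16)
  comb <- hb_recording(oxy = 2 * rec1$oxy - 3 * rec2$oxy,
                       deoxy = 2 * rec1$deoxy - 3 * rec2$deoxy,
                       sampling_interval = 0.027)
  f_comb <- bandpass(comb)
  f1 <- bandpass(rec1)
  f2 <- bandpass(rec2)
  scale_ref <- max(abs(f_comb$oxy))
  expect_lt(max(abs(f_comb$oxy - (2 * f1$oxy - 3 * f2$oxy))) / scale_ref, 1e-4)
  # total identity survives filtering (each chromophore filtered separately)
  expect_lt(max(abs(f_comb$total - (f_comb$oxy + f_comb$deoxy))) /
              max(1, max(abs(f_comb$total))), 1e-4)
})

test_that("band edges are validated against the Nyquist frequency", {
  rec <- noise_recording(1, 3000, seed = 17)
  expect_error(bandpass(rec, low = 0.08, high = 0.009), "band edges")
  expect_error(bandpass(rec, low = 0.009, high = 30), "band edges")
  short_rec <- noise_recording(1, 20, seed = 18)
  expect_error(bandpass(short_rec), "too short")
})
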