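#' Detect sharp signal changes (motion artifact surrogate)
#'
#' Flags samples whose first difference, on any channel of the oxy or
#' deoxy series, is an outlier under a robust z-score (median/MAD of the
#' channel's differences; falls back to mean/SD when the MAD is zero, and
#' flags nothing on a channel whose SD is also zero). A square-pulse
#' artifact produces sharp changes only at its onset and offset, so
#' short runs of clean-looking samples *between* two flagged sharp
#' changes (closer than `max_gap`) are bridged and flagged too -- they
#' are the displaced plateau. Finally flags are dilated by `dilation`
#' samples on both sides. This is an automated surrogate for manual
#' video-assisted inspection; an externally supplied mask can always be
#' attached to `rec$valid_mask` instead.
#'
#' @param rec an `hb_recording` with at least 3 samples.
#' @param z_threshold robust z-score cutoff (default 5).
#' @param dilation dilation half-width in samples; default
#'   `round(0.5 / sampling_interval)` (0.5 s).
#' @param max_gap longest gap, in samples, bridged between two flagged
#'   sharp changes; default `round(2 / sampling_interval)` (2 s).
#' @return logical validity mask (per sample, `TRUE` = keep): the AND of
#'   `rec$valid_mask` and the new no-artifact flags.
#' @export
detect_sharp_changes <- function(rec, z_threshold = 5, dilation = NULL,
                                 max_gap = NULL) {
  stopifnot(inherits(rec, "hb_recording"))
  n_s <- n_samples(rec)
  if (n_s < 3) stop("recording must have at least 3 samples")
  if (is.null(dilation)) dilation <- as.integer(round(0.5 / rec$sampling_interval))
  dilation <- max(0L, as.integer(dilation))
  if (is.null(max_gap)) max_gap <- as.integer(round(2 / rec$sampling_interval))
  max_gap <- max(0L, as.integer(max_gap))
  # count, per sample, how many channel-series show an outlying first
  # difference; motion artifacts hit all channels at once, so requiring a
  # consensus of >= 2 series suppresses single-channel noise flukes
  hits <- integer(n_s)
  n_series <- 0L
  for (mat in list(rec$oxy, rec$deoxy)) {
    d <- mat[, -1, drop = FALSE] - mat[, -n_s, drop = FALSE]
    n_series <- n_series + nrow(d)
    for (ch in seq_len(nrow(d))) {
      x <- d[ch, ]
      s <- stats::mad(x)
      if (s == 0) s <- stats::sd(x)
      if (is.na(s) || s == 0) next
      z <- abs(x - stats::median(x)) / s
      hit <- which(z > z_threshold)
      if (length(hit)) {
        idx <- unique(c(hit, hit + 1L))
        hits[idx] <- hits[idx] + 1L
      }
    }
  }
  bad <- hits >= min(2L, n_series)
  if (any(bad)) {
    idx <- which(bad)
    if (max_gap > 0 && length(idx) > 1) {
      gaps <- which(diff(idx) > 1 & diff(idx) - 1 <= max_gap)
      for (g in gaps) bad[(idx[g] + 1L):(idx[g + 1L] - 1L)] <- TRUE
    }
    if (dilation > 0) {
      idx <- which(bad)
      idx <- unique(unlist(lapply(idx, function(i)
        max(1L, i - dilation):min(n_s, i + dilation))))
      bad[idx] <- TRUE
    }
  }
  rec$valid_mask & !bad
}

#' Excise invalid samples from a recording
#'
#' Drops all samples marked invalid in the recording's `valid_mask` and
#' concatenates the remaining segments in their original order; retained
#' values are unchanged unless segment correction is requested.
#' `demean_segments` removes each contiguous retained segment's mean (per
#' channel and chromophore) before concatenation; `detrend_segments`
#' additionally removes each segment's linear trend. The pipeline uses
#' detrending ahead of band-pass filtering: splice discontinuities excite
#' long filter ringing at the 0.009 Hz corner, and their size is set by
#' the within-segment trend (baseline drift), which detrending removes.
#' Both corrections are linear, so the total = oxy + deoxy identity is
#' preserved.
#'
#' @param rec an `hb_recording`.
#' @param demean_segments de-mean each retained segment (default `FALSE`).
#' @param detrend_segments remove each retained segment's linear trend,
#'   implying de-meaning (default `FALSE`).
#' @return list with `recording` (all-valid, possibly shorter) and
#'   `report`, a `quality_report`: `excluded_fraction`,
#'   `retained_duration_min`, and per-channel zero-variance flags.
#' @export
excise <- function(rec, demean_segments = FALSE, detrend_segments = FALSE) {
  stopifnot(inherits(rec, "hb_recording"))
  keep <- rec$valid_mask
  if (sum(keep) < 2) stop("fewer than 2 valid samples remain; cannot excise")
  seg_id <- cumsum(c(1L, diff(which(keep)) != 1L))
  seg_qr <- NULL
  if (detrend_segments) {
    seg_qr <- lapply(split(seq_along(seg_id), seg_id), function(cols)
      qr(cbind(1, seq_along(cols))))
  }
  mats <- lapply(rec[c("oxy", "deoxy", "total")], function(m) {
    m <- m[, keep, drop = FALSE]
    if (demean_segments || detrend_segments) {
      for (s in unique(seg_id)) {
        cols <- which(seg_id == s)
        if (detrend_segments && length(cols) >= 3) {
          m[, cols] <- t(qr.resid(seg_qr[[as.character(s)]],
                                  t(m[, cols, drop = FALSE])))
        } else {
          m[, cols] <- m[, cols, drop = FALSE] -
            rowMeans(m[, cols, drop = FALSE])
        }
      }
    }
    m
  })
  out <- hb_recording(oxy = mats$oxy, deoxy = mats$deoxy, total = mats$total,
                      sampling_interval = rec$sampling_interval,
                      channel_labels = rec$channel_labels)
  report <- structure(
    list(excluded_fraction = mean(!keep),
         retained_duration_min = sum(keep) * rec$sampling_interval / 60,
         channel_zero_variance = apply(mats$oxy, 1, stats::sd) == 0),
    class = "quality_report")
  list(recording = out, report = report)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %.1f%% excluded, %.2f min retained, %d flat channel(s)\n",
              100 * x$excluded_fraction, x$retained_duration_min,
              sum(x$channel_zero_variance)))
  invisible(x)
}

# Zero-phase band-pass: cascade of 4th-order Butterworth low-pass and
# high-pass, each applied forward-backward. A single band-pass transfer
# function is numerically unstable at the very small normalized corner
# frequencies involved (0.009 Hz at ~37 Hz sampling); the cascade is
# stable and equally zero-phase.
bandpass_filters <- function(low, high, fs) {
  nyquist <- fs / 2
  if (!(0 < low && low < high && high < nyquist))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  list(lp = signal::butter(4, high / nyquist, type = "low"),
       hp = signal::butter(4, low / nyquist, type = "high"))
}

# Steady-state filter state for a unit constant input (the lfilter_zi
# construction): scaling it by a series' first value initializes the
# filter as if that value had been applied forever, removing the
# start-up transient a zero-initial-state filter would inject. That
# matters at the 0.009 Hz corner, where transients decay over ~100 s
# and the series may sit far from zero (baseline drift).
steady_state_zi <- function(b, a) {
  k <- length(a) - 1L
  companion <- rbind(-a[-1], cbind(diag(1, k - 1L), 0))
  rhs <- b[-1] - a[-1] * b[1]
  solve(diag(1, k) - t(companion), rhs)
}

# one steady-initialized pass down the rows of M (samples x channels)
iir_steady <- function(flt, M) {
  b <- flt$b
  a <- flt$a
  zi <- steady_state_zi(b, a)
  .iir_df2t(b, a, M, outer(zi, M[1, ]))
}

zero_phase <- function(flt, M) {
  Y <- iir_steady(flt, M)
  n <- nrow(Y)
  Y <- iir_steady(flt, Y[n:1, , drop = FALSE])
  Y[n:1, , drop = FALSE]
}

bandpass_matrix <- function(mat, filters) {
  M <- t(mat)
  t(zero_phase(filters$hp, zero_phase(filters$lp, M)))
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' independently to every channel of every chromophore. The default band,
#' 0.009-0.08 Hz, isolates the slow oscillations carrying resting-state
#' connectivity while suppressing drift below and cardiac/respiratory
#' activity above. Output length equals input length; the
#' total = oxy + deoxy identity is preserved to numerical tolerance by
#' linearity (each series is filtered independently).
#'
#' @param rec an `hb_recording` (typically already excised).
#' @param low,high band edges in Hz (defaults 0.009 and 0.08).
#' @return the filtered `hb_recording`.
#' @export
bandpass <- function(rec, low = 0.009, high = 0.08) {
  stopifnot(inherits(rec, "hb_recording"))
  fs <- 1 / rec$sampling_interval
  filters <- bandpass_filters(low, high, fs)
  n_s <- n_samples(rec)
  # filtfilt needs enough samples to pad past the filter edge transient
  if (n_s <= 3 * (length(filters$lp$a) + length(filters$hp$a)))
    stop("recording too short for the band-pass filter warm-up")
  oxy <- bandpass_matrix(rec$oxy, filters)
  deoxy <- bandpass_matrix(rec$deoxy, filters)
  total <- bandpass_matrix(rec$total, filters)
  hb_recording(oxy = oxy, deoxy = deoxy, total = total,
               sampling_interval = rec$sampling_interval,
               valid_mask = rec$valid_mask,
               channel_labels = rec$channel_labels)
}

#' Preprocess a recording (detect, excise, filter)
#'
#' Convenience wrapper running the pipeline's fixed preprocessing order:
#' sharp-change detection, excision of invalid samples (with per-segment
#' de-meaning), then band-pass filtering of the concatenated retained
#' series.
#'
#' @param rec an `hb_recording`.
#' @param z_threshold,dilation passed to [detect_sharp_changes()].
#' @param low,high passed to [bandpass()].
#' @param detrend_segments passed to [excise()] (default `TRUE` here).
#' @return list with `recording` (preprocessed) and `report`
#'   (`quality_report`).
#' @export
preprocess_recording <- function(rec, z_threshold = 5, dilation = NULL,
                                 low = 0.009, high = 0.08,
                                 detrend_segments = TRUE) {
  rec$valid_mask <- detect_sharp_changes(rec, z_threshold, dilation)
  ex <- excise(rec, detrend_segments = detrend_segments)
  list(recording = bandpass(ex$recording, low, high), report = ex$report)
}
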