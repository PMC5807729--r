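#' Signal-model parameters for synthetic fNIRS recordings
#'
#' Collects every tunable of the hemodynamic signal simulator. Defaults
#' emulate a continuous-wave fNIRS acquisition: 27 ms sampling interval,
#' about ten minutes of recording, connectivity carried by slow
#' oscillations inside the analysis band, plus cardiac and respiratory
#' sinusoids, slow linear drift, broadband sensor noise, and occasional
#' large motion artifacts.
#'
#' @param sampling_interval seconds per sample (default 0.027, i.e. ~37 Hz).
#' @param duration raw recording length in seconds (default 660, i.e. 11
#'   min: after the expected ~6.9% artifact exclusion the retained length
#'   is about 10.24 min).
#' @param connectivity_band two Hz values; the band carrying the shared
#'   (connectivity-bearing) oscillations. Must sit inside the analysis
#'   band used downstream. Default 0.01-0.07 Hz.
#' @param cardiac_freq,respiratory_freq physiological nuisance frequencies
#'   in Hz (defaults 1.2 and 0.3).
#' @param cardiac_amp,respiratory_amp their amplitudes in concentration
#'   units (defaults 1 and 0.5), scaled per channel by a random factor in
#'   `[0.5, 1.5]`.
#' @param drift_slope scale of slow baseline wander, in concentration
#'   units per second (default 0.01): each channel receives an
#'   independent random sub-0.003 Hz drift process with RMS amplitude
#'   `drift_slope * duration`, comparable to a linear ramp of that slope.
#'   Drift is channel-specific (as baseline wander is in practice), so it
#'   does not induce spurious inter-channel correlation.
#' @param noise_sd standard deviation of broadband white sensor noise in
#'   concentration units (default 1).
#' @param edge_coupling unitless shared-variance weight in `[0, 1)`: the
#'   target Pearson correlation, within the connectivity band, between
#'   channels joined by a ground-truth edge (default 0.7).
#' @param deoxy_ratio scaling of the shared component in the deoxy series
#'   relative to oxy (default -0.5: anti-correlated at half amplitude).
#' @param artifact_rate motion-artifact events per minute (default 1.4).
#'   With the default 1.8 s events this contaminates ~4.2% of samples;
#'   after the default detector dilation of 0.5 s per side, the expected
#'   *excised* fraction is ~6.9%, the operational exclusion rate the
#'   simulation is calibrated to.
#' @param artifact_amplitude artifact height in multiples of `noise_sd`
#'   (default 10).
#' @param artifact_duration event length in seconds (default 1.8).
#' @param seed optional integer seed.
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(sampling_interval = 0.027,
                          duration = 660,
                          connectivity_band = c(0.01, 0.07),
                          cardiac_freq = 1.2,
                          respiratory_freq = 0.3,
                          cardiac_amp = 1,
                          respiratory_amp = 0.5,
                          drift_slope = 0.01,
                          noise_sd = 1,
                          edge_coupling = 0.7,
                          deoxy_ratio = -0.5,
                          artifact_rate = 1.4,
                          artifact_amplitude = 10,
                          artifact_duration = 1.8,
                          seed = NULL) {
  p <- list(sampling_interval = sampling_interval, duration = duration,
            connectivity_band = as.numeric(connectivity_band),
            cardiac_freq = cardiac_freq, respiratory_freq = respiratory_freq,
            cardiac_amp = cardiac_amp, respiratory_amp = respiratory_amp,
            drift_slope = drift_slope, noise_sd = noise_sd,
            edge_coupling = edge_coupling, deoxy_ratio = deoxy_ratio,
            artifact_rate = artifact_rate,
            artifact_amplitude = artifact_amplitude,
            artifact_duration = artifact_duration, seed = seed)
  validate_signal_params(p)
  structure(p, class = "signal_params")
}

validate_signal_params <- function(p) {
  if (p$sampling_interval <= 0) stop("sampling_interval must be > 0")
  nyquist <- 1 / (2 * p$sampling_interval)
  freqs <- c(p$connectivity_band, p$cardiac_freq, p$respiratory_freq)
  if (any(freqs <= 0) || any(freqs >= nyquist))
    stop("all model frequencies must lie in (0, Nyquist)")
  if (length(p$connectivity_band) != 2L ||
      p$connectivity_band[1] >= p$connectivity_band[2])
    stop("connectivity_band must be an increasing pair of frequencies")
  if (round(p$duration / p$sampling_interval) < 2)
    stop("duration must cover at least 2 samples")
  if (p$edge_coupling < 0 || p$edge_coupling >= 1)
    stop("edge_coupling must be in [0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$artifact_rate < 0) stop("artifact_rate must be >= 0")
  invisible(p)
}

# Band-limited unit-variance Gaussian series by spectral synthesis:
# complex Gaussian amplitudes on the Fourier bins inside [f1, f2]
# (Hermitian-symmetrized), inverse FFT, per-channel standardization.
# Synthesis runs at the next 2-3-5-smooth length (fast mixed-radix FFT)
# and is truncated to the requested sample count. Returns
# channels x samples.
band_limited_noise <- function(n_channels, n_samples, f1, f2, dt) {
  nfft <- stats::nextn(n_samples, c(2, 3, 5))
  freqs <- (seq_len(nfft) - 1) / (nfft * dt)
  k <- which(freqs >= f1 & freqs <= f2)
  k <- k[k >= 2L & k <= floor(nfft / 2)]
  if (length(k) == 0L) {
    # series too short for the requested band: use the bin nearest its center
    k <- max(2L, min(floor(nfft / 2),
                     which.min(abs(freqs - (f1 + f2) / 2))))
  }
  spec <- matrix(0 + 0i, nfft, n_channels)
  spec[k, ] <- complex(real = stats::rnorm(length(k) * n_channels),
                       imaginary = stats::rnorm(length(k) * n_channels))
  spec[nfft + 2L - k, ] <- Conj(spec[k, ])
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n_samples), , drop = FALSE] / nfft
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  t(sweep(x, 2, sds, "/"))
}

# Target correlation matrix implied by a graph at a given coupling.
# I + c*A, projected onto the PSD cone by eigenvalue clipping and
# renormalized to unit diagonal when the raw target is not PSD (exact,
# no projection needed, for clique-union graphs with c < 1).
graph_correlation <- function(adjacency, coupling) {
  n <- nrow(adjacency)
  if (coupling == 0) return(diag(n))
  R <- diag(n) + coupling * (adjacency * 1)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    R <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
    R <- stats::cov2cor((R + t(R)) / 2)
  }
  R
}

#' Generate a synthetic hemoglobin recording from a ground-truth graph
#'
#' Builds channels x samples oxy-, deoxy- and total-hemoglobin series
#' whose band-limited correlation structure is induced by the graph:
#' independent band-limited Gaussian latents are mixed with the Cholesky
#' factor of the graph's target correlation matrix (`I + c A`, PSD-projected
#' when necessary), so channels joined by an edge share variance with
#' target correlation `edge_coupling`. On top of the structured component
#' every channel receives independent white noise, cardiac and respiratory
#' sinusoids (common phase, channel-specific amplitude) and a linear drift.
#' The deoxy series carries the shared component scaled by `deoxy_ratio`
#' (negative by default, giving the physiologically typical oxy/deoxy
#' anti-correlation) plus its own band-limited and white noise; total is
#' the exact sample-wise sum.
#'
#' @param graph a `gt_graph` from [generate_graph()].
#' @param params a `signal_params` object.
#' @return An `hb_recording`. Deterministic given `params$seed`.
#' @export
generate_hemoglobin <- function(graph, params = signal_params()) {
  stopifnot(inherits(graph, "gt_graph"))
  validate_signal_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  dt <- params$sampling_interval
  n_s <- max(2L, as.integer(round(params$duration / dt)))
  n <- graph$n_nodes
  tt <- (seq_len(n_s) - 1) * dt

  Z <- band_limited_noise(n, n_s, params$connectivity_band[1],
                          params$connectivity_band[2], dt)
  R <- graph_correlation(graph$adjacency, params$edge_coupling)
  S <- if (params$edge_coupling == 0) Z else
    t(chol(R + diag(1e-10, n))) %*% Z
  Zd <- band_limited_noise(n, n_s, params$connectivity_band[1],
                           params$connectivity_band[2], dt)

  phase_c <- stats::runif(1, 0, 2 * pi)
  phase_r <- stats::runif(1, 0, 2 * pi)
  physio <- params$cardiac_amp * sin(2 * pi * params$cardiac_freq * tt + phase_c) +
    params$respiratory_amp * sin(2 * pi * params$respiratory_freq * tt + phase_r)
  amp <- stats::runif(n, 0.5, 1.5)
  drift <- (params$drift_slope * params$duration) *
    band_limited_noise(n, n_s, 1 / (n_s * dt), 0.003, dt)

  oxy <- S + params$noise_sd * matrix(stats::rnorm(n * n_s), n) +
    amp %o% physio + drift
  deoxy <- params$deoxy_ratio * S + abs(params$deoxy_ratio) * Zd +
    0.5 * params$noise_sd * matrix(stats::rnorm(n * n_s), n) +
    (-0.3 * amp) %o% physio + (-0.3) * drift

  hb_recording(oxy = oxy, deoxy = deoxy, sampling_interval = dt)
}

#' Inject motion-like artifacts into a recording
#'
#' Adds square-pulse artifacts (height `artifact_amplitude * noise_sd`,
#' random sign, length `artifact_duration`) at Poisson-distributed onset
#' times, simultaneously on every channel of the oxy and deoxy series
#' (total is recomputed as their sum). The recording's own `valid_mask`
#' is left untouched -- contamination is what the preprocessing stage has
#' to find -- and the ground-truth clean/contaminated mask is returned
#' alongside.
#'
#' @param rec an `hb_recording`.
#' @param params a `signal_params`; uses `artifact_rate` (events/min),
#'   `artifact_amplitude`, `artifact_duration`, `noise_sd` and `seed`.
#' @return list with `recording` (contaminated copy) and `truth_mask`
#'   (logical per sample, `TRUE` = clean). Deterministic given seed.
#' @export
inject_artifacts <- function(rec, params = signal_params()) {
  stopifnot(inherits(rec, "hb_recording"))
  if (params$artifact_rate < 0) stop("artifact_rate must be >= 0")
  n_s <- n_samples(rec)
  truth_mask <- rep(TRUE, n_s)
  if (params$artifact_rate == 0)
    return(list(recording = rec, truth_mask = truth_mask))
  if (!is.null(params$seed))
    set.seed((params$seed + 999983L) %% .Machine$integer.max)
  dt <- rec$sampling_interval
  duration_min <- n_s * dt / 60
  n_events <- stats::rpois(1, params$artifact_rate * duration_min)
  if (n_events == 0) return(list(recording = rec, truth_mask = truth_mask))
  win <- max(1L, as.integer(round(params$artifact_duration / dt)))
  onsets <- sample.int(max(1L, n_s - win + 1L), n_events, replace = TRUE)
  signs <- sample(c(-1, 1), n_events, replace = TRUE)
  amp <- params$artifact_amplitude * params$noise_sd
  oxy <- rec$oxy
  deoxy <- rec$deoxy
  for (e in seq_len(n_events)) {
    idx <- onsets[e]:min(n_s, onsets[e] + win - 1L)
    oxy[, idx] <- oxy[, idx] + signs[e] * amp
    deoxy[, idx] <- deoxy[, idx] + signs[e] * amp
    truth_mask[idx] <- FALSE
  }
  out <- hb_recording(oxy = oxy, deoxy = deoxy,
                      sampling_interval = dt, valid_mask = rec$valid_mask,
                      channel_labels = rec$channel_labels)
  list(recording = out, truth_mask = truth_mask)
}
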