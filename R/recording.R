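#' Hemoglobin recording container
#'
#' Bundles concentration-change time series for the three chromophores
#' (oxy-, deoxy- and total-hemoglobin) measured over a set of optode
#' channels, together with the sampling interval, a per-sample validity
#' mask and channel labels. Total hemoglobin is definitionally the
#' sample-wise sum of the oxy and deoxy series; the constructor enforces
#' this to numerical tolerance and fills it in when omitted.
#'
#' @param oxy,deoxy numeric matrices, channels x samples, concentration
#'   change in arbitrary units (e.g. mM x mm).
#' @param total optional channels x samples matrix; defaults to
#'   `oxy + deoxy`.
#' @param sampling_interval sampling interval in seconds (> 0).
#' @param valid_mask logical vector, one entry per sample; `TRUE` marks a
#'   valid sample. Defaults to all valid.
#' @param channel_labels character vector of channel identifiers; defaults
#'   to `CH01 ... CHnn`.
#' @return An object of class `hb_recording`: a list with elements `oxy`,
#'   `deoxy`, `total`, `sampling_interval`, `valid_mask`, `channel_labels`.
#' @export
hb_recording <- function(oxy, deoxy, total = NULL, sampling_interval,
                         valid_mask = NULL, channel_labels = NULL) {
  oxy <- as.matrix(oxy)
  deoxy <- as.matrix(deoxy)
  if (!all(dim(oxy) == dim(deoxy)))
    stop("oxy and deoxy must have identical dimensions")
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      !is.finite(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be a single positive number")
  n_ch <- nrow(oxy)
  n_s <- ncol(oxy)
  if (is.null(total)) {
    total <- oxy + deoxy
  } else {
    total <- as.matrix(total)
    if (!all(dim(total) == dim(oxy)))
      stop("total must match the dimensions of oxy/deoxy")
    # tolerance sized for zero-phase IIR filtering round-off, which breaks
    # exact linearity at ~1e-6 of signal scale with near-unit-circle poles
    tol <- 1e-4 * max(1, max(abs(total)))
    if (max(abs(total - (oxy + deoxy))) > tol)
      stop("total hemoglobin must equal oxy + deoxy sample-wise")
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n_s)
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != n_s)
    stop("valid_mask length must equal the number of samples")
  if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(n_ch))
  if (length(channel_labels) != n_ch)
    stop("channel_labels length must equal the number of channels")
  structure(
    list(oxy = oxy, deoxy = deoxy, total = total,
         sampling_interval = sampling_interval,
         valid_mask = valid_mask,
         channel_labels = as.character(channel_labels)),
    class = "hb_recording")
}

#' @export
print.hb_recording <- function(x, ...) {
  cat(sprintf(
    "<hb_recording> %d channels x %d samples @ %.4g s (%.2f min), %.1f%% valid\n",
    nrow(x$oxy), ncol(x$oxy), x$sampling_interval,
    ncol(x$oxy) * x$sampling_interval / 60, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Number of samples / channels in a recording
#' @param rec an `hb_recording` or `od_recording`.
#' @return integer count.
#' @export
n_samples <- function(rec) {
  if (inherits(rec, "hb_recording")) ncol(rec$oxy)
  else if (inherits(rec, "od_recording")) dim(rec$delta_od)[3]
  else stop("not a recording")
}

#' @rdname n_samples
#' @export
n_channels <- function(rec) {
  if (inherits(rec, "hb_recording")) nrow(rec$oxy)
  else if (inherits(rec, "od_recording")) dim(rec$delta_od)[2]
  else stop("not a recording")
}

#' Optical-density recording container
#'
#' Optical density changes at three near-infrared wavelengths per channel
#' and sample, as produced by the forward modified Beer-Lambert model or
#' read from instrument exports.
#'
#' @param delta_od numeric array, wavelength(3) x channel x sample.
#' @param wavelengths numeric vector of the three wavelengths in nm
#'   (default 780, 805, 830).
#' @param sampling_interval seconds (> 0).
#' @param channel_labels optional channel identifiers.
#' @return An object of class `od_recording`.
#' @export
od_recording <- function(delta_od, wavelengths = c(780, 805, 830),
                         sampling_interval, channel_labels = NULL) {
  delta_od <- as.array(delta_od)
  if (length(dim(delta_od)) != 3L || dim(delta_od)[1] != 3L)
    stop("delta_od must be a 3 x channels x samples array")
  if (length(wavelengths) != 3L)
    stop("exactly 3 wavelengths are required")
  if (!all(is.finite(delta_od)))
    stop("delta_od must be finite")
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0)
    stop("sampling_interval must be a single positive number")
  n_ch <- dim(delta_od)[2]
  if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(n_ch))
  structure(
    list(delta_od = delta_od, wavelengths = as.numeric(wavelengths),
         sampling_interval = sampling_interval,
         channel_labels = as.character(channel_labels)),
    class = "od_recording")
}

#' @export
print.od_recording <- function(x, ...) {
  cat(sprintf("<od_recording> %d channels x %d samples @ %.4g s, wavelengths %s nm\n",
              dim(x$delta_od)[2], dim(x$delta_od)[3], x$sampling_interval,
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}
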