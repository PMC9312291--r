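# Canonical double-gamma hemodynamic response function.
#
# The kernel is the difference of two gamma densities, parameterized so
# that the mode of the positive lobe sits at `peak_delay` and the mode of
# the undershoot at `undershoot_delay` (shape = delay/dispersion + 1,
# rate = 1/dispersion). The evaluated kernel is scaled to unit peak.

#' Default canonical HRF parameters
#'
#' Peak at 6 s, undershoot at 16 s, unit dispersions, undershoot ratio
#' 1/6, 16 microtime bins per TR for regressor construction.
#' @return a list of class `hrf`.
#' @export
default_hrf <- function() {
  structure(list(
    kind = "double-gamma",
    peak_delay = 6,
    undershoot_delay = 16,
    peak_dispersion = 1,
    undershoot_dispersion = 1,
    undershoot_ratio = 1 / 6,
    microtime_bins = 16L
  ), class = "hrf")
}

hrf_raw <- function(hrf, t) {
  a1 <- hrf$peak_delay / hrf$peak_dispersion + 1
  a2 <- hrf$undershoot_delay / hrf$undershoot_dispersion + 1
  stats::dgamma(t, shape = a1, rate = 1 / hrf$peak_dispersion) -
    hrf$undershoot_ratio *
      stats::dgamma(t, shape = a2, rate = 1 / hrf$undershoot_dispersion)
}

hrf_peak_value <- function(hrf) {
  # unit-peak normalization constant; the peak is near peak_delay
  tg <- seq(0, hrf$undershoot_delay + 16, by = 0.01)
  max(hrf_raw(hrf, tg))
}

#' Evaluate the canonical HRF at times t (unit peak)
#'
#' @param hrf an `hrf` object from [default_hrf()].
#' @param t times in seconds, all `>= 0`.
#' @return response values, 0 at t = 0, peak value 1 near `peak_delay`.
#' @export
hrf_evaluate <- function(hrf = default_hrf(), t) {
  if (any(t < 0)) stopf("hrf_evaluate: t must be >= 0")
  if (any(c(hrf$peak_dispersion, hrf$undershoot_dispersion) <= 0)) {
    stopf("hrf_evaluate: dispersions must be > 0")
  }
  hrf_raw(hrf, t) / hrf_peak_value(hrf)
}

# Sampled kernel at microtime resolution, normalized to unit *integral* so
# that a sustained block regressor plateaus at 1 and condition amplitudes
# read as percent signal change at plateau.
hrf_kernel <- function(hrf, dt, span = 32) {
  tk <- seq(0, span, by = dt)
  k <- hrf_raw(hrf, tk)
  k / (sum(k) * dt) * dt # scaled so convolution with a unit boxcar -> plateau 1
}
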