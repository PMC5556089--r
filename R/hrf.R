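#' Canonical double-gamma haemodynamic response function
#'
#' Parameterization of the canonical HRF used throughout the package: a
#' difference of two gamma densities, peaking around 6 s with a late
#' undershoot around 16 s, truncated at `length_s`. The curve is scaled so
#' its maximum is 1, making convolved regressor amplitudes interpretable as
#' peak signal change.
#'
#' @param peak_delay Delay of the positive response peak, seconds.
#' @param undershoot_delay Delay of the undershoot, seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Support of the kernel in seconds.
#' @param dispersion Dispersion (gamma scale) of both lobes, seconds.
#'
#' @return An object of class `hrf_spec`.
#' @examples
#' h <- hrf_spec()
#' t <- seq(0, 32, by = 0.1)
#' plot(t, eval_hrf(h, t), type = "l")
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16, ratio = 6,
                     length_s = 32, dispersion = 1) {
  stopifnot_scalar_number(peak_delay, "peak_delay", lower = 0.1)
  stopifnot_scalar_number(undershoot_delay, "undershoot_delay", lower = 0.1)
  stopifnot_scalar_number(ratio, "ratio", lower = 1e-6)
  stopifnot_scalar_number(length_s, "length_s", lower = 1)
  stopifnot_scalar_number(dispersion, "dispersion", lower = 1e-6)
  structure(
    list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
         ratio = ratio, length_s = length_s, dispersion = dispersion),
    class = "hrf_spec"
  )
}

#' Evaluate an HRF at given times
#'
#' @param hrf An [hrf_spec()].
#' @param t Times in seconds (values outside `[0, length_s]` give 0).
#' @return Numeric vector of responses, peak-normalized to 1.
#' @export
eval_hrf <- function(hrf, t) {
  stopifnot(inherits(hrf, "hrf_spec"))
  d <- hrf$dispersion
  raw <- function(tt) {
    dgamma(tt, shape = hrf$peak_delay / d, scale = d) -
      dgamma(tt, shape = hrf$undershoot_delay / d, scale = d) / hrf$ratio
  }
  tg <- seq(0, hrf$length_s, by = 0.01)
  peak <- max(raw(tg))
  out <- raw(t) / peak
  out[t < 0 | t > hrf$length_s] <- 0
  out
}

# Sample the HRF kernel on a fine grid of step dt.
hrf_kernel <- function(hrf, dt) {
  eval_hrf(hrf, seq(0, hrf$length_s, by = dt))
}

# Build HRF-convolved boxcar regressors sampled at the volume times.
#
# onsets/durations/amplitudes are per-event vectors within one run;
# returns an n_vols x n_events matrix (one column per event) when
# `separate = TRUE`, else a single summed column. Convolution is carried
# out on an internal fine grid of step `dt` before resampling at the TR.
convolve_events <- function(onsets, durations, amplitudes, n_vols, tr,
                            hrf = hrf_spec(), dt = 0.1, separate = TRUE) {
  stopifnot(length(onsets) == length(durations))
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, length(onsets))
  run_dur <- n_vols * tr
  n_fine <- ceiling(run_dur / dt) + 1L
  kern <- hrf_kernel(hrf, dt)
  vol_idx <- round((0:(n_vols - 1L)) * tr / dt) + 1L
  # Unit-amplitude column, peak-normalized on the fine grid so that an
  # event of amplitude A produces a regressor (and simulated response)
  # peaking at A, independent of boxcar duration and of dt. The
  # convolution is evaluated only over the event's support window
  # (boxcar plus kernel length), which is exact since the response is
  # zero elsewhere.
  one <- function(on, du, am) {
    i0 <- floor(on / dt) + 1L
    i1 <- min(n_fine, floor((on + max(du, dt)) / dt))
    stim_local <- rep(1, i1 - i0 + 1L)
    y_local <- convolve(stim_local, rev(kern), type = "open")
    peak <- max(abs(y_local))
    if (peak < .Machine$double.eps) peak <- 1
    full <- numeric(n_fine + length(y_local))
    idx <- i0:(i0 + length(y_local) - 1L)
    full[idx] <- y_local / peak
    am * full[vol_idx]
  }
  cols <- mapply(one, onsets, durations, amplitudes)
  cols <- matrix(cols, nrow = n_vols)
  if (separate) cols else rowSums(cols)
}
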