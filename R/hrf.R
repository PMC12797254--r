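# Canonical double-gamma haemodynamic response and regressor construction.

#' Canonical double-gamma HRF
#'
#' The canonical haemodynamic response used throughout: a gamma density
#' peaking near 6 s minus an undershoot gamma peaking near 16 s, weighted
#' 1/6, no temporal or dispersion derivatives. The kernel is scaled to unit
#' peak so condition amplitudes are expressed in signal units at the response
#' peak.
#'
#' @param t vector of times in seconds (values < 0 return 0).
#' @param peak_delay,undershoot_delay gamma shape parameters (rate 1).
#' @param undershoot_ratio weight of the undershoot component.
#' @return numeric vector, same length as `t`.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' max(hrf_double_gamma(t))  # 1
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = peak_delay, rate = 1) -
                undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1))
  # unit-peak normalization on a fine reference grid (constant for defaults)
  tref <- seq(0, 32, by = 0.01)
  peak <- max(stats::dgamma(tref, shape = peak_delay, rate = 1) -
                undershoot_ratio * stats::dgamma(tref, shape = undershoot_delay, rate = 1))
  h / peak
}

#' HRF-convolved condition regressor
#'
#' Builds the boxcar for a set of events on a fine time grid (`dt` seconds),
#' convolves it with the canonical double-gamma HRF and samples the result at
#' volume acquisition times `(0, TR, 2 TR, ...)`.
#'
#' @param onsets,durations event onsets and durations in seconds.
#' @param spec an [acquisition_spec()].
#' @param dt fine-grid resolution in seconds.
#' @return numeric vector of length `spec$n_volumes`.
#' @export
hrf_regressor <- function(onsets, durations, spec, dt = 0.1) {
  stopifnot(length(onsets) == length(durations))
  total <- run_duration(spec)
  n_fine <- ceiling(total / dt) + 1
  box <- numeric(n_fine)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1
    i1 <- min(n_fine, ceiling((onsets[k] + durations[k]) / dt))
    box[i0:i1] <- 1
  }
  kern <- hrf_double_gamma(seq(0, 32, by = dt)) * dt
  kern <- kern / sum(kern)  # sustained blocks plateau at the condition amplitude
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
  vol_idx <- round((0:(spec$n_volumes - 1)) * spec$tr_seconds / dt) + 1
  conv[pmin(vol_idx, n_fine)]
}
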