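# Waveform templates shared by the synthetic generators and, for the
# analytic rise/decay helpers, by the kinetics tests.

#' Peak-normalized difference-of-exponentials synaptic waveform
#'
#' The canonical postsynaptic-current shape
#' \eqn{g(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / N}, peak-normalized so that
#' \eqn{\max_t g(t) = 1}. Used for miniature and evoked synaptic events and,
#' rescaled, for MEA field-response templates.
#'
#' @param t time from event onset, ms (values <= 0 give 0)
#' @param rise_tau,decay_tau time constants, ms; `rise_tau < decay_tau`
#' @return numeric vector of template values in `[0, 1]`
#' @export
synaptic_template <- function(t, rise_tau, decay_tau) {
  check_positive(rise_tau, "rise_tau")
  check_positive(decay_tau, "decay_tau")
  if (rise_tau >= decay_tau) stop("'rise_tau' must be < 'decay_tau'", call. = FALSE)
  pk <- template_peak_time(rise_tau, decay_tau)
  norm <- exp(-pk / decay_tau) - exp(-pk / rise_tau)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / norm
  out
}

#' Analytic peak time of the difference-of-exponentials template
#'
#' @inheritParams synaptic_template
#' @return peak time from onset, ms
#' @export
template_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

#' Analytic 10--90% rise time of the synaptic template
#'
#' Time between the 10% and 90%-of-peak crossings on the rising limb,
#' solved to numerical precision on the continuous template.
#'
#' @inheritParams synaptic_template
#' @return 10--90% rise time, ms
#' @export
template_rise_time <- function(rise_tau, decay_tau) {
  pk <- template_peak_time(rise_tau, decay_tau)
  cross <- function(level) {
    stats::uniroot(function(x) synaptic_template(x, rise_tau, decay_tau) - level,
                   lower = pk * 1e-9, upper = pk, tol = 1e-12)$root
  }
  cross(0.9) - cross(0.1)
}

#' Invert the 10--90% rise time for the template rise constant
#'
#' Finds the `rise_tau` for which [template_rise_time()] equals
#' `rise_time_10_90` at the given decay constant. Convenient when a
#' generator must reproduce a measured rise time exactly.
#'
#' @param rise_time_10_90 target 10--90% rise time, ms
#' @param decay_tau decay constant, ms
#' @return rise_tau, ms
#' @export
rise_tau_for_rise_time <- function(rise_time_10_90, decay_tau) {
  check_positive(rise_time_10_90, "rise_time_10_90")
  stats::uniroot(function(tr) template_rise_time(tr, decay_tau) - rise_time_10_90,
                 lower = decay_tau * 1e-5, upper = decay_tau * 0.999,
                 tol = 1e-12)$root
}

# Stereotyped action-potential waveform pasted onto simulated sweeps when
# the membrane crosses threshold. Shape: linear rise from threshold to the
# overshoot peak (rise_ms), linear repolarization down to the AHP minimum
# (fall_ms). The segment after the template is left to the passive membrane,
# which relaxes exponentially from the AHP minimum, so the first
# post-repolarization dV/dt zero crossing sits exactly at the AHP minimum.
# The steep linear rise guarantees a unique, well-separated phase-plane
# threshold crossing (dV/dt jumps far above 10 mV/ms at onset).
ap_waveform <- function(threshold_mv, peak_mv, ahp_mv, sampling_rate_khz,
                        rise_ms = 0.5, fall_ms = 1.0) {
  n_rise <- max(2L, round(rise_ms * sampling_rate_khz))
  n_fall <- max(2L, round(fall_ms * sampling_rate_khz))
  up <- seq(threshold_mv, peak_mv, length.out = n_rise + 1L)
  down <- seq(peak_mv, ahp_mv, length.out = n_fall + 1L)[-1L]
  c(up, down)
}

# Field-postsynaptic-potential template: the synaptic biexponential shifted
# so its continuous-time peak lands `peak_latency_ms` after the stimulus.
fpsp_template <- function(t_ms, stim_ms, peak_latency_ms, rise_tau, decay_tau) {
  onset <- stim_ms + peak_latency_ms - template_peak_time(rise_tau, decay_tau)
  synaptic_template(t_ms - onset, rise_tau, decay_tau)
}
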