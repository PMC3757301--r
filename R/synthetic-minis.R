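# Synthetic voltage-clamp traces containing spontaneous miniature EPSCs:
# Poisson event timing, truncated-Gaussian amplitudes, difference-of-
# exponentials kinetics, additive Gaussian recording noise. Overlapping
# events sum linearly, reproducing the multipeak phenomenology of real
# high-frequency recordings.

#' Parameters for miniature-EPSC trace synthesis
#'
#' Defaults correspond to a wild-type-like mossy cell: large, frequent
#' minis with 10--90% rise 0.83 ms and decay tau 4.39 ms.
#'
#' @param event_rate Poisson event rate, Hz (>= 0)
#' @param amplitude_mean,amplitude_sd Gaussian amplitude distribution, pA;
#'   draws are truncated at 0 (redrawn) so amplitudes stay positive
#' @param rise_tau,decay_tau template time constants, ms
#'   (`rise_tau < decay_tau`); defaults chosen so the template's analytic
#'   10--90% rise time is 0.83 ms at decay 4.39 ms
#' @param noise_sd recording noise, pA
#' @param duration trace length, s (> 0)
#' @param sampling_rate kHz
#' @param seed integer seed
#' @return object of class `mini_gen_params`
#' @export
mini_gen_params <- function(event_rate = 5, amplitude_mean = 30,
                            amplitude_sd = 5,
                            rise_tau = rise_tau_for_rise_time(0.83, 4.39),
                            decay_tau = 4.39, noise_sd = 2, duration = 30,
                            sampling_rate = 20, seed = NULL) {
  p <- list(event_rate = event_rate, amplitude_mean = amplitude_mean,
            amplitude_sd = amplitude_sd, rise_tau = rise_tau,
            decay_tau = decay_tau, noise_sd = noise_sd, duration = duration,
            sampling_rate = sampling_rate, seed = seed)
  for (nm in setdiff(names(p), "seed")) stop_if_not_finite(p[[nm]], nm)
  check_positive(p$event_rate, "event_rate", strict = FALSE)
  check_positive(p$duration, "duration")
  check_positive(p$noise_sd, "noise_sd", strict = FALSE)
  if (p$rise_tau >= p$decay_tau)
    stop("'rise_tau' must be < 'decay_tau'", call. = FALSE)
  structure(p, class = "mini_gen_params")
}

#' Synthesize a miniature-EPSC trace with ground truth
#'
#' Event onsets form a Poisson process at `event_rate`; each event is an
#' inward (negative) peak-normalized difference-of-exponentials scaled by a
#' truncated-Gaussian amplitude; events sum linearly where they overlap;
#' Gaussian noise is added on top.
#'
#' @param p a [mini_gen_params()]
#' @param onsets_ms,amplitudes_pa optional fixed event onsets and
#'   amplitudes that bypass the Poisson/Gaussian draws (both or neither);
#'   useful for calibration experiments with known event layouts
#' @return object of class `mini_trace`: list with `current_pa` (numeric
#'   trace, pA), `sampling_rate_khz`, `duration_s`, `params`, and `truth`,
#'   a data.frame with `onset_ms`, `peak_ms`, `amplitude_pa` per event
#' @export
synthesize_mini_trace <- function(p, onsets_ms = NULL, amplitudes_pa = NULL) {
  stopifnot(inherits(p, "mini_gen_params"))
  if (xor(is.null(onsets_ms), is.null(amplitudes_pa)) ||
      (!is.null(onsets_ms) && length(onsets_ms) != length(amplitudes_pa)))
    stop("'onsets_ms' and 'amplitudes_pa' must be given together, ",
         "with equal lengths", call. = FALSE)
  fs <- p$sampling_rate
  n <- round(p$duration * fs * 1000)
  dur_ms <- p$duration * 1000
  tpk <- template_peak_time(p$rise_tau, p$decay_tau)
  gen <- function() {
    if (is.null(onsets_ms)) {
      n_ev <- rpois(1L, p$event_rate * p$duration)
      onsets <- sort(runif(n_ev, 0, dur_ms))
      amps <- numeric(n_ev)
      for (i in seq_len(n_ev)) {
        a <- rnorm(1L, p$amplitude_mean, p$amplitude_sd)
        while (a <= 0) a <- rnorm(1L, p$amplitude_mean, p$amplitude_sd)
        amps[i] <- a
      }
    } else {
      ord <- order(onsets_ms)
      onsets <- onsets_ms[ord]
      amps <- amplitudes_pa[ord]
      n_ev <- length(onsets)
    }
    trace <- if (p$noise_sd > 0) rnorm(n, 0, p$noise_sd) else numeric(n)
    # paste each event over a window long enough for the tail to vanish
    win <- round((tpk + 12 * p$decay_tau) * fs)
    tgrid <- (seq_len(win) - 1) / fs
    for (i in seq_len(n_ev)) {
      i0 <- floor(onsets[i] * fs) + 1L
      m <- min(win, n - i0 + 1L)
      if (m < 1L) next
      tt <- (seq_len(m) - 1) / fs + ((i0 - 1) / fs - onsets[i])
      trace[i0:(i0 + m - 1L)] <- trace[i0:(i0 + m - 1L)] -
        amps[i] * synaptic_template(tt, p$rise_tau, p$decay_tau)
    }
    list(trace = trace, onsets = onsets, amps = amps)
  }
  g <- with_local_seed(p$seed, gen())
  structure(list(
    current_pa = g$trace,
    sampling_rate_khz = fs,
    duration_s = p$duration,
    params = p,
    truth = data.frame(onset_ms = g$onsets,
                       peak_ms = g$onsets + tpk,
                       amplitude_pa = g$amps)),
    class = "mini_trace")
}
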