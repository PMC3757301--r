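# Synthetic paired evoked trains: an excitatory train recorded at -80 mV
# (inward, negative pulses) and an inhibitory train at 0 mV (outward,
# positive), on a shared time base, with per-pulse depression profiles and
# known per-pulse ground-truth amplitudes.

#' Parameters for paired evoked-train synthesis
#'
#' @param e_first_amplitude,i_first_amplitude first-pulse amplitudes, pA
#'   (magnitudes; the excitatory trace is drawn negative)
#' @param e_depression_profile,i_depression_profile per-pulse scale factors,
#'   length `n_pulses`, first element 1
#' @param n_pulses number of pulses
#' @param frequency train frequency, Hz (default 40 Hz, 2 s -> 80 pulses)
#' @param rise_tau,decay_tau event kinetics, ms
#' @param noise_sd recording noise, pA
#' @param baseline_ms pre-train baseline, ms
#' @param tail_ms post-train tail, ms
#' @param sampling_rate kHz
#' @param seed integer seed
#' @return object of class `evoked_gen_params`
#' @export
evoked_gen_params <- function(e_first_amplitude = 100,
                              i_first_amplitude = 150,
                              e_depression_profile = NULL,
                              i_depression_profile = NULL,
                              n_pulses = 80, frequency = 40,
                              rise_tau = 0.5, decay_tau = 5,
                              noise_sd = 0, baseline_ms = 50, tail_ms = 100,
                              sampling_rate = 20, seed = NULL) {
  n_pulses <- as.integer(n_pulses)
  if (is.null(e_depression_profile)) e_depression_profile <- rep(1, n_pulses)
  if (is.null(i_depression_profile)) i_depression_profile <- rep(1, n_pulses)
  p <- list(e_first_amplitude = e_first_amplitude,
            i_first_amplitude = i_first_amplitude,
            e_depression_profile = e_depression_profile,
            i_depression_profile = i_depression_profile,
            n_pulses = n_pulses, frequency = frequency,
            rise_tau = rise_tau, decay_tau = decay_tau,
            noise_sd = noise_sd, baseline_ms = baseline_ms,
            tail_ms = tail_ms, sampling_rate = sampling_rate, seed = seed)
  for (nm in setdiff(names(p), "seed")) stop_if_not_finite(p[[nm]], nm)
  check_positive(p$e_first_amplitude, "e_first_amplitude")
  check_positive(p$i_first_amplitude, "i_first_amplitude")
  check_positive(p$frequency, "frequency")
  if (length(p$e_depression_profile) != n_pulses ||
      length(p$i_depression_profile) != n_pulses)
    stop("depression profiles must have length 'n_pulses'", call. = FALSE)
  if (abs(p$e_depression_profile[1] - 1) > 1e-12 ||
      abs(p$i_depression_profile[1] - 1) > 1e-12)
    stop("depression profiles must start at 1", call. = FALSE)
  if (p$rise_tau >= p$decay_tau)
    stop("'rise_tau' must be < 'decay_tau'", call. = FALSE)
  structure(p, class = "evoked_gen_params")
}

#' Exponential-plateau depression profile
#'
#' Per-pulse scale factors relaxing from 1 toward `plateau` with pulse
#' constant `tau_pulses`: \eqn{s_k = p + (1-p) e^{-(k-1)/\tau}}. A
#' convenient way to emulate steady-state multiple-pulse depression.
#'
#' @param n_pulses number of pulses
#' @param plateau asymptotic scale factor
#' @param tau_pulses relaxation constant in units of pulses
#' @return numeric vector of length `n_pulses`, first element 1
#' @export
depression_profile <- function(n_pulses, plateau, tau_pulses = 5) {
  plateau + (1 - plateau) * exp(-(seq_len(n_pulses) - 1) / tau_pulses)
}

#' Synthesize a matched excitatory/inhibitory evoked-train pair
#'
#' @param p an [evoked_gen_params()]
#' @return object of class `evoked_pair`: list with `e_trace`, `i_trace`
#'   (pA, shared time base), `pulse_times_ms`, `sampling_rate_khz`,
#'   `frequency_hz`, `params`, and `truth` with per-pulse ground-truth
#'   amplitudes (`e_amplitudes_pa`, `i_amplitudes_pa`, magnitudes)
#' @export
synthesize_evoked_trains <- function(p) {
  stopifnot(inherits(p, "evoked_gen_params"))
  fs <- p$sampling_rate
  isi_ms <- 1000 / p$frequency
  pulse_times <- p$baseline_ms + (seq_len(p$n_pulses) - 1) * isi_ms
  total_ms <- p$baseline_ms + p$n_pulses * isi_ms + p$tail_ms
  n <- round(total_ms * fs)
  t_ms <- (seq_len(n) - 1) / fs
  e_amps <- p$e_first_amplitude * p$e_depression_profile
  i_amps <- p$i_first_amplitude * p$i_depression_profile
  build <- function(amps, sign) {
    tr <- numeric(n)
    win <- round((template_peak_time(p$rise_tau, p$decay_tau) +
                    12 * p$decay_tau) * fs)
    for (k in seq_len(p$n_pulses)) {
      i0 <- floor(pulse_times[k] * fs) + 1L
      m <- min(win, n - i0 + 1L)
      idx <- i0:(i0 + m - 1L)
      tr[idx] <- tr[idx] + sign * amps[k] *
        synaptic_template(t_ms[idx] - pulse_times[k], p$rise_tau, p$decay_tau)
    }
    tr
  }
  e_trace <- build(e_amps, -1)
  i_trace <- build(i_amps, +1)
  if (p$noise_sd > 0) {
    noise <- with_local_seed(p$seed, list(rnorm(n, 0, p$noise_sd),
                                          rnorm(n, 0, p$noise_sd)))
    e_trace <- e_trace + noise[[1]]
    i_trace <- i_trace + noise[[2]]
  }
  structure(list(
    e_trace = e_trace, i_trace = i_trace,
    pulse_times_ms = pulse_times,
    sampling_rate_khz = fs,
    frequency_hz = p$frequency,
    params = p,
    truth = list(e_amplitudes_pa = e_amps, i_amplitudes_pa = i_amps)),
    class = "evoked_pair")
}
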