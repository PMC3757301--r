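# Synthetic whole-cell current-clamp recordings: a leaky integrate-and-fire
# membrane driven by a square-step protocol, with a stereotyped AP waveform
# pasted at each threshold crossing. Ground truth (spike times, rheobase,
# input resistance) is returned alongside, so every downstream intrinsic
# measurement can be checked against known values.

#' Passive-membrane and spiking parameters for the simulator
#'
#' Defaults describe a wild-type-like hilar mossy cell: input resistance
#' 396 MOhm and a threshold gap giving a true rheobase of ~45 pA.
#'
#' @param resting_potential resting membrane potential, mV
#' @param input_resistance input resistance, MOhm (> 0)
#' @param membrane_time_constant membrane time constant, ms (> 0)
#' @param spike_threshold spike threshold, mV (> resting_potential)
#' @param spike_reset voltage the membrane restarts from after a spike, mV.
#'   This is also the AP waveform's afterhyperpolarization minimum. Default
#'   `resting_potential - ahp_depth`.
#' @param refractory_period absolute refractory period after the AP
#'   waveform, ms
#' @param ahp_depth depth of the afterhyperpolarization below rest, mV;
#'   used for the default `spike_reset`
#' @param noise_sd recording-noise standard deviation added to the voltage
#'   trace, mV (>= 0). Noise is observational: spike generation runs on the
#'   noiseless dynamics so ground truth stays exact.
#' @param ap_peak overshoot peak of the pasted AP waveform, mV
#' @return object of class `passive_cell_params`
#' @export
passive_cell_params <- function(resting_potential = -65,
                                input_resistance = 396,
                                membrane_time_constant = 25,
                                spike_threshold = -47.2,
                                spike_reset = NULL,
                                refractory_period = 2,
                                ahp_depth = 5,
                                noise_sd = 0,
                                ap_peak = 30) {
  if (is.null(spike_reset)) spike_reset <- resting_potential - ahp_depth
  p <- list(resting_potential = resting_potential,
            input_resistance = input_resistance,
            membrane_time_constant = membrane_time_constant,
            spike_threshold = spike_threshold,
            spike_reset = spike_reset,
            refractory_period = refractory_period,
            ahp_depth = ahp_depth,
            noise_sd = noise_sd,
            ap_peak = ap_peak)
  for (nm in names(p)) stop_if_not_finite(p[[nm]], nm)
  check_positive(p$input_resistance, "input_resistance")
  check_positive(p$membrane_time_constant, "membrane_time_constant")
  check_positive(p$noise_sd, "noise_sd", strict = FALSE)
  if (p$spike_threshold <= p$resting_potential)
    stop("'spike_threshold' must exceed 'resting_potential'", call. = FALSE)
  if (p$spike_reset > p$spike_threshold)
    stop("'spike_reset' must not exceed 'spike_threshold'", call. = FALSE)
  structure(p, class = "passive_cell_params")
}

#' Current-step stimulation protocol
#'
#' Defaults follow the standard mossy/granule-cell protocol: 30 steps of
#' 1 s, starting at -100 pA in +10 pA increments.
#'
#' @param n_steps number of current steps (>= 1)
#' @param start_current first step amplitude, pA
#' @param increment step-to-step increment, pA
#' @param step_duration duration of each step, ms
#' @param baseline_duration pre-step baseline, ms
#' @param tail_duration post-step tail, ms
#' @param sampling_rate sampling rate, kHz
#' @return object of class `step_protocol`
#' @export
step_protocol <- function(n_steps = 30, start_current = -100, increment = 10,
                          step_duration = 1000, baseline_duration = 100,
                          tail_duration = 100, sampling_rate = 20) {
  p <- list(n_steps = as.integer(n_steps), start_current = start_current,
            increment = increment, step_duration = step_duration,
            baseline_duration = baseline_duration,
            tail_duration = tail_duration, sampling_rate = sampling_rate)
  for (nm in names(p)) stop_if_not_finite(p[[nm]], nm)
  if (p$n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  check_positive(p$step_duration, "step_duration")
  check_positive(p$sampling_rate, "sampling_rate")
  check_positive(p$baseline_duration, "baseline_duration", strict = FALSE)
  check_positive(p$tail_duration, "tail_duration", strict = FALSE)
  structure(p, class = "step_protocol")
}

#' Protocol step currents, pA
#' @param protocol a [step_protocol()]
#' @return numeric vector of injected currents
#' @export
protocol_currents <- function(protocol) {
  protocol$start_current + protocol$increment * (seq_len(protocol$n_steps) - 1)
}

#' Simulate a current-clamp step experiment
#'
#' Integrates a leaky integrate-and-fire membrane,
#' \eqn{dV/dt = (V_{rest} - V)/\tau_m + I R_{in}/\tau_m}, exactly
#' (exponential update) over each step. When the noiseless voltage crosses
#' `spike_threshold`, the stereotyped AP waveform (linear rise to the
#' overshoot peak, linear fall to the AHP minimum) is pasted, the membrane
#' restarts from `spike_reset`, and threshold checks are
#' suppressed for the refractory period. Gaussian recording noise is added
#' afterwards, so ground-truth spike times are exact.
#'
#' @param cell a [passive_cell_params()]
#' @param protocol a [step_protocol()]
#' @param seed integer seed for the recording noise (optional when
#'   `noise_sd = 0`)
#' @return object of class `cclamp_sweeps`: list with `sweeps` (one numeric
#'   voltage vector, mV, per step), `currents_pa`, `sampling_rate_khz`,
#'   `protocol`, `cell`, and `truth` (per-sweep spike times in ms,
#'   `rheobase_pa` = closed-form \eqn{(V_{th}-V_{rest})/R_{in}},
#'   `input_resistance_mohm`, `resting_potential_mv`)
#' @export
simulate_current_clamp <- function(cell, protocol, seed = NULL) {
  stopifnot(inherits(cell, "passive_cell_params"),
            inherits(protocol, "step_protocol"))
  fs <- protocol$sampling_rate
  dt <- 1 / fs
  n_base <- round(protocol$baseline_duration * fs)
  n_step <- round(protocol$step_duration * fs)
  n_tail <- round(protocol$tail_duration * fs)
  currents <- protocol_currents(protocol)
  alpha <- exp(-dt / cell$membrane_time_constant)
  ap <- ap_waveform(cell$spike_threshold, cell$ap_peak, cell$spike_reset, fs)
  n_refr <- round(cell$refractory_period * fs)

  run_step <- function(i_pa) {
    v_inf <- cell$resting_potential + i_pa * cell$input_resistance / 1000
    v <- numeric(n_step)
    spikes_ms <- numeric(0)
    k <- 1L
    v0 <- cell$resting_potential
    while (k <= n_step) {
      m <- n_step - k + 1L
      seg <- v_inf + (v0 - v_inf) * alpha^(seq_len(m) - 1L)
      if (v_inf < cell$spike_threshold) {
        v[k:n_step] <- seg
        break
      }
      hit <- which(seg >= cell$spike_threshold)
      if (length(hit) == 0L) {
        v[k:n_step] <- seg
        break
      }
      h <- hit[1L]
      if (h > 1L) v[k:(k + h - 2L)] <- seg[seq_len(h - 1L)]
      i_spk <- k + h - 1L
      spikes_ms <- c(spikes_ms, (i_spk - 1L) * dt)
      n_paste <- min(length(ap), n_step - i_spk + 1L)
      v[i_spk:(i_spk + n_paste - 1L)] <- ap[seq_len(n_paste)]
      k2 <- i_spk + length(ap)
      # hold at the AHP minimum through the refractory period
      if (n_refr > 0L && k2 <= n_step) {
        hold <- min(n_refr, n_step - k2 + 1L)
        v[k2:(k2 + hold - 1L)] <- cell$spike_reset
        k2 <- k2 + hold
      }
      v0 <- cell$spike_reset
      k <- k2
    }
    list(v = v, spikes_ms = spikes_ms)
  }

  sweeps <- vector("list", protocol$n_steps)
  spike_times <- vector("list", protocol$n_steps)
  for (s in seq_along(currents)) {
    st <- run_step(currents[s])
    sweeps[[s]] <- c(rep(cell$resting_potential, n_base), st$v,
                     rep(cell$resting_potential, n_tail))
    spike_times[[s]] <- st$spikes_ms + protocol$baseline_duration
  }
  if (cell$noise_sd > 0) {
    if (is.null(seed))
      stop("a 'seed' is required when 'noise_sd' > 0", call. = FALSE)
    sweeps <- with_local_seed(seed, lapply(sweeps, function(v)
      v + rnorm(length(v), 0, cell$noise_sd)))
  }
  structure(list(
    sweeps = sweeps,
    currents_pa = currents,
    sampling_rate_khz = fs,
    protocol = protocol,
    cell = cell,
    truth = list(
      spike_times = spike_times,
      rheobase_pa = (cell$spike_threshold - cell$resting_potential) /
        cell$input_resistance * 1000,
      input_resistance_mohm = cell$input_resistance,
      resting_potential_mv = cell$resting_potential)),
    class = "cclamp_sweeps")
}

#' Simulate a zero-current resting-potential recording
#'
#' A long voltage trace at rest with Gaussian recording noise, the input
#' expected by [estimate_resting_potential()].
#'
#' @param cell a [passive_cell_params()]
#' @param duration_s recording length, s (default 60 s)
#' @param sampling_rate kHz
#' @param seed integer seed
#' @return numeric voltage vector, mV, with attribute `sampling_rate_khz`
#' @export
simulate_resting_trace <- function(cell, duration_s = 60, sampling_rate = 20,
                                   seed = NULL) {
  check_positive(duration_s, "duration_s")
  n <- round(duration_s * sampling_rate * 1000)
  v <- with_local_seed(seed,
    cell$resting_potential + rnorm(n, 0, cell$noise_sd))
  attr(v, "sampling_rate_khz") <- sampling_rate
  v
}
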