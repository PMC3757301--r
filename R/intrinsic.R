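# Intrinsic membrane and firing properties from current-clamp step
# recordings: resting potential by Gaussian fit to the voltage histogram,
# phase-plane spike threshold (dV/dt criterion), AP amplitude / AHP /
# half-width, rheobase, three-point input resistance, F-I curve, and the
# recording-quality filter.

#' Resting membrane potential from a voltage histogram
#'
#' The voltage trace is binned and the histogram fitted with a Gaussian by
#' nonlinear least squares; the resting potential is the fitted mean. The
#' fit is restricted to the contiguous bins around the dominant mode, so a
#' secondary mode (e.g. up/down states) does not drag the estimate; a
#' warning is raised when such a secondary mode is present.
#'
#' @param trace voltage recording at zero holding current, mV (>= 100
#'   samples; >= 10 s recommended, 1 min typical)
#' @param bin_width histogram bin width, mV
#' @return list with `v_m_mv` (fitted mean), `sd_mv` (fitted Gaussian sd),
#'   `fit_r2` (coefficient of determination on bin counts), `multimodal`
#' @export
estimate_resting_potential <- function(trace, bin_width = 0.5) {
  trace <- as.numeric(trace)
  if (length(trace) < 100L)
    stop("need at least 100 samples to estimate the resting potential",
         call. = FALSE)
  check_positive(bin_width, "bin_width")
  if (sd(trace) < bin_width / 100) {
    return(list(v_m_mv = mean(trace), sd_mv = 0, fit_r2 = 1,
                multimodal = FALSE))
  }
  breaks <- seq(floor(min(trace) / bin_width) * bin_width - bin_width,
                ceiling(max(trace) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(trace, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  imode <- which.max(counts)
  keep <- counts >= 0.05 * counts[imode]
  # contiguous run of retained bins around the dominant mode
  lo <- imode; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- imode; while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
  outside <- counts
  outside[lo:hi] <- 0
  multimodal <- any(outside >= 0.2 * counts[imode])
  if (multimodal)
    warning("voltage histogram is multimodal; reporting the dominant mode",
            call. = FALSE)
  win <- lo:hi
  w_counts <- counts[win]; w_mids <- mids[win]
  mu0 <- sum(w_mids * w_counts) / sum(w_counts)
  s0 <- max(bin_width / 2,
            sqrt(sum(w_counts * (w_mids - mu0)^2) / sum(w_counts)))
  fit <- tryCatch(
    minpack.lm::nlsLM(cnt ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      data = list(cnt = w_counts, x = w_mids),
                      start = list(a = max(w_counts), mu = mu0, s = s0)),
    error = function(e)
      stop("Gaussian fit to the voltage histogram did not converge; ",
           "consider the trace median as a fallback", call. = FALSE))
  co <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((w_counts - mean(w_counts))^2)
  list(v_m_mv = unname(co["mu"]), sd_mv = abs(unname(co["s"])),
       fit_r2 = r2, multimodal = multimodal)
}

#' Detect action potentials on a voltage sweep
#'
#' The phase-plane criterion: the sweep is lightly smoothed (3-point moving
#' average), dV/dt is taken by central differences, and the threshold
#' voltage \eqn{V_s} is the first sample within each AP epoch where dV/dt
#' exceeds `dvdt_threshold`. Epochs are delimited by upward crossings of
#' `epoch_split_mv`, which prevents double counting. AP amplitude is the
#' overshoot peak minus \eqn{V_s}; the AHP is the voltage at the first
#' dV/dt zero crossing after repolarization below \eqn{V_s} (searched up to
#' `ahp_window_ms` past the peak); the half-amplitude width is measured at
#' \eqn{V_s + amplitude/2} with linear interpolation.
#'
#' @param sweep voltage sweep, mV
#' @param sampling_rate_khz sampling rate, kHz
#' @param dvdt_threshold phase-plane threshold, mV/ms (default 10)
#' @param epoch_split_mv epoch delimiter voltage, mV
#' @param ahp_window_ms AHP search window after the peak, ms
#' @return data.frame of class `ap_table`, one row per AP: `time_ms` (at
#'   \eqn{V_s}), `threshold_mv`, `peak_mv`, `amplitude_mv`, `ahp_mv`,
#'   `half_width_ms`. Zero rows when threshold is never crossed.
#' @export
detect_action_potentials <- function(sweep, sampling_rate_khz,
                                     dvdt_threshold = 10,
                                     epoch_split_mv = -20,
                                     ahp_window_ms = 50) {
  v <- as.numeric(sweep)  # voltages reported from the raw trace
  vs <- smooth3(v)        # smoothing only stabilizes the derivative
  n <- length(v)
  dv <- central_diff(vs, sampling_rate_khz)
  up <- which(v[-n] < epoch_split_mv & v[-1L] >= epoch_split_mv)
  empty <- data.frame(time_ms = numeric(0), threshold_mv = numeric(0),
                      peak_mv = numeric(0), amplitude_mv = numeric(0),
                      ahp_mv = numeric(0), half_width_ms = numeric(0))
  class(empty) <- c("ap_table", "data.frame")
  if (!length(up)) return(empty)
  bounds <- c(1L, floor((up[-1L] + up[-length(up)]) / 2), n)
  rows <- vector("list", length(up))
  for (k in seq_along(up)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    # V_s: start of the contiguous dV/dt > threshold upstroke containing
    # the epoch's -20 mV crossing; walking back from the crossing keeps
    # isolated derivative-noise excursions elsewhere in the epoch from
    # masquerading as threshold
    j <- up[k]
    if (dv[j] <= dvdt_threshold) {
      fwd <- j:hi
      hit <- fwd[dv[fwd] > dvdt_threshold]
      if (!length(hit)) next
      j <- hit[1L]
    }
    while (j > lo && dv[j - 1L] > dvdt_threshold) j <- j - 1L
    i_s <- j
    rest <- i_s:hi
    i_pk <- rest[which.max(v[rest])]
    v_s <- v[i_s]
    amp <- v[i_pk] - v_s
    # AHP: first dV/dt zero crossing after repolarization below V_s
    ahp_mv <- NA_real_
    hi_a <- min(n - 1L, i_pk + round(ahp_window_ms * sampling_rate_khz))
    j <- i_pk + 1L
    while (j <= hi_a) {
      if (v[j] < v_s && dv[j - 1L] < 0 && dv[j] >= 0) { ahp_mv <- v[j]; break }
      j <- j + 1L
    }
    half <- v_s + amp / 2
    c_up <- first_crossing(v, half, i_s:(i_pk - 1L), "up")
    c_dn <- first_crossing(v, half, i_pk:(hi - 1L), "down")
    hw <- if (is.na(c_up) || is.na(c_dn)) NA_real_ else
      (c_dn - c_up) / sampling_rate_khz
    rows[[k]] <- data.frame(time_ms = index_to_ms(i_s, sampling_rate_khz),
                            threshold_mv = v_s, peak_mv = v[i_pk],
                            amplitude_mv = amp, ahp_mv = ahp_mv,
                            half_width_ms = hw)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("ap_table", "data.frame")
  out
}

#' Rheobase: smallest current step eliciting an action potential
#'
#' @param sweeps a `cclamp_sweeps` object (steps in increasing current
#'   order) as returned by [simulate_current_clamp()]
#' @param ... passed to [detect_action_potentials()]
#' @return list with `rheobase_pa` (NA when no step spikes), `defined`,
#'   `step_index`
#' @export
estimate_rheobase <- function(sweeps, ...) {
  stopifnot(inherits(sweeps, "cclamp_sweeps"))
  if (is.unsorted(sweeps$currents_pa, strictly = TRUE))
    stop("current steps must be strictly increasing", call. = FALSE)
  for (s in seq_along(sweeps$currents_pa)) {
    if (sweeps$currents_pa[s] <= 0) next
    aps <- detect_action_potentials(sweeps$sweeps[[s]],
                                    sweeps$sampling_rate_khz, ...)
    if (nrow(aps) > 0L)
      return(list(rheobase_pa = sweeps$currents_pa[s], defined = TRUE,
                  step_index = s))
  }
  list(rheobase_pa = NA_real_, defined = FALSE, step_index = NA_integer_)
}

#' Input resistance by three-point linear regression
#'
#' Steady-state voltages of the -10 pA, 0 pA and +10 pA steps (mean over
#' the last `steady_window_ms` of the step) are regressed against injected
#' current by ordinary least squares; the input resistance is the slope.
#' The result is flagged when \eqn{R^2 \le 0.95}.
#'
#' @param sweeps a `cclamp_sweeps` object containing the three steps
#' @param steady_window_ms steady-state averaging window at the end of the
#'   step, ms
#' @return list with `input_resistance_mohm`, `r_squared`, `flagged`, and
#'   `points` (the fitted I/V pairs)
#' @export
fit_input_resistance <- function(sweeps, steady_window_ms = 200) {
  stopifnot(inherits(sweeps, "cclamp_sweeps"))
  want <- c(-10, 0, 10)
  idx <- match(want, sweeps$currents_pa)
  if (anyNA(idx))
    stop("protocol must contain the -10, 0 and +10 pA steps", call. = FALSE)
  fs <- sweeps$sampling_rate_khz
  prot <- sweeps$protocol
  i_end <- round((prot$baseline_duration + prot$step_duration) * fs)
  i_start <- i_end - round(steady_window_ms * fs) + 1L
  v_ss <- vapply(idx, function(s) mean(sweeps$sweeps[[s]][i_start:i_end]),
                 numeric(1))
  fit <- lm(v_ss ~ want)
  r2 <- 1 - sum(residuals(fit)^2) / sum((v_ss - mean(v_ss))^2)
  slope_mohm <- unname(coef(fit)[2]) * 1000  # mV/pA = GOhm -> MOhm
  list(input_resistance_mohm = slope_mohm, r_squared = r2,
       flagged = r2 <= 0.95,
       points = data.frame(current_pa = want, v_steady_mv = v_ss))
}

#' F-I curve: firing frequency versus injected current
#'
#' @param sweeps a `cclamp_sweeps` object
#' @param ... passed to [detect_action_potentials()]
#' @return data.frame with `current_pa` and `frequency_hz`
#'   (AP count / step duration); subthreshold steps keep 0 Hz entries
#' @export
build_fi_curve <- function(sweeps, ...) {
  stopifnot(inherits(sweeps, "cclamp_sweeps"))
  dur_s <- sweeps$protocol$step_duration / 1000
  freq <- vapply(seq_along(sweeps$sweeps), function(s) {
    nrow(detect_action_potentials(sweeps$sweeps[[s]],
                                  sweeps$sampling_rate_khz, ...)) / dur_s
  }, numeric(1))
  data.frame(current_pa = sweeps$currents_pa, frequency_hz = freq)
}

#' Recording-quality record
#'
#' @param r_a_series access (series) resistance over the recording, MOhm
#' @param r_m membrane resistance, MOhm (required for granule cells)
#' @return object of class `qc_record`
#' @export
qc_record <- function(r_a_series, r_m = NA_real_) {
  if (!length(r_a_series)) stop("'r_a_series' must be non-empty", call. = FALSE)
  structure(list(r_a_series = r_a_series, r_m = r_m,
                 passed = NA, reasons = character(0)),
            class = "qc_record")
}

#' Recording-quality filter
#'
#' Exclusion rules: access resistance deviating by more than 20% from its
#' initial value, or exceeding 15 MOhm at any point; granule cells are
#' additionally rejected as immature when the membrane resistance reaches
#' 300 MOhm or more.
#'
#' @param rec a [qc_record()]
#' @param cell_class `"mossy"` or `"granule"`
#' @return the record with `passed` and `reasons` filled in
#' @export
qc_filter <- function(rec, cell_class = c("mossy", "granule")) {
  stopifnot(inherits(rec, "qc_record"))
  cell_class <- match.arg(cell_class)
  reasons <- character(0)
  ra <- rec$r_a_series
  if (max(abs(ra - ra[1])) > 0.2 * ra[1])
    reasons <- c(reasons, "unstable R_a (>20% change)")
  if (any(ra > 15))
    reasons <- c(reasons, "R_a > 15 MOhm")
  if (cell_class == "granule") {
    if (is.na(rec$r_m))
      stop("granule-cell QC requires 'r_m'", call. = FALSE)
    if (rec$r_m >= 300)
      reasons <- c(reasons, "immature (R_m >= 300 MOhm)")
  }
  rec$passed <- length(reasons) == 0L
  rec$reasons <- reasons
  rec
}

#' Full intrinsic profile of a current-clamp experiment
#'
#' Convenience wrapper assembling resting potential, AP features (from the
#' first AP at rheobase), rheobase, input resistance and the F-I curve.
#'
#' @param sweeps a `cclamp_sweeps` object
#' @param vm_trace optional long zero-current recording for the resting
#'   potential; defaults to the 0 pA sweep
#' @param ... passed to [detect_action_potentials()]
#' @return object of class `intrinsic_profile`
#' @export
intrinsic_profile <- function(sweeps, vm_trace = NULL, ...) {
  stopifnot(inherits(sweeps, "cclamp_sweeps"))
  if (is.null(vm_trace)) {
    s0 <- match(0, sweeps$currents_pa)
    if (is.na(s0)) stop("no 0 pA sweep for the resting potential", call. = FALSE)
    vm_trace <- sweeps$sweeps[[s0]]
  }
  vm <- estimate_resting_potential(vm_trace)
  rheo <- estimate_rheobase(sweeps, ...)
  rin <- fit_input_resistance(sweeps)
  fi <- build_fi_curve(sweeps, ...)
  ap <- if (rheo$defined) {
    detect_action_potentials(sweeps$sweeps[[rheo$step_index]],
                             sweeps$sampling_rate_khz, ...)[1L, ]
  } else {
    data.frame(threshold_mv = NA_real_, peak_mv = NA_real_,
               amplitude_mv = NA_real_, ahp_mv = NA_real_,
               half_width_ms = NA_real_)
  }
  structure(list(resting_potential_mv = vm$v_m_mv,
                 ap_threshold_mv = ap$threshold_mv,
                 ap_amplitude_mv = ap$amplitude_mv,
                 ahp_value_mv = ap$ahp_mv,
                 half_amplitude_width_ms = ap$half_width_ms,
                 rheobase_pa = rheo$rheobase_pa,
                 rheobase_defined = rheo$defined,
                 input_resistance_mohm = rin$input_resistance_mohm,
                 fit_r2 = rin$r_squared,
                 fi_curve = fi),
            class = "intrinsic_profile")
}
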