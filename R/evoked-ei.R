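# Evoked excitation/inhibition analysis: per-pulse amplitudes of paired
# eEPSC (-80 mV, inward) / eIPSC (0 mV, outward) trains, normalized
# depression time courses, and E/I ratios for single pulses and for the
# last 10 responses of a 40 Hz train.

# Per-pulse amplitudes of one positive-going train.
measure_train <- function(y, pulse_times, fs, pulse_offset_ms,
                          correct_tails, tail_fit_ms = 5) {
  n <- length(y)
  n_pulses <- length(pulse_times)
  isi <- if (n_pulses > 1L) diff(pulse_times)[1] else 25
  amps <- numeric(n_pulses)
  for (k in seq_len(n_pulses)) {
    t0 <- pulse_times[k] + pulse_offset_ms
    t1 <- if (k < n_pulses) pulse_times[k + 1L] else pulse_times[k] + isi
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(floor(t1 * fs), n)
    if (i0 >= i1) stop("empty pulse window", call. = FALSE)
    seg <- y[i0:i1]
    ipk <- which.max(seg)
    qp <- quadratic_peak(seg, ipk)
    t_pk <- ((i0 - 1L + qp$index) - 1) / fs
    if (k == 1L || !correct_tails) {
      j1 <- floor(pulse_times[k] * fs)
      j0 <- max(1L, j1 - round(1 * fs))
      base <- mean(y[j0:j1])
    } else {
      # extrapolate the previous pulse's monoexponential tail to the peak
      j1 <- floor(pulse_times[k] * fs)
      j0 <- max(1L, j1 - round(tail_fit_ms * fs))
      ys <- y[j0:j1]
      tt <- ((j0:j1) - 1) / fs
      base <- if (all(ys > 0)) {
        lf <- lm(log(ys) ~ tt)
        b <- unname(coef(lf)[2])
        # decaying tails only; anything else falls back to a flat baseline
        if (!is.finite(b) || b >= 0) mean(ys)
        else exp(unname(coef(lf)[1]) + b * t_pk)
      } else mean(ys)
    }
    amps[k] <- qp$value - base
  }
  amps
}

#' Measure per-pulse amplitudes of a paired evoked train
#'
#' Each pulse's amplitude is the peak within its window
#' (`[pulse + pulse_offset_ms, next pulse)`, parabolic sub-sample peak
#' refinement) minus a local baseline. For trains at >= 20 Hz the decaying
#' tail of the preceding pulse overlaps the window, so the baseline is the
#' preceding tail's monoexponential extrapolation to the peak time
#' (toggleable via `correct_tails`); otherwise it is the mean of the 1 ms
#' preceding the pulse.
#'
#' @param pair an `evoked_pair` from [synthesize_evoked_trains()]
#' @param pulse_offset_ms start of the pulse search window after the
#'   stimulus, ms
#' @param correct_tails logical; default `NULL` enables the correction for
#'   trains at >= 20 Hz
#' @return list of class `evoked_amplitudes`: `e_amplitudes_pa`,
#'   `i_amplitudes_pa` (magnitudes), `pulse_times_ms`
#' @export
measure_evoked_amplitudes <- function(pair, pulse_offset_ms = 1,
                                      correct_tails = NULL) {
  stopifnot(inherits(pair, "evoked_pair"))
  if (is.null(correct_tails)) correct_tails <- pair$frequency_hz >= 20
  fs <- pair$sampling_rate_khz
  e <- measure_train(-pair$e_trace, pair$pulse_times_ms, fs,
                     pulse_offset_ms, correct_tails)
  i <- measure_train(pair$i_trace, pair$pulse_times_ms, fs,
                     pulse_offset_ms, correct_tails)
  structure(list(e_amplitudes_pa = e, i_amplitudes_pa = i,
                 pulse_times_ms = pair$pulse_times_ms),
            class = "evoked_amplitudes")
}

#' Normalize a train of amplitudes to its first pulse
#'
#' @param amplitudes per-pulse amplitudes, pA
#' @return per-pulse fractions of the first pulse; element 1 is exactly 1
#' @export
normalize_train <- function(amplitudes) {
  if (!length(amplitudes)) stop("empty amplitude train", call. = FALSE)
  if (amplitudes[1] <= 0)
    stop("first-pulse amplitude must be > 0", call. = FALSE)
  out <- amplitudes / amplitudes[1]
  out[1] <- 1
  out
}

#' Excitation/inhibition ratio of a paired evoked train
#'
#' `single` mode: ratio of the first-pulse excitatory and inhibitory
#' amplitudes. `last10` mode: ratio of the mean amplitudes over the final
#' 10 pulses. Both are scale-invariant.
#'
#' @param pair an `evoked_pair`, or an `evoked_amplitudes` result
#' @param mode `"single"` or `"last10"`
#' @param ... passed to [measure_evoked_amplitudes()] when `pair` is an
#'   `evoked_pair`
#' @return object of class `ei_ratio_result`: `single_pulse_ratio`,
#'   `last10_ratio` (NA when not requested/available), `normalized_e_train`,
#'   `normalized_i_train`, `defined`
#' @export
ei_ratio <- function(pair, mode = c("single", "last10"), ...) {
  mode <- match.arg(mode)
  meas <- if (inherits(pair, "evoked_amplitudes")) pair
          else measure_evoked_amplitudes(pair, ...)
  e <- meas$e_amplitudes_pa
  i <- meas$i_amplitudes_pa
  n <- length(e)
  if (mode == "last10" && n < 10L)
    stop("'last10' mode needs a train of >= 10 pulses", call. = FALSE)
  single <- if (i[1] > 0) e[1] / i[1] else NA_real_
  last10 <- if (n >= 10L) {
    di <- mean(tail(i, 10L))
    if (di > 0) mean(tail(e, 10L)) / di else NA_real_
  } else NA_real_
  defined <- if (mode == "single") is.finite(single) else is.finite(last10)
  if (!defined)
    warning("inhibitory denominator is zero; E/I ratio undefined",
            call. = FALSE)
  structure(list(single_pulse_ratio = single,
                 last10_ratio = last10,
                 normalized_e_train = normalize_train(e),
                 normalized_i_train = normalize_train(i),
                 mode = mode, defined = defined),
            class = "ei_ratio_result")
}
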