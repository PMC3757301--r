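# Miniature-EPSC analysis: automated event detection (smoothed-trace local
# maxima with a partial-repolarization rule for multipeak events),
# amplitude / inter-event-interval statistics and cumulative distributions,
# 50%-rise-aligned averaging, and rise/decay kinetics of the average.

#' Detect miniature synaptic events on a voltage-clamp current trace
#'
#' The trace (inward events by default, i.e. negative deflections) is
#' median-centred, sign-flipped to positive-going, and smoothed with a
#' short moving average. Local maxima become candidate peaks; a candidate
#' is a separate event only if the signal between it and the preceding
#' accepted peak repolarizes by at least `repolarization_fraction` of the
#' preceding event's amplitude, which resolves multipeak events without
#' double counting single bumpy ones. Each event's amplitude is measured
#' from a local baseline, the median of the `baseline_ms` preceding its
#' onset; events below `min_amplitude` are dropped. Events whose
#' inter-event valley stays well above the global baseline are flagged
#' `"overlapping"`, the rest `"clean"`.
#'
#' @param trace a `mini_trace` from [synthesize_mini_trace()], or a numeric
#'   current trace in pA (then `sampling_rate_khz` is required)
#' @param min_amplitude detection threshold, pA (default 8)
#' @param sampling_rate_khz sampling rate when `trace` is a bare vector
#' @param polarity -1 for inward (negative) events, +1 for outward
#' @param smooth_ms moving-average width, ms
#' @param baseline_ms local-baseline window before onset, ms
#' @param repolarization_fraction partial-repolarization fraction that
#'   splits two peaks into separate events (default 0.25)
#' @return data.frame of class `mini_events`: `onset_ms`, `peak_ms`,
#'   `amplitude_pa` (baseline-to-peak magnitude), `baseline_pa`, `flag`
#' @export
detect_events <- function(trace, min_amplitude = 8,
                          sampling_rate_khz = NULL, polarity = -1,
                          smooth_ms = 0.25, baseline_ms = 5,
                          repolarization_fraction = 0.25) {
  if (inherits(trace, "mini_trace")) {
    y <- trace$current_pa
    fs <- trace$sampling_rate_khz
  } else {
    y <- as.numeric(trace)
    fs <- sampling_rate_khz
    if (is.null(fs)) stop("'sampling_rate_khz' is required", call. = FALSE)
  }
  check_positive(min_amplitude, "min_amplitude")
  y <- polarity * (y - median(y))  # polarity -1: inward deflections now positive
  w <- max(3L, round(smooth_ms * fs))
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- 0
  n <- length(s)
  nb <- max(1L, round(baseline_ms * fs))
  # candidate local maxima above a coarse floor
  cand <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  cand <- cand[s[cand] >= min_amplitude * 0.5]
  events <- list()
  prev <- NULL  # list(peak_idx, peak_val, amplitude, valley_ok_val)
  for (i in cand) {
    if (!is.null(prev)) {
      valley <- min(s[prev$peak_idx:i])
      if ((prev$peak_val - valley) <
          repolarization_fraction * prev$amplitude) {
        # same event: keep the taller peak
        if (s[i] > prev$peak_val) {
          prev$peak_idx <- i
          prev$peak_val <- s[i]
          prev$amplitude <- s[i] - prev$baseline
          events[[length(events)]] <- prev
        }
        next
      }
      # repolarized, but a separate event must also rise clear of the
      # valley; small bumps riding a decay are noise, not events
      if ((s[i] - valley) < min_amplitude) next
    }
    # onset: walk back to the preceding smoothed-signal valley
    j <- i
    while (j > 1L && s[j - 1L] < s[j]) j <- j - 1L
    onset <- j
    base_lo <- max(1L, onset - nb)
    baseline <- median(y[base_lo:onset])
    amp <- s[i] - baseline
    if (amp < min_amplitude) { next }
    valley_before <- s[onset]
    ev <- list(peak_idx = i, peak_val = s[i], amplitude = amp,
               onset_idx = onset, baseline = baseline,
               valley_before = valley_before)
    events[[length(events) + 1L]] <- ev
    prev <- ev
  }
  if (!length(events)) {
    out <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      amplitude_pa = numeric(0), baseline_pa = numeric(0),
                      flag = character(0))
    class(out) <- c("mini_events", "data.frame")
    attr(out, "sampling_rate_khz") <- fs
    return(out)
  }
  onset_ms <- vapply(events, function(e)
    index_to_ms(e$onset_idx, fs), numeric(1))
  peak_ms <- vapply(events, function(e)
    index_to_ms(e$peak_idx, fs), numeric(1))
  amp <- vapply(events, function(e) e$amplitude, numeric(1))
  base <- vapply(events, function(e) e$baseline, numeric(1))
  valley <- vapply(events, function(e) e$valley_before, numeric(1))
  # overlap flag: the pre-onset valley never returned near global baseline,
  # or the next event rides on this one's decay
  elevated <- valley > 0.2 * amp
  flag <- rep("clean", length(events))
  flag[elevated] <- "overlapping"
  if (length(events) > 1L) {
    before <- setdiff(which(elevated) - 1L, 0L)
    flag[before] <- "overlapping"
  }
  out <- data.frame(onset_ms = onset_ms, peak_ms = peak_ms,
                    amplitude_pa = amp, baseline_pa = base, flag = flag)
  class(out) <- c("mini_events", "data.frame")
  attr(out, "sampling_rate_khz") <- fs
  out
}

#' Event statistics and cumulative distributions
#'
#' @param events a `mini_events` data.frame (or ground-truth table with
#'   `amplitude_pa` and one of `peak_ms`/`onset_ms`)
#' @param duration_s recording duration, s (> 0)
#' @return list of class `mini_stats`: `frequency_hz` (count/duration),
#'   `amplitudes_pa`, `iei_ms` (inter-event intervals),
#'   `inst_freq_hz` (reciprocal intervals), and empirical cumulative
#'   distributions `amplitude_ecdf`, `iei_ecdf` as sorted value/fraction
#'   tables ending at 1
#' @export
event_statistics <- function(events, duration_s) {
  check_positive(duration_s, "duration_s")
  n <- nrow(events)
  times <- if ("peak_ms" %in% names(events)) events$peak_ms else events$onset_ms
  ecdf_table <- function(x) {
    if (!length(x)) return(data.frame(value = numeric(0),
                                      fraction = numeric(0)))
    xs <- sort(x)
    data.frame(value = xs, fraction = seq_along(xs) / length(xs))
  }
  iei <- if (n >= 2L) diff(sort(times)) else numeric(0)
  structure(list(
    frequency_hz = n / duration_s,
    amplitudes_pa = events$amplitude_pa,
    iei_ms = iei,
    inst_freq_hz = if (length(iei)) 1000 / iei else numeric(0),
    amplitude_ecdf = ecdf_table(events$amplitude_pa),
    iei_ecdf = ecdf_table(iei)),
    class = "mini_stats")
}

#' Average events aligned at the 50%-rise point
#'
#' Selects 40--60 clean (non-overlapping) events, extracts a snippet around
#' each, shifts it so the 50%-of-peak rising crossing sits at a common
#' reference sample, and returns the pointwise mean.
#'
#' @param trace the `mini_trace` (or numeric trace, pA) the events came from
#' @param events a `mini_events` data.frame from [detect_events()]
#' @param n_events maximum number of events to average (40--60 typical)
#' @param pre_ms,post_ms snippet extent around the alignment point, ms
#' @param sampling_rate_khz required when `trace` is a bare vector
#' @return list of class `avg_event`: `current_pa` (mean waveform, original
#'   polarity), `sampling_rate_khz`, `align_index`, `n_events`
#' @export
average_aligned_events <- function(trace, events, n_events = 60,
                                   pre_ms = 5, post_ms = 30,
                                   sampling_rate_khz = NULL) {
  if (inherits(trace, "mini_trace")) {
    y <- trace$current_pa
    fs <- trace$sampling_rate_khz
  } else {
    y <- as.numeric(trace)
    fs <- sampling_rate_khz
    if (is.null(fs)) stop("'sampling_rate_khz' is required", call. = FALSE)
  }
  # events suitable for kinetics: non-overlapping AND temporally isolated,
  # so the snippet holds one clear rise and one clear decay
  iso <- rep(TRUE, nrow(events))
  if (nrow(events) > 1L) {
    gap_prev <- c(Inf, events$onset_ms[-1L] - events$peak_ms[-nrow(events)])
    gap_next <- c(events$onset_ms[-1L] - events$peak_ms[-nrow(events)], Inf)
    iso <- gap_prev >= pre_ms & gap_next >= post_ms
  }
  clean <- events[events$flag == "clean" & iso, , drop = FALSE]
  if (nrow(clean) < 40L)
    stop(sprintf(paste0("only %d clean events available; at least 40 are ",
                        "needed - record a longer trace"), nrow(clean)),
         call. = FALSE)
  clean <- clean[seq_len(min(n_events, nrow(clean))), , drop = FALSE]
  yy <- -(y - median(y))  # positive-going
  n <- length(yy)
  npre <- round(pre_ms * fs); npost <- round(post_ms * fs)
  snips <- matrix(NA_real_, nrow = nrow(clean), ncol = npre + npost + 1L)
  kept <- 0L
  for (e in seq_len(nrow(clean))) {
    i_on <- ms_to_index(clean$onset_ms[e], fs)
    i_pk <- ms_to_index(clean$peak_ms[e], fs)
    level <- clean$baseline_pa[e] + 0.5 * clean$amplitude_pa[e]
    c50 <- first_crossing(yy, level, i_on:max(i_on, i_pk - 1L), "up")
    if (is.na(c50)) c50 <- i_pk
    i50 <- round(c50)
    if (i50 - npre < 1L || i50 + npost > n) next
    kept <- kept + 1L
    snips[kept, ] <- yy[(i50 - npre):(i50 + npost)]
  }
  if (kept < 40L)
    stop("fewer than 40 events with complete snippets", call. = FALSE)
  avg <- colMeans(snips[seq_len(kept), , drop = FALSE])
  structure(list(current_pa = -avg, sampling_rate_khz = fs,
                 align_index = npre + 1L, n_events = kept),
            class = "avg_event")
}

#' Rise and decay kinetics of an averaged event
#'
#' The 10--90% rise time is the time between the 10% and 90%-of-peak
#' crossings on the rising limb (linear interpolation between samples; the
#' peak is refined by a parabolic fit through the discrete maximum). The
#' decay constant comes from a monoexponential fit restricted to the
#' 90%-to-10% falling segment. The default fitter regresses the
#' log-magnitude on time, which weights the whole segment evenly;
#' `method = "nls"` refines it by nonlinear least squares in linear space.
#'
#' @param avg an `avg_event` from [average_aligned_events()], or a numeric
#'   waveform (pA, inward-negative) with `sampling_rate_khz` supplied
#' @param method `"loglinear"` (default) or `"nls"`
#' @param sampling_rate_khz required when `avg` is a bare vector
#' @return object of class `mini_kinetics`: `rise_time_10_90_ms`,
#'   `decay_tau_ms`, `n_events_averaged`, `fit_r2` (coefficient of
#'   determination of the decay fit in linear space)
#' @export
fit_kinetics <- function(avg, method = c("loglinear", "nls"),
                         sampling_rate_khz = NULL) {
  method <- match.arg(method)
  if (inherits(avg, "avg_event")) {
    w <- avg$current_pa
    fs <- avg$sampling_rate_khz
    n_ev <- avg$n_events
  } else {
    w <- as.numeric(avg)
    fs <- sampling_rate_khz
    if (is.null(fs)) stop("'sampling_rate_khz' is required", call. = FALSE)
    n_ev <- NA_integer_
  }
  y <- -w  # positive-going magnitude
  n <- length(y)
  i_pk <- which.max(y)
  if (i_pk <= 2L || i_pk >= n - 2L)
    stop("waveform peak lies at the trace edge", call. = FALSE)
  qp <- quadratic_peak(y, i_pk)
  a_pk <- qp$value
  # rising limb crossings
  c10 <- first_crossing(y, 0.1 * a_pk, 1:(i_pk - 1L), "up")
  c90 <- first_crossing(y, 0.9 * a_pk, 1:(i_pk - 1L), "up")
  if (is.na(c10) || is.na(c90))
    stop("rising limb does not span 10-90% of the peak", call. = FALSE)
  rise_ms <- (c90 - c10) / fs
  # decay segment: 90% down to 10% of peak
  d90 <- first_crossing(y, 0.9 * a_pk, i_pk:(n - 1L), "down")
  d10 <- first_crossing(y, 0.1 * a_pk, i_pk:(n - 1L), "down")
  if (is.na(d90) || is.na(d10))
    stop("decay does not reach 10% of the peak within the waveform",
         call. = FALSE)
  seg <- ceiling(d90):floor(d10)
  t_ms <- (seg - 1) / fs
  ys <- y[seg]
  pos <- ys > 0
  lf <- lm(log(ys[pos]) ~ t_ms[pos])
  tau <- -1 / unname(coef(lf)[2])
  amp0 <- exp(unname(coef(lf)[1]))
  if (method == "nls") {
    fit <- minpack.lm::nlsLM(ys ~ a * exp(-t_ms / tt),
                             start = list(a = amp0, tt = tau))
    tau <- unname(coef(fit)["tt"])
    pred <- fitted(fit)
  } else {
    pred <- amp0 * exp(-t_ms / tau)
  }
  r2 <- 1 - sum((ys - pred)^2) / sum((ys - mean(ys))^2)
  structure(list(rise_time_10_90_ms = rise_ms, decay_tau_ms = tau,
                 n_events_averaged = n_ev, fit_r2 = r2),
            class = "mini_kinetics")
}
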