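# MEA field-response metrics: per-pixel peak amplitudes averaged over
# stimuli, representative-pixel region summaries, area-mean amplitude at
# the frame of highest response, input-output curves, granule-to-hilus
# propagation time, and train depression ratios.

# Post-stimulus analysis window [start, end] in sample indices for pulse k.
stim_window <- function(rec, k, blanking_ms, max_window_ms = 100) {
  fs <- rec$sampling_rate_khz
  st <- rec$stimulus_times_ms
  t0 <- st[k] + blanking_ms
  t1 <- if (k < length(st)) st[k + 1L] else st[k] + max_window_ms
  t1 <- min(t1, st[k] + max_window_ms)
  i0 <- floor(t0 * fs) + 1L
  i1 <- floor(t1 * fs)
  if (i1 > ncol(rec$data))
    stop("analysis window extends past the end of the recording",
         call. = FALSE)
  c(i0, i1)
}

region_of_pixel <- function(rec) {
  out <- rep(NA_character_, prod(rec$grid_shape))
  for (lab in names(rec$region_index)) out[rec$region_index[[lab]]] <- lab
  out
}

#' Extract evoked field-response metrics from an MEA recording
#'
#' For each stimulus and pixel the amplitude is the maximum absolute
#' deflection in the post-blanking window, sign-resolved by the pixel's
#' region polarity (minimum for sinks, maximum for sources); amplitudes
#' are averaged over the first `n_events_avg` stimuli and, when a control
#' response is supplied, normalized to it. Region summaries use the 3
#' highest-amplitude pixels per region (or explicit coordinates); the
#' region peak latency is the quadratic-interpolated peak time of the top
#' representative pixel relative to the stimulus.
#'
#' @param rec an `mea_recording`
#' @param blanking_ms artifact blanking window after each stimulus, ms
#'   (default 2; must cover the artifact)
#' @param n_events_avg number of stimuli to average (default 10, capped at
#'   the number available)
#' @param control optional `field_response` used for normalization
#' @param representative_pixels either an integer (pixels per region,
#'   default 3) or a named list of (row, col) coordinate matrices
#' @return object of class `field_response`: `per_pixel_amplitude_uv`,
#'   `region_amplitude_uv` (representative-pixel mean), `area_mean_uv`,
#'   `peak_latency_ms`, `representative_index`, `normalized`,
#'   `n_events_avg`
#' @export
extract_field_response <- function(rec, blanking_ms = 2, n_events_avg = 10,
                                   control = NULL,
                                   representative_pixels = 3L) {
  stopifnot(inherits(rec, "mea_recording"))
  if (blanking_ms < rec$params$artifact_duration)
    stop("'blanking_ms' must cover the stimulation artifact", call. = FALSE)
  fs <- rec$sampling_rate_khz
  n_stim <- length(rec$stimulus_times_ms)
  use <- seq_len(min(n_events_avg, n_stim))
  npix <- prod(rec$grid_shape)
  pol <- rep(0, npix)
  for (lab in names(rec$region_index))
    pol[rec$region_index[[lab]]] <- rec$params$region_polarity[[lab]]
  amp_sum <- numeric(npix)
  for (k in use) {
    wnd <- stim_window(rec, k, blanking_ms)
    sub <- rec$data[, wnd[1]:wnd[2], drop = FALSE]
    mx <- apply(sub, 1L, max)
    mn <- apply(sub, 1L, min)
    a <- ifelse(pol < 0, -mn, ifelse(pol > 0, mx, pmax(mx, -mn)))
    amp_sum <- amp_sum + a
  }
  per_pixel <- amp_sum / length(use)
  labs <- names(rec$region_index)
  rep_idx <- list(); region_amp <- numeric(0); latency <- numeric(0)
  for (lab in labs) {
    idx <- rec$region_index[[lab]]
    if (is.list(representative_pixels)) {
      coords <- representative_pixels[[lab]]
      sel <- pixel_index(coords, rec$grid_shape)
      if (!all(sel %in% idx))
        stop(sprintf("representative pixel outside the '%s' mask", lab),
             call. = FALSE)
    } else {
      k3 <- min(as.integer(representative_pixels), length(idx))
      sel <- idx[order(per_pixel[idx], decreasing = TRUE)[seq_len(k3)]]
    }
    rep_idx[[lab]] <- sel
    region_amp[lab] <- mean(per_pixel[sel])
    # latency from the first stimulus on the top representative pixel
    wnd <- stim_window(rec, 1L, blanking_ms)
    tr <- rec$data[sel[1L], wnd[1]:wnd[2]]
    sgn <- if (pol[sel[1L]] < 0) -1 else 1
    yy <- sgn * tr
    ipk <- which.max(yy)
    qp <- quadratic_peak(yy, ipk)
    latency[lab] <- index_to_ms(wnd[1] - 1L + qp$index, fs) -
      rec$stimulus_times_ms[1L]
  }
  area <- vapply(labs, function(lab)
    area_mean_amplitude(rec, lab, stimulus = 1L,
                        blanking_ms = blanking_ms), numeric(1))
  names(area) <- labs
  normalized <- if (is.null(control)) {
    setNames(rep(1, length(labs)), labs)
  } else {
    region_amp / control$region_amplitude_uv[labs]
  }
  structure(list(per_pixel_amplitude_uv = per_pixel,
                 region_amplitude_uv = region_amp,
                 area_mean_uv = area,
                 peak_latency_ms = latency,
                 representative_index = rep_idx,
                 normalized = normalized,
                 n_events_avg = length(use)),
            class = "field_response")
}

#' Area-mean amplitude at the frame of highest response
#'
#' The mean intensity over the region mask in the image taken at the point
#' of highest response: the frame where the mask-mean (polarity-resolved)
#' response peaks. Because the pixel intensities here are the recorded
#' voltages themselves, the conventional rescaling of the maximum image
#' intensity to the maximum voltage of the same response is the identity
#' and the mask mean is returned directly; `frame_halfwidth` frames on
#' each side of the peak are averaged to stabilise the image against
#' recording noise. A uniform map is a fixed point.
#'
#' @param rec an `mea_recording`
#' @param region region label
#' @param stimulus stimulus index defining the response window
#' @param blanking_ms artifact blanking, ms
#' @param frame_halfwidth frames averaged on each side of the peak frame
#' @return area-mean amplitude, uV (0 with a warning for an all-zero
#'   region)
#' @export
area_mean_amplitude <- function(rec, region, stimulus = 1L,
                                blanking_ms = 2, frame_halfwidth = 1L) {
  stopifnot(inherits(rec, "mea_recording"))
  idx <- rec$region_index[[region]]
  if (is.null(idx) || !length(idx))
    stop(sprintf("unknown or empty region '%s'", region), call. = FALSE)
  pol <- rec$params$region_polarity[[region]]
  wnd <- stim_window(rec, stimulus, blanking_ms)
  sub <- pol * rec$data[idx, wnd[1]:wnd[2], drop = FALSE]
  if (all(sub == 0)) {
    warning(sprintf("region '%s' shows no response", region), call. = FALSE)
    return(0)
  }
  f <- which.max(colMeans(sub))
  cols <- max(1L, f - frame_halfwidth):min(ncol(sub), f + frame_halfwidth)
  frame <- rowMeans(sub[, cols, drop = FALSE])
  mean(frame)
}

#' Input-output curve over stimulation intensities
#'
#' @param recs list of `mea_recording` objects, one per intensity (single
#'   stimulus each, intensity recorded in the object)
#' @param region region label
#' @param pixels integer number of representative pixels (default 3,
#'   chosen as the highest-amplitude pixels at the largest intensity and
#'   reused across intensities) or an explicit (row, col) matrix
#' @param blanking_ms artifact blanking, ms
#' @return data.frame with `intensity_ua`, `mean_uv`, `sem_uv`
#' @export
io_curve <- function(recs, region, pixels = 3L, blanking_ms = 2) {
  if (length(recs) < 2L)
    stop("need recordings at >= 2 intensities", call. = FALSE)
  intens <- vapply(recs, function(r) r$stimulus_intensities_ua[1L],
                   numeric(1))
  per_pix <- lapply(recs, function(r) {
    fr <- extract_field_response(r, blanking_ms = blanking_ms,
                                 n_events_avg = 1L)
    fr$per_pixel_amplitude_uv
  })
  idx <- recs[[1L]]$region_index[[region]]
  if (is.null(idx)) stop(sprintf("unknown region '%s'", region), call. = FALSE)
  if (is.matrix(pixels)) {
    sel <- pixel_index(pixels, recs[[1L]]$grid_shape)
    if (!all(sel %in% idx))
      stop("selected pixel outside the region mask", call. = FALSE)
  } else {
    top <- per_pix[[which.max(intens)]]
    k3 <- min(as.integer(pixels), length(idx))
    sel <- idx[order(top[idx], decreasing = TRUE)[seq_len(k3)]]
  }
  mean_uv <- vapply(per_pix, function(a) mean(a[sel]), numeric(1))
  sem_uv <- vapply(per_pix, function(a)
    stats::sd(a[sel]) / sqrt(length(sel)), numeric(1))
  out <- data.frame(intensity_ua = intens, mean_uv = mean_uv,
                    sem_uv = sem_uv)
  out[order(out$intensity_ua), ]
}

#' Propagation time between two regions' response peaks
#'
#' Latency of the target region minus latency of the source region, each
#' measured at its representative pixel. Antisymmetric in its arguments;
#' undefined (NA, flagged) when either region did not respond.
#'
#' @param resp a `field_response`
#' @param from,to region labels
#' @param min_amplitude noise floor, uV; a region below it counts as
#'   non-responding
#' @return list with `propagation_ms` and `defined`
#' @export
propagation_time <- function(resp, from, to, min_amplitude = 0) {
  stopifnot(inherits(resp, "field_response"))
  for (lab in c(from, to)) {
    if (!lab %in% names(resp$peak_latency_ms))
      stop(sprintf("unknown region '%s'", lab), call. = FALSE)
  }
  if (resp$region_amplitude_uv[from] <= min_amplitude ||
      resp$region_amplitude_uv[to] <= min_amplitude) {
    warning("one of the regions did not respond; propagation undefined",
            call. = FALSE)
    return(list(propagation_ms = NA_real_, defined = FALSE))
  }
  list(propagation_ms = unname(resp$peak_latency_ms[to] -
                                 resp$peak_latency_ms[from]),
       defined = TRUE)
}

#' Train depression ratio (last over first pulse)
#'
#' Ratio between the area-mean amplitudes of the last and the first evoked
#' response of a stimulus train over a region mask. Values below 1 indicate
#' depression.
#'
#' @param rec an `mea_recording` containing a stimulus train
#' @param region region label
#' @param blanking_ms artifact blanking, ms
#' @return list with `ratio`, `first_uv`, `last_uv`, `defined`
#' @export
train_depression_ratio <- function(rec, region, blanking_ms = 2) {
  stopifnot(inherits(rec, "mea_recording"))
  n_stim <- length(rec$stimulus_times_ms)
  if (n_stim < 2L) stop("train must contain >= 2 pulses", call. = FALSE)
  first_uv <- area_mean_amplitude(rec, region, stimulus = 1L,
                                  blanking_ms = blanking_ms)
  last_uv <- area_mean_amplitude(rec, region, stimulus = n_stim,
                                 blanking_ms = blanking_ms)
  if (first_uv == 0) {
    warning("first-pulse amplitude is zero; ratio undefined", call. = FALSE)
    return(list(ratio = NA_real_, first_uv = first_uv, last_uv = last_uv,
                defined = FALSE))
  }
  list(ratio = last_uv / first_uv, first_uv = first_uv, last_uv = last_uv,
       defined = TRUE)
}
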