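# Synthetic high-density MEA recordings: a 64 x 64 active-pixel grid sampled
# at 7.7 kHz, with evoked field-postsynaptic-potential (fPSP) templates
# inserted on two anatomical region masks. Polarity follows the sink/source
# convention: granule/molecular-layer responses are negative (current sink),
# hilar responses positive (current source). A saturating stimulation
# artifact is placed on all channels at each stimulus time.

#' Rectangular pixel mask
#'
#' @param rows,cols integer vectors of row and column indices (1-based)
#' @return 2-column matrix of (row, col) coordinates, row-major order
#' @export
rect_mask <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))[, c("row", "col"),
                                                 drop = FALSE]
}

# (row, col) coordinates -> linear pixel indices, row-major, 1-based
pixel_index <- function(coords, grid_shape) {
  (coords[, 1] - 1L) * grid_shape[2] + coords[, 2]
}

#' Parameters for synthetic MEA recordings
#'
#' `region_peak_amplitude` is the plateau fPSP amplitude delivered on each
#' mask pixel by a calibrated stimulus (scalar per region, or one value per
#' mask pixel for spatially non-uniform maps). When a stimulus carries an
#' intensity in microamps, the amplitude is additionally scaled by the
#' logistic input-output function
#' \eqn{L(I) = 1/(1+e^{-s(I - I_{50})/I_{50}})}, which equals 1/2 at the
#' half-maximum intensity `io_halfmax`.
#'
#' @param grid_shape integer (rows, cols); default 64 x 64
#' @param sampling_rate kHz; default 7.7
#' @param region_masks named list of 2-column (row, col) coordinate
#'   matrices; masks must be disjoint and lie within the grid
#' @param region_peak_amplitude named list/vector, uV
#' @param region_polarity named vector of +1 (source) / -1 (sink)
#' @param peak_latency named vector, ms from stimulus to response peak
#' @param fpsp_rise_tau,fpsp_decay_tau fPSP template kinetics, ms
#' @param io_halfmax half-maximum stimulation intensity, uA
#' @param io_slope dimensionless logistic steepness
#' @param last_over_first_ratio train depression: pulse k is scaled by a
#'   linear interpolation from 1 (first pulse) to this value (last pulse)
#' @param artifact_duration stimulation-artifact length, ms
#' @param artifact_amplitude artifact saturation level, uV
#' @param noise_sd recording noise, uV
#' @param baseline_ms pre-stimulus baseline, ms
#' @param tail_ms tail after the last response window, ms
#' @param seed integer seed
#' @return object of class `mea_gen_params`
#' @export
mea_gen_params <- function(grid_shape = c(64, 64), sampling_rate = 7.7,
                           region_masks = list(
                             granule = rect_mask(20:29, 16:47),
                             hilus = rect_mask(36:45, 16:47)),
                           region_peak_amplitude = c(granule = 153.7,
                                                     hilus = 143.0),
                           region_polarity = c(granule = -1, hilus = +1),
                           peak_latency = c(granule = 5.0, hilus = 7.8),
                           fpsp_rise_tau = 1.2, fpsp_decay_tau = 6,
                           io_halfmax = 300, io_slope = 4,
                           last_over_first_ratio = 1,
                           artifact_duration = 1, artifact_amplitude = 3000,
                           noise_sd = 0, baseline_ms = 50, tail_ms = 100,
                           seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  labels <- names(region_masks)
  if (is.null(labels) || any(labels == ""))
    stop("'region_masks' must be a named list", call. = FALSE)
  for (nm in c("region_peak_amplitude", "region_polarity", "peak_latency")) {
    v <- get(nm)
    if (!all(labels %in% names(v)))
      stop(sprintf("'%s' must be named for every region mask", nm),
           call. = FALSE)
  }
  idx <- lapply(region_masks, function(m) {
    if (any(m[, 1] < 1 | m[, 1] > grid_shape[1] |
            m[, 2] < 1 | m[, 2] > grid_shape[2]))
      stop("region mask outside the grid", call. = FALSE)
    pixel_index(m, grid_shape)
  })
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx))
    stop("region masks must be disjoint", call. = FALSE)
  if (last_over_first_ratio <= 0 || last_over_first_ratio > 1.5)
    stop("'last_over_first_ratio' must be in (0, 1.5]", call. = FALSE)
  check_positive(sampling_rate, "sampling_rate")
  if (fpsp_rise_tau >= fpsp_decay_tau)
    stop("'fpsp_rise_tau' must be < 'fpsp_decay_tau'", call. = FALSE)
  structure(list(
    grid_shape = grid_shape, sampling_rate = sampling_rate,
    region_masks = region_masks, region_index = idx,
    region_peak_amplitude = region_peak_amplitude,
    region_polarity = region_polarity, peak_latency = peak_latency,
    fpsp_rise_tau = fpsp_rise_tau, fpsp_decay_tau = fpsp_decay_tau,
    io_halfmax = io_halfmax, io_slope = io_slope,
    last_over_first_ratio = last_over_first_ratio,
    artifact_duration = artifact_duration,
    artifact_amplitude = artifact_amplitude,
    noise_sd = noise_sd, baseline_ms = baseline_ms, tail_ms = tail_ms,
    seed = seed), class = "mea_gen_params")
}

#' Single-shock stimulus specification
#'
#' @param intensities stimulation intensities, uA, one shock per entry;
#'   `NA` means a calibrated stimulus delivering the plateau amplitude
#'   (no input-output scaling)
#' @param interval_ms spacing between successive shocks
#' @return stimulus specification for [synthesize_mea_recording()]
#' @export
mea_single_stimuli <- function(intensities = NA_real_, interval_ms = 200) {
  structure(list(type = "single", intensities = intensities,
                 interval_ms = interval_ms), class = "mea_stimulus")
}

#' Stimulus-train specification
#'
#' @param frequency train frequency, Hz (default 20 Hz)
#' @param duration_s train duration, s (default 5 s)
#' @param intensity intensity, uA, or `NA` for a calibrated stimulus
#' @return stimulus specification for [synthesize_mea_recording()]
#' @export
mea_train_stimulus <- function(frequency = 20, duration_s = 5,
                               intensity = NA_real_) {
  structure(list(type = "train", frequency = frequency,
                 duration_s = duration_s, intensity = intensity),
            class = "mea_stimulus")
}

io_logistic <- function(intensity, halfmax, slope) {
  ifelse(is.na(intensity), 1,
         stats::plogis(slope * (intensity - halfmax) / halfmax))
}

#' Synthesize an evoked MEA recording with ground truth
#'
#' Each stimulus inserts, on every region-mask pixel, the fPSP template with
#' the region's polarity and peak latency, scaled by the plateau amplitude,
#' the logistic input-output factor of the stimulus intensity, and (for
#' trains) the linear first-to-last depression factor. A saturating artifact
#' covers all channels for `artifact_duration` after each stimulus.
#'
#' @param p an [mea_gen_params()]
#' @param stimulus an [mea_single_stimuli()] or [mea_train_stimulus()]
#' @return object of class `mea_recording`: list with `data` (pixels x time
#'   matrix, uV; rows in row-major (row, col) order), `grid_shape`,
#'   `sampling_rate_khz`, `stimulus_times_ms`, `stimulus_intensities_ua`,
#'   `region_masks`, `region_index`, `params`, and `truth` (per-region
#'   per-pulse signed amplitudes and peak latencies)
#' @export
synthesize_mea_recording <- function(p, stimulus = mea_single_stimuli()) {
  stopifnot(inherits(p, "mea_gen_params"), inherits(stimulus, "mea_stimulus"))
  fs <- p$sampling_rate
  if (stimulus$type == "single") {
    n_stim <- length(stimulus$intensities)
    stim_times <- p$baseline_ms + (seq_len(n_stim) - 1) * stimulus$interval_ms
    intensities <- stimulus$intensities
    pulse_scale <- rep(1, n_stim)
  } else {
    isi <- 1000 / stimulus$frequency
    n_stim <- round(stimulus$duration_s * stimulus$frequency)
    stim_times <- p$baseline_ms + (seq_len(n_stim) - 1) * isi
    intensities <- rep(stimulus$intensity, n_stim)
    r <- p$last_over_first_ratio
    pulse_scale <- if (n_stim == 1L) 1 else
      1 + (seq_len(n_stim) - 1) / (n_stim - 1) * (r - 1)
  }
  tpk <- template_peak_time(p$fpsp_rise_tau, p$fpsp_decay_tau)
  onset_gap <- min(p$peak_latency[names(p$region_masks)]) - tpk
  if (onset_gap < p$artifact_duration)
    stop(sprintf(paste0("artifact window (%.2f ms) overlaps the earliest ",
                        "response onset (%.2f ms after stimulus)"),
                 p$artifact_duration, onset_gap), call. = FALSE)
  win_ms <- max(p$peak_latency[names(p$region_masks)]) +
    8 * p$fpsp_decay_tau
  total_ms <- stim_times[n_stim] + win_ms + p$tail_ms
  n_t <- round(total_ms * fs)
  npix <- prod(p$grid_shape)
  data <- matrix(0, nrow = npix, ncol = n_t)
  if (p$noise_sd > 0) {
    data[] <- with_local_seed(p$seed, rnorm(npix * n_t, 0, p$noise_sd))
  }
  t_ms <- (seq_len(n_t) - 1) / fs
  io <- io_logistic(intensities, p$io_halfmax, p$io_slope)
  truth_amp <- list()
  for (lab in names(p$region_masks)) {
    idx <- p$region_index[[lab]]
    base_amp <- p$region_peak_amplitude[[lab]]
    if (length(base_amp) == 1L) base_amp <- rep(base_amp, length(idx))
    pol <- p$region_polarity[[lab]]
    lat <- p$peak_latency[[lab]]
    win <- round((lat + 8 * p$fpsp_decay_tau) * fs)
    amp_mat <- matrix(NA_real_, nrow = length(idx), ncol = n_stim)
    for (k in seq_len(n_stim)) {
      i0 <- floor(stim_times[k] * fs) + 1L
      m <- min(win, n_t - i0 + 1L)
      cols <- i0:(i0 + m - 1L)
      tmpl <- fpsp_template(t_ms[cols], stim_times[k], lat,
                            p$fpsp_rise_tau, p$fpsp_decay_tau)
      amps <- pol * base_amp * io[k] * pulse_scale[k]
      data[idx, cols] <- data[idx, cols] + outer(amps, tmpl)
      amp_mat[, k] <- amps
    }
    truth_amp[[lab]] <- amp_mat
  }
  n_art <- max(1L, round(p$artifact_duration * fs))
  for (k in seq_len(n_stim)) {
    i0 <- floor(stim_times[k] * fs) + 1L
    cols <- i0:min(i0 + n_art - 1L, n_t)
    data[, cols] <- p$artifact_amplitude
  }
  structure(list(
    data = data, grid_shape = p$grid_shape, sampling_rate_khz = fs,
    stimulus_times_ms = stim_times, stimulus_intensities_ua = intensities,
    region_masks = p$region_masks, region_index = p$region_index,
    params = p,
    truth = list(amplitudes_uv = truth_amp,
                 pulse_scale = pulse_scale,
                 io_scale = io,
                 peak_latency_ms = p$peak_latency)),
    class = "mea_recording")
}
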