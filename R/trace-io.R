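# Shared trace container and tabular export. The container is a validated,
# versioned R-native serialization (one file, lossless for arrays and
# metadata); CSV/JSON exports carry the pipeline's tabular results.

#' Build a trace container
#'
#' A container holds an ordered set of sweeps on a common sampling rate.
#' Each sweep is a list with `data` (numeric vector, or channels x samples
#' matrix), a per-channel `unit` string (`"mV"`, `"pA"` or `"uV"`), and
#' optional metadata: `clamp_mode`, `holding_mv`, `injected_current_pa`,
#' `stimulus_times_ms`. Sample 0 is t = 0 ms; the time axis is implicit in
#' the sampling rate.
#'
#' @param sweeps list of sweep lists (see Details)
#' @param sampling_rate_khz shared sampling rate, kHz
#' @param provenance free-form named list of attributes
#' @return object of class `trace_container`
#' @export
trace_container <- function(sweeps, sampling_rate_khz, provenance = list()) {
  x <- structure(list(sweeps = sweeps,
                      sampling_rate_khz = sampling_rate_khz,
                      provenance = provenance),
                 class = "trace_container")
  validate_trace_container(x)
}

validate_trace_container <- function(x) {
  if (is.null(x$sampling_rate_khz) || !is.finite(x$sampling_rate_khz) ||
      x$sampling_rate_khz <= 0)
    stop("trace container is missing a valid 'sampling_rate' (kHz)",
         call. = FALSE)
  if (!length(x$sweeps)) stop("trace container has no sweeps", call. = FALSE)
  for (i in seq_along(x$sweeps)) {
    sw <- x$sweeps[[i]]
    if (is.null(sw$data) || !is.numeric(sw$data))
      stop(sprintf("sweep %d is missing numeric 'data'", i), call. = FALSE)
    nch <- if (is.matrix(sw$data)) nrow(sw$data) else 1L
    if (is.null(sw$unit))
      stop(sprintf("sweep %d is missing 'units'", i), call. = FALSE)
    if (!length(sw$unit) %in% c(1L, nch))
      stop(sprintf("sweep %d: 'units' must be per-channel", i), call. = FALSE)
  }
  x
}

#' Write / read a trace container
#'
#' `read_container(write_container(x, path))` reproduces `x` exactly
#' (bit-identical arrays, metadata and sweep ordering). Files are validated
#' on read; a file lacking the sampling rate or per-channel units fails
#' with the offending field named.
#'
#' @param container a [trace_container()]
#' @param path file path
#' @return `write_container` returns `path` invisibly; `read_container`
#'   returns the container
#' @export
write_container <- function(container, path) {
  validate_trace_container(container)
  payload <- list(format = "dgephys-trace-container", version = 1L,
                  sampling_rate_khz = container$sampling_rate_khz,
                  sweeps = container$sweeps,
                  provenance = container$provenance)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "dgephys-trace-container"))
    stop("not a dgephys trace container", call. = FALSE)
  if (is.null(payload$sampling_rate_khz))
    stop("container file is missing 'sampling_rate'", call. = FALSE)
  trace_container(payload$sweeps, payload$sampling_rate_khz,
                  payload$provenance)
}

#' Convert pipeline objects to a trace container
#' @param x a `cclamp_sweeps`, `mini_trace` or `evoked_pair` object
#' @param ... unused
#' @return a [trace_container()]
#' @export
as_trace_container <- function(x, ...) UseMethod("as_trace_container")

#' @export
as_trace_container.cclamp_sweeps <- function(x, ...) {
  sweeps <- lapply(seq_along(x$sweeps), function(i) {
    list(data = x$sweeps[[i]], unit = "mV", clamp_mode = "current",
         injected_current_pa = x$currents_pa[i])
  })
  trace_container(sweeps, x$sampling_rate_khz,
                  provenance = list(source = "simulate_current_clamp"))
}

#' @export
as_trace_container.mini_trace <- function(x, ...) {
  trace_container(list(list(data = x$current_pa, unit = "pA",
                            clamp_mode = "voltage", holding_mv = -70)),
                  x$sampling_rate_khz,
                  provenance = list(source = "synthesize_mini_trace"))
}

#' @export
as_trace_container.evoked_pair <- function(x, ...) {
  trace_container(list(
    list(data = x$e_trace, unit = "pA", clamp_mode = "voltage",
         holding_mv = -80, stimulus_times_ms = x$pulse_times_ms),
    list(data = x$i_trace, unit = "pA", clamp_mode = "voltage",
         holding_mv = 0, stimulus_times_ms = x$pulse_times_ms)),
    x$sampling_rate_khz,
    provenance = list(source = "synthesize_evoked_trains"))
}

#' Export a pipeline result to CSV or JSON
#'
#' Registered result types: `intrinsic_profile` (one-row CSV / JSON),
#' `mini_events` (one row per event; header-only CSV when empty),
#' `mini_kinetics`, `field_response` (region summary), `ei_ratio_result`,
#' `group_comparison` and `ks_result`. Floats are written with 6
#' significant digits; column sets are stable across versions.
#'
#' @param results a registered result object
#' @param path output file path
#' @param format `"csv"` or `"json"`
#' @return `path`, invisibly
#' @export
export_table <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as_export_df(results)
  if (format == "csv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = 6, dataframe = "rows",
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

as_export_df <- function(x) UseMethod("as_export_df")

#' @export
as_export_df.default <- function(x) {
  stop(sprintf("no export registered for class '%s'", class(x)[1]),
       call. = FALSE)
}

#' @export
as_export_df.intrinsic_profile <- function(x) {
  data.frame(resting_potential_mv = x$resting_potential_mv,
             ap_threshold_mv = x$ap_threshold_mv,
             ap_amplitude_mv = x$ap_amplitude_mv,
             ahp_value_mv = x$ahp_value_mv,
             half_amplitude_width_ms = x$half_amplitude_width_ms,
             rheobase_pa = x$rheobase_pa,
             input_resistance_mohm = x$input_resistance_mohm,
             fit_r2 = x$fit_r2)
}

#' @export
as_export_df.mini_events <- function(x) {
  data.frame(onset_ms = x$onset_ms, peak_ms = x$peak_ms,
             amplitude_pa = x$amplitude_pa, flag = x$flag)
}

#' @export
as_export_df.mini_kinetics <- function(x) {
  data.frame(rise_time_10_90_ms = x$rise_time_10_90_ms,
             decay_tau_ms = x$decay_tau_ms,
             n_events_averaged = x$n_events_averaged,
             fit_r2 = x$fit_r2)
}

#' @export
as_export_df.ks_result <- function(x) {
  data.frame(statistic = x$statistic, p_value = x$p_value,
             n_x = x$n_x, n_y = x$n_y)
}

#' @export
as_export_df.ei_ratio_result <- function(x) {
  data.frame(single_pulse_ratio = x$single_pulse_ratio,
             last10_ratio = x$last10_ratio)
}

#' @export
as_export_df.field_response <- function(x) {
  data.frame(region = names(x$region_amplitude_uv),
             region_amplitude_uv = unname(x$region_amplitude_uv),
             area_mean_uv = unname(x$area_mean_uv[names(x$region_amplitude_uv)]),
             peak_latency_ms = unname(x$peak_latency_ms[names(x$region_amplitude_uv)]),
             normalized = unname(x$normalized[names(x$region_amplitude_uv)]))
}

#' @export
as_export_df.group_comparison <- function(x) {
  data.frame(group = x$summary$group, mean = x$summary$mean,
             sem = x$summary$sem, n = x$summary$n,
             test = x$test, statistic = x$statistic, p_value = x$p_value)
}
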