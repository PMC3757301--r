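# Shared fixtures and independent oracles, built in code at test time.

# Trace with events at fixed onsets (regular spacing by default) -- the
# deterministic layout used for averaging/kinetics checks.
make_regular_mini_trace <- function(n_events = 50, amplitude = 30,
                                    spacing_ms = 100, noise_sd = 0,
                                    rise_time = 0.83, decay_tau = 4.39,
                                    seed = NULL) {
  onsets <- 50 + (seq_len(n_events) - 1) * spacing_ms
  dur_s <- (max(onsets) + 100) / 1000
  p <- mini_gen_params(event_rate = 0, amplitude_mean = amplitude,
                       rise_tau = rise_tau_for_rise_time(rise_time, decay_tau),
                       decay_tau = decay_tau, noise_sd = noise_sd,
                       duration = dur_s, seed = seed)
  synthesize_mini_trace(p, onsets_ms = onsets,
                        amplitudes_pa = rep(amplitude, n_events))
}

# Match detected events to ground truth by peak time (greedy, one-to-one).
match_events <- function(detected_ms, truth_ms, tol_ms = 3) {
  used <- rep(FALSE, length(truth_ms))
  hits <- 0L
  for (t in detected_ms) {
    d <- abs(truth_ms - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_ms) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# Brute-force two-sample KS statistic: sup of |ECDF difference| evaluated
# on the pooled support.
ks_d_bruteforce <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g)
    mean(x <= g) - mean(y <= g), numeric(1))))
}

# Hand-computed classical two-sample t statistic (pooled variance).
t_stat_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Small MEA parameter set on a 16 x 16 grid for fast tests.
small_mea_params <- function(...) {
  mea_gen_params(grid_shape = c(16, 16),
                 region_masks = list(granule = rect_mask(3:6, 3:14),
                                     hilus = rect_mask(10:13, 3:14)),
                 ...)
}
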