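# Intrinsic-property extraction: resting potential, phase-plane AP
# detection, rheobase, input resistance, F-I curve, and QC rules.

test_that("resting potential: constant, Gaussian and bimodal traces", {
  expect_equal(estimate_resting_potential(rep(-70, 5000))$v_m_mv, -70)
  expect_error(estimate_resting_potential(rep(-70, 50)), "100 samples")

  trace <- simulate_resting_trace(passive_cell_params(resting_potential = -65,
                                                      noise_sd = 1),
                                  duration_s = 60, seed = 11)
  est <- estimate_resting_potential(trace)
  expect_equal(est$v_m_mv, -65, tolerance = 0.05 / 65)
  expect_false(est$multimodal)

  set.seed(21)
  bimodal <- c(rnorm(70000, -70, 1), rnorm(30000, -50, 1))
  expect_warning(est2 <- estimate_resting_potential(bimodal), "multimodal")
  expect_equal(est2$v_m_mv, -70, tolerance = 0.2 / 70)
})

test_that("phase-plane AP detection matches a numeric-differentiation oracle", {
  fs <- 20
  ap <- dgephys:::ap_waveform(-42, 30, -75, fs)
  # continuous approach to threshold (5.6 mV/ms, below the criterion),
  # then the stereotyped waveform
  approach <- seq(-70, -42, length.out = 5 * fs + 1L)[- (5 * fs + 1L)]
  sweep <- c(rep(-70, 2000), approach, ap, rep(-75, 2000))
  aps <- detect_action_potentials(sweep, fs)
  expect_equal(nrow(aps), 1L)
  # oracle: smoothed central-difference derivative computed independently;
  # V_s is the raw voltage at the first sample beyond 10 mV/ms
  v <- stats::filter(sweep, rep(1 / 3, 3), sides = 2)
  v[c(1, length(v))] <- sweep[c(1, length(sweep))]
  dv <- (as.numeric(v)[3:length(v)] - as.numeric(v)[1:(length(v) - 2)]) /
    2 * fs
  i_s <- which(dv > 10)[1] + 1L
  expect_equal(aps$threshold_mv, sweep[i_s])
  expect_equal(aps$threshold_mv, -42, tolerance = 0.1)
  expect_equal(aps$amplitude_mv, 72, tolerance = 0.03)
  expect_equal(aps$peak_mv, 30, tolerance = 0.05)
  expect_equal(aps$ahp_mv, -75, tolerance = 0.02)
  expect_gt(aps$half_width_ms, 0)
  expect_lt(aps$half_width_ms, 2)
})

test_that("slow depolarizations below the dV/dt criterion yield no APs", {
  fs <- 20
  ramp <- seq(-80, -10, length.out = fs * 1000)  # max dV/dt 0.07 mV/ms
  expect_equal(nrow(detect_action_potentials(ramp, fs)), 0L)
})

test_that("two pasted APs give two records at the right spacing", {
  fs <- 20
  ap <- dgephys:::ap_waveform(-42, 30, -75, fs)
  gap <- rep(-70, 100 * fs - length(ap))
  sweep <- c(rep(-70, 1000), ap, gap, ap, rep(-70, 1000))
  aps <- detect_action_potentials(sweep, fs)
  expect_equal(nrow(aps), 2L)
  expect_equal(diff(aps$time_ms), 100, tolerance = 1e-6)
})

test_that("rheobase follows the first-spiking-step definition", {
  cell <- passive_cell_params(resting_potential = -70, input_resistance = 100,
                              spike_threshold = -65.3,
                              membrane_time_constant = 20)
  cc <- simulate_current_clamp(cell, step_protocol(n_steps = 16,
                                                   start_current = -100))
  rh <- estimate_rheobase(cc)
  expect_true(rh$defined)
  expect_equal(rh$rheobase_pa, 50)  # true 47 pA quantized up to the grid
  expect_gte(rh$rheobase_pa, cc$truth$rheobase_pa)
  expect_lte(rh$rheobase_pa - cc$truth$rheobase_pa, 10)

  # all-subthreshold cell: flagged undefined
  quiet <- simulate_current_clamp(
    passive_cell_params(spike_threshold = -20, input_resistance = 100),
    step_protocol(n_steps = 10, start_current = -50))
  rq <- estimate_rheobase(quiet)
  expect_false(rq$defined)
  expect_true(is.na(rq$rheobase_pa))
})

test_that("input resistance: Ohm's law, paper-scale recovery, noise bias", {
  cell <- passive_cell_params(resting_potential = -70, input_resistance = 100,
                              membrane_time_constant = 20)
  cc <- simulate_current_clamp(cell, step_protocol(n_steps = 3,
                                                   start_current = -10))
  fit <- fit_input_resistance(cc)
  expect_equal(fit$input_resistance_mohm, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$flagged)

  cell396 <- passive_cell_params(input_resistance = 396)
  cc396 <- simulate_current_clamp(cell396, step_protocol(n_steps = 3,
                                                         start_current = -10))
  expect_equal(fit_input_resistance(cc396)$input_resistance_mohm, 396,
               tolerance = 1e-6)

  # least-squares slope is unbiased under recording noise
  prot <- step_protocol(n_steps = 3, start_current = -10, step_duration = 400,
                        sampling_rate = 5)
  noisy_cell <- passive_cell_params(input_resistance = 300, noise_sd = 1)
  slopes <- vapply(1:100, function(s)
    fit_input_resistance(simulate_current_clamp(noisy_cell, prot,
                                                seed = s))$input_resistance_mohm,
    numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 300), 3 * se + 0.01)

  expect_error(fit_input_resistance(
    simulate_current_clamp(cell, step_protocol(n_steps = 3,
                                               start_current = 0,
                                               increment = 30))),
    "-10, 0 and \\+10")
})

test_that("F-I curve counts APs per step and is monotone for the LIF", {
  cell <- passive_cell_params()
  cc <- simulate_current_clamp(cell, step_protocol())
  fi <- build_fi_curve(cc)
  expect_equal(nrow(fi), 30L)
  # frequency = count / duration, checked against simulator ground truth
  truth_hz <- vapply(cc$truth$spike_times, length, numeric(1)) /
    (cc$protocol$step_duration / 1000)
  expect_equal(fi$frequency_hz, truth_hz)
  expect_true(any(fi$frequency_hz == 0))  # subthreshold steps retained
  expect_true(all(diff(fi$frequency_hz) >= 0))
})

test_that("QC rules follow the access/membrane-resistance criteria", {
  ok <- qc_filter(qc_record(rep(10, 5), r_m = 250), "granule")
  expect_true(ok$passed)
  expect_length(ok$reasons, 0)

  drift <- qc_filter(qc_record(c(10, 11, 12.5)), "mossy")
  expect_false(drift$passed)
  expect_match(drift$reasons, "unstable", all = FALSE)

  high <- qc_filter(qc_record(c(14, 16)), "mossy")
  expect_match(high$reasons, "15 MOhm", all = FALSE)

  immature <- qc_filter(qc_record(rep(10, 3), r_m = 320), "granule")
  expect_false(immature$passed)
  expect_match(immature$reasons, "immature", all = FALSE)
})

test_that("noiseless parameter recovery is exact and counts match truth", {
  cell <- passive_cell_params(input_resistance = 250,
                              membrane_time_constant = 30)
  cc <- simulate_current_clamp(cell, step_protocol())
  prof <- intrinsic_profile(cc)
  expect_equal(prof$input_resistance_mohm, 250, tolerance = 1e-6)
  expect_equal(prof$resting_potential_mv, cell$resting_potential,
               tolerance = 1e-6)
  # detected AP count equals simulator ground truth on every sweep,
  # including under recording noise
  for (s in 1:6) {
    ccn <- simulate_current_clamp(passive_cell_params(noise_sd = 0.5),
                                  step_protocol(), seed = s)
    cnt <- vapply(seq_along(ccn$sweeps), function(i)
      nrow(detect_action_potentials(ccn$sweeps[[i]],
                                    ccn$sampling_rate_khz)), numeric(1))
    expect_equal(cnt, vapply(ccn$truth$spike_times, length, numeric(1)))
  }
})
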