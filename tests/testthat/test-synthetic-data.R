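# Generators: closed-form behaviour with zero noise, ground-truth
# consistency, seed reproducibility, and sampling-law calibration.

test_that("passive membrane obeys Ohm's law at steady state", {
  cell <- passive_cell_params(resting_potential = -70, input_resistance = 100,
                              membrane_time_constant = 20, noise_sd = 0)
  prot <- step_protocol(n_steps = 3, start_current = -10, increment = 10,
                        step_duration = 500)
  cc <- simulate_current_clamp(cell, prot)
  fs <- cc$sampling_rate_khz
  i_end <- round((prot$baseline_duration + prot$step_duration) * fs)
  # -10 pA x 100 MOhm -> -1.0 mV deflection
  expect_equal(cc$sweeps[[1]][i_end], -71, tolerance = 1e-8)
  # zero-amplitude step: sweep identically at rest
  expect_true(all(cc$sweeps[[2]] == -70))
})

test_that("LIF rheobase is the closed-form threshold gap over R_in", {
  # gap 4.7 mV, R_in 100 MOhm -> 47 pA; first spiking step on a 10 pA grid
  # is 50 pA
  cell <- passive_cell_params(resting_potential = -70, input_resistance = 100,
                              spike_threshold = -65.3,
                              membrane_time_constant = 20)
  prot <- step_protocol(n_steps = 16, start_current = -100)
  cc <- simulate_current_clamp(cell, prot)
  expect_equal(cc$truth$rheobase_pa, 47, tolerance = 1e-10)
  spiking <- vapply(cc$truth$spike_times, function(s) length(s) > 0,
                    logical(1))
  expect_equal(cc$currents_pa[which(spiking)[1]], 50)
  # no spikes on the 40 pA step, spikes on 50 pA
  expect_false(spiking[match(40, cc$currents_pa)])
})

test_that("mini generator: empty at rate 0, exact single-event shape", {
  p0 <- mini_gen_params(event_rate = 0, noise_sd = 0, duration = 2, seed = 1)
  mt0 <- synthesize_mini_trace(p0)
  expect_equal(nrow(mt0$truth), 0L)
  expect_true(all(mt0$current_pa == 0))

  # one noiseless 30 pA event: trace minimum -30 pA at the analytic peak
  p1 <- mini_gen_params(event_rate = 0, noise_sd = 0, duration = 2)
  mt1 <- synthesize_mini_trace(p1, onsets_ms = 500, amplitudes_pa = 30)
  tpk <- template_peak_time(p1$rise_tau, p1$decay_tau)
  expect_equal(min(mt1$current_pa), -30, tolerance = 1e-3)
  t_min <- (which.min(mt1$current_pa) - 1) / mt1$sampling_rate_khz
  expect_equal(t_min, 500 + tpk, tolerance = 0.05)
})

test_that("Poisson event counts are calibrated over many seeds", {
  # short traces, no noise: only the event layout matters here
  rate <- 5; dur <- 30; n_seeds <- 150
  counts <- vapply(seq_len(n_seeds), function(s) {
    p <- mini_gen_params(event_rate = rate, noise_sd = 0, duration = dur,
                         sampling_rate = 2, seed = s)
    nrow(synthesize_mini_trace(p)$truth)
  }, numeric(1))
  total <- sum(counts)
  lambda <- rate * dur * n_seeds
  ci <- qpois(c(0.005, 0.995), lambda)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
  # amplitude moments match the nominal Gaussian within sampling error
  p <- mini_gen_params(event_rate = 10, noise_sd = 0, duration = 60,
                       sampling_rate = 2, seed = 99)
  amps <- synthesize_mini_trace(p)$truth$amplitude_pa
  expect_equal(mean(amps), 30, tolerance = 3 * 5 / sqrt(length(amps)) / 30)
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- mini_gen_params(seed = 7, duration = 5)
  expect_identical(synthesize_mini_trace(p)$current_pa,
                   synthesize_mini_trace(p)$current_pa)
  cell <- passive_cell_params(noise_sd = 0.5)
  prot <- step_protocol(n_steps = 3, step_duration = 200)
  expect_identical(simulate_current_clamp(cell, prot, seed = 3)$sweeps,
                   simulate_current_clamp(cell, prot, seed = 3)$sweeps)
})

test_that("evoked trains honour their depression profiles", {
  p <- evoked_gen_params(e_first_amplitude = 100, i_first_amplitude = 100,
                         n_pulses = 5, noise_sd = 0)
  pair <- synthesize_evoked_trains(p)
  expect_equal(pair$truth$e_amplitudes_pa, rep(100, 5))
  # excitatory inward, inhibitory outward
  expect_lt(min(pair$e_trace), -90)
  expect_gt(max(pair$i_trace), 90)

  p2 <- evoked_gen_params(n_pulses = 2, frequency = 10,
                          e_depression_profile = c(1, 0.5),
                          i_depression_profile = c(1, 1), noise_sd = 0)
  pr2 <- synthesize_evoked_trains(p2)
  expect_equal(pr2$truth$e_amplitudes_pa[2],
               pr2$truth$e_amplitudes_pa[1] / 2)

  r <- 0.97
  p3 <- evoked_gen_params(e_depression_profile = r^(0:79),
                          i_depression_profile = rep(1, 80), n_pulses = 80)
  pr3 <- synthesize_evoked_trains(p3)
  expect_equal(pr3$truth$e_amplitudes_pa[80] / pr3$truth$e_amplitudes_pa[1],
               r^79, tolerance = 1e-12)
})

test_that("profile validation rejects malformed depression profiles", {
  expect_error(evoked_gen_params(e_depression_profile = c(0.9, 0.5),
                                 n_pulses = 2), "start at 1")
  expect_error(evoked_gen_params(e_depression_profile = c(1, 0.5),
                                 n_pulses = 3), "length")
})

test_that("MEA generator respects polarity, logistic IO and latency truth", {
  p <- small_mea_params()
  rec <- synthesize_mea_recording(p, mea_single_stimuli())
  g <- rec$region_index$granule; h <- rec$region_index$hilus
  post <- (round(52 * 7.7)):ncol(rec$data)  # past the artifact
  expect_lt(min(rec$data[g, post]), -100)   # sink: negative extrema
  expect_gt(max(rec$data[h, post]), 100)    # source: positive extrema
  # ground-truth latency difference is the generating value
  expect_equal(unname(p$peak_latency["hilus"] - p$peak_latency["granule"]),
               2.8)
  # logistic midpoint: half the plateau at the half-max intensity
  rec50 <- synthesize_mea_recording(p, mea_single_stimuli(p$io_halfmax))
  expect_equal(unname(rec50$truth$amplitudes_uv$hilus[1, 1]),
               143.0 / 2, tolerance = 1e-10)
  # train with ratio 1: all ground-truth pulse amplitudes equal
  p1 <- small_mea_params(last_over_first_ratio = 1)
  rec1 <- synthesize_mea_recording(p1, mea_train_stimulus(20, 0.5))
  expect_equal(length(unique(rec1$truth$pulse_scale)), 1L)
})

test_that("MEA generator rejects artifact/response overlap", {
  p <- small_mea_params(peak_latency = c(granule = 1.0, hilus = 2.0),
                        artifact_duration = 1)
  expect_error(synthesize_mea_recording(p, mea_single_stimuli()),
               "artifact")
})
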