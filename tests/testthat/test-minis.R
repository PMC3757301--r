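# Mini-EPSC detection, event statistics, aligned averaging and kinetics.

test_that("detection threshold separates large from small events", {
  # 5 events of 30 pA and 2 of 5 pA, well separated, light noise
  onsets <- c(100, 400, 700, 1000, 1300, 1600, 1900)
  amps <- c(30, 5, 30, 30, 5, 30, 30)
  p <- mini_gen_params(event_rate = 0, noise_sd = 0.5, duration = 2.2,
                       seed = 3)
  mt <- synthesize_mini_trace(p, onsets_ms = onsets, amplitudes_pa = amps)
  ev <- detect_events(mt, min_amplitude = 8)
  expect_equal(nrow(ev), 5L)
  expect_true(all(abs(ev$amplitude_pa - 30) < 3))
})

test_that("multipeak events are split and flagged overlapping", {
  p <- mini_gen_params(event_rate = 0, rise_tau = 0.3, decay_tau = 5,
                       noise_sd = 0, duration = 1)
  mt <- synthesize_mini_trace(p, onsets_ms = c(400, 404),
                              amplitudes_pa = c(30, 30))
  ev <- detect_events(mt)
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$flag == "overlapping"))
})

test_that("pure noise yields no detections over 30 s", {
  p <- mini_gen_params(event_rate = 0, noise_sd = 2, duration = 30,
                       seed = 17)
  ev <- detect_events(synthesize_mini_trace(p))
  expect_equal(nrow(ev), 0L)
})

test_that("event statistics: frequency, ECDF shape and DKW consistency", {
  ev3 <- data.frame(onset_ms = c(10, 20, 30), peak_ms = c(11, 21, 31),
                    amplitude_pa = c(10, 20, 30), flag = "clean")
  st <- event_statistics(ev3, duration_s = 30)
  expect_equal(st$frequency_hz, 0.1)
  expect_equal(st$amplitude_ecdf$fraction, c(1, 2, 3) / 3)
  expect_equal(tail(st$amplitude_ecdf$fraction, 1), 1)
  expect_true(all(diff(st$amplitude_ecdf$fraction) >= 0))

  st150 <- event_statistics(data.frame(onset_ms = seq_len(150) * 200,
                                       amplitude_pa = rep(10, 150)),
                            duration_s = 30)
  expect_equal(st150$frequency_hz, 5)

  # empty input: zero frequency, empty distributions
  st0 <- event_statistics(data.frame(onset_ms = numeric(0),
                                     amplitude_pa = numeric(0)), 30)
  expect_equal(st0$frequency_hz, 0)
  expect_equal(nrow(st0$amplitude_ecdf), 0L)

  # generated Gaussian amplitudes sit inside the 99% DKW band of the
  # generating CDF
  p <- mini_gen_params(event_rate = 20, noise_sd = 0, duration = 60,
                       sampling_rate = 2, seed = 5)
  amps <- synthesize_mini_trace(p)$truth$amplitude_pa
  n <- length(amps)
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  grid <- sort(amps)
  sup_dev <- max(abs(seq_len(n) / n - pnorm(grid, 30, 5)),
                 abs((seq_len(n) - 1) / n - pnorm(grid, 30, 5)))
  expect_lte(sup_dev, eps)
})

test_that("aligned averaging reproduces the event template", {
  mt <- make_regular_mini_trace(n_events = 45, amplitude = 30)
  ev <- detect_events(mt)
  expect_equal(nrow(ev), 45L)
  avg <- average_aligned_events(mt, ev, n_events = 45)
  expect_equal(avg$n_events, 45L)
  # identical noiseless events: the average is the single-event waveform
  expect_equal(min(avg$current_pa), -30, tolerance = 1e-3)
  k <- fit_kinetics(avg)
  expect_equal(k$rise_time_10_90_ms, 0.83, tolerance = 0.01)
  expect_equal(k$decay_tau_ms, 4.39, tolerance = 0.01)

  # mixed amplitudes, same kinetics: averaging preserves the shape
  onsets <- 50 + (0:44) * 100
  p <- mini_gen_params(event_rate = 0, noise_sd = 0, duration = 5)
  mt2 <- synthesize_mini_trace(p, onsets_ms = onsets,
                               amplitudes_pa = rep(c(15, 30, 60), 15))
  ev2 <- detect_events(mt2)
  k2 <- fit_kinetics(average_aligned_events(mt2, ev2, n_events = 45))
  expect_equal(k2$decay_tau_ms, k$decay_tau_ms, tolerance = 0.01)
  expect_equal(k2$rise_time_10_90_ms, k$rise_time_10_90_ms,
               tolerance = 0.02)

  # sub-sample onset jitter barely affects the averaged peak
  mt3 <- synthesize_mini_trace(p, onsets_ms = onsets +
                                 runif(45, -0.025, 0.025),
                               amplitudes_pa = rep(30, 45))
  avg3 <- average_aligned_events(mt3, detect_events(mt3), n_events = 45)
  expect_equal(min(avg3$current_pa), -30, tolerance = 0.02)

  expect_error(average_aligned_events(mt, ev[1:10, ]), "at least 40")
})

test_that("kinetics fit recovers a pure monoexponential decay exactly", {
  fs <- 20
  t_ms <- seq(0, 20, by = 1 / fs)
  w <- -c(rep(0, 100), 30 * exp(-t_ms / 1))
  k <- fit_kinetics(w, sampling_rate_khz = fs)
  expect_equal(k$decay_tau_ms, 1, tolerance = 1e-6)
  expect_gt(k$fit_r2, 0.999)
  # peak at the trace edge is rejected
  expect_error(fit_kinetics(-c(30, 29, 28, 5, 1), sampling_rate_khz = 1),
               "edge")
})

test_that("detection stays reliable at high SNR and degrades with noise", {
  fidelity_at <- function(noise_sd, seeds = 1:6) {
    prf <- vapply(seeds, function(s) {
      p <- mini_gen_params(event_rate = 5, amplitude_mean = 30,
                           amplitude_sd = 3, noise_sd = noise_sd,
                           duration = 20, seed = s)
      mt <- synthesize_mini_trace(p)
      ev <- detect_events(mt)
      hits <- match_events(ev$peak_ms, mt$truth$peak_ms)
      c(recall = hits / max(1L, nrow(mt$truth)),
        precision = if (nrow(ev)) hits / nrow(ev) else 1)
    }, numeric(2))
    rowMeans(prf)
  }
  good <- fidelity_at(2)   # SNR 15
  bad <- fidelity_at(8)    # SNR < 4
  expect_gte(good["recall"], 0.95)
  expect_gte(good["precision"], 0.95)
  f1 <- function(x) 2 * x["recall"] * x["precision"] /
    (x["recall"] + x["precision"])
  expect_lt(f1(bad), f1(good))  # monotone degradation with noise
})
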