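test_that("smoothed derivative is exact for ramps and sinusoids", {
  t <- seq(0, 2, by = 1e-3)
  ramp <- diastolica:::as_pressure_waveform(t, 5 * t)
  for (w in c(1, 21, 51)) {
    d <- compute_dpdt(ramp, smooth_window = w)
    interior <- d[(w + 1):(length(d) - w)]
    expect_equal(interior, rep(5, length(interior)), tolerance = 1e-8)
  }
  sine <- diastolica:::as_pressure_waveform(t, sin(2 * pi * t))
  d <- compute_dpdt(sine, smooth_window = 1)
  expect_lt(abs(max(d) - 2 * pi) / (2 * pi), 0.001)
})

test_that("window 1 reduces to the raw centred difference", {
  wf <- simulate_waveform(waveform_params(seed = 1))$waveform
  d <- compute_dpdt(wf, smooth_window = 1)
  n <- length(wf$pressure)
  raw <- (wf$pressure[3:n] - wf$pressure[1:(n - 2)]) * wf$sampling_rate / 2
  expect_equal(d[2:(n - 1)], raw, tolerance = 1e-12)
})

test_that("invalid smoothing windows are rejected", {
  wf <- simulate_waveform(noiseless_params())$waveform
  expect_error(compute_dpdt(wf, smooth_window = 20), "odd")
  expect_error(compute_dpdt(wf, smooth_window = -3), "odd")
  too_long <- length(wf$pressure) + length(wf$pressure) %% 2 + 1  # odd, > n
  expect_error(compute_dpdt(wf, smooth_window = too_long),
               "smaller than the series length")
})

test_that("cycle segmentation finds one cycle per simulated beat", {
  wf0 <- simulate_waveform(noiseless_params())$waveform
  expect_equal(nrow(segment_cycles(wf0)), 10)
  wfn <- simulate_waveform(waveform_params(noise_sd = 0.5, seed = 11))$waveform
  expect_equal(nrow(segment_cycles(wfn)), 10)
  cyc <- segment_cycles(wfn)
  expect_true(all(cyc[-1, "start"] == cyc[-nrow(cyc), "end"] + 1))
})

test_that("segmentation rejects degenerate inputs", {
  flat <- diastolica:::as_pressure_waveform(seq(0, 2, 1e-3),
                                            rep(10, 2001))
  expect_error(segment_cycles(flat), "segmentation error")
  short <- simulate_waveform(noiseless_params())$waveform
  short$time <- short$time[1:400]; short$pressure <- short$pressure[1:400]
  expect_error(segment_cycles(short), "at least 1 s")
})

test_that("fiducials recovered within 5 ms over a noiseless parameter sweep", {
  for (p_ed in c(8, 12, 20, 25)) {
    for (hr in c(50, 70, 100)) {
      p <- noiseless_params(p_ed = p_ed, heart_rate = hr, n_cycles = 6)
      sim <- simulate_waveform(p)
      wf <- sim$waveform
      cyc <- segment_cycles(wf)
      for (i in seq_len(nrow(cyc))) {
        f <- detect_fiducials(wf, cyc[i, ])
        # match against the ground-truth cycle containing this onset
        tr_row <- which.min(abs(sim$truth$fiducials$end_diastole -
                                wf$time[f$end_diastole]))
        tr <- sim$truth$fiducials[tr_row, ]
        expect_lt(abs(wf$time[f$end_diastole] - tr$end_diastole), 0.005)
        expect_lt(abs(wf$time[f$peak_systole] - tr$peak_systole), 0.005)
        expect_lt(abs(wf$time[f$end_systole] - tr$end_systole), 0.005)
      }
    }
  }
})

test_that("degenerate cycles raise fiducial errors", {
  t <- seq(0, 1.2, 1e-3)
  rising <- diastolica:::as_pressure_waveform(t, 10 + 100 * t)
  expect_error(detect_fiducials(rising, c(1, length(t))), "fiducial error")
})

test_that("end-expiration selection finds the respiratory trough", {
  # no modulation: all runs tie, earliest run wins
  wf0 <- simulate_waveform(noiseless_params())$waveform
  cyc0 <- segment_cycles(wf0)
  expect_identical(select_end_expiration_cycles(wf0, cyc0, k = 5), 1:5)
  # modulation: the selected run's baseline sits below the overall mean
  wfr <- simulate_waveform(waveform_params(noise_sd = 0, seed = 3))$waveform
  cycr <- segment_cycles(wfr)
  sel <- select_end_expiration_cycles(wfr, cycr, k = 5)
  expect_length(sel, 5)
  expect_identical(diff(sel), rep(1L, 4))
  d <- compute_dpdt(wfr)
  sm <- diastolica:::smooth_pressure(wfr$pressure, 21)
  base <- vapply(seq_len(nrow(cycr)), function(i)
    detect_fiducials(wfr, cycr[i, ])$p_end_diastole, numeric(1))
  expect_lt(mean(base[sel]), mean(base))
  # too few cycles
  wf3 <- simulate_waveform(noiseless_params(n_cycles = 3))$waveform
  cyc3 <- segment_cycles(wf3)
  expect_error(select_end_expiration_cycles(wf3, cyc3, k = 5),
               "selection error")
})

test_that("extracted parameters match the analytic ground truth", {
  p <- noiseless_params()
  hp <- compute_hemodynamic_params(simulate_waveform(p)$waveform)
  ex <- analytic_extrema(p)
  expect_equal(hp$n_cycles_used, 5)
  expect_lt(abs(hp$contraction_integral - 158), 0.5)
  expect_lt(abs(hp$relaxation_integral - 168), 0.5)
  expect_lt(abs(hp$max_dpdt - ex["max_dpdt"]) / ex["max_dpdt"], 0.01)
  expect_lt(abs(hp$min_dpdt - ex["min_dpdt"]) / abs(ex["min_dpdt"]), 0.01)
  expect_lt(abs(hp$lvedp - p$p_ed), 0.5)
  expect_lt(abs(hp$lvesp - p$p_es), 0.5)
  expect_false(hp$diastolic_dysfunction)
})

test_that("dP/dt integrals telescope to detected pressure differences", {
  # fundamental theorem of calculus: integral of dP/dt between fiducials
  # equals the pressure difference between them
  for (seed_pars in list(noiseless_params(),
                         noiseless_params(p_ed = 20, p_peak = 150, p_es = 6),
                         noiseless_params(heart_rate = 55, p_ed = 9))) {
    wf <- simulate_waveform(seed_pars)$waveform
    cyc <- segment_cycles(wf)
    sel <- select_end_expiration_cycles(wf, cyc, k = 5)
    hp <- compute_hemodynamic_params(wf)
    f <- detect_fiducials(wf, cyc[sel[3], ])
    expect_lt(abs(hp$contraction_integral -
                  (f$p_peak_systole - f$p_end_diastole)), 0.5)
    expect_lt(abs(hp$relaxation_integral -
                  (f$p_peak_systole - f$p_end_systole)), 0.5)
  }
})

test_that("averaged LVEDP is robust to measurement noise", {
  p_hat <- vapply(1:20, function(s) {
    wf <- simulate_waveform(waveform_params(noise_sd = 1, resp_amplitude = 0,
                                            seed = 1000 + s))$waveform
    compute_hemodynamic_params(wf)$lvedp
  }, numeric(1))
  expect_lt(abs(mean(p_hat) - 12), 0.5)
})

test_that("reported LVEDP increases strictly with true end-diastolic pressure", {
  lvedps <- vapply(c(8, 12, 16, 20, 25), function(pe) {
    wf <- simulate_waveform(noiseless_params(p_ed = pe))$waveform
    compute_hemodynamic_params(wf)$lvedp
  }, numeric(1))
  expect_true(all(diff(lvedps) > 0))
})

test_that("integrals are stable under doubling of the sampling rate", {
  hp1 <- compute_hemodynamic_params(
    simulate_waveform(noiseless_params(sampling_rate = 1000))$waveform)
  hp2 <- compute_hemodynamic_params(
    simulate_waveform(noiseless_params(sampling_rate = 2000))$waveform,
    smooth_window = 41)
  for (fld in c("contraction_integral", "relaxation_integral",
                "diastolic_integral")) {
    expect_lt(abs(hp1[[fld]] - hp2[[fld]]) / abs(hp2[[fld]]), 0.002)
  }
})

test_that("diastolic dysfunction is a strict >15 mmHg call", {
  expect_true(classify_diastolic_dysfunction(20))
  expect_false(classify_diastolic_dysfunction(15.0))
  expect_false(classify_diastolic_dysfunction(8))
  expect_identical(classify_diastolic_dysfunction(c(14, 15.01)),
                   c(FALSE, TRUE))
  expect_error(classify_diastolic_dysfunction(NaN), "finite")
})
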