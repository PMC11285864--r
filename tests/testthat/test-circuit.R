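test_that("closed-form discharge matches an independent ODE integration in all damping regimes", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  for (rep in 1:6) {
    L <- runif(1, 0.05, 0.5)
    C <- runif(1, 1e-5, 1e-3)
    U0 <- runif(1, 50, 400)
    r_crit <- 2 * sqrt(L / C)
    for (R in c(runif(1, 1.2, 3) * r_crit,   # overdamped
                r_crit,                      # critical
                runif(1, 0.05, 0.6) * r_crit)) {  # underdamped
      circ <- pulse_circuit(u0 = U0, capacitance = C, inductance = L,
                            r_total = R, t_d = 5e-3)
      w <- solve_discharge(circ, grid_step = 5e-6)
      i_ode <- ode_discharge(circ, w$t)
      expect_lt(max(abs(w$i - i_ode)) / max(abs(w$i)), 1e-6)
    }
  }
})

test_that("current starts at zero with slope U0/L", {
  for (circ in list(treat_2020(), treat_2021())) {
    w <- solve_discharge(circ)
    expect_identical(w$i[1], 0)
    fwd <- (w$i[2] - w$i[1]) / (w$t[2] - w$t[1])
    expect_lt(abs(fwd / (circ$u0 / circ$inductance) - 1), 1e-3)
  }
  expect_equal(initial_current_rate(treat_2020()), 230 / 0.17 / 1e3,
               tolerance = 1e-12)  # 1.3529 A/ms
  dbl <- circuit_profile("mp09_2020", u0 = 460)
  expect_equal(initial_current_rate(dbl), 2 * initial_current_rate(treat_2020()))
  expect_equal(initial_current_rate(circuit_profile("mp09_2020", u0 = 0)), 0)
})

test_that("both device generations reproduce their printed peak currents", {
  w21 <- solve_discharge(treat_2021())
  m21 <- waveform_metrics(w21)
  expect_equal(m21$i_peak, 2.65, tolerance = 0.01)
  expect_gt(m21$t_peak, 7.5e-3)
  expect_lt(m21$t_peak, 8.5e-3)
  w20 <- solve_discharge(treat_2020())
  m20 <- waveform_metrics(w20)
  expect_equal(m20$i_peak, 2.4, tolerance = 0.01)
  expect_gt(m20$t_peak, 5.6e-3)
  expect_lt(m20$t_peak, 5.9e-3)
  expect_equal(w20$i[length(w20$i)], 2.25, tolerance = 0.02)  # I at 9 ms
})

test_that("zero drive voltage gives an identically zero pulse", {
  circ <- circuit_profile("mp09_2020", u0 = 0)
  w <- simulate_pulse(circ)
  expect_true(all(w$i == 0))
  m <- waveform_metrics(w)
  expect_identical(m$i_peak, 0)
  expect_identical(m$t_peak, 0)
  expect_identical(m$b_peak, 0)
})

test_that("waveforms scale linearly in U0 and satisfy the energy bound", {
  set.seed(7)
  for (rep in 1:5) {
    circ <- pulse_circuit(u0 = runif(1, 10, 500),
                          capacitance = runif(1, 1e-5, 1e-3),
                          inductance = runif(1, 0.05, 0.5),
                          r_total = runif(1, 20, 200), t_d = 5e-3)
    w <- solve_discharge(circ, grid_step = 5e-6)
    circ2 <- circ; circ2$u0 <- 3 * circ$u0
    w2 <- solve_discharge(circ2, grid_step = 5e-6)
    expect_equal(w2$i, 3 * w$i, tolerance = 1e-12)
    # capacitor energy strictly bounds peak coil energy when R > 0
    e_cap <- 0.5 * circ$capacitance * circ$u0^2
    e_coil <- 0.5 * circ$inductance * max(w$i)^2
    expect_lt(e_coil, e_cap)
  }
})

test_that("field is current times k everywhere and the sham on-phase is a prefix of the treatment's", {
  w <- solve_discharge(treat_2020())
  expect_equal(w$b_mt, w$i * 24, tolerance = 1e-15)
  ws <- solve_discharge(sham_2020())
  n <- length(ws$t)
  expect_equal(ws$i, w$i[seq_len(n)], tolerance = 1e-12)
  # hence identical onset dB/dt over the shared window
  ms <- waveform_metrics(ws)
  mt <- waveform_metrics(solve_discharge(treat_2020()),
                         onset_window = 0.05 * 0.2e-3)
  expect_equal(ms$onset_field_rate, mt$onset_field_rate, tolerance = 1e-9)
})

test_that("invalid parameters and too-coarse grids are rejected", {
  expect_error(pulse_circuit(u0 = NaN), "invalid-parameter")
  expect_error(pulse_circuit(inductance = -1), "invalid-parameter")
  expect_error(pulse_circuit(capacitance = 0), "invalid-parameter")
  expect_error(solve_discharge(treat_2020(), grid_step = 1e-3),
               "resolution")
  expect_error(solve_discharge(treat_2020(), grid_step = 0),
               "invalid-parameter")
})

test_that("shut-off models append the documented descents", {
  # 2020 treatment: 2.25 A ramped down over 0.69 ms -> mean 3.26 A/ms
  w <- simulate_pulse(treat_2020())
  m <- waveform_metrics(w)
  expect_equal(m$shutoff_current_rate, 2.2255 / 0.69, tolerance = 0.01)
  expect_equal(m$duration_fall, 0.69e-3, tolerance = 1e-9)
  expect_equal(w$i[length(w$i)], 0)
  # 2021 flyback: relaxation time L/R = 2.125 ms; tail truncated at 1e-4 peak
  circ <- treat_2021()
  expect_equal(circ$inductance / circ$r_total, 2.125e-3)
  wf <- simulate_pulse(circ)
  off <- wf$t >= wf$phase_marks[["shutoff_start"]]
  i_d <- wf$i[which(off)[1]]
  tau_fit <- -1 / coef(lm(log(wf$i[off]) ~ wf$t[off]))[2]
  expect_equal(unname(tau_fit), 2.125e-3, tolerance = 1e-6)
  expect_lt(wf$i[length(wf$i)], 1.001e-4 * max(wf$i))
  # zero current at shut-off -> identically zero tail
  w0 <- simulate_pulse(circuit_profile("mp09_2020", u0 = 0))
  expect_true(all(w0$i == 0))
})

test_that("induced voltage follows -a_eff dB/dt with linear pickup scaling", {
  # constant-field segment: zero voltage
  flat <- pulsesham:::new_pulse_waveform(
    t = seq(0, 1e-3, 1e-5), i = rep(2, 101), k_field = 24,
    phase_marks = c(switch_on = 0, shutoff_start = 1e-3, end = 1e-3),
    grid_step = 1e-5)
  expect_true(all(induced_voltage(flat, pickup_coil(1)) == 0))
  w <- simulate_pulse(treat_2020())
  u1 <- induced_voltage(w, pickup_coil(2))
  u2 <- induced_voltage(w, pickup_coil(1))
  expect_equal(u1, 2 * u2, tolerance = 1e-12)
  # sham and treatment onset spikes agree (same circuit, same start)
  us <- induced_voltage(simulate_pulse(sham_2020()), pickup_coil(1))
  expect_equal(us[1], u2[1], tolerance = 0.01 * abs(u2[1]))
  short <- pulsesham:::new_pulse_waveform(
    t = c(0, 1e-5), i = c(0, 1), k_field = 24,
    phase_marks = c(switch_on = 0, shutoff_start = 1e-5, end = 1e-5),
    grid_step = 1e-5)
  expect_error(induced_voltage(short, pickup_coil(1)), "resolution")
})

test_that("onset field rate reflects k times the initial current slope", {
  # instantaneous rate: k * U0 / L = 32.5 mT/ms
  expect_equal(24 * initial_current_rate(treat_2020()), 32.47, tolerance = 1e-3)
  # the fitted 5%-window slope sits a little below it (curvature), near the
  # 30 mT/ms scale of the physical device
  m <- waveform_metrics(solve_discharge(treat_2020()))
  expect_gt(m$onset_field_rate, 28)
  expect_lt(m$onset_field_rate, 32.5)
})

test_that("waveform CSV round trip preserves traces to 9 significant digits", {
  w <- simulate_pulse(treat_2020())
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path, pickup = pickup_coil(1.5))
  expect_identical(readLines(path, n = 1), "t_s,i_a,b_mt,u_v")
  w2 <- read_waveform_csv(path)
  expect_equal(w2$t, w$t, tolerance = 1e-8)
  expect_equal(w2$i, w$i, tolerance = 1e-8)
  expect_equal(w2$b_mt, w$b_mt, tolerance = 1e-8)
})
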