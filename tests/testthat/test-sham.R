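test_that("designed sham duration hits the target peak ratio", {
  circ <- treat_2020()
  i_peak <- max(solve_discharge(circ)$i)
  fn <- pulsesham:::discharge_current_fn(circ)
  for (ratio in c(0.02, 0.1, 0.5, 0.9)) {
    dur <- design_sham_duration(circ, 9e-3, ratio)
    expect_equal(fn(dur) / i_peak, ratio, tolerance = 1e-6)
  }
  # the 10% design lands near the duration used on the physical device
  dur10 <- design_sham_duration(circ, 9e-3, 0.1)
  expect_gt(dur10, 0.17e-3)
  expect_lt(dur10, 0.20e-3)
})

test_that("sham duration is monotone in the target ratio and bounded by the peak time", {
  circ <- treat_2021()
  ratios <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  durs <- vapply(ratios, function(r) design_sham_duration(circ, 10e-3, r),
                 numeric(1))
  expect_true(all(diff(durs) > 0))
  t_peak <- waveform_metrics(solve_discharge(circ))$t_peak
  expect_true(all(durs < t_peak))
  # ratio -> 1 approaches the peak time
  expect_equal(design_sham_duration(circ, 10e-3, 1 - 1e-9), t_peak,
               tolerance = 1e-3)
  expect_error(design_sham_duration(circ, 10e-3, 1), "domain error")
  expect_error(design_sham_duration(circ, 10e-3, 1.2), "domain error")
  expect_error(design_sham_duration(circuit_profile("mp09_2020", u0 = 0),
                                    9e-3, 0.1), "domain error")
})

test_that("adequacy verification applies the four criteria", {
  # measured pair at the bird position: 5.2 / 52 mT with matched onset rates
  rep_ok <- verify_sham_adequacy(pulse_metrics(5.2, onset_field_rate = 30),
                                 pulse_metrics(52, onset_field_rate = 30))
  expect_true(all(rep_ok$pass))
  expect_true(attr(rep_ok, "overall"))
  # identical pulses: onset matches but the peak-ratio bound fails
  same <- verify_sham_adequacy(pulse_metrics(52, onset_field_rate = 30),
                               pulse_metrics(52, onset_field_rate = 30))
  expect_true(same$pass[same$criterion == "onset_rate_match"])
  expect_false(same$pass[same$criterion == "peak_ratio_bound"])
  expect_false(attr(same, "overall"))
  # 15 mT sham exceeds the 12 mT no-effect threshold
  hot <- verify_sham_adequacy(pulse_metrics(15, onset_field_rate = 30),
                              pulse_metrics(52, onset_field_rate = 30))
  expect_false(hot$pass[hot$criterion == "sham_below_no_effect"])
  expect_error(verify_sham_adequacy(pulse_metrics(5.2, onset_field_rate = 30),
                                    pulse_metrics(0, onset_field_rate = 30)),
               "undefined-ratio")
})

test_that("swapping sham and treatment can never yield an all-pass report", {
  set.seed(31)
  for (rep in 1:20) {
    b_s <- runif(1, 1, 60); b_t <- runif(1, 1, 60)
    rate <- runif(1, 10, 40)
    ms <- pulse_metrics(b_s, onset_field_rate = rate)
    mt <- pulse_metrics(b_t, onset_field_rate = rate)
    fwd <- attr(verify_sham_adequacy(ms, mt), "overall")
    bwd <- attr(verify_sham_adequacy(mt, ms), "overall")
    expect_false(fwd && bwd)
  }
})

test_that("remagnetization classification is monotone with inclusive strong-side boundaries", {
  expect_identical(classify_remagnetization(5.2), "sub_threshold")
  expect_identical(classify_remagnetization(52), "full_switch")
  expect_identical(classify_remagnetization(25), "full_switch")  # inclusive
  expect_identical(classify_remagnetization(12), "partial")
  expect_identical(classify_remagnetization(11.999), "sub_threshold")
  labels <- classify_remagnetization(seq(0, 60, by = 0.5))
  ord <- c(sub_threshold = 1, partial = 2, full_switch = 3)
  expect_true(all(diff(ord[labels]) >= 0))
  expect_error(classify_remagnetization(-1), "invalid-input")
})

test_that("criteria and switching constructors reject invalid values", {
  expect_error(sham_criteria(max_peak_ratio = 1.5), "invalid-parameter")
  expect_error(sham_criteria(onset_rate_tolerance = 0), "invalid-parameter")
  expect_error(switching_model(b_no_effect = 30, b_full_switch = 25),
               "invalid-parameter")
})
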