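test_that("cohort generation is reproducible and internally consistent", {
  cfg <- cohort_config(n = 25)
  c1 <- generate_cohort(cfg, seed = 42)
  c2 <- generate_cohort(cfg, seed = 42)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 25 * 8)
  # first-night departure consistent with a zero-night stopover
  expect_identical(c1$departed_first_night, c1$stopover_nights == 0L)
  # rounding induces ties in bearings and timings
  expect_gt(sum(duplicated(c1$departure_bearing_deg)), 0)
  expect_gt(sum(duplicated(c1$night_fraction)), 0)
  # a different seed moves the draws
  expect_false(identical(c1, generate_cohort(cfg, seed = 43)))
})

test_that("degenerate configurations behave as declared", {
  empty <- generate_cohort(cohort_config(n = 0), seed = 1)
  expect_equal(nrow(empty), 0)
  all_dep <- generate_cohort(cohort_config(n = 15, p_dep = 1), seed = 1)
  expect_true(all(all_dep$stopover_nights == 0))
  expect_error(cohort_config(n = -1), "configuration error")
  expect_error(cohort_config(p_dep = 1.1), "configuration error")
  expect_error(cohort_config(mu_stopover = 0.5), "configuration error")
  expect_error(cohort_config(kappa_direction = -1), "configuration error")
})

test_that("departure fractions track the configured probability at large n", {
  cfg <- cohort_config(n = 10000, years = 2020, ages = "adult",
                       groups = "sham", p_dep = 0.5)
  coh <- generate_cohort(cfg, seed = 8)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(mean(coh$departed_first_night) - 0.5), 3 * se)
})

test_that("generated bearings recover the von Mises concentration", {
  # mean resultant length should match A(kappa) = I1(kappa)/I0(kappa)
  for (kappa in c(1, 4)) {
    cfg <- cohort_config(n = 20000, years = 2020, ages = "adult",
                         groups = "sham", mu_direction = 120,
                         kappa_direction = kappa,
                         round_bearing = 0.01)  # fine grid: rounding bias off
    coh <- generate_cohort(cfg, seed = 13)
    r <- rayleigh_test(coh$departure_bearing_deg)$extras
    a_kappa <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(r$r, a_kappa, tolerance = 0.02)
    expect_lt(abs(pulsesham:::wrap_diff_deg(r$mean_direction, 120)), 2)
  }
})

test_that("default cohorts resemble the field summaries they emulate", {
  coh <- generate_cohort(cohort_config(n = 60), seed = 2)
  juv <- coh[coh$age == "juvenile", ]
  expect_lte(median(juv$stopover_nights), 1)
  expect_gt(median(coh$night_fraction), 0.1)
  expect_lt(median(coh$night_fraction), 0.4)
  r_dir <- rayleigh_test(juv$departure_bearing_deg)$extras$r
  expect_gt(r_dir, 0.3); expect_lt(r_dir, 0.9)
})

test_that("the power harness is reproducible and saturates under a large bearing shift", {
  null_cfg <- cohort_config(n = 50, years = 2020, ages = "adult",
                            kappa_direction = 4)
  eff_cfg <- null_cfg
  eff_cfg$mu_direction <- ifelse(eff_cfg$group == "treatment",
                                 eff_cfg$mu_direction + 90,
                                 eff_cfg$mu_direction)
  t1 <- monte_carlo_power(null_cfg, eff_cfg, reps = 100, seed = 5,
                          mww_reps = 30, wilcoxon_policy = "normal")
  t2 <- monte_carlo_power(null_cfg, eff_cfg, reps = 100, seed = 5,
                          mww_reps = 30, wilcoxon_policy = "normal")
  expect_identical(t1, t2)
  pow_dir <- t1$rejection_rate[t1$trait == "departure_direction" &
                                 t1$condition == "effect"]
  expect_gt(pow_dir, 0.9)   # 90 deg shift at kappa = 4, n = 50/group
  # Wilson intervals bracket their rates
  expect_true(all(t1$ci_lower <= t1$rejection_rate &
                    t1$rejection_rate <= t1$ci_upper))
  expect_error(monte_carlo_power(null_cfg, reps = 10), "invalid-input")
  expect_error(monte_carlo_power(cohort_config(n = 0), reps = 100),
               "configuration error")
})
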