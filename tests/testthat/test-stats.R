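test_that("continuity-corrected chi-square matches the base-R oracle on random tables", {
  set.seed(11)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi2_yates_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square handles balanced tables, zero margins and relabeling", {
  bal <- chi2_yates_2x2(10, 10, 10, 10)
  expect_identical(bal$statistic, 0)
  expect_identical(bal$p, 1)
  expect_error(chi2_yates_2x2(0, 0, 5, 5), "degenerate-table")
  expect_error(chi2_yates_2x2(5, 0, 5, 0), "degenerate-table")
  # transposing the table (swapping rows with columns) leaves the statistic
  a <- chi2_yates_2x2(12, 7, 5, 16)
  b <- chi2_yates_2x2(12, 5, 7, 16)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_gte(a$statistic, 0)
})

test_that("exact Wilcoxon reproduces small enumerations and tie conventions", {
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_identical(r$statistic, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  same <- wilcoxon_ranksum(c(1, 1, 2), c(1, 1, 2))
  expect_equal(same$p, 1, tolerance = 1e-12)
  # W convention matches the Mann-Whitney count printed by R (tie-free case)
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(wilcoxon_ranksum(x, y)$statistic,
               unname(suppressWarnings(wilcox.test(x, y))$statistic))
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "invalid-input")
})

test_that("exact Wilcoxon p equals brute-force enumeration on random small samples with ties", {
  set.seed(23)
  for (rep in 1:30) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(1:4, nx, replace = TRUE)   # heavy ties
    y <- sample(2:5, ny, replace = TRUE)
    expect_equal(wilcoxon_ranksum(x, y, policy = "exact")$p,
                 brute_wilcoxon_p(x, y), tolerance = 1e-12,
                 label = sprintf("x=%s y=%s", toString(x), toString(y)))
  }
})

test_that("the normal-approximation route matches the base-R tie-corrected test", {
  set.seed(9)
  for (rep in 1:10) {
    x <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
    y <- sample(seq(0, 1, 0.1), 45, replace = TRUE)
    ours <- wilcoxon_ranksum(x, y, policy = "normal")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # auto policy: exact for small N, exact under ties up to the cap, else normal
  expect_true(wilcoxon_ranksum(1:10, 2:12)$extras$exact)
  big_ties <- wilcoxon_ranksum(rep(1:20, 2), rep(2:21, 2))
  expect_true(big_ties$extras$exact)
  huge <- wilcoxon_ranksum(rep(1:60, 2), rep(2:61, 2))
  expect_false(huge$extras$exact)
})

test_that("Rayleigh statistics follow the direct vector sums", {
  ten <- rayleigh_test(rep(90, 10))
  expect_equal(ten$extras$r, 1, tolerance = 1e-12)
  expect_lt(ten$p, 0.001)
  expect_equal(rayleigh_test(c(0, 180))$extras$r, 0, tolerance = 1e-12)
  expect_equal(rayleigh_test(c(0, 90))$extras$r, sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(rayleigh_test(c(0, 90))$extras$mean_direction, 45,
               tolerance = 1e-9)
  expect_error(rayleigh_test(90), "invalid-input")
})

test_that("Rayleigh r is rotation invariant", {
  set.seed(3)
  ang <- runif(25, 0, 360)
  r0 <- rayleigh_test(ang)$extras$r
  for (shift in c(10, 123, 300))
    expect_equal(rayleigh_test((ang + shift) %% 360)$extras$r, r0,
                 tolerance = 1e-12)
})

test_that("MWW is invariant to rotation and group relabeling, and single-run without ties", {
  set.seed(17)
  a1 <- runif(12, 0, 360); a2 <- runif(14, 0, 360)
  w <- mww_test(a1, a2, seed = 1)
  expect_identical(w$extras$reps, 1L)       # tie-free: one evaluation
  expect_false(w$extras$ties)
  expect_equal(mww_test((a1 + 77) %% 360, (a2 + 77) %% 360, seed = 1)$statistic,
               w$statistic, tolerance = 1e-9)
  expect_equal(mww_test(a2, a1, seed = 1)$statistic, w$statistic,
               tolerance = 1e-9)
  expect_equal(w$p, pchisq(w$statistic, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("two tight antipodal clusters are detected decisively", {
  set.seed(29)
  a1 <- (rnorm(20, 0, 5)) %% 360
  a2 <- (rnorm(20, 180, 5)) %% 360
  expect_lt(mww_test(a1, a2, seed = 1)$p, 0.001)
  expect_lt(mww_test(a1, a2, seed = 1, p_method = "permutation",
                     n_perm = 3000)$p, 0.001)
})

test_that("tied MWW is seed-reproducible and its median is stable across seeds", {
  set.seed(41)
  a1 <- round(rnorm(20, 100, 20)) %% 360
  a2 <- round(rnorm(20, 120, 20)) %% 360
  r1 <- mww_test(a1, a2, seed = 7, reps = 400)
  r2 <- mww_test(a1, a2, seed = 7, reps = 400)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p, r2$p)
  expect_true(r1$extras$ties)
  # across seeds the median moves less than the central spread of one run
  meds <- vapply(1:5, function(s)
    mww_test(a1, a2, seed = s, reps = 400)$statistic, numeric(1))
  iqr <- diff(r1$extras$w_spread)
  expect_lt(max(meds) - min(meds), iqr)
  expect_error(mww_test(a1, a2, seed = 1, reps = 0), "invalid-input")
  expect_error(mww_test(1:3, a2, seed = 1), "sample-size")
})

test_that("the pooled t-test handles exact and degenerate cases", {
  expect_identical(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_identical(two_sample_t(c(0, 1), c(0, 1))$statistic, 0)
  hand <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(hand$statistic, -3.674, tolerance = 1e-3)
  const <- two_sample_t(c(2, 2), c(2, 2))
  expect_identical(const$p, 1)
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "degenerate-input")
  expect_error(two_sample_t(1, c(1, 2)), "invalid-input")
})
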