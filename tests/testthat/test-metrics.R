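test_that("diode band selection uses inclusive 60-85% bounds", {
  expect_equal(select_diodes(c(0.5, 0.7, 0.9)), 2L)
  expect_length(select_diodes(rep(2.5, 10)), 0)  # everything at the max
  expect_equal(select_diodes(c(0.60, 0.85, 1.0)), c(1L, 2L))  # inclusive
  expect_warning(out <- select_diodes(rep(0, 5)), "zero")
  expect_length(out, 0)
})

test_that("deviation statistics use the sample sd and mean absolute difference", {
  expect_equal(deviation_stats(1:5, 1:5),
               c(sigma = 0, mad = 0))
  s <- deviation_stats(c(1.1, 0.9), c(1, 1))
  expect_equal(unname(s["mad"]), 0.1)
  expect_equal(unname(s["sigma"]), sqrt(2) * 0.1, tolerance = 1e-12)
  # a constant offset is invisible to sigma but not to the MAD
  s <- deviation_stats(c(1.2, 1.2, 1.2), c(1, 1, 1))
  expect_equal(unname(s["sigma"]), 0)
  expect_equal(unname(s["mad"]), 0.2)
  expect_error(deviation_stats(1:3, 1:3, selection = 2), "at least two")
  expect_error(deviation_stats(1:3, 1:4), "length")
})

test_that("deviation series evaluates cumulative doses at each MU point", {
  mu <- c(10, 20, 30)
  meas <- matrix(c(1, 2, 3, 1, 2, 3), 3)
  planned <- meas
  calc <- meas + 0.1
  out <- deviation_series(meas, planned, calc, mu, selection = 1:2)
  expect_equal(nrow(out), length(mu))
  expect_true(all(out$sigma_p == 0) && all(out$mad_p == 0))
  expect_true(all(abs(out$mad_c - 0.1) < 1e-12))
  expect_error(deviation_series(meas, planned, calc, mu[1:2], 1:2),
               "misaligned")
})

test_that("dose-volume coverage counts the mask fraction above threshold", {
  g <- water_box(10, 5)
  mask <- rtdose:::grid_like(g, 1)
  rx <- 7.5
  expect_equal(v_threshold(rtdose:::grid_like(g, rx), mask, rx), 100)
  expect_equal(v_threshold(rtdose:::grid_like(g, 0), mask, rx), 0)
  half <- array(0, dim(g$values)); half[1:5, , ] <- rx
  expect_equal(v_threshold(rtdose:::grid_like(g, half), mask, rx), 50)
  # exactly at the threshold counts as covered
  expect_equal(v_threshold(rtdose:::grid_like(g, 0.95 * rx), mask, rx), 100)
  expect_error(v_threshold(rtdose:::grid_like(g, rx),
                           rtdose:::grid_like(g, 0), rx), "empty mask")

  # monotone in dose: adding dose anywhere cannot lower the coverage
  set.seed(1)
  base <- rtdose:::grid_like(g, array(runif(1000, 0, 10), dim(g$values)))
  more <- rtdose:::grid_like(g, base$values +
                               array(runif(1000, 0, 2), dim(g$values)))
  expect_gte(v_threshold(more, mask, rx), v_threshold(base, mask, rx))
})

test_that("gamma analysis matches its closed-form cases", {
  set.seed(3)
  f <- matrix(0, 26, 26)
  f[] <- outer(1:26, 1:26, function(i, j)
    exp(-((i - 13)^2 + (j - 13)^2) / 60))
  g0 <- gamma_index(f, f, spacing_mm = 2)
  expect_equal(g0$pass_rate, 100)
  expect_equal(g0$max_gamma, 0)

  # uniform 2% overdose with a 2% criterion: gamma 1 everywhere, all pass
  u <- matrix(1, 20, 20)
  gu <- gamma_index(u, 1.02 * u, spacing_mm = 2)
  expect_true(all(abs(gu$gamma$values - 1) < 1e-9))
  expect_equal(gu$pass_rate, 100)

  # rescaling reference values that sit below the evaluation threshold
  # changes neither the evaluated set nor the pass rate
  e <- f * 1.01
  sub <- f < 0.05 * max(f)
  f2 <- f; f2[sub] <- 0.5 * f[sub]
  g1 <- gamma_index(f, e, spacing_mm = 2)
  g2 <- gamma_index(f2, e, spacing_mm = 2)
  expect_equal(g2$n_evaluated, g1$n_evaluated)
  expect_equal(g2$pass_rate, g1$pass_rate)

  # tightening either criterion never increases the pass rate
  e <- f * (1 + 0.03 * sin(row(f) / 2))
  loose <- gamma_index(f, e, dd_percent = 3, dta_mm = 3, step_mm = 0.5,
                       spacing_mm = 2)
  tight_dd <- gamma_index(f, e, dd_percent = 2, dta_mm = 3, step_mm = 0.5,
                          spacing_mm = 2)
  tight_dta <- gamma_index(f, e, dd_percent = 3, dta_mm = 2, step_mm = 0.5,
                           spacing_mm = 2)
  expect_lte(tight_dd$pass_rate, loose$pass_rate)
  expect_lte(tight_dta$pass_rate, loose$pass_rate)

  expect_error(gamma_index(0 * f, f, spacing_mm = 2), "threshold")
})

test_that("fast gamma equals the exhaustive brute-force search", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 16
    base <- array(rnorm(n^3), rep(n, 3))
    ref <- voxel_grid(base, spacing = c(3, 3, 3))
    ref <- smooth_grid(ref, 6)
    ref$values <- ref$values - min(ref$values) + 0.1
    ev <- ref
    ev$values <- ev$values * (1 + 0.04 * sin(seq_len(n^3) / 500))
    dta <- 2; dd_abs <- 0.02 * max(ref$values)
    cutoff <- 0.05 * max(ref$values)
    step <- dta / 5
    fast <- rtdose:::cpp_gamma(as.numeric(ref$values), as.numeric(ev$values),
                               dim(ref$values), ref$spacing, ref$origin,
                               dd_abs, dta, cutoff, step)
    brute <- brute_gamma(ref, ev, dd_abs, dta, cutoff, step)
    expect_lt(max(abs(array(fast, dim(ref$values)) - brute), na.rm = TRUE),
              1e-6)
    expect_identical(is.na(as.numeric(brute)), is.na(fast))
  }
})

test_that("doses convert to percentages of the fraction dose", {
  expect_equal(gy_to_percent(0.17, 7.5), 2.3)
  expect_equal(gy_to_percent(0.98, 7.5), 13.1)
  expect_equal(gy_to_percent(0.19, 7.5), 2.5)
  expect_equal(gy_to_percent(0, 3), 0)
  expect_error(gy_to_percent(1, 0), "> 0")
})
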