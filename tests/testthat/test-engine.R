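test_that("radiological depth integrates density exactly along rays", {
  box <- water_box(41, 3)
  src <- c(0, 1435, 0)
  # grid spans y in [-61.5, 61.5]; 5 cm beyond the entry surface
  expect_equal(radiological_depth(box, src, c(0, 61.5 - 50, 0)), 5.0)
  half <- water_box(41, 3, density = 0.5)
  expect_equal(radiological_depth(half, src, c(0, 61.5 - 50, 0)), 2.5)
  # target before the phantom entry: empty path
  expect_equal(radiological_depth(box, src, c(0, 100, 0)), 0.0)
  # zero-length ray
  expect_equal(radiological_depth(box, c(0, 0, 0), c(0, 0, 0)), 0.0)

  # oblique ray cross-checked by dense step sampling
  tgt <- c(20, -40, 15)
  d <- radiological_depth(box, src, tgt)
  tt <- seq(0, 1, length.out = 20001)
  pts <- cbind(src[1] + tt * (tgt[1] - src[1]),
               src[2] + tt * (tgt[2] - src[2]),
               src[3] + tt * (tgt[3] - src[3]))
  inside <- abs(pts[, 1]) <= 61.5 & abs(pts[, 2]) <= 61.5 &
    abs(pts[, 3]) <= 61.5
  step_len <- sqrt(sum((tgt - src)^2)) / (length(tt) - 1)
  d_ref <- sum(inside) * step_len / 10
  expect_equal(d, d_ref, tolerance = 0.01)
})

test_that("aperture fluence reproduces its limit cases", {
  closed <- aperture(0, c(-5, 5, -5, 5), rbind(rep(0, 20), rep(0, 20)))
  f <- aperture_fluence(closed, seq(-60, 60, by = 5), seq(-60, 60, by = 5))
  expect_true(all(f == 0))

  open <- open_aperture(5)
  # sigma -> 0: indicator of the open square
  f <- aperture_fluence(open, c(-49, 0, 49, 51), c(0, 0, 0, 0),
                        penumbra_sigma_mm = 0)
  expect_equal(f[, 1], c(1, 1, 1, 0))
  # finite penumbra: exactly one half at a straight field edge
  f <- aperture_fluence(open, 50, 0, penumbra_sigma_mm = 5)
  expect_equal(as.numeric(f), 0.5, tolerance = 1e-6)
  # fluence never exceeds 1
  f <- aperture_fluence(open, seq(-60, 60, 2), seq(-60, 60, 2),
                        penumbra_sigma_mm = 3)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("segment dose follows the analytic depth-dose model", {
  box <- water_box(41, 3)
  m <- quiet_model()
  ap <- open_aperture(5)

  expect_true(all(compute_segment_dose(box, ap, 0, m)$values == 0))

  # linearity in MU
  d1 <- compute_segment_dose(box, ap, 5, m)
  d2 <- compute_segment_dose(box, ap, 10, m)
  expect_equal(d2$values, 2 * d1$values)

  # central-axis ratio equals attenuation x inverse square
  pts <- rbind(c(0, 30, 0), c(0, -21, 0))
  src <- c(0, m$sad_mm, 0)
  dd <- dose_at_points(box, ap, 10, m, pts)
  dep <- radiological_depth(box, src, pts[1, ]) -
    radiological_depth(box, src, pts[2, ])
  r1 <- m$sad_mm - 30; r2 <- m$sad_mm + 21
  expect_equal(dd[2] / dd[1], exp(m$mu_water_per_cm * dep) * (r1 / r2)^2,
               tolerance = 1e-6)

  # central-axis dose strictly decreases with depth (noise off)
  axis_pts <- cbind(0, seq(55, -55, by = -3), 0)
  prof <- dose_at_points(box, ap, 10, m, axis_pts)
  expect_true(all(diff(prof) < 0))
})

test_that("plan segment doses sum to the full plan dose", {
  ph <- build_phantom("delta4_like", n = 24, spacing_mm = 6, radius_mm = 60,
                      diode_extent_mm = 40)
  plan <- make_plan(4, 6, 7.5, seed = 5, total_mu = 60, field_v_cm = 6)
  m <- quiet_model()
  seg_doses <- plan_segment_doses(plan, ph, m)
  total <- Reduce(`+`, lapply(seg_doses, `[[`, "values"))
  full <- planned_dose_at_mu(plan, ph, plan$total_mu, m)
  expect_lt(max(abs(total - full$values)), 1e-9)
})

test_that("per-voxel noise behaves like independent relative uncertainty", {
  box <- water_box(9, 6)
  m <- beam_model(noise_rel_sd = 0.05)
  nf <- quiet_model()
  ap <- open_aperture(3)
  clean <- compute_segment_dose(box, ap, 10, nf)
  hot <- clean$values >= 0.5 * max(clean$values)

  # deterministic given the seed
  a <- compute_segment_dose(box, ap, 10, m, noise_seed = 42)
  b <- compute_segment_dose(box, ap, 10, m, noise_seed = 42)
  expect_identical(a$values, b$values)

  # relative sd of a single calculation at high-dose voxels is ~5%
  rel <- (a$values[hot] - clean$values[hot]) / clean$values[hot]
  expect_equal(sd(rel), 0.05, tolerance = 0.2)

  # accumulating n equal noisy segments shrinks the relative sd as 1/sqrt(n):
  # slope of log(sd) vs log(n) is -0.5
  reps <- 200
  sds <- vapply(c(1, 4, 16), function(n) {
    rel_sds <- vapply(seq_len(reps), function(r) {
      acc <- 0
      for (j in seq_len(n))
        acc <- acc + compute_segment_dose(box, ap, 10 / n, m,
                                          noise_seed = 1000 * n + 100 * r + j)$values
      mean((acc[hot] - clean$values[hot] * (1)) / (clean$values[hot]))
    }, numeric(1))
    sd(rel_sds)
  }, numeric(1))
  fit <- stats::lm(log(sds) ~ log(c(1, 4, 16)))
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("combined uncertainty follows 1/sqrt(n)", {
  expect_equal(combined_uncertainty(0.05, 3), 0.05 / sqrt(3))
  expect_lt(combined_uncertainty(0.05, 3), 0.03)
  expect_equal(combined_uncertainty(0.05, 1), 0.05)
  expect_error(combined_uncertainty(0.05, 0), ">= 1")
})

test_that("output calibration normalizes the planned CTV mean dose", {
  ph <- build_phantom("delta4_like", n = 24, spacing_mm = 6, radius_mm = 60)
  plan <- make_plan(4, 6, 7.5, seed = 5, total_mu = 60, field_v_cm = 6)
  m <- calibrate_output(plan, ph, quiet_model())
  pd <- planned_dose_at_mu(plan, ph, plan$total_mu, m)
  expect_equal(mean(pd$values[ph$masks$ctv$values != 0]), 1.02 * 7.5,
               tolerance = 1e-6)
})
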