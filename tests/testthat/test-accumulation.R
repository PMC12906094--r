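seg_for <- function(ap, dmu) list(aperture = ap, delta_mu = dmu)

test_that("rigid reconstruction is exact under the frame equivalence", {
  ph <- build_phantom("delta4_like", n = 24, spacing_mm = 6, radius_mm = 60)
  m <- quiet_model()
  ap <- open_aperture(4)

  # identity state reproduces the reference computation
  st0 <- anatomy_state(0, translation = c(0, 0, 0))
  d0 <- reconstruct_segment(ph, st0, seg_for(ap, 10), m)
  expect_equal(d0$values, compute_segment_dose(ph, ap, 10, m)$values)

  # a CC shift displaces the dose pattern by -t on the reference frame:
  # for the z-invariant cylinder this equals sampling the unshifted dose
  # at x + t
  tr <- c(0, 0, 10)
  st <- anatomy_state(0, translation = tr)
  d <- reconstruct_segment(ph, st, seg_for(ap, 10), m)
  pts <- grid_points(ph$density)
  interior <- abs(pts[, 3]) < 50 & pts[, 1]^2 + pts[, 2]^2 < 50^2
  oracle <- dose_at_points(ph, ap, 10, m,
                           cbind(pts[, 1], pts[, 2], pts[, 3] + tr[3]))
  expect_lt(max(abs(as.numeric(d$values)[interior] - oracle[interior])),
            1e-9)
})

test_that("deformable reconstruction matches a point-composed oracle", {
  ph <- build_phantom("waterbag_film")
  m <- quiet_model()
  ap <- open_aperture(5)
  u <- roll_dvf(ph$density, c(0, 0, -25), 14, 15)
  inv <- invert_dvf(u)
  st <- anatomy_state(0, u = u, dvf_inv = inv)
  d <- reconstruct_segment(ph, st, seg_for(ap, 50), m)

  # oracle: evaluate the dose on the deformed anatomy directly at the
  # pulled-back film points (no dose-grid resampling)
  dens_cur <- warp_volume(ph$density, u, fill = ph$densities$air)
  fpts <- ph$film$points
  cur_pts <- fpts + rtdose:::sample_dvf(inv, fpts)
  oracle <- dose_at_points(dens_cur, ap, 50, m, cur_pts)
  got <- interp_grid(d, fpts)
  expect_lt(max(abs(got - oracle)) / max(oracle), 0.02)
})

test_that("accumulation keeps its MU ledger and adds element-wise", {
  g <- water_box(12, 6)
  acc <- new_accumulated(g)
  m <- quiet_model()
  ap <- open_aperture(3)
  d1 <- compute_segment_dose(g, ap, 4, m)
  acc <- accumulate(acc, d1, 4, state_id = 1)
  acc <- accumulate(acc, d1, 2.5, state_id = 2)
  expect_equal(acc$delivered_mu, 6.5)
  expect_equal(sum(acc$ledger$delta_mu), acc$delivered_mu)
  expect_equal(acc$dose$values, 2 * d1$values)
  expect_error(accumulate(acc, d1, 0), "> 0")
  expect_error(accumulate(acc, compute_segment_dose(water_box(10), ap, 1, m), 1),
               "grids do not match")
})

test_that("planned dose to a given MU splits the straddled segment linearly", {
  ph <- build_phantom("delta4_like", n = 24, spacing_mm = 6, radius_mm = 60)
  m <- quiet_model()
  segs <- make_plan(2, 6, 7.5, seed = 6, total_mu = 200,
                    field_v_cm = 6)$segments
  segs[[1]]$mu <- 100; segs[[2]]$mu <- 100
  plan <- treatment_plan(segs, 7.5)
  sd_ <- plan_segment_doses(plan, ph, m)
  expect_true(all(planned_dose_at_mu(plan, ph, 0, m, sd_)$values == 0))
  expect_equal(planned_dose_at_mu(plan, ph, plan$total_mu, m, sd_)$values,
               sd_[[1]]$values + sd_[[2]]$values)
  half <- planned_dose_at_mu(plan, ph, 150, m, sd_)
  expect_equal(half$values, sd_[[1]]$values + 0.5 * sd_[[2]]$values)
  expect_error(planned_dose_at_mu(plan, ph, 201, m, sd_), "outside")
})

test_that("forecasts are consistent with the planned dose for identity states", {
  ph <- build_phantom("delta4_like", n = 24, spacing_mm = 6, radius_mm = 60)
  plan <- make_plan(3, 6, 7.5, seed = 6, total_mu = 45, field_v_cm = 6)
  m <- calibrate_output(plan, ph, quiet_model())
  ctv <- ph$masks$ctv
  full <- planned_dose_at_mu(plan, ph, plan$total_mu, m)
  v95_plan <- v_threshold(full, ctv, plan$prescription_gy)
  st0 <- anatomy_state(0, translation = c(0, 0, 0))

  # nothing delivered: forecast equals the full planned dose
  acc0 <- new_accumulated(ph)
  fc <- forecast_dose(acc0, plan, st0, ph, m, ctv)
  expect_lt(max(abs(fc$dose$values - full$values)), 1e-9)
  expect_equal(fc$v95, v95_plan)

  # partially delivered on static anatomy: the two decompositions agree
  for (mu_cut in c(20, 37.5)) {
    acc <- new_accumulated(ph)
    acc$dose <- planned_dose_at_mu(plan, ph, mu_cut, m)
    acc$delivered_mu <- mu_cut
    fc <- forecast_dose(acc, plan, st0, ph, m, ctv)
    expect_lt(max(abs(fc$dose$values - full$values)), 1e-9)
  }

  # fully delivered: forecast equals the accumulation exactly
  accf <- new_accumulated(ph)
  accf$dose <- full
  accf$delivered_mu <- plan$total_mu
  fc <- forecast_dose(accf, plan, st0, ph, m, ctv)
  expect_identical(fc$dose$values, full$values)
  expect_equal(fc$n_remaining, 0)
})
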