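test_that("water cylinder phantom is homogeneous with an air surround", {
  ph <- build_phantom("water_cylinder", n = 32, spacing_mm = 3,
                      radius_mm = 40)
  pts <- grid_points(ph$density)
  incyl <- pts[, 1]^2 + pts[, 2]^2 <= 40^2
  expect_true(all(ph$density$values[incyl] == 1.0))
  expect_true(all(ph$density$values[!incyl] <= 0.0012))
  expect_error(build_phantom("water_cylinder", n = 16, radius_mm = 90),
               "exceeds")
})

test_that("diode phantom carries a lattice of interior diodes and a CTV", {
  ph <- build_phantom("delta4_like", n = 32, spacing_mm = 6,
                      radius_mm = 80, diode_extent_mm = 50,
                      diode_spacing_mm = 5)
  d <- ph$diodes
  # positions distinct and inside the cylinder
  expect_false(any(duplicated(d[, c("x_mm", "y_mm", "z_mm")])))
  expect_true(all(d$x_mm^2 + d$y_mm^2 <= 80^2))
  # two orthogonal planes: every diode on y = 0 or x = 0
  expect_true(all(d$y_mm == 0 | d$x_mm == 0))
  # lattice size: 21 x 21 per plane minus the duplicated common line
  expect_equal(nrow(d), 2 * 21 * 21 - 21)
  expect_equal(ph$readout_hz, 40)
  # CTV sits inside the body
  expect_true(all(ph$masks$body$values[ph$masks$ctv$values != 0] == 1))
})

test_that("water-bag film phantom has the film at the interface and markers", {
  ph <- build_phantom("waterbag_film")
  expect_equal(ph$film$plane_y_mm, 0)
  f <- ph$film$points
  # film pixels straddle the water(1.0)/slab(1.02) interface
  above <- interp_grid(ph$density, cbind(f[, 1], 3, f[, 3]))
  below <- interp_grid(ph$density, cbind(f[, 1], -3, f[, 3]))
  expect_true(all(abs(above - 1.0) < 0.02))
  expect_true(all(abs(below - 1.02) < 0.02))
  # fiducial markers visible in the image channel at the film ends
  for (i in 1:2) {
    v <- interp_grid(ph$image, rbind(ph$markers[i, ]))
    expect_gt(v, 1.2)
  }
})

test_that("generated plans are reproducible and conserve MU", {
  plan <- make_plan(9, 8, 7.5, seed = 1)
  expect_equal(plan$total_mu,
               sum(vapply(plan$segments, `[[`, numeric(1), "mu")))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_plan_json(make_plan(9, 8, 7.5, seed = 1), f1)
  write_plan_json(make_plan(9, 8, 7.5, seed = 1), f2)
  expect_identical(readLines(f1), readLines(f2))

  # single open field of the deformable test: a 10 x 10 cm aperture
  p1 <- make_plan(1, 10, 7.5, seed = 2, field_v_cm = 10)
  s <- p1$segments[[1]]
  expect_equal(s$gantry_deg, 0)
  expect_equal(s$jaws_cm, c(-5, 5, -5, 5))
  expect_true(all(s$mlc_cm[1, ] == -5) && all(s$mlc_cm[2, ] == 5))
})

test_that("generated streams respect rate, holds and plan boundaries", {
  plan <- make_plan(3, 8, 7.5, seed = 4, total_mu = 42)
  st <- gen_stream(plan, msg_rate_hz = 5)
  t <- vapply(st, `[[`, numeric(1), "t")
  expect_equal(unique(round(diff(t), 10)), 0.2)
  expect_equal(st[[length(st)]]$mu, plan$total_mu)

  # each streamed segment lies within a single plan segment
  segs <- make_segments(st)
  cum <- c(0, cumsum(vapply(plan$segments, `[[`, numeric(1), "mu")))
  mu_at <- function(tt) st[[which(t == tt)]]$mu
  for (s in segs) {
    lo <- mu_at(s$t_start); hi <- lo + s$delta_mu
    bin_lo <- findInterval(lo + 1e-9, cum)
    bin_hi <- findInterval(hi - 1e-9, cum)
    expect_equal(bin_lo, bin_hi)
  }

  # an inserted hold suppresses beam and MU over the window
  st2 <- gen_stream(plan, beam_holds = list(c(1, 2)))
  t2 <- vapply(st2, `[[`, numeric(1), "t")
  inhold <- t2 >= 1 & t2 < 2
  expect_true(all(!vapply(st2, `[[`, logical(1), "beam_on")[inhold]))
  mus <- vapply(st2, `[[`, numeric(1), "mu")
  expect_equal(diff(range(mus[t2 >= 1 & t2 <= 2])), 0)
  expect_equal(st2[[length(st2)]]$mu, plan$total_mu)

  # degenerate dose rate: MU stays flat, no segments downstream
  st3 <- gen_stream(plan, dose_rate_mu_per_min = 0)
  expect_length(make_segments(st3), 0)
})

test_that("motion traces match their stated shapes", {
  m <- gen_motion("static", 10)
  expect_true(all(m[, c("dx_mm", "dy_mm", "dz_mm")] == 0))

  m <- gen_motion("linear_drift", 10, amplitude_mm = 10)
  expect_equal(unname(as.numeric(m[nrow(m), c("dx_mm", "dy_mm", "dz_mm")])),
               c(0, 0, 10))
  expect_true(all(diff(m$dz_mm) >= 0))  # monotone CC drift
  expect_true(all(m$dx_mm == 0) && all(m$dy_mm == 0))

  m <- gen_motion("patient_like", 100, apex_mm = 8, return_to_mm = 2)
  expect_equal(max(abs(m$dz_mm)), 8)
  expect_equal(abs(m$dz_mm[nrow(m)]), 2)

  expect_error(gen_motion("wobble", 10))
  expect_error(gen_motion("static", -1))
})

test_that("the roll displacement field is a bounded smooth ridge", {
  # odd grid so the crest lies exactly on a voxel center
  g <- voxel_grid(array(1, c(31, 31, 31)), spacing = c(3, 3, 3))
  u0 <- roll_dvf(g, c(0, 0, 0), 0, 15)
  expect_equal(max(abs(u0$d)), 0)

  u <- roll_dvf(g, c(0, 0, 0), 10, 12)
  mag <- sqrt(u$d[, , , 1]^2 + u$d[, , , 2]^2 + u$d[, , , 3]^2)
  expect_equal(max(mag), 10, tolerance = 1e-6)
  # decayed below 1% of the amplitude beyond 3 widths from the ridge
  pts <- grid_points(g)
  far <- sqrt(pts[, 2]^2 + pts[, 3]^2) > 3 * 12
  expect_lt(max(mag[far]), 0.01 * 10)
  # zero at the grid boundary
  expect_equal(max(abs(u$d[1, , , ])), 0)
  expect_equal(max(abs(u$d[, 1, , ])), 0)
  # smoothness: neighbour differences bounded by amplitude/width * spacing * 2
  expect_lt(rtdose:::max_neighbour_diff(u), 2 * 10 / 12 * 3)
})

test_that("virtual diode measurement reproduces the plan when static", {
  ph <- build_phantom("delta4_like", n = 32, spacing_mm = 6, radius_mm = 80)
  plan <- make_plan(3, 8, 7.5, seed = 4, total_mu = 42)
  m <- quiet_model()
  st <- gen_stream(plan)
  motion <- gen_motion("static", st[[length(st)]]$t + 1)
  meas <- virtual_measurement(ph, st, m, motion = motion)
  pts <- as.matrix(ph$diodes[, c("x_mm", "y_mm", "z_mm")])
  planned <- Reduce(`+`, lapply(seq_along(plan$segments), function(i)
    dose_at_points(ph, plan$segments[[i]], plan$segments[[i]]$mu, m, pts)))
  expect_lt(max(abs(meas$final - planned)), 1e-9)

  # readout sample count at the diode rate
  t_end <- st[[length(st)]]$t
  expect_length(meas$times, ceiling(t_end * 40))

  # a rigid CC shift changes a gradient diode by ~gradient x shift
  shift <- 10
  motion2 <- gen_motion("static", t_end + 1)
  motion2$dz_mm <- shift
  meas2 <- virtual_measurement(ph, st, m, motion = motion2)
  band <- select_diodes(planned)
  # finite-difference oracle for the planned dose field at the diodes
  grad <- (Reduce(`+`, lapply(seq_along(plan$segments), function(i)
    dose_at_points(ph, plan$segments[[i]], plan$segments[[i]]$mu, m,
                   cbind(pts[, 1], pts[, 2], pts[, 3] + shift)))) - planned)
  moved <- meas2$final - planned
  big <- band[abs(grad[band]) > 0.1 * max(abs(grad))]
  expect_lt(median(abs(moved[big] - grad[big]) / abs(grad[big])), 0.1)
})
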