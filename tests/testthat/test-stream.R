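test_that("segments are built from beam-on control-point pairs", {
  # beam never on -> no segments
  st <- toy_stream(t = c(0, 0.2, 0.4), mu = c(0, 0, 0), on = c(FALSE, FALSE, FALSE))
  expect_length(make_segments(st), 0)

  # continuous delivery at 420 MU/min sampled at 5 Hz -> 1.4 MU per segment
  t <- seq(0, 4, by = 0.2)
  mu <- 7 * t
  st <- toy_stream(t, mu, on = c(rep(TRUE, length(t) - 1), FALSE))
  segs <- make_segments(st)
  expect_length(segs, length(t) - 1)
  expect_equal(vapply(segs, `[[`, numeric(1), "delta_mu"),
               rep(1.4, length(t) - 1))

  # hand-enumerated pairs: beam on across (1,2) and (3,4) only
  st <- toy_stream(c(0, 1, 2, 3), c(0, 2, 2, 5),
                   on = c(TRUE, FALSE, TRUE, FALSE))
  segs <- make_segments(st)
  expect_length(segs, 2)
  expect_equal(vapply(segs, `[[`, numeric(1), "delta_mu"), c(2, 3))
  expect_equal(vapply(segs, `[[`, numeric(1), "t_start"), c(0, 2))

  # re-running yields identical segments, ordered in time
  expect_identical(segs, make_segments(st))

  # segment MU sums to the beam-on MU increase
  expect_equal(sum(vapply(segs, `[[`, numeric(1), "delta_mu")), 5)
})

test_that("invalid streams are rejected with the offending index", {
  ap <- open_aperture()
  expect_error(linac_stream(c(0, 0.2, 0.1), c(0, 1, 2), rep(TRUE, 3), ap),
               "timestamp at message 3")
  expect_error(linac_stream(c(0, 0.2, 0.4), c(0, 2, 1), rep(TRUE, 3), ap),
               "decreasing cumulative MU at message 3")
  expect_error(linac_stream(c(0, 0.2, 0.4), c(0, 1, 2), c(FALSE, TRUE, FALSE), ap),
               "beam off at message 1")
  expect_error(aperture(0, c(-5, 5, -5, 5), rbind(1, -1)), "cross")
})

test_that("motion sync pairs nearest samples, earlier on ties, holds last", {
  st <- toy_stream(c(0, 0.2, 0.4), c(0, 1, 2), c(TRUE, TRUE, FALSE))
  motion <- data.frame(t = c(0, 0.2, 0.4), dx_mm = 1:3, dy_mm = 0, dz_mm = 0)
  expect_equal(sync_motion(st, motion)[, 1], c(1, 2, 3))

  # message at 0.20 equidistant from samples at 0.15 and 0.25 -> earlier
  st1 <- toy_stream(0.20, 5, TRUE)
  motion <- data.frame(t = c(0.15, 0.25), dx_mm = c(10, 20), dy_mm = 0,
                       dz_mm = 0)
  expect_equal(sync_motion(st1, motion)[1, 1], 10)

  # motion ends early -> last sample held
  st2 <- toy_stream(c(0, 5, 10), c(0, 1, 2), c(TRUE, TRUE, FALSE))
  motion <- data.frame(t = c(0, 5), dx_mm = 0, dy_mm = 0, dz_mm = c(0, 7))
  expect_equal(sync_motion(st2, motion)[, 3], c(0, 7, 7))

  expect_error(sync_motion(st2, motion[0, ]), "empty motion")
})

test_that("duty cycle follows the first-beam-on to last-beam-off definition", {
  mk <- function(t, on)
    toy_stream(t, cumsum(c(0, utils::head(on, -1) * diff(t) * 7)), on)
  t <- seq(0, 10, by = 0.2)
  # continuously on
  st <- mk(t, c(rep(TRUE, length(t) - 1), FALSE))
  expect_equal(duty_cycle(st), 1.0)
  # on 0-6, off 6-8, on 8-10 -> 8 s on over a 10 s span
  on <- t < 6 | (t >= 8 & t < 10)
  st <- mk(t, on)
  expect_equal(duty_cycle(st), 0.8)
  # on 0-5 only: the denominator ends at the last beam-off
  on <- t < 5
  st <- mk(t, on)
  expect_equal(duty_cycle(st), 1.0)
  # inserting a hold strictly decreases the duty cycle
  on2 <- (t < 2 | t >= 3) & t < 5
  expect_lt(duty_cycle(mk(t, on2)), 1.0)
  # no beam-on interval -> undefined
  expect_error(duty_cycle(mk(t, rep(FALSE, length(t)))), "no beam-on")
})

test_that("plan remainder preserves MU and splits the straddled segment", {
  plan <- make_plan(2, 8, 7.5, seed = 3, total_mu = 200)
  plan$segments[[1]]$mu <- 100
  plan$segments[[2]]$mu <- 100
  plan <- treatment_plan(plan$segments, 7.5)
  expect_length(plan_remaining(plan, 0), 2)
  expect_length(plan_remaining(plan, plan$total_mu), 0)
  rem <- plan_remaining(plan, 150)
  expect_length(rem, 1)
  expect_equal(rem[[1]]$mu, 50)
  expect_error(plan_remaining(plan, 201), "outside")

  # MU conservation at arbitrary cut points
  for (cut in c(0, 37.5, 100, 140.2)) {
    expect_equal(sum(vapply(plan_remaining(plan, cut), `[[`, numeric(1), "mu")),
                 plan$total_mu - cut)
  }
})

test_that("streams, motion traces and plans round-trip through their files", {
  plan <- make_plan(3, 8, 7.5, seed = 4, total_mu = 30)
  st <- gen_stream(plan)
  f <- withr::local_tempfile()
  write_stream_jsonl(st, f)
  st2 <- read_stream_jsonl(f)
  expect_equal(vapply(st, `[[`, numeric(1), "mu"),
               vapply(st2, `[[`, numeric(1), "mu"))
  expect_identical(make_segments(st)[[1]]$aperture,
                   make_segments(st2)[[1]]$aperture)

  motion <- gen_motion("linear_drift", 5)
  fm <- withr::local_tempfile()
  write_motion_jsonl(motion, fm)
  expect_equal(read_motion_jsonl(fm), motion, ignore_attr = TRUE)

  fp <- withr::local_tempfile()
  write_plan_json(plan, fp)
  expect_equal(read_plan_json(fp), plan)
})
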