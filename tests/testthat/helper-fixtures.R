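# shared fixtures built in code

water_box <- function(n = 21, spacing = 3, density = 1.0) {
  voxel_grid(array(density, rep(n, 3)), spacing = rep(spacing, 3))
}

open_aperture <- function(half_cm = 5, gantry = 0, n_leaves = 20) {
  aperture(gantry, c(-half_cm, half_cm, -half_cm, half_cm),
           rbind(rep(-half_cm, n_leaves), rep(half_cm, n_leaves)))
}

quiet_model <- function(...) beam_model(noise_rel_sd = 0, ...)

# minimal hand-built stream: messages at `t` with cumulative `mu` and
# beam flags, constant aperture
toy_stream <- function(t, mu, on, ap = open_aperture()) {
  linac_stream(t, mu, on, ap)
}

# textured spherical object for registration tests (intensity gradient
# everywhere inside the object, as in a structured MR volume)
textured_blob <- function(n = 32, spacing = 3, seed = 7) {
  g <- voxel_grid(array(0, rep(n, 3)), spacing = rep(spacing, 3))
  pts <- grid_points(g)
  blob <- exp(-(pts[, 1]^2 + pts[, 2]^2 + pts[, 3]^2) / (2 * 25^2))
  set.seed(seed)
  tex <- smooth_grid(voxel_grid(array(rnorm(n^3), rep(n, 3)),
                                spacing = rep(spacing, 3)), 6)
  tex$values <- tex$values / sd(tex$values) * 0.25
  g$values <- array(blob, rep(n, 3)) + tex$values * (blob > 0.2)
  g
}

# sessions used by several acceptance checks, computed once per test run
.session_cache <- new.env(parent = emptyenv())

acceptance_phantom <- function() {
  if (is.null(.session_cache$ph))
    .session_cache$ph <- build_phantom("delta4_like")
  .session_cache$ph
}

acceptance_plan <- function() {
  if (is.null(.session_cache$plan))
    .session_cache$plan <- make_plan(9, 8, 7.5, seed = 1, total_mu = 240)
  .session_cache$plan
}

acceptance_model <- function() {
  if (is.null(.session_cache$model))
    .session_cache$model <- calibrate_output(acceptance_plan(),
                                             acceptance_phantom(),
                                             beam_model())
  .session_cache$model
}

acceptance_session <- function(kind) {
  key <- paste0("session_", kind)
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- switch(
      kind,
      static = {
        m <- acceptance_model(); m$noise_rel_sd <- 0
        run_session(acceptance_plan(), acceptance_phantom(),
                    rigid_scenario("static"), m, session_config(), seed = 11)
      },
      drift = run_session(acceptance_plan(), acceptance_phantom(),
                          rigid_scenario("linear_drift", amplitude_mm = 10),
                          acceptance_model(), session_config(), seed = 11),
      deformable = {
        plan <- make_plan(1, 10, prescription_gy = 7.5, seed = 2,
                          total_mu = 120, field_v_cm = 10)
        run_session(plan, build_phantom("waterbag_film"),
                    roll_scenario(), beam_model(), session_config(),
                    seed = 5)
      })
  }
  .session_cache[[key]]
}

# exhaustive gamma search over the same candidate lattice as the fast
# implementation, written independently in plain R: no early termination,
# own trilinear interpolation, looping over offsets with vectorized point
# evaluation
brute_gamma <- function(reference, evaluated, dd_abs, dta, cutoff, step) {
  dm <- dim(reference$values)
  sp <- reference$spacing
  org <- reference$origin
  ax <- function(k) if (dm[k] > 1) seq(-3 * dta, 3 * dta, by = step) else 0
  offs <- expand.grid(x = ax(1), y = ax(2), z = ax(3))
  offs <- offs[offs$x^2 + offs$y^2 + offs$z^2 <= (3 * dta)^2 + 1e-12, ]
  pts <- grid_points(reference)
  ev <- evaluated$values
  tri <- function(p) {
    # vectorized trilinear sample of `ev`; NA outside the hull
    f1 <- (p[, 1] - org[1]) / sp[1]
    f2 <- (p[, 2] - org[2]) / sp[2]
    f3 <- (p[, 3] - org[3]) / sp[3]
    bad <- f1 < 0 | f2 < 0 | f3 < 0 |
      f1 > dm[1] - 1 | f2 > dm[2] - 1 | f3 > dm[3] - 1
    i1 <- pmin(floor(f1), max(dm[1] - 2, 0)); t1 <- if (dm[1] > 1) f1 - i1 else 0
    i2 <- pmin(floor(f2), max(dm[2] - 2, 0)); t2 <- if (dm[2] > 1) f2 - i2 else 0
    i3 <- pmin(floor(f3), max(dm[3] - 2, 0)); t3 <- if (dm[3] > 1) f3 - i3 else 0
    i1[bad] <- 0; i2[bad] <- 0; i3[bad] <- 0
    s2 <- dm[1]; s3 <- dm[1] * dm[2]
    d1 <- as.integer(dm[1] > 1); d2 <- as.integer(dm[2] > 1)
    d3 <- as.integer(dm[3] > 1)
    base <- 1 + i1 + i2 * s2 + i3 * s3
    val <- (1 - t1) * (1 - t2) * (1 - t3) * ev[base] +
      t1 * (1 - t2) * (1 - t3) * ev[base + d1] +
      (1 - t1) * t2 * (1 - t3) * ev[base + d2 * s2] +
      t1 * t2 * (1 - t3) * ev[base + d1 + d2 * s2] +
      (1 - t1) * (1 - t2) * t3 * ev[base + d3 * s3] +
      t1 * (1 - t2) * t3 * ev[base + d1 + d3 * s3] +
      (1 - t1) * t2 * t3 * ev[base + d2 * s2 + d3 * s3] +
      t1 * t2 * t3 * ev[base + d1 + d2 * s2 + d3 * s3]
    val[bad] <- NA_real_
    val
  }
  dr <- as.numeric(reference$values)
  best <- rep(Inf, length(dr))
  for (o in seq_len(nrow(offs))) {
    p <- cbind(pts[, 1] + offs$x[o], pts[, 2] + offs$y[o],
               pts[, 3] + offs$z[o])
    de <- tri(p)
    g2 <- (offs$x[o]^2 + offs$y[o]^2 + offs$z[o]^2) / dta^2 +
      (de - dr)^2 / dd_abs^2
    upd <- !is.na(g2) & g2 < best
    best[upd] <- g2[upd]
  }
  out <- sqrt(best)
  out[dr < cutoff] <- NA_real_
  array(out, dm)
}
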