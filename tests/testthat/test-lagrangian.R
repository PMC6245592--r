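test_that("a uniform flow translates the particle in a straight line", {
  g <- grid2d(16)
  v <- velocity_field(g, matrix(1e-4, 16, 16), matrix(5e-5, 16, 16))
  tr <- trace_particle(v, c(0.001, 0.001), T = 50, dt = 0.1)
  expect_equal(tr$x, 0.001 + 1e-4 * tr$t, tolerance = 1e-12)
  expect_equal(tr$z, 0.001 + 5e-5 * tr$t, tolerance = 1e-12)
  expect_true(all(diff(tr$t) > 0))
})

test_that("the streamfunction is an invariant of motion in the analytic vortex", {
  g <- grid2d(48)
  v <- analytic_vortex(g, 1e-6)
  psi <- attr(v, "psi_fun")
  tr <- trace_particle(v, c(0.005, 0.01), T = 200, dt = 0.02)
  vals <- psi(tr$x, tr$z)
  expect_lt(max(abs(vals - vals[1])) / abs(vals[1]), 1e-10)
  # interpolated velocities stay close to the analytic streamline too
  tri <- trace_particle(v, c(0.005, 0.01), T = 200, dt = 0.02, exact = FALSE)
  vi <- psi(tri$x, tri$z)
  expect_lt(max(abs(vi - vi[1])) / abs(vi[1]), 1e-4)
})

test_that("the tracer integrator converges at fourth order in dt", {
  g <- grid2d(32)
  v <- analytic_vortex(g, 2e-6)
  ref <- trace_particle(v, c(0.004, 0.012), T = 40, dt = 0.005)
  endpoint <- function(dt) {
    tr <- trace_particle(v, c(0.004, 0.012), T = 40, dt = dt)
    unlist(tail(tr[, c("x", "z")], 1))
  }
  e1 <- sqrt(sum((endpoint(0.4) - unlist(tail(ref[, c("x", "z")], 1)))^2))
  e2 <- sqrt(sum((endpoint(0.2) - unlist(tail(ref[, c("x", "z")], 1)))^2))
  expect_gt(e1 / e2, 10)   # ~16 expected for RK4
})

test_that("particles never leave the closed domain and corners are flagged", {
  g <- grid2d(24)
  fld <- solve_cavity(400, g)
  tr <- trace_particle(fld, c(0.001, 0.0195), T = 120, dt = 0.01)
  expect_true(all(tr$x >= 0 & tr$x <= g$L & tr$z >= 0 & tr$z <= g$L))
  # the analytic vortex has exactly zero velocity at the corner (bilinear
  # interpolation of the solved field leaves a ~1e-6 m/s residual there)
  vtx <- analytic_vortex(g, 2e-5)
  expect_warning(out <- trace_particle(vtx, c(0, 0), T = 1, dt = 0.1),
                 "stagnation")
  expect_equal(max(abs(out$x)), 0)
})

test_that("irradiance history concatenates trajectory and light field", {
  g <- grid2d(24)
  lf <- table1_light()
  # stationary particle: constant u
  vz0 <- velocity_field(g, matrix(0, 24, 24), matrix(0, 24, 24))
  tr0 <- suppressWarnings(trace_particle(vz0, c(0.01, 0.005), T = 10, dt = 0.1))
  h0 <- irradiance_history(tr0, lf)
  expect_equal(max(h0$u) - min(h0$u), 0)
  expect_equal(h0$u[1], irradiance_at(lf, 0.005))
  # transparent medium: constant u regardless of motion
  v <- analytic_vortex(g, 1e-5)
  tr <- trace_particle(v, c(0.005, 0.01), T = 60, dt = 0.02)
  clear <- light_field(L = 0.02, Lambda = 0, u0 = 2)
  expect_equal(range(irradiance_history(tr, clear)$u), c(2, 2))
  # a depth-spanning orbit cycles between bright and dark extremes
  h <- irradiance_history(tr, lf)
  expect_equal(min(h$u), lf$u0 * exp(-lf$Lambda * max(tr$z)), tolerance = 1e-12)
  expect_equal(max(h$u), lf$u0 * exp(-lf$Lambda * min(tr$z)), tolerance = 1e-12)
  expect_gt(max(h$u) / min(h$u), 5)   # strong light/dark contrast
  # and does so periodically: successive orbit maxima agree
  pk <- which(diff(sign(diff(h$u))) < 0) + 1L
  if (length(pk) >= 2) {
    expect_lt(abs(h$u[pk[1]] - h$u[pk[2]]) / h$u[pk[1]], 0.01)
  }
})

test_that("kinetics along a constant history reduces to the plain ODE", {
  h <- make_history(seq(0, 100, 0.5), 1)
  out <- kinetics_along(h, case_study_reparam(), dt_out = 1)
  ref <- simulate_psf(1, c(1, 0, 0), c(0, 100), dt_out = 1,
                      reparam = case_study_reparam())
  expect_equal(out$yA, ref$yA, tolerance = 1e-7)
})

test_that("fast light/dark cycles average the generator: the flashing-light limit", {
  rp <- case_study_reparam()
  y1 <- as.numeric(psf_steady_state(1, rp))
  t <- seq(0, 50, 0.025)
  fast <- make_history(t, square_signal(2, 0, 0.5)(t))   # period 0.5 s, mean 1
  out <- kinetics_along(fast, rp, y0 = y1, dt_out = 0.05)
  avg <- mean(out$yA[out$t >= 10])
  expect_equal(avg, 0.625, tolerance = 0.02)   # yA_ss(mean u)
})

test_that("slow cycles follow the quasi-static steady-state curve instead", {
  rp <- case_study_reparam()
  y05 <- as.numeric(psf_steady_state(0.5, rp))
  t <- seq(0, 30000, 10)
  slow <- make_history(t, square_signal(0.5, 1.5, 30000)(t))
  out <- kinetics_along(slow, rp, y0 = y05, dt_out = 20)
  quasi <- (yA_ss(0.5) + yA_ss(1.5)) / 2
  expect_equal(mean(out$yA), quasi, tolerance = 0.02)
})

test_that("for equal mean light, fast cycling outperforms slow cycling", {
  rp <- case_study_reparam()
  y1 <- as.numeric(psf_steady_state(1, rp))
  t <- seq(0, 120, 0.025)
  fast <- kinetics_along(make_history(t, square_signal(2, 0, 0.5)(t)),
                         rp, y0 = y1, dt_out = 0.1)
  slow <- kinetics_along(make_history(t, square_signal(2, 0, 40)(t)),
                         rp, y0 = y1, dt_out = 0.1)
  expect_gt(mean(fast$yA[fast$t >= 10]), mean(slow$yA[slow$t >= 10]) + 0.05)
})

test_that("Eulerian and Lagrangian descriptions agree along a closed streamline", {
  g <- grid2d(32)
  lf <- table1_light()
  rp <- case_study_reparam()
  A <- 2e-5
  v <- analytic_vortex(g, A)
  cfg <- transport_config(De = 0, dt = 0.05, T = 400, reaction = "full",
                          mixing = "advect", dt_out = 50)
  eul <- simulate_transport(v, lf, rp, cfg)
  tr <- trace_particle(v, c(0.005, 0.01), T = 400, dt = 0.02)
  lag <- kinetics_along(irradiance_history(tr, lf), rp, dt_out = 0.5)
  lag_avg <- mean(lag$yA[lag$t >= 300])
  # cells within the same streamline band (5% of psi)
  psi0 <- attr(v, "psi_fun")(0.005, 0.01)
  psic <- A * outer(sin(pi * g$xc / g$L), sin(pi * g$zc / g$L))
  band <- abs(psic - psi0) < 0.05 * abs(psi0)
  expect_gt(sum(band), 10)
  eul_avg <- mean(eul$fields$yA[band])
  expect_lt(abs(lag_avg - eul_avg), 0.05)
})
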