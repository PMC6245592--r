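test_that("species fields validate the simplex invariants", {
  g <- grid2d(8)
  f <- species_fields(g)
  expect_equal(mean(f$yR), 1)
  expect_error(species_fields(g, yR = 0.5, yA = 0.2, yB = 0.2), "equal 1")
  expect_error(species_fields(g, yR = 1.5, yA = -0.5, yB = 0), "\\[0, 1\\]")
  expect_error(transport_config(dt = -1), "dt")
  expect_error(transport_config(De = -1), "De")
  expect_error(transport_config(advection_order = 3), "advection_order")
})

test_that("a step with no flow, no dispersion and no reaction is the identity", {
  g <- grid2d(12)
  cfg <- transport_config(De = 0, dt = 0.05, T = 1, reaction = "none",
                          mixing = "none")
  init <- species_fields(g, yR = 0.3, yA = 0.45, yB = 0.25)
  out <- transport_step(init, zero_flow(g), table1_light(), config = cfg)
  expect_identical(out$yA, init$yA)
  expect_identical(out$yR, init$yR)
})

test_that("advection of spatially uniform fields leaves them unchanged", {
  # the streamfunction-based face fluxes are exactly divergence-free, so a
  # constant is advected to itself for any recirculating flow
  g <- grid2d(24)
  init <- species_fields(g, yR = 0.2, yA = 0.5, yB = 0.3)
  for (ord in 1:2) {
    cfg <- transport_config(De = 1e-6, dt = 0.05, T = 2, reaction = "none",
                            mixing = "advect", advection_order = ord)
    res <- simulate_transport(analytic_vortex(g, 2e-5), table1_light(),
                              config = cfg, initial = init)
    expect_lt(max(abs(res$fields$yA - 0.5)), 1e-13)
    expect_lt(max(abs(res$fields$yB - 0.3)), 1e-13)
  }
})

test_that("the reaction sub-step reproduces the per-cell stiff ODE", {
  g <- grid2d(8)
  lf <- table1_light()
  rp <- case_study_reparam()
  cfg <- transport_config(De = 0, dt = 0.025, T = 0.025, reaction = "full",
                          mixing = "none")
  init <- species_fields(g, yR = 0.6, yA = 0.3, yB = 0.1)
  out <- transport_step(init, zero_flow(g), lf, rp, cfg)
  for (j in c(1, 4, 8)) {
    u <- irradiance_at(lf, g$zc[j])
    ode <- simulate_psf(u, c(0.6, 0.3, 0.1), c(0, 0.025), dt_out = 0.025,
                        reparam = rp, rtol = 1e-11, atol = 1e-13)
    expect_equal(out$yA[1, j], tail(ode$yA, 1), tolerance = 1e-8)
    expect_equal(out$yB[1, j], tail(ode$yB, 1), tolerance = 1e-8)
  }
})

test_that("transport conserves the domain total and the per-cell sum", {
  g <- grid2d(32)
  v <- analytic_vortex(g, 3e-5)
  cfg <- transport_config(De = 1e-6, dt = 0.05, T = 500, reaction = "full",
                          mixing = "advect", dt_out = 50)
  res <- simulate_transport(v, table1_light(), case_study_reparam(), cfg)
  expect_lt(res$drift, 1e-8)                         # per-cell sum
  tot <- res$traj$mean_yR + res$traj$mean_yA + res$traj$mean_yB
  expect_lt(max(abs(tot - 1)), 1e-8)                 # domain total over time
  expect_gte(res$fields$t, 500)
})

test_that("an unmixed culture relaxes pointwise to the local steady state", {
  g <- grid2d(16)
  lf <- table1_light()
  rp <- case_study_reparam()
  cfg <- transport_config(De = 0, dt = 0.05, T = 20000, reaction = "full",
                          mixing = "none", dt_out = 1000)
  res <- simulate_transport(zero_flow(g), lf, rp, cfg)
  uz <- irradiance_at(lf, g$zc)
  target <- psf_steady_state(uz, rp)[, "yA"] / (1 + rp$q5)  # exact nullspace
  expect_lt(max(abs(res$fields$yA[1, ] - target)), 1e-4)
  # its spatial mean approaches the closed-form depth average (0.3986)
  expect_equal(mean(res$fields$yA), mean(target), tolerance = 1e-4)
  expect_equal(mean(res$fields$yA), 0.3986, tolerance = 2e-3)
})

test_that("ideal mixing homogenizes the culture and attains the lumped optimum", {
  g <- grid2d(16)
  cfg <- transport_config(dt = 0.05, T = 20000, reaction = "full",
                          mixing = "ideal", dt_out = 1000)
  res <- simulate_transport(zero_flow(g), table1_light(),
                            case_study_reparam(), cfg)
  expect_lt(stats::sd(res$fields$yA), 1e-12)
  expect_equal(mean(res$fields$yA), 0.625, tolerance = 1e-3)
  # the discrete mean irradiance carries the midpoint-quadrature error of the
  # exponential profile, O((Ot/nz)^2) ~ 0.5% at nz = 16; yA sits at its
  # maximum and is insensitive, while yB (nonzero slope) tracks the closed
  # form at the discrete mean exactly
  um <- mean(irradiance_at(table1_light(), g$zc))
  expect_equal(mean(res$fields$yB), psf_steady_state(um, 0.3)[["yB"]],
               tolerance = 1e-4)
  expect_lt(abs(mean(res$fields$yB) - 0.1875), 2e-3)
})

test_that("reduced mode shows no slow photoinhibition transient", {
  g <- grid2d(16)
  cfg <- transport_config(De = 0, dt = 0.05, T = 300, reaction = "reduced",
                          mixing = "none", dt_out = 5)
  res <- simulate_transport(zero_flow(g), table1_light(),
                            case_study_reparam(), cfg)
  # yB pinned at the frozen steady level, yA settled well inside the horizon:
  # the slowest cell (deepest, u ~ 0.02) relaxes at q4(u + q2) ~ 0.16 1/s
  expect_equal(mean(res$fields$yB), 0.1875, tolerance = 1e-12)
  late <- res$traj$mean_yA[res$traj$t >= 150]
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("explicit stability is enforced: rejection without sub-cycling, sub-steps with", {
  g <- grid2d(32)
  v <- analytic_vortex(g, 5e-4)   # peak speed ~0.08 m/s: CFL >> 1 at dt = 0.05
  cfg <- transport_config(De = 1e-6, dt = 0.05, T = 1, reaction = "none",
                          mixing = "advect", subcycle = FALSE)
  expect_error(simulate_transport(v, table1_light(), config = cfg),
               "stability number")
  cfg2 <- transport_config(De = 1e-6, dt = 0.05, T = 1, reaction = "none",
                           mixing = "advect")
  res <- simulate_transport(v, table1_light(), config = cfg2,
                            initial = species_fields(g, 0.2, 0.5, 0.3))
  expect_gt(res$nsub, 1)
  expect_true(all(c("advective", "diffusive", "stability") %in% names(res$cfl)))
  expect_lt(max(abs(res$fields$yA - 0.5)), 1e-12)
})

test_that("steady-state detection flags constant but not drifting trajectories", {
  flat <- data.frame(t = seq(0, 100, 10), mean_yA = 0.5, mean_yB = 0.2)
  d <- steady_state_detect(flat, tol = 1e-6)
  expect_true(d$steady)
  expect_equal(d$time, 10)
  drift <- data.frame(t = seq(0, 100, 10),
                      mean_yA = 0.5 + 1e-3 * seq(0, 100, 10),
                      mean_yB = 0.2)
  expect_false(steady_state_detect(drift, tol = 1e-6)$steady)
})

test_that("the Re=1000 mean activated fraction is grid-independent over a fixed flow", {
  # grid convergence of the species solve is assessed over one well-resolved
  # flow field, restricted exactly through its streamfunction, so that flow
  # discretization does not alias into the transport comparison; the limited
  # second-order scheme is used because first-order upwind diffusion decays
  # only linearly in h
  lf <- table1_light()
  rp <- case_study_reparam()
  vf <- solve_cavity(1000, grid2d(64))
  J <- vapply(c(4, 2), function(f) {
    cfg <- transport_config(De = 1e-6, dt = 0.05, T = 2000, reaction = "full",
                            mixing = "advect", advection_order = 2,
                            dt_out = 200)
    mean(simulate_transport(coarsen_field(vf, f), lf, rp, cfg)$fields$yA)
  }, numeric(1))
  expect_lt(abs(J[2] - J[1]) / J[2], 0.01)
})

test_that("coarsening a streamfunction field preserves exact incompressibility", {
  vf <- analytic_vortex(grid2d(32), 1e-5)
  vc <- coarsen_field(vf, 4)
  expect_equal(vc$grid$nx, 8L)
  expect_lt(max(abs(divergence(vc))), 1e-12)
  expect_error(coarsen_field(vc, 3), "divide")
  raw <- velocity_field(vf$grid, vf$vx, vf$vz)
  expect_error(coarsen_field(raw, 2), "streamfunction")
})

test_that("mean activated fraction becomes steady long before the inhibited pool", {
  # time-scale separation: with the stiffness ratio ~1e3, yA reaches its
  # quasi-steady level in seconds while yB needs hours
  g <- grid2d(16)
  cfg <- transport_config(De = 0, dt = 0.05, T = 600, reaction = "full",
                          mixing = "none", dt_out = 2)
  res <- simulate_transport(zero_flow(g), table1_light(),
                            case_study_reparam(), cfg)
  traj <- res$traj
  relchange <- function(v) abs(diff(v)) / pmax(abs(v[-1]), 1e-12)
  tA <- traj$t[which(relchange(traj$mean_yA) < 1e-4)[1] + 1L]
  tB <- traj$t[which(relchange(traj$mean_yB) < 1e-4)[1] + 1L]
  expect_lt(tA, 60)
  expect_true(is.na(tB) || tB > 10 * tA)
})
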