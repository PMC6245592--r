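test_that("re-parametrization reproduces the published derived constants", {
  q <- reparametrize(wu_merchuk_rates())
  # q1 is the optimal irradiance of 250 uE m-2 s-1; q2 rounds to the 0.3
  # used throughout the case study
  expect_equal(q$q1, 250.105849, tolerance = 1e-8)
  expect_equal(q$q2, 0.30159086, tolerance = 1e-7)
  expect_equal(q$q3, 1.7649832e-3, tolerance = 1e-7)
  expect_equal(q$q4, 0.48395480, tolerance = 1e-7)
  expect_equal(q$q5, 2.9896641e-4, tolerance = 1e-7)
  # internal consistency of the defining relations
  r <- wu_merchuk_rates()
  expect_equal(q$q5, r$beta / r$alpha)
  expect_equal(q$q4, r$alpha * q$q1)
  expect_equal(q$q1, sqrt(r$gamma * r$delta / (r$alpha * r$beta)))
})

test_that("re-parametrization of unit rates gives the hand-computed values", {
  q <- reparametrize(psf_rates(1, 1, 1, 1, kappa = 1))
  expect_equal(unlist(q[c("q1", "q2", "q3", "q4", "q5")]),
               c(q1 = 1, q2 = 0.5, q3 = 1, q4 = 1, q5 = 1))
})

test_that("invalid rate constants are rejected with the offending field named", {
  expect_error(psf_rates(alpha = -1, beta = 1, gamma = 1, delta = 1), "alpha")
  expect_error(psf_rates(alpha = 1, beta = 0, gamma = 1, delta = 1), "beta")
  expect_error(psf_rates(alpha = 1, beta = 1, gamma = 1, delta = 1, Me = -1), "Me")
  expect_error(psf_reparam(1, -0.3, 1, 1, 1), "q2")
})

test_that("the reaction generator conserves total fraction and matches the raw form", {
  rp <- reparametrize(wu_merchuk_rates())
  for (u in c(0, 0.01, 0.3, 1, 5, 50)) {
    expect_equal(colSums(reaction_generator(u, rp)), c(yR = 0, yA = 0, yB = 0),
                 tolerance = 1e-14)
  }
  # normalized form at u = I/q1 equals the original parametrization at I
  I <- 250
  M_raw <- psf_generator(I, wu_merchuk_rates())
  M_q <- reaction_generator(I / rp$q1, rp)
  expect_equal(M_q, M_raw, tolerance = 1e-12)
  expect_error(reaction_generator(-0.1, rp), "u must be >= 0")
})

test_that("generator spectrum: the published eigenvalues, dark limit, and sign pattern", {
  rp <- reparametrize(wu_merchuk_rates())
  # at I = 250 uE m-2 s-1 the nonzero eigenvalues are -0.63 and -0.59e-3 s-1
  ev <- psf_eigenvalues(250 / rp$q1, rp)
  expect_equal(ev[1], -0.6297835, tolerance = 1e-6)
  expect_equal(ev[2], -5.907742e-4, tolerance = 1e-6)
  expect_equal(signif(ev, 2), c(-0.63, -0.00059))
  # dark limit: spectrum of the light-independent part is {0, -gamma, -delta}
  r <- wu_merchuk_rates()
  ev0 <- sort(eigen(psf_generator(0, r), only.values = TRUE)$values)
  expect_equal(ev0, sort(c(0, -r$gamma, -r$delta)), tolerance = 1e-12)
  # for all u >= 0: exactly one zero eigenvalue, two with negative real part
  for (u in c(0.01, 0.1, 0.5, 1, 2, 10, 100)) {
    lam <- eigen(reaction_generator(u, rp), only.values = TRUE)$values
    expect_lt(max(abs(Im(lam))), 1e-12)
    lam <- sort(Re(lam))
    expect_lt(abs(lam[3]), 1e-12 * max(abs(lam)))
    expect_lt(lam[2], 0)
    expect_lt(lam[1], 0)
  }
})

test_that("stiffness ratio is of order 1e3 for the published set, O(1) for balanced rates", {
  rp <- reparametrize(wu_merchuk_rates())
  # at u = 1 the physical irradiance is q1 = 250.106, slightly above the
  # rounded 250 of the printed spectrum, hence 1066.27 rather than 1066.03
  expect_equal(stiffness_ratio(1, rp), 1066.2728, tolerance = 1e-6)
  expect_equal(stiffness_ratio(1, case_study_reparam()), 1060.16, tolerance = 1e-4)
  # balanced rate magnitudes: no time-scale separation
  expect_lt(stiffness_ratio(1, reparametrize(psf_rates(1, 1, 1, 1))), 10)
})

test_that("steady states match the closed forms and the generator nullspace", {
  expect_equal(psf_steady_state(1, 0.3)[["yA"]], 0.625, tolerance = 1e-12)
  expect_equal(psf_steady_state(1, 0.3)[["yB"]], 0.1875, tolerance = 1e-12)
  expect_equal(as.numeric(psf_steady_state(0, 0.3)), c(1, 0, 0))
  s10 <- psf_steady_state(10, 0.3)
  expect_equal(s10[["yB"]], 100 / (100 + 100 / 3 + 1), tolerance = 1e-12)
  expect_equal(s10[["yA"]], 0.2481390, tolerance = 1e-6)
  expect_equal(s10[["yR"]], 0.0074442, tolerance = 1e-5)
  # exact stationary vector: annihilated by M(u) to rounding, for a spread of u
  rp <- case_study_reparam()
  for (u in c(0.01, 0.1, 1, 10, 100)) {
    y <- as.numeric(psf_steady_state(u, rp, exact = TRUE))
    expect_lt(max(abs(reaction_generator(u, rp) %*% y)), 1e-10)
    # the leading-order closed form differs from it only at O(q5)
    y0 <- as.numeric(psf_steady_state(u, rp))
    expect_lt(max(abs(y - y0)), 2 * rp$q5)
  }
  expect_error(psf_steady_state(1, 0.3, exact = TRUE), "q5")
})

test_that("the steady activated fraction is maximized at u = 1", {
  u <- c(0.25, 0.5, 0.9, 0.99, 1, 1.01, 1.1, 2, 4)
  v <- psf_steady_state(u, 0.3)[, "yA"]
  expect_equal(u[which.max(v)], 1)
  expect_true(all(v <= v[u == 1]))
})

test_that("full ODE integration conserves the total and relaxes to the fixed point", {
  rp <- case_study_reparam()
  tr <- simulate_psf(1, c(1, 0, 0), c(0, 20000), dt_out = 200, reparam = rp)
  expect_lt(max(abs(tr$yR + tr$yA + tr$yB - 1)), 1e-8)
  ss <- psf_steady_state(1, rp, exact = TRUE)
  expect_equal(tail(tr$yA, 1), ss[["yA"]], tolerance = 1e-5)
  # starting at the fixed point the trajectory stays there
  tr2 <- simulate_psf(1, as.numeric(ss), c(0, 100), dt_out = 10, reparam = rp)
  expect_lt(max(abs(tr2$yA - ss[["yA"]])), 1e-7)
  expect_error(simulate_psf(-1, c(1, 0, 0), c(0, 10)), ">= 0")
  expect_error(simulate_psf(1, c(1, 0, 0), c(10, 0)), "increasing")
})

test_that("constant light drives two-phase dynamics: fast activation, slow photoinhibition", {
  tr <- simulate_psf(1, c(1, 0, 0), c(0, 5000), dt_out = 1)
  peak_t <- tr$t[which.max(tr$yA)]
  expect_lt(peak_t, 60)                       # fast rise within seconds
  expect_gt(max(tr$yA), tail(tr$yA, 1) + 0.05) # then slow decline
  expect_gt(tail(tr$yB, 1), 0.15)             # as the inhibited pool fills
})

test_that("the fast-reduced model has the right fixed point and relaxation time", {
  rp <- case_study_reparam()
  red <- simulate_psf_reduced(1, 1, yA0 = 0, c(0, 30), dt_out = 0.01, reparam = rp)
  expect_equal(tail(red$yA, 1), 0.625, tolerance = 1e-6)
  # t_r = 1/(q4 (u_av + q2)) = 1.538 s: at t = t_r the gap has shrunk by 1/e
  t_r <- 1 / (rp$q4 * (1 + rp$q2))
  expect_equal(t_r, 1.538462, tolerance = 1e-6)
  i <- which.min(abs(red$t - t_r))
  expect_equal(red$yA[i], 0.625 * (1 - exp(-1)), tolerance = 1e-3)
  # starting at the fixed point: constant
  red2 <- simulate_psf_reduced(1, 1, yA0 = 0.625, c(0, 10), reparam = rp)
  expect_equal(red2$yA, rep(0.625, nrow(red2)))
  expect_error(simulate_psf_reduced(1, 0, 0, c(0, 1)), "u_av")
})

test_that("reduced and full dynamics agree on the fast time scale", {
  # full model started on the slow manifold (yB frozen at its u_av steady
  # level) tracks the scalar reduced model to within 0.02 over 0-40 s
  rp <- case_study_reparam()
  yBf <- yB_ss(1, rp$q2)
  for (u in c(0.5, 1, 2)) {
    full <- simulate_psf(u, c(1 - yBf, 0, yBf), c(0, 40), dt_out = 0.5, reparam = rp)
    red <- simulate_psf_reduced(u, 1, yA0 = 0, c(0, 40), dt_out = 0.5, reparam = rp)
    expect_lt(max(abs(full$yA - red$yA)), 0.02)
  }
})
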