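#' Trace a passive particle through a steady velocity field
#'
#' Integrates `dx/dt = v(x)` with classical 4th-order Runge-Kutta. Cells are
#' massless tracers (no inertia, no shear response): a cell's trajectory,
#' combined with the light field, yields its "irradiance history" — the
#' hydrodynamically induced light/dark cycle that drives the flashing-light
#' effect. The velocity is evaluated by bilinear interpolation of the
#' cell-centered field (or exactly, if the field carries an analytic
#' `velocity_fun` attribute, as [analytic_vortex()] fields do). Walls are
#' impermeable: a particle crossing a wall is specularly reflected, so the
#' trajectory never leaves the closed domain.
#'
#' @param velocity a [velocity_field()].
#' @param x0 numeric length-2, starting position `c(x, z)` (m), inside the
#'   domain.
#' @param T trace horizon (s).
#' @param dt integration step (s).
#' @param exact if `TRUE` and the field has an analytic `velocity_fun`,
#'   evaluate it instead of interpolating (default: use it when available).
#' @return An object of class `trajectory`: data.frame `t, x, z` with the
#'   grid attached as an attribute.
#' @export
trace_particle <- function(velocity, x0, T, dt = 0.01, exact = NA) {
  stopifnot(inherits(velocity, "velocity_field"))
  g <- velocity$grid
  x0 <- as.numeric(x0)
  if (length(x0) != 2L || any(x0 < 0) || x0[1] > g$L || x0[2] > g$L) {
    stop("trace_particle: x0 must be a position inside the domain")
  }
  vfun_exact <- attr(velocity, "velocity_fun")
  use_exact <- if (is.na(exact)) !is.null(vfun_exact) else isTRUE(exact)
  if (use_exact && is.null(vfun_exact)) {
    stop("trace_particle: exact evaluation requested but the field has no velocity_fun")
  }
  vfun <- if (use_exact) vfun_exact else function(x, z) {
    bilinear_velocity(velocity, x, z)
  }
  n <- max(1L, as.integer(ceiling(T / dt)))
  ts <- (0:n) * dt
  xs <- numeric(n + 1); zs <- numeric(n + 1)
  xs[1] <- x0[1]; zs[1] <- x0[2]
  p <- x0
  v0 <- vfun(p[1], p[2])
  if (sqrt(sum(v0^2)) < .Machine$double.eps) {
    # stagnation start (e.g. exact corner): stationary trajectory
    warning("trace_particle: starting point is a stagnation point; ",
            "returning a stationary trajectory")
  }
  for (k in seq_len(n)) {
    k1 <- vfun(p[1], p[2])
    p2 <- p + dt / 2 * k1
    k2 <- vfun(p2[1], p2[2])
    p3 <- p + dt / 2 * k2
    k3 <- vfun(p3[1], p3[2])
    p4 <- p + dt * k3
    k4 <- vfun(p4[1], p4[2])
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    # impermeable walls: specular reflection back into [0, L]^2
    for (d in 1:2) {
      if (p[d] < 0) p[d] <- -p[d]
      if (p[d] > g$L) p[d] <- 2 * g$L - p[d]
      p[d] <- min(max(p[d], 0), g$L)
    }
    xs[k + 1] <- p[1]; zs[k + 1] <- p[2]
  }
  structure(data.frame(t = ts, x = xs, z = zs),
            class = c("trajectory", "data.frame"), grid = g)
}

# bilinear interpolation of the cell-centered velocity at (x, z); outside
# the outermost cell centers coordinates clamp to the boundary values
bilinear_velocity <- function(velocity, x, z) {
  g <- velocity$grid
  fx <- (x / g$dx) + 0.5   # fractional cell-center index
  fz <- (z / g$dz) + 0.5
  i0 <- floor(fx); j0 <- floor(fz)
  i0 <- min(max(i0, 1), g$nx - 1)
  j0 <- min(max(j0, 1), g$nz - 1)
  wx <- min(max(fx - i0, 0), 1)
  wz <- min(max(fz - j0, 0), 1)
  ix <- c(i0, i0 + 1); jz <- c(j0, j0 + 1)
  wgt <- c((1 - wx) * (1 - wz), wx * (1 - wz), (1 - wx) * wz, wx * wz)
  idx <- cbind(ix[c(1, 2, 1, 2)], jz[c(1, 1, 2, 2)])
  c(sum(wgt * velocity$vx[idx]), sum(wgt * velocity$vz[idx]))
}

#' Irradiance history along a trajectory
#'
#' Concatenates a particle trajectory with the Beer-Lambert light field:
#' `u(t) = u(z(t))`. On a closed orbit spanning the culture depth, `u(t)`
#' oscillates between roughly `u0` and `u0 exp(-Lambda L)` at the orbit
#' period — the hydrodynamically induced light/dark cycle.
#'
#' @param traj a [trace_particle()] trajectory.
#' @param light a [light_field()].
#' @return An object of class `irradiance_history`: data.frame `t, u`.
#' @export
irradiance_history <- function(traj, light) {
  stopifnot(inherits(traj, "trajectory"), inherits(light, "light_field"))
  g <- attr(traj, "grid")
  if (abs(g$L - light$L) > 1e-12) {
    stop("irradiance_history: trajectory and light field geometries differ")
  }
  structure(data.frame(t = traj$t, u = irradiance_at(light, traj$z)),
            class = c("irradiance_history", "data.frame"))
}

#' Integrate PSF kinetics along an irradiance history
#'
#' Drives the full (stiff) PSF model with the piecewise-linearly
#' interpolated irradiance history of a traced cell — the Lagrangian
#' counterpart of the Eulerian transport-reaction solve. For a fast periodic
#' history (period much shorter than the photosynthetic relaxation time) the
#' time-averaged `yA` approaches `yA_ss(mean u)`: the flashing-light
#' enhancement seen from a single cell.
#'
#' @param history an [irradiance_history()].
#' @param kinetics a [psf_reparam()] object.
#' @param y0 initial state, default rested `(1, 0, 0)`.
#' @param dt_out output sampling (s); defaults to the history sampling.
#' @param rtol,atol integrator tolerances.
#' @return A data.frame `t, yR, yA, yB`.
#' @export
kinetics_along <- function(history, kinetics = case_study_reparam(),
                           y0 = c(1, 0, 0), dt_out = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(history, "irradiance_history"))
  if (is.null(dt_out)) dt_out <- mean(diff(history$t))
  ufun <- stats::approxfun(history$t, history$u, rule = 2)
  simulate_psf(ufun, y0, t_span = range(history$t), dt_out = dt_out,
               reparam = kinetics, rtol = rtol, atol = atol)
}
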