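#' Species fraction fields on a grid
#'
#' Per-cell molar fractions of the three PSF states. Defaults to the
#' case-study initial condition: every photosynthetic unit rested
#' (`yR = 1, yA = yB = 0`).
#'
#' @param grid a [grid2d()].
#' @param yR,yA,yB scalar fractions or `nx x nz` matrices; per cell the
#'   three must sum to 1 within `tol` and lie in `[0, 1]`.
#' @param t simulation clock (s).
#' @param tol invariant tolerance.
#' @return An object of class `species_fields`.
#' @export
species_fields <- function(grid, yR = 1, yA = 0, yB = 0, t = 0, tol = 1e-8) {
  stopifnot(inherits(grid, "grid2d"))
  expand <- function(v) {
    if (is.matrix(v)) {
      if (!all(dim(v) == c(grid$nx, grid$nz))) {
        stop("species_fields: field matrices must be nx x nz")
      }
      v
    } else matrix(v, grid$nx, grid$nz)
  }
  yR <- expand(yR); yA <- expand(yA); yB <- expand(yB)
  s <- yR + yA + yB
  if (max(abs(s - 1)) > tol) {
    stop("species_fields: per-cell yR + yA + yB must equal 1 (max deviation ",
         signif(max(abs(s - 1)), 3), ")")
  }
  if (min(yR, yA, yB) < -tol || max(yR, yA, yB) > 1 + tol) {
    stop("species_fields: fractions must lie in [0, 1]")
  }
  structure(list(grid = grid, yR = yR, yA = yA, yB = yB, t = t),
            class = "species_fields")
}

#' @export
print.species_fields <- function(x, ...) {
  cat(sprintf(
    "species_fields on %d x %d grid at t = %.6g s: mean yR = %.4f, yA = %.4f, yB = %.4f\n",
    x$grid$nx, x$grid$nz, x$t, mean(x$yR), mean(x$yA), mean(x$yB)))
  invisible(x)
}

#' Transport-reaction configuration
#'
#' @param De isotropic dispersion coefficient (m2/s), >= 0. Default
#'   `1e-6` (molecular-scale: kinematic viscosity of water at Schmidt
#'   number 1).
#' @param dt operator-splitting time step (s); the reaction sub-step is
#'   solved exactly over `dt`, so `dt` controls only the splitting error.
#' @param T simulation horizon (s).
#' @param reaction `"full"` (3x3 exact propagator of the full PSF
#'   generator), `"reduced"` (fast-reduced scalar relaxation of `yA` with
#'   `yB` frozen at `yB_ss(u_av)`), or `"none"`.
#' @param mixing `"advect"` (sub-cycled explicit upwind advection +
#'   diffusion), `"ideal"` (exact spatial homogenization each step, the
#'   well-mixed/large-De limit used to represent turbulent cases), or
#'   `"none"` (pure local reaction).
#' @param dt_out sampling interval for the recorded spatial-mean trajectory
#'   (s); rounded to a multiple of `dt`.
#' @param advection_order `1` (default) for bounded, monotone first-order
#'   upwind advection, or `2` for the MUSCL scheme with minmod-limited
#'   reconstruction (sharper fronts, markedly less numerical diffusion,
#'   stricter sub-step bound).
#' @param subcycle if `TRUE` (default) the advection-diffusion sub-step is
#'   automatically subdivided to satisfy the explicit stability (CFL +
#'   diffusion number) bound; if `FALSE`, a step violating the bound is
#'   rejected with an error.
#' @param cfl_target stability-number target (< 1) for sub-cycling.
#' @param steady_tol relative change of the spatial means per unit model
#'   time below which [steady_state_detect()] flags steadiness (s-1).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(De = 1e-6, dt = 0.025, T = 2000,
                             reaction = c("full", "reduced", "none"),
                             mixing = c("advect", "ideal", "none"),
                             advection_order = 1L,
                             dt_out = 10, subcycle = TRUE, cfl_target = NULL,
                             steady_tol = 1e-6) {
  reaction <- match.arg(reaction)
  mixing <- match.arg(mixing)
  advection_order <- as.integer(advection_order)
  if (!advection_order %in% c(1L, 2L)) {
    stop("transport_config: advection_order must be 1 or 2")
  }
  # the TVD bound of the limited scheme is roughly half the first-order one
  if (is.null(cfl_target)) cfl_target <- if (advection_order == 2L) 0.45 else 0.9
  if (!is.finite(De) || De < 0) stop("transport_config: De must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("transport_config: dt must be > 0")
  if (!is.finite(T) || T <= 0) stop("transport_config: T must be > 0")
  structure(list(De = De, dt = dt, T = T, reaction = reaction,
                 mixing = mixing, advection_order = advection_order,
                 dt_out = max(dt_out, dt),
                 subcycle = isTRUE(subcycle), cfl_target = cfl_target,
                 steady_tol = steady_tol),
            class = "transport_config")
}

# stability numbers of the explicit advection-diffusion sub-step; the
# combined bound is per cell (the largest x-face and z-face speed seen by
# any one cell), which is sharper than pairing the global maxima, since in
# a vortex the fastest x-faces and z-faces lie on different walls
transport_cfl <- function(velocity, config) {
  g <- velocity$grid
  nx <- g$nx; nz <- g$nz
  fl <- face_fluxes(velocity)
  aue <- abs(fl$ue); avn <- abs(fl$vn)
  cell_u <- pmax(aue[1:nx, , drop = FALSE], aue[2:(nx + 1), , drop = FALSE])
  cell_v <- pmax(avn[, 1:nz, drop = FALSE], avn[, 2:(nz + 1), drop = FALSE])
  adv <- max(cell_u / g$dx + cell_v / g$dz)
  dif <- 2 * config$De * (1 / g$dx^2 + 1 / g$dz^2)
  c(advective = max(aue) * config$dt / g$dx,
    diffusive = config$De * config$dt / g$dx^2,
    stability = (adv + dif) * config$dt)
}

# precompute the per-z-level reaction data: exact 3x3 propagators (full
# mode) or relaxation rate/fixed point (reduced mode). In ideal-mixing mode
# cells are homogenized continuously, so every cell reacts under the
# *averaged* generator: because the PSF generator is linear in u, the
# infinite-mixing limit is exactly M(mean u), not the mean of local
# propagators (which would leave an O(dt) splitting bias).
reaction_tables <- function(grid, light, reparam, config) {
  uz <- irradiance_at(light, grid$zc)
  if (config$mixing == "ideal") uz[] <- mean(uz)
  u_av <- average_irradiance(light)
  out <- list(uz = uz, u_av = u_av)
  if (config$reaction == "full") {
    prop <- matrix(0, 9, grid$nz)
    for (j in seq_len(grid$nz)) {
      prop[, j] <- as.vector(expm3(reaction_generator(uz[j], reparam) * config$dt))
    }
    out$prop <- prop
  } else if (config$reaction == "reduced") {
    q2 <- reparam$q2; q4 <- reparam$q4
    yA_ss_av <- (u_av / q2) / (u_av^2 + u_av / q2 + 1)
    k <- q4 * (uz + q2)
    out$edk <- exp(-k * config$dt)
    out$fp <- (uz / u_av) * (u_av + q2) * yA_ss_av / (uz + q2)
    out$yB_frozen <- u_av^2 / (u_av^2 + u_av / q2 + 1)
  }
  out
}

#' Advance the coupled transport-reaction system
#'
#' `simulate_transport()` advances the three species-fraction fields under
#' one Lie (first-order) operator splitting per step: sub-cycled explicit
#' upwind advection + diffusion over the frozen velocity field, followed by
#' the per-cell reaction sub-step solved *exactly* over `dt` (3x3 matrix
#' exponential of the local generator `M(u(z))` in full mode; scalar linear
#' closed form in reduced mode), which makes the stiff reaction
#' unconditionally stable. Walls are impermeable (zero flux), so the domain
#' totals and the per-cell sum `yR + yA + yB = 1` are conserved to rounding.
#' `transport_step()` performs a single step of `dt`.
#'
#' @param velocity a [velocity_field()] (or `NULL` for a quiescent domain).
#' @param light a [light_field()] on the same geometry.
#' @param kinetics a [psf_reparam()] object.
#' @param config a [transport_config()].
#' @param initial a [species_fields()]; default rested culture.
#' @return A list of class `transport_result`: final `fields`
#'   ([species_fields()]), `traj` (data.frame `t, mean_yR, mean_yA,
#'   mean_yB`), stability diagnostics `cfl`, sub-step count `nsub`, and
#'   conservation drift `drift` (max deviation of the per-cell sum from 1).
#' @export
simulate_transport <- function(velocity, light, kinetics = case_study_reparam(),
                               config = transport_config(),
                               initial = NULL) {
  stopifnot(inherits(light, "light_field"), inherits(kinetics, "psf_reparam"),
            inherits(config, "transport_config"))
  if (is.null(velocity)) {
    stop("simulate_transport: velocity is required (use a zero field for Re = 0)")
  }
  stopifnot(inherits(velocity, "velocity_field"))
  g <- velocity$grid
  if (abs(g$L - light$L) > 1e-12) {
    stop("simulate_transport: grid depth (", g$L,
         ") and light-field depth (", light$L, ") differ")
  }
  if (is.null(initial)) initial <- species_fields(g)
  stopifnot(inherits(initial, "species_fields"))
  if (!identical(dim(initial$yA), c(g$nx, g$nz))) {
    stop("simulate_transport: initial fields are on a different grid")
  }

  nsteps <- max(1L, as.integer(round(config$T / config$dt)))
  rec_stride <- max(1L, as.integer(round(config$dt_out / config$dt)))

  mixing_mode <- switch(config$mixing, advect = 0L, ideal = 1L, none = 2L)
  fl <- face_fluxes(velocity)
  nsub <- 1L
  cfl <- transport_cfl(velocity, config)
  if (mixing_mode == 0L) {
    if (cfl[["stability"]] > config$cfl_target) {
      if (!config$subcycle && cfl[["stability"]] > 1) {
        stop(sprintf(
          "simulate_transport: explicit stability number %.3g > 1 at dt = %g s; reduce dt or enable subcycle",
          cfl[["stability"]], config$dt))
      }
      if (config$subcycle) {
        nsub <- as.integer(ceiling(cfl[["stability"]] / config$cfl_target))
      }
    }
  }

  react_mode <- switch(config$reaction, none = 0L, full = 1L, reduced = 2L)
  rt <- reaction_tables(g, light, kinetics, config)
  prop <- if (react_mode == 1L) rt$prop else matrix(0, 9, g$nz)
  edk <- if (react_mode == 2L) rt$edk else numeric(g$nz)
  fp <- if (react_mode == 2L) rt$fp else numeric(g$nz)
  yB_frozen <- if (react_mode == 2L) rt$yB_frozen else 0

  res <- transport_run_cpp(initial$yR, initial$yA, initial$yB,
                           fl$ue, fl$vn, config$De, g$dx, g$dz, config$dt,
                           nsteps, nsub, mixing_mode, react_mode,
                           prop, edk, fp, yB_frozen, rec_stride, initial$t,
                           config$advection_order)
  if (res$min_fraction < -1e-6 || res$max_fraction > 1 + 1e-6) {
    warning(sprintf(
      "simulate_transport: fractions left [0, 1] (range %.3g .. %.3g); solution clipped on output",
      res$min_fraction, res$max_fraction))
  }
  drift <- max(abs(res$yR + res$yA + res$yB - 1))
  fields <- species_fields(g, yR = pmin(pmax(res$yR, 0), 1),
                           yA = pmin(pmax(res$yA, 0), 1),
                           yB = pmin(pmax(res$yB, 0), 1),
                           t = initial$t + nsteps * config$dt,
                           tol = max(1e-8, 2 * drift))
  traj <- data.frame(t = res$traj[, 1], mean_yR = res$traj[, 2],
                     mean_yA = res$traj[, 3], mean_yB = res$traj[, 4])
  structure(list(fields = fields, traj = traj, cfl = cfl, nsub = nsub,
                 drift = drift, config = config, u_av = rt$u_av),
            class = "transport_result")
}

#' @rdname simulate_transport
#' @param fields a [species_fields()] to advance by a single step `dt`.
#' @export
transport_step <- function(fields, velocity, light,
                           kinetics = case_study_reparam(),
                           config = transport_config()) {
  cfg1 <- config
  cfg1$T <- config$dt
  cfg1$dt_out <- config$dt
  simulate_transport(velocity, light, kinetics, cfg1, initial = fields)$fields
}

#' @export
print.transport_result <- function(x, ...) {
  n <- nrow(x$traj)
  cat(sprintf("transport_result: %d recorded samples to t = %.6g s\n",
              n, x$traj$t[n]))
  cat(sprintf("  mixing = %s (%d sub-steps), reaction = %s\n",
              x$config$mixing, x$nsub, x$config$reaction))
  cat(sprintf("  final mean yA = %.4f, yB = %.4f; conservation drift %.2g\n",
              x$traj$mean_yA[n], x$traj$mean_yB[n], x$drift))
  invisible(x)
}

#' Detect steady state in a recorded trajectory
#'
#' Flags steadiness when the relative change of the spatial means of `yA`
#' and `yB` per unit model time drops below `tol` (s-1).
#'
#' @param traj data.frame with columns `t`, `mean_yA`, `mean_yB` (as
#'   produced by [simulate_transport()]), or a `transport_result`.
#' @param tol threshold rate (s-1).
#' @return List with `steady` (logical) and `time` (first time the
#'   criterion holds, NA if never).
#' @export
steady_state_detect <- function(traj, tol = 1e-6) {
  if (inherits(traj, "transport_result")) traj <- traj$traj
  stopifnot(is.data.frame(traj), nrow(traj) >= 2L)
  dt <- diff(traj$t)
  rate <- function(v) abs(diff(v)) / pmax(abs(v[-1]), 1e-12) / dt
  r <- pmax(rate(traj$mean_yA), rate(traj$mean_yB))
  idx <- which(r < tol)
  if (length(idx) == 0L) {
    list(steady = FALSE, time = NA_real_)
  } else {
    list(steady = TRUE, time = traj$t[idx[1] + 1L])
  }
}
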