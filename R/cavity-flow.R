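#' Uniform structured 2-D grid
#'
#' Cell-centered uniform grid on the square (or rectangular) culture domain.
#' `x` runs along the lid, `z` upward from the illuminated bottom wall.
#'
#' @param nx,nz cell counts in x and z (>= 4).
#' @param L domain side length (m); cells are `L/nx` by `L/nz`.
#' @return An object of class `grid2d` with cell-centered coordinates `xc`,
#'   `zc`, spacings `dx`, `dz` and node coordinates `xn`, `zn`.
#' @export
grid2d <- function(nx, nz = nx, L = 0.02) {
  nx <- as.integer(nx); nz <- as.integer(nz)
  if (nx < 4L || nz < 4L) stop("grid2d: nx and nz must be >= 4")
  if (!is.finite(L) || L <= 0) stop("grid2d: L must be > 0")
  dx <- L / nx; dz <- L / nz
  structure(list(nx = nx, nz = nz, L = L, dx = dx, dz = dz,
                 xc = (seq_len(nx) - 0.5) * dx, zc = (seq_len(nz) - 0.5) * dz,
                 xn = (0:nx) * dx, zn = (0:nz) * dz),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %d x %d cells on [0, %.4g] m square (dx = %.3g m)\n",
              x$nx, x$nz, x$L, x$dx))
  invisible(x)
}

#' Construct a 2-D velocity field on a grid
#'
#' Container for a steady velocity field: cell-centered components and,
#' when available, the streamfunction on the grid nodes. When `psi` is
#' present the transport solver uses exactly divergence-free face fluxes
#' derived from it (flux through a face = streamfunction difference between
#' its end nodes).
#'
#' @param grid a [grid2d()].
#' @param vx,vz cell-centered velocity components, `nx x nz` matrices (m/s).
#' @param psi optional streamfunction on the `(nx+1) x (nz+1)` nodes
#'   (m2/s), zero on walls.
#' @param v_lid lid (top-wall) tangential velocity (m/s), if meaningful.
#' @param Re Reynolds number `v_lid L / nu`, if meaningful.
#' @param nu kinematic viscosity (m2/s).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, vx, vz, psi = NULL, v_lid = NA_real_,
                           Re = NA_real_, nu = 1e-6) {
  stopifnot(inherits(grid, "grid2d"))
  vx <- as.matrix(vx); vz <- as.matrix(vz)
  if (!all(dim(vx) == c(grid$nx, grid$nz)) ||
      !all(dim(vz) == c(grid$nx, grid$nz))) {
    stop("velocity_field: vx and vz must be nx x nz matrices")
  }
  if (!is.null(psi) && !all(dim(psi) == c(grid$nx + 1L, grid$nz + 1L))) {
    stop("velocity_field: psi must be an (nx+1) x (nz+1) node matrix")
  }
  structure(list(grid = grid, vx = vx, vz = vz, psi = psi,
                 v_lid = v_lid, Re = Re, nu = nu),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field on %d x %d grid (L = %.4g m): max |v| = %.4g m/s",
              x$grid$nx, x$grid$nz, x$grid$L, max(abs(x$vx), abs(x$vz))))
  if (is.finite(x$Re)) cat(sprintf(", Re = %g", x$Re))
  cat(if (is.null(x$psi)) "; no streamfunction\n" else "; streamfunction attached\n")
  invisible(x)
}

#' Reynolds number of the cavity
#'
#' `Re = v_L L / nu` with lid velocity `v_L`, cavity size `L` and kinematic
#' viscosity `nu`.
#'
#' @param v_L lid velocity (m/s).
#' @param L cavity side (m).
#' @param nu kinematic viscosity (m2/s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(v_L, L = 0.02, nu = 1e-6) {
  if (!is.finite(L) || L <= 0) stop("reynolds: L must be > 0")
  if (!is.finite(nu) || nu <= 0) stop("reynolds: nu must be > 0")
  v_L * L / nu
}

# cell-centered velocities from a node streamfunction:
# vx = dpsi/dz, vz = -dpsi/dx, averaged over the two cell faces
cellVelocitiesFromPsi <- function(grid, psi) {
  nx <- grid$nx; nz <- grid$nz
  i <- seq_len(nx); j <- seq_len(nz)
  vx <- (psi[i, j + 1] + psi[i + 1, j + 1] - psi[i, j] - psi[i + 1, j]) /
    (2 * grid$dz)
  vz <- -(psi[i + 1, j] + psi[i + 1, j + 1] - psi[i, j] - psi[i, j + 1]) /
    (2 * grid$dx)
  list(vx = vx, vz = vz)
}

#' Solve the steady lid-driven cavity flow
#'
#' Computes the steady incompressible flow in a square cavity whose top wall
#' (the lid, at z = L) moves with velocity `v_L` in +x, by pseudo-time
#' marching of the streamfunction-vorticity equations (first-order upwind
#' convection, central diffusion, Thom wall-vorticity closures, SOR Poisson
#' sweeps). This is the laminar benchmark flow standing in for one Taylor
#' vortex cell of a Couette-Taylor culture device. The solver is laminar:
#' above `Re ~ 5000` a warning is issued (well-mixed turbulent regimes are
#' represented by the transport module's ideal-mixing mode instead).
#'
#' @param Re Reynolds number (>= 0). `Re = 0` (or `v_L = 0`) returns the
#'   zero field.
#' @param grid a square [grid2d()] (`nx == nz`).
#' @param nu kinematic viscosity (m2/s); default water, 1e-6.
#' @param v_L lid velocity (m/s); default derived from `Re` as `Re nu / L`.
#' @param tol steady-state residual tolerance (max |d omega/dt|, lid units).
#' @param max_iter maximum pseudo-time iterations.
#' @param n_sor SOR sweeps of the Poisson equation per pseudo-time step.
#' @return A [velocity_field()] with node streamfunction attached and
#'   attributes `iterations`, `residual`, `converged`.
#' @export
solve_cavity <- function(Re, grid = grid2d(100), nu = 1e-6, v_L = NULL,
                         tol = 1e-6, max_iter = 200000L, n_sor = 4L) {
  stopifnot(inherits(grid, "grid2d"))
  if (grid$nx != grid$nz) stop("solve_cavity: grid must be square (nx == nz)")
  if (!is.finite(Re) || Re < 0) stop("solve_cavity: Re must be >= 0")
  if (is.null(v_L)) v_L <- Re * nu / grid$L
  if (Re > 5000) {
    warning("solve_cavity: Re = ", Re, " is beyond the laminar regime; ",
            "use the ideal-mixing transport mode for well-mixed cases")
  }
  n <- grid$nx
  if (v_L == 0 || Re == 0) {
    zero <- matrix(0, n, n)
    fld <- velocity_field(grid, zero, zero,
                          psi = matrix(0, n + 1, n + 1),
                          v_lid = 0, Re = 0, nu = nu)
    attr(fld, "iterations") <- 0L
    attr(fld, "residual") <- 0
    attr(fld, "converged") <- TRUE
    return(fld)
  }
  beta <- 2 / (1 + sin(pi / n))   # near-optimal SOR relaxation
  sol <- cavity_solve_cpp(n, Re, tol, as.integer(max_iter), beta,
                          as.integer(n_sor))
  if (!sol$converged) {
    stop(sprintf(
      "solve_cavity: no steady solution within %d iterations (residual %.3g > tol %.3g)",
      max_iter, sol$residual, tol))
  }
  psi <- sol$psi * v_L * grid$L   # lid units -> physical m2/s
  cv <- cellVelocitiesFromPsi(grid, psi)
  fld <- velocity_field(grid, cv$vx, cv$vz, psi = psi, v_lid = v_L,
                        Re = reynolds(v_L, grid$L, nu), nu = nu)
  attr(fld, "iterations") <- sol$iterations
  attr(fld, "residual") <- sol$residual
  attr(fld, "converged") <- sol$converged
  fld
}

#' Analytic single-vortex velocity field
#'
#' Divergence-free recirculating fixture flow from the streamfunction
#' `psi = A sin(pi x / L) sin(pi z / L)`: a single closed vortex with zero
#' normal velocity on all walls. Streamlines are level curves of `psi`, which
#' is an exact invariant of particle motion — useful as an analytic oracle
#' for the transport and tracer modules.
#'
#' @param grid a [grid2d()].
#' @param amplitude streamfunction amplitude `A` (m2/s), >= 0. The peak
#'   speed is `pi A / L`.
#' @return A [velocity_field()] with node streamfunction and an attached
#'   `velocity_fun(x, z)` attribute returning the exact analytic velocity.
#' @export
analytic_vortex <- function(grid, amplitude) {
  stopifnot(inherits(grid, "grid2d"))
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("analytic_vortex: amplitude must be >= 0")
  }
  L <- grid$L
  psi <- amplitude * outer(sin(pi * grid$xn / L), sin(pi * grid$zn / L))
  vx <- amplitude * (pi / L) *
    outer(sin(pi * grid$xc / L), cos(pi * grid$zc / L))
  vz <- -amplitude * (pi / L) *
    outer(cos(pi * grid$xc / L), sin(pi * grid$zc / L))
  fld <- velocity_field(grid, vx, vz, psi = psi, v_lid = 0, Re = NA_real_)
  attr(fld, "velocity_fun") <- function(x, z) {
    c(amplitude * (pi / L) * sin(pi * x / L) * cos(pi * z / L),
      -amplitude * (pi / L) * cos(pi * x / L) * sin(pi * z / L))
  }
  attr(fld, "psi_fun") <- function(x, z) {
    amplitude * sin(pi * x / L) * sin(pi * z / L)
  }
  fld
}

#' Discrete divergence of a velocity field
#'
#' For streamfunction-backed fields the finite-volume face fluxes telescope
#' and the per-cell divergence is zero to rounding; for raw cell-centered
#' fields a second-order central estimate on interior cells is returned.
#'
#' @param field a [velocity_field()].
#' @return Matrix of per-cell divergence (s-1); interior cells only for raw
#'   fields (boundary cells set to NA).
#' @export
divergence <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  g <- field$grid
  if (!is.null(field$psi)) {
    fl <- face_fluxes(field)
    nx <- g$nx; nz <- g$nz
    (fl$ue[2:(nx + 1), , drop = FALSE] - fl$ue[1:nx, , drop = FALSE]) / g$dx +
      (fl$vn[, 2:(nz + 1), drop = FALSE] - fl$vn[, 1:nz, drop = FALSE]) / g$dz
  } else {
    nx <- g$nx; nz <- g$nz
    d <- matrix(NA_real_, nx, nz)
    i <- 2:(nx - 1); j <- 2:(nz - 1)
    d[i, j] <- (field$vx[i + 1, j] - field$vx[i - 1, j]) / (2 * g$dx) +
      (field$vz[i, j + 1] - field$vz[i, j - 1]) / (2 * g$dz)
    d
  }
}

# face-normal velocities for the finite-volume transport step:
# ue is (nx+1) x nz (x-faces), vn is nx x (nz+1) (z-faces). Derived exactly
# from the streamfunction when present (ue = dpsi/dz across the face), else
# by averaging adjacent cell-centered values with impermeable walls.
face_fluxes <- function(field) {
  g <- field$grid
  nx <- g$nx; nz <- g$nz
  if (!is.null(field$psi)) {
    psi <- field$psi
    ue <- (psi[, 2:(nz + 1), drop = FALSE] - psi[, 1:nz, drop = FALSE]) / g$dz
    vn <- -(psi[2:(nx + 1), , drop = FALSE] - psi[1:nx, , drop = FALSE]) / g$dx
  } else {
    ue <- matrix(0, nx + 1, nz)
    ue[2:nx, ] <- (field$vx[1:(nx - 1), ] + field$vx[2:nx, ]) / 2
    vn <- matrix(0, nx, nz + 1)
    vn[, 2:nz] <- (field$vz[, 1:(nz - 1)] + field$vz[, 2:nz]) / 2
  }
  list(ue = ue, vn = vn)
}

#' Write / read a velocity field
#'
#' `write_velocity_field()` stores the grid metadata and cell-centered
#' velocities as CSV (columns `x, z, vx, vz`, metadata in `#`-comment
#' header) or as a legacy-VTK structured-points file with a `velocity`
#' vector field (write-only, for external viewers). `read_velocity_field()`
#' reads the CSV form back losslessly (grid + velocities; a streamfunction,
#' being node-based, is not carried through the CSV exchange format).
#'
#' @param field a [velocity_field()].
#' @param path file path.
#' @param format `"csv"` or `"vtk"`.
#' @return `read_velocity_field()` returns a [velocity_field()];
#'   `write_velocity_field()` returns `path` invisibly.
#' @export
write_velocity_field <- function(field, path, format = c("csv", "vtk")) {
  stopifnot(inherits(field, "velocity_field"))
  format <- match.arg(format)
  g <- field$grid
  if (format == "vtk") {
    write_vtk(path, g, list(),
              vectors = list(velocity = list(vx = field$vx, vz = field$vz)))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# psfcav velocity field"),
    sprintf("# nx=%d nz=%d L=%.17g", g$nx, g$nz, g$L),
    sprintf("# v_lid=%.17g Re=%.17g nu=%.17g", field$v_lid, field$Re, field$nu),
    "x,z,vx,vz"), con)
  idx <- expand.grid(i = seq_len(g$nx), j = seq_len(g$nz))
  df <- data.frame(x = g$xc[idx$i], z = g$zc[idx$j],
                   vx = field$vx[cbind(idx$i, idx$j)],
                   vz = field$vz[cbind(idx$i, idx$j)])
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  if (!file.exists(path)) stop("read_velocity_field: no such file: ", path)
  hdr <- readLines(path, n = 4L)
  if (length(hdr) < 4L || !grepl("psfcav velocity field", hdr[1], fixed = TRUE)) {
    stop("read_velocity_field: ", path, ": not a psfcav velocity CSV (bad header)")
  }
  meta1 <- as.numeric(sub(".*nx=(\\S+) nz=(\\S+) L=(\\S+).*", "\\1 \\2 \\3", hdr[2]) |>
                        strsplit(" ") |> unlist())
  meta2 <- suppressWarnings(as.numeric(
    sub(".*v_lid=(\\S+) Re=(\\S+) nu=(\\S+).*", "\\1 \\2 \\3", hdr[3]) |>
      strsplit(" ") |> unlist()))
  if (length(meta1) != 3L || any(!is.finite(meta1))) {
    stop("read_velocity_field: ", path, ": malformed grid metadata (line 2)")
  }
  nx <- as.integer(meta1[1]); nz <- as.integer(meta1[2]); L <- meta1[3]
  df <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(df), c("x", "z", "vx", "vz"))) {
    stop("read_velocity_field: ", path, ": expected columns x,z,vx,vz")
  }
  if (nrow(df) != nx * nz) {
    stop("read_velocity_field: ", path, ": grid mismatch, expected ",
         nx * nz, " rows, found ", nrow(df))
  }
  g <- grid2d(nx, nz, L)
  velocity_field(g, matrix(df$vx, nx, nz), matrix(df$vz, nx, nz),
                 v_lid = meta2[1], Re = meta2[2],
                 nu = if (is.finite(meta2[3])) meta2[3] else 1e-6)
}

#' Write scalar/vector fields as legacy VTK structured points
#'
#' Minimal writer for the plain-text legacy VTK format (viewable in
#' ParaView/VisIt): cell-centered fields are written as point data on the
#' cell-center lattice.
#'
#' @param path output file.
#' @param grid a [grid2d()].
#' @param scalars named list of `nx x nz` matrices.
#' @param vectors named list of `list(vx=, vz=)` pairs.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, grid, scalars = list(), vectors = list()) {
  stopifnot(inherits(grid, "grid2d"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$nx * grid$nz
  writeLines(c("# vtk DataFile Version 3.0",
               "psfcav fields", "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$nz),
               sprintf("ORIGIN %.9g %.9g 0", grid$xc[1], grid$zc[1]),
               sprintf("SPACING %.9g %.9g 1", grid$dx, grid$dz),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.vector(scalars[[nm]])), con)
  }
  for (nm in names(vectors)) {
    writeLines(sprintf("VECTORS %s double", nm), con)
    v <- vectors[[nm]]
    writeLines(sprintf("%.9g %.9g 0", as.vector(v$vx), as.vector(v$vz)), con)
  }
  invisible(path)
}
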