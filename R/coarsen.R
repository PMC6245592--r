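#' Restrict a streamfunction-backed velocity field to a coarser grid
#'
#' Takes every `factor`-th node of the streamfunction, producing the same
#' flow on an `nx/factor` grid. Because face fluxes are streamfunction
#' differences, each coarse-face flux is exactly the sum of the fine-face
#' fluxes it replaces: the restricted field is divergence-free to rounding
#' and carries identical wall fluxes. Used to study transport-grid
#' convergence over one fixed, well-resolved flow solution.
#'
#' @param field a [velocity_field()] with a streamfunction attached.
#' @param factor integer coarsening factor; must divide `nx` and `nz`.
#' @return A [velocity_field()] on the coarser grid.
#' @export
coarsen_field <- function(field, factor) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(field$psi)) {
    stop("coarsen_field: the field has no streamfunction to restrict")
  }
  g <- field$grid
  factor <- as.integer(factor)
  if (factor < 1L || g$nx %% factor != 0L || g$nz %% factor != 0L) {
    stop("coarsen_field: factor must divide nx (", g$nx, ") and nz (", g$nz, ")")
  }
  gc <- grid2d(g$nx %/% factor, g$nz %/% factor, g$L)
  psi <- field$psi[seq(1, g$nx + 1, by = factor),
                   seq(1, g$nz + 1, by = factor)]
  cv <- cellVelocitiesFromPsi(gc, psi)
  velocity_field(gc, cv$vx, cv$vz, psi = psi, v_lid = field$v_lid,
                 Re = field$Re, nu = field$nu)
}
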