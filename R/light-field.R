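#' Beer-Lambert light field of the culture
#'
#' The culture is illuminated from one wall (by default the bottom, z = 0)
#' and the irradiance decays exponentially along the light path:
#' `u(z) = u0 exp(-Lambda z)`, in normalized units `u = I / q1`. The field is
#' specified by the culture depth `L`, the optical thickness `Ot = Lambda L`
#' (or equivalently the attenuation coefficient `Lambda`), and exactly one of
#' the incident irradiance `u0` or the target depth-averaged irradiance
#' `u_av` (from which `u0` is recovered by inverting the closed-form
#' average).
#'
#' @param L culture depth along the light path (m).
#' @param Ot dimensionless optical thickness `Lambda * L` (>= 0). Give either
#'   `Ot` or `Lambda`.
#' @param Lambda attenuation coefficient (m-1).
#' @param u0 normalized incident irradiance at the illuminated wall.
#' @param u_av target normalized depth-averaged irradiance. Exactly one of
#'   `u0` and `u_av` must be supplied.
#' @param side which wall is illuminated; only `"bottom"` is implemented
#'   (light decays with height z measured from the bottom).
#' @return An object of class `light_field` with fields `u0`, `Lambda`, `L`,
#'   `Ot`, `side`.
#' @export
#' @examples
#' lf <- light_field(L = 0.02, Ot = 8 * log(2), u_av = 1)
#' lf$u0                    # 5.5669: incident value giving mean u of 1
#' optical_thickness(lf)    # 5.545, i.e. ~5.5
light_field <- function(L = 0.02, Ot = NULL, Lambda = NULL,
                        u0 = NULL, u_av = NULL, side = "bottom") {
  if (!is.finite(L) || L <= 0) stop("light_field: L must be > 0")
  side <- match.arg(side, "bottom")
  if (is.null(Ot) + is.null(Lambda) != 1L) {
    stop("light_field: give exactly one of 'Ot' or 'Lambda'")
  }
  if (is.null(Ot)) {
    if (Lambda < 0) stop("light_field: Lambda must be >= 0")
    Ot <- Lambda * L
  } else {
    if (Ot < 0) stop("light_field: Ot must be >= 0")
    Lambda <- Ot / L
  }
  if (is.null(u0) + is.null(u_av) != 1L) {
    stop("light_field: give exactly one of 'u0' or 'u_av' (they are mutually exclusive)")
  }
  if (is.null(u0)) {
    if (u_av <= 0) stop("light_field: u_av must be > 0")
    u0 <- u0_for_average(u_av, Ot)
  }
  if (u0 < 0) stop("light_field: u0 must be >= 0")
  structure(list(u0 = u0, Lambda = Lambda, L = L, Ot = Ot, side = side),
            class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf(
    "Beer-Lambert light field: u0 = %.4g, Lambda = %.4g m-1, L = %.4g m (Ot = %.3g)\n",
    x$u0, x$Lambda, x$L, x$Ot))
  cat(sprintf("  illuminated side: %s; u_av = %.4g\n", x$side,
              average_irradiance(x)))
  invisible(x)
}

#' Normalized irradiance at depth z
#'
#' `u(z) = u0 exp(-Lambda z)`, with `z` the distance from the illuminated
#' wall. Monotone non-increasing in `z`; the half-value length satisfies
#' `r_half / L = ln(2) / Ot`.
#'
#' @param field a [light_field()].
#' @param z depth(s) from the illuminated wall, in `[0, L]` (m).
#' @return Normalized irradiance, same length as `z`.
#' @export
irradiance_at <- function(field, z) {
  stopifnot(inherits(field, "light_field"))
  if (any(!is.finite(z)) || any(z < -1e-12) || any(z > field$L + 1e-12)) {
    stop("irradiance_at: z must lie within [0, L] = [0, ", field$L, "]")
  }
  field$u0 * exp(-field$Lambda * pmin(pmax(z, 0), field$L))
}

#' Depth-averaged normalized irradiance
#'
#' Closed form `u_av = u0 (1 - exp(-Lambda L)) / (Lambda L)`; the transparent
#' limit `Ot -> 0` gives `u_av = u0`.
#'
#' @param field a [light_field()].
#' @return The depth-averaged normalized irradiance.
#' @export
average_irradiance <- function(field) {
  stopifnot(inherits(field, "light_field"))
  Ot <- field$Ot
  if (Ot < 1e-12) return(field$u0)
  field$u0 * (1 - exp(-Ot)) / Ot
}

#' Incident irradiance producing a given depth average
#'
#' Inverts the closed-form depth average: `u0 = u_av * Ot / (1 - exp(-Ot))`,
#' with the transparent limit `u0 = u_av` at `Ot = 0`. Exact inverse of
#' [average_irradiance()].
#'
#' @param u_av_target desired depth-averaged normalized irradiance (> 0).
#' @param Ot optical thickness (>= 0).
#' @return The incident normalized irradiance `u0`.
#' @export
u0_for_average <- function(u_av_target, Ot) {
  if (!is.finite(u_av_target) || u_av_target <= 0) {
    stop("u0_for_average: u_av_target must be > 0")
  }
  if (!is.finite(Ot) || Ot < 0) stop("u0_for_average: Ot must be >= 0")
  if (Ot < 1e-12) return(u_av_target)
  u_av_target * Ot / (1 - exp(-Ot))
}

#' Optical thickness of a light field
#'
#' `Ot = Lambda * L`, the dimensionless attenuation across the culture depth.
#' The case-study value `8 ln 2` evaluates to 5.545, i.e. about 5.5: incident
#' light is halved eight times across the depth.
#'
#' @param field a [light_field()].
#' @return The dimensionless optical thickness.
#' @export
optical_thickness <- function(field) {
  stopifnot(inherits(field, "light_field"))
  field$Lambda * field$L
}

#' Thin-culture approximation of the irradiance profile
#'
#' The approximate ratio `u(z)/u_av ~ Lambda L exp(-Lambda L z/L)`, obtained
#' by dropping `exp(-Lambda L)` against 1 in the depth average. Note: the
#' case-study culture (Ot ~ 5.5) is optically thick, where the dropped term
#' is only 2^-8 ~ 0.4% — the approximation is good *because* Ot is large, in
#' spite of its conventional "optically thin" label. Exact forms are used
#' everywhere else in the package.
#'
#' @param field a [light_field()].
#' @param z depth(s) from the illuminated wall (m).
#' @return The approximate ratio `u(z) / u_av`.
#' @export
irradiance_ratio_approx <- function(field, z) {
  stopifnot(inherits(field, "light_field"))
  Ot <- field$Ot
  Ot * exp(-Ot * z / field$L)
}
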