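#' Optical context: wavelength, particle size and refractive indices
#'
#' Bundles the physical inputs of a single-sphere scattering problem and
#' derives the three dimensionless parameters that govern it:
#' the relative refractive index `m = n_particle / n_medium`, the Mie size
#' parameter `x = pi * a * n_medium / lambda` (with `a` the particle
#' *diameter*), and the generalized size parameter `X = a / lambda`
#' (diameter over wavelength, so `X = x / (pi * n_medium)`).
#'
#' Units are converted here once and nowhere else: wavelengths are given
#' in nanometres, diameters in micrometres; all downstream mathematics is
#' dimensionless.
#'
#' @param wavelength_nm Wavelength of the incident light in nm (> 0).
#' @param diameter_um Particle diameter in micrometres (> 0).
#' @param n_particle Refractive index of the particle (default 1.59,
#'   typical of organic biological scatterers).
#' @param n_medium Refractive index of the surrounding medium
#'   (default 1.33, water).
#' @return An object of class `optical_context`: a list with the four
#'   inputs plus derived `m`, `x` and `X`.
#' @examples
#' ctx <- optical_context(1000, 9)   # X = 9 at 1000 nm
#' ctx$m   # ~ 1.195
#' ctx$X   # 9
#' @export
optical_context <- function(wavelength_nm, diameter_um,
                            n_particle = 1.59, n_medium = 1.33) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            is.finite(wavelength_nm), wavelength_nm > 0,
            is.numeric(diameter_um), length(diameter_um) == 1L,
            is.finite(diameter_um), diameter_um > 0,
            is.numeric(n_particle), is.finite(n_particle), n_particle > 0,
            is.numeric(n_medium), is.finite(n_medium), n_medium > 0)
  lambda_um <- wavelength_nm * 1e-3
  ctx <- list(
    wavelength_nm = wavelength_nm,
    diameter_um   = diameter_um,
    n_particle    = n_particle,
    n_medium      = n_medium,
    m = n_particle / n_medium,
    x = pi * diameter_um * n_medium / lambda_um,
    X = diameter_um / lambda_um
  )
  stopifnot(is.finite(ctx$m), ctx$m > 0, is.finite(ctx$x), ctx$x > 0,
            is.finite(ctx$X), ctx$X > 0)
  class(ctx) <- "optical_context"
  ctx
}

#' @export
print.optical_context <- function(x, ...) {
  cat(sprintf(
    "<optical_context> lambda = %g nm, a = %g um, n_p = %g, n_m = %g\n",
    x$wavelength_nm, x$diameter_um, x$n_particle, x$n_medium))
  cat(sprintf("  m = %.6g   x = %.6g   X = a/lambda = %.6g\n", x$m, x$x, x$X))
  invisible(x)
}
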