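#' Stokes vectors and their elementary transformations
#'
#' A Stokes vector (S0, S1, S2, S3) describes intensity and polarization
#' relative to a stated reference plane: S0 total intensity, S1 linear
#' polarization along the reference plane, S2 linear at 45 degrees,
#' S3 right-handed circular.  Physical states satisfy
#' `S1^2 + S2^2 + S3^2 <= S0^2`.
#'
#' @param s0,s1,s2,s3 Stokes parameters; `s0 >= 0`.
#' @param tol Slack allowed on the polarization bound (numerical noise).
#' @return Numeric vector of class `stokes` with names S0..S3.
#' @examples
#' stokes_vector(1, 0, 0, 1)    # right-circular
#' @export
stokes_vector <- function(s0, s1 = 0, s2 = 0, s3 = 0, tol = 1e-9) {
  s <- c(S0 = unname(s0), S1 = unname(s1), S2 = unname(s2), S3 = unname(s3))
  stopifnot(all(is.finite(s)), s0 >= 0)
  if (s1^2 + s2^2 + s3^2 > s0^2 * (1 + tol) + tol) {
    stop("stokes_vector: polarization bound S1^2+S2^2+S3^2 <= S0^2 violated")
  }
  class(s) <- "stokes"
  s
}

#' Scatter a Stokes vector with the sphere Mueller matrix
#'
#' Applies the block-diagonal single-sphere Mueller matrix
#' \preformatted{ | M11  M12   0    0  |
#'  | M12  M11   0    0  |
#'  |  0    0   M33  M34 |
#'  |  0    0  -M34  M33 | }
#' to an incident Stokes vector expressed in the scattering-plane frame.
#'
#' @param s_in Incident [stokes_vector()] (or plain length-4 numeric).
#' @param elements One row of [mueller_elements()] (list/data.frame with
#'   `M11`, `M12`, `M33`, `M34`).
#' @return Scattered `stokes` vector (relative intensity units).
#' @export
scatter_stokes <- function(s_in, elements) {
  s <- unclass(s_in)
  stopifnot(length(s) == 4L)
  with(as.list(elements[c("M11", "M12", "M33", "M34")]), {
    stokes_vector(M11 * s[1] + M12 * s[2],
                  M12 * s[1] + M11 * s[2],
                  M33 * s[3] + M34 * s[4],
                  -M34 * s[3] + M33 * s[4],
                  tol = 1e-7)
  })
}

#' Rotate the Stokes reference plane
#'
#' Rotation of the reference plane by an angle `psi` about the propagation
#' direction mixes the linear components by `2*psi` and leaves S0 and S3
#' unchanged:
#' `S1' = S1 cos(2 psi) + S2 sin(2 psi)`,
#' `S2' = -S1 sin(2 psi) + S2 cos(2 psi)`.
#' Composition of rotations by `psi` and `-psi` is the identity; the
#' meridian-plane Monte Carlo uses this operator both to rotate into the
#' scattering plane and back into the new meridian plane.
#'
#' @param s A `stokes` vector.
#' @param psi Rotation angle in radians.
#' @return Rotated `stokes` vector.
#' @export
rotate_stokes <- function(s, psi) {
  s <- unclass(s)
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  stokes_vector(s[1],
                c2 * s[2] + s2 * s[3],
                -s2 * s[2] + c2 * s[3],
                s[4])
}
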