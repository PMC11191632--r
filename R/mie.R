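#' Series truncation order for Mie sums
#'
#' Wiscombe's validated stopping criterion,
#' `n_max = ceiling(x + 4.05 x^(1/3) + 2)`.
#'
#' @param x Size parameter (> 0).
#' @return Integer truncation order.
#' @export
mie_n_max <- function(x) {
  stopifnot(is.finite(x), x > 0)
  as.integer(ceiling(x + 4.05 * x^(1/3) + 2))
}

#' Mie coefficients a_n, b_n
#'
#' Scattering coefficients of a homogeneous sphere of relative refractive
#' index `m` and size parameter `x`:
#' \deqn{a_n = \frac{m\psi_n(mx)\psi_n'(x) - \psi_n(x)\psi_n'(mx)}
#'             {m\psi_n(mx)\xi_n'(x)  - \xi_n(x)\psi_n'(mx)}}
#' and the analogous `b_n` with the factors of `m` interchanged.
#' Evaluated in the standard numerically stable form: the logarithmic
#' derivative `D_n(mx) = psi_n'(mx)/psi_n(mx)` by downward recurrence
#' (seeded 15 orders above `n_max`), `psi_n(x)` and `xi_n(x)` by upward
#' recurrence.
#'
#' @param m Relative refractive index (real or complex).  `m = 1` is a
#'   non-scattering sphere: all coefficients are zero (with a warning).
#' @param x Size parameter (> 0).
#' @param n_max Truncation order, or `"auto"` (default) for
#'   [mie_n_max()].
#' @return List of class `mie_coefficients` with complex vectors `a`, `b`
#'   (length `n_max`), and `m`, `x`, `n_max`.
#' @examples
#' co <- mie_coefficients(1.195, 5)
#' Mod(co$a)    # all <= 1 for real m
#' @export
mie_coefficients <- function(m, x, n_max = "auto") {
  stopifnot(length(m) == 1L, length(x) == 1L, is.numeric(x),
            is.finite(x), x > 0)
  if (identical(n_max, "auto")) n_max <- mie_n_max(x)
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 1)

  if (identical(Mod(m - 1), 0)) {
    warning("m = 1: index-matched sphere scatters nothing; returning zero coefficients")
    out <- list(a = complex(n_max), b = complex(n_max),
                m = m, x = x, n_max = n_max)
    class(out) <- "mie_coefficients"
    return(out)
  }

  mx <- m * x
  # logarithmic derivative D_n(mx), downward
  nmx <- n_max + 15L
  D <- complex(nmx)
  for (n in nmx:2) {
    D[n - 1L] <- n / mx - 1 / (D[n] + n / mx)
  }

  # psi, chi upward (real x)
  psi <- numeric(n_max); chi <- numeric(n_max)
  psi_m1 <- sin(x); chi_m1 <- cos(x)              # order 0
  psi[1] <- sin(x) / x - cos(x)
  chi[1] <- cos(x) / x + sin(x)
  if (n_max >= 2) {
    for (n in 2:n_max) {
      psi[n] <- (2 * n - 1) / x * psi[n - 1L] - (if (n == 2) psi_m1 else psi[n - 2L])
      chi[n] <- (2 * n - 1) / x * chi[n - 1L] - (if (n == 2) chi_m1 else chi[n - 2L])
    }
  }
  xi <- complex(real = psi, imaginary = -chi)     # xi_n = psi_n - i chi_n = x h1_n
  psi_prev <- c(psi_m1, psi[-n_max])
  xi_prev  <- complex(real = psi_prev,
                      imaginary = -c(chi_m1, chi[-n_max]))

  n <- seq_len(n_max)
  Dn <- D[n]
  fa <- Dn / m + n / x
  fb <- Dn * m + n / x
  a <- (fa * psi - psi_prev) / (fa * xi - xi_prev)
  b <- (fb * psi - psi_prev) / (fb * xi - xi_prev)

  if (any(!is.finite(Re(a)) | !is.finite(Re(b)))) {
    stop("mie_coefficients: non-finite terms (series truncation error)")
  }
  out <- list(a = a, b = b, m = m, x = x, n_max = n_max)
  class(out) <- "mie_coefficients"
  out
}

#' Angle-dependent functions pi_n and tau_n
#'
#' The Mie angular functions built on the associated Legendre functions
#' P_n^1: `pi_n = P_n^1 / sin(theta)`, `tau_n = d P_n^1 / d theta`,
#' computed by the standard upward recurrences
#' `pi_n = ((2n-1)/(n-1)) cos(theta) pi_{n-1} - (n/(n-1)) pi_{n-2}` and
#' `tau_n = n cos(theta) pi_n - (n+1) pi_{n-1}` with seeds `pi_0 = 0`,
#' `pi_1 = 1`.
#'
#' @param theta Scattering angle in radians, in `[0, pi]` (may be a vector).
#' @param n_max Highest order.
#' @return List with matrices `pi_n`, `tau_n` of dimension
#'   `n_max x length(theta)` (row `n` is order `n`) and the input `theta`.
#' @export
angular_functions <- function(theta, n_max) {
  stopifnot(is.numeric(theta), all(is.finite(theta)),
            all(theta >= 0 - 1e-12), all(theta <= pi + 1e-12),
            n_max >= 1)
  n_max <- as.integer(n_max)
  mu <- cos(theta)
  nt <- length(theta)
  pi_n <- matrix(0, n_max, nt)
  tau_n <- matrix(0, n_max, nt)
  pi_n[1, ] <- 1
  tau_n[1, ] <- mu
  if (n_max >= 2) {
    pi_prev2 <- rep(0, nt)     # pi_0
    for (n in 2:n_max) {
      pi_n[n, ] <- (2 * n - 1) / (n - 1) * mu * pi_n[n - 1L, ] -
        n / (n - 1) * (if (n == 2) pi_prev2 else pi_n[n - 2L, ])
      tau_n[n, ] <- n * mu * pi_n[n, ] - (n + 1) * pi_n[n - 1L, ]
    }
  }
  list(theta = theta, pi_n = pi_n, tau_n = tau_n)
}

#' Scattering amplitude functions
#'
#' The two complex amplitudes of sphere scattering,
#' \deqn{M_1(\theta) = \sum_n \frac{2n+1}{n(n+1)} (a_n \pi_n + b_n \tau_n), \quad
#'       M_2(\theta) = \sum_n \frac{2n+1}{n(n+1)} (a_n \tau_n + b_n \pi_n)}
#' (`M_1` perpendicular, `M_2` parallel to the scattering plane; the
#' conventional S1, S2).
#'
#' @param m Relative refractive index.
#' @param x Size parameter.
#' @param theta Scattering angle(s) in radians.
#' @param coefficients Optional precomputed [mie_coefficients()] object.
#' @return List with `theta` and complex vectors `M1`, `M2`.
#' @export
amplitude_functions <- function(m, x, theta, coefficients = NULL) {
  co <- if (is.null(coefficients)) mie_coefficients(m, x) else coefficients
  ang <- angular_functions(theta, co$n_max)
  n <- seq_len(co$n_max)
  w <- (2 * n + 1) / (n * (n + 1))
  # amplitudes as matrix products over the order index
  M1 <- t(ang$pi_n) %*% (w * co$a) + t(ang$tau_n) %*% (w * co$b)
  M2 <- t(ang$tau_n) %*% (w * co$a) + t(ang$pi_n) %*% (w * co$b)
  list(theta = theta, M1 = drop(M1), M2 = drop(M2))
}

#' Sphere Mueller-matrix elements
#'
#' The four independent elements of the block-diagonal single-sphere
#' Mueller matrix:
#' \deqn{M_{11} = \tfrac12(|M_2|^2 + |M_1|^2),\;
#'       M_{12} = \tfrac12(|M_2|^2 - |M_1|^2),\;
#'       M_{33} = \mathrm{Re}(M_2 M_1^*),\;
#'       M_{34} = \mathrm{Im}(M_2 M_1^*).}
#' They satisfy the pure-Mueller identity
#' `M11^2 = M12^2 + M33^2 + M34^2` exactly, and the limits
#' `M33(0) = M11(0)` (forward scattering preserves circular polarization)
#' and `M33(pi) = -M11(pi)` (exact helicity flip on backscatter).
#'
#' @inheritParams amplitude_functions
#' @return Data frame with columns `theta`, `M11`, `M12`, `M33`, `M34`.
#' @examples
#' el <- mueller_elements(1.195, 10, c(0, pi/2, pi))
#' el$M33[1] / el$M11[1]    # +1
#' el$M33[3] / el$M11[3]    # -1
#' @export
mueller_elements <- function(m, x, theta, coefficients = NULL) {
  amp <- amplitude_functions(m, x, theta, coefficients)
  a1 <- Mod(amp$M1)^2
  a2 <- Mod(amp$M2)^2
  cross <- amp$M2 * Conj(amp$M1)
  data.frame(theta = theta,
             M11 = (a2 + a1) / 2,
             M12 = (a2 - a1) / 2,
             M33 = Re(cross),
             M34 = Im(cross))
}

#' Default fringe-resolving scattering-angle grid
#'
#' Mie angular patterns carry interference fringes of period ~ `pi/x`
#' radians; the default grid step is `min(0.1, 180/(20*x))` degrees with
#' the endpoints 0 and 180 degrees included exactly.
#'
#' @param x Size parameter.
#' @param refine Integer refinement factor (halves the step `refine`
#'   times); used for quadrature convergence checks.
#' @return Numeric vector of angles in radians spanning `[0, pi]`.
#' @export
default_theta_grid <- function(x, refine = 0L) {
  step_deg <- min(0.1, 180 / (20 * x)) / 2^refine
  n <- ceiling(180 / step_deg)
  seq(0, pi, length.out = n + 1L)
}
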