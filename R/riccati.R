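#' Riccati-Bessel functions and derivatives
#'
#' Computes the Riccati-Bessel functions
#' \deqn{\psi_n(z) = z\,j_n(z), \qquad \xi_n(z) = z\,(j_n(z) + i\,y_n(z)) = z\,h_n^{(1)}(z)}
#' and their first derivatives for orders `n = 1..n_max`, for real or
#' complex argument (complex arguments arise as `m*x` when the particle
#' index is complex).
#'
#' `psi` is evaluated by Miller's downward recurrence for the spherical
#' Bessel functions `j_n` (started well above `n_max` and normalized with
#' `j_0 = sin(z)/z`), which is stable for all orders; the irregular part
#' `y_n` uses the upward recurrence, stable in that direction.  Derivatives
#' follow from `psi_n' = psi_{n-1} - n psi_n / z`.
#'
#' @param x Argument `z` (real or complex, nonzero).
#' @param n_max Highest order (integer >= 1).
#' @return A list with complex vectors `psi`, `dpsi`, `xi`, `dxi`
#'   (element `n` is order `n`) plus the order-0 values `psi0`, `xi0`.
#'   For real `x` the `psi` components are real-valued (returned as real).
#' @examples
#' rb <- riccati_bessel(2, 5)
#' rb$psi[1]          # sin(2)/2 - cos(2)
#' @export
riccati_bessel <- function(x, n_max) {
  stopifnot(length(x) == 1L, is.numeric(x) || is.complex(x),
            is.finite(Re(x)), is.finite(Im(as.complex(x))),
            Mod(x) > 0,
            length(n_max) == 1L, n_max >= 1)
  n_max <- as.integer(n_max)
  z <- as.complex(x)

  # downward recurrence for j_n (Miller), extra headroom above n_max
  n_start <- n_max + max(15L, ceiling(Mod(z)^(1/3) * 4))
  j <- complex(n_start + 2L)
  j[n_start + 2L] <- 0
  j[n_start + 1L] <- 1e-30
  for (n in n_start:1) {            # index shift: j[k] holds order k-1
    j[n] <- (2 * n + 1) / z * j[n + 1L] - j[n + 2L]
  }
  scale <- (sin(z) / z) / j[1L]
  j <- j * scale

  # upward recurrence for y_n
  y <- complex(n_max + 1L)
  y[1L] <- -cos(z) / z
  y[2L] <- -cos(z) / z^2 - sin(z) / z
  if (n_max >= 2) {
    for (n in 2:n_max) y[n + 1L] <- (2 * n - 1) / z * y[n] - y[n - 1L]
  }

  psi_all <- z * j[seq_len(n_max + 1L)]         # orders 0..n_max
  xi_all  <- z * (j[seq_len(n_max + 1L)] + 1i * y)
  if (any(!is.finite(Re(xi_all)) | !is.finite(Im(xi_all)))) {
    stop("riccati_bessel: overflow in xi_n; series truncation too aggressive for this argument")
  }
  n <- seq_len(n_max)
  dpsi <- psi_all[n] - n * psi_all[n + 1L] / z
  dxi  <- xi_all[n]  - n * xi_all[n + 1L] / z

  drop_imag <- function(v) if (all(abs(Im(v)) < 1e-12 * (abs(Re(v)) + 1))) Re(v) else v
  out <- list(psi = psi_all[n + 1L], dpsi = dpsi,
              xi = xi_all[n + 1L], dxi = dxi,
              psi0 = psi_all[1L], xi0 = xi_all[1L])
  if (is.numeric(x)) {
    out$psi  <- drop_imag(out$psi)
    out$dpsi <- drop_imag(out$dpsi)
    out$psi0 <- drop_imag(out$psi0)
  }
  out
}
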