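#' Angular intensity and circular-polarization profile of one scattering event
#'
#' For an incident Stokes vector scattered once by a sphere, returns the
#' relative scattered intensity S0'(theta) and the degree of circular
#' polarization s3(theta) = S3'/S0' over a fringe-resolving angular grid.
#' For circularly polarized input the azimuthal symmetry makes
#' `s3 = M33/M11` exactly.
#'
#' @param ctx An [optical_context()].
#' @param s_in Incident [stokes_vector()]; default right-circular (1,0,0,1).
#' @param theta_grid Angles in radians within `[0, pi]`; default
#'   [default_theta_grid()] for the context's size parameter.
#' @return Data frame of class `angular_profile` with columns `theta`,
#'   `intensity` (relative), `s3`.
#' @examples
#' prof <- angular_profile(optical_context(1000, 9))
#' prof$s3[1]                    # +1 in the exact forward direction
#' @export
angular_profile <- function(ctx, s_in = stokes_vector(1, 0, 0, 1),
                            theta_grid = NULL) {
  stopifnot(inherits(ctx, "optical_context"))
  if (is.null(theta_grid)) theta_grid <- default_theta_grid(ctx$x)
  stopifnot(all(theta_grid >= -1e-12), all(theta_grid <= pi + 1e-12))
  el <- mueller_elements(ctx$m, ctx$x, theta_grid)
  s <- unclass(s_in)
  s0p <- el$M11 * s[1] + el$M12 * s[2]
  s3p <- -el$M34 * s[3] + el$M33 * s[4]
  out <- data.frame(theta = theta_grid, intensity = s0p, s3 = s3p / s0p)
  class(out) <- c("angular_profile", class(out))
  out
}

#' Expected circular polarization after a single scattering event
#'
#' The mean S3 emitted by one scattering event of right-circular light,
#' i.e. the scattering-probability-weighted (solid-angle) average of the
#' per-angle degree of circular polarization:
#' \deqn{\langle S_3\rangle = \frac{\int_0^\pi M_{33}(\theta)\sin\theta\,d\theta}
#'                                 {\int_0^\pi M_{11}(\theta)\sin\theta\,d\theta}.}
#' Quadrature is composite Simpson on the fringe-resolving grid, refined
#' (step halving) until successive estimates agree to `tol`.
#'
#' @param m Relative refractive index (used with `X`).
#' @param X Generalized size parameter, diameter/wavelength.
#' @param ctx Alternatively, an [optical_context()] (overrides `m`, `X`).
#' @param n_medium Medium index used to convert `X` to the Mie size
#'   parameter `x = pi * X * n_medium` (default 1.33).
#' @param tol Convergence tolerance on the refinement (default 1e-6).
#' @param max_refine Maximum number of step halvings (default 3).
#' @return Scalar `<S3>` in `[-1, 1]`.
#' @examples
#' expected_s3_single(1.195, 9)
#' @export
expected_s3_single <- function(m = NULL, X = NULL, ctx = NULL,
                               n_medium = 1.33, tol = 1e-6, max_refine = 3L) {
  if (!is.null(ctx)) {
    stopifnot(inherits(ctx, "optical_context"))
    m <- ctx$m; x <- ctx$x
  } else {
    stopifnot(is.numeric(m), is.numeric(X), X > 0)
    x <- pi * X * n_medium
  }
  co <- mie_coefficients(m, x)
  est_prev <- NA_real_
  for (r in 0:max_refine) {
    grid <- default_theta_grid(x, refine = r)
    el <- mueller_elements(m, x, grid, coefficients = co)
    num <- simpson(grid, el$M33 * sin(grid))
    den <- simpson(grid, el$M11 * sin(grid))
    est <- num / den
    if (!is.na(est_prev) && abs(est - est_prev) < tol) return(est)
    est_prev <- est
  }
  if (max_refine == 0L) return(est_prev)
  warning(sprintf(
    "expected_s3_single: quadrature change %.2e above tol after %d refinements (grid %d points)",
    abs(est - est_prev), max_refine, length(grid)))
  est
}

# composite Simpson on a uniform grid (falls back to trapezoid on the
# final interval when the point count is even)
simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  h <- x[2] - x[1]
  m <- if (n %% 2L == 1L) n else n - 1L
  i <- seq(2L, m - 1L)
  w <- rep(c(4, 2), length.out = m - 2L)
  s <- h / 3 * (y[1] + sum(w * y[i]) + y[m])
  if (m < n) s <- s + h * (y[n] + y[n - 1L]) / 2
  s
}

#' Detect depolarization minima of an expected-S3 curve
#'
#' Local minima of `<S3>(X)` mark the generalized size parameters at which
#' single scattering depolarizes circularly polarized light most strongly.
#' The curve carries two scales of structure: broad interference dips
#' (width ~1 in X) and much finer morphology-dependent resonance ripple.
#' The curve is therefore first lightly smoothed (centered moving average
#' over a window in X), and a minimum is reported as *pronounced* when its
#' depth below the local upper envelope of the curve (a moving maximum
#' over `envelope_halfwidth` on each side) exceeds `prominence`.  The
#' envelope-relative depth, rather than classic topographic prominence,
#' correctly ranks dips that sit inside a wider depression (e.g. the
#' neighbouring troughs near X = 9 and X = 12) and rejects ripple minima
#' on a low saddle.
#'
#' @param curve Data frame with columns `X` and `s3` (e.g. from
#'   [sweep_expected_s3()]), or a numeric vector `s3` with `X` supplied
#'   separately.
#' @param X Optional X grid when `curve` is a bare numeric vector.
#' @param prominence Minimum envelope-relative depth in `<S3>` units
#'   (default 0.015, which admits the dominant troughs while rejecting
#'   saddle ripple; the weak outer troughs near X = 17, 19, 22, 26 are
#'   shallow resonance dips and need `smooth_window = 0` with a threshold
#'   around 0.008 to be picked up).
#' @param smooth_window Moving-average window width in X units
#'   (default 0.3); set to 0 to disable smoothing.  When positive, the
#'   effective window is never narrower than two grid steps: structure
#'   narrower than that is aliased by the sampling and cannot be a
#'   resolved trough (this matters for coarse Monte Carlo sweeps, where
#'   narrow single-scattering resonance dips alias onto single grid
#'   points).
#' @param envelope_halfwidth Half-width in X units of the moving-maximum
#'   upper envelope (default 2.5).
#' @param min_separation Minima closer than this in X to a deeper
#'   minimum are treated as ripple on the same trough and pruned
#'   (default 2.0 -- distinct troughs of the expected-S3 curve are never
#'   closer than about two X units); set to 0 to disable pruning.
#' @return Data frame with columns `X` (minimum locations, ascending),
#'   `s3` (smoothed value there) and `prominence` (depth below envelope).
#' @examples
#' xs <- seq(0, 20, 0.05)
#' find_depolarization_minima(data.frame(X = xs, s3 = cos(xs) + xs / 100),
#'                            smooth_window = 0)
#' @export
find_depolarization_minima <- function(curve, X = NULL, prominence = 0.015,
                                       smooth_window = 0.3,
                                       envelope_halfwidth = 2.5,
                                       min_separation = 2.0) {
  if (is.data.frame(curve)) {
    stopifnot(all(c("X", "s3") %in% names(curve)))
    xg <- curve$X; y <- curve$s3
  } else {
    stopifnot(is.numeric(curve), !is.null(X), length(X) == length(curve))
    xg <- X; y <- curve
  }
  if (length(y) == 0L) stop("find_depolarization_minima: empty curve")
  if (length(y) < 3L) {
    return(data.frame(X = numeric(), s3 = numeric(), prominence = numeric()))
  }
  step <- median(diff(xg))
  if (smooth_window > 0 && step > 0) {
    smooth_window <- max(smooth_window, 2 * step)   # Nyquist floor
    k <- max(1L, round(smooth_window / step))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L && k < length(y)) {
      y <- stats::filter(y, rep(1 / k, k), sides = 2)
      keep <- !is.na(y)
      y <- as.numeric(y[keep]); xg <- xg[keep]
    }
  }
  n <- length(y)
  is_min <- which(diff(sign(diff(y))) > 0) + 1L
  if (length(is_min) == 0L) {
    return(data.frame(X = numeric(), s3 = numeric(), prominence = numeric()))
  }
  k_env <- max(1L, round(envelope_halfwidth / max(step, 1e-12)))
  envelope <- vapply(seq_len(n), function(i) {
    max(y[max(1L, i - k_env):min(n, i + k_env)])
  }, numeric(1))
  prom <- envelope[is_min] - y[is_min]
  keep <- prom >= prominence
  out <- data.frame(X = xg[is_min][keep], s3 = y[is_min][keep],
                    prominence = prom[keep])
  # prune minima closer than min_separation to a deeper one (greedy,
  # deepest first), so each reported trough is the local champion
  if (nrow(out) > 1L && min_separation > 0) {
    ord <- order(-out$prominence)
    kept <- numeric(0)
    keep_row <- logical(nrow(out))
    for (i in ord) {
      if (!length(kept) || min(abs(out$X[i] - kept)) > min_separation) {
        kept <- c(kept, out$X[i])
        keep_row[i] <- TRUE
      }
    }
    out <- out[keep_row, ]
    rownames(out) <- NULL
  }
  out
}
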