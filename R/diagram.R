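#' Expected single-scattering S3 over a grid of size parameters
#'
#' Sweeps [expected_s3_single()] over a grid of generalized size
#' parameters X = diameter/wavelength at fixed relative index m, the
#' single-scattering depolarization curve whose troughs mark the
#' strongly depolarizing particle-size-to-wavelength ratios.
#'
#' @param m Relative refractive index.
#' @param X_grid Increasing grid of X values (> 0).
#' @param n_medium Medium index (converts X to the Mie parameter x).
#' @param tol,max_refine Quadrature controls, see [expected_s3_single()].
#' @return Data frame of class `expected_s3_curve` with columns `X`,
#'   `s3`; attribute `m`.
#' @examples
#' \donttest{
#' cv <- sweep_expected_s3(1.195, seq(7, 11, 0.5))
#' }
#' @export
sweep_expected_s3 <- function(m, X_grid, n_medium = 1.33,
                              tol = 1e-6, max_refine = 1L) {
  stopifnot(all(X_grid > 0), !is.unsorted(X_grid))
  s3 <- vapply(X_grid, function(X) {
    expected_s3_single(m, X, n_medium = n_medium, tol = tol,
                       max_refine = max_refine)
  }, numeric(1))
  out <- data.frame(X = X_grid, s3 = s3)
  attr(out, "m") <- m
  class(out) <- c("expected_s3_curve", class(out))
  out
}

#' Monte Carlo resultant S3 over a grid of size parameters
#'
#' For each X the particle diameter is set to `a = X * lambda` at fixed
#' wavelength (default 1000 nm) and a full slab simulation is run; the
#' detected mean S3 in each geometry traces the multiple-scattering
#' counterpart of the single-scattering curve.  Per-point seeds are
#' `seed + point index` so the sweep is reproducible and cells are
#' independent.
#'
#' @param X_grid Increasing grid of X values.
#' @param photons Photons per grid point (>= 1).
#' @param seed Base seed.
#' @param lambda_nm Fixed wavelength (default 1000).
#' @param geometry `"reflection"`, `"transmission"` or `"both"` (one
#'   transport run scores both sides; this only filters the output).
#' @param config Base configuration overridden per point.
#' @return Data frame with columns `X`, `geometry`, `s3_mean`, `se`,
#'   `n_detected`, `n_events_mean`.
#' @export
sweep_mc_s3 <- function(X_grid, photons = 20000L, seed = 1L,
                        lambda_nm = 1000,
                        geometry = c("both", "reflection", "transmission"),
                        config = default_config()) {
  geometry <- match.arg(geometry)
  stopifnot(all(X_grid > 0), !is.unsorted(X_grid), photons >= 1)
  rows <- list()
  for (i in seq_along(X_grid)) {
    cfg <- merge_config(unclass(config), list(
      medium = list(wavelength_nm = lambda_nm,
                    diameter_um = X_grid[i] * lambda_nm * 1e-3),
      photons = as.integer(photons),
      seed = as.integer(seed + i)))
    res <- simulate_slab(validate_config(cfg))
    for (g in c("reflection", "transmission")) {
      if (geometry != "both" && geometry != g) next
      s <- res[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        X = X_grid[i], geometry = g, s3_mean = s$mean_s3, se = s$se,
        n_detected = s$n_detected, n_events_mean = s$n_events_mean)
    }
  }
  do.call(rbind, rows)
}

#' Build a depolarization diagram over (diameter, wavelength)
#'
#' Mean resultant S3 on a diameter x wavelength lattice.  For
#' `geometry = "single"` the value depends on (m, X) only, so cells
#' sharing the same X = a/lambda are computed once and reused; Monte
#' Carlo cells (`"reflection"`, `"transmission"`) are always simulated,
#' with per-cell seed `seed + cell index`.
#'
#' @param a_grid Increasing diameters (um).
#' @param lambda_grid Increasing wavelengths (nm); the canonical diagram
#'   covers 600-1500 nm.
#' @param geometry `"single"`, `"reflection"` or `"transmission"`.
#' @param photons Photons per MC cell.
#' @param seed Base seed for MC cells.
#' @param n_particle,n_medium Refractive indices.
#' @param config Base MC configuration.
#' @return Object of class `diagram_grid`: `a_um`, `lambda_nm`, matrix
#'   `values` (rows = wavelengths, cols = diameters), `geometry`, and for
#'   MC grids `se` and `n_detected` matrices plus `mc_meta`.
#' @export
build_diagram <- function(a_grid, lambda_grid,
                          geometry = c("single", "reflection", "transmission"),
                          photons = 20000L, seed = 1L,
                          n_particle = 1.59, n_medium = 1.33,
                          config = default_config()) {
  geometry <- match.arg(geometry)
  stopifnot(all(a_grid > 0), !is.unsorted(a_grid), length(a_grid) >= 1,
            all(lambda_grid > 0), !is.unsorted(lambda_grid))
  m <- n_particle / n_medium
  nl <- length(lambda_grid); na <- length(a_grid)
  vals <- matrix(NA_real_, nl, na)
  se <- nd <- NULL
  if (geometry == "single") {
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nl)) for (j in seq_len(na)) {
      X <- a_grid[j] / (lambda_grid[i] * 1e-3)
      key <- sprintf("%.12g", X)
      if (is.null(cache[[key]])) {
        cache[[key]] <- expected_s3_single(m, X, n_medium = n_medium,
                                           max_refine = 1L)
      }
      vals[i, j] <- cache[[key]]
    }
  } else {
    se <- nd <- matrix(NA_real_, nl, na)
    cell <- 0L
    for (i in seq_len(nl)) for (j in seq_len(na)) {
      cell <- cell + 1L
      cfg <- merge_config(unclass(config), list(
        medium = list(wavelength_nm = lambda_grid[i],
                      diameter_um = a_grid[j],
                      n_particle = n_particle, n_medium = n_medium),
        photons = as.integer(photons),
        seed = as.integer(seed + cell)))
      s <- simulate_slab(validate_config(cfg))[[geometry]]
      vals[i, j] <- s$mean_s3; se[i, j] <- s$se; nd[i, j] <- s$n_detected
    }
  }
  structure(list(a_um = a_grid, lambda_nm = lambda_grid, values = vals,
                 se = se, n_detected = nd, geometry = geometry,
                 mc_meta = if (geometry != "single")
                   list(photons = photons, seed = seed)),
            class = "diagram_grid")
}

#' Single-scattering depolarization map over (X, m)
#'
#' Expected single-scattering S3 on a lattice of generalized size
#' parameter X (columns... rows = m values, cols = X values).  Cells with
#' m <= 1 are not computed (flagged NA): index-matched or inverted
#' contrast is outside the sphere-in-lower-index-medium model and
#' scattering vanishes near m = 1.
#'
#' @param m_grid Increasing relative-index grid (values <= 1 flagged).
#' @param X_grid Increasing X grid.
#' @param n_medium Medium index.
#' @return `diagram_grid` with `axis` fields `X` and `m`
#'   (`values[i, j]` = m_grid[i], X_grid[j]), geometry `"single"`.
#' @export
refractive_map <- function(m_grid, X_grid, n_medium = 1.33) {
  stopifnot(!is.unsorted(m_grid), !is.unsorted(X_grid), all(X_grid > 0))
  vals <- matrix(NA_real_, length(m_grid), length(X_grid))
  for (i in seq_along(m_grid)) {
    if (m_grid[i] <= 1) next
    for (j in seq_along(X_grid)) {
      vals[i, j] <- expected_s3_single(m_grid[i], X_grid[j],
                                       n_medium = n_medium, max_refine = 1L)
    }
  }
  structure(list(m = m_grid, X = X_grid, values = vals,
                 geometry = "single", axes = c("m", "X")),
            class = c("refractive_map", "diagram_grid"))
}

#' Extract iso-X depolarization lines from a diagram
#'
#' The strongly depolarizing regions of a (diameter, wavelength) diagram
#' are rays a = X * lambda through the origin, so every cell is first
#' mapped to its generalized size parameter X = a/lambda (for
#' single-scattering grids all rows sample the same underlying curve;
#' for Monte Carlo grids the pooling also averages independent noise).
#' The pooled profile is reduced to a median per X bin and scanned with
#' [find_depolarization_minima()]; each detected trough becomes a line,
#' reported with its exact ray endpoints at the diagram's wavelength
#' range and the number of wavelength rows sampling it.
#'
#' @param grid A `diagram_grid` from [build_diagram()].
#' @param prominence,smooth_window,min_separation Passed to
#'   [find_depolarization_minima()] (defaults 0.015 / 0.3 / 2.0, the
#'   "pronounced trough" operating point; use `prominence = 0.008`,
#'   `smooth_window = 0`, `min_separation = 0.6` to pick up weak narrow
#'   lines such as X = 22).
#' @param min_row_fraction Minimum fraction of wavelength rows whose X
#'   range covers the line (default 0.5).
#' @return Data frame of class `depolarization_lines`: `X_value`,
#'   endpoints `a_at_lambda_min`/`a_at_lambda_max` (um), `lambda_min_nm`,
#'   `lambda_max_nm`, `strength` (envelope depth), `n_rows`.
#' @export
extract_lines <- function(grid, prominence = 0.015, smooth_window = 0.3,
                          min_separation = 2.0, min_row_fraction = 0.5) {
  stopifnot(inherits(grid, "diagram_grid"), !is.null(grid$a_um))
  pts <- do.call(rbind, lapply(seq_along(grid$lambda_nm), function(i) {
    data.frame(row = i, X = grid$a_um / (grid$lambda_nm[i] * 1e-3),
               s3 = grid$values[i, ])
  }))
  pts <- pts[is.finite(pts$s3), ]
  empty <- structure(
    data.frame(X_value = numeric(), a_at_lambda_min = numeric(),
               a_at_lambda_max = numeric(), lambda_min_nm = numeric(),
               lambda_max_nm = numeric(), strength = numeric(),
               n_rows = integer()),
    class = c("depolarization_lines", "data.frame"))
  if (nrow(pts) < 5L) return(empty)

  # median-binned profile on the finest row resolution
  bw <- min(diff(grid$a_um)) / (max(grid$lambda_nm) * 1e-3)
  bin <- round(pts$X / bw)
  prof <- data.frame(
    X = tapply(pts$X, bin, median),
    s3 = tapply(pts$s3, bin, median))
  prof <- prof[order(prof$X), ]
  mm <- find_depolarization_minima(prof, prominence = prominence,
                                   smooth_window = smooth_window,
                                   min_separation = min_separation)
  if (!nrow(mm)) return(empty)

  nl <- length(grid$lambda_nm)
  rows_covering <- vapply(mm$X, function(Xv) {
    sum(vapply(seq_len(nl), function(i) {
      Xr <- range(grid$a_um) / (grid$lambda_nm[i] * 1e-3)
      Xv >= Xr[1] && Xv <= Xr[2]
    }, logical(1)))
  }, numeric(1))
  keep <- rows_covering >= min_row_fraction * nl
  if (!any(keep)) return(empty)
  out <- data.frame(X_value = mm$X[keep],
                    a_at_lambda_min = mm$X[keep] * min(grid$lambda_nm) * 1e-3,
                    a_at_lambda_max = mm$X[keep] * max(grid$lambda_nm) * 1e-3,
                    lambda_min_nm = min(grid$lambda_nm),
                    lambda_max_nm = max(grid$lambda_nm),
                    strength = mm$prominence[keep],
                    n_rows = as.integer(rows_covering[keep]))
  structure(out, class = c("depolarization_lines", "data.frame"))
}

#' Render a depolarization diagram as a heat map
#'
#' @param x A `diagram_grid`.
#' @param zlim Colour range (default the S3 window `c(0, 1)` clamped to
#'   the data).
#' @param ... Passed to [graphics::image()].
#' @export
plot.diagram_grid <- function(x, zlim = NULL, ...) {
  if (!is.null(x$a_um)) {
    xs <- x$a_um; ys <- x$lambda_nm
    xlab <- "diameter a (um)"; ylab <- "wavelength (nm)"
  } else {
    xs <- x$X; ys <- x$m
    xlab <- "generalized size parameter X"; ylab <- "relative index m"
  }
  z <- t(x$values)
  if (is.null(zlim)) zlim <- range(0, 1, z, finite = TRUE)
  graphics::image(xs, ys, z, zlim = zlim, xlab = xlab, ylab = ylab,
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE), ...)
  invisible(x)
}

#' Write a diagram to long-format CSV plus JSON metadata
#'
#' @param grid A `diagram_grid`.
#' @param csv_path Output CSV (columns a_um, lambda_nm, s3_mean and, for
#'   MC grids, s3_se, n_detected).
#' @param json_path Optional JSON metadata path (geometry, seeds).
#' @return `csv_path`, invisibly.
#' @export
write_diagram <- function(grid, csv_path, json_path = NULL) {
  stopifnot(inherits(grid, "diagram_grid"), !is.null(grid$a_um))
  long <- expand.grid(lambda_nm = grid$lambda_nm, a_um = grid$a_um)
  long$s3_mean <- as.vector(grid$values)
  if (!is.null(grid$se)) {
    long$s3_se <- as.vector(grid$se)
    long$n_detected <- as.vector(grid$n_detected)
  }
  long <- long[, c("a_um", "lambda_nm", setdiff(names(long),
                                                c("a_um", "lambda_nm")))]
  write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(geometry = grid$geometry,
                              mc_meta = grid$mc_meta,
                              a_um = grid$a_um,
                              lambda_nm = grid$lambda_nm),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
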