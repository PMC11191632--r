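#' Optical description of the turbid medium
#'
#' Absorption and scattering coefficients of the slab plus the particle /
#' host optics.  Defaults are the fixed baseline of the slab model:
#' `mu_a = 0.10` and `mu_s = 6.86` per mm, polystyrene-like particles
#' (n = 1.59) in water (n = 1.33).  The coefficients are deliberately
#' independent of wavelength and particle size: they set the number of
#' scattering events, while the single-event polarization physics is
#' carried entirely by (m, x).
#'
#' @param mu_a Absorption coefficient (1/mm, >= 0).
#' @param mu_s Scattering coefficient (1/mm, > 0).
#' @param wavelength_nm,diameter_um,n_particle,n_medium Passed to
#'   [optical_context()].
#' @return List of class `medium_optics` (includes the derived `ctx`).
#' @export
medium_optics <- function(mu_a = 0.10, mu_s = 6.86,
                          wavelength_nm = 1000, diameter_um = 10,
                          n_particle = 1.59, n_medium = 1.33) {
  stopifnot(is.numeric(mu_a), mu_a >= 0, is.numeric(mu_s), mu_s > 0)
  out <- list(mu_a = mu_a, mu_s = mu_s,
              ctx = optical_context(wavelength_nm, diameter_um,
                                    n_particle, n_medium))
  class(out) <- "medium_optics"
  out
}

#' Slab geometry
#'
#' The scattering slab: lateral width along x (default 12 mm, wide enough
#' that lateral losses are negligible) and depth along the beam axis
#' (default 6 mm).  The origin is the centre of the illuminated surface.
#'
#' @param width_mm Lateral extent (> 0).
#' @param depth_mm Thickness (> 0).
#' @return List of class `slab_geometry`.
#' @export
slab_geometry <- function(width_mm = 12, depth_mm = 6) {
  stopifnot(width_mm > 0, depth_mm > 0)
  structure(list(width_mm = width_mm, depth_mm = depth_mm),
            class = "slab_geometry")
}

#' Sample exponential free path lengths
#'
#' Step lengths between interactions, `s = -log(u)/mu_t` with `u` uniform
#' on (0, 1].
#'
#' @param mu_t Total attenuation coefficient `mu_a + mu_s` (1/mm, > 0).
#' @param n Number of samples.
#' @return Numeric vector of path lengths in mm.
#' @export
sample_step <- function(mu_t, n = 1L) {
  stopifnot(mu_t > 0)
  -log(runif(n)) / mu_t
}

#' Tabulated Mueller phase table for Monte Carlo sampling
#'
#' Precomputes the four sphere Mueller elements on a fringe-resolving
#' angular grid together with the cumulative distribution of the
#' unpolarized phase function `M11 sin(theta)`; the transport kernel and
#' the angle samplers interpolate in this table.
#'
#' @param m Relative refractive index.
#' @param x Mie size parameter.
#' @return List of class `phase_table`: `theta`, `M11`, `M12`, `M33`,
#'   `M34`, `cdf`, and `m`, `x`.
#' @export
phase_table <- function(m, x) {
  grid <- default_theta_grid(x)
  el <- mueller_elements(m, x, grid)
  seg <- diff(grid) * (head(el$M11 * sin(grid), -1) +
                       tail(el$M11 * sin(grid), -1)) / 2
  cdf <- c(0, cumsum(seg))
  structure(list(theta = grid, M11 = el$M11, M12 = el$M12,
                 M33 = el$M33, M34 = el$M34,
                 cdf = cdf / cdf[length(cdf)], m = m, x = x),
            class = "phase_table")
}

#' Rejection-sample scattering and azimuth angles
#'
#' Draws (theta, phi) pairs from the meridian-plane bivariate density of a
#' polarized scattering event,
#' \deqn{P(\theta,\phi) \propto [M_{11} S_0 + M_{12}(S_1\cos 2\phi +
#'       S_2\sin 2\phi)]\,\sin\theta,}
#' by plain rejection against a flat envelope at the global maximum of the
#' density (the textbook method).  For circular input the phi marginal is
#' uniform and the theta marginal reduces to the unpolarized phase
#' function `M11 sin(theta)`.
#'
#' The transport kernel itself uses the exact marginal/conditional
#' decomposition of the same density (inverse-CDF in theta, bounded
#' rejection in phi), which is distributionally identical but orders of
#' magnitude faster for forward-peaked phase functions; this sampler is
#' the reference implementation the kernel is validated against.
#'
#' @param stokes Incident [stokes_vector()], normalized to `S0 = 1`.
#' @param m,x Optical parameters (ignored when `table` given).
#' @param n Number of draws.
#' @param table Optional precomputed [phase_table()].
#' @param min_acceptance Error out below this acceptance rate.
#' @return Data frame with columns `theta`, `phi`.
#' @export
rejection_sample_angles <- function(stokes, m = NULL, x = NULL, n = 1L,
                                    table = NULL, min_acceptance = 1e-3) {
  s <- unclass(stokes)
  stopifnot(abs(s[1] - 1) < 1e-9)
  tb <- if (is.null(table)) phase_table(m, x) else table
  # global max of the density over (theta, phi)
  amp <- sqrt(s[2]^2 + s[3]^2)
  dens_max <- max((tb$M11 + abs(tb$M12) * amp) * sin(tb$theta)) * 1.0000001
  th_out <- numeric(0); ph_out <- numeric(0)
  proposed <- 0L
  while (length(th_out) < n) {
    batch <- max(2048L, ceiling((n - length(th_out)) * 4))
    th <- runif(batch, 0, pi)
    ph <- runif(batch, 0, 2 * pi)
    m11 <- approx(tb$theta, tb$M11, th)$y
    m12 <- approx(tb$theta, tb$M12, th)$y
    dens <- (m11 + m12 * (s[2] * cos(2 * ph) + s[3] * sin(2 * ph))) * sin(th)
    acc <- runif(batch) * dens_max <= dens
    th_out <- c(th_out, th[acc]); ph_out <- c(ph_out, ph[acc])
    proposed <- proposed + batch
    if (proposed > 1e4 && length(th_out) / proposed < min_acceptance) {
      stop(sprintf(
        "rejection_sample_angles: acceptance rate %.2e below %g; envelope too loose for x = %g",
        length(th_out) / proposed, min_acceptance, tb$x))
    }
  }
  data.frame(theta = th_out[seq_len(n)], phi = ph_out[seq_len(n)])
}

#' Run the polarized Monte Carlo slab simulation
#'
#' Launches right-circularly polarized photon packets into the slab at
#' the origin (1 degree off the inward normal), transports them with
#' exponential steps, polarized Mie scattering and implicit-capture
#' absorption, and scores every packet that leaves through the top
#' (reflection side) or bottom (transmission side) surface.  Detected
#' packets are those exiting within the configured detector strips; the
#' reported `mean_s3` is their intensity-weighted mean degree of circular
#' polarization, averaged over all exit angles.
#'
#' Given the same config (including `seed`) the result is bit-identical.
#'
#' @param config A run configuration from [default_config()] /
#'   [load_config()] / [make_fixture()] (or a list merged onto the
#'   defaults).
#' @param keep_records Keep per-photon detection records (matrix
#'   `records`)?  Default from config.
#' @param passage Accumulate passage-probability maps of detected
#'   trajectories?  Default from config.
#' @return Object of class `mc_result`: per-geometry summaries
#'   (`mean_s3`, `se`, `n_detected`, `n_events_mean`, `phi_bins`),
#'   conservation tallies, and optionally `records` and passage maps.
#' @examples
#' \donttest{
#' res <- simulate_slab(make_fixture("smoke"))
#' res$reflection$mean_s3
#' }
#' @export
simulate_slab <- function(config, keep_records = NULL, passage = NULL) {
  config <- validate_config(config)
  if (is.null(keep_records)) keep_records <- isTRUE(config$keep_records)
  if (is.null(passage)) passage <- isTRUE(config$passage$enabled)
  med <- config$medium
  ctx <- optical_context(med$wavelength_nm, med$diameter_um,
                         med$n_particle, med$n_medium)
  tb <- phase_table(ctx$m, ctx$x)
  set.seed(config$seed)
  raw <- .mc_kernel(tb$theta, tb$M11, tb$M12, tb$M33, tb$M34,
                    med$mu_a, med$mu_s,
                    config$slab$width_mm / 2, config$slab$depth_mm,
                    config$detectors$strip_half_mm,
                    config$detectors$reflection[1], config$detectors$reflection[2],
                    config$detectors$transmission[1], config$detectors$transmission[2],
                    as.integer(config$photons),
                    config$incident_deg * pi / 180,
                    config$weight_min, config$p_survive,
                    as.integer(config$max_events),
                    keep_records, passage,
                    as.integer(config$passage$nx), as.integer(config$passage$nz))

  side_summary <- function(sl) {
    if (sl$w <= 0) {
      return(list(mean_s3 = NA_real_, se = NA_real_, n_detected = 0L,
                  n_events_mean = NA_real_, phi_bins = NULL,
                  sum_weight = 0, weight_outside = sl$w_outside))
    }
    mean_s3 <- sl$ws3 / sl$w
    v <- max(0, sl$ws3sq / sl$w - mean_s3^2)
    bins <- data.frame(phi_deg_lo = seq(0, 80, 10), phi_deg_hi = seq(10, 90, 10),
                       weight = sl$bin_w,
                       mean_s3 = ifelse(sl$bin_w > 0, sl$bin_ws3 / sl$bin_w, NA))
    list(mean_s3 = mean_s3, se = sqrt(v / sl$n), n_detected = sl$n,
         n_events_mean = sl$wev / sl$w, phi_bins = bins,
         sum_weight = sl$w, weight_outside = sl$w_outside)
  }
  out <- list(
    reflection = side_summary(raw$reflection),
    transmission = side_summary(raw$transmission),
    conservation = list(
      n_photons = raw$n_photons,
      detected = raw$reflection$w + raw$transmission$w,
      exited_outside_detectors = raw$reflection$w_outside + raw$transmission$w_outside,
      lateral_escape = raw$lateral_escape,
      absorbed = raw$absorbed,
      roulette_kill = raw$roulette_kill,
      roulette_gain = raw$roulette_gain,
      n_runaway = raw$n_runaway,
      total_events = raw$total_events),
    config = config)
  if (keep_records) out$records <- raw$records
  if (passage) {
    norm_map <- function(mp) if (max(mp) > 0) mp / max(mp) else mp
    out$passage <- list(reflection = norm_map(raw$map_reflection),
                        transmission = norm_map(raw$map_trans),
                        x_mm = seq(-config$slab$width_mm / 2,
                                   config$slab$width_mm / 2,
                                   length.out = config$passage$nx + 1L),
                        z_mm = seq(0, config$slab$depth_mm,
                                   length.out = config$passage$nz + 1L))
  }
  class(out) <- "mc_result"
  out
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", x$config$photons, "photons, seed", x$config$seed, "\n")
  for (g in c("reflection", "transmission")) {
    s <- x[[g]]
    cat(sprintf("  %-12s mean S3 = %s (se %s), n = %d, <events> = %s\n", g,
                format(s$mean_s3, digits = 4), format(s$se, digits = 2),
                s$n_detected, format(s$n_events_mean, digits = 4)))
  }
  invisible(x)
}

#' Trace a single photon packet
#'
#' Runs the transport kernel for one photon and reports its fate: a
#' detection record (surface exit), lateral escape, or termination by
#' roulette (absorption).
#'
#' @param config Run configuration; `photons` is forced to 1.
#' @param seed RNG seed for this photon (default from config).
#' @return List with `status` ("detected", "exited", "escaped" or
#'   "absorbed") and, for surface exits, the detection `record` row.
#' @export
propagate_photon <- function(config = default_config(), seed = NULL) {
  config <- validate_config(config)
  config$photons <- 1L
  if (!is.null(seed)) config$seed <- seed
  res <- simulate_slab(config, keep_records = TRUE, passage = FALSE)
  rec <- res$records
  if (nrow(rec) == 1L) {
    detected <- res$reflection$n_detected + res$transmission$n_detected
    return(list(status = if (detected > 0) "detected" else "exited",
                record = rec[1, ]))
  }
  if (res$conservation$lateral_escape > 0) return(list(status = "escaped"))
  list(status = "absorbed")
}

#' Passage-probability map of detected light
#'
#' Diagnostic heat map: the accumulated per-cell weight of scattering
#' events along trajectories that ended in a detector, normalized to a
#' maximum of 1.  Reflection-geometry maps show the banana-shaped cloud
#' connecting source and detector strip; transmission maps the channel
#' from the source to the far-side window.
#'
#' @param config Run configuration.
#' @return List with matrices `reflection` and `transmission`
#'   (rows = depth cells, cols = lateral cells) and the cell edges.
#' @export
passage_probability_map <- function(config = default_config()) {
  config <- validate_config(config)
  res <- simulate_slab(config, passage = TRUE)
  det <- res$reflection$n_detected + res$transmission$n_detected
  if (det == 0) stop("passage_probability_map: no detected photons; increase photons")
  res$passage
}
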