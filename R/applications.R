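#' Wavelength at which a particle size sits on an iso-X line
#'
#' The iso-X depolarization lines are rays a = X * lambda; a particle of
#' diameter `a` (um) crosses the line X at
#' `lambda = 1000 * a / X` nm, rounded to the nearest 10 nm.
#'
#' @param a_um Particle diameter (um).
#' @param X Generalized size parameter of the line.
#' @return Wavelength in nm (multiple of 10).
#' @examples
#' wavelength_on_line(6, 9)    # 670 nm
#' wavelength_on_line(11, 12)  # 920 nm
#' @export
wavelength_on_line <- function(a_um, X) {
  stopifnot(a_um > 0, X > 0)
  round(1000 * a_um / X / 10) * 10
}

#' Default iso-X line sets per detection geometry
#'
#' Reflection diagrams carry strong X = 9, 12 and 22 lines; in
#' transmission the X = 22 line is narrow and weak, so only 9 and 12 are
#' active, while the broad shallow depolarization region near X = 5 and
#' the weak X = 22 line (transmission) and the weak 19/26 side bands
#' (reflection) are advisory: never recommended themselves, and when the
#' contrast population falls near one the recommendation is flagged
#' (`advisory_overlap`) rather than rejected.
#'
#' @param geometry `"reflection"` or `"transmission"`.
#' @return List with numeric vectors `active` and `advisory`.
#' @export
iso_x_lines <- function(geometry = c("reflection", "transmission")) {
  geometry <- match.arg(geometry)
  switch(geometry,
         reflection = list(active = c(9, 12, 22), advisory = c(19, 26)),
         transmission = list(active = c(9, 12), advisory = c(5, 22)))
}

parse_size <- function(a) {
  # scalar size or interval c(lo, hi)
  stopifnot(is.numeric(a), length(a) %in% 1:2, all(a > 0))
  if (length(a) == 2L) { stopifnot(a[1] < a[2]); a } else c(a, a)
}

#' Recommend discriminating wavelengths for two particle populations
#'
#' Finds wavelengths (for scalar sizes) or wavelength bands (for size
#' intervals) at which one population sits on an iso-X depolarization
#' line while the other is clear of all depolarizing regions, so that a
#' change in detected circular polarization at that wavelength can be
#' attributed to the selected population alone.
#'
#' For an interval `[a_min, a_max]` crossing a line X, the band edges are
#' the line crossings of the interval ends,
#' `1000*a_min/X` to `1000*a_max/X` nm (the diagonal-rectangle
#' construction on the diagram); the band qualifies only if the other
#' population's X range over that band misses every active and advisory
#' line by more than `clearance`.
#'
#' Wavelengths above 1100 nm are flagged with a water-absorption warning:
#' strong absorption bands of water near 1200 and 1450 nm make them
#' unattractive in vivo even when the scattering contrast is good.
#'
#' @param a_um Size (um) or interval `c(lo, hi)` of population A.
#' @param b_um Size or interval of population B.
#' @param geometry Detection geometry (selects the line set).
#' @param lambda_range_nm Search window, default `c(600, 1500)`.
#' @param clearance Minimum |X| distance of the other population from any
#'   line (default 1).
#' @param diagram Optional MC `diagram_grid`; when supplied, the contrast
#'   is read off the diagram and the trough wavelength nearest the
#'   analytic ray is also reported as `lambda_empirical_nm`.
#' @param m Relative index for the analytic contrast estimate.
#' @return Data frame of class `wavelength_recommendation`: target
#'   population, `lambda_nm` (band midpoint for intervals), band edges,
#'   the line `X_line` used, analytic `contrast` |<S3>_A - <S3>_B|, and
#'   `water_warning`.
#' @examples
#' \donttest{
#' recommend_wavelengths(6, 11, "reflection", c(600, 1300))
#' }
#' @export
recommend_wavelengths <- function(a_um, b_um,
                                  geometry = c("reflection", "transmission"),
                                  lambda_range_nm = c(600, 1500),
                                  clearance = 1, diagram = NULL,
                                  m = 1.195) {
  geometry <- match.arg(geometry)
  A <- parse_size(a_um); B <- parse_size(b_um)
  lines <- iso_x_lines(geometry)
  pops <- list(A = A, B = B)
  out <- list()
  for (tgt in c("A", "B")) {
    sel <- pops[[tgt]]; oth <- pops[[setdiff(c("A", "B"), tgt)]]
    if (isTRUE(all.equal(sel, oth))) next   # identical sizes: no contrast
    for (Xl in lines$active) {
      lo <- 1000 * sel[1] / Xl
      hi <- 1000 * sel[2] / Xl
      if (hi < lambda_range_nm[1] || lo > lambda_range_nm[2]) next
      if (lo < lambda_range_nm[1] || hi > lambda_range_nm[2]) next
      # X range spanned by the other population across the band; it must
      # be clear of every active line (advisory regions only raise a flag)
      oX <- range(oth[1] / (hi * 1e-3), oth[2] / (lo * 1e-3))
      dist <- min(abs(outer(lines$active, oX, "-")))
      inside <- any(lines$active >= oX[1] & lines$active <= oX[2])
      if (inside || dist < clearance - 1e-9) next
      advisory_hit <- any(lines$advisory >= oX[1] - clearance &
                          lines$advisory <= oX[2] + clearance)
      lo_r <- wavelength_on_line(sel[1], Xl)
      hi_r <- wavelength_on_line(sel[2], Xl)
      lam_mid <- round((lo_r + hi_r) / 2 / 10) * 10
      contrast <- tryCatch({
        sA <- expected_s3_single(m, mean(sel) / (lam_mid * 1e-3), max_refine = 0L)
        sB <- expected_s3_single(m, mean(oth) / (lam_mid * 1e-3), max_refine = 0L)
        abs(sA - sB)
      }, error = function(e) NA_real_)
      rec <- data.frame(selective_for = tgt,
                        diameter_um = mean(sel),
                        X_line = Xl,
                        lambda_nm = lam_mid,
                        band_lo_nm = lo_r, band_hi_nm = hi_r,
                        contrast = contrast,
                        water_warning = lam_mid > 1100,
                        advisory_overlap = advisory_hit)
      if (!is.null(diagram)) {
        rec$lambda_empirical_nm <- empirical_trough(diagram, mean(sel), lam_mid)
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) {
    res <- data.frame(selective_for = character(), diameter_um = numeric(),
                      X_line = numeric(), lambda_nm = numeric(),
                      band_lo_nm = numeric(), band_hi_nm = numeric(),
                      contrast = numeric(), water_warning = logical(),
                      advisory_overlap = logical())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$lambda_nm), ]
    rownames(res) <- NULL
  }
  structure(res, class = c("wavelength_recommendation", "data.frame"))
}

# nearest S3 trough of the diagram column at diameter a to lambda0
empirical_trough <- function(diagram, a_um, lambda0) {
  j <- which.min(abs(diagram$a_um - a_um))
  col <- diagram$values[, j]
  ok <- is.finite(col)
  if (sum(ok) < 3) return(NA_real_)
  lam <- diagram$lambda_nm[ok]; col <- col[ok]
  mins <- which(diff(sign(diff(col))) > 0) + 1L
  if (!length(mins)) return(NA_real_)
  lam[mins][which.min(abs(lam[mins] - lambda0))]
}
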