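#' Default Monte Carlo run configuration
#'
#' The baseline slab-model conditions: mu_a = 0.10 / mm, mu_s = 6.86 / mm,
#' a 12 x 6 mm slab, particle/medium indices 1.59/1.33, incident beam 1
#' degree off the inward normal, a reflection detector strip from x = 1
#' to 3 mm on the illuminated surface and a transmission strip from
#' x = -1 to 1 mm on the far surface (both with 1 mm half-extent
#' out-of-plane), refractive-index-matched boundaries (no Fresnel terms,
#' recorded as `fresnel = "off"`).
#'
#' @param ... Named overrides merged (recursively) onto the defaults.
#' @return Validated config list of class `mc_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    medium = list(mu_a = 0.10, mu_s = 6.86,
                  wavelength_nm = 1000, diameter_um = 10,
                  n_particle = 1.59, n_medium = 1.33),
    slab = list(width_mm = 12, depth_mm = 6),
    detectors = list(reflection = c(1, 3), transmission = c(-1, 1),
                     strip_half_mm = 1),
    photons = 20000L,
    seed = 1L,
    incident_deg = 1,
    fresnel = "off",
    weight_min = 1e-4,
    p_survive = 0.1,
    max_events = 1e6,
    keep_records = FALSE,
    passage = list(enabled = FALSE, nx = 120L, nz = 60L)
  )
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  validate_config(cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate (and normalize) a run configuration
#'
#' Checks every field of an MC run configuration against its physical
#' constraints, collecting all violations into a single error message.
#' Unknown top-level keys are rejected.
#'
#' @param config A config list (possibly partial: merged onto defaults).
#' @return The validated config, classed `mc_config`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "mc_config")) return(config)
  base <- list(
    medium = list(mu_a = 0.10, mu_s = 6.86,
                  wavelength_nm = 1000, diameter_um = 10,
                  n_particle = 1.59, n_medium = 1.33),
    slab = list(width_mm = 12, depth_mm = 6),
    detectors = list(reflection = c(1, 3), transmission = c(-1, 1),
                     strip_half_mm = 1),
    photons = 20000L, seed = 1L, incident_deg = 1, fresnel = "off",
    weight_min = 1e-4, p_survive = 0.1, max_events = 1e6,
    keep_records = FALSE,
    passage = list(enabled = FALSE, nx = 120L, nz = 60L))
  unknown <- setdiff(names(config), c(names(base), "output_dir"))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- merge_config(base, config)
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$medium$mu_a) && cfg$medium$mu_a >= 0, "medium$mu_a must be >= 0")
  chk(is.numeric(cfg$medium$mu_s) && cfg$medium$mu_s > 0, "medium$mu_s must be > 0")
  chk(cfg$medium$wavelength_nm > 0, "medium$wavelength_nm must be > 0")
  chk(cfg$medium$diameter_um > 0, "medium$diameter_um must be > 0")
  chk(cfg$medium$n_particle > 0, "medium$n_particle must be > 0")
  chk(cfg$medium$n_medium > 0, "medium$n_medium must be > 0")
  chk(cfg$slab$width_mm > 0, "slab$width_mm must be > 0")
  chk(cfg$slab$depth_mm > 0, "slab$depth_mm must be > 0")
  half <- cfg$slab$width_mm / 2
  chk(length(cfg$detectors$reflection) == 2L &&
        cfg$detectors$reflection[1] < cfg$detectors$reflection[2] &&
        all(abs(cfg$detectors$reflection) <= half),
      "detectors$reflection must be an increasing interval within the slab width")
  chk(length(cfg$detectors$transmission) == 2L &&
        cfg$detectors$transmission[1] < cfg$detectors$transmission[2] &&
        all(abs(cfg$detectors$transmission) <= half),
      "detectors$transmission must be an increasing interval within the slab width")
  chk(cfg$detectors$strip_half_mm > 0, "detectors$strip_half_mm must be > 0")
  chk(cfg$photons >= 1, "photons must be >= 1")
  chk(is.numeric(cfg$seed) && abs(cfg$seed) < 2^31, "seed must be a 32-bit integer")
  chk(cfg$weight_min > 0 && cfg$weight_min < 1, "weight_min must be in (0,1)")
  chk(cfg$p_survive > 0 && cfg$p_survive <= 1, "p_survive must be in (0,1]")
  chk(cfg$max_events >= 1, "max_events must be >= 1")
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg$photons <- as.integer(cfg$photons)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("mc_config", "list")
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Missing fields are filled with the model defaults (an empty file gives
#' the full default configuration); unknown keys are rejected.
#'
#' @param path Path to a YAML config file.
#' @return Validated `mc_config`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  for (k in c("reflection", "transmission")) {
    if (!is.null(cfg$detectors[[k]])) cfg$detectors[[k]] <- as.numeric(cfg$detectors[[k]])
  }
  validate_config(cfg)
}

#' Write a run configuration to YAML
#'
#' @param config An `mc_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out$output_dir <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Fast fixture configurations for tests and smoke runs
#'
#' * `smoke`: 1000 photons, default medium — end-to-end in well under a
#'   second.
#' * `thin_slab`: optically thin slab (`mu_s * depth = 0.05`) so that
#'   transmitted light is overwhelmingly unscattered (ballistic limit).
#' * `rayleigh`: particle much smaller than the wavelength (X = 0.1),
#'   where circular polarization is rapidly destroyed by multiple
#'   scattering.
#'
#' @param profile One of `"smoke"`, `"thin_slab"`, `"rayleigh"`.
#' @param ... Further overrides.
#' @return Validated `mc_config`.
#' @export
make_fixture <- function(profile = c("smoke", "thin_slab", "rayleigh"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    smoke = default_config(photons = 1000L),
    thin_slab = default_config(photons = 5000L,
                               medium = list(mu_s = 0.05 / 6),
                               detectors = list(transmission = c(-3, 3),
                                                strip_half_mm = 3)),
    rayleigh = default_config(photons = 5000L,
                              medium = list(diameter_um = 0.1,
                                            wavelength_nm = 1000)))
  if (length(list(...))) cfg <- validate_config(merge_config(unclass(cfg), list(...)))
  cfg
}

#' Provenance block for an output file
#'
#' @param config The config used.
#' @return List with the config, package version and seed — embedded in
#'   JSON summaries so any output can be reproduced.
#' @export
run_provenance <- function(config) {
  config <- validate_config(config)
  list(package = "miepol",
       version = as.character(utils::packageVersion("miepol")),
       seed = config$seed,
       config = unclass(config))
}
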