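# YAML configuration: beam, beamline geometry toggles, material overrides,
# fluence and engine constants. The built-in defaults mirror the study's
# component table and I-value table; a config file can override any of
# them without touching code.

#' Default configuration
#'
#' @return Nested list describing the beam (68 MeV, zero reference spread,
#'   2 x 3 mm spot), the beamline (scatterer flag, aperture radius),
#'   material I-value overrides (none by default), and engine constants
#'   (nuclear mean free path 100 cm of water, 0.2 mm scoring grid).
#' @export
default_config <- function() {
  list(
    beam = list(energy_mev = 68, sigma_e_mev = 0, fwhm_mm = c(2, 3)),
    beamline = list(with_scatterer = FALSE, aperture_radius_mm = NULL),
    target = list(type = "water", length_mm = 40, i_value_water = 78,
                  shift_cm = 0),
    materials = list(),   # e.g. list(aluminum = list(i_value = 168))
    engine = list(nuclear_mfp_cm = 100, n_energy_nodes = 9)
  )
}

#' Write / read a configuration file
#'
#' @param config Configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `read_config()` returns the file's settings merged over the
#'   defaults (file wins).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  modifyList(default_config(), yaml::read_yaml(path))
}

config_materials <- function(config) {
  mats <- default_materials()
  for (nm in names(config$materials)) {
    if (is.null(mats[[nm]])) stop("unknown material in config: ", nm,
                                  call. = FALSE)
    for (fld in names(config$materials[[nm]])) {
      mats[[nm]][[fld]] <- config$materials[[nm]][[fld]]
    }
  }
  mats
}

#' Run the configured water-target calculation
#'
#' @param config Configuration list.
#' @return A `depth_dose` for the configured beamline and water target.
#' @export
config_profile <- function(config = default_config()) {
  ws <- isTRUE(config$beamline$with_scatterer)
  bl <- build_beamline(
    with_scatterer = ws,
    aperture_radius_mm = config$beamline$aperture_radius_mm %||%
      (if (ws) 5 else 3.5),
    materials = config_materials(config)
  )
  water_depth_dose(
    with_scatterer = ws,
    sigma_e = config$beam$sigma_e_mev,
    i_value_water = config$target$i_value_water,
    target_shift_cm = config$target$shift_cm,
    beamline = bl,
    length_mm = config$target$length_mm,
    energy = config$beam$energy_mev,
    n_components = config$engine$n_energy_nodes,
    nuclear_mfp_cm = config$engine$nuclear_mfp_cm
  )
}
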