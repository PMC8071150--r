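# Central-axis depth-dose engine.
#
# Dose-to-water is computed in water-equivalent (WE) depth: the energy
# deposited per unit WE path is evaluated exactly as energy differences of
# the range-energy relation on a fine grid (0.05 mm), range straggling is
# applied as a Gaussian blur in residual-range space (Bohr accumulation in
# the beamline plus the medium), nuclear removal as an exponential fluence
# survival, and the geometric fluence factor (inverse square + in-field
# erosion) multiplies the result after mapping back to geometric depth on
# the 0.2 mm scoring grid.

.FINE_DZ_MM <- 0.05
.GRID_DZ_MM <- 0.2

#' Layered medium along the beam axis
#'
#' @param materials List of `proton_material` objects, one per layer.
#' @param density Mass densities in g/cm^3 (defaults to each material's
#'   nominal density).
#' @param thickness_mm Geometric layer thicknesses in mm (> 0).
#' @param provenance `"water"` or `"phantom column"`.
#' @return An object of class `layered_medium`.
#' @export
layered_medium <- function(materials, density = NULL, thickness_mm,
                           provenance = "water") {
  if (!is.null(names(materials)) && inherits(materials, "proton_material")) {
    materials <- list(materials)
  }
  if (is.null(density)) {
    density <- vapply(materials, function(m) m$density, 0)
  }
  stopifnot(length(materials) == length(thickness_mm),
            length(density) == length(thickness_mm),
            all(thickness_mm > 0), all(density > 0))
  structure(list(materials = materials, density = density,
                 thickness_mm = thickness_mm, provenance = provenance),
            class = "layered_medium")
}

#' Uniform water target
#'
#' The biological-sample target: a water cylinder along the beam axis
#' (default 40 mm, the 4 cm tank).
#'
#' @param length_mm Target length along the axis, mm.
#' @param i_value I-value of the target water in eV (78 reference; 76/80 in
#'   the water I-value scenarios).
#' @return A `layered_medium`.
#' @export
water_medium <- function(length_mm = 40, i_value = 78) {
  w <- default_materials()$water
  w$i_value <- i_value
  layered_medium(list(w), 1.000, length_mm, provenance = "water")
}

# Cumulative water-equivalent depth (mm) at geometric boundaries; relative
# stopping power per layer at the reference energy.
medium_we_map <- function(medium, e_ref) {
  water <- default_materials()$water
  s_water <- mass_stopping_power(water, e_ref)
  key <- vapply(medium$materials,
                function(m) sprintf("%.8g|%.8g", m$z_over_a, m$i_value), "")
  uk <- !duplicated(key)
  s_by_key <- vapply(medium$materials[uk],
                     function(m) mass_stopping_power(m, e_ref), 0)
  names(s_by_key) <- key[uk]
  rsp <- medium$density * s_by_key[key] / s_water
  zb <- c(0, cumsum(medium$thickness_mm))
  wb <- c(0, cumsum(medium$thickness_mm * rsp))
  list(zb = zb, wb = wb, rsp = unname(rsp))
}

#' Monoenergetic central-axis Bragg curve
#'
#' @param state A [transport_beam()] beam state at the target entrance.
#' @param medium A [layered_medium()] (the water tank or a phantom column).
#' @param energy Mean proton energy at the medium entrance, MeV; defaults
#'   to the transported mean energy.
#' @param fluence_params Calibrated fluence constants
#'   ([calibrate_fluence()]).
#' @param target_shift_cm Axial setup shift of the target (+ downstream).
#' @param nuclear_mfp_cm Mean free path of the exponential nuclear-removal
#'   survival term, in cm of water (default 100, i.e. ~1%/cm).
#' @param extra_sigma_e Additional Gaussian energy spread (MeV) folded into
#'   the range-straggling blur (used internally; source energy spread is
#'   normally handled by [convolve_energy_spread()]).
#' @return A `depth_dose` object: data frame with `depth_mm` (0.2 mm grid)
#'   and `dose` (dose-to-water, arbitrary units consistent across stacks).
#' @export
bragg_curve <- function(state, medium, energy = state$mean_energy,
                        fluence_params = calibrate_fluence(state$with_scatterer),
                        target_shift_cm = 0, nuclear_mfp_cm = 100,
                        extra_sigma_e = 0) {
  if (sum(medium$thickness_mm) <= 0) stop("zero-length medium", call. = FALSE)
  water <- default_materials()$water
  map <- medium_we_map(medium, energy)
  wet_total <- max(map$wb)

  r0_mm <- 10 * csda_range(water, energy)
  sigma_straggle <- sqrt(max(state$sigma_e^2 - state$source_sigma_e^2, 0) +
                           extra_sigma_e^2)
  sigma_mm <- 10 * sqrt(bohr_range_sigma(water, energy)^2 +
                          (sigma_straggle / mass_stopping_power(water, energy))^2)

  # fine WE grid; keep it just past the stopping depth or the medium end
  w_end <- min(wet_total, r0_mm + 6 * sigma_mm + 2)
  wb <- seq(0, w_end, by = .FINE_DZ_MM)
  residual_mm <- 10 * .RESIDUAL_RANGE
  e_fun <- function(w) {
    r <- (r0_mm - w) / 10
    out <- numeric(length(w))
    alive <- r > .RESIDUAL_RANGE * (1 + 1e-9)
    out[alive] <- energy_at_range(water, r[alive])
    out
  }
  e_bound <- e_fun(wb)
  deposit <- -diff(c(e_bound, e_fun(w_end + .FINE_DZ_MM)))
  w_mid <- wb + .FINE_DZ_MM / 2
  deposit <- deposit * exp(-(w_mid / 10) / nuclear_mfp_cm)

  # range-straggling blur (Gaussian in residual-range space)
  half <- max(3L, ceiling(5 * sigma_mm / .FINE_DZ_MM))
  kern <- stats::dnorm(seq(-half, half) * .FINE_DZ_MM, sd = sigma_mm)
  kern <- kern / sum(kern)
  padded <- c(rep(deposit[1], half), deposit, rep(deposit[length(deposit)], half))
  blurred <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + length(deposit))]

  # map back to the geometric 0.2 mm scoring grid
  z_total <- sum(medium$thickness_mm)
  z <- seq(.GRID_DZ_MM / 2, z_total - .GRID_DZ_MM / 2 + 1e-9, by = .GRID_DZ_MM)
  w_of_z <- stats::approx(map$zb, map$wb, xout = z)$y
  dose_we <- stats::approx(w_mid, as.numeric(blurred), xout = w_of_z,
                           yleft = blurred[1], yright = 0, rule = 2)$y
  dose_we[w_of_z > w_end] <- 0

  gap_cm <- state$target_entrance_cm - state$collimator_exit_cm
  flu <- state$axial_amplitude *
    fluence_factor(state, gap_cm + target_shift_cm + z / 10,
                   aperture_radius_mm = state$aperture_radius_mm,
                   target_depth_mm = w_of_z, params = fluence_params)
  depth_dose(z, dose_we * flu, provenance = medium$provenance)
}

depth_dose <- function(depth_mm, dose, normalization = "raw",
                       provenance = "water") {
  stopifnot(length(depth_mm) == length(dose), all(dose >= -1e-12))
  d <- data.frame(depth_mm = depth_mm, dose = pmax(dose, 0))
  structure(d, class = c("depth_dose", "data.frame"),
            spacing_mm = .GRID_DZ_MM, normalization = normalization,
            provenance = provenance)
}

#' @export
print.depth_dose <- function(x, ...) {
  cat(sprintf("<depth_dose> %d samples, 0--%.1f mm at %.1f mm spacing (%s, %s)\n",
              nrow(x), max(x$depth_mm), attr(x, "spacing_mm"),
              attr(x, "normalization"), attr(x, "provenance")))
  cat(sprintf("  peak %.4g at %.1f mm; entrance %.4g\n",
              max(x$dose), x$depth_mm[which.max(x$dose)], x$dose[1]))
  invisible(x)
}

#' @export
plot.depth_dose <- function(x, normalize = TRUE, ...) {
  y <- if (normalize) x$dose / max(x$dose) else x$dose
  graphics::plot(x$depth_mm, y, type = "l", xlab = "depth [mm]",
                 ylab = if (normalize) "dose (relative to maximum)" else "dose [a.u.]",
                 ...)
  invisible(x)
}

#' Normalize a depth-dose profile to its maximum
#' @param profile A `depth_dose`.
#' @return The profile rescaled so its maximum equals 1.
#' @export
peak_normalize <- function(profile) {
  out <- depth_dose(profile$depth_mm, profile$dose / max(profile$dose),
                    normalization = "peak-normalized",
                    provenance = attr(profile, "provenance"))
  out
}

#' Write a profile as a two-column CSV
#' @param profile A `depth_dose`.
#' @param path Output file path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(depth_mm = profile$depth_mm,
                              dose = profile$dose),
                   path, row.names = FALSE)
  invisible(path)
}

#' Energy-spread convolution of Bragg curves
#'
#' Gauss--Hermite quadrature over a Gaussian source energy spectrum:
#' a weighted sum of monoenergetic curves at `energy + node * sqrt(2) *
#' sigma_e`. With `sigma_e = 0` the monoenergetic curve is returned
#' bit-identically.
#'
#' @param curve_fn Function of one argument (source energy, MeV) returning
#'   a `depth_dose` on a common grid.
#' @param energy Nominal source energy, MeV.
#' @param sigma_e Gaussian energy spread, MeV (>= 0).
#' @param n_components Odd number of quadrature nodes (default 9).
#' @return A `depth_dose`.
#' @export
convolve_energy_spread <- function(curve_fn, energy, sigma_e,
                                   n_components = 9) {
  stopifnot(sigma_e >= 0, n_components >= 1, n_components %% 2 == 1)
  if (sigma_e == 0) return(curve_fn(energy))
  gh <- pracma::gaussHermite(n_components)
  dose <- NULL
  depth <- NULL
  for (k in seq_along(gh$x)) {
    p <- curve_fn(energy + sqrt(2) * sigma_e * gh$x[k])
    if (is.null(dose)) {
      dose <- gh$w[k] * p$dose
      depth <- p$depth_mm
    } else {
      dose <- dose + gh$w[k] * p$dose
    }
  }
  depth_dose(depth, dose / sqrt(pi))
}

#' Depth dose in the water target for a full beamline configuration
#'
#' Transports the source through the component stack (optionally energy
#' spread via Gauss--Hermite nodes, each transported separately) and scores
#' the Bragg curve in the water tank.
#'
#' @param with_scatterer Tungsten foil in or out.
#' @param sigma_e Source Gaussian energy spread, MeV.
#' @param i_value_water Water target I-value, eV.
#' @param target_shift_cm Axial target setup shift, cm.
#' @param beamline Optional pre-built (possibly perturbed) stack.
#' @param length_mm Water target length, mm.
#' @param energy Nominal source energy, MeV.
#' @param n_components Quadrature nodes for the energy spread.
#' @param ... Passed to [bragg_curve()].
#' @return A `depth_dose`.
#' @export
water_depth_dose <- function(with_scatterer = FALSE, sigma_e = 0,
                             i_value_water = 78, target_shift_cm = 0,
                             beamline = build_beamline(with_scatterer),
                             length_mm = 40, energy = 68,
                             n_components = 9, ...) {
  medium <- water_medium(length_mm, i_value_water)
  params <- calibrate_fluence(beamline$with_scatterer)
  convolve_energy_spread(function(e0) {
    state <- transport_beam(beam_source(e0, sigma_e = 0), beamline)
    bragg_curve(state, medium, fluence_params = params,
                target_shift_cm = target_shift_cm, ...)
  }, energy, sigma_e, n_components)
}
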