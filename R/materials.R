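# Materials and proton stopping-power / range model.
#
# The engine uses the relativistic Bethe mass stopping power without shell,
# density-effect or Barkas corrections; those omissions are below 1% for
# protons above a few MeV and are absorbed into the engine's stated
# half-millimetre tolerance on absolute peak depth. The I-value dependence,
# which drives the range sensitivities studied here, is exact.

.K_BETHE <- 0.307075    # MeV cm^2 / g (4 pi N_A r_e^2 m_e c^2)
.ME_MEV  <- 0.5109989   # electron rest energy, MeV
.MP_MEV  <- 938.27209   # proton rest energy, MeV
.E_MIN   <- 1           # MeV, low-energy validity cutoff of the model
.E_MAX   <- 250         # MeV, upper validity bound
# CSDA range left below the 1 MeV cutoff, g/cm^2 (fine-grid oracle value
# for water; sub-cutoff transport never matters for plateau metrics).
.RESIDUAL_RANGE <- 0.0025

#' Define a material for proton transport
#'
#' @param name Material name.
#' @param composition Element symbols and mass fractions (see
#'   [bragg_additivity_i()]); fractions must sum to 1.
#' @param density Mass density in g/cm^3. Zero is allowed only for the
#'   special name `"vacuum"`.
#' @param i_value Mean excitation energy in eV. Defaults to the Bragg
#'   additivity value of the composition.
#' @param i_uncertainty One-sigma I-value uncertainty in eV (>= 0).
#' @return An object of class `proton_material`.
#' @examples
#' material("water", data.frame(element = c("H", "O"),
#'                              fraction = c(0.111894, 0.888106)),
#'          density = 1, i_value = 78, i_uncertainty = 2)
#' @export
material <- function(name, composition, density,
                     i_value = bragg_additivity_i(composition),
                     i_uncertainty = 0.06 * i_value) {
  comp <- as_composition(composition)
  if (!(density > 0 || identical(name, "vacuum"))) {
    stop("density must be > 0", call. = FALSE)
  }
  if (i_value <= 0) stop("i_value must be > 0", call. = FALSE)
  if (i_uncertainty < 0) stop("i_uncertainty must be >= 0", call. = FALSE)
  el <- element_data(comp$element)
  structure(
    list(name = name, composition = comp, density = density,
         i_value = i_value, i_uncertainty = i_uncertainty,
         z_over_a = sum(comp$fraction * el$Z / el$A),
         x0_gcm2 = 1 / sum(comp$fraction / el$X0_gcm2)),
    class = "proton_material"
  )
}

#' @export
print.proton_material <- function(x, ...) {
  cat(sprintf("<proton_material> %s: rho = %g g/cm^3, I = %g +/- %g eV, Z/A = %.4f\n",
              x$name, x$density, x$i_value, x$i_uncertainty, x$z_over_a))
  invisible(x)
}

#' Built-in material set
#'
#' Beamline materials with the study's I-values (aluminum 166.0+-2.0 eV,
#' tungsten 727.0+-30.0 eV, Kapton 79.6+-4.8 eV, air 85.7+-5.1 eV, water
#' 78+-2 eV) plus a small tissue set (lung, adipose, bone) for
#' HU-calibrated phantom columns. Tissue I-value uncertainty defaults to
#' +-6%.
#'
#' @return Named list of `proton_material` objects.
#' @export
default_materials <- function() {
  water_comp <- formula_composition(c("H", "O"), c(2, 1))
  list(
    vacuum = material("vacuum", data.frame(element = "H", fraction = 1),
                      density = 0, i_value = 19.2, i_uncertainty = 0),
    water = material("water", water_comp, density = 1.000,
                     i_value = 78, i_uncertainty = 2),
    air = material("air",
                   data.frame(element = c("N", "O", "Ar"),
                              fraction = c(0.755, 0.232, 0.013)),
                   density = 1.205e-3, i_value = 85.7, i_uncertainty = 5.1),
    kapton = material("kapton",
                      formula_composition(c("C", "H", "N", "O"),
                                          c(22, 10, 2, 5)),
                      density = 1.42, i_value = 79.6, i_uncertainty = 4.8),
    aluminum = material("aluminum", data.frame(element = "Al", fraction = 1),
                        density = 2.699, i_value = 166.0, i_uncertainty = 2.0),
    copper = material("copper", data.frame(element = "Cu", fraction = 1),
                      density = 8.96, i_value = 322.0),
    tungsten = material("tungsten", data.frame(element = "W", fraction = 1),
                        density = 19.3, i_value = 727.0, i_uncertainty = 30.0),
    lung = material("lung",
                    data.frame(element = c("H", "C", "N", "O"),
                               fraction = c(0.103, 0.105, 0.031, 0.761)),
                    density = 0.26, i_value = 75.3),
    adipose = material("adipose",
                       data.frame(element = c("H", "C", "N", "O"),
                                  fraction = c(0.114, 0.598, 0.007, 0.281)),
                       density = 0.95, i_value = 63.2),
    bone = material("bone",
                    data.frame(element = c("H", "C", "N", "O", "P", "Ca"),
                               fraction = c(0.064, 0.278, 0.027, 0.414,
                                            0.070, 0.147)),
                    density = 1.45, i_value = 106.4)
  )
}

# ---- Bethe stopping power ------------------------------------------------

check_energy_window <- function(energy) {
  if (any(energy < .E_MIN | energy > .E_MAX)) {
    stop(sprintf("proton energy must lie within [%g, %g] MeV", .E_MIN, .E_MAX),
         call. = FALSE)
  }
}

# beta^2*gamma^2 and beta^2 for a proton of kinetic energy E (MeV)
proton_kinematics <- function(energy) {
  bg2 <- energy * (energy + 2 * .MP_MEV) / .MP_MEV^2
  list(bg2 = bg2, b2 = bg2 / (1 + bg2))
}

#' Proton mass stopping power
#'
#' Relativistic Bethe formula (no shell or density-effect corrections),
#' valid for 1--250 MeV protons. Strictly decreasing in the material's
#' I-value at fixed energy.
#'
#' @param mat A `proton_material`.
#' @param energy Proton kinetic energy in MeV (vectorised).
#' @return Mass stopping power in MeV cm^2/g.
#' @export
mass_stopping_power <- function(mat, energy) {
  check_energy_window(energy)
  if (mat$density <= 0) stop("material has no substance (vacuum)", call. = FALSE)
  kin <- proton_kinematics(energy)
  w_max <- 2 * .ME_MEV * kin$bg2                 # heavy-particle approximation
  i_mev <- mat$i_value * 1e-6
  .K_BETHE * mat$z_over_a / kin$b2 * (log(w_max / i_mev) - kin$b2)
}

# ---- CSDA range via cached cumulative integration ------------------------

.stopping_cache <- new.env(parent = emptyenv())

range_model <- function(mat) {
  key <- sprintf("%.10g|%.10g", mat$z_over_a, mat$i_value)
  mod <- .stopping_cache[[key]]
  if (!is.null(mod)) return(mod)
  # dense log-spaced energy grid; trapezoidal cumulative integral of 1/S
  e <- exp(seq(log(.E_MIN), log(.E_MAX), length.out = 4000))
  s <- mass_stopping_power(mat, e)
  r <- .RESIDUAL_RANGE + pracma::cumtrapz(e, 1 / s)[, 1]
  mod <- list(
    range_of_e = stats::splinefun(log(e), r, method = "hyman"),
    e_of_range = stats::splinefun(r, log(e), method = "hyman")
  )
  .stopping_cache[[key]] <- mod
  mod
}

#' CSDA range of a proton
#'
#' Continuous-slowing-down range: the integral of the inverse mass stopping
#' power from the 1 MeV model cutoff up to `energy`, plus a fixed
#' sub-cutoff residual of 0.0025 g/cm^2. Strictly increasing in both the
#' energy and the material's I-value.
#'
#' @inheritParams mass_stopping_power
#' @return Range in g/cm^2.
#' @export
csda_range <- function(mat, energy) {
  check_energy_window(energy)
  range_model(mat)$range_of_e(log(energy))
}

# Inverse of csda_range: energy (MeV) whose CSDA range equals `r` (g/cm^2).
energy_at_range <- function(mat, r) {
  exp(range_model(mat)$e_of_range(r))
}

#' Proton energy after traversing a slab
#'
#' Solves the range equation `range(E_out) = range(E_in) - t` for the exit
#' energy; exact range additivity over split slabs holds by construction.
#'
#' @inheritParams mass_stopping_power
#' @param energy_in Entrance kinetic energy, MeV.
#' @param areal_thickness Slab areal density in g/cm^2 (>= 0).
#' @return Exit kinetic energy in MeV.
#' @export
energy_after_slab <- function(mat, energy_in, areal_thickness) {
  if (areal_thickness < 0) stop("areal_thickness must be >= 0", call. = FALSE)
  if (areal_thickness == 0) return(energy_in)
  r_out <- csda_range(mat, energy_in) - areal_thickness
  if (r_out <= .RESIDUAL_RANGE + 1e-9) {
    stop(sprintf("proton stops in slab of %s (residual range exhausted)",
                 mat$name), call. = FALSE)
  }
  energy_at_range(mat, r_out)
}

# ---- Straggling and scattering building blocks ---------------------------

# Bohr energy-straggling variance (MeV^2) acquired over a slab, with the
# standard relativistic factor; evaluated at the slab's midpoint energy.
bohr_variance_slab <- function(mat, energy_in, areal_thickness) {
  if (areal_thickness <= 0) return(0)
  e_mid <- energy_after_slab(mat, energy_in, areal_thickness / 2)
  b2 <- proton_kinematics(e_mid)$b2
  0.1569 * mat$z_over_a * areal_thickness * (1 - b2 / 2) / (1 - b2)
}

# Range-straggling sigma (g/cm^2) for a proton slowing from `energy` to rest
# in `mat`: sigma_R^2 = int dE (dVar/dx) / S^3.
bohr_range_sigma <- function(mat, energy) {
  e <- seq(.E_MIN, energy, length.out = 600)
  s <- mass_stopping_power(mat, e)
  b2 <- proton_kinematics(e)$b2
  dvar <- 0.1569 * mat$z_over_a * (1 - b2 / 2) / (1 - b2)
  sqrt(pracma::trapz(e, dvar / s^3))
}

# Highland multiple-scattering angle (rad) for one slab.
highland_angle <- function(mat, energy, areal_thickness) {
  if (areal_thickness <= 0 || mat$density <= 0) return(0)
  kin <- proton_kinematics(energy)
  pc <- sqrt(energy * (energy + 2 * .MP_MEV))    # momentum * c, MeV
  beta <- sqrt(kin$b2)
  u <- areal_thickness / mat$x0_gcm2
  corr <- max(1 + 0.038 * log(u), 0.05)
  13.6 / (beta * pc) * sqrt(u) * corr
}
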