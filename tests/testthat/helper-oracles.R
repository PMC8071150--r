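# Independent brute-force oracles, kept deliberately separate from the
# package's cached-spline / filter-based implementations.

# Relativistic Bethe mass stopping power, written out directly.
oracle_stopping <- function(z_over_a, i_ev, energy_mev) {
  me <- 0.5109989; mp <- 938.27209; K <- 0.307075
  bg2 <- energy_mev * (energy_mev + 2 * mp) / mp^2
  b2 <- bg2 / (1 + bg2)
  K * z_over_a / b2 * (log(2 * me * bg2 / (i_ev * 1e-6)) - b2)
}

# CSDA range by adaptive quadrature of the inverse stopping power from the
# 1 MeV cutoff, plus the same sub-cutoff residual constant.
oracle_range <- function(z_over_a, i_ev, energy_mev) {
  stats::integrate(function(e) 1 / oracle_stopping(z_over_a, i_ev, e),
                   1, energy_mev, rel.tol = 1e-10)$value + 0.0025
}

# Sort-based percentile with the linear-interpolation convention.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_hi98 <- function(dose) {
  (oracle_percentile(dose, 0.98) - oracle_percentile(dose, 0.02)) /
    oracle_percentile(dose, 0.5)
}

# A beamline with no material in the beam path: zero-thickness collimator
# right at the target entrance, vacuum pipe upstream.
empty_beamline <- function() {
  bl <- build_beamline(FALSE)
  bl$components <- data.frame(
    name = c("beam_pipe", "collimator"),
    material = c("vacuum", "aluminum"),
    shape = c("slab", "aperture"),
    position_cm = c(-10, 0),
    thickness_cm = c(10, 0),
    stringsAsFactors = FALSE
  )
  bl$target_entrance_cm <- 0
  bl
}

# A beamline whose only substance is aluminum foil(s) in vacuum, for
# slab-splitting bookkeeping checks.
foil_beamline <- function(positions_cm, thicknesses_cm) {
  bl <- empty_beamline()
  n <- length(positions_cm)
  bl$components <- rbind(
    data.frame(name = "beam_pipe", material = "vacuum", shape = "slab",
               position_cm = -10, thickness_cm = 10 + positions_cm[1],
               stringsAsFactors = FALSE),
    data.frame(name = paste0("foil_", seq_len(n)), material = "aluminum",
               shape = "slab", position_cm = positions_cm,
               thickness_cm = thicknesses_cm, stringsAsFactors = FALSE),
    data.frame(name = "collimator", material = "aluminum",
               shape = "aperture",
               position_cm = positions_cm[n] + thicknesses_cm[n],
               thickness_cm = 0, stringsAsFactors = FALSE)
  )
  # vacuum between foils, not air: pad each foil flush with the next
  bl$components$thickness_cm[1] <- 10 + positions_cm[1]
  bl$target_entrance_cm <- positions_cm[n] + thicknesses_cm[n]
  bl
}

flat_fluence <- list(source_distance_cm = 1e12, erosion_rate = 0,
                     sigma_lat0_mm = 2.5, nominal_gap_cm = 3.25)
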