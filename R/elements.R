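# Elemental constants used by the stopping-power and scattering models.
# I-values follow ICRU report 37; radiation lengths are the standard
# elemental values in g/cm^2.

.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "Al", "P", "Ar", "Ca", "Cu", "W"),
  Z      = c(1, 6, 7, 8, 13, 15, 18, 20, 29, 74),
  A      = c(1.008, 12.011, 14.007, 15.999, 26.9815, 30.9738, 39.948,
             40.078, 63.546, 183.84),
  I_eV   = c(19.2, 78.0, 82.0, 95.0, 166.0, 173.0, 188.0, 191.0, 322.0,
             727.0),
  X0_gcm2 = c(63.04, 42.70, 37.99, 34.24, 24.01, 21.21, 19.55, 16.14,
              12.86, 6.76),
  stringsAsFactors = FALSE
)

element_data <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "), call. = FALSE)
  }
  .element_table[i, , drop = FALSE]
}

#' Mean excitation energy of a compound by the Bragg additivity rule
#'
#' Combines elemental I-values into a compound value as the exponential of
#' the electron-weighted (Z/A-weighted) mean of `log(I)`, the convention
#' used for materials whose I-value has not been measured directly.
#'
#' @param composition A two-column data frame or list of pairs giving
#'   element symbols and mass fractions. Mass fractions must sum to 1
#'   within `1e-6`.
#' @return Mean excitation energy in eV.
#' @examples
#' bragg_additivity_i(data.frame(element = "Al", fraction = 1))
#' @export
bragg_additivity_i <- function(composition) {
  comp <- as_composition(composition)
  el <- element_data(comp$element)
  w_e <- comp$fraction * el$Z / el$A    # electrons per gram, relative
  exp(sum(w_e * log(el$I_eV)) / sum(w_e))
}

# Normalise the accepted composition representations to a data frame with
# columns element / fraction and check the mass-fraction closure.
as_composition <- function(composition) {
  if (is.list(composition) && !is.data.frame(composition) &&
      all(vapply(composition, length, 1L) == 2L)) {
    composition <- data.frame(
      element  = vapply(composition, function(p) as.character(p[[1]]), ""),
      fraction = vapply(composition, function(p) as.numeric(p[[2]]), 0),
      stringsAsFactors = FALSE
    )
  }
  comp <- as.data.frame(composition, stringsAsFactors = FALSE)
  names(comp)[1:2] <- c("element", "fraction")
  comp$fraction <- as.numeric(comp$fraction)
  if (abs(sum(comp$fraction) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", sum(comp$fraction), ")",
         call. = FALSE)
  }
  comp
}

# Mass-fraction composition from an integer chemical formula.
formula_composition <- function(symbols, counts) {
  el <- element_data(symbols)
  m <- counts * el$A
  data.frame(element = symbols, fraction = m / sum(m),
             stringsAsFactors = FALSE)
}
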