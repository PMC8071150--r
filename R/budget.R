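# Scenario driver and uncertainty-budget arithmetic.
#
# Per-source uncertainties on proton range, plateau dose and HI98 are
# either computed by the engine (run_scenario) or taken from the study's
# published per-source table (literature_budget), and combined in
# quadrature into total range/dose uncertainties with the study's
# exclusion rules: beam-component entries are absorbed by a commissioning
# measurement, CT-dependent entries (^) do not apply to water-like
# biological samples, and the water I-value entry (+) does not apply to
# mice.

#' Quadrature combination of uncertainty magnitudes
#'
#' Square root of the sum of squares, rounded to one decimal for reporting
#' (the table's precision). An empty set combines to 0.
#'
#' @param magnitudes Non-negative uncertainty magnitudes.
#' @param round_digits Decimals for reporting; `NULL` for unrounded.
#' @return Combined magnitude.
#' @export
quadrature_total <- function(magnitudes, round_digits = 1) {
  magnitudes <- magnitudes[!is.na(magnitudes)]
  if (any(magnitudes < 0)) stop("magnitudes must be >= 0", call. = FALSE)
  tot <- sqrt(sum(magnitudes^2))
  if (is.null(round_digits)) tot else round(tot, round_digits)
}

budget_entry <- function(source, label, role, tag = "",
                         range_mm = NA_real_, range_ns = NA,
                         dose_with_pct = NA_real_, dose_with_ns = NA,
                         dose_without_pct = NA_real_, dose_without_ns = NA,
                         hi98_delta = NA_real_, hi98_ns = NA) {
  data.frame(source = source, label = label, role = role, tag = tag,
             range_mm = range_mm, range_ns = range_ns,
             dose_with_pct = dose_with_pct, dose_with_ns = dose_with_ns,
             dose_without_pct = dose_without_pct,
             dose_without_ns = dose_without_ns,
             hi98_delta = hi98_delta, hi98_ns = hi98_ns,
             stringsAsFactors = FALSE)
}

#' Published per-source uncertainty table
#'
#' The study's per-source maxima: commissioning measurement +-2.0%, beam
#' component thickness +-3.5% (scatterer only), component position +-2.7%
#' with / +-4.7% without the scatterer, target setup +-4.4% / +-1.4%, CT
#' noise +-0.3 mm, CT grid size +-0.6 mm, tissue I-values +-0.2 mm, water
#' I-value +-0.2 mm; all other cells non-significant. `^` marks
#' CT-dependent sources (not applicable to water-like biological samples),
#' `+` the water-target I-value (not applicable to mice).
#'
#' @return A data frame of budget entries (one row per source).
#' @export
literature_budget <- function() {
  rbind(
    budget_entry("commissioning", "Measurement uncertainty for commissioning",
                 "commissioning",
                 dose_with_pct = 2.0, dose_with_ns = FALSE,
                 dose_without_pct = 2.0, dose_without_ns = FALSE),
    budget_entry("energy_spread", "Beam energy spread (spread +-1 MeV)",
                 "beam",
                 range_mm = 0, range_ns = TRUE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("component_thickness", "Beam component thickness (+-5%)",
                 "beam",
                 range_mm = 0, range_ns = TRUE,
                 dose_with_pct = 3.5, dose_with_ns = FALSE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("component_position", "Beam component position (+-1 cm)",
                 "beam",
                 range_mm = 0, range_ns = TRUE,
                 dose_with_pct = 2.7, dose_with_ns = FALSE,
                 dose_without_pct = 4.7, dose_without_ns = FALSE),
    budget_entry("target_position", "Sample or animal setup in the beam axis (+-1 cm)",
                 "setup",
                 range_mm = 0, range_ns = TRUE,
                 dose_with_pct = 4.4, dose_with_ns = FALSE,
                 dose_without_pct = 1.4, dose_without_ns = FALSE),
    budget_entry("hu_noise", "CT imaging and calibration (+-40 HU)",
                 "ct", tag = "^",
                 range_mm = 0.3, range_ns = FALSE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("grid_size", "CT grid size (0.2/0.4/0.8 mm)",
                 "ct", tag = "^",
                 range_mm = 0.6, range_ns = FALSE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("i_value_components", "Mean excitation energy of beam components",
                 "beam",
                 range_mm = 0, range_ns = TRUE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("i_value_tissues", "Mean excitation energy (+-6%) in tissues",
                 "ct", tag = "^",
                 range_mm = 0.2, range_ns = FALSE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE),
    budget_entry("i_value_water", "Mean excitation energy in water",
                 "target", tag = "+",
                 range_mm = 0.2, range_ns = FALSE,
                 dose_with_pct = 0, dose_with_ns = TRUE,
                 dose_without_pct = 0, dose_without_ns = TRUE)
  )
}

# Significant dose magnitudes for one scatterer column.
dose_column <- function(entries, scatterer) {
  v <- if (scatterer == "with") entries$dose_with_pct else entries$dose_without_pct
  ns <- if (scatterer == "with") entries$dose_with_ns else entries$dose_without_ns
  v[!is.na(v) & !ns]
}

#' Assemble the uncertainty budget
#'
#' Combines per-source entries in quadrature. Dose totals per scatterer
#' column: `raw` includes every significant dose entry (commissioning,
#' beam-component thickness and position, target setup); `commissioned`
#' assumes a reference measurement at each setup, which absorbs the
#' beam-component entries, leaving commissioning and target setup. Range
#' totals: biological samples exclude the CT-dependent (`^`) entries, mice
#' exclude the water I-value (`+`) entry.
#'
#' @param entries Budget entry table ([literature_budget()] or rows built
#'   by [run_scenario()]).
#' @return An `uncertainty_budget` with the entry table and all totals.
#' @export
build_budget <- function(entries = literature_budget()) {
  required <- c("commissioning", "target_position")
  if (!all(required %in% entries$source)) {
    stop("missing required entries: ",
         paste(setdiff(required, entries$source), collapse = ", "),
         call. = FALSE)
  }
  commissioned_roles <- c("commissioning", "setup")
  totals <- list()
  for (sc in c("with", "without")) {
    raw <- dose_column(entries, sc)
    comm <- dose_column(entries[entries$role %in% commissioned_roles, ], sc)
    totals[[paste0("dose_", sc, "_raw_pct")]] <- quadrature_total(raw)
    totals[[paste0("dose_", sc, "_commissioned_pct")]] <- quadrature_total(comm)
  }
  rng <- entries$range_mm
  ok <- !is.na(rng) & !entries$range_ns
  totals$range_biological_mm <-
    quadrature_total(rng[ok & entries$tag != "^"])
  totals$range_mouse_mm <- quadrature_total(rng[ok & entries$tag != "+"])
  structure(list(entries = entries, totals = totals),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("<uncertainty_budget>\n")
  print(format_budget_table(x), row.names = FALSE)
  t <- x$totals
  cat(sprintf("  Dose totals   with scatterer: +-%.1f%% (+-%.1f%% commissioned)\n",
              t$dose_with_raw_pct, t$dose_with_commissioned_pct))
  cat(sprintf("             without scatterer: +-%.1f%% (+-%.1f%% commissioned)\n",
              t$dose_without_raw_pct, t$dose_without_commissioned_pct))
  cat(sprintf("  Range totals  biological samples (excl ^): +-%.1f mm; mice (excl +): +-%.1f mm\n",
              t$range_biological_mm, t$range_mouse_mm))
  invisible(x)
}

format_cell <- function(value, ns, unit) {
  ifelse(is.na(value), "-", ifelse(ns, "NS",
                                   sprintf("+-%.1f%s", value, unit)))
}

format_budget_table <- function(budget) {
  e <- budget$entries
  data.frame(
    source = paste0(e$label, ifelse(e$tag == "", "", paste0(" ", e$tag))),
    range = format_cell(e$range_mm, e$range_ns, " mm"),
    dose_with_scatterer = format_cell(e$dose_with_pct, e$dose_with_ns, "%"),
    dose_without_scatterer = format_cell(e$dose_without_pct,
                                         e$dose_without_ns, "%"),
    stringsAsFactors = FALSE
  )
}

#' Export the budget as CSV and/or JSON
#'
#' The CSV mirrors the study's table layout (one row per source, range and
#' per-column dose cells, NS rendered literally, totals appended); the
#' JSON carries the raw entries and totals and round-trips through
#' [budget_from_json()].
#'
#' @param budget An `uncertainty_budget`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The formatted table, invisibly.
#' @export
report_budget <- function(budget, csv_path = NULL, json_path = NULL) {
  tab <- format_budget_table(budget)
  t <- budget$totals
  tab <- rbind(tab,
               data.frame(source = "Overall, biological samples (excluding ^)",
                          range = sprintf("+-%.1f mm", t$range_biological_mm),
                          dose_with_scatterer =
                            sprintf("+-%.1f%% (+-%.1f%% **)",
                                    t$dose_with_raw_pct,
                                    t$dose_with_commissioned_pct),
                          dose_without_scatterer =
                            sprintf("+-%.1f%% (+-%.1f%% **)",
                                    t$dose_without_raw_pct,
                                    t$dose_without_commissioned_pct)),
               data.frame(source = "Overall, mice (excluding +)",
                          range = sprintf("+-%.1f mm", t$range_mouse_mm),
                          dose_with_scatterer =
                            sprintf("+-%.1f%% (+-%.1f%% **)",
                                    t$dose_with_raw_pct,
                                    t$dose_with_commissioned_pct),
                          dose_without_scatterer =
                            sprintf("+-%.1f%% (+-%.1f%% **)",
                                    t$dose_without_raw_pct,
                                    t$dose_without_commissioned_pct)))
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(entries = budget$entries,
                              totals = budget$totals),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(tab)
}

#' Rebuild a budget from its JSON export
#' @param path JSON path written by [report_budget()].
#' @return An `uncertainty_budget`.
#' @export
budget_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  num <- c("range_mm", "dose_with_pct", "dose_without_pct", "hi98_delta")
  lgl <- c("range_ns", "dose_with_ns", "dose_without_ns", "hi98_ns")
  for (cn in num) entries[[cn]] <- as.numeric(entries[[cn]])
  for (cn in lgl) entries[[cn]] <- as.logical(entries[[cn]])
  build_budget(entries)
}
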