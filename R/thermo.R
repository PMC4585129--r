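# Thermodynamics of AOM coupled to sulfate reduction:
#   CH4 + SO4^2- -> HCO3-/CO2 + HS- (+ H2O), 1:1:1:1 stoichiometry.
# Activities are taken equal to molar concentrations (coefficients 1, water
# activity 1); with 1:1:1:1 stoichiometry the quotient is unit-free, so
# concentrations enter in mM directly.

#' Thermodynamic parameters for the AOM energy calculation
#'
#' @param delta_g0_prime_kj Standard transformed Gibbs energy of AOM coupled
#'   to sulfate reduction, kJ per mol CH4, with methane as a gas molecule and
#'   products as CO2 and HS-. Default -21.
#' @param temperature_K Temperature used in the RT term, K. The default
#'   293.15 K (20 degC) matches the reference state of the methane
#'   solubility value used for the dissolved CH4 concentration; the 15 degC
#'   incubation temperature (288.15 K) can be substituted here.
#' @param gas_constant_kj Molar gas constant, kJ mol^-1 K^-1.
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(delta_g0_prime_kj = -21,
                          temperature_K = 293.15,
                          gas_constant_kj = 0.0083145) {
  stopifnot(temperature_K > 0, gas_constant_kj > 0)
  structure(list(delta_g0_prime_kj = delta_g0_prime_kj,
                 temperature_K = temperature_K,
                 gas_constant_kj = gas_constant_kj),
            class = "thermo_params")
}

#' Bioenergetic thresholds for classifying incubation conditions
#'
#' Cutoffs on the free energy yield per mol CH4 (signed scale: more negative
#' means more energy available). The growth threshold of -19 kJ mol^-1
#' corresponds to the energy of translocating one proton in sulfate
#' reducers; -10.6 kJ mol^-1 is the analogous minimum for methanogenic
#' archaea, and -10 kJ mol^-1 an estimate for ANME/SRB aggregates.
#'
#' @param growth_threshold_kj Energy yield below which growth is predicted.
#' @param maintenance_threshold_kj Minimum-energy (maintenance) cutoff.
#' @param aggregate_threshold_kj Critical yield estimate for ANME/SRB
#'   aggregates; stored for reference, not used by the classifier.
#' @return A list of class `energy_thresholds`.
#' @export
energy_thresholds <- function(growth_threshold_kj = -19,
                              maintenance_threshold_kj = -10.6,
                              aggregate_threshold_kj = -10) {
  if (growth_threshold_kj > maintenance_threshold_kj)
    stop("growth threshold must be <= maintenance threshold on the signed scale",
         call. = FALSE)
  structure(list(growth_threshold_kj = growth_threshold_kj,
                 maintenance_threshold_kj = maintenance_threshold_kj,
                 aggregate_threshold_kj = aggregate_threshold_kj),
            class = "energy_thresholds")
}

#' Methane solubility parameters
#'
#' @param ch4_sat_mM Dissolved CH4 concentration at saturation under 1 bar
#'   CH4; default 1.31 mM at salinity 30 and 20 degC.
#' @param salinity Practical salinity of the reference value.
#' @param reference_temp_C Reference temperature of the solubility value.
#' @param neglect_overpressure If `TRUE` (default), the 0.5-1 bar headspace
#'   overpressure is taken as negligible and the saturation value is used as
#'   is.
#' @return A list of class `solubility_params`.
#' @export
solubility_params <- function(ch4_sat_mM = 1.31, salinity = 30,
                              reference_temp_C = 20,
                              neglect_overpressure = TRUE) {
  stopifnot(ch4_sat_mM > 0)
  structure(list(ch4_sat_mM = ch4_sat_mM, salinity = salinity,
                 reference_temp_C = reference_temp_C,
                 neglect_overpressure = isTRUE(neglect_overpressure)),
            class = "solubility_params")
}

# Pull the four concentration columns out of a condition record (one-row or
# multi-row data.frame, or a plain named list), vectorized.
.cond_fields <- function(cond) {
  if (is.data.frame(cond) || is.list(cond)) {
    need <- c("sulfate_mM", "sulfide_mM", "methane_mM", "co2_mM")
    miss <- setdiff(need, names(cond))
    if (length(miss))
      stop("condition is missing fields: ", paste(miss, collapse = ", "),
           call. = FALSE)
    lapply(cond[need], as.numeric)
  } else {
    stop("condition must be a data.frame or named list", call. = FALSE)
  }
}

#' Reaction quotient of sulfate-coupled AOM
#'
#' Q = (\[CO2\]\[HS-\]) / (\[CH4\]\[SO4^2-\]). The 1:1:1:1 stoichiometry
#' makes Q dimensionless, so mM concentrations are used directly; Q is
#' invariant to scaling all four concentrations by a common factor.
#'
#' @param cond A condition record ([incubation_condition()] row or any
#'   data.frame/list with fields `sulfate_mM`, `sulfide_mM`, `methane_mM`,
#'   `co2_mM`). Vectorized over rows.
#' @return Numeric vector of reaction quotients.
#' @export
#' @examples
#' reaction_quotient(incubation_conditions()[1, ])
reaction_quotient <- function(cond) {
  f <- .cond_fields(cond)
  bad_ch4 <- !is.na(f$methane_mM) & f$methane_mM <= 0
  bad_so4 <- !is.na(f$sulfate_mM) & f$sulfate_mM <= 0
  if (any(bad_ch4))
    stop("reaction quotient undefined: methane_mM is zero", call. = FALSE)
  if (any(bad_so4))
    stop("reaction quotient undefined: sulfate_mM is zero", call. = FALSE)
  (f$co2_mM * f$sulfide_mM) / (f$methane_mM * f$sulfate_mM)
}

#' Transformed Gibbs free energy of AOM at in-situ concentrations
#'
#' Computes dG' = dG0' + RT ln Q, in kJ per mol CH4, from a condition's
#' dissolved concentrations.
#'
#' @inheritParams reaction_quotient
#' @param params A [thermo_params()] object.
#' @return Numeric vector of dG' values, kJ per mol CH4.
#' @export
#' @examples
#' conds <- incubation_conditions()
#' delta_g_prime(conds[conds$methane_added, ])
delta_g_prime <- function(cond, params = thermo_params()) {
  q <- reaction_quotient(cond)
  params$delta_g0_prime_kj +
    params$gas_constant_kj * params$temperature_K * log(q)
}

#' Classify a free energy yield against bioenergetic thresholds
#'
#' Conditions at or below the growth threshold are `growth_permissive`;
#' between the growth and maintenance thresholds, `maintenance_only`; above
#' the maintenance threshold, `below_quantum`. Boundary ties resolve to the
#' more permissive class (a condition exactly at -19 counts as
#' growth-permissive).
#'
#' @param dg Numeric vector of free energy yields, kJ per mol CH4.
#' @param thresholds An [energy_thresholds()] object.
#' @return Character vector of regime labels.
#' @export
classify_energetic_regime <- function(dg, thresholds = energy_thresholds()) {
  if (any(!is.finite(dg)))
    stop("dg must be finite", call. = FALSE)
  ifelse(dg <= thresholds$growth_threshold_kj, "growth_permissive",
         ifelse(dg <= thresholds$maintenance_threshold_kj,
                "maintenance_only", "below_quantum"))
}

#' Dissolved methane concentration under a methane headspace
#'
#' With `neglect_overpressure = TRUE` (the default and the study's working
#' assumption) the saturation value is returned unchanged for any headspace
#' pressure. Setting it to `FALSE` enables linear Henry-law scaling with the
#' CH4 partial pressure relative to 1 bar; this is an extension beyond the
#' study's assumption.
#'
#' @param sol A [solubility_params()] object.
#' @param headspace_bar CH4 partial pressure in the headspace, bar.
#' @return Dissolved CH4 concentration, mM.
#' @export
dissolved_methane <- function(sol = solubility_params(), headspace_bar = 1.8) {
  if (any(headspace_bar < 0))
    stop("headspace pressure must be >= 0", call. = FALSE)
  if (sol$neglect_overpressure) rep(sol$ch4_sat_mM, length(headspace_bar))
  else sol$ch4_sat_mM * headspace_bar
}

#' Energetics report for a condition table
#'
#' One row per condition with the reaction quotient, dG', and the energetic
#' regime. Conditions without methane in the headspace get `NA` for all
#' three (rendered as an em-dash in the formatted column, mirroring the
#' study's convention for its non-methane controls).
#'
#' @param conditions A condition data.frame as from
#'   [incubation_conditions()] or [read_conditions()].
#' @param params A [thermo_params()] object.
#' @param thresholds An [energy_thresholds()] object.
#' @return The condition data.frame with columns `Q`, `delta_g_kj`, `regime`
#'   and a formatted `delta_g_label` (one decimal, em-dash when undefined)
#'   appended.
#' @export
#' @examples
#' energetics_table(incubation_conditions())
energetics_table <- function(conditions, params = thermo_params(),
                             thresholds = energy_thresholds()) {
  out <- conditions
  n <- nrow(out)
  out$Q <- rep(NA_real_, n)
  out$delta_g_kj <- rep(NA_real_, n)
  out$regime <- rep(NA_character_, n)
  has_ch4 <- out$methane_added & !is.na(out$methane_mM) & out$methane_mM > 0
  bad <- out$methane_added & (is.na(out$methane_mM) | out$methane_mM <= 0)
  if (any(bad))
    out$regime[bad] <- "error: methane_added but methane_mM is zero"
  if (any(has_ch4)) {
    sub <- out[has_ch4, , drop = FALSE]
    out$Q[has_ch4] <- reaction_quotient(sub)
    out$delta_g_kj[has_ch4] <- delta_g_prime(sub, params)
    out$regime[has_ch4] <-
      classify_energetic_regime(out$delta_g_kj[has_ch4], thresholds)
  }
  out$delta_g_label <- ifelse(is.na(out$delta_g_kj), "—",
                              sprintf("%.1f", out$delta_g_kj))
  out
}

#' @rdname energetics_table
#' @param x An energetics table.
#' @param file Output CSV path.
#' @export
write_energetics <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}
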