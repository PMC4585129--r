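# 13CH4 tracer bookkeeping. Mass-spectral deconvolution is upstream of this
# module: inputs are already two-isotopologue amounts (12C and 13C) per
# species and time point, per bottle.

#' Serum-bottle geometry and incubation conditions
#'
#' @param total_volume_L Bottle volume, L (244 mL serum bottle).
#' @param liquid_volume_L Liquid phase, L (30 mL sediment + 90 mL medium).
#' @param headspace_pressure_bar Total headspace pressure, bar.
#' @param temperature_K Incubation temperature, K (15 degC).
#' @return A list of class `bottle_spec` with the derived
#'   `headspace_volume_L`.
#' @export
bottle_spec <- function(total_volume_L = 0.244, liquid_volume_L = 0.120,
                        headspace_pressure_bar = 1.8,
                        temperature_K = 288.15) {
  if (liquid_volume_L >= total_volume_L)
    stop("liquid volume must be smaller than total volume", call. = FALSE)
  stopifnot(temperature_K > 0, headspace_pressure_bar >= 0)
  structure(list(total_volume_L = total_volume_L,
                 liquid_volume_L = liquid_volume_L,
                 headspace_volume_L = total_volume_L - liquid_volume_L,
                 headspace_pressure_bar = headspace_pressure_bar,
                 temperature_K = temperature_K),
            class = "bottle_spec")
}

#' Labeling scheme for the 13CH4 tracer addition
#'
#' At the label-start day the headspace is topped up with 12CH4 and then
#' 13CH4, so a known fraction of headspace methane carries the label.
#'
#' @param label_start_day Day of 13CH4 addition.
#' @param f13_ch4 Fraction of headspace CH4 that is 13CH4 after labeling.
#'   Default 0.2/1.8 (label added from 1.6 to 1.8 bar).
#' @param natural_abundance Natural 13C abundance.
#' @return A list of class `label_state`.
#' @export
label_state <- function(label_start_day = 540, f13_ch4 = 0.2 / 1.8,
                        natural_abundance = 0.011) {
  stopifnot(f13_ch4 >= 0, f13_ch4 <= 1,
            natural_abundance >= 0, natural_abundance <= 0.02)
  structure(list(label_start_day = label_start_day, f13_ch4 = f13_ch4,
                 natural_abundance = natural_abundance),
            class = "label_state")
}

# L bar / (mol K)
.R_Lbar <- 0.083145

#' Ideal-gas amount of a headspace component
#'
#' n = P V_headspace / (R T), reported in mmol.
#'
#' @param spec A [bottle_spec()] object.
#' @param partial_pressure_bar Partial pressure of the component, bar.
#' @return Amount in mmol (vectorized over pressures).
#' @export
#' @examples
#' headspace_amount(bottle_spec(), 1.8)  # ~9.32 mmol CH4
headspace_amount <- function(spec = bottle_spec(), partial_pressure_bar) {
  if (any(partial_pressure_bar < 0))
    stop("partial pressure must be >= 0", call. = FALSE)
  1000 * partial_pressure_bar * spec$headspace_volume_L /
    (.R_Lbar * spec$temperature_K)
}

#' 13C isotopologue fraction of a gas pool
#'
#' Raw fraction amount_13 / (amount_12 + amount_13); optionally corrected by
#' subtracting the natural 13C abundance (clamped to \[0, 1\]).
#'
#' @param amount_12,amount_13 Amounts of the 12C and 13C isotopologues (any
#'   common unit). Vectorized.
#' @param correct_natural Subtract `natural_abundance` from the raw
#'   fraction? Off by default: the production readout is baseline-anchored
#'   at label addition, which removes the natural background anyway.
#' @param natural_abundance Natural 13C abundance.
#' @return Label fraction in \[0, 1\].
#' @export
isotope_fraction <- function(amount_12, amount_13, correct_natural = FALSE,
                             natural_abundance = 0.011) {
  if (any(amount_12 < 0) || any(amount_13 < 0))
    stop("isotopologue amounts must be >= 0", call. = FALSE)
  total <- amount_12 + amount_13
  if (any(total == 0))
    stop("isotope fraction undefined: total amount is zero", call. = FALSE)
  f <- amount_13 / total
  if (correct_natural) f <- pmin(pmax(f - natural_abundance, 0), 1)
  f
}

#' Produced 13CO2 as a percentage, anchored at label addition
#'
#' For a per-bottle CO2 isotopologue time series, returns
#' 100 * (f13(t) - f13(t0)) for every t at or after the label-start day,
#' where t0 is the last observation at or before label start. The anchor
#' point is 0 by construction; the readout is invariant to any constant
#' offset in the fractions.
#'
#' @param series A data.frame with columns `day`, `amount12_mmol`,
#'   `amount13_mmol` for CO2, sorted by day (one bottle).
#' @param label A [label_state()] object.
#' @return A data.frame `day`, `pct_13co2` for days >= label start.
#' @export
percent_13co2 <- function(series, label = label_state()) {
  need <- c("day", "amount12_mmol", "amount13_mmol")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("series is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(series$day))
    stop("series must be sorted by day", call. = FALSE)
  f <- isotope_fraction(series$amount12_mmol, series$amount13_mmol)
  base_idx <- which(series$day <= label$label_start_day)
  if (!length(base_idx))
    stop("no baseline reading at or before the label-start day",
         call. = FALSE)
  f0 <- f[max(base_idx)]
  keep <- series$day >= label$label_start_day
  data.frame(day = series$day[keep], pct_13co2 = 100 * (f[keep] - f0))
}

#' Methane oxidized from 13CO2 production (label dilution)
#'
#' Produced 13CO2 divided by the 13C fraction of the methane pool gives the
#' total methane oxidized, since only a fraction `f13_ch4` of oxidized
#' methane carries the label.
#'
#' @param delta_13co2_mmol 13CO2 produced since label addition, mmol.
#' @param f13_ch4 Fraction of headspace CH4 that is labeled.
#' @return Estimated CH4 oxidized, mmol.
#' @export
methane_oxidized <- function(delta_13co2_mmol, f13_ch4) {
  if (any(f13_ch4 <= 0) || any(f13_ch4 > 1))
    stop("f13_ch4 must be in (0, 1]", call. = FALSE)
  delta_13co2_mmol / f13_ch4
}

#' Read a per-bottle gas time series
#'
#' Gas series CSV dialect: `bottle_id,day,species,amount12_mmol,amount13_mmol`
#' with `species` in `CO2`, `CH4`.
#'
#' @param file Path to a CSV file.
#' @return A data.frame.
#' @export
read_gas_series <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("bottle_id", "day", "species", "amount12_mmol", "amount13_mmol")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("gas series file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x[need]
}

#' Per-bottle 13CO2 production table
#'
#' Applies [percent_13co2()] to each bottle of a multi-bottle gas series.
#'
#' @param gas A gas series data.frame (see [read_gas_series()]).
#' @param label A [label_state()] object.
#' @return A data.frame `bottle_id`, `day`, `pct_13co2`.
#' @export
pct13co2_table <- function(gas, label = label_state()) {
  co2 <- gas[gas$species == "CO2", , drop = FALSE]
  parts <- lapply(split(co2, co2$bottle_id), function(b) {
    b <- b[order(b$day), , drop = FALSE]
    p <- percent_13co2(b, label)
    cbind(bottle_id = b$bottle_id[1], p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
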