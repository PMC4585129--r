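# Setpoint maintenance: the incubations hold sulfide and sulfate at their
# condition targets by episodic reagent additions. FeCl2 precipitates excess
# sulfide as FeS (instantaneous, complete, 1:1 Fe:S, no redissolution);
# Na2SO4 replenishes sulfate; FeSO4 does both with one dose.

#' Per-bottle geochemical state
#'
#' @param day Observation day.
#' @param sulfate_mM,sulfide_mM Dissolved pools, mM.
#' @param fes_mmol Cumulative FeS precipitated in the bottle, mmol.
#' @param liquid_volume_L Liquid volume, L.
#' @return A list of class `geochem_state`.
#' @export
geochem_state <- function(day = 0, sulfate_mM, sulfide_mM, fes_mmol = 0,
                          liquid_volume_L = 0.120) {
  if (any(c(sulfate_mM, sulfide_mM, fes_mmol) < 0))
    stop("pools must be >= 0", call. = FALSE)
  stopifnot(liquid_volume_L > 0)
  structure(list(day = day, sulfate_mM = sulfate_mM,
                 sulfide_mM = sulfide_mM, fes_mmol = fes_mmol,
                 liquid_volume_L = liquid_volume_L),
            class = "geochem_state")
}

#' Sulfide/sulfate setpoints for one condition
#'
#' Amendments trigger when sulfide exceeds `sulfide_max_mM` or sulfate drops
#' below `sulfate_min_mM`, and correct back to the *target*, not the
#' boundary, producing the characteristic sawtooth of a maintained
#' incubation.
#'
#' @param sulfide_target_mM,sulfide_max_mM Sulfide target and trigger, mM.
#' @param sulfate_target_mM,sulfate_min_mM Sulfate target and trigger, mM.
#' @return A list of class `setpoints`.
#' @export
setpoints <- function(sulfide_target_mM, sulfide_max_mM,
                      sulfate_target_mM, sulfate_min_mM) {
  if (sulfide_max_mM < sulfide_target_mM || sulfide_target_mM < 0)
    stop("need sulfide_max >= sulfide_target >= 0", call. = FALSE)
  if (sulfate_target_mM < sulfate_min_mM || sulfate_min_mM < 0)
    stop("need sulfate_target >= sulfate_min >= 0", call. = FALSE)
  structure(list(sulfide_target_mM = sulfide_target_mM,
                 sulfide_max_mM = sulfide_max_mM,
                 sulfate_target_mM = sulfate_target_mM,
                 sulfate_min_mM = sulfate_min_mM),
            class = "setpoints")
}

#' Default setpoints for the seven-condition study
#'
#' Targets follow each condition's nominal concentrations; the endogenous
#' conditions (methane only, sulfide only) receive no sulfate or sulfide
#' amendments.
#'
#' @return A named list of [setpoints()], keyed by condition id.
#' @export
default_setpoints <- function() {
  conds <- incubation_conditions()
  amended <- list(
    c(0.4, 1.0, 21.6, 19.0),  # 1: CH4 highSO4
    c(3.8, 4.5, 21.1, 19.0),  # 2: CH4 highSO4 highS
    c(0.4, 1.0, 3.6, 3.0),    # 3: CH4 lowSO4
    c(3.6, 4.2, 4.0, 3.4),    # 4: CH4 lowSO4 highS
    c(0.2, 1.0, 21.6, 19.0),  # 5: highSO4
    NULL,                     # 6: CH4 (endogenous pools, no amendments)
    NULL                      # 7: highS (no amendments in scope)
  )
  out <- lapply(amended, function(v) {
    if (is.null(v)) setpoints(0, Inf, 0, 0)
    else setpoints(v[1], v[2], v[3], v[4])
  })
  names(out) <- conds$id
  out
}

#' Amendment doses needed to restore setpoints
#'
#' Excess sulfide n1 = (sulfide - target) * V when sulfide is above its
#' trigger; sulfate deficit n2 = (target - sulfate) * V when sulfate is
#' below its trigger. When both occur, FeSO4 covers min(n1, n2) (its dose
#' both precipitates sulfide and adds sulfate mol-for-mol), then FeCl2 tops
#' up any remaining sulfide excess and Na2SO4 any remaining sulfate deficit.
#' This never overshoots either setpoint.
#'
#' @param state A [geochem_state()].
#' @param sp A [setpoints()] object.
#' @return A data.frame `reagent`, `dose_mmol` (zero rows when in range).
#' @export
#' @examples
#' st <- geochem_state(day = 100, sulfate_mM = 21, sulfide_mM = 6)
#' required_amendments(st, setpoints(4, 4.5, 21.6, 19))
required_amendments <- function(state, sp) {
  V <- state$liquid_volume_L
  n1 <- if (state$sulfide_mM > sp$sulfide_max_mM)
    (state$sulfide_mM - sp$sulfide_target_mM) * V else 0
  n2 <- if (state$sulfate_mM < sp$sulfate_min_mM)
    (sp$sulfate_target_mM - state$sulfate_mM) * V else 0
  reagent <- character(0); dose <- numeric(0)
  if (n1 > 0 && n2 > 0) {
    shared <- min(n1, n2)
    reagent <- "FeSO4"; dose <- shared
    if (n1 > shared) { reagent <- c(reagent, "FeCl2"); dose <- c(dose, n1 - shared) }
    if (n2 > shared) { reagent <- c(reagent, "Na2SO4"); dose <- c(dose, n2 - shared) }
  } else if (n1 > 0) {
    reagent <- "FeCl2"; dose <- n1
  } else if (n2 > 0) {
    reagent <- "Na2SO4"; dose <- n2
  }
  data.frame(reagent = reagent, dose_mmol = dose, stringsAsFactors = FALSE)
}

#' Apply one amendment to a geochemical state
#'
#' FeCl2 removes `dose` mmol of dissolved sulfide into the FeS pool (floored
#' at the available sulfide); Na2SO4 adds `dose` mmol of sulfate; FeSO4 does
#' both with the same dose.
#'
#' @param state A [geochem_state()].
#' @param reagent One of `"FeCl2"`, `"Na2SO4"`, `"FeSO4"`.
#' @param dose_mmol Dose in mmol (>= 0).
#' @return The updated [geochem_state()].
#' @export
apply_amendment <- function(state, reagent, dose_mmol) {
  stopifnot(dose_mmol >= 0)
  reagent <- match.arg(reagent, c("FeCl2", "Na2SO4", "FeSO4"))
  V <- state$liquid_volume_L
  if (reagent %in% c("FeCl2", "FeSO4")) {
    avail <- state$sulfide_mM * V
    removed <- min(dose_mmol, avail)
    state$sulfide_mM <- state$sulfide_mM - removed / V
    state$fes_mmol <- state$fes_mmol + removed
  }
  if (reagent %in% c("Na2SO4", "FeSO4")) {
    state$sulfate_mM <- state$sulfate_mM + dose_mmol / V
  }
  state
}

#' Sulfur mass-balance residual over a bottle history
#'
#' Total sulfur (dissolved sulfate + dissolved sulfide + FeS pool) changes
#' only through sulfate-bearing amendments (Na2SO4, FeSO4) — AOM converts
#' sulfate to sulfide 1:1 and FeS precipitation moves sulfide between
#' pools. The residual is the change in total sulfur minus the sulfur added
#' by amendments; it is zero in a closed, noiseless system.
#'
#' @param states A data.frame of bottle states over time with columns `day`,
#'   `sulfate_mM`, `sulfide_mM`, `fes_mmol`, `liquid_volume_L`, in
#'   chronological order. Zero rows give a residual of 0.
#' @param amendments A data.frame `day`, `reagent`, `dose_mmol` of applied
#'   amendments (optional).
#' @return Residual in mmol.
#' @export
sulfur_balance <- function(states, amendments = NULL) {
  if (is.null(states) || nrow(states) == 0L) return(0)
  if (is.unsorted(states$day))
    stop("state history must be in chronological order", call. = FALSE)
  tot <- function(row)
    (row$sulfate_mM + row$sulfide_mM) * row$liquid_volume_L + row$fes_mmol
  added <- 0
  if (!is.null(amendments) && nrow(amendments) > 0L) {
    s_bearing <- amendments$reagent %in% c("Na2SO4", "FeSO4")
    added <- sum(amendments$dose_mmol[s_bearing])
  }
  tot(states[nrow(states), , drop = FALSE]) -
    tot(states[1L, , drop = FALSE]) - added
}
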