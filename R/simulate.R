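# Seeded generator of a complete synthetic incubation study: 7 conditions x
# 3 bottles x 947 days, with the mechanistic structure the analysis assumes
# (Monod sulfate kinetics with a hard thermodynamic gate, setpoint
# amendments, 13C labeling at day 540, linear-yield ANME growth) plus a
# ground-truth ledger, so every analysis stage is testable without
# laboratory data.

#' Simulation parameters for the synthetic study
#'
#' @param vmax_mM_per_day Maximal AOM rate, mM CH4 per day. The study
#'   reports no absolute rates; the default 0.005 is a realistic order of
#'   magnitude for a non-seep sediment slurry, and all rate-dependent checks
#'   are relative.
#' @param km_sulfate_mM Monod half-saturation for sulfate, mM. Default 1.5,
#'   consistent with a Km below 2 mM for this sediment.
#' @param dg_crit_kj Hard energetic gate: AOM runs only while the in-state
#'   dG' is at or below this value (default -19 kJ per mol CH4).
#' @param methanogenesis_rate_mM_per_day Background CO2-to-CH4 rate, applied
#'   only in the sulfide-only condition where methane accumulation was
#'   observed. Default 0.002; the realized rate saturates in the CO2 pool
#'   (half-saturation 0.5 mM) so dissolved inorganic carbon is drawn down
#'   asymptotically, never exhausted.
#' @param growth_yield Named per-clade yields: ANME 16S copies per g wet
#'   weight produced per mmol CH4 oxidized. Defaults give the dominant
#'   clade roughly a 2-3 fold increase by day 344 under the most favorable
#'   condition, keeping simulated Cq values inside the standard range.
#' @param clade_niche Clade-by-condition matrix of multipliers on the
#'   growth yield (rows ANME1/ANME2ab/ANME2c, one column per condition).
#' @param inoculum_copies Named day-0 copies per g wet weight; the default
#'   ordering (ANME2ab > ANME1 > ANME2c) reflects the inoculum.
#' @param noise_sd Relative s.d. of the multiplicative lognormal measurement
#'   noise on observed concentration and gas series.
#' @param cq_noise_sd Additive Gaussian s.d. on simulated Cq values.
#' @param seed Master RNG seed; per-bottle streams are derived from it by
#'   fixed offsets.
#' @param dt_days Forward-Euler time step, days.
#' @param n_days Length of the incubation, days.
#' @param sampling_interval_days Days between observations (and controller
#'   checks).
#' @param conditions Condition table, default [incubation_conditions()].
#' @param setpoints_list Named list of [setpoints()] per condition id.
#' @param label A [label_state()] object.
#' @param bottle A [bottle_spec()] object.
#' @param thermo A [thermo_params()] object used inside the energetic gate.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(vmax_mM_per_day = 0.005,
                       km_sulfate_mM = 1.5,
                       dg_crit_kj = -19,
                       methanogenesis_rate_mM_per_day = 0.002,
                       growth_yield = c(ANME1 = 5e6, ANME2ab = 4e7,
                                        ANME2c = 1e5),
                       clade_niche = NULL,
                       inoculum_copies = c(ANME1 = 1e6, ANME2ab = 5e6,
                                           ANME2c = 1e5),
                       noise_sd = 0.05,
                       cq_noise_sd = 0.15,
                       seed = 1L,
                       dt_days = 1,
                       n_days = 947,
                       sampling_interval_days = 30,
                       conditions = incubation_conditions(),
                       setpoints_list = default_setpoints(),
                       label = label_state(),
                       bottle = bottle_spec(),
                       thermo = thermo_params()) {
  stopifnot(vmax_mM_per_day >= 0, km_sulfate_mM > 0,
            methanogenesis_rate_mM_per_day >= 0,
            all(growth_yield >= 0), noise_sd >= 0, cq_noise_sd >= 0,
            dt_days > 0, n_days > 0)
  clades <- c("ANME1", "ANME2ab", "ANME2c")
  stopifnot(all(clades %in% names(growth_yield)),
            all(clades %in% names(inoculum_copies)))
  if (!(inoculum_copies["ANME2ab"] > inoculum_copies["ANME1"] &&
        inoculum_copies["ANME1"] > inoculum_copies["ANME2c"]))
    stop("inoculum ordering must be ANME2ab > ANME1 > ANME2c",
         call. = FALSE)
  if (is.null(clade_niche)) {
    nc <- nrow(conditions)
    clade_niche <- rbind(
      ANME1 = rep(0.3, nc),          # grows wherever oxidation happens
      ANME2ab = c(1, 1, 0.5, 0.2, 0, 0.3, 0)[seq_len(nc)],
      ANME2c = rep(0.05, nc)
    )
    colnames(clade_niche) <- conditions$id
  }
  structure(list(vmax_mM_per_day = vmax_mM_per_day,
                 km_sulfate_mM = km_sulfate_mM,
                 dg_crit_kj = dg_crit_kj,
                 methanogenesis_rate_mM_per_day = methanogenesis_rate_mM_per_day,
                 growth_yield = growth_yield, clade_niche = clade_niche,
                 inoculum_copies = inoculum_copies,
                 noise_sd = noise_sd, cq_noise_sd = cq_noise_sd,
                 seed = as.integer(seed), dt_days = dt_days,
                 n_days = n_days,
                 sampling_interval_days = sampling_interval_days,
                 conditions = conditions, setpoints_list = setpoints_list,
                 label = label, bottle = bottle, thermo = thermo),
            class = "sim_params")
}

#' Instantaneous AOM rate of a bottle state
#'
#' Monod kinetics in sulfate multiplied by a hard thermodynamic gate:
#' `vmax * [SO4]/(Km + [SO4])` while the in-state dG' is at or below
#' `dg_crit_kj`, zero otherwise, and zero when methane is absent.
#'
#' @param sulfate_mM,sulfide_mM,co2_mM Current dissolved concentrations.
#' @param methane_mM Dissolved methane (0 or NA when no methane headspace).
#' @param p A [sim_params()] object.
#' @return Rate in mM CH4 per day.
#' @export
aom_rate <- function(sulfate_mM, sulfide_mM, methane_mM, co2_mM, p) {
  if (is.na(methane_mM) || methane_mM <= 0 || sulfate_mM <= 0) return(0)
  dg <- delta_g_prime(list(sulfate_mM = sulfate_mM, sulfide_mM = sulfide_mM,
                           methane_mM = methane_mM, co2_mM = co2_mM),
                      p$thermo)
  if (dg > p$dg_crit_kj) return(0)
  p$vmax_mM_per_day * sulfate_mM / (p$km_sulfate_mM + sulfate_mM)
}

# One forward-Euler step of a bottle's internal (noiseless) state. `st` is a
# plain list; 1:1:1:1 CH4:SO4:HS:CO2 stoichiometry holds exactly in the
# ledger.
step_bottle <- function(st, p, dt = p$dt_days) {
  stopifnot(dt > 0)
  V <- p$bottle$liquid_volume_L
  r <- aom_rate(st$sulfate_mM, st$sulfide_mM, st$methane_mM, st$co2_mM, p)
  d <- r * dt
  if (d > st$sulfate_mM) d <- st$sulfate_mM  # never draw the pool negative
  st$sulfate_mM <- st$sulfate_mM - d
  st$sulfide_mM <- st$sulfide_mM + d
  st$co2_mM <- st$co2_mM + d
  st$cum_ox_mmol <- st$cum_ox_mmol + d * V
  if (st$labeled) st$co2_13_mmol <- st$co2_13_mmol + d * V * p$label$f13_ch4
  # CO2-to-CH4 background; saturating in CO2 so the pool is never exhausted
  m <- st$methanogenesis_mM_per_day * dt * st$co2_mM / (0.5 + st$co2_mM)
  if (m > 0) {
    m <- min(m, st$co2_mM)
    st$co2_mM <- st$co2_mM - m
    st$ch4_acc_mM <- st$ch4_acc_mM + m
    st$cum_methanogenesis_mmol <- st$cum_methanogenesis_mmol + m * V
  }
  st$day <- st$day + dt
  st
}

# derive a reproducible sub-seed (kept well below 2^31)
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

#' Generate a complete synthetic incubation study
#'
#' Runs all conditions in triplicate over the full incubation, applying
#' setpoint amendments at sampling days, adding the 13CH4 label at the
#' label-start day, and emitting observed tables with multiplicative
#' lognormal measurement noise plus a noiseless ground-truth ledger.
#' Identical parameters (including `seed`) give identical output.
#'
#' @param p A [sim_params()] object.
#' @return An object of class `aom_study`: list with `conditions`,
#'   `geochem` (observed concentration series), `gas` (observed CO2/CH4
#'   isotopologue series, mmol), `amendments` (log), `qpcr` (plate table
#'   with standards and day-0/day-344 samples), and `truth` (noiseless
#'   ledger: per-bottle final states, cumulative CH4 oxidized, true copy
#'   trajectories, the planted standard curve and parameters).
#' @export
#' @examples
#' study <- generate_study(sim_params(seed = 42, n_days = 60))
#' study
generate_study <- function(p = sim_params()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  conds <- p$conditions
  V <- p$bottle$liquid_volume_L
  qpcr_days <- c(0, 344)
  sample_days <- unique(c(seq(0, p$n_days, by = p$sampling_interval_days),
                          p$label$label_start_day, qpcr_days, p$n_days))
  sample_days <- sort(sample_days[sample_days <= p$n_days])
  qpcr_days <- qpcr_days[qpcr_days %in% sample_days]
  # planted standard curve: perfect doubling, typical intercept
  true_slope <- -3.3219; true_intercept <- 38
  geochem <- list(); gas <- list(); amend <- list()
  truth_states <- list(); truth_copies <- list(); truth_ox <- list()
  bottle_i <- 0L
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    sp <- p$setpoints_list[[cond$id]]
    if (is.null(sp)) sp <- setpoints(0, Inf, 0, 0)
    for (rep_i in 1:3) {
      bottle_i <- bottle_i + 1L
      bid <- sprintf("%d%s", ci, LETTERS[rep_i])
      set.seed(.sub_seed(p$seed, bottle_i))
      st <- list(day = 0,
                 sulfate_mM = cond$sulfate_mM,
                 sulfide_mM = cond$sulfide_mM,
                 co2_mM = cond$co2_mM,
                 methane_mM = if (cond$methane_added) cond$methane_mM else 0,
                 ch4_acc_mM = 0, fes_mmol = 0,
                 cum_ox_mmol = 0, co2_13_mmol = 0,
                 cum_methanogenesis_mmol = 0,
                 labeled = FALSE,
                 methanogenesis_mM_per_day =
                   if (!cond$methane_added && cond$sulfide_mM >= 1)
                     p$methanogenesis_rate_mM_per_day *
                       stats::rlnorm(1, 0, 0.5) else 0)
      copies <- p$inoculum_copies
      niche <- p$clade_niche[, ci]
      last_ox <- 0
      states_rows <- list(); gas_rows <- list(); amend_rows <- list()
      copies_rows <- list()
      obs_noise <- function(x) {
        if (p$noise_sd == 0) x
        else x * stats::rlnorm(length(x), -p$noise_sd^2 / 2, p$noise_sd)
      }
      record <- function(st) {
        states_rows[[length(states_rows) + 1L]] <<- data.frame(
          bottle_id = bid, condition_id = cond$id, replicate = rep_i,
          day = st$day,
          sulfate_mM = obs_noise(st$sulfate_mM),
          sulfide_mM = obs_noise(st$sulfide_mM),
          ch4_mM = obs_noise(st$methane_mM + st$ch4_acc_mM),
          co2_mM = obs_noise(st$co2_mM),
          fes_mmol = st$fes_mmol,
          liquid_volume_L = V,
          true_sulfate_mM = st$sulfate_mM, true_sulfide_mM = st$sulfide_mM,
          true_co2_mM = st$co2_mM,
          stringsAsFactors = FALSE)
        co2_tot <- st$co2_mM * V
        co2_13 <- p$label$natural_abundance * co2_tot + st$co2_13_mmol
        co2_13 <- min(co2_13, co2_tot)
        ch4_tot <- headspace_amount(p$bottle,
                                    if (cond$methane_added)
                                      p$bottle$headspace_pressure_bar else 0) +
          (st$methane_mM + st$ch4_acc_mM) * V
        f13_ch4 <- if (st$labeled) p$label$f13_ch4 else p$label$natural_abundance
        gas_rows[[length(gas_rows) + 1L]] <<- data.frame(
          bottle_id = bid, day = st$day,
          species = c("CO2", "CH4"),
          amount12_mmol = obs_noise(c(co2_tot - co2_13,
                                      ch4_tot * (1 - f13_ch4))),
          amount13_mmol = obs_noise(c(co2_13, ch4_tot * f13_ch4)),
          true_amount13_mmol = c(co2_13, ch4_tot * f13_ch4),
          stringsAsFactors = FALSE)
      }
      record(st)
      copies_rows[[1L]] <- data.frame(bottle_id = bid, day = 0,
                                      clade = names(copies),
                                      true_copies_per_g = unname(copies),
                                      stringsAsFactors = FALSE)
      for (k in 2:length(sample_days)) {
        nstep <- round((sample_days[k] - sample_days[k - 1L]) / p$dt_days)
        for (s in seq_len(nstep)) st <- step_bottle(st, p)
        # growth: linear yield on newly oxidized methane
        new_ox <- st$cum_ox_mmol - last_ox
        copies <- copies + p$growth_yield * niche * new_ox
        last_ox <- st$cum_ox_mmol
        if (st$day == p$label$label_start_day && cond$methane_added)
          st$labeled <- TRUE
        # controller check at the sampling day
        gst <- geochem_state(st$day, st$sulfate_mM, st$sulfide_mM,
                             st$fes_mmol, V)
        acts <- required_amendments(gst, sp)
        if (nrow(acts)) {
          for (ai in seq_len(nrow(acts))) {
            gst <- apply_amendment(gst, acts$reagent[ai], acts$dose_mmol[ai])
          }
          amend_rows[[length(amend_rows) + 1L]] <-
            cbind(bottle_id = bid, day = st$day, acts,
                  stringsAsFactors = FALSE)
          st$sulfate_mM <- gst$sulfate_mM
          st$sulfide_mM <- gst$sulfide_mM
          st$fes_mmol <- gst$fes_mmol
        }
        record(st)
        if (st$day %in% qpcr_days)
          copies_rows[[length(copies_rows) + 1L]] <-
            data.frame(bottle_id = bid, day = st$day, clade = names(copies),
                       true_copies_per_g = unname(copies),
                       stringsAsFactors = FALSE)
      }
      geochem[[bottle_i]] <- do.call(rbind, states_rows)
      gas[[bottle_i]] <- do.call(rbind, gas_rows)
      if (length(amend_rows))
        amend[[length(amend) + 1L]] <- do.call(rbind, amend_rows)
      truth_copies[[bottle_i]] <- do.call(rbind, copies_rows)
      truth_states[[bottle_i]] <- data.frame(
        bottle_id = bid, condition_id = cond$id,
        final_sulfate_mM = st$sulfate_mM, final_sulfide_mM = st$sulfide_mM,
        final_co2_mM = st$co2_mM, final_ch4_acc_mM = st$ch4_acc_mM,
        fes_mmol = st$fes_mmol,
        cum_ox_mmol = st$cum_ox_mmol, co2_13_mmol = st$co2_13_mmol,
        cum_methanogenesis_mmol = st$cum_methanogenesis_mmol,
        stringsAsFactors = FALSE)
    }
  }
  geochem <- do.call(rbind, geochem)
  gas <- do.call(rbind, gas)
  amendments <- if (length(amend)) do.call(rbind, amend)
    else data.frame(bottle_id = character(0), day = numeric(0),
                    reagent = character(0), dose_mmol = numeric(0))
  truth_copies <- do.call(rbind, truth_copies)
  truth_states <- do.call(rbind, truth_states)
  rownames(geochem) <- rownames(gas) <- rownames(amendments) <-
    rownames(truth_copies) <- rownames(truth_states) <- NULL
  qpcr <- .make_qpcr_plates(truth_copies, p, true_slope, true_intercept)
  structure(list(
    conditions = conds, geochem = geochem, gas = gas,
    amendments = amendments, qpcr = qpcr,
    truth = list(states = truth_states, copies = truth_copies,
                 curve = list(slope = true_slope, intercept = true_intercept),
                 params = p),
    sample_days = sample_days),
    class = "aom_study")
}

# qPCR plate table: triplicate 10-fold standard series (2e5 .. 2e-2
# copies/ul) per clade plus day-0/day-344 samples whose Cq is derived from
# the true copies through the planted curve and the extraction chain.
.make_qpcr_plates <- function(truth_copies, p, slope, intercept) {
  set.seed(.sub_seed(p$seed, 500L))
  template_ng <- 5; extract_ng_per_ul <- 10; elution_ul <- 100
  sample_g_wet <- 2
  std_copies <- rep(2 * 10^(5:-2), each = 3)
  clades <- c("ANME1", "ANME2ab", "ANME2c")
  rows <- list()
  for (cl in clades) {
    cq_std <- intercept + slope * log10(std_copies) +
      stats::rnorm(length(std_copies), 0, p$cq_noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = paste0("std_", cl), target = cl, well_type = "standard",
      bottle_id = NA_character_, day = NA_real_,
      copies_per_ul = std_copies, cq = cq_std,
      template_ng = template_ng, sample_g_wet = NA_real_,
      extract_ng_per_ul = NA_real_, elution_ul = NA_real_,
      stringsAsFactors = FALSE)
  }
  tc <- truth_copies
  copies_rxn <- tc$true_copies_per_g * sample_g_wet /
    (extract_ng_per_ul * elution_ul) * template_ng
  cq <- intercept + slope * log10(copies_rxn) +
    stats::rnorm(nrow(tc), 0, p$cq_noise_sd)
  rows[[length(rows) + 1L]] <- data.frame(
    plate_id = "samples", target = tc$clade, well_type = "sample",
    bottle_id = tc$bottle_id, day = tc$day,
    copies_per_ul = NA_real_, cq = cq,
    template_ng = template_ng, sample_g_wet = sample_g_wet,
    extract_ng_per_ul = extract_ng_per_ul, elution_ul = elution_ul,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sulfur and carbon mass-balance residuals of a simulated study
#'
#' Sulfur: change in (dissolved sulfate + sulfide + FeS) minus sulfur added
#' by Na2SO4/FeSO4 amendments. Carbon: change in the (CO2 + accumulated
#' CH4) liquid pools minus the methane carbon imported by AOM from the
#' headspace. Both are zero up to floating-point accumulation in a closed
#' noiseless bottle. Residuals are computed from the ground-truth ledger, so
#' they are noise-free regardless of `noise_sd`.
#'
#' @param study An `aom_study`.
#' @return A data.frame with one row per bottle: `bottle_id`,
#'   `sulfur_residual_mmol`, `carbon_residual_mmol`.
#' @export
study_balances <- function(study) {
  p <- study$truth$params
  V <- p$bottle$liquid_volume_L
  conds <- study$conditions
  tr <- study$truth$states
  out <- lapply(seq_len(nrow(tr)), function(i) {
    row <- tr[i, ]
    cond <- conds[conds$id == row$condition_id, ]
    am <- study$amendments[study$amendments$bottle_id == row$bottle_id, ,
                           drop = FALSE]
    s_added <- if (nrow(am))
      sum(am$dose_mmol[am$reagent %in% c("Na2SO4", "FeSO4")]) else 0
    s_res <- (row$final_sulfate_mM + row$final_sulfide_mM) * V +
      row$fes_mmol -
      (cond$sulfate_mM + cond$sulfide_mM) * V - s_added
    c_res <- (row$final_co2_mM + row$final_ch4_acc_mM - cond$co2_mM) * V -
      row$cum_ox_mmol
    data.frame(bottle_id = row$bottle_id, sulfur_residual_mmol = s_res,
               carbon_residual_mmol = c_res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit Monod parameters to rate-versus-sulfate data
#'
#' Nonlinear least squares for `rate = vmax * s / (Km + s)`, started from a
#' Lineweaver-Burk linearization.
#'
#' @param sulfate_mM Sulfate concentrations, mM.
#' @param rate Observed rates at those concentrations.
#' @return A list with `vmax`, `km` and the underlying `nls` fit.
#' @export
fit_monod <- function(sulfate_mM, rate) {
  stopifnot(length(sulfate_mM) == length(rate), length(rate) >= 3L)
  ok <- sulfate_mM > 0 & rate > 0
  lb <- stats::lm(I(1 / rate[ok]) ~ I(1 / sulfate_mM[ok]))
  v0 <- 1 / stats::coef(lb)[1L]
  k0 <- stats::coef(lb)[2L] * v0
  if (!is.finite(v0) || v0 <= 0) v0 <- max(rate)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(sulfate_mM)
  # scaleOffset keeps the convergence test meaningful on near-exact data
  fit <- stats::nls(rate ~ vmax * sulfate_mM / (km + sulfate_mM),
                    start = list(vmax = unname(v0), km = unname(k0)),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  est <- stats::coef(fit)
  list(vmax = unname(est["vmax"]), km = unname(est["km"]), fit = fit)
}

#' @export
print.aom_study <- function(x, ...) {
  cat("Synthetic AOM incubation study\n")
  cat(sprintf("  %d conditions x 3 bottles, %d sampling days over %g days\n",
              nrow(x$conditions), length(x$sample_days),
              max(x$sample_days)))
  cat(sprintf("  %d geochemistry observations, %d gas observations, %d amendments\n",
              nrow(x$geochem), nrow(x$gas), nrow(x$amendments)))
  cat(sprintf("  qPCR plate: %d standard wells, %d sample wells\n",
              sum(x$qpcr$well_type == "standard"),
              sum(x$qpcr$well_type == "sample")))
  invisible(x)
}

#' @export
summary.aom_study <- function(object, ...) {
  tr <- object$truth$states
  out <- data.frame(bottle_id = tr$bottle_id,
                    condition_id = tr$condition_id,
                    cum_ox_mmol = tr$cum_ox_mmol,
                    fes_mmol = tr$fes_mmol,
                    ch4_accumulated_mM = tr$final_ch4_acc_mM)
  class(out) <- c("summary.aom_study", "data.frame")
  out
}

#' @export
print.summary.aom_study <- function(x, ...) {
  cat("Per-bottle ground truth (noiseless ledger):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Sawtooth plot of a simulated bottle's sulfate and sulfide
#'
#' @param x An `aom_study`.
#' @param bottle_id Which bottle to draw (default the first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aom_study <- function(x, bottle_id = x$geochem$bottle_id[1], ...) {
  b <- x$geochem[x$geochem$bottle_id == bottle_id, ]
  graphics::plot(b$day, b$sulfate_mM, type = "b", pch = 16,
                 xlab = "day", ylab = "concentration (mM)",
                 main = paste("bottle", bottle_id), ...)
  graphics::lines(b$day, b$sulfide_mM, type = "b", pch = 1, col = 2)
  graphics::legend("topright", c("sulfate", "sulfide"), pch = c(16, 1),
                   col = c(1, 2), bty = "n")
  invisible(x)
}

#' Write a synthetic study to a directory of CSV files
#'
#' Emits `geochem.csv`, `gas.csv`, `amendments.csv`, `qpcr.csv`,
#' `conditions.csv` in the dialects the analysis functions read, plus
#' `ground_truth.json`.
#'
#' @param study An `aom_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$geochem, file.path(dir, "geochem.csv"),
                   row.names = FALSE)
  utils::write.csv(study$gas[c("bottle_id", "day", "species",
                               "amount12_mmol", "amount13_mmol")],
                   file.path(dir, "gas.csv"), row.names = FALSE)
  utils::write.csv(study$amendments, file.path(dir, "amendments.csv"),
                   row.names = FALSE)
  utils::write.csv(study$qpcr, file.path(dir, "qpcr.csv"),
                   row.names = FALSE)
  write_conditions(study$conditions, file.path(dir, "conditions.csv"))
  jsonlite::write_json(
    list(states = study$truth$states, copies = study$truth$copies,
         curve = study$truth$curve),
    file.path(dir, "ground_truth.json"), dataframe = "columns",
    digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
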