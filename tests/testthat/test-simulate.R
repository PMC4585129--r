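test_that("the AOM rate law combines Monod kinetics with the energy gate", {
  p <- sim_params()
  # saturating sulfate with a wide-open gate approaches vmax
  r_sat <- aom_rate(1000, 0.4, 1.31, 3.8, p)
  expect_equal(r_sat, p$vmax_mM_per_day, tolerance = 2e-3)
  # half saturation
  r_half <- aom_rate(p$km_sulfate_mM, 0.05, 1.31, 1.0, p)
  expect_equal(r_half, p$vmax_mM_per_day / 2, tolerance = 1e-10)
  # gate closed at the low-sulfate/high-sulfide condition (~ -17.4)
  expect_identical(aom_rate(4.0, 3.6, 1.31, 6.4, p), 0)
  # no methane, no oxidation
  expect_identical(aom_rate(21.6, 0.4, 0, 3.2, p), 0)
  expect_identical(aom_rate(21.6, 0.4, NA, 3.2, p), 0)
})

test_that("stepping preserves 1:1 stoichiometry and leaves inert bottles flat", {
  p <- sim_params(vmax_mM_per_day = 0)
  st <- list(day = 0, sulfate_mM = 21.6, sulfide_mM = 0.4, co2_mM = 3.8,
             methane_mM = 1.31, ch4_acc_mM = 0, fes_mmol = 0,
             cum_ox_mmol = 0, co2_13_mmol = 0,
             cum_methanogenesis_mmol = 0, labeled = FALSE,
             methanogenesis_mM_per_day = 0)
  st2 <- st
  for (i in 1:100) st2 <- aombatch:::step_bottle(st2, p)
  expect_equal(st2$sulfate_mM, st$sulfate_mM)
  expect_equal(st2$sulfide_mM, st$sulfide_mM)
  expect_equal(st2$cum_ox_mmol, 0)
  # active bottle: sulfate consumed equals sulfide produced equals CO2 made
  pa <- sim_params()
  st3 <- st
  for (i in 1:100) st3 <- aombatch:::step_bottle(st3, pa)
  d_so4 <- st$sulfate_mM - st3$sulfate_mM
  expect_gt(d_so4, 0)
  expect_equal(st3$sulfide_mM - st$sulfide_mM, d_so4)
  expect_equal(st3$co2_mM - st$co2_mM, d_so4)
  expect_equal(st3$cum_ox_mmol, d_so4 * pa$bottle$liquid_volume_L)
})

test_that("identical seeds give bit-identical studies; different seeds differ", {
  p <- sim_params(seed = 123, n_days = 200)
  s1 <- generate_study(p)
  s2 <- generate_study(p)
  expect_identical(s1, s2)
  s3 <- generate_study(sim_params(seed = 124, n_days = 200))
  expect_false(identical(s1$geochem, s3$geochem))
})

test_that("zero noise makes observations equal ground truth", {
  s <- generate_study(sim_params(seed = 6, noise_sd = 0, n_days = 300))
  expect_equal(s$geochem$sulfate_mM, s$geochem$true_sulfate_mM)
  expect_equal(s$geochem$sulfide_mM, s$geochem$true_sulfide_mM)
  expect_equal(s$gas$amount13_mmol, s$gas$true_amount13_mmol)
})

test_that("the sulfide-only condition accumulates methane monotonically", {
  s <- generate_study(sim_params(seed = 10, noise_sd = 0))
  g7 <- s$geochem[s$geochem$condition_id == "7: highS", ]
  for (bid in unique(g7$bottle_id)) {
    ch4 <- g7$ch4_mM[g7$bottle_id == bid]
    expect_true(all(diff(ch4) >= 0))
    expect_gt(ch4[length(ch4)], 0.3)
  }
  # methane-oxidizing bottles do not accumulate methane
  g1 <- s$geochem[s$geochem$condition_id == "1: CH4 highSO4", ]
  expect_equal(unique(g1$ch4_mM), 1.31)
})

test_that("tracer round trip recovers the ledger's cumulative oxidation", {
  p <- sim_params(seed = 12, noise_sd = 0.05)
  s <- generate_study(p)
  tr <- s$truth$states
  b1 <- tr[tr$condition_id == "1: CH4 highSO4", ]
  for (i in seq_len(nrow(b1))) {
    gas <- s$gas[s$gas$bottle_id == b1$bottle_id[i] &
                   s$gas$species == "CO2", ]
    gas <- gas[order(gas$day), ]
    d13 <- gas$amount13_mmol[nrow(gas)] -
      gas$amount13_mmol[gas$day == p$label$label_start_day]
    est <- methane_oxidized(d13, p$label$f13_ch4)
    # truth: oxidation between label start and the end of the run
    true_ox <- b1$co2_13_mmol[i] / p$label$f13_ch4
    # tolerance: 3 x relative noise on the amounts involved
    expect_equal(est, true_ox, tolerance = 3 * p$noise_sd +
                   0.011 / p$label$f13_ch4)
  }
})

test_that("Monod parameters are recoverable from rate-vs-sulfate data", {
  p <- sim_params()
  grid <- rep(c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 20, 25), each = 3)
  rate <- vapply(grid, function(s) aom_rate(s, 0.05, 1.31, 1.0, p), 1)
  f <- fit_monod(grid, rate)
  expect_equal(f$vmax, p$vmax_mM_per_day, tolerance = 1e-6)
  expect_equal(f$km, p$km_sulfate_mM, tolerance = 1e-6)
})

test_that("study files round-trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  s <- generate_study(sim_params(seed = 2, n_days = 120))
  write_study(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("geochem.csv", "gas.csv", "amendments.csv", "qpcr.csv",
      "conditions.csv", "ground_truth.json")))))
  gas <- read_gas_series(file.path(dir, "gas.csv"))
  expect_equal(nrow(gas), nrow(s$gas))
  conds <- read_conditions(file.path(dir, "conditions.csv"))
  expect_equal(conds$id, s$conditions$id)
})
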