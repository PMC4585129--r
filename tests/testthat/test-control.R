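test_that("amendment doses follow the 1:1 FeS stoichiometry", {
  sp <- setpoints(sulfide_target_mM = 4.0, sulfide_max_mM = 4.5,
                  sulfate_target_mM = 21.6, sulfate_min_mM = 19)
  # sulfide 6.0 mM over a 4.0 target in 0.120 L -> 0.24 mmol FeCl2
  st <- geochem_state(day = 10, sulfate_mM = 21, sulfide_mM = 6.0)
  a <- required_amendments(st, sp)
  expect_identical(a$reagent, "FeCl2")
  expect_equal(a$dose_mmol, 0.24)
  # both in range: nothing to do (and the controller is idempotent there)
  ok <- geochem_state(day = 10, sulfate_mM = 21, sulfide_mM = 4.2)
  expect_identical(nrow(required_amendments(ok, sp)), 0L)
})

test_that("dual deficiency uses FeSO4 for the shared part then tops up", {
  # excess sulfide 0.24 mmol and sulfate deficit 0.36 mmol
  sp <- setpoints(4.0, 4.5, 21.0, 19)
  st <- geochem_state(day = 0, sulfate_mM = 18.0, sulfide_mM = 6.0)
  a <- required_amendments(st, sp)
  expect_identical(a$reagent, c("FeSO4", "Na2SO4"))
  expect_equal(a$dose_mmol, c(0.24, 0.12))
  # mirrored case: deficit smaller than excess tops up with FeCl2
  sp2 <- setpoints(4.0, 4.5, 21.0, 19)
  st2 <- geochem_state(day = 0, sulfate_mM = 18.9, sulfide_mM = 9.0)
  a2 <- required_amendments(st2, sp2)
  expect_identical(a2$reagent, c("FeSO4", "FeCl2"))
  expect_equal(a2$dose_mmol, c((21.0 - 18.9) * 0.120,
                               (9.0 - 4.0) * 0.120 - (21.0 - 18.9) * 0.120))
})

test_that("applying amendments updates pools per reagent semantics", {
  st <- geochem_state(day = 0, sulfate_mM = 2.0, sulfide_mM = 6.0)
  fe <- apply_amendment(st, "FeCl2", 0.24)
  expect_equal(fe$sulfide_mM, 4.0)
  expect_equal(fe$fes_mmol, 0.24)
  expect_equal(fe$sulfate_mM, 2.0)
  zero <- apply_amendment(st, "Na2SO4", 0)
  expect_equal(zero, st)
  both <- apply_amendment(st, "FeSO4", 0.24)
  expect_equal(both$sulfide_mM, 4.0)
  expect_equal(both$sulfate_mM, 4.0)
  expect_equal(both$fes_mmol, 0.24)
  # FeCl2 overdose floors sulfide at zero, precipitating only what exists
  over <- apply_amendment(st, "FeCl2", 5)
  expect_equal(over$sulfide_mM, 0)
  expect_equal(over$fes_mmol, 6.0 * 0.120)
})

test_that("one controller step restores both setpoints in the noiseless case", {
  set.seed(21)
  for (i in 1:50) {
    s_t <- runif(1, 0.1, 4); so4_t <- runif(1, 4, 22)
    sp <- setpoints(sulfide_target_mM = s_t,
                    sulfide_max_mM = s_t + runif(1, 0.1, 1),
                    sulfate_target_mM = so4_t,
                    sulfate_min_mM = max(0, so4_t - runif(1, 0.5, 3)))
    st <- geochem_state(day = 0, sulfate_mM = runif(1, 0, 25),
                        sulfide_mM = runif(1, 0, 8))
    a <- required_amendments(st, sp)
    if (nrow(a)) for (k in seq_len(nrow(a)))
      st <- apply_amendment(st, a$reagent[k], a$dose_mmol[k])
    expect_lte(st$sulfide_mM, sp$sulfide_max_mM + 1e-12)
    expect_gte(st$sulfate_mM, sp$sulfate_min_mM - 1e-12)
    # idempotent on the corrected state
    expect_identical(nrow(required_amendments(st, sp)), 0L)
  }
})

test_that("sulfur balance closes over amended histories", {
  expect_identical(sulfur_balance(data.frame()[0, ]), 0)
  # one Na2SO4 addition, fully accounted
  V <- 0.120
  states <- data.frame(day = c(0, 50),
                       sulfate_mM = c(10, 13), sulfide_mM = c(1, 1),
                       fes_mmol = c(0, 0), liquid_volume_L = V)
  amendments <- data.frame(day = 50, reagent = "Na2SO4",
                           dose_mmol = 3 * V)
  expect_equal(sulfur_balance(states, amendments), 0)
  # unaccounted addition shows up as a residual
  expect_equal(sulfur_balance(states, NULL), 3 * V)
  bad <- states[c(2, 1), ]
  expect_error(sulfur_balance(bad), "chronological")
})

test_that("total sulfur changes only through sulfate-bearing amendments", {
  study <- generate_study(sim_params(seed = 9, noise_sd = 0, n_days = 400))
  for (bid in unique(study$geochem$bottle_id)) {
    states <- study$geochem[study$geochem$bottle_id == bid, ]
    am <- study$amendments[study$amendments$bottle_id == bid, ]
    expect_lt(abs(sulfur_balance(states, am)), 1e-9)
  }
})
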