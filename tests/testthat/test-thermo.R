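test_that("reaction quotient matches hand arithmetic and is scale invariant", {
  expect_equal(reaction_quotient(list(sulfate_mM = 1, sulfide_mM = 1,
                                      methane_mM = 1, co2_mM = 1)), 1.0)
  # (3.8 * 0.4) / (1.31 * 21.6) and (6.9 * 3.8) / (1.31 * 21.1)
  expect_equal(reaction_quotient(list(sulfate_mM = 21.6, sulfide_mM = 0.4,
                                      methane_mM = 1.31, co2_mM = 3.8)),
               0.0537178, tolerance = 1e-6)
  expect_equal(reaction_quotient(list(sulfate_mM = 21.1, sulfide_mM = 3.8,
                                      methane_mM = 1.31, co2_mM = 6.9)),
               0.948591, tolerance = 1e-6)
  for (k in c(0.1, 3, 1000)) {
    base <- list(sulfate_mM = 4, sulfide_mM = 0.3, methane_mM = 1.31,
                 co2_mM = 6)
    scaled <- lapply(base, `*`, k)
    expect_equal(reaction_quotient(scaled), reaction_quotient(base))
  }
})

test_that("undefined quotients name the offending species", {
  expect_error(reaction_quotient(list(sulfate_mM = 1, sulfide_mM = 1,
                                      methane_mM = 0, co2_mM = 1)),
               "methane")
  expect_error(reaction_quotient(list(sulfate_mM = 0, sulfide_mM = 1,
                                      methane_mM = 1, co2_mM = 1)),
               "sulfate")
})

test_that("delta_g_prime equals dG0' at Q = 1 and is vectorized over rows", {
  even <- list(sulfate_mM = 2, sulfide_mM = 2, methane_mM = 2, co2_mM = 2)
  expect_identical(delta_g_prime(even), -21)
  conds <- incubation_conditions()
  dg <- delta_g_prime(conds[conds$methane_added, ])
  expect_length(dg, 5L)
})

test_that("dG' is monotone in each concentration in the expected direction", {
  set.seed(11)
  for (i in 1:200) {
    base <- list(sulfate_mM = runif(1, 0.1, 25), sulfide_mM = runif(1, 0.1, 5),
                 methane_mM = runif(1, 0.1, 2), co2_mM = runif(1, 0.5, 10))
    dg0 <- delta_g_prime(base)
    up <- function(field) {
      b <- base; b[[field]] <- b[[field]] * 1.5; delta_g_prime(b)
    }
    expect_lt(up("sulfate_mM"), dg0)   # reactants: more -> more negative
    expect_lt(up("methane_mM"), dg0)
    expect_gt(up("sulfide_mM"), dg0)   # products: more -> less negative
    expect_gt(up("co2_mM"), dg0)
  }
})

test_that("regime classification respects thresholds, ties, and monotonicity", {
  expect_identical(classify_energetic_regime(-28.1), "growth_permissive")
  expect_identical(classify_energetic_regime(-17.4), "maintenance_only")
  expect_identical(classify_energetic_regime(-19.0), "growth_permissive")
  expect_identical(classify_energetic_regime(-10.6), "maintenance_only")
  expect_identical(classify_energetic_regime(-5), "below_quantum")
  # more negative energy is never classified as less permissive
  rank <- c(growth_permissive = 1, maintenance_only = 2, below_quantum = 3)
  dg <- sort(runif(50, -40, 0))
  r <- rank[classify_energetic_regime(dg)]
  expect_true(all(diff(r) >= 0))
  expect_error(classify_energetic_regime(NaN), "finite")
})

test_that("dissolved methane honors the overpressure assumption", {
  expect_equal(dissolved_methane(solubility_params(), 1.8), 1.31)
  expect_equal(dissolved_methane(solubility_params(), 1.0), 1.31)
  henry <- solubility_params(neglect_overpressure = FALSE)
  expect_equal(dissolved_methane(henry, 2.0), 2.62)
  expect_error(dissolved_methane(solubility_params(), -0.1), "pressure")
})

test_that("energetics table blanks non-methane conditions and flags bad rows", {
  et <- energetics_table(incubation_conditions())
  expect_identical(et$delta_g_label[!et$methane_added], c("—", "—"))
  expect_true(all(is.na(et$delta_g_kj[!et$methane_added])))
  expect_identical(et$regime[1], "growth_permissive")
  expect_identical(et$regime[4], "maintenance_only")
  # degenerate: methane flagged as added but zero concentration
  bad <- incubation_condition("x", 5, 0.5, 0, 3, methane_added = TRUE)
  eb <- energetics_table(bad)
  expect_match(eb$regime, "error")
  expect_true(is.na(eb$delta_g_kj))
  # empty table round-trips
  empty <- incubation_conditions()[0, ]
  expect_identical(nrow(energetics_table(empty)), 0L)
})

test_that("condition tables round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  conds <- incubation_conditions()
  write_conditions(conds, f)
  back <- read_conditions(f)
  expect_equal(back, conds)
  expect_error(read_conditions(textConnection("id,foo\n1,2")), "missing")
})
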