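test_that("solve_flux handles the trivial and ideal-membrane limits", {
  mem <- default_membrane()
  # zero driving force
  expect_equal(as.numeric(solve_flux(10, 10, 0, mem)), 0)
  # pressure exceeding the effective osmotic difference: exhausted flag
  J <- solve_flux(10, 8, 5, mem)
  expect_equal(as.numeric(J), 0)
  expect_true(isTRUE(attr(J, "exhausted")))
  # ideal membrane (B = 0, no support layer, huge k): J = A (dpi - P)
  ideal <- pro_membrane(A = 1.2e-7, B = 0, S_struct = 0, k = 1e3)
  expect_equal(solve_flux(36.2, 2.4, 16.9, ideal), 1.2e-7 * 16.9,
               tolerance = 1e-6)
  expect_error(solve_flux(NaN, 0, 0, mem), "non-finite")
  expect_error(solve_flux(5, 10, 0, mem), "pi_D >= pi_F")
})

test_that("solve_flux agrees with the dense grid-scan oracle on random draws", {
  cases <- draw_flux_cases(100)
  for (cs in cases) {
    J_pkg <- as.numeric(solve_flux(cs$pi_D, cs$pi_F, cs$P, cs$mem))
    J_orc <- oracle_grid_flux(cs$pi_D, cs$pi_F, cs$P, cs$mem)
    expect_lt(abs(J_pkg - J_orc), 1e-4 * max(J_orc, 1e-12))
  }
})

test_that("flux is non-increasing in applied pressure at fixed osmotic state", {
  mem <- default_membrane()
  P <- seq(0, 40, by = 2.5)
  J <- vapply(P, function(p) as.numeric(solve_flux(39.7, 1.9, p, mem)),
              numeric(1))
  expect_true(all(diff(J) <= 1e-15))
  expect_equal(J[length(J)], 0)   # beyond the effective osmotic difference
})

test_that("reverse salt flux follows B J / (A i R T) and is linear in J", {
  mem <- default_membrane()
  cc <- phys_constants()
  J <- 2e-6
  expect_equal(reverse_salt_flux(J, mem),
               mem$B * J / (mem$A * 2 * 8.3145e-5 * 298.15),
               tolerance = 1e-12)
  expect_identical(reverse_salt_flux(0, mem), 0)
  expect_equal(reverse_salt_flux(2 * J, mem), 2 * reverse_salt_flux(J, mem),
               tolerance = 1e-12)
  ideal <- pro_membrane(A = 1e-7, B = 0, S_struct = 0)
  expect_identical(reverse_salt_flux(5e-6, ideal), 0)
})

test_that("pressure policies implement the maximum-power schedule", {
  half <- pressure_policy("half_delta_pi")
  expect_equal(applied_pressure(half, 36.2, 2.4), 16.9)
  expect_equal(applied_pressure(half, 10, 10), 0)
  rev <- applied_pressure(half, 5, 10)
  expect_equal(as.numeric(rev), 0)
  expect_true(isTRUE(attr(rev, "reversed")))
  const <- pressure_policy("constant", P_const = 1)
  expect_equal(applied_pressure(const, 36.2, 2.4), 1)
  expect_equal(applied_pressure(const, 80, 2), 1)
  expect_error(pressure_policy("constant", P_const = -1))
})

test_that("batch PRO conserves volume, salt and substrate at every step", {
  run <- simulate_pro(dt_s = 120)
  tr <- run$trajectory
  expect_equal(tr$V_F_L + tr$V_D_L, rep(1.2, nrow(tr)), tolerance = 1e-9)
  # salt: reconstruct amounts from recorded pressures (pi = iRT C, phi = 1)
  iRT <- 2 * 0.083145 * 298.15
  n_tot <- tr$pi_F_bar / iRT * tr$V_F_L + tr$pi_D_bar / iRT * tr$V_D_L
  expect_equal(n_tot, rep(n_tot[1], nrow(tr)), tolerance = 1e-9)
  # substrate: conserved mass, exact concentration identity in the effluent
  eff <- effluent_summary(run)
  expect_equal(eff$feed$substrate_mg_L * eff$feed$volume_mL,
               600 * 193, tolerance = 1e-9)
  # cumulative energy never decreases; time strictly increasing
  expect_true(all(diff(tr$Q_J) >= 0))
  expect_true(all(diff(tr$t_s) > 0))
  expect_equal(run$summary$stop_reason, "flux_below_threshold")
  expect_lt(tr$J_LMH[nrow(tr)], 0.5)
})

test_that("a feed matched to the draw gives a single zero-flux state", {
  # draw molarity equal to the feed equivalent molarity: no driving force
  C_eq <- conductivity_to_molarity(18.3 * 115 / 600)
  run <- simulate_pro(draw_molarity_M = C_eq)
  expect_equal(nrow(run$trajectory), 1L)
  expect_equal(run$summary$Q_PRO_J, 0)
  expect_equal(run$summary$water_recovered_mL, 0)
  eff <- effluent_summary(run)
  expect_equal(eff$feed$substrate_mg_L, 193, tolerance = 1e-12)
  expect_equal(eff$concentration_factor, 1, tolerance = 1e-12)
})

test_that("zero applied pressure harvests zero energy", {
  run <- simulate_pro(policy = pressure_policy("constant", P_const = 0),
                      t_max_h = 2)
  expect_equal(run$summary$Q_PRO_J, 0)
  expect_gt(run$summary$water_recovered_mL, 0)   # still an osmotic flow
})

test_that("halving the time step moves the endpoint by under 0.1%", {
  a <- simulate_pro(dt_s = 60)$summary
  b <- simulate_pro(dt_s = 30)$summary
  expect_lt(abs(a$V_F_end_mL - b$V_F_end_mL) / b$V_F_end_mL, 1e-3)
  expect_lt(abs(a$Q_PRO_J - b$Q_PRO_J) / b$Q_PRO_J, 1e-3)
})

test_that("the feed-side effluent concentrates conductivity by the volume ratio", {
  run <- simulate_pro()
  eff <- effluent_summary(run)
  cf <- 600 / run$summary$V_F_end_mL
  expect_equal(eff$concentration_factor, cf, tolerance = 1e-12)
  expect_equal(eff$feed$conductivity_mS_cm, 18.3 * 115 / 600 * cf,
               tolerance = 1e-12)
  # draw molarity from the salt balance over the diluted volume
  expect_equal(eff$draw$molarity_M,
               run$summary$n_D_end_mol / (run$summary$V_D_end_mL / 1000),
               tolerance = 1e-12)
})
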