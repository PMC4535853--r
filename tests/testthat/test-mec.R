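test_that("electrode potentials match closed-form Nernst values", {
  p <- mec_params()
  cc <- phys_constants()
  RT_F <- 8.3145 * 298.15 / 96485
  # cathode at pH 11: -(RT/2F) ln(10^22) = -0.6508 V
  expect_equal(cathode_potential(p), -RT_F / 2 * log(10^22),
               tolerance = 1e-12)
  expect_equal(cathode_potential(p), -0.651, tolerance = 1e-3)
  expect_equal(cathode_potential(mec_params(cathode_pH = 7)),
               -RT_F / 2 * log(10^14), tolerance = 1e-12)
  # anode: reaction quotient of one gives the standard potential
  S_unit <- 82 * 1000 * (6.24e-4)^2 * (1e-7)^9   # S_molar = HCO3^2 H^9
  expect_equal(anode_potential(S_unit, 6.24e-4, 1e-7, p), 0.187,
               tolerance = 1e-12)
  # reference anolyte state, frozen from the closed form:
  # 0.187 - (RT/8F) ln(0.012280 / (6.24e-4^2 * 1e-63)) = -0.31215 V
  expect_equal(anode_potential(1007, 6.24e-4, 1e-7, p), -0.31215,
               tolerance = 1e-4)
  # more protons -> higher (less negative) anode potential
  EA <- vapply(c(1e-8, 1e-7, 1e-6), function(h)
    anode_potential(1007, 6.24e-4, h, p), numeric(1))
  expect_true(all(diff(EA) > 0))
  expect_error(anode_potential(0, 1e-3, 1e-7, p), "positive")
})

test_that("concentration overpotential follows the mediator/substrate logs", {
  p <- mec_params()
  RT_F <- 8.3145 * 298.15 / 96485
  expect_equal(concentration_overpotential(0, 1007, 1007, p), 0)
  expect_equal(concentration_overpotential(p$M_Total / 2, 1007, 1007, p),
               RT_F * log(2), tolerance = 1e-12)
  expect_equal(concentration_overpotential(0, 100.7, 1007, p),
               RT_F * log(10), tolerance = 1e-12)
  expect_identical(concentration_overpotential(p$M_Total, 500, 1007, p), Inf)
  expect_identical(concentration_overpotential(0.01, 0, 1007, p), Inf)
})

test_that("internal resistance interpolates between its bounds", {
  p <- mec_params(R_min = 10, R_max = 200, K_R = 0.05)
  expect_equal(internal_resistance(0, p), 200)
  expect_equal(internal_resistance(1e6, p), 10)
  x <- seq(0, 300, by = 10)
  R <- internal_resistance(x, p)
  expect_true(all(diff(R) < 0))
  expect_true(all(R >= 10 & R <= 200))
})

test_that("current is floored at zero and throttled by the mediator pool", {
  p <- mec_params()
  # fully oxidised pool carries no current
  expect_equal(mec_current(1007, p$M_Total, 100, 6.24e-4, 1e-7, 1007, p), 0)
  # voltage below the thermodynamic deficit: no current
  p_low <- mec_params(E_ext = 0.05)
  expect_equal(mec_current(1007, 0.02, 100, 6.24e-4, 1e-7, 1007, p_low), 0)
  # nominal feasibility state at 0.8 V: a few mA
  I <- mec_current(1007, 0.02, 100, 6.24e-4, 1e-7, 1007, p)
  expect_gt(I * 1000, 2)
  expect_lt(I * 1000, 8)
})

test_that("energy and hydrogen are exact functions of the charge", {
  run <- simulate_mec(mec_params(), stop = list(t_max_h = 60))
  tr <- run$trajectory
  cc <- phys_constants()
  expect_equal(tr$Q_J, 0.8 * tr$charge_C, tolerance = 1e-12)
  expect_equal(tr$V_H2_mL,
               0.475 * tr$charge_C / (2 * cc$F_C) * cc$molar_volume_L * 1000,
               tolerance = 1e-12)
  # 587.5 C at 100% cathodic efficiency: 587.5/(2 x 96485) mol x 24465 mL/mol
  v587 <- 587.5 / (2 * 96485) * cc$molar_volume_L * 1000
  expect_equal(v587, 74.5, tolerance = 1e-3)
  # charge, energy, hydrogen never decrease; substrate never increases
  expect_true(all(diff(tr$charge_C) >= 0))
  expect_true(all(diff(tr$S_mg_L) <= 1e-9))
  # mediator fraction and internal resistance stay inside their bounds
  expect_true(all(tr$M_OX >= -1e-9 & tr$M_OX <= 0.05 + 1e-9))
  expect_true(all(tr$R_in_ohm >= 85 - 1e-9 & tr$R_in_ohm <= 140 + 1e-9))
})

test_that("the current-free single-population limit matches an RK4 oracle", {
  # methanogens alone, no external voltage: pure Monod depletion with growth
  p <- mec_params(x_e_0 = 0, x_m_0 = 40, mu_m_max = 0.9, d_m = 0.05,
                  E_ext = 0, beta = 0)
  run <- simulate_mec(p, stop = list(removal_fraction = 0.9999,
                                     t_max_h = 36))
  tr <- run$trajectory
  expect_equal(max(tr$I_mA), 0)
  t_end_d <- tr$t_h[nrow(tr)] / 24
  ref <- oracle_monod_rk4(S0 = 1007, x0 = 40, q = 8.2, K = 80,
                          mu = 0.9, d = 0.05, t_end_d = t_end_d)
  expect_equal(tr$S_mg_L[nrow(tr)], ref[1], tolerance = 1e-6)
  expect_equal(tr$x_m_mg_L[nrow(tr)], ref[2], tolerance = 1e-6)
})

test_that("degenerate starts leave the substrate untouched", {
  p0 <- mec_params(x_e_0 = 0, x_m_0 = 0)
  run <- simulate_mec(p0, stop = list(t_max_h = 12))
  expect_equal(run$trajectory$S_mg_L[nrow(run$trajectory)], 1007,
               tolerance = 1e-6)
  expect_equal(run$summary$stop_reason, "t_max")
  # zero energy budget: immediate stop, nothing produced
  run0 <- simulate_mec(mec_params(), stop = list(energy_budget_J = 0))
  expect_equal(run0$summary$V_H2_mL, 0)
  expect_equal(run0$summary$removal_pct, 0)
  expect_equal(run0$summary$stop_reason, "energy_budget")
})

test_that("stop criteria fire in the right order", {
  p <- mec_params()
  full <- simulate_mec(p)
  expect_equal(full$summary$stop_reason, "substrate_removed")
  expect_equal(full$summary$removal_pct, 99.9, tolerance = 1e-4)
  capped <- simulate_mec(p, stop = list(energy_budget_J = 200))
  expect_equal(capped$summary$stop_reason, "energy_budget")
  expect_equal(capped$summary$Q_MEC_J, 200, tolerance = 1e-3)
  expect_lt(capped$summary$removal_pct, full$summary$removal_pct)
  short <- simulate_mec(p, stop = list(t_max_h = 5))
  expect_equal(short$summary$stop_reason, "t_max")
  expect_equal(short$summary$hrt_h, 5, tolerance = 1e-6)
})

test_that("refining the output grid leaves the terminal charge unchanged", {
  a <- simulate_mec(mec_params(), dt_out_h = 0.2)$summary
  b <- simulate_mec(mec_params(), dt_out_h = 0.1)$summary
  expect_lt(abs(a$charge_C - b$charge_C) / b$charge_C, 1e-3)
})

test_that("performance metrics recompute the efficiency definitions", {
  run <- simulate_mec(mec_params())
  met <- performance_metrics(run)
  cc <- phys_constants()
  # Coulombic efficiency: charge over 8F per mole of removed acetate
  dS_mol <- (1007 - run$trajectory$S_mg_L[nrow(run$trajectory)]) *
    0.115 / 82000
  expect_equal(met$coulombic_efficiency_pct,
               100 * run$summary$charge_C / (8 * cc$F_C * dS_mol),
               tolerance = 1e-9)
  # cathodic efficiency is the Y_H2 parameter, by construction
  expect_equal(met$cathodic_efficiency_pct, 47.5, tolerance = 1e-6)
  # volumetric rate: the reference 32.8 mL over 1.085 L and 46.9 h is
  # 0.0155 m3 m-3 d-1
  expect_equal((32.8e-6) / (1.085e-3 * 46.9 / 24), 0.0155,
               tolerance = 2e-3)
  expect_gt(met$H2_rate_m3_m3_d, 0.01)
  expect_lt(met$H2_rate_m3_m3_d, 0.03)
})
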