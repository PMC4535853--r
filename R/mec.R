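#' Kinetic and electrochemical parameters of the batch MEC model
#'
#' Bundles everything a batch two-chamber MEC run needs: Monod kinetics of
#' the two anode populations (exoelectrogens feeding electrons into an
#' intracellular mediator pool, acetoclastic methanogens consuming acetate
#' without current), the mediator pool constants, Nernst potential inputs,
#' the internal-resistance law, the external circuit, electrolyte volumes and
#' initial state. Defaults are the calibrated reference set (see
#' [default_mec_params()] for provenance); every field can be overridden.
#'
#' Rates are per day, concentrations mg/L, mediator fractions mg-M per mg of
#' exoelectrogen biomass, volumes L, potentials V, resistances ohm.
#'
#' @param q_e_max,q_m_max Maximum specific substrate consumption rates of
#'   exoelectrogens / methanogens, mg-S mg-x-1 d-1.
#' @param mu_e_max,mu_m_max Maximum growth rates, d-1.
#' @param d_e,d_m Decay rates, d-1.
#' @param K_e,K_m Substrate half-saturations, mg-S L-1.
#' @param K_M Mediator half-saturation, mg-M mg-x-1.
#' @param Y_M Mediator yield, mg-M per mg-S oxidised by exoelectrogens.
#' @param gamma Mediator molar mass, mg-M mol-1.
#' @param M_Total Total mediator fraction per exoelectrogen, mg-M mg-x-1.
#' @param n_e Electrons transferred per mediator molecule.
#' @param eps Mediator saturation constant in the current expression,
#'   mg-M mg-x-1.
#' @param E_A0 Standard anode (HCO3-/acetate) reduction potential, V.
#' @param E_C0 Standard cathode (H+/H2) reduction potential, V.
#' @param cathode_pH Fixed catholyte pH (no buffer; stabilises near 11).
#' @param HCO3_0 Bicarbonate concentration in the PRO feed influent, M.
#' @param m_S Substrate (acetate) molar mass, g mol-1.
#' @param beta Buffer efficiency of the anolyte, percent; a *signed*
#'   calibration parameter of the proton balance. The calibrated default is
#'   negative (-0.003): acetate oxidation releases protons faster than the
#'   phosphate buffer absorbs them, so the anolyte acidifies slowly as
#'   substrate is consumed, raising the anode potential and choking the
#'   current at low applied voltage. Set 0 for a perfectly buffered anolyte.
#' @param CE_param Coulombic efficiency used in the proton balance, percent.
#' @param Y_H2 Cathodic efficiency: fraction of circuit charge recovered as
#'   H2, percent.
#' @param E_ext External applied voltage, V.
#' @param R_ext External (measurement) resistance, ohm.
#' @param R_min,R_max Internal-resistance bounds, ohm.
#' @param K_R Internal-resistance steepness, L mg-x-1.
#' @param V_a,V_c Anolyte and catholyte volumes, L.
#' @param conc_factor PRO concentration factor V_F,0/V_F,end applied to the
#'   influent bicarbonate (and reported conductivity).
#' @param S_0 Initial anolyte substrate, mg L-1.
#' @param x_e_0,x_m_0 Initial biomass concentrations, mg-x L-1.
#' @param M_OX_0 Initial oxidised mediator fraction, mg-M mg-x-1.
#' @param pH_anolyte Initial anolyte pH (sets the proton state).
#' @return A list of class `mec_params`.
#' @export
mec_params <- function(q_e_max = 8.48, q_m_max = 8.2,
                       mu_e_max = 0.15, mu_m_max = 0.9,
                       d_e = 0.04, d_m = 0.01,
                       K_e = 20, K_m = 80, K_M = 0.01,
                       Y_M = 22.75, gamma = 663400, M_Total = 0.05,
                       n_e = 2, eps = 1e-4,
                       E_A0 = 0.187, E_C0 = 0, cathode_pH = 11,
                       HCO3_0 = 0.00012, m_S = 82,
                       beta = -0.003, CE_param = 57.5, Y_H2 = 47.5,
                       E_ext = 0.8, R_ext = 1,
                       R_min = 85, R_max = 140, K_R = 0.024,
                       V_a = 0.115, V_c = 1.085, conc_factor = 600 / 115,
                       S_0 = 1007, x_e_0 = 100, x_m_0 = 10,
                       M_OX_0 = 0.05, pH_anolyte = 7) {
  p <- as.list(environment())
  pos <- c("q_e_max", "q_m_max", "mu_e_max", "mu_m_max", "K_e", "K_m",
           "K_M", "Y_M", "gamma", "M_Total", "n_e", "eps", "R_min", "R_max",
           "K_R", "V_a", "V_c", "conc_factor", "m_S", "S_0")
  vals <- unlist(p[pos])
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("kinetic/electrochemical parameters must be finite and positive")
  stopifnot(p$x_e_0 >= 0, p$x_m_0 >= 0,
            p$d_e >= 0, p$d_m >= 0, p$R_min <= p$R_max,
            p$CE_param >= 0, p$CE_param <= 100,
            p$Y_H2 >= 0, p$Y_H2 <= 100,
            p$M_OX_0 >= 0, p$M_OX_0 <= p$M_Total,
            p$E_ext >= 0, p$R_ext >= 0, p$HCO3_0 > 0)
  class(p) <- "mec_params"
  p
}

#' Calibrated default MEC parameter set
#'
#' Alias of [mec_params()] with no overrides. The stoichiometric and mediator
#' constants (M_Total, gamma, n_e, Y_M, K_e, K_m, q_max values) follow the
#' two-population mediator-pool model lineage this model extends; the
#' remaining free parameters (initial biomasses, methanogen growth,
#' internal-resistance law) were calibrated against the reference bench MEC:
#' current levels of ~2.7 mA at 0.6 V, ~4.5 mA at 0.8 V and ~6.6 mA at
#' 1.0 V, the 0.8 V reference outputs (488 J consumed and 99.9% removal of
#' 1007 mg/L acetate in 115 mL of anolyte), and the batch durations of
#' roughly 69/47/31 h at 0.5/0.8/1.0 V.
#'
#' @return A `mec_params` object.
#' @export
default_mec_params <- function() mec_params()

#' Anode Nernst potential
#'
#' E_A = E_A0 - (RT/8F) ln( S / ([HCO3-]^2 [H+]^9) ) with the substrate
#' concentration converted to mol/L. All activities are approximated by
#' molar concentrations.
#'
#' @param S Substrate concentration, mg L-1 (> 0).
#' @param HCO3 Anolyte bicarbonate, mol L-1 (> 0).
#' @param Hplus Anolyte proton concentration, mol L-1 (> 0).
#' @param p A [mec_params()].
#' @param consts A [phys_constants()] list.
#' @return Potential in V.
#' @export
anode_potential <- function(S, HCO3, Hplus, p = mec_params(),
                            consts = phys_constants()) {
  if (!all(is.finite(c(S, HCO3, Hplus))) || any(c(S, HCO3, Hplus) <= 0))
    stop("anode potential needs strictly positive S, HCO3 and H+")
  S_molar <- S / (p$m_S * 1000)
  p$E_A0 - (consts$R_J * consts$T_K / (8 * consts$F_C)) *
    log(S_molar / (HCO3^2 * Hplus^9))
}

#' Cathode Nernst potential
#'
#' E_C = E_C0 - (RT/2F) ln(1 / [H+]^2) at the fixed catholyte pH; constant
#' during a run (the unbuffered catholyte stabilises near pH 11).
#'
#' @param p A [mec_params()].
#' @param consts A [phys_constants()] list.
#' @return Potential in V (about -0.651 V at pH 11).
#' @export
cathode_potential <- function(p = mec_params(), consts = phys_constants()) {
  p$E_C0 - (consts$R_J * consts$T_K / (2 * consts$F_C)) *
    log(10^(2 * p$cathode_pH))
}

#' Anode concentration overpotential
#'
#' eta_con = (RT/F) ln( M_Total/(M_Total - M_OX) * S_0/S ): the voltage loss
#' from depletion of reduced mediator and of substrate. Diverges as the
#' mediator pool fully oxidises or the substrate runs out, which chokes the
#' current off.
#'
#' @param M_OX Oxidised mediator fraction, mg-M mg-x-1 in `[0, M_Total]`.
#' @param S Current substrate concentration, mg L-1 (0 < S <= S_0).
#' @param S_0 Initial substrate concentration, mg L-1.
#' @param p A [mec_params()].
#' @param consts A [phys_constants()] list.
#' @return Overpotential in V (>= 0; `Inf` when S = 0 or M_OX = M_Total).
#' @export
concentration_overpotential <- function(M_OX, S, S_0, p = mec_params(),
                                        consts = phys_constants()) {
  stopifnot(M_OX >= 0, M_OX <= p$M_Total, S >= 0, S_0 > 0)
  if (S <= 0 || M_OX >= p$M_Total) return(Inf)
  (consts$R_J * consts$T_K / consts$F_C) *
    log((p$M_Total / (p$M_Total - M_OX)) * (S_0 / S))
}

#' Biomass-dependent internal resistance
#'
#' R_in = R_min + (R_max - R_min) exp(-K_R x_e): a sparse anode biofilm shows
#' the highest observed resistance, a mature one the lowest.
#'
#' @param x_e Exoelectrogen concentration, mg-x L-1 (>= 0); vectorised.
#' @param p A [mec_params()].
#' @return Resistance in ohm, within `[R_min, R_max]`.
#' @export
internal_resistance <- function(x_e, p = mec_params()) {
  stopifnot(is.numeric(x_e), all(is.finite(x_e)))
  if (any(x_e < 0)) stop("negative biomass")
  p$R_min + (p$R_max - p$R_min) * exp(-p$K_R * x_e)
}

#' Circuit current of the MEC
#'
#' I = ((E_C - E_A) + E_ext - eta_con) / (R_ext + R_in) *
#'     (M_Total - M_OX) / (eps + M_Total - M_OX),
#' floored at zero (no reverse current). The last factor throttles the
#' current as the pool of reduced mediator (M_Total - M_OX) empties.
#'
#' @param S,M_OX,x_e,HCO3,Hplus Current anolyte state (see [mec_rhs()]).
#' @param S_0 Initial substrate concentration, mg L-1.
#' @param p A [mec_params()].
#' @param consts A [phys_constants()] list.
#' @return Current in A.
#' @export
mec_current <- function(S, M_OX, x_e, HCO3, Hplus, S_0, p = mec_params(),
                        consts = phys_constants()) {
  if (S <= 0 || M_OX >= p$M_Total) return(0)
  eta <- concentration_overpotential(M_OX, S, S_0, p, consts)
  E_A <- anode_potential(S, HCO3, Hplus, p, consts)
  E_C <- cathode_potential(p, consts)
  drive <- (E_C - E_A) + p$E_ext - eta
  if (drive <= 0) return(0)
  sat <- (p$M_Total - M_OX) / (p$eps + p$M_Total - M_OX)
  drive / (p$R_ext + internal_resistance(x_e, p)) * sat
}

# Anolyte bicarbonate from the algebraic balance: the influent value,
# concentrated by the PRO, plus 2 mol per mol of acetate consumed.
hco3_conc <- function(S, p) {
  p$HCO3_0 * p$conc_factor + 2 * (p$S_0 - S) / (p$m_S * 1000)
}

#' Time derivatives of the batch MEC state
#'
#' State vector (time in days): `S` substrate mg/L, `x_e`, `x_m` biomass
#' mg/L, `M_OX` oxidised mediator fraction mg-M/mg-x, `Hplus` anolyte proton
#' molarity, `charge` cumulative coulombs. Substrate is consumed by both
#' populations (double-Monod for the exoelectrogens, whose rate also needs
#' oxidised mediator); biomass grows with the same saturation terms minus
#' first-order decay; the mediator pool is drained by substrate oxidation
#' (Y_M per mg-S) and replenished by the anodic current; bicarbonate follows
#' the algebraic balance; protons follow the buffered stoichiometric balance
#' (9 - 8 CE Y_H2 protons per acetate remain in the anolyte).
#'
#' @param t Time, days (unused; autonomous system).
#' @param y Named state vector.
#' @param p A [mec_params()].
#' @param consts A [phys_constants()] list.
#' @return `list(dy)` in deSolve convention, with the instantaneous current
#'   (A) and related diagnostics as attributes.
#' @export
mec_rhs <- function(t, y, p, consts = phys_constants()) {
  S <- max(y[["S"]], 0)
  x_e <- max(y[["x_e"]], 0)
  x_m <- max(y[["x_m"]], 0)
  M_OX <- min(max(y[["M_OX"]], 0), p$M_Total)
  Hplus <- max(y[["Hplus"]], 1e-14)
  HCO3 <- max(hco3_conc(S, p), 1e-12)  # guards rejected trial steps
  I <- if (S > 0) mec_current(S, M_OX, x_e, HCO3, Hplus, p$S_0, p, consts)
       else 0
  mon_Se <- S / (p$K_e + S)
  mon_Sm <- S / (p$K_m + S)
  mon_M <- M_OX / (p$K_M + M_OX)
  r_e <- p$q_e_max * mon_Se * mon_M * x_e     # mg-S L-1 d-1
  r_m <- p$q_m_max * mon_Sm * x_m
  dS <- -(r_e + r_m)
  dx_e <- (p$mu_e_max * mon_Se * mon_M - p$d_e) * x_e
  dx_m <- (p$mu_m_max * mon_Sm - p$d_m) * x_m
  # the mediator pool is bookkept per unit of exoelectrogen biomass; with no
  # exoelectrogens it is undefined and stays frozen
  if (x_e > 0) {
    reox <- p$gamma / (p$V_a * x_e) * I / (p$n_e * consts$F_C) * 86400
    dM_OX <- -p$Y_M * p$q_e_max * mon_Se * mon_M + reox
    # keep the pool inside [0, M_Total] against integrator overshoot
    if (M_OX >= p$M_Total && dM_OX > 0) dM_OX <- 0
    if (M_OX <= 0 && dM_OX < 0) dM_OX <- 0
  } else {
    dM_OX <- 0
  }
  dH <- (p$beta / 100) / (p$m_S * 1000) * dS *
    (9 - 8 * (p$CE_param / 100) * (p$Y_H2 / 100))
  if (Hplus <= 1e-14 && dH < 0) dH <- 0
  list(c(S = dS, x_e = dx_e, x_m = dx_m, M_OX = dM_OX, Hplus = dH,
         charge = I * 86400),
       I_A = I, HCO3_M = HCO3)
}

#' Simulate a batch MEC run
#'
#' Integrates [mec_rhs()] with an adaptive stiff-capable solver (deSolve
#' lsodar), the current being closed algebraically from the state at every
#' evaluation. The run stops at the first of: the substrate-removal target,
#' the electrical energy budget (E_ext x charge reaching `energy_budget_J`,
#' the coupling constraint when the MEC runs on harvested PRO energy), or
#' `t_max_h`. Cumulative energy and hydrogen follow identically from the
#' charge: Q_MEC = E_ext * charge and V_H2 = (Y_H2/100) * charge/(2F) * RT/P.
#'
#' @param p A [mec_params()].
#' @param stop List with any of `removal_fraction` (default 0.999),
#'   `energy_budget_J` (default `NULL` = unconstrained), `t_max_h`
#'   (default 240).
#' @param dt_out_h Output grid spacing, h (solver steps are adaptive).
#' @param consts A [phys_constants()] list.
#' @return An object of class `mec_trajectory`: `trajectory` data frame
#'   (t_s, t_h, S_mg_L, x_e_mg_L, x_m_mg_L, M_OX, Hplus_M, HCO3_M, E_A_V,
#'   eta_con_V, R_in_ohm, I_mA, charge_C, Q_J, V_H2_mL), a `summary` list
#'   (removal %, HRT h, charge, energy, hydrogen, currents, stop reason) and
#'   the inputs.
#' @export
simulate_mec <- function(p = mec_params(), stop = list(), dt_out_h = 0.1,
                         consts = phys_constants()) {
  stopifnot(inherits(p, "mec_params"))
  removal <- if (is.null(stop$removal_fraction)) 0.999 else
    stop$removal_fraction
  budget <- stop$energy_budget_J
  t_max_h <- if (is.null(stop$t_max_h)) 240 else stop$t_max_h
  stopifnot(removal > 0, removal <= 1, t_max_h > 0,
            is.null(budget) || budget >= 0)
  if (!is.null(budget) && budget == 0) {
    tr <- mec_traj_frame(0, p, consts,
                         cbind(S = p$S_0, x_e = p$x_e_0, x_m = p$x_m_0,
                               M_OX = p$M_OX_0, Hplus = 10^(-p$pH_anolyte),
                               charge = 0))
    return(mec_result(tr, "energy_budget", p, stop))
  }
  y0 <- c(S = p$S_0, x_e = p$x_e_0, x_m = p$x_m_0, M_OX = p$M_OX_0,
          Hplus = 10^(-p$pH_anolyte), charge = 0)
  S_stop <- p$S_0 * (1 - removal)
  rootfun <- function(t, y, parms, ...) {
    g <- y[["S"]] - S_stop
    if (!is.null(budget)) g <- c(g, budget - p$E_ext * y[["charge"]])
    g
  }
  times <- seq(0, t_max_h / 24, by = dt_out_h / 24)
  sol <- deSolve::lsodar(y = y0, times = times, func = mec_rhs, parms = p,
                         consts = consts, rootfunc = rootfun,
                         rtol = 1e-8, atol = c(1e-8, 1e-8, 1e-8, 1e-12,
                                               1e-16, 1e-6))
  if (any(!is.finite(sol[nrow(sol), ])))
    stop("non-finite MEC state at t = ", sol[nrow(sol), 1], " d")
  t_d <- sol[, "time"]
  last <- sol[nrow(sol), ]
  stop_reason <- if (!is.null(budget) &&
                     p$E_ext * last[["charge"]] >= budget * (1 - 1e-6)) {
    "energy_budget"
  } else if (last[["S"]] <= S_stop * (1 + 1e-6) + 1e-12) {
    "substrate_removed"
  } else "t_max"
  tr <- mec_traj_frame(t_d, p, consts,
                       sol[, c("S", "x_e", "x_m", "M_OX", "Hplus", "charge"),
                           drop = FALSE])
  mec_result(tr, stop_reason, p, stop)
}

# Build the output data frame with the algebraic diagnostics recomputed on
# the output grid.
mec_traj_frame <- function(t_d, p, consts, states) {
  states <- as.data.frame(states)
  n <- nrow(states)
  HCO3 <- hco3_conc(pmax(states$S, 0), p)
  I <- numeric(n)
  E_A <- rep(NA_real_, n)
  eta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Si <- max(states$S[i], 0)
    Mi <- min(max(states$M_OX[i], 0), p$M_Total)
    if (Si > 0) {
      E_A[i] <- anode_potential(Si, HCO3[i], max(states$Hplus[i], 1e-14),
                                p, consts)
      eta[i] <- concentration_overpotential(Mi, Si, p$S_0, p, consts)
      I[i] <- mec_current(Si, Mi, max(states$x_e[i], 0), HCO3[i],
                          max(states$Hplus[i], 1e-14), p$S_0, p, consts)
    }
  }
  data.frame(
    t_s = t_d * 86400, t_h = t_d * 24,
    S_mg_L = states$S, x_e_mg_L = states$x_e, x_m_mg_L = states$x_m,
    M_OX = states$M_OX, Hplus_M = states$Hplus, HCO3_M = HCO3,
    E_A_V = E_A, eta_con_V = eta,
    R_in_ohm = internal_resistance(pmax(states$x_e, 0), p),
    I_mA = I * 1000, charge_C = states$charge,
    Q_J = p$E_ext * states$charge,
    V_H2_mL = (p$Y_H2 / 100) * states$charge / (2 * consts$F_C) *
      consts$molar_volume_L * 1000
  )
}

mec_result <- function(tr, stop_reason, p, stop) {
  last <- tr[nrow(tr), ]
  out <- list(
    trajectory = tr,
    summary = list(
      removal_pct = 100 * (p$S_0 - max(last$S_mg_L, 0)) / p$S_0,
      hrt_h = last$t_h,
      charge_C = last$charge_C,
      Q_MEC_J = last$Q_J,
      V_H2_mL = last$V_H2_mL,
      mean_current_mA = if (nrow(tr) > 1)
        last$charge_C / last$t_s * 1000 else 0,
      max_current_mA = max(tr$I_mA),
      stop_reason = stop_reason
    ),
    params = p, stop = stop
  )
  class(out) <- "mec_trajectory"
  out
}

#' @export
print.mec_trajectory <- function(x, ...) {
  s <- x$summary
  cat("Batch MEC simulation\n")
  cat(sprintf("  stop: %s after %.1f h\n", s$stop_reason, s$hrt_h))
  cat(sprintf("  removal: %.1f %%   charge: %.1f C   energy: %.1f J\n",
              s$removal_pct, s$charge_C, s$Q_MEC_J))
  cat(sprintf("  H2: %.1f mL   current mean/max: %.2f / %.2f mA\n",
              s$V_H2_mL, s$mean_current_mA, s$max_current_mA))
  invisible(x)
}

#' Derived performance metrics of a completed MEC run
#'
#' Removal, Coulombic efficiency (charge recovered over the 8 F per mole of
#' acetate available in the removed substrate), cathodic efficiency (H2
#' recovered over the coulombic maximum; equals the Y_H2 parameter by
#' construction), volumetric H2 production rate normalised by the catholyte
#' volume, and the hydraulic retention time.
#'
#' @param run A `mec_trajectory` from [simulate_mec()].
#' @return List with `removal_pct`, `coulombic_efficiency_pct`,
#'   `cathodic_efficiency_pct`, `H2_rate_m3_m3_d`, `HRT_h`. The Coulombic
#'   efficiency is `NA` when no substrate was removed.
#' @export
performance_metrics <- function(run) {
  stopifnot(inherits(run, "mec_trajectory"))
  p <- run$params
  s <- run$summary
  consts <- phys_constants()
  dS_mol <- (p$S_0 - run$trajectory$S_mg_L[nrow(run$trajectory)]) *
    p$V_a / (p$m_S * 1000)
  CE <- if (dS_mol > 0) 100 * s$charge_C / (8 * consts$F_C * dS_mol) else NA
  n_H2 <- s$V_H2_mL / 1000 / consts$molar_volume_L
  cat_eff <- if (s$charge_C > 0)
    100 * 2 * consts$F_C * n_H2 / s$charge_C else 0
  rate <- if (s$hrt_h > 0)
    (s$V_H2_mL * 1e-6) / ((p$V_c * 1e-3) * (s$hrt_h / 24)) else 0
  list(removal_pct = s$removal_pct,
       coulombic_efficiency_pct = CE,
       cathodic_efficiency_pct = cat_eff,
       H2_rate_m3_m3_d = rate,
       HRT_h = s$hrt_h)
}
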