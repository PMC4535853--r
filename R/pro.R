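# m3 m-2 s-1 per L m-2 h-1
LMH <- 1e-3 / 3600

#' Membrane transport parameters for the PRO unit
#'
#' @param A Water permeability, m3 m-2 s-1 bar-1.
#' @param B Salt permeability, m3 m-2 s-1.
#' @param S_struct Support-layer structural parameter, m.
#' @param D NaCl diffusion coefficient in the support layer, m2 s-1.
#' @param k External mass-transfer coefficient on the draw side, m3 m-2 s-1.
#' @param area Membrane area, m2 (0.014 m2 for the bench cell the reference
#'   scenarios describe).
#' @return A list of class `pro_membrane`.
#' @export
pro_membrane <- function(A, B, S_struct, D = 1.5e-9, k = 3e-5, area = 0.014) {
  vals <- c(A = A, B = B, S_struct = S_struct, D = D, k = k, area = area)
  if (!all(is.finite(vals)))
    stop("all membrane parameters must be finite")
  if (any(vals[c("A", "D", "k", "area")] <= 0))
    stop("A, D, k and area must be strictly positive")
  if (B < 0 || S_struct < 0)   # 0 = ideal (perfectly selective / no ICP)
    stop("B and S_struct must be non-negative")
  structure(as.list(vals), class = "pro_membrane")
}

#' Default (calibrated) membrane parameter set
#'
#' The shipped defaults were obtained with [calibrate_membrane()]: the salt
#' permeability `B` (1.35e-7 m s-1) and structural parameter `S_struct`
#' (6.78e-4 m) are held at published values for the cellulose-triacetate
#' forward-osmosis membrane used in the bench cell, the support-layer
#' diffusivity `D` is fixed at 1.5e-9 m2 s-1 and the draw-side mass-transfer
#' coefficient `k` at 3e-5 m s-1 (laminar Sherwood estimate for the
#' cross-flow cell), and the water permeability `A` is fitted so that the
#' 0.8 M / 1 bar / 6 h validation run ends at a feed volume of 138 mL. The
#' fitted A (~1.19e-7 m s-1 bar-1) agrees with published CTA permeabilities.
#'
#' @return A `pro_membrane` object.
#' @export
default_membrane <- function() {
  pro_membrane(A = 1.18918e-07, B = 1.35e-7, S_struct = 6.78e-4)
}

#' Hydraulic-pressure policy for the PRO draw chamber
#'
#' Either a constant applied pressure or the maximum-power schedule
#' P_t = (pi_D,t - pi_F,t) / 2.
#'
#' @param mode `"half_delta_pi"` or `"constant"`.
#' @param P_const Applied pressure in bar (constant mode only), >= 0.
#' @return A list of class `pressure_policy`.
#' @export
pressure_policy <- function(mode = c("half_delta_pi", "constant"),
                            P_const = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    stopifnot(is.numeric(P_const), length(P_const) == 1L,
              is.finite(P_const), P_const >= 0)
  } else {
    P_const <- NULL
  }
  structure(list(mode = mode, P_const = P_const), class = "pressure_policy")
}

#' Applied hydraulic pressure under a policy
#'
#' @param policy A [pressure_policy()].
#' @param pi_D,pi_F Bulk draw and feed osmotic pressures, bar.
#' @return Pressure in bar. When the osmotic gradient is reversed
#'   (`pi_D < pi_F`) the half-delta-pi policy returns 0 with attribute
#'   `reversed = TRUE`.
#' @export
applied_pressure <- function(policy, pi_D, pi_F) {
  stopifnot(inherits(policy, "pressure_policy"),
            is.finite(pi_D), is.finite(pi_F))
  if (policy$mode == "constant") return(policy$P_const)
  if (pi_D < pi_F) return(structure(0, reversed = TRUE))
  (pi_D - pi_F) / 2
}

# Residual of the implicit flux equation; J in m3 m-2 s-1.
flux_residual <- function(J, pi_D, pi_F, P, mem) {
  e_icp <- exp(J * mem$S_struct / mem$D)   # concentrative ICP on the feed side
  e_ecp <- exp(-J / mem$k)                 # dilutive ECP on the draw side
  eff <- (pi_D * e_ecp - pi_F * e_icp) /
    (1 + (mem$B / J) * (e_icp - e_ecp))
  mem$A * (eff - P) - J
}

#' Solve the implicit PRO water-flux equation
#'
#' Finds the water flux J satisfying
#' J = A * ( (pi_D e^(-J/k) - pi_F e^(J S/D)) /
#'           (1 + (B/J) (e^(J S/D) - e^(-J/k))) - P )
#' by bracketed root-finding on (0, A * pi_D]. The J -> 0 limit of the
#' effective driving force, (pi_D - pi_F) / (1 + B (S/D + 1/k)) - P, decides
#' whether a positive root exists; when it does not the driving force is
#' exhausted and the flux is 0.
#'
#' @param pi_D,pi_F Bulk draw and feed osmotic pressures, bar
#'   (`pi_D >= pi_F >= 0`).
#' @param P Applied hydraulic pressure, bar, >= 0.
#' @param mem A [pro_membrane()].
#' @return Flux in m3 m-2 s-1 (>= 0). A zero caused by an exhausted driving
#'   force carries attribute `exhausted = TRUE`.
#' @export
solve_flux <- function(pi_D, pi_F, P, mem) {
  stopifnot(inherits(mem, "pro_membrane"))
  if (!all(is.finite(c(pi_D, pi_F, P)))) stop("non-finite flux inputs")
  if (pi_F < 0 || pi_D < pi_F) stop("require pi_D >= pi_F >= 0")
  if (P < 0) stop("negative applied pressure")
  drive0 <- (pi_D - pi_F) / (1 + mem$B * (mem$S_struct / mem$D + 1 / mem$k)) - P
  if (drive0 <= 0) return(structure(0, exhausted = TRUE))
  lo <- 1e-10
  hi <- mem$A * pi_D
  f_lo <- flux_residual(lo, pi_D, pi_F, P, mem)
  if (f_lo <= 0) return(structure(0, exhausted = TRUE))
  f_hi <- flux_residual(hi, pi_D, pi_F, P, mem)
  while (f_hi > 0) {          # defensive; J <= A pi_D in theory
    hi <- hi * 2
    f_hi <- flux_residual(hi, pi_D, pi_F, P, mem)
  }
  stats::uniroot(flux_residual, c(lo, hi), pi_D = pi_D, pi_F = pi_F, P = P,
                 mem = mem, tol = 1e-15)$root
}

#' Reverse salt flux through the membrane
#'
#' J_S = B J / (A i R T), the diffusive leak of draw salt into the feed that
#' accompanies a water flux J.
#'
#' @param J Water flux, m3 m-2 s-1, >= 0; vectorised.
#' @param mem A [pro_membrane()].
#' @param consts A [phys_constants()] list.
#' @return Salt flux in mol m-2 s-1.
#' @export
reverse_salt_flux <- function(J, mem, consts = phys_constants()) {
  stopifnot(is.numeric(J), all(is.finite(J)))
  if (any(J < 0)) stop("negative water flux")
  mem$B * J / (mem$A * consts$i_vant_hoff * consts$R_m3bar * consts$T_K)
}

#' Simulate a batch PRO run
#'
#' Advances feed and draw state on a fixed time grid with a quasi-static flux:
#' at each step the bulk osmotic pressures are recomputed from the current
#' salt amounts and volumes, the applied pressure from the policy, and the
#' water flux from [solve_flux()]; then the permeate volume a J dt moves from
#' feed to draw, a J_S dt moles of salt leak from draw to feed, and the
#' harvested osmotic energy grows by a P J dt. The run terminates when the
#' flux falls below `flux_stop_LMH`, at `t_max_h`, or when the feed is
#' exhausted.
#'
#' The feed is a multi-solute stream carried as an equivalent-NaCl molarity,
#' derived by default from its measured conductivity through the 0.64 g/L per
#' mS/cm rule; alternatively a measured osmotic pressure `feed_pi_bar` may be
#' given, which overrides the conductivity route (conversion through the
#' active osmotic model). The dissolved substrate (acetate) is fully rejected
#' by the membrane, so its mass is conserved and only concentrates.
#'
#' @param feed_volume_mL,draw_volume_mL Initial volumes, mL.
#' @param feed_conductivity_mS_cm Feed influent conductivity, mS cm-1; sets
#'   the feed equivalent-NaCl molarity and is concentrated by the recovery
#'   factor in the effluent summary. The default, 18.3 x 115/600 = 3.5075,
#'   is the influent implied by the reference anolyte conductivity.
#' @param feed_pi_bar Optional measured feed osmotic pressure, bar; when
#'   given it sets the feed equivalent molarity instead of the conductivity.
#' @param feed_substrate_mg_L Initial feed substrate (acetate), mg L-1.
#' @param draw_molarity_M Initial draw NaCl molarity, mol L-1.
#' @param membrane A [pro_membrane()].
#' @param policy A [pressure_policy()].
#' @param flux_stop_LMH Stop threshold on the water flux, L m-2 h-1.
#' @param t_max_h Maximum simulated time, h.
#' @param dt_s Fixed integration step, s.
#' @param osm An [osmotic_model()].
#' @param consts A [phys_constants()] list.
#' @return An object of class `pro_trajectory`: list with `trajectory` (data
#'   frame with columns `t_s`, `V_F_L`, `V_D_L`, `pi_F_bar`, `pi_D_bar`,
#'   `P_bar`, `J_LMH`, `Q_J`), `summary` (water recovered, energy, stop time,
#'   stop reason, final amounts) and the inputs.
#' @export
simulate_pro <- function(feed_volume_mL = 600,
                         feed_conductivity_mS_cm = 18.3 * 115 / 600,
                         feed_pi_bar = NULL,
                         feed_substrate_mg_L = 193,
                         draw_molarity_M = 0.8, draw_volume_mL = 600,
                         membrane = default_membrane(),
                         policy = pressure_policy("half_delta_pi"),
                         flux_stop_LMH = 0.5, t_max_h = 48, dt_s = 60,
                         osm = osmotic_model(), consts = phys_constants()) {
  stopifnot(feed_volume_mL > 0, draw_volume_mL > 0,
            feed_conductivity_mS_cm >= 0,
            feed_substrate_mg_L >= 0, draw_molarity_M >= 0,
            flux_stop_LMH > 0, t_max_h > 0, dt_s > 0)
  V_F <- feed_volume_mL / 1000   # L
  V_D <- draw_volume_mL / 1000
  V_F0 <- V_F
  V_D0 <- V_D
  C_F0 <- if (is.null(feed_pi_bar)) {
    conductivity_to_molarity(feed_conductivity_mS_cm, consts)
  } else {
    molarity_from_pressure(feed_pi_bar, osm, consts)
  }
  n_F <- C_F0 * V_F              # mol equivalent NaCl
  n_D <- draw_molarity_M * V_D
  m_sub <- feed_substrate_mg_L * V_F   # mg, conserved
  J_stop <- flux_stop_LMH * LMH
  t_max <- t_max_h * 3600
  a <- membrane$area

  n_max <- ceiling(t_max / dt_s) + 1L
  rec <- matrix(NA_real_, nrow = n_max, ncol = 8L)
  colnames(rec) <- c("t_s", "V_F_L", "V_D_L", "pi_F_bar", "pi_D_bar",
                     "P_bar", "J_LMH", "Q_J")
  t <- 0
  Q <- 0
  i <- 0L
  stop_reason <- "t_max"
  repeat {
    if (!all(is.finite(c(V_F, V_D, n_F, n_D, Q))))
      stop("non-finite PRO state at t = ", t, " s")
    pi_F <- osmotic_pressure(n_F / V_F, osm, consts)
    pi_D <- osmotic_pressure(n_D / V_D, osm, consts)
    if (pi_D >= pi_F) {
      P <- as.numeric(applied_pressure(policy, pi_D, pi_F))
      J <- as.numeric(solve_flux(pi_D, pi_F, P, membrane))
    } else {              # osmotic gradient reversed: PRO regime over
      P <- 0
      J <- 0
    }
    i <- i + 1L
    rec[i, ] <- c(t, V_F, V_D, pi_F, pi_D, P, J / LMH, Q)
    if (J < J_stop) { stop_reason <- "flux_below_threshold"; break }
    if (t >= t_max) { stop_reason <- "t_max"; break }
    dt <- min(dt_s, t_max - t)
    dV <- J * a * dt * 1000          # L
    if (V_F - dV <= 0) { stop_reason <- "feed_exhausted"; break }
    dn <- reverse_salt_flux(J, membrane, consts) * a * dt   # mol
    V_F <- V_F - dV
    V_D <- V_D + dV
    n_F <- n_F + dn
    n_D <- n_D - dn
    Q <- Q + a * P * J * dt * 1e5    # bar m3 -> J
    t <- t + dt
  }
  traj <- as.data.frame(rec[seq_len(i), , drop = FALSE])
  out <- list(
    trajectory = traj,
    summary = list(
      water_recovered_mL = (V_F0 - V_F) * 1000,
      Q_PRO_J = Q,
      hrt_h = t / 3600,
      stop_reason = stop_reason,
      V_F_end_mL = V_F * 1000,
      V_D_end_mL = V_D * 1000,
      n_F_end_mol = n_F,
      n_D_end_mol = n_D,
      m_sub_mg = m_sub
    ),
    inputs = list(
      feed_volume_mL = feed_volume_mL, feed_pi_bar = feed_pi_bar,
      feed_substrate_mg_L = feed_substrate_mg_L,
      feed_conductivity_mS_cm = feed_conductivity_mS_cm,
      draw_molarity_M = draw_molarity_M, draw_volume_mL = draw_volume_mL,
      membrane = membrane, policy = policy, flux_stop_LMH = flux_stop_LMH,
      t_max_h = t_max_h, dt_s = dt_s, osm = osm, consts = consts
    )
  )
  class(out) <- "pro_trajectory"
  out
}

#' Feed and draw effluent states of a completed PRO run
#'
#' The membrane fully rejects the substrate, so the feed effluent substrate
#' concentration is the conserved mass over the final feed volume, and the
#' measured feed conductivity concentrates by the same volume factor. The draw
#' effluent NaCl molarity comes from the salt mass balance (salt amount over
#' the diluted volume) and its conductivity from
#' [molarity_to_conductivity()].
#'
#' @param traj A `pro_trajectory` from [simulate_pro()].
#' @return A list with `feed` and `draw` solution states (volume, substrate
#'   or NaCl concentration, conductivity, equivalent molarity) and the
#'   concentration factor V_F,0 / V_F,end.
#' @export
effluent_summary <- function(traj) {
  stopifnot(inherits(traj, "pro_trajectory"))
  s <- traj$summary
  inp <- traj$inputs
  cf <- inp$feed_volume_mL / s$V_F_end_mL
  C_D <- s$n_D_end_mol / (s$V_D_end_mL / 1000)
  list(
    feed = list(
      volume_mL = s$V_F_end_mL,
      substrate_mg_L = s$m_sub_mg / (s$V_F_end_mL / 1000),
      conductivity_mS_cm = inp$feed_conductivity_mS_cm * cf,
      equivalent_molarity_M = s$n_F_end_mol / (s$V_F_end_mL / 1000)
    ),
    draw = list(
      volume_mL = s$V_D_end_mL,
      molarity_M = C_D,
      conductivity_mS_cm = molarity_to_conductivity(C_D, inp$consts)
    ),
    concentration_factor = cf
  )
}

#' @export
print.pro_trajectory <- function(x, ...) {
  s <- x$summary
  cat("Batch PRO simulation\n")
  cat(sprintf("  stop: %s after %.2f h (%d grid points)\n",
              s$stop_reason, s$hrt_h, nrow(x$trajectory)))
  cat(sprintf("  feed: %.1f -> %.1f mL   draw: %.1f -> %.1f mL\n",
              x$inputs$feed_volume_mL, s$V_F_end_mL,
              x$inputs$draw_volume_mL, s$V_D_end_mL))
  cat(sprintf("  water recovered: %.1f mL   energy: %.1f J\n",
              s$water_recovered_mL, s$Q_PRO_J))
  invisible(x)
}
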