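#' Physical constants shared by the PRO and MEC models
#'
#' Returns the constant set used throughout the package: the ideal gas
#' constant, absolute temperature, Faraday constant, cathode gas pressure and
#' the van't Hoff dissociation count and molar mass for NaCl. The gas constant
#' is also carried in L.bar and m3.bar units so that osmotic pressures stay in
#' bar while fluxes stay in SI.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 298.15 K.
#' @return A list of class `phys_constants` with elements `R_J` (J mol-1 K-1),
#'   `R_Lbar` (L bar mol-1 K-1), `R_m3bar` (m3 bar mol-1 K-1), `T_K`,
#'   `F_C` (C mol-1), `P_atm` (atm), `i_vant_hoff`, `M_NaCl` (g mol-1) and
#'   `molar_volume_L` (L mol-1 of ideal gas at `T_K` and 1 atm).
#' @export
phys_constants <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  R_J <- 8.3145
  out <- list(
    R_J = R_J,
    R_Lbar = R_J / 100,          # 0.083145 L bar mol-1 K-1
    R_m3bar = R_J / 1e5,         # 8.3145e-5 m3 bar mol-1 K-1
    T_K = temperature_K,
    F_C = 96485,
    P_atm = 1,
    i_vant_hoff = 2,
    M_NaCl = 58.5,
    # ideal-gas molar volume at T and 1 atm, used for H2 volume bookkeeping
    molar_volume_L = R_J * temperature_K / 101325 * 1000
  )
  class(out) <- "phys_constants"
  out
}

#' Osmotic-coefficient model for van't Hoff pressures
#'
#' Osmotic pressures are computed as pi = phi i R T C. The default `phi = 1`
#' is the literal van't Hoff relation, which is what the process simulations
#' use throughout (it reproduces the reference scenarios' energy and timing).
#' Real NaCl solutions fall somewhat below the ideal pressure; see
#' [phi_measured_nacl()] for the multiplier that maps 0.8 M onto the measured
#' 36.2 bar of the bench draw solution, useful when converting a *measured*
#' osmotic pressure into an equivalent molarity.
#'
#' @param phi Dimensionless osmotic-coefficient multiplier, in (0, 1.2].
#' @return A list of class `osmotic_model`.
#' @export
osmotic_model <- function(phi = 1) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi),
            phi > 0, phi <= 1.2)
  structure(list(phi = phi), class = "osmotic_model")
}

#' Osmotic-coefficient multiplier matching the measured NaCl draw pressure
#'
#' The bench 0.8 M NaCl draw measured 36.2 bar, below the ideal van't Hoff
#' 39.66 bar; this multiplier, 36.2 / (2 x 0.083145 x 298.15 x 0.8) = 0.9127,
#' reconciles the two. It is *not* used by the default scenario simulations
#' (which use the literal relation, phi = 1); it exists for converting
#' measured pressures of real solutions to equivalent molarities.
#'
#' @return A single number, about 0.913.
#' @export
phi_measured_nacl <- function() {
  consts <- phys_constants()
  36.2 / (consts$i_vant_hoff * consts$R_Lbar * consts$T_K * 0.8)
}

#' Osmotic pressure of an equivalent-NaCl solution
#'
#' van't Hoff relation with the osmotic-coefficient multiplier:
#' pi = phi i R T C, in bar.
#'
#' @param C Molar concentration (mol L-1), non-negative; vectorised.
#' @param model An [osmotic_model()].
#' @param consts A [phys_constants()] list.
#' @return Osmotic pressure in bar, same length as `C`.
#' @export
osmotic_pressure <- function(C, model = osmotic_model(),
                             consts = phys_constants()) {
  stopifnot(is.numeric(C), all(is.finite(C)))
  if (any(C < 0)) stop("negative concentration")
  model$phi * consts$i_vant_hoff * consts$R_Lbar * consts$T_K * C
}

#' Equivalent-NaCl molarity with a given osmotic pressure
#'
#' Inverse of [osmotic_pressure()]; used to carry a multi-solute feed (whose
#' osmotic pressure is measured, not computed) as an equivalent NaCl molarity.
#'
#' @param pi_bar Osmotic pressure in bar, non-negative.
#' @inheritParams osmotic_pressure
#' @return Molar concentration (mol L-1).
#' @export
molarity_from_pressure <- function(pi_bar, model = osmotic_model(),
                                   consts = phys_constants()) {
  stopifnot(is.numeric(pi_bar), all(is.finite(pi_bar)))
  if (any(pi_bar < 0)) stop("negative pressure")
  pi_bar / (model$phi * consts$i_vant_hoff * consts$R_Lbar * consts$T_K)
}

#' Convert conductivity to equivalent-NaCl molarity
#'
#' Uses the empirical factor 0.64 g L-1 of TDS per mS cm-1 (1 mS cm-1 ~ 640
#' ppm) and the molar mass of NaCl (58.5 g mol-1).
#'
#' @param kappa Conductivity in mS cm-1, non-negative; vectorised.
#' @param consts A [phys_constants()] list.
#' @return Molar concentration (mol L-1).
#' @export
conductivity_to_molarity <- function(kappa, consts = phys_constants()) {
  stopifnot(is.numeric(kappa), all(is.finite(kappa)))
  if (any(kappa < 0)) stop("negative conductivity")
  kappa * 0.64 / consts$M_NaCl
}

#' Convert equivalent-NaCl molarity to conductivity
#'
#' Exact inverse of [conductivity_to_molarity()].
#'
#' @param C Molar concentration (mol L-1), non-negative; vectorised.
#' @param consts A [phys_constants()] list.
#' @return Conductivity in mS cm-1.
#' @export
molarity_to_conductivity <- function(C, consts = phys_constants()) {
  stopifnot(is.numeric(C), all(is.finite(C)))
  if (any(C < 0)) stop("negative concentration")
  C * consts$M_NaCl / 0.64
}
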