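#' Build MEC initial conditions from a completed PRO run
#'
#' The hydraulic coupling of the two units: the PRO feed effluent (reduced
#' volume, concentrated substrate and salts) becomes the MEC anolyte, the
#' diluted PRO draw effluent becomes the catholyte, and the harvested osmotic
#' energy Q_PRO becomes the electrical budget available to the MEC.
#'
#' @param pro A `pro_trajectory` from [simulate_pro()].
#' @param mec_base A [mec_params()] carrying the kinetic/electrochemical
#'   configuration; its volume, substrate, bicarbonate-concentration and
#'   catholyte fields are overwritten from the PRO effluents.
#' @param min_anolyte_mL Smallest feed effluent volume considered operable;
#'   below it the scenario is infeasible.
#' @return A list with `params` (the updated `mec_params`),
#'   `energy_budget_J`, and the `effluents` summary.
#' @export
couple <- function(pro, mec_base = mec_params(), min_anolyte_mL = 1) {
  stopifnot(inherits(pro, "pro_trajectory"), inherits(mec_base, "mec_params"))
  eff <- effluent_summary(pro)
  if (eff$feed$volume_mL < min_anolyte_mL)
    stop("scenario infeasible: feed effluent ", round(eff$feed$volume_mL, 2),
         " mL below the operable minimum")
  p <- mec_params_update(mec_base,
                         V_a = eff$feed$volume_mL / 1000,
                         V_c = eff$draw$volume_mL / 1000,
                         S_0 = eff$feed$substrate_mg_L,
                         conc_factor = eff$concentration_factor)
  list(params = p, energy_budget_J = pro$summary$Q_PRO_J, effluents = eff)
}

# Rebuild a mec_params with some fields replaced (repassing through the
# validating constructor).
mec_params_update <- function(p, ...) {
  new <- utils::modifyList(unclass(p), list(...))
  do.call(mec_params, new)
}

#' Scenario description for a coupled PRO-MEC run
#'
#' @param pro Named list of [simulate_pro()] arguments (defaults are the
#'   reference feasibility scenario).
#' @param mec A [mec_params()] kinetic/electrochemical configuration.
#' @param use_pro_energy_budget Cap the MEC energy consumption at Q_PRO.
#' @param anolyte_from_feed_effluent,catholyte_from_draw_effluent Route the
#'   PRO effluents into the MEC chambers (when `FALSE` the corresponding
#'   fields of `mec` are kept as given).
#' @param mec_stop Extra MEC stop settings (`removal_fraction`, `t_max_h`).
#' @return A list of class `system_scenario`.
#' @export
system_scenario <- function(pro = list(), mec = mec_params(),
                            use_pro_energy_budget = TRUE,
                            anolyte_from_feed_effluent = TRUE,
                            catholyte_from_draw_effluent = TRUE,
                            mec_stop = list()) {
  stopifnot(is.list(pro), inherits(mec, "mec_params"))
  structure(list(pro = pro, mec = mec,
                 use_pro_energy_budget = use_pro_energy_budget,
                 anolyte_from_feed_effluent = anolyte_from_feed_effluent,
                 catholyte_from_draw_effluent = catholyte_from_draw_effluent,
                 mec_stop = mec_stop),
            class = "system_scenario")
}

#' Run a full coupled PRO-MEC scenario
#'
#' Simulates the PRO batch, routes its effluents and energy into the MEC via
#' [couple()], simulates the MEC batch under the removal target and (when
#' enabled) the PRO energy budget, and assembles the system summary.
#'
#' @param s A [system_scenario()].
#' @return An object of class `system_result`: `pro` and `mec` trajectories
#'   plus a `summary` list (water recovered, Q_PRO, Q_MEC, energy surplus,
#'   H2, removal, both HRTs).
#' @export
run_system <- function(s) {
  stopifnot(inherits(s, "system_scenario"))
  pro <- do.call(simulate_pro, s$pro)
  cp <- couple(pro, s$mec)
  p <- cp$params
  if (!s$anolyte_from_feed_effluent)
    p <- mec_params_update(p, V_a = s$mec$V_a, S_0 = s$mec$S_0,
                           conc_factor = s$mec$conc_factor)
  if (!s$catholyte_from_draw_effluent)
    p <- mec_params_update(p, V_c = s$mec$V_c)
  stop <- s$mec_stop
  if (s$use_pro_energy_budget)
    stop$energy_budget_J <- cp$energy_budget_J
  mec <- simulate_mec(p, stop = stop)
  out <- list(
    pro = pro, mec = mec, effluents = cp$effluents,
    summary = list(
      water_recovered_mL = pro$summary$water_recovered_mL,
      Q_PRO_J = pro$summary$Q_PRO_J,
      Q_MEC_J = mec$summary$Q_MEC_J,
      energy_surplus_J = pro$summary$Q_PRO_J - mec$summary$Q_MEC_J,
      V_H2_mL = mec$summary$V_H2_mL,
      removal_pct = mec$summary$removal_pct,
      pro_hrt_h = pro$summary$hrt_h,
      mec_hrt_h = mec$summary$hrt_h,
      mec_stop_reason = mec$summary$stop_reason
    )
  )
  class(out) <- "system_result"
  out
}

#' @export
print.system_result <- function(x, ...) {
  s <- x$summary
  cat("Coupled PRO-MEC run\n")
  cat(sprintf("  PRO:  %.0f mL water, %.0f J in %.1f h\n",
              s$water_recovered_mL, s$Q_PRO_J, s$pro_hrt_h))
  cat(sprintf("  MEC:  %.1f %% removal, %.1f mL H2, %.0f J in %.1f h (%s)\n",
              s$removal_pct, s$V_H2_mL, s$Q_MEC_J, s$mec_hrt_h,
              s$mec_stop_reason))
  cat(sprintf("  energy surplus: %.0f J\n", s$energy_surplus_J))
  invisible(x)
}

#' Sweep one scenario variable over a grid
#'
#' Reruns the full coupled system along a grid of one of the three study
#' variables: the PRO influent volume (feed and draw changed together), the
#' draw NaCl molarity, or the MEC external voltage.
#'
#' @param s A [system_scenario()] providing the base configuration.
#' @param variable `"pro_influent_volume"` (mL), `"draw_molarity"` (M) or
#'   `"voltage"` (V).
#' @param grid Numeric vector of grid points.
#' @return A data frame, one row per grid point, with the system summary
#'   columns plus the swept value.
#' @export
sweep_system <- function(s, variable = c("pro_influent_volume",
                                         "draw_molarity", "voltage"),
                         grid) {
  stopifnot(inherits(s, "system_scenario"), is.numeric(grid),
            length(grid) >= 1L, all(is.finite(grid)))
  variable <- match.arg(variable)
  rows <- lapply(grid, function(v) {
    si <- s
    if (variable == "pro_influent_volume") {
      si$pro$feed_volume_mL <- v
      si$pro$draw_volume_mL <- v
    } else if (variable == "draw_molarity") {
      si$pro$draw_molarity_M <- v
    } else {
      si$mec <- mec_params_update(si$mec, E_ext = v)
    }
    res <- run_system(si)$summary
    data.frame(variable = variable, value = v,
               water_recovered_mL = res$water_recovered_mL,
               Q_PRO_J = res$Q_PRO_J, Q_MEC_J = res$Q_MEC_J,
               energy_surplus_J = res$energy_surplus_J,
               V_H2_mL = res$V_H2_mL, removal_pct = res$removal_pct,
               pro_hrt_h = res$pro_hrt_h, mec_hrt_h = res$mec_hrt_h,
               mec_stop_reason = res$mec_stop_reason)
  })
  do.call(rbind, rows)
}
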