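# Allowed configuration keys, by section. Unknown keys are rejected so that
# typos fail loudly instead of silently falling back to defaults.
config_schema <- list(
  top = c("scenario", "seed", "integrator", "pro", "mec", "coupling",
          "sweep"),
  integrator = c("dt_s", "dt_out_h"),
  pro = c("feed_volume_mL", "feed_substrate_mg_L", "feed_conductivity_mS_cm",
          "feed_pi_bar", "draw_molarity_M", "draw_volume_mL",
          "pressure_policy", "P_bar", "flux_stop_LMH", "t_max_h",
          "membrane", "phi"),
  membrane = c("A", "B", "S_struct", "D", "k", "area"),
  mec = c("voltage_V", "R_ext_ohm", "anolyte", "catholyte", "kinetics",
          "stop"),
  anolyte = c("volume_mL", "substrate_mg_L", "conductivity_mS_cm",
              "HCO3_0_M", "conc_factor", "pH"),
  catholyte = c("volume_mL", "molarity_M", "pH"),
  stop = c("removal", "energy_budget_J", "t_max_h"),
  coupling = c("use_pro_energy_budget", "anolyte_from_feed_effluent",
               "catholyte_from_draw_effluent"),
  sweep = c("variable", "grid")
)

check_keys <- function(x, section) {
  allowed <- config_schema[[section]]
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(x)
}

#' Load and validate a scenario configuration file
#'
#' Reads a YAML scenario description covering a PRO run, an MEC run, a
#' coupled system run or a sweep. Every key is checked against the schema
#' (unknown keys are an error), types are validated and defaults applied; the
#' kinetics section may override any [mec_params()] field.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated list of class `run_config` with sections `scenario`
#'   (`"pro"`, `"mec"`, `"system"` or `"sweep"`), `seed`, `integrator`,
#'   `pro`, `mec`, `coupling` and (for sweeps) `sweep`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0)
    stop("empty config; required keys: ",
         paste(config_schema$top, collapse = ", "))
  check_keys(raw, "top")
  scenario <- raw$scenario
  if (is.null(scenario) ||
      !scenario %in% c("pro", "mec", "system", "sweep"))
    stop("'scenario' must be one of pro, mec, system, sweep")
  cfg <- list(
    scenario = scenario,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    integrator = utils::modifyList(list(dt_s = 60, dt_out_h = 0.1),
                                   check_num(raw$integrator, "integrator"))
  )
  cfg$pro <- normalise_pro(raw$pro)
  cfg$mec <- normalise_mec(raw$mec)
  cfg$coupling <- utils::modifyList(
    list(use_pro_energy_budget = TRUE, anolyte_from_feed_effluent = TRUE,
         catholyte_from_draw_effluent = TRUE),
    check_flags(raw$coupling, "coupling"))
  if (scenario == "sweep") {
    sw <- raw$sweep
    check_keys(sw, "sweep")
    if (is.null(sw$variable) || is.null(sw$grid))
      stop("sweep scenario needs 'sweep: {variable, grid}'")
    stopifnot(sw$variable %in% c("pro_influent_volume", "draw_molarity",
                                 "voltage"))
    cfg$sweep <- list(variable = sw$variable, grid = as.numeric(sw$grid))
  }
  class(cfg) <- "run_config"
  cfg
}

check_num <- function(x, section) {
  if (is.null(x)) return(list())
  check_keys(x, section)
  bad <- names(x)[!vapply(x, function(v)
    is.numeric(v) && all(is.finite(v)), TRUE)]
  if (length(bad) > 0)
    stop("non-numeric value for key(s) in '", section, "': ",
         paste(bad, collapse = ", "))
  x
}

check_flags <- function(x, section) {
  if (is.null(x)) return(list())
  check_keys(x, section)
  bad <- names(x)[!vapply(x, is.logical, TRUE)]
  if (length(bad) > 0)
    stop("non-logical value for key(s) in '", section, "': ",
         paste(bad, collapse = ", "))
  x
}

normalise_pro <- function(pro) {
  if (is.null(pro)) pro <- list()
  check_keys(pro, "pro")
  scalars <- setdiff(names(pro), c("pressure_policy", "membrane"))
  bad <- scalars[!vapply(pro[scalars], function(v)
    is.numeric(v) && all(is.finite(v)), TRUE)]
  if (length(bad) > 0)
    stop("non-numeric value for key(s) in 'pro': ",
         paste(bad, collapse = ", "))
  mem <- pro$membrane
  if (!is.null(mem)) check_num(mem, "membrane")
  policy_mode <- if (is.null(pro$pressure_policy)) "half_delta_pi" else
    pro$pressure_policy
  if (!policy_mode %in% c("half_delta_pi", "constant"))
    stop("pressure_policy must be half_delta_pi or constant")
  if (policy_mode == "constant" && is.null(pro$P_bar))
    stop("constant pressure policy needs P_bar")
  out <- utils::modifyList(
    list(feed_volume_mL = 600, feed_substrate_mg_L = 193,
         feed_conductivity_mS_cm = 18.3 * 115 / 600,
         draw_molarity_M = 0.8, draw_volume_mL = 600,
         flux_stop_LMH = 0.5, t_max_h = 48, phi = 1),
    pro[setdiff(names(pro), c("pressure_policy", "P_bar", "membrane"))])
  out$policy_mode <- policy_mode
  out$P_bar <- pro$P_bar
  out$membrane <- mem
  out
}

normalise_mec <- function(mec) {
  if (is.null(mec)) mec <- list()
  check_keys(mec, "mec")
  for (sec in c("anolyte", "catholyte", "stop"))
    if (!is.null(mec[[sec]])) check_num(mec[[sec]], sec)
  defaults <- list(
    voltage_V = 0.8, R_ext_ohm = 1,
    anolyte = list(volume_mL = 115, substrate_mg_L = 1007,
                   conductivity_mS_cm = 18.3, HCO3_0_M = 0.00012,
                   conc_factor = 600 / 115, pH = 7),
    catholyte = list(volume_mL = 1085, molarity_M = 0.46, pH = 11),
    kinetics = list(),
    stop = list(removal = 0.999, t_max_h = 240))
  utils::modifyList(defaults, mec)
}

# Assemble package objects from a validated config.
config_pro_args <- function(cfg) {
  pro <- cfg$pro
  mem <- if (is.null(pro$membrane)) default_membrane() else
    do.call(pro_membrane, utils::modifyList(unclass(default_membrane()),
                                            pro$membrane))
  policy <- if (pro$policy_mode == "constant")
    pressure_policy("constant", P_const = pro$P_bar)
  else pressure_policy("half_delta_pi")
  args <- list(feed_volume_mL = pro$feed_volume_mL,
               feed_substrate_mg_L = pro$feed_substrate_mg_L,
               feed_conductivity_mS_cm = pro$feed_conductivity_mS_cm,
               draw_molarity_M = pro$draw_molarity_M,
               draw_volume_mL = pro$draw_volume_mL,
               membrane = mem, policy = policy,
               flux_stop_LMH = pro$flux_stop_LMH, t_max_h = pro$t_max_h,
               dt_s = cfg$integrator$dt_s,
               osm = osmotic_model(pro$phi))
  if (!is.null(pro$feed_pi_bar)) args$feed_pi_bar <- pro$feed_pi_bar
  args
}

config_mec_params <- function(cfg) {
  m <- cfg$mec
  args <- utils::modifyList(
    list(E_ext = m$voltage_V, R_ext = m$R_ext_ohm,
         V_a = m$anolyte$volume_mL / 1000, S_0 = m$anolyte$substrate_mg_L,
         HCO3_0 = m$anolyte$HCO3_0_M, conc_factor = m$anolyte$conc_factor,
         pH_anolyte = m$anolyte$pH, V_c = m$catholyte$volume_mL / 1000,
         cathode_pH = m$catholyte$pH),
    m$kinetics)
  do.call(mec_params, args)
}

config_mec_stop <- function(cfg) {
  st <- cfg$mec$stop
  out <- list(removal_fraction = st$removal, t_max_h = st$t_max_h)
  if (!is.null(st$energy_budget_J)) out$energy_budget_J <- st$energy_budget_J
  out
}

config_system_scenario <- function(cfg) {
  system_scenario(pro = config_pro_args(cfg), mec = config_mec_params(cfg),
                  use_pro_energy_budget = cfg$coupling$use_pro_energy_budget,
                  anolyte_from_feed_effluent =
                    cfg$coupling$anolyte_from_feed_effluent,
                  catholyte_from_draw_effluent =
                    cfg$coupling$catholyte_from_draw_effluent,
                  mec_stop = config_mec_stop(cfg))
}

#' Run the scenario described by a configuration
#'
#' Dispatches a validated [load_config()] object to [simulate_pro()],
#' [simulate_mec()], [run_system()] or [sweep_system()].
#'
#' @param cfg A `run_config`.
#' @return The corresponding result object (`pro_trajectory`,
#'   `mec_trajectory`, `system_result`, or a sweep data frame).
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  switch(cfg$scenario,
    pro = do.call(simulate_pro, config_pro_args(cfg)),
    mec = simulate_mec(config_mec_params(cfg), stop = config_mec_stop(cfg),
                       dt_out_h = cfg$integrator$dt_out_h),
    system = run_system(config_system_scenario(cfg)),
    sweep = sweep_system(config_system_scenario(cfg),
                         variable = cfg$sweep$variable,
                         grid = cfg$sweep$grid))
}

#' List the shipped scenario presets
#'
#' The five reference scenarios (model validation, system feasibility and
#' the three sweeps) ship as YAML files under `inst/extdata/presets`.
#'
#' @return Named character vector of preset file paths.
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "promec")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(files, sub("\\.yaml$", "", basename(files)))
}

#' Load a shipped preset configuration
#'
#' @param name Preset name, e.g. `"exp2_feasibility"`; see [list_presets()].
#' @return A `run_config`.
#' @export
load_preset <- function(name) {
  presets <- list_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  load_config(presets[[name]])
}

#' Write result tables, summary and run log to a directory
#'
#' Trajectories are written as comma-separated tables with SI-suffixed
#' column names, the summary as a key-value text file, and a log file with
#' package version, configuration hash and seed, so that a run is fully
#' reproducible from its output directory.
#'
#' @param result A result object from [run_config()] (or the underlying
#'   simulators).
#' @param dir Output directory (created if missing).
#' @param cfg Optional `run_config` used for the log.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr_summary <- function(s, name) {
    p <- file.path(dir, name)
    writeLines(paste0(names(s), " = ",
                      vapply(s, function(v) paste(format(v, digits = 10),
                                                  collapse = " "),
                             character(1))), p)
    paths <<- c(paths, p)
  }
  if (inherits(result, "pro_trajectory")) {
    wr_csv(result$trajectory, "pro_trajectory.csv")
    wr_summary(result$summary, "pro_summary.txt")
  } else if (inherits(result, "mec_trajectory")) {
    wr_csv(result$trajectory, "mec_trajectory.csv")
    wr_summary(result$summary, "mec_summary.txt")
  } else if (inherits(result, "system_result")) {
    wr_csv(result$pro$trajectory, "pro_trajectory.csv")
    wr_csv(result$mec$trajectory, "mec_trajectory.csv")
    wr_summary(result$summary, "system_summary.txt")
  } else if (is.data.frame(result)) {
    wr_csv(result, "sweep.csv")
  } else stop("unknown result type")
  log <- c(
    paste0("promec version: ",
           as.character(utils::packageVersion("promec"))),
    paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (!is.null(cfg)) paste0("seed: ", cfg$seed),
    if (!is.null(cfg)) paste0("config sha: ", config_hash(cfg)))
  p <- file.path(dir, "run_log.txt")
  writeLines(log, p)
  invisible(c(paths, p))
}

# Deterministic hash of the (normalised) configuration, for the run log.
config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(unclass(cfg))),
               collapse = "\n")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}
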