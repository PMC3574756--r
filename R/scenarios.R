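#' Builtin scenario registry
#'
#' The canned configurations reproduce the published parameter sets:
#' `fig3` (discrete-limit single type), `fig4` (continuous-limit single
#' type), `fig7` (initial form and mutant), `fig9` (pathogen eliminated),
#' `fig10` (oscillatory chronic case), `fig12` (antigenic variation) and
#' `fig13` (T-cell maturation schedule). `load_scenario()` accepts a
#' builtin name or a YAML/JSON file with the same keys and validates the
#' configuration before returning it.
#'
#' @param name builtin scenario name or a path to a YAML/JSON config file.
#' @return a `gw_scenario_config`: list with `name`, `kind` (`"single"`,
#'   `"twotype"`, `"immune"`, `"variable"`, `"maturation"`), `scenario`
#'   (the model's parameter object) and `generations` (the published
#'   horizon).
#' @examples
#' cfg <- load_scenario("fig3")
#' cfg$scenario$alpha  # 1
#' @export
load_scenario <- function(name) {
  builtin <- builtin_scenarios()
  if (name %in% names(builtin)) {
    return(builtin[[name]]())
  }
  if (file.exists(name)) {
    return(scenario_from_list(read_config_file(name), name))
  }
  stop(sprintf("unknown scenario '%s' (builtins: %s)", name,
               paste(names(builtin), collapse = ", ")), call. = FALSE)
}

#' @rdname load_scenario
#' @export
list_scenarios <- function() names(builtin_scenarios())

builtin_scenarios <- function() {
  list(
    fig3 = function() new_scenario_config(
      "fig3", "single",
      single_type_params(alpha = 1, beta = 2 / 3, rho = 2, n_max = 128),
      generations = 50),
    fig4 = function() new_scenario_config(
      "fig4", "single",
      single_type_params(alpha = 0.1, beta = 0.9664, rho = 2, n_max = 128),
      generations = 150),
    fig7 = function() new_scenario_config(
      "fig7", "twotype",
      two_type_params(alpha_A = 0.1, alpha_B = 0.1, rho_A = 3, rho_B = 6,
                      beta_A = 0.95, beta_B = 0.95,
                      eps_AB = 0.01, eps_BA = 0.001, n_max = 32),
      generations = 600),
    fig9 = function() new_scenario_config(
      "fig9", "immune", immune_scenario_fig9(), generations = 200),
    fig10 = function() new_scenario_config(
      "fig10", "immune", immune_scenario_fig10(), generations = 100),
    fig12 = function() new_scenario_config(
      "fig12", "variable", variable_scenario_fig12(), generations = 100),
    fig13 = function() new_scenario_config(
      "fig13", "maturation", maturation_schedule_fig13(),
      generations = 150)
  )
}

new_scenario_config <- function(name, kind, scenario, generations) {
  structure(list(name = name, kind = kind, scenario = scenario,
                 generations = generations),
            class = "gw_scenario_config")
}

#' @export
print.gw_scenario_config <- function(x, ...) {
  cat(sprintf("<scenario '%s'> kind %s, horizon %d generations\n",
              x$name, x$kind, x$generations))
  invisible(x)
}

# The published coupled-model parameter sets. The pathogen switches on the
# effector mean (set point T_E); the immune pair switches on the pathogen
# mean (set point T_P).
immune_scenario_fig9 <- function() {
  immune_scenario(
    n_max = 32, alpha_P = 0.1, alpha_E = 0.1, alpha_M = 0.1,
    pathogen_rule = coupling_rule(
      threshold = 1.5,                       # T_E
      below = list(rho_P = 6, beta_P = 0.96),
      above = list(rho_P = 2, beta_P = 0.65)),
    immune_rule = coupling_rule(
      threshold = 0.5,                       # T_P
      below = list(rho_E = 2, rho_M = 2, eps_EM = 0.50, eps_ME = 0.01,
                   beta_E = 0.90, beta_M = 0.93),
      above = list(rho_E = 6, rho_M = 2, eps_EM = 0.50, eps_ME = 0.50,
                   beta_E = 0.95, beta_M = 0.93)))
}

# fig10 = fig9 with the documented overrides: weaker active-effector
# pressure on the pathogen (beta_P 0.75), a higher pathogen-detection set
# point (T_P 1.5) and weaker effector survival (0.85 below / 0.90 above).
immune_scenario_fig10 <- function() {
  scn <- immune_scenario_fig9()
  scn$pathogen_rule$above$beta_P <- 0.75
  scn$immune_rule$threshold <- 1.5
  scn$immune_rule$below$beta_E <- 0.85
  scn$immune_rule$above$beta_E <- 0.90
  scn
}

variable_scenario_fig12 <- function() {
  base <- immune_scenario_fig9()
  arm_rule <- base$immune_rule
  arm_rule$threshold <- 1.5                  # T_PA = T_PB
  variable_scenario(
    n_max = 32, alpha_P = 0.1, eps_AB = 0.01, eps_BA = 0.001,
    strain_rule_a = base$pathogen_rule,
    arm_rule_a = arm_rule,
    alpha_E = base$alpha_E, alpha_M = base$alpha_M)
}

maturation_schedule_fig13 <- function() {
  phase <- function(rho_matA, beta_matI, beta_matA) maturation_params(
    alpha = c(0.1, 0.1, 0.1, 0.1),
    rho = c(2, 1, 1, rho_matA),
    beta = c(0.95, 0.75, beta_matI, beta_matA),
    eps = c(0.7, 0.7, 0.7),
    n_max = 16)
  maturation_schedule(list(
    list(from = 0, params = phase(1, 0.99, 0.99)),
    list(from = 50, params = phase(4, 0.75, 0.98)),
    list(from = 100, params = phase(1, 0.75, 0.75))))
}

## ---- config files ----

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

scenario_from_list <- function(cfg, origin) {
  kinds <- c("single", "twotype", "immune", "variable", "maturation")
  if (is.null(cfg$kind) || !cfg$kind %in% kinds) {
    stop(sprintf("config '%s': `kind` must be one of %s", origin,
                 paste(kinds, collapse = ", ")), call. = FALSE)
  }
  known <- switch(cfg$kind,
    single = c("alpha", "beta", "rho", "n_max"),
    twotype = c("alpha_A", "alpha_B", "rho_A", "rho_B", "beta_A", "beta_B",
                "eps_AB", "eps_BA", "n_max"),
    immune = c("n_max", "alpha_P", "alpha_E", "alpha_M", "pathogen_rule",
               "immune_rule", "init_P", "init_EM"),
    variable = c("n_max", "alpha_P", "eps_AB", "eps_BA", "strain_rule_a",
                 "strain_rule_b", "arm_rule_a", "arm_rule_b", "alpha_E",
                 "alpha_M", "init_P", "init_a", "init_b"),
    maturation = c("phases"))
  extra <- setdiff(setdiff(names(cfg), c("kind", "name", "generations")),
                   known)
  if (length(extra)) {
    stop(sprintf("config '%s': unknown key(s): %s", origin,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  args <- cfg[intersect(names(cfg), known)]
  scenario <- switch(cfg$kind,
    single = do.call(single_type_params, args),
    twotype = do.call(two_type_params, args),
    immune = {
      args$pathogen_rule <- do.call(coupling_rule, args$pathogen_rule)
      args$immune_rule <- do.call(coupling_rule, args$immune_rule)
      do.call(immune_scenario, args)
    },
    variable = {
      for (k in intersect(names(args), c("strain_rule_a", "strain_rule_b",
                                         "arm_rule_a", "arm_rule_b"))) {
        args[[k]] <- do.call(coupling_rule, args[[k]])
      }
      do.call(variable_scenario, args)
    },
    maturation = maturation_schedule(lapply(cfg$phases, function(ph) {
      list(from = ph$from, params = do.call(maturation_params, ph$params))
    })))
  new_scenario_config(cfg$name %||% origin, cfg$kind, scenario,
                      cfg$generations %||% 100L)
}

#' Run a scenario configuration to its published horizon
#'
#' Dispatches to the matching run function.
#'
#' @param config a `gw_scenario_config` from [load_scenario()], or a
#'   builtin name.
#' @param generations optional override of the configured horizon.
#' @param ... passed to the underlying run function.
#' @return a `gw_run`.
#' @export
run_scenario <- function(config, generations = NULL, ...) {
  if (is.character(config)) config <- load_scenario(config)
  stopifnot(inherits(config, "gw_scenario_config"))
  g <- generations %||% config$generations
  switch(config$kind,
         single = run_single(config$scenario, g, ...),
         twotype = run_two_type(config$scenario, g, ...),
         immune = run_immune(config$scenario, g, ...),
         variable = run_variable(config$scenario, g, ...),
         maturation = run_maturation(config$scenario, g, ...))
}
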