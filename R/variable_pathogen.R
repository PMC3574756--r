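#' Two-strain variable-pathogen scenario
#'
#' A pathogen with two antigen types A and B (mutating into each other
#' during copying with `eps_AB`, `eps_BA`) faces two independent immune
#' arms. Recognition is lock-and-key: each strain's multiplication and
#' survival parameters switch on its cognate arm's effector mean (set point
#' `T_E` in the strain rules), and each arm's parameters switch on its
#' cognate strain's mean (set point `T_P` in the arm rules). The two arms
#' never exchange individuals and have their own capacity simplexes; the
#' two strains share one.
#'
#' @param n_max shared pathogen carrying capacity (also used per arm).
#' @param alpha_P pathogen copy probability (both strains).
#' @param eps_AB,eps_BA per-copy antigen-switch probabilities.
#' @param strain_rule_a,strain_rule_b [coupling_rule()]s with bundles
#'   `rho_P`, `beta_P`, gated by the cognate effector mean.
#' @param arm_rule_a,arm_rule_b [coupling_rule()]s with the immune bundles
#'   of [resolve_parameters()], gated by the cognate strain mean.
#' @param alpha_E,alpha_M immune copy probabilities (both arms).
#' @param init_P initial `(N_PA, N_PB)` counts.
#' @param init_a,init_b initial `(effector, memory)` counts per arm.
#' @return a `gw_variable_scenario`.
#' @export
variable_scenario <- function(n_max, alpha_P, eps_AB, eps_BA,
                              strain_rule_a, strain_rule_b = strain_rule_a,
                              arm_rule_a, arm_rule_b = arm_rule_a,
                              alpha_E = 0.1, alpha_M = 0.1,
                              init_P = c(1L, 0L), init_a = c(1L, 0L),
                              init_b = c(1L, 0L)) {
  check_prob(alpha_P, "alpha_P")
  check_prob(eps_AB, "eps_AB"); check_prob(eps_BA, "eps_BA")
  for (r in list(strain_rule_a, strain_rule_b, arm_rule_a, arm_rule_b)) {
    stopifnot(inherits(r, "gw_coupling_rule"))
  }
  structure(list(n_max = as.integer(n_max), alpha_P = alpha_P,
                 eps_AB = eps_AB, eps_BA = eps_BA,
                 strain_rule_a = strain_rule_a, strain_rule_b = strain_rule_b,
                 arm_rule_a = arm_rule_a, arm_rule_b = arm_rule_b,
                 alpha_E = alpha_E, alpha_M = alpha_M,
                 init_P = as.integer(init_P), init_a = as.integer(init_a),
                 init_b = as.integer(init_b)),
            class = "gw_variable_scenario")
}

advance_immune_arm <- function(arm_dist, bundle, alpha_E, alpha_M, n_max) {
  prm <- two_type_params(alpha_E, alpha_M, bundle$rho_E, bundle$rho_M,
                         bundle$beta_E, bundle$beta_M,
                         bundle$eps_EM, bundle$eps_ME, n_max)
  idx <- simplex_index(n_max, 2L)
  wm <- renormalize_dist(state_vec_to_dist(
    as.vector(mult_matrix_2d(prm) %*% dist_to_state_vec(arm_dist, idx)),
    idx, n_max, 2L))
  sel_op_2d(wm, prm$beta_A, prm$beta_B)
}

#' Advance the variable-pathogen model by one generation
#'
#' Strain and arm parameters are resolved from the previous generation's
#' post-selection means (simultaneous update), then the two-strain pathogen
#' advances through the joint multiplication/selection phases and each arm
#' through its own effector/memory phases.
#'
#' @param state list with `pathogen`, `arm_a`, `arm_b` (2D `gw_dist`s).
#' @param scenario a [variable_scenario()].
#' @return the new state with `active_params` attached.
#' @export
variable_generation <- function(state, scenario) {
  scn <- scenario
  pm <- dist_mean(state$pathogen)
  ea <- dist_mean(state$arm_a, axis = 1L)
  eb <- dist_mean(state$arm_b, axis = 1L)
  res <- list(strain_a = resolve_rule(scn$strain_rule_a, ea),
              strain_b = resolve_rule(scn$strain_rule_b, eb),
              arm_a = resolve_rule(scn$arm_rule_a, pm[1]),
              arm_b = resolve_rule(scn$arm_rule_b, pm[2]))
  pprm <- two_type_params(scn$alpha_P, scn$alpha_P,
                          res$strain_a$rho_P, res$strain_b$rho_P,
                          res$strain_a$beta_P, res$strain_b$beta_P,
                          scn$eps_AB, scn$eps_BA, scn$n_max)
  idx <- simplex_index(scn$n_max, 2L)
  wp <- renormalize_dist(state_vec_to_dist(
    as.vector(mult_matrix_2d(pprm) %*% dist_to_state_vec(state$pathogen, idx)),
    idx, scn$n_max, 2L))
  wp <- sel_op_2d(wp, pprm$beta_A, pprm$beta_B)
  list(pathogen = wp,
       arm_a = advance_immune_arm(state$arm_a, res$arm_a,
                                  scn$alpha_E, scn$alpha_M, scn$n_max),
       arm_b = advance_immune_arm(state$arm_b, res$arm_b,
                                  scn$alpha_E, scn$alpha_M, scn$n_max),
       active_params = res,
       generation = (state$generation %||% 0L) + 1L)
}

#' Run the variable-pathogen model
#'
#' @param scenario a [variable_scenario()] or the builtin name `"fig12"`.
#' @param generations number of generations (0 returns the initial state's
#'   trajectory row only).
#' @param keep retain per-generation distributions (`"last"`, `"all"`,
#'   `"none"`).
#' @return a `gw_run`; `tidy()` gives per-generation strain means
#'   (`pA_mean`, `pB_mean`), arm means (`ea_mean`, `ma_mean`, `eb_mean`,
#'   `mb_mean`), strain extinction masses (`ext_A`, `ext_B`), total
#'   pathogen extinction `w0_pathogen`, arm extinctions and branch flags.
#' @export
run_variable <- function(scenario, generations,
                         keep = c("last", "all", "none")) {
  keep <- match.arg(keep)
  if (is.character(scenario)) scenario <- load_scenario(scenario)$scenario
  stopifnot(inherits(scenario, "gw_variable_scenario"), generations >= 0)
  state <- list(pathogen = point_dist(scenario$n_max, scenario$init_P),
                arm_a = point_dist(scenario$n_max, scenario$init_a),
                arm_b = point_dist(scenario$n_max, scenario$init_b),
                generation = 0L)
  rows <- vector("list", generations + 1L)
  dists <- if (keep == "all") vector("list", generations + 1L) else NULL
  rows[[1]] <- variable_traj_row(0L, state, NULL)
  if (keep == "all") dists[[1]] <- state[c("pathogen", "arm_a", "arm_b")]
  for (n in seq_len(generations)) {
    state <- variable_generation(state, scenario)
    rows[[n + 1L]] <- variable_traj_row(n, state, state$active_params)
    if (keep == "all") dists[[n + 1L]] <- state[c("pathogen", "arm_a", "arm_b")]
  }
  new_gw_run(kind = "variable", trajectory = dplyr::bind_rows(rows),
             final = state[c("pathogen", "arm_a", "arm_b")],
             distributions = dists, params = scenario,
             generations = generations)
}

variable_traj_row <- function(n, state, res) {
  pm <- dist_mean(state$pathogen)
  ma <- dist_mean(state$arm_a); mb <- dist_mean(state$arm_b)
  pa_marg <- marginal(state$pathogen, 1L)
  pb_marg <- marginal(state$pathogen, 2L)
  br <- function(x) if (is.null(res)) NA_character_ else res[[x]]$branch
  tibble::tibble(
    generation = n,
    pA_mean = pm[1], pB_mean = pm[2],
    ea_mean = ma[1], ma_mean = ma[2],
    eb_mean = mb[1], mb_mean = mb[2],
    ext_A = pa_marg$probs[1], ext_B = pb_marg$probs[1],
    w0_pathogen = extinction_mass(state$pathogen),
    w0_arm_a = extinction_mass(state$arm_a),
    w0_arm_b = extinction_mass(state$arm_b),
    strain_a_branch = br("strain_a"), strain_b_branch = br("strain_b"),
    arm_a_branch = br("arm_a"), arm_b_branch = br("arm_b"))
}
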