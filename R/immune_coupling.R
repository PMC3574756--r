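#' Threshold coupling rule
#'
#' The pathogen and the immune system are interlocked through step
#' functions of each other's previous-generation mean counts: a rule holds
#' a set point and two complete parameter bundles, one used while the
#' observed mean is at or below the threshold and one above it (exact
#' set-point equality resolves to the below branch).
#'
#' @param threshold mean-count set point (>= 0).
#' @param below,above named lists of parameter overrides for the two
#'   branches.
#' @return a `gw_coupling_rule`.
#' @export
coupling_rule <- function(threshold, below, above) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  if (!setequal(names(below), names(above))) {
    stop("`below` and `above` bundles must carry the same parameters",
         call. = FALSE)
  }
  structure(list(threshold = threshold, below = below, above = above),
            class = "gw_coupling_rule")
}

resolve_rule <- function(rule, observed_mean) {
  branch <- if (observed_mean > rule$threshold) "above" else "below"
  c(rule[[branch]], list(branch = branch))
}

#' Resolve the generation's active parameters from the coupled means
#'
#' The pathogen's `(rho_P, beta_P)` are chosen by comparing the effector
#' mean to the rule's set point `T_E`; the immune bundle
#' `(rho_E, rho_M, eps_EM, eps_ME, beta_E, beta_M)` by comparing the
#' pathogen mean to `T_P`. Both comparisons use the previous generation's
#' post-selection means (simultaneous update).
#'
#' @param p_mean,e_mean pathogen and effector (marginal) mean counts.
#' @param pathogen_rule [coupling_rule()] with set point `T_E` and bundles
#'   `rho_P`, `beta_P`.
#' @param immune_rule [coupling_rule()] with set point `T_P` and bundles
#'   `rho_E`, `rho_M`, `eps_EM`, `eps_ME`, `beta_E`, `beta_M`.
#' @return list with elements `pathogen` and `immune`, each the resolved
#'   bundle plus a `branch` flag (`"below"`/`"above"`).
#' @export
resolve_parameters <- function(p_mean, e_mean, pathogen_rule, immune_rule) {
  stopifnot(p_mean >= 0, e_mean >= 0)
  list(pathogen = resolve_rule(pathogen_rule, e_mean),
       immune = resolve_rule(immune_rule, p_mean))
}

#' Immune-response scenario configuration
#'
#' Bundles everything one coupled pathogen/effector-memory run needs: the
#' shared capacity, the copy probabilities (fixed across branches), the two
#' coupling rules and the initial counts.
#'
#' @param n_max shared carrying capacity.
#' @param alpha_P,alpha_E,alpha_M copy probabilities.
#' @param pathogen_rule,immune_rule [coupling_rule()]s (see
#'   [resolve_parameters()]).
#' @param init_P initial pathogen count (point mass).
#' @param init_EM initial `(effector, memory)` counts (point mass).
#' @return a `gw_immune_scenario`.
#' @export
immune_scenario <- function(n_max, alpha_P, alpha_E, alpha_M,
                            pathogen_rule, immune_rule,
                            init_P = 1L, init_EM = c(1L, 0L)) {
  check_prob(alpha_P, "alpha_P"); check_prob(alpha_E, "alpha_E")
  check_prob(alpha_M, "alpha_M")
  stopifnot(inherits(pathogen_rule, "gw_coupling_rule"),
            inherits(immune_rule, "gw_coupling_rule"))
  need_p <- c("rho_P", "beta_P")
  need_i <- c("rho_E", "rho_M", "eps_EM", "eps_ME", "beta_E", "beta_M")
  if (!setequal(names(pathogen_rule$below), need_p)) {
    stop("pathogen rule bundles must carry: ", paste(need_p, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(names(immune_rule$below), need_i)) {
    stop("immune rule bundles must carry: ", paste(need_i, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_max = as.integer(n_max), alpha_P = alpha_P,
                 alpha_E = alpha_E, alpha_M = alpha_M,
                 pathogen_rule = pathogen_rule, immune_rule = immune_rule,
                 init_P = as.integer(init_P),
                 init_EM = as.integer(init_EM)),
            class = "gw_immune_scenario")
}

immune_state_params <- function(scn, resolved) {
  pp <- resolved$pathogen; ip <- resolved$immune
  list(
    pathogen = single_type_params(scn$alpha_P, pp$beta_P, pp$rho_P, scn$n_max),
    immune = two_type_params(scn$alpha_E, scn$alpha_M, ip$rho_E, ip$rho_M,
                             ip$beta_E, ip$beta_M, ip$eps_EM, ip$eps_ME,
                             scn$n_max))
}

#' Advance the coupled pathogen/immune model by one generation
#'
#' Computes the pathogen mean and the effector marginal mean from the
#' previous generation's post-selection distributions, resolves the active
#' parameter bundles, then advances the pathogen (single-type phases with
#' its own cut-off) and the immune pair (two-type phases with the joint
#' cut-off). Both entities see the same previous-generation means.
#'
#' @param state list with `pathogen` (1D `gw_dist`) and `immune`
#'   (2D `gw_dist` over effector/memory counts).
#' @param scenario a [immune_scenario()].
#' @return the new state, with the resolved `active_params` attached.
#' @export
immune_generation <- function(state, scenario) {
  p_mean <- dist_mean(state$pathogen)
  e_mean <- dist_mean(state$immune, axis = 1L)
  resolved <- resolve_parameters(p_mean, e_mean,
                                 scenario$pathogen_rule, scenario$immune_rule)
  prm <- immune_state_params(scenario, resolved)
  idx <- simplex_index(scenario$n_max, 2L)
  wp <- apply_op_1d(state$pathogen, mult_matrix_1d(prm$pathogen))
  wp <- apply_op_1d(wp, sel_matrix_1d(prm$pathogen$beta, scenario$n_max))
  wi <- renormalize_dist(state_vec_to_dist(
    as.vector(mult_matrix_2d(prm$immune) %*%
                dist_to_state_vec(state$immune, idx)),
    idx, scenario$n_max, 2L))
  wi <- sel_op_2d(wi, prm$immune$beta_A, prm$immune$beta_B)
  list(pathogen = wp, immune = wi, active_params = resolved,
       generation = (state$generation %||% 0L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the coupled pathogen/immune model
#'
#' Iterates [immune_generation()] from one pathogen ancestor and one
#' effector ancestor (configurable through the scenario). Optional
#' reinfection events shift the pathogen count distribution up by one
#' individual (mass already at `n_max` stays) at the start of the listed
#' generations.
#'
#' @param scenario a [immune_scenario()], or a builtin name accepted by
#'   [load_scenario()] (`"fig9"`, `"fig10"`).
#' @param generations number of generations.
#' @param reinfect_at integer vector of generations at which a reinfection
#'   event is applied (default none).
#' @param keep retain per-generation post-selection distributions:
#'   `"last"`, `"all"` or `"none"`.
#' @return a `gw_run`; `tidy()` gives columns `generation`, `p_mean`,
#'   `e_mean`, `m_mean`, `w0_pathogen`, `w0_immune`, `pathogen_branch`,
#'   `immune_branch`.
#' @export
run_immune <- function(scenario, generations, reinfect_at = integer(0),
                       keep = c("last", "all", "none")) {
  keep <- match.arg(keep)
  if (is.character(scenario)) scenario <- load_scenario(scenario)$scenario
  stopifnot(inherits(scenario, "gw_immune_scenario"), generations >= 1)
  state <- list(pathogen = point_dist(scenario$n_max, scenario$init_P),
                immune = point_dist(scenario$n_max, scenario$init_EM),
                generation = 0L)
  rows <- vector("list", generations + 1L)
  dists <- if (keep == "all") vector("list", generations + 1L) else NULL
  rows[[1]] <- immune_traj_row(0L, state, NULL)
  if (keep == "all") dists[[1]] <- state[c("pathogen", "immune")]
  for (n in seq_len(generations)) {
    if (n %in% reinfect_at) {
      state$pathogen <- shift_up_one(state$pathogen)
    }
    state <- immune_generation(state, scenario)
    rows[[n + 1L]] <- immune_traj_row(n, state, state$active_params)
    if (keep == "all") dists[[n + 1L]] <- state[c("pathogen", "immune")]
  }
  new_gw_run(kind = "immune", trajectory = dplyr::bind_rows(rows),
             final = state[c("pathogen", "immune")], distributions = dists,
             params = scenario, generations = generations,
             reinfect_at = reinfect_at)
}

immune_traj_row <- function(n, state, resolved) {
  em <- dist_mean(state$immune)
  tibble::tibble(
    generation = n,
    p_mean = dist_mean(state$pathogen),
    e_mean = em[1], m_mean = em[2],
    w0_pathogen = extinction_mass(state$pathogen),
    w0_immune = extinction_mass(state$immune),
    pathogen_branch = if (is.null(resolved)) NA_character_ else
      resolved$pathogen$branch,
    immune_branch = if (is.null(resolved)) NA_character_ else
      resolved$immune$branch)
}

# reinfection: one more individual arrives; counts already at n_max stay
shift_up_one <- function(dist) {
  p <- as.vector(dist$probs)
  n <- length(p)
  out <- c(0, p[-n])
  out[n] <- out[n] + p[n]
  structure(list(probs = as.array(out), n_max = dist$n_max),
            class = "gw_dist")
}
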