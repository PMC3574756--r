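# Monte-Carlo replays of the coupled models. The threshold switching is a
# deterministic function of the exact-run means, so the agent-level sampler
# can replay the same per-generation parameter bundles and its empirical
# distributions must converge to the exact ones.

mc_immune_replay <- function(scn, exact_run, generations, replicates, seed) {
  tr <- tidy(exact_run)
  set.seed(seed)
  pop_p <- matrix(scn$init_P, replicates, 1)
  pop_i <- matrix(rep(scn$init_EM, each = replicates), replicates, 2)
  for (n in seq_len(generations)) {
    res <- resolve_parameters(tr$p_mean[n], tr$e_mean[n],
                              scn$pathogen_rule, scn$immune_rule)
    prm_p <- single_type_params(scn$alpha_P, res$pathogen$beta_P,
                                res$pathogen$rho_P, scn$n_max)
    prm_i <- two_type_params(scn$alpha_E, scn$alpha_M,
                             res$immune$rho_E, res$immune$rho_M,
                             res$immune$beta_E, res$immune$beta_M,
                             res$immune$eps_EM, res$immune$eps_ME, scn$n_max)
    pop_p <- mc_generation(pop_p, prm_p)$after_sel
    pop_i <- mc_generation(pop_i, prm_i)$after_sel
  }
  list(pathogen = empirical_dist(pop_p, scn$n_max),
       immune = empirical_dist(pop_i, scn$n_max))
}

mc_variable_replay <- function(scn, exact_run, generations, replicates, seed) {
  tr <- tidy(exact_run)
  set.seed(seed)
  pop_p <- matrix(rep(scn$init_P, each = replicates), replicates, 2)
  pop_a <- matrix(rep(scn$init_a, each = replicates), replicates, 2)
  pop_b <- matrix(rep(scn$init_b, each = replicates), replicates, 2)
  arm_params <- function(bundle) {
    two_type_params(scn$alpha_E, scn$alpha_M, bundle$rho_E, bundle$rho_M,
                    bundle$beta_E, bundle$beta_M,
                    bundle$eps_EM, bundle$eps_ME, scn$n_max)
  }
  for (n in seq_len(generations)) {
    sa <- gwimmune:::resolve_rule(scn$strain_rule_a, tr$ea_mean[n])
    sb <- gwimmune:::resolve_rule(scn$strain_rule_b, tr$eb_mean[n])
    aa <- gwimmune:::resolve_rule(scn$arm_rule_a, tr$pA_mean[n])
    ab <- gwimmune:::resolve_rule(scn$arm_rule_b, tr$pB_mean[n])
    prm_p <- two_type_params(scn$alpha_P, scn$alpha_P,
                             sa$rho_P, sb$rho_P, sa$beta_P, sb$beta_P,
                             scn$eps_AB, scn$eps_BA, scn$n_max)
    pop_p <- mc_generation(pop_p, prm_p)$after_sel
    pop_a <- mc_generation(pop_a, arm_params(aa))$after_sel
    pop_b <- mc_generation(pop_b, arm_params(ab))$after_sel
  }
  list(pathogen = empirical_dist(pop_p, scn$n_max),
       arm_a = empirical_dist(pop_a, scn$n_max),
       arm_b = empirical_dist(pop_b, scn$n_max))
}
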