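test_that("threshold rules resolve branches as printed, equality below", {
  scn <- fig9_scenario_fixture()
  r1 <- resolve_parameters(0.4, 1.0, scn$pathogen_rule, scn$immune_rule)
  expect_equal(r1$pathogen[c("rho_P", "beta_P")], list(rho_P = 6, beta_P = 0.96))
  expect_equal(r1$immune$branch, "below")
  expect_equal(r1$immune[c("rho_E", "eps_ME", "beta_E")],
               list(rho_E = 2, eps_ME = 0.01, beta_E = 0.90))
  r2 <- resolve_parameters(0.6, 2.0, scn$pathogen_rule, scn$immune_rule)
  expect_equal(r2$pathogen[c("rho_P", "beta_P")], list(rho_P = 2, beta_P = 0.65))
  expect_equal(r2$immune[c("rho_E", "eps_ME", "beta_E")],
               list(rho_E = 6, eps_ME = 0.50, beta_E = 0.95))
  # set-point equality resolves below
  r3 <- resolve_parameters(0.5, 1.5, scn$pathogen_rule, scn$immune_rule)
  expect_equal(r3$pathogen$branch, "below")
  expect_equal(r3$immune$branch, "below")
})

test_that("one coupled generation composes the resolved single- and two-type phases", {
  scn <- fig9_scenario_fixture()
  state <- list(pathogen = point_dist(32, 1L),
                immune = point_dist(32, c(1L, 0L)), generation = 0L)
  nxt <- immune_generation(state, scn)
  # below/below branch at the start: rho_P = 6, beta_P = 0.96 ... wait,
  # P-bar = 1 > T_P = 0.5 so the immune side is on the "seen" branch
  expect_equal(nxt$active_params$pathogen$branch, "below")
  expect_equal(nxt$active_params$immune$branch, "above")
  pp <- single_type_params(scn$alpha_P, 0.96, 6, 32)
  expect_dist_equal(nxt$pathogen,
                    brute_sel_single(brute_mult_single(state$pathogen, pp), 0.96))
  ip <- two_type_params(0.1, 0.1, 6, 2, 0.95, 0.93, 0.50, 0.50, 32)
  expect_dist_equal(nxt$immune,
                    brute_sel_two(brute_mult_two(state$immune, ip), ip))
})

test_that("an unseen pathogen leaves the immune side on the dormant branch", {
  scn <- fig9_scenario_fixture()
  state <- list(pathogen = point_dist(32, 0L),
                immune = point_dist(32, c(1L, 1L)), generation = 0L)
  nxt <- immune_generation(state, scn)
  expect_equal(nxt$active_params$immune$branch, "below")
  expect_equal(nxt$active_params$immune$eps_ME, 0.01)  # memory decays slowly
  expect_equal(extinction_mass(nxt$pathogen), 1)       # absorbing
  # global extinction is absorbing
  dead <- list(pathogen = point_dist(32, 0L),
               immune = point_dist(32, c(0L, 0L)), generation = 0L)
  nxt2 <- immune_generation(dead, scn)
  expect_equal(extinction_mass(nxt2$immune), 1)
})

test_that("logged branch flags replay deterministically from logged means", {
  scn <- fig9_scenario_fixture()
  run <- run_immune(scn, 40, keep = "none")
  tr <- tidy(run)
  for (i in 2:nrow(tr)) {
    res <- resolve_parameters(tr$p_mean[i - 1], tr$e_mean[i - 1],
                              scn$pathogen_rule, scn$immune_rule)
    expect_equal(res$pathogen$branch, tr$pathogen_branch[i])
    expect_equal(res$immune$branch, tr$immune_branch[i])
  }
  expect_true(all(diff(tr$w0_pathogen) >= -1e-12))  # no reinfection events
})

test_that("the chronic configuration differs from the clearance one only in the documented overrides", {
  f9 <- load_scenario("fig9")$scenario
  f10 <- load_scenario("fig10")$scenario
  expect_equal(f10$pathogen_rule$above$beta_P, 0.75)
  expect_equal(f10$immune_rule$threshold, 1.5)
  expect_equal(f10$immune_rule$below$beta_E, 0.85)
  expect_equal(f10$immune_rule$above$beta_E, 0.90)
  # revert the overrides and the configs must be identical
  f10$pathogen_rule$above$beta_P <- f9$pathogen_rule$above$beta_P
  f10$immune_rule$threshold <- f9$immune_rule$threshold
  f10$immune_rule$below$beta_E <- f9$immune_rule$below$beta_E
  f10$immune_rule$above$beta_E <- f9$immune_rule$above$beta_E
  expect_identical(f10, f9)
})

test_that("reinfection shifts the pathogen distribution up by one", {
  scn <- fig9_scenario_fixture()
  base <- run_immune(scn, 6, keep = "none")
  re <- run_immune(scn, 6, reinfect_at = 4L, keep = "none")
  trb <- tidy(base); trr <- tidy(re)
  expect_equal(trr$p_mean[1:3], trb$p_mean[1:3])
  expect_gt(trr$p_mean[5], trb$p_mean[5])
  # a reinfection event may revive an extinct line: w0 can drop there
  expect_lt(trr$w0_pathogen[5], trb$w0_pathogen[5])
})

test_that("zero-pathogen start keeps the pathogen extinct throughout", {
  scn <- fig9_scenario_fixture()
  scn$init_P <- 0L
  run <- run_immune(scn, 10, keep = "none")
  tr <- tidy(run)
  expect_true(all(tr$w0_pathogen == 1))
  expect_true(all(tr$immune_branch[-1] == "below"))
})
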