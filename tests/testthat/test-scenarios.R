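test_that("every builtin scenario loads, validates and runs a few generations", {
  for (nm in list_scenarios()) {
    cfg <- load_scenario(nm)
    expect_s3_class(cfg, "gw_scenario_config")
    run <- run_scenario(cfg, generations = 2, keep = "none")
    tr <- tidy(run)
    expect_gt(nrow(tr), 1)
    w0_col <- intersect(c("w0", "w0_pathogen"), names(tr))[1]
    expect_true(all(tr[[w0_col]] >= 0 & tr[[w0_col]] <= 1))
  }
})

test_that("the published single-type parameter sets are encoded as printed", {
  f3 <- load_scenario("fig3")$scenario
  expect_equal(f3[c("alpha", "beta", "rho", "n_max")],
               list(alpha = 1, beta = 2 / 3, rho = 2L, n_max = 128L))
  f4 <- load_scenario("fig4")$scenario
  expect_equal(f4[c("alpha", "beta", "rho", "n_max")],
               list(alpha = 0.1, beta = 0.9664, rho = 2L, n_max = 128L))
  f7 <- load_scenario("fig7")$scenario
  expect_equal(f7[c("rho_A", "rho_B", "eps_AB", "eps_BA", "beta_A")],
               list(rho_A = 3L, rho_B = 6L, eps_AB = 0.01, eps_BA = 0.001,
                    beta_A = 0.95))
})

test_that("invalid configurations raise descriptive validation errors", {
  expect_error(load_scenario("fig99"), "unknown scenario")
  expect_error(single_type_params(1.2, 0.5, 2, 16), "probability")
  expect_error(single_type_params(0.5, 0.5, 0, 16), "positive integer")
  expect_error(two_type_params(0.1, 0.1, 3, 6, 0.95, 1.2, 0.01, 0.001, 32),
               "beta_B")
  expect_error(coupling_rule(1.5, below = list(a = 1), above = list(b = 2)),
               "same parameters")
  expect_error(maturation_schedule(list(list(from = 5, params = NULL))),
               "start at 0")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("kind: single", "alpha: 0.5", "beta: 0.5", "rho: 2",
               "n_max: 16", "bogus_key: 1"), path)
  expect_error(load_scenario(path), "unknown key")
})

test_that("YAML and JSON configs round into validated scenarios", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("kind: single", "name: custom", "generations: 12",
               "alpha: 0.25", "beta: 0.9", "rho: 3", "n_max: 24"), path)
  cfg <- load_scenario(path)
  expect_equal(cfg$kind, "single")
  expect_equal(cfg$generations, 12)
  expect_equal(cfg$scenario$rho, 3L)
  jpath <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "immune", n_max = 8,
                            alpha_P = 0.1, alpha_E = 0.1, alpha_M = 0.1,
    pathogen_rule = list(threshold = 1.5,
                         below = list(rho_P = 6, beta_P = 0.96),
                         above = list(rho_P = 2, beta_P = 0.65)),
    immune_rule = list(threshold = 0.5,
      below = list(rho_E = 2, rho_M = 2, eps_EM = 0.5, eps_ME = 0.01,
                   beta_E = 0.9, beta_M = 0.93),
      above = list(rho_E = 6, rho_M = 2, eps_EM = 0.5, eps_ME = 0.5,
                   beta_E = 0.95, beta_M = 0.93))),
    jpath, auto_unbox = TRUE)
  cfg2 <- load_scenario(jpath)
  expect_s3_class(cfg2$scenario, "gw_immune_scenario")
  run <- run_immune(cfg2$scenario, 3, keep = "none")
  expect_equal(nrow(tidy(run)), 4L)
})

test_that("trajectory output round-trips through the TSV writer", {
  run <- run_single(single_type_params(0.5, 0.8, 2, 16), 4, keep = "all")
  out <- tempfile()
  write_trajectory(run, out, dump_distributions = TRUE, seed = 7)
  tr <- read_trajectory(file.path(out, "trajectory.tsv"))
  expect_equal(nrow(tr), nrow(tidy(run)))
  expect_equal(tr$mean, tidy(run)$mean)
  mf <- jsonlite::read_json(file.path(out, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$kind, "single")
  expect_equal(mf$seed, 7)
  expect_equal(mf$config$alpha, 0.5)
  dumps <- list.files(file.path(out, "distributions"), full.names = TRUE)
  expect_equal(length(dumps), 9L)
  back <- read_dist_tsv(dumps[9])
  expect_identical(back$probs, run$distributions[[9]]$probs)
  # final-state distribution written at 17 significant digits
  expect_lt(tv_distance(back, run$final), 1e-16)
})

test_that("runs expose tidy, glance and plot surfaces", {
  run <- run_immune(fig9_scenario_fixture(), 5, keep = "none")
  g <- glance(run)
  expect_equal(g$kind, "immune")
  expect_true(all(c("final_p_mean", "final_w0_pathogen") %in% names(g)))
  plt <- ggplot2::ggplot_build(autoplot(run))
  expect_gt(nrow(plt$data[[1]]), 0)
  d <- run$final$immune
  plt2 <- ggplot2::ggplot_build(plot_distribution(d))
  expect_gt(nrow(plt2$data[[1]]), 0)
  expect_error(plot_distribution(point_dist(4, c(0L, 0L, 0L, 0L))), "marginal")
})
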