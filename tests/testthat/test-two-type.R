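two_params <- function(...) {
  args <- utils::modifyList(
    list(alpha_A = 0.1, alpha_B = 0.1, rho_A = 3, rho_B = 6,
         beta_A = 0.95, beta_B = 0.95, eps_AB = 0.01, eps_BA = 0.001,
         n_max = 8),
    list(...))
  do.call(two_type_params, args)
}

test_that("a single copy mutates with probability eps", {
  p <- two_params(alpha_A = 1, rho_A = 2, eps_AB = 0.01, n_max = 16)
  d <- multiplication_step_two(point_dist(16, c(1L, 0L)), p)
  expect_equal(d$probs[3, 1], 0.99)
  expect_equal(d$probs[2, 2], 0.01)
  # extinction absorbing
  z <- multiplication_step_two(point_dist(16, c(0L, 0L)), p)
  expect_equal(extinction_mass(z), 1)
})

test_that("multiplication matches the literal quadruple sum with masked terms", {
  set.seed(23)
  raw <- matrix(stats::runif(81), 9, 9)
  raw[outer(0:8, 0:8, `+`) > 8] <- 0
  d <- gw_dist(raw / sum(raw), 8)
  for (p in list(two_params(),                        # cut-off active regime
                 two_params(eps_AB = 0.3, eps_BA = 0.2),
                 two_params(rho_A = 2, rho_B = 2, n_max = 8),
                 two_params(alpha_A = 0.9, alpha_B = 0.7, eps_AB = 0))) {
    expect_dist_equal(multiplication_step_two(d, p), brute_mult_two(d, p))
  }
})

test_that("selection matches the literal thinning convolution", {
  set.seed(29)
  raw <- matrix(stats::runif(49), 7, 7)
  raw[outer(0:6, 0:6, `+`) > 6] <- 0
  d <- gw_dist(raw / sum(raw), 6)
  p <- two_params(beta_A = 2 / 3, beta_B = 0.4, n_max = 6)
  expect_dist_equal(selection_step_two(d, p), brute_sel_two(d, p))
  # printed example: two A individuals, beta_A = 2/3
  d2 <- selection_step_two(point_dist(6, c(2L, 0L)), p)
  expect_equal(d2$probs[1:3, 1], c(1 / 9, 4 / 9, 4 / 9))
  # certain survival; certain death of B
  p1 <- two_params(beta_A = 1, beta_B = 1, n_max = 6)
  expect_dist_equal(selection_step_two(d, p1), d)
  p0 <- two_params(beta_A = 1, beta_B = 0, n_max = 6)
  d3 <- selection_step_two(point_dist(6, c(1L, 1L)), p0)
  expect_equal(d3$probs[2, 1], 1)
})

test_that("with no mutation the types decouple into single-type factors", {
  pa <- single_type_params(0.3, 0.9, 2, 40)
  pb <- single_type_params(0.6, 0.8, 2, 40)
  p2 <- two_type_params(0.3, 0.6, 2, 2, 0.9, 0.8, 0, 0, 40)
  # product-form input far from the cut-off stays product-form
  da <- selection_step(multiplication_step(point_dist(40, 2L), pa), pa)
  db <- selection_step(multiplication_step(point_dist(40, 1L), pb), pb)
  joint <- multiplication_step_two(point_dist(40, c(2L, 1L)), p2)
  joint <- selection_step_two(joint, p2)
  expect_lt(max(abs(joint$probs - outer(as.vector(da$probs),
                                        as.vector(db$probs)))), 1e-12)
  # and B never appears from a pure-A start
  r <- run_two_type(p2, 5, keep = "last")
  expect_equal(dist_mean(marginal(r$final, 2)), 0)
})

test_that("symmetric parameters give an exchange-symmetric law", {
  p <- two_type_params(0.2, 0.2, 3, 3, 0.9, 0.9, 0.05, 0.05, 10)
  init <- gw_dist({
    m <- matrix(0, 11, 11); m[2, 2] <- 1; m
  }, 10)
  state <- init
  for (n in 1:6) {
    state <- selection_step_two(multiplication_step_two(state, p), p)
    expect_lt(max(abs(state$probs - t(state$probs))), 1e-12)
  }
})

test_that("the mutant with the larger multiplication factor takes over", {
  p7 <- two_type_params(0.1, 0.1, 3, 6, 0.95, 0.95, 0.01, 0.001, 32)
  run <- run_two_type(p7, 120, keep = "none")
  tr <- dplyr::filter(tidy(run), phase == "S")
  expect_true(all(diff(tr$w0) >= -1e-12))
  last <- dplyr::slice_tail(tr, n = 1)
  expect_gt(last$mean_B, last$mean_A)
})

test_that("two-species comparator reduces to the logistic closed form", {
  # no second species: N_A follows the logistic solution
  out <- two_species_ode(Ra = 0.2, Rb = 0.5, K = 30, NA0 = 1, NB0 = 0,
                         times = seq(0, 60, by = 1))
  expect_equal(out$N_B, rep(0, 61))
  expect_equal(out$N_A, logistic_solution(0.2, 30, 1, out$time),
               tolerance = 1e-6)
  # empty system stays empty
  z <- two_species_ode(0.2, 0.5, 30, 0, 0, times = 0:10)
  expect_true(all(z$N_A == 0 & z$N_B == 0))
})
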