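test_that("multiplication phase matches its direct binomial form", {
  # deterministic doubling (discrete limit)
  p <- single_type_params(1, 2 / 3, 2, 128)
  d <- multiplication_step(point_dist(128, 1L), p)
  expect_equal(dist_mean(d), 2)
  expect_equal(d$probs[3], 1)
  # continuous limit: one parent, one slot
  p2 <- single_type_params(0.1, 0.9664, 2, 128)
  d2 <- multiplication_step(point_dist(128, 1L), p2)
  expect_equal(d2$probs[2], 0.9)
  expect_equal(d2$probs[3], 0.1)
  # cut-off truncates the slots: mu = min(140, 128)
  d3 <- multiplication_step(point_dist(128, 70L), p)
  expect_equal(d3$probs[129], 1)
  # alpha = 0 leaves any distribution unchanged
  start <- selection_step(d2, p2)
  p0 <- single_type_params(0, 0.5, 2, 128)
  expect_dist_equal(multiplication_step(start, p0), start)
  expect_error(multiplication_step(point_dist(16, 1L), p), "n_max")
})

test_that("selection phase is exact binomial thinning", {
  p <- single_type_params(1, 2 / 3, 2, 8)
  d <- selection_step(point_dist(8, 2L), p)
  expect_equal(as.vector(d$probs)[1:3], c(1 / 9, 4 / 9, 4 / 9))
  # certain survival is the identity
  p1 <- single_type_params(0.5, 1, 2, 8)
  dd <- multiplication_step(point_dist(8, 2L), p1)
  expect_dist_equal(selection_step(dd, p1), dd)
  # extinction is absorbing
  expect_equal(extinction_mass(selection_step(point_dist(8, 0L), p)), 1)
})

test_that("phases agree with the literal convolution sums", {
  set.seed(11)
  for (rep in 1:5) {
    p <- single_type_params(stats::runif(1), stats::runif(1),
                            sample(2:4, 1), 10)
    raw <- stats::runif(11)
    d <- gw_dist(raw / sum(raw), 10)
    expect_dist_equal(multiplication_step(d, p), brute_mult_single(d, p))
    expect_dist_equal(selection_step(d, p), brute_sel_single(d, p$beta))
  }
})

test_that("a full generation matches per-slot exhaustive enumeration", {
  for (cfg in list(list(a = 0.3, b = 0.6, N = 2, nm = 12),
                   list(a = 0.9, b = 0.2, N = 3, nm = 12),
                   list(a = 0.5, b = 0.5, N = 3, nm = 4))) {  # active cut-off
    p <- single_type_params(cfg$a, cfg$b, 2, cfg$nm)
    got <- selection_step(multiplication_step(point_dist(cfg$nm, cfg$N), p), p)
    expect_dist_equal(got, enum_generation_single(cfg$N, p))
  }
})

test_that("PGF coefficients reproduce the closed product form", {
  # G_N(s) = (1-b+bs)^N (1-ab+abs)^N away from the cut-off
  set.seed(5)
  for (rep in 1:6) {
    alpha <- stats::runif(1); beta <- stats::runif(1)
    N <- sample(1:6, 1)
    p <- single_type_params(alpha, beta, 2, 12)
    g <- one_generation_pgf(N, p)
    expect_equal(sum(g$coeffs), 1, tolerance = 1e-12)
    for (s in c(0, 0.3, 0.7, 1)) {
      closed <- ((1 - beta + beta * s) * (1 - alpha * beta + alpha * beta * s))^N
      expect_equal(pgf_eval(g, s), closed, tolerance = 1e-12)
    }
    # one generation of the phase operators equals the PGF coefficients
    gen <- selection_step(multiplication_step(point_dist(12, N), p), p)
    expect_dist_equal(gen, gw_dist(g$coeffs, 12))
  }
  expect_equal(pgf_eval(one_generation_pgf(1, single_type_params(1, 2/3, 2, 8)), 0),
               1 / 9)
  expect_error(one_generation_pgf(5, single_type_params(1, 2/3, 2, 8)),
               "cut-off")
  expect_error(one_generation_pgf(1, single_type_params(1, 2/3, 3, 8)),
               "rho = 2")
})

test_that("mean growth follows beta * (1 + alpha * (rho - 1)) below the cut-off", {
  for (cfg in list(c(1, 2 / 3, 2), c(0.1, 0.9664, 2), c(0.4, 0.8, 3))) {
    p <- single_type_params(cfg[1], cfg[2], cfg[3], 2048)
    r <- cfg[2] * (1 + cfg[1] * (cfg[3] - 1))
    run <- run_single(p, 6, keep = "none")
    tr <- dplyr::filter(tidy(run), phase == "S")
    expect_equal(tr$mean, r^(0:6), tolerance = 1e-9)
  }
})

test_that("extinction probability is non-decreasing and the discrete limit grows like r^n", {
  p <- single_type_params(1, 2 / 3, 2, 128)
  run <- run_single(p, 12, keep = "none")
  tr <- dplyr::filter(tidy(run), phase == "S")
  expect_true(all(diff(tr$w0) >= -1e-12))
  expect_equal(tr$mean[1:8], (4 / 3)^(0:7), tolerance = 1e-9)
  # continuous limit saturates with a rising extinction mass
  p4 <- single_type_params(0.1, 0.9664, 2, 128)
  run4 <- run_single(p4, 150, keep = "none")
  tr4 <- dplyr::filter(tidy(run4), phase == "S")
  expect_true(all(diff(tr4$w0) >= -1e-12))
  expect_gt(tr4$mean[151], 60)            # saturation near K
  expect_lt(tr4$mean[151], 128)
  expect_gt(tr4$w0[151], 0.3)             # substantial extinction mass
  expect_lt(abs(tr4$mean[151] - tr4$mean[141]), 0.5)  # plateau
})

test_that("run records both phases and honors a custom initial state", {
  p <- single_type_params(0.5, 0.8, 2, 16)
  init <- gw_dist(c(0.5, 0, 0.5, rep(0, 14)), 16)
  run <- run_single(p, 3, initial = init, keep = "all")
  tr <- tidy(run)
  expect_equal(nrow(tr), 7L)
  expect_equal(tr$phase, c("S", rep(c("M", "S"), 3)))
  expect_equal(tr$mean[1], 1)
  expect_length(run$distributions, 7L)
  expect_equal(glance(run)$final_w0, tr$w0[7])
})
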