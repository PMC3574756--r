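# Independent brute-force oracles. These deliberately follow the literal
# nested-sum form of the one-generation convolutions (with out-of-range
# binomial terms masked to zero), not the kernel/transition-matrix
# organization of the package internals, so the two routes check each other.

expect_dist_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a$probs), dim(b$probs))
  expect_lt(max(abs(a$probs - b$probs)), tol)
}

# single-type multiplication, literal convolution of the binomial kernel
brute_mult_single <- function(dist, params) {
  n_max <- params$n_max
  w <- as.vector(dist$probs)
  out <- numeric(n_max + 1)
  for (v in 0:n_max) {
    acc <- 0
    for (N in 0:n_max) {
      mu <- min(params$rho * N, n_max)
      acc <- acc + safe_binomial_pmf(v - N, mu - N, params$alpha) * w[N + 1]
    }
    out[v + 1] <- acc
  }
  gw_dist(out, n_max)
}

# single-type selection, literal binomial thinning sum
brute_sel_single <- function(dist, beta) {
  n_max <- dist$n_max
  w <- as.vector(dist$probs)
  out <- numeric(n_max + 1)
  for (N in 0:n_max) {
    out[N + 1] <- sum(safe_binomial_pmf(N, 0:n_max, beta) * w)
  }
  gw_dist(out, n_max)
}

# one full single-type generation from a point mass, by exhaustive
# enumeration of every per-slot copy outcome and per-individual survival
# outcome (2^slots * 2^v paths) -- fully independent of the binomial pmf
enum_generation_single <- function(N0, params) {
  n_max <- params$n_max
  out <- numeric(n_max + 1)
  mu <- min(params$rho * N0, n_max)
  slots <- mu - N0
  copy_grid <- expand.grid(rep(list(0:1), slots))
  if (slots == 0) copy_grid <- data.frame(row.names = 1)
  for (i in seq_len(nrow(copy_grid))) {
    copies <- if (slots) sum(copy_grid[i, ]) else 0
    p_copy <- params$alpha^copies * (1 - params$alpha)^(slots - copies)
    v <- N0 + copies
    surv_grid <- expand.grid(rep(list(0:1), v))
    if (v == 0) surv_grid <- data.frame(row.names = 1)
    for (j in seq_len(nrow(surv_grid))) {
      s <- if (v) sum(surv_grid[j, ]) else 0
      p_surv <- params$beta^s * (1 - params$beta)^(v - s)
      out[s + 1] <- out[s + 1] + p_copy * p_surv
    }
  }
  gw_dist(out, n_max)
}

# two-type multiplication phase: the literal quadruple sum with the two
# dependent indices and masked binomial factors
brute_mult_two <- function(dist, params) {
  n_max <- params$n_max
  out <- matrix(0, n_max + 1, n_max + 1)
  for (NA_ in 0:n_max) for (NB_ in 0:(n_max - NA_)) {
    wp <- dist$probs[NA_ + 1, NB_ + 1]
    if (wp == 0) next
    caps <- cutoff_capacities(c(NA_, NB_), c(params$rho_A, params$rho_B),
                              n_max)
    for (ci in seq_along(caps$weight)) {
      muA <- caps$mu[ci, 1]; muB <- caps$mu[ci, 2]
      wgt <- caps$weight[ci] * wp
      for (vA in 0:n_max) for (vB in 0:(n_max - vA)) {
        acc <- 0
        for (kA in 0:(muA - NA_)) for (kAB in 0:(muA - kA - NA_)) {
          kB <- muA + muB - vA - vB - kA
          kBA <- vA + kAB + kA - muA
          acc <- acc +
            safe_binomial_pmf(kA, muA - NA_, 1 - params$alpha_A) *
            safe_binomial_pmf(kAB, muA - kA - NA_, params$eps_AB) *
            safe_binomial_pmf(kB, muB - NB_, 1 - params$alpha_B) *
            safe_binomial_pmf(kBA, muB - kB - NB_, params$eps_BA)
        }
        out[vA + 1, vB + 1] <- out[vA + 1, vB + 1] + wgt * acc
      }
    }
  }
  gw_dist(out, n_max)
}

# two-type selection phase, literal double convolution
brute_sel_two <- function(dist, params) {
  n_max <- dist$n_max
  out <- matrix(0, n_max + 1, n_max + 1)
  for (NA_ in 0:n_max) for (NB_ in 0:(n_max - NA_)) {
    acc <- 0
    for (vA in NA_:n_max) for (vB in NB_:(n_max - vA)) {
      acc <- acc + dist$probs[vA + 1, vB + 1] *
        safe_binomial_pmf(NA_, vA, params$beta_A) *
        safe_binomial_pmf(NB_, vB, params$beta_B)
    }
    out[NA_ + 1, NB_ + 1] <- acc
  }
  gw_dist(out, n_max)
}

# maturation multiplication from a point-mass parent state, by exhaustive
# enumeration of every naive slot's outcome (empty / stay / one of three
# fates, per fate ordering) and every downstream slot's outcome
enum_mult_maturation <- function(N0, params) {
  n_max <- params$n_max
  out <- array(0, dim = rep(n_max + 1, 4))
  caps <- cutoff_capacities(N0, params$rho, n_max)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (ci in seq_along(caps$weight)) {
    slots <- caps$mu[ci, ] - N0
    # downstream slot outcomes: 0/1 copy each
    down_grids <- lapply(slots[2:4], function(s) {
      if (s == 0) matrix(0, 1, 0) else as.matrix(expand.grid(rep(list(0:1), s)))
    })
    for (perm in perms) {
      # per-slot outcome for naive: 0 empty, 1 stay, 2/3/4 fate by ordering
      eps_o <- params$eps[perm]
      p_slot <- c(1 - params$alpha[1],
                  params$alpha[1] * prod(1 - eps_o),
                  params$alpha[1] * eps_o[1],
                  params$alpha[1] * (1 - eps_o[1]) * eps_o[2],
                  params$alpha[1] * prod(1 - eps_o[1:2]) * eps_o[3])
    naive_grid <- if (slots[1] == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(0:4), slots[1])))
      for (i in seq_len(nrow(naive_grid))) {
        oc <- naive_grid[i, ]
        p_n <- prod(p_slot[oc + 1])
        fates <- integer(3)
        for (f in 1:3) fates[perm[f]] <- sum(oc == f + 1)
        stay <- sum(oc == 1)
        for (g2 in seq_len(nrow(down_grids[[1]]))) {
          c2 <- sum(down_grids[[1]][g2, ])
          p2 <- params$alpha[2]^c2 * (1 - params$alpha[2])^(slots[2] - c2)
          for (g3 in seq_len(nrow(down_grids[[2]]))) {
            c3 <- sum(down_grids[[2]][g3, ])
            p3 <- params$alpha[3]^c3 * (1 - params$alpha[3])^(slots[3] - c3)
            for (g4 in seq_len(nrow(down_grids[[3]]))) {
              c4 <- sum(down_grids[[3]][g4, ])
              p4 <- params$alpha[4]^c4 * (1 - params$alpha[4])^(slots[4] - c4)
              v <- c(N0[1] + stay,
                     N0[2] + c2 + fates[1],
                     N0[3] + c3 + fates[2],
                     N0[4] + c4 + fates[3])
              out[matrix(v + 1, 1)] <- out[matrix(v + 1, 1)] +
                caps$weight[ci] / 6 * p_n * p2 * p3 * p4
            }
          }
        }
      }
    }
  }
  gw_dist(out, n_max)
}

# the published coupled-model configurations, rebuilt here in full from
# their captions (kept independent of the package's scenario registry)
fig9_scenario_fixture <- function() {
  immune_scenario(
    n_max = 32, alpha_P = 0.1, alpha_E = 0.1, alpha_M = 0.1,
    pathogen_rule = coupling_rule(1.5,
      below = list(rho_P = 6, beta_P = 0.96),
      above = list(rho_P = 2, beta_P = 0.65)),
    immune_rule = coupling_rule(0.5,
      below = list(rho_E = 2, rho_M = 2, eps_EM = 0.50, eps_ME = 0.01,
                   beta_E = 0.90, beta_M = 0.93),
      above = list(rho_E = 6, rho_M = 2, eps_EM = 0.50, eps_ME = 0.50,
                   beta_E = 0.95, beta_M = 0.93)))
}
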