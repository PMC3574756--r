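#' Agent-level Monte-Carlo oracle
#'
#' Samples the identical stochastic rules that the exact recursions
#' propagate — Bernoulli copies per available slot up to the cut-off
#' capacity, Bernoulli mutation/differentiation per realized copy, then
#' Bernoulli survival per individual — one replicate being one agent-level
#' population path. Used as an independent correctness check of the exact
#' distribution propagation: the empirical distribution over many
#' replicates must converge to the exact one.
#'
#' `mc_generation()` advances a matrix of replicate populations by one
#' generation and returns both phases; `mc_ensemble()` runs whole
#' trajectories and returns the empirical post-selection (and optionally
#' post-multiplication) distributions per generation.
#'
#' Where the cut-off allocation has two equidistant lattice candidates, the
#' exact recursion splits mass equally; the sampler draws a fair coin per
#' replicate, so the two semantics coincide.
#'
#' @param pop integer matrix of populations, one row per replicate, one
#'   column per entity type (1, 2 or 4 columns).
#' @param params a `gw_params_single`, `gw_params_two` or
#'   `gw_params_maturation` bundle matching the column count.
#' @return `mc_generation()`: list with `after_mult` and `after_sel`
#'   matrices.
#' @export
mc_generation <- function(pop, params) {
  pop <- as.matrix(pop)
  wm <- mc_multiplication(pop, params)
  ws <- mc_selection(wm, params)
  list(after_mult = wm, after_sel = ws)
}

mc_multiplication <- function(pop, params) {
  UseMethod("mc_multiplication", params)
}

mc_selection <- function(pop, params) {
  beta <- switch(class(params)[1],
                 gw_params_single = params$beta,
                 gw_params_two = c(params$beta_A, params$beta_B),
                 gw_params_maturation = params$beta,
                 stop("unsupported parameter bundle", call. = FALSE))
  out <- pop
  for (j in seq_len(ncol(pop))) {
    out[, j] <- stats::rbinom(nrow(pop), pop[, j], beta[j])
  }
  out
}

#' @export
mc_multiplication.gw_params_single <- function(pop, params) {
  N <- pop[, 1]
  mu <- pmin(params$rho * N, params$n_max)
  cbind(N + stats::rbinom(length(N), mu - N, params$alpha))
}

# capacity draw shared by the multitype samplers: per unique parent state
# compute the exact allocation; equidistant ties pick uniformly per replicate
mc_capacities <- function(pop, rho, n_max) {
  key <- apply(pop, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  alloc <- lapply(which(uniq), function(i)
    cutoff_capacities(pop[i, ], rho, n_max))
  names(alloc) <- key[uniq]
  mu <- matrix(0, nrow(pop), ncol(pop))
  for (k in names(alloc)) {
    rows <- which(key == k)
    a <- alloc[[k]]
    if (length(a$weight) == 1L) {
      mu[rows, ] <- matrix(a$mu, length(rows), ncol(pop), byrow = TRUE)
    } else {
      pick <- sample.int(length(a$weight), length(rows), replace = TRUE,
                         prob = a$weight)
      mu[rows, ] <- a$mu[pick, , drop = FALSE]
    }
  }
  mu
}

#' @export
mc_multiplication.gw_params_two <- function(pop, params) {
  n <- nrow(pop)
  mu <- mc_capacities(pop, c(params$rho_A, params$rho_B), params$n_max)
  cA <- stats::rbinom(n, mu[, 1] - pop[, 1], params$alpha_A)
  cB <- stats::rbinom(n, mu[, 2] - pop[, 2], params$alpha_B)
  mAB <- stats::rbinom(n, cA, params$eps_AB)
  mBA <- stats::rbinom(n, cB, params$eps_BA)
  cbind(pop[, 1] + cA - mAB + mBA,
        pop[, 2] + cB - mBA + mAB)
}

#' @export
mc_multiplication.gw_params_maturation <- function(pop, params) {
  n <- nrow(pop)
  mu <- mc_capacities(pop, params$rho, params$n_max)
  slots <- mu - pop
  copies <- matrix(0L, n, 4L)
  for (j in 1:4) {
    copies[, j] <- stats::rbinom(n, slots[, j], params$alpha[j])
  }
  # each replicate draws one of the six fate orderings for its naive copies
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ord <- sample.int(6, n, replace = TRUE)
  diff <- matrix(0L, n, 3L)
  remaining <- copies[, 1]
  for (step in 1:3) {
    for (pi in 1:6) {
      rows <- which(ord == pi)
      if (!length(rows)) next
      fate <- perms[[pi]][step]
      d <- stats::rbinom(length(rows), remaining[rows], params$eps[fate])
      diff[rows, fate] <- diff[rows, fate] + d
      remaining[rows] <- remaining[rows] - d
    }
  }
  cbind(pop[, 1] + remaining,
        pop[, 2] + copies[, 2] + diff[, 1],
        pop[, 3] + copies[, 3] + diff[, 2],
        pop[, 4] + copies[, 4] + diff[, 3])
}

#' @rdname mc_generation
#' @param initial integer vector of initial counts per type (every
#'   replicate starts there).
#' @param generations number of generations.
#' @param replicates number of independent replicates (>= 1).
#' @param seed integer seed for the single RNG stream.
#' @param record which generations' empirical distributions to return
#'   (default all).
#' @return `mc_ensemble()`: list with `after_sel` (named list of empirical
#'   `gw_dist`s per recorded generation) and `after_mult`.
#' @export
mc_ensemble <- function(initial, params, generations, replicates, seed,
                        record = seq_len(generations)) {
  stopifnot(replicates >= 1, generations >= 1)
  set.seed(seed)
  pop <- matrix(rep(as.integer(initial), each = replicates),
                nrow = replicates)
  out_sel <- list(); out_mult <- list()
  for (n in seq_len(generations)) {
    step <- mc_generation(pop, params)
    pop <- step$after_sel
    if (n %in% record) {
      out_mult[[as.character(n)]] <- empirical_dist(step$after_mult,
                                                    params$n_max)
      out_sel[[as.character(n)]] <- empirical_dist(pop, params$n_max)
    }
  }
  list(after_sel = out_sel, after_mult = out_mult)
}

#' Empirical distribution of a replicate population matrix
#'
#' @param pop integer matrix (replicates x types).
#' @param n_max carrying capacity of the resulting `gw_dist`.
#' @return a `gw_dist` of the matching dimensionality.
#' @export
empirical_dist <- function(pop, n_max) {
  pop <- as.matrix(pop)
  nd <- ncol(pop)
  probs <- array(0, dim = rep(n_max + 1L, nd))
  cell <- pop + 1L
  tab <- table(apply(cell, 1, paste, collapse = ","))
  coords <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  probs[coords] <- as.vector(tab) / nrow(pop)
  gw_dist(probs, n_max)
}
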