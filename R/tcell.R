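#' Parameters of the four-type T-lymphocyte maturation process
#'
#' Four cell types share one capacity simplex: naive cells (which
#' self-copy and whose realized copies can differentiate), self-reactive
#' cells, matured-inactivated and matured-activated cells (which only
#' self-copy). Realized naive copies differentiate into the three
#' downstream fates by a sequential-binomial cascade: under a fixed
#' ordering of the fates each remaining undifferentiated copy takes the
#' next fate with its `eps`, and the operator is the average of the six
#' fate orderings with weight 1/6. Selection thins each type independently
#' with its `beta`.
#'
#' @param alpha length-4 copy probabilities
#'   (naive, self, matured-inactivated, matured-activated).
#' @param rho length-4 multiplication factors (positive integers).
#' @param beta length-4 survival probabilities.
#' @param eps length-3 differentiation probabilities of a realized naive
#'   copy (to self, to matured-inactivated, to matured-activated).
#' @param n_max shared carrying capacity.
#' @return a `gw_params_maturation`.
#' @export
maturation_params <- function(alpha, rho, beta, eps, n_max) {
  stopifnot(length(alpha) == 4, length(rho) == 4, length(beta) == 4,
            length(eps) == 3)
  for (x in c(alpha, beta, eps)) {
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  rho <- as.integer(rho)
  if (any(is.na(rho)) || any(rho < 1)) {
    stop("multiplication factors must be positive integers", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), rho = rho,
                 beta = as.numeric(beta), eps = as.numeric(eps),
                 n_max = as.integer(n_max)),
            class = "gw_params_maturation")
}

# Naive-copy kernel: K[i+1, s+1, m+1, a+1] = P(i copies stay naive, (s,m,a)
# copies differentiate to (self, mat->I, mat->A) | slots naive copy slots).
# Mixture with weight 1/6 over the 3! fate orderings of the sequential
# binomial cascade; realized copies are Binomial(slots, alpha).
naive_diff_kernel <- function(slots, alpha, eps) {
  K <- array(0, dim = rep(slots + 1L, 4L))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (perm in perms) {
    for (cc in 0:slots) {
      pc <- stats::dbinom(cc, slots, alpha) / 6
      if (pc == 0) next
      for (m1 in 0:cc) {
        p1 <- pc * stats::dbinom(m1, cc, eps[perm[1]])
        if (p1 == 0) next
        for (m2 in 0:(cc - m1)) {
          p2 <- p1 * stats::dbinom(m2, cc - m1, eps[perm[2]])
          if (p2 == 0) next
          for (m3 in 0:(cc - m1 - m2)) {
            p3 <- p2 * stats::dbinom(m3, cc - m1 - m2, eps[perm[3]])
            if (p3 == 0) next
            m <- integer(3)
            m[perm] <- c(m1, m2, m3)
            i <- cc - m1 - m2 - m3
            K[i + 1L, m[1] + 1L, m[2] + 1L, m[3] + 1L] <-
              K[i + 1L, m[1] + 1L, m[2] + 1L, m[3] + 1L] + p3
          }
        }
      }
    }
  }
  K
}

# Multiplication transition matrix over 4D simplex states; cached per
# parameter bundle (the schedule phases reuse matrices with equal
# alpha/rho/eps).
mult_matrix_4d <- local({
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- paste(c(params$alpha, params$rho, params$eps, params$n_max),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_max <- params$n_max
    idx <- simplex_index(n_max, 4L)
    ns <- idx$n_states
    kern_cache <- new.env(parent = emptyenv())
    naive_kern <- function(slots) {
      k <- as.character(slots)
      if (is.null(kern_cache[[k]])) {
        kern_cache[[k]] <- naive_diff_kernel(slots, params$alpha[1],
                                             params$eps)
      }
      kern_cache[[k]]
    }
    M <- matrix(0, ns, ns)
    dims <- rep(n_max + 1L, 4L)
    for (s in seq_len(ns)) {
      N <- idx$states[s, ]
      caps <- cutoff_capacities(N, params$rho, n_max)
      out <- array(0, dim = dims)
      for (ci in seq_along(caps$weight)) {
        slots <- caps$mu[ci, ] - N
        K <- naive_kern(slots[1])
        v2 <- stats::dbinom(0:slots[2], slots[2], params$alpha[2])
        v3 <- stats::dbinom(0:slots[3], slots[3], params$alpha[3])
        v4 <- stats::dbinom(0:slots[4], slots[4], params$alpha[4])
        block0 <- caps$weight[ci] * (v2 %o% v3 %o% v4)
        nz <- which(K > 0)
        coords <- arrayInd(nz, dim(K)) - 1L
        for (r in seq_len(nrow(coords))) {
          i <- coords[r, 1]; m <- coords[r, 2:4]
          out[N[1] + i + 1L,
              N[2] + m[1] + 0:slots[2] + 1L,
              N[3] + m[2] + 0:slots[3] + 1L,
              N[4] + m[3] + 0:slots[4] + 1L] <-
            out[N[1] + i + 1L,
                N[2] + m[1] + 0:slots[2] + 1L,
                N[3] + m[2] + 0:slots[3] + 1L,
                N[4] + m[3] + 0:slots[4] + 1L] + K[nz[r]] * block0
        }
      }
      M[, s] <- out[idx$cells]
    }
    cache[[key]] <- M
    M
  }
})

#' Four-type maturation phases
#'
#' `maturation_multiplication()` applies the joint copy/differentiation
#' convolution with the shared simplex cut-off (capacity allocated along
#' the demand ray, ties mass-split); `maturation_selection()` thins each of
#' the four types independently with its `beta`.
#'
#' @param dist a 4D `gw_dist`.
#' @param params a [maturation_params()].
#' @return the transformed 4D `gw_dist`.
#' @export
maturation_multiplication <- function(dist, params) {
  check_capacity(dist, params)
  idx <- simplex_index(params$n_max, 4L)
  w <- mult_matrix_4d(params) %*% dist_to_state_vec(dist, idx)
  renormalize_dist(state_vec_to_dist(as.vector(w), idx, params$n_max, 4L))
}

#' @rdname maturation_multiplication
#' @export
maturation_selection <- function(dist, params) {
  check_capacity(dist, params)
  p <- dist$probs
  for (ax in 1:4) {
    p <- contract_axis(p, sel_matrix_1d(params$beta[ax], params$n_max), ax)
  }
  renormalize_dist(structure(list(probs = p, n_max = dist$n_max),
                             class = "gw_dist"))
}

# apply a (k x k) linear map along one axis of a dense array
contract_axis <- function(arr, op, axis) {
  d <- dim(arr)
  perm <- c(axis, seq_along(d)[-axis])
  a <- aperm(arr, perm)
  a <- op %*% matrix(a, nrow = d[axis])
  a <- array(a, dim = d[perm])
  aperm(a, order(perm))
}

#' Maturation schedule
#'
#' A piecewise-constant parameter schedule: each phase holds a
#' [maturation_params()] bundle and applies from its `from` generation
#' (inclusive) up to the next phase's start.
#'
#' @param phases list of `list(from = <generation>, params = <bundle>)`,
#'   ordered, with `from = 0` first.
#' @return a `gw_maturation_schedule`.
#' @export
maturation_schedule <- function(phases) {
  froms <- vapply(phases, function(p) p$from, numeric(1))
  if (froms[1] != 0 || is.unsorted(froms, strictly = TRUE)) {
    stop("schedule phases must start at 0 and have strictly increasing `from`",
         call. = FALSE)
  }
  structure(list(phases = phases), class = "gw_maturation_schedule")
}

schedule_params <- function(schedule, n) {
  froms <- vapply(schedule$phases, function(p) p$from, numeric(1))
  schedule$phases[[max(which(froms <= n))]]$params
}

#' Run the T-lymphocyte maturation process
#'
#' Iterates the four-type multiplication and selection phases from one
#' naive ancestor, switching parameter bundles per the schedule.
#'
#' @param schedule a [maturation_schedule()] or the builtin name
#'   `"fig13"`.
#' @param generations number of generations.
#' @param initial optional 4D `gw_dist` (default: one naive ancestor).
#' @param keep retain per-generation distributions (`"last"`, `"all"`,
#'   `"none"`); 4D arrays are sizeable, default keeps only the final one.
#' @return a `gw_run`; `tidy()` gives per-type means and sds
#'   (`*_naive`, `*_self`, `*_matI`, `*_matA`) and the total extinction
#'   probability `w0`.
#' @export
run_maturation <- function(schedule, generations, initial = NULL,
                           keep = c("last", "all", "none")) {
  keep <- match.arg(keep)
  if (is.character(schedule)) schedule <- load_scenario(schedule)$scenario
  stopifnot(inherits(schedule, "gw_maturation_schedule"), generations >= 1)
  n_max <- schedule$phases[[1]]$params$n_max
  if (is.null(initial)) initial <- point_dist(n_max, c(1L, 0L, 0L, 0L))
  state <- initial
  rows <- vector("list", generations + 1L)
  dists <- if (keep == "all") vector("list", generations + 1L) else NULL
  rows[[1]] <- maturation_traj_row(0L, state)
  if (keep == "all") dists[[1]] <- state
  for (n in seq_len(generations)) {
    prm <- schedule_params(schedule, n)  # phase by generation index
    state <- maturation_multiplication(state, prm)
    state <- maturation_selection(state, prm)
    rows[[n + 1L]] <- maturation_traj_row(n, state)
    if (keep == "all") dists[[n + 1L]] <- state
  }
  new_gw_run(kind = "maturation", trajectory = dplyr::bind_rows(rows),
             final = state, distributions = dists, params = schedule,
             generations = generations)
}

maturation_traj_row <- function(n, dist) {
  m <- dist_mean(dist); s <- dist_sd(dist)
  tibble::tibble(generation = n,
                 mean_naive = m[1], mean_self = m[2],
                 mean_matI = m[3], mean_matA = m[4],
                 sd_naive = s[1], sd_self = s[2],
                 sd_matI = s[3], sd_matA = s[4],
                 w0 = extinction_mass(dist))
}
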