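#' Parameters of the two-type branching process with mutation
#'
#' Initial form A and mutant B multiply on a shared capacity simplex
#' `N_A + N_B <= n_max`. In the multiplication phase each type's copy slots
#' fill independently with probability `alpha_X`; every realized copy of A
#' mutates into B with probability `eps_AB` (and symmetrically B into A with
#' `eps_BA`). Selection thins each type independently with `beta_X`.
#'
#' @param alpha_A,alpha_B copy probabilities.
#' @param rho_A,rho_B multiplication factors (positive integers).
#' @param beta_A,beta_B survival probabilities.
#' @param eps_AB,eps_BA per-copy mutation probabilities.
#' @param n_max shared carrying capacity.
#' @return a `gw_params_two` object.
#' @export
two_type_params <- function(alpha_A, alpha_B, rho_A, rho_B,
                            beta_A, beta_B, eps_AB, eps_BA, n_max) {
  for (nm in c("alpha_A", "alpha_B", "beta_A", "beta_B", "eps_AB", "eps_BA")) {
    check_prob(get(nm), nm)
  }
  rho_A <- as.integer(rho_A); rho_B <- as.integer(rho_B)
  n_max <- as.integer(n_max)
  if (any(is.na(c(rho_A, rho_B))) || rho_A < 1 || rho_B < 1) {
    stop("multiplication factors must be positive integers", call. = FALSE)
  }
  stopifnot(n_max >= 1)
  structure(list(alpha_A = alpha_A, alpha_B = alpha_B,
                 rho_A = rho_A, rho_B = rho_B,
                 beta_A = beta_A, beta_B = beta_B,
                 eps_AB = eps_AB, eps_BA = eps_BA, n_max = n_max),
            class = "gw_params_two")
}

# Per-type copy/mutation kernel: K[i+1, j+1] = P(i copies stay, j copies
# mutate | s slots). Each slot independently is empty (1-alpha), a copy
# that keeps its type (alpha*(1-eps)) or a copy that mutates (alpha*eps),
# so (i, j) is trinomial; built as Binomial(slots, alpha) compounded with
# Binomial(copies, eps).
copy_mut_kernel <- function(slots, alpha, eps) {
  K <- matrix(0, slots + 1L, slots + 1L)
  for (cc in 0:slots) {
    pc <- stats::dbinom(cc, slots, alpha)
    j <- 0:cc
    K[cbind(cc - j + 1L, j + 1L)] <- pc * stats::dbinom(j, cc, eps)
  }
  K
}

# Parent-state -> offspring-state transition matrix for the joint
# multiplication phase, over simplex state ids. Cached per parameter bundle.
mult_matrix_2d <- local({
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- paste(unlist(params), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_max <- params$n_max
    idx <- simplex_index(n_max, 2L)
    ns <- idx$n_states
    M <- matrix(0, ns, ns)
    for (s in seq_len(ns)) {
      NA_ <- idx$states[s, 1]; NB_ <- idx$states[s, 2]
      caps <- cutoff_capacities(c(NA_, NB_), c(params$rho_A, params$rho_B),
                                n_max)
      out <- matrix(0, n_max + 1L, n_max + 1L)
      for (ci in seq_along(caps$weight)) {
        sA <- caps$mu[ci, 1] - NA_
        sB <- caps$mu[ci, 2] - NB_
        KA <- copy_mut_kernel(sA, params$alpha_A, params$eps_AB)
        KBt <- t(copy_mut_kernel(sB, params$alpha_B, params$eps_BA))
        w <- caps$weight[ci]
        # offspring: vA = NA + iA + jB, vB = NB + jA + iB
        for (iA in 0:sA) for (jA in 0:(sA - iA)) {
          pa <- KA[iA + 1L, jA + 1L]
          if (pa == 0) next
          rows <- NA_ + iA + 0:sB + 1L
          cols <- NB_ + jA + 0:sB + 1L
          out[rows, cols] <- out[rows, cols] + (w * pa) * KBt
        }
      }
      M[, s] <- out[idx$cells]
    }
    cache[[key]] <- M
    M
  }
})

sel_op_2d <- function(dist, beta_A, beta_B) {
  TA <- sel_matrix_1d(beta_A, dist$n_max)
  TB <- sel_matrix_1d(beta_B, dist$n_max)
  probs <- TA %*% dist$probs %*% t(TB)
  renormalize_dist(structure(list(probs = as.array(probs), n_max = dist$n_max),
                             class = "gw_dist"))
}

#' Two-type multiplication and selection phases
#'
#' Exact one-phase updates of the joint distribution `W(N_A, N_B)`.
#' `multiplication_step_two()` applies the copy/mutation convolution with
#' the joint cut-off (capacity allocated along the demand ray when
#' `rho_A*N_A + rho_B*N_B > n_max`, equidistant ties mass-split);
#' `selection_step_two()` thins each type independently.
#'
#' @param dist a 2D `gw_dist`.
#' @param params a [two_type_params()] bundle.
#' @return the transformed 2D `gw_dist`.
#' @export
multiplication_step_two <- function(dist, params) {
  check_capacity(dist, params)
  idx <- simplex_index(params$n_max, 2L)
  w <- mult_matrix_2d(params) %*% dist_to_state_vec(dist, idx)
  renormalize_dist(state_vec_to_dist(as.vector(w), idx, params$n_max, 2L))
}

#' @rdname multiplication_step_two
#' @export
selection_step_two <- function(dist, params) {
  check_capacity(dist, params)
  sel_op_2d(dist, params$beta_A, params$beta_B)
}

#' Run the two-type mutation process
#'
#' Starts from one ancestor of the initial form A (point mass at `(1, 0)`)
#' unless `initial` is given, and alternates joint multiplication and
#' selection. The trajectory records per-type unconditional means and
#' standard deviations and the total extinction probability `W(0, 0)`.
#'
#' @inheritParams run_single
#' @param params a [two_type_params()] bundle.
#' @param initial optional initial 2D `gw_dist`.
#' @return a `gw_run`; `tidy()` gives columns `generation`, `phase`,
#'   `mean_A`, `mean_B`, `sd_A`, `sd_B`, `w0`.
#' @export
run_two_type <- function(params, generations, initial = NULL,
                         keep = c("last", "all", "none")) {
  keep <- match.arg(keep)
  stopifnot(generations >= 1)
  if (is.null(initial)) initial <- point_dist(params$n_max, c(1L, 0L))
  check_capacity(initial, params)
  idx <- simplex_index(params$n_max, 2L)
  M <- mult_matrix_2d(params)
  state <- initial
  rows <- vector("list", 2L * generations + 1L)
  dists <- if (keep == "all") vector("list", 2L * generations + 1L) else NULL
  rows[[1]] <- traj_row_2d(0L, "S", state)
  if (keep == "all") dists[[1]] <- state
  for (n in seq_len(generations)) {
    wm <- renormalize_dist(state_vec_to_dist(
      as.vector(M %*% dist_to_state_vec(state, idx)), idx, params$n_max, 2L))
    state <- sel_op_2d(wm, params$beta_A, params$beta_B)
    rows[[2L * n]] <- traj_row_2d(n, "M", wm)
    rows[[2L * n + 1L]] <- traj_row_2d(n, "S", state)
    if (keep == "all") {
      dists[[2L * n]] <- wm
      dists[[2L * n + 1L]] <- state
    }
  }
  new_gw_run(kind = "twotype",
             trajectory = dplyr::bind_rows(rows),
             final = state, distributions = dists,
             params = params, generations = generations)
}

traj_row_2d <- function(n, phase, dist, prefix = c("A", "B")) {
  m <- dist_mean(dist); s <- dist_sd(dist)
  out <- tibble::tibble(generation = n, phase = phase)
  out[[paste0("mean_", prefix[1])]] <- m[1]
  out[[paste0("mean_", prefix[2])]] <- m[2]
  out[[paste0("sd_", prefix[1])]] <- s[1]
  out[[paste0("sd_", prefix[2])]] <- s[2]
  out$w0 <- extinction_mass(dist)
  out
}
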