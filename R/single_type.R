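#' Parameters of the single-type multiplication/selection process
#'
#' One Darwinian entity per generation goes through a multiplication phase
#' (each of the `mu - N` available copy slots fills independently with
#' probability `alpha`, where `mu = min(rho * N, n_max)` is the capacity
#' under the nutrient cut-off) and a selection phase (each individual
#' survives independently with probability `beta`).
#'
#' @param alpha copy probability in `[0, 1]`.
#' @param beta survival probability in `[0, 1]`.
#' @param rho multiplication factor (positive integer).
#' @param n_max carrying capacity (positive integer).
#' @return a `gw_params_single` object.
#' @examples
#' single_type_params(alpha = 1, beta = 2/3, rho = 2, n_max = 128)
#' @export
single_type_params <- function(alpha, beta, rho, n_max) {
  check_prob(alpha, "alpha"); check_prob(beta, "beta")
  rho <- as.integer(rho); n_max <- as.integer(n_max)
  if (is.na(rho) || rho < 1) stop("`rho` must be a positive integer", call. = FALSE)
  if (is.na(n_max) || n_max < 1) stop("`n_max` must be a positive integer", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, rho = rho, n_max = n_max),
            class = "gw_params_single")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# One-generation linear operators. M[v+1, N+1] = P(v offspring-state | N
# parents) for the multiplication phase; S[N+1, v+1] = P(N survivors | v)
# for selection. Both are column-stochastic by construction.
mult_matrix_1d <- function(params) {
  n_max <- params$n_max
  M <- matrix(0, n_max + 1L, n_max + 1L)
  for (N in 0:n_max) {
    mu <- min(params$rho * N, n_max)
    v <- N:mu
    M[v + 1L, N + 1L] <- stats::dbinom(v - N, mu - N, params$alpha)
  }
  M
}

sel_matrix_1d <- function(beta, n_max) {
  S <- matrix(0, n_max + 1L, n_max + 1L)
  for (v in 0:n_max) S[0:v + 1L, v + 1L] <- stats::dbinom(0:v, v, beta)
  S
}

#' Single-type multiplication and selection phases
#'
#' `multiplication_step()` maps the end-of-selection distribution
#' `W(N)` to the post-multiplication distribution `W(v)`: from `N` parents,
#' `v - N` of the `mu - N` copy slots fill independently with probability
#' `alpha`, with capacity `mu = min(rho * N, n_max)`. `selection_step()`
#' thins binomially: each individual survives with probability `beta`.
#'
#' @param dist a 1D `gw_dist` with `n_max` matching `params`.
#' @param params a [single_type_params()] bundle.
#' @return the transformed 1D `gw_dist`.
#' @export
multiplication_step <- function(dist, params) {
  check_capacity(dist, params)
  apply_op_1d(dist, mult_matrix_1d(params))
}

#' @rdname multiplication_step
#' @export
selection_step <- function(dist, params) {
  check_capacity(dist, params)
  apply_op_1d(dist, sel_matrix_1d(params$beta, params$n_max))
}

check_capacity <- function(dist, params) {
  if (dist$n_max != params$n_max) {
    stop("distribution and parameter capacities (n_max) disagree", call. = FALSE)
  }
}

apply_op_1d <- function(dist, op) {
  out <- as.vector(op %*% as.vector(dist$probs))
  renormalize_dist(structure(list(probs = as.array(out), n_max = dist$n_max),
                             class = "gw_dist"))
}

#' One-generation probability generating function
#'
#' For `rho = 2` and no active cut-off (`2 * N <= n_max`) the composition of
#' one multiplication and one selection phase from exactly `N` parents has
#' the closed-form PGF
#' `G_N(s) = (1 - beta + beta*s)^N * (1 - alpha*beta + alpha*beta*s)^N`:
#' each parent contributes one surviving-original factor and one
#' copy-that-survives factor. `one_generation_pgf()` returns the offspring
#' distribution `P_N(j)` assembled from the literal two-phase convolution;
#' `pgf_eval()` evaluates the polynomial, and `pgf_mean()` its derivative at
#' `s = 1` (the mean offspring number).
#'
#' @param parent_count integer number of parents `N`.
#' @param params a [single_type_params()] bundle with `rho = 2` and
#'   `2 * parent_count <= n_max`.
#' @return a `gw_pgf` object with fields `coeffs` (`P_N(j)`, `j = 0..n_max`)
#'   and `parent_count`.
#' @examples
#' g <- one_generation_pgf(1, single_type_params(1, 2/3, 2, 128))
#' pgf_mean(g)        # rho * beta = 4/3
#' log(pgf_mean(g))   # 0.288
#' @export
one_generation_pgf <- function(parent_count, params) {
  N <- as.integer(parent_count)
  if (params$rho != 2L || params$rho * N > params$n_max) {
    stop("closed-form PGF requires rho = 2 and rho * N <= n_max (no cut-off)",
         call. = FALSE)
  }
  mu <- params$rho * N
  alpha <- params$alpha; beta <- params$beta
  coeffs <- vapply(0:params$n_max, function(j) {
    v <- j:mu
    sum(safe_binomial_pmf(v - N, mu - N, alpha) *
          safe_binomial_pmf(j, v, beta))
  }, numeric(1))
  structure(list(coeffs = coeffs, parent_count = N,
                 alpha = alpha, beta = beta),
            class = "gw_pgf")
}

#' @rdname one_generation_pgf
#' @param pgf a `gw_pgf`.
#' @param s evaluation argument (vectorized).
#' @export
pgf_eval <- function(pgf, s) {
  vapply(s, function(si) sum(pgf$coeffs * si^(seq_along(pgf$coeffs) - 1)),
         numeric(1))
}

#' @rdname one_generation_pgf
#' @export
pgf_mean <- function(pgf) {
  sum((seq_along(pgf$coeffs) - 1) * pgf$coeffs)
}

#' Run the single-type process for a number of generations
#'
#' Starts from one ancestor (`W_0(1) = 1`) unless `initial` is supplied and
#' alternates multiplication and selection, recording both phase
#' distributions each generation together with their unconditional means,
#' standard deviations and extinction probability `W(0)`.
#'
#' @param params a [single_type_params()] bundle.
#' @param generations number of generations to run (>= 1).
#' @param initial optional initial 1D `gw_dist` (default: point mass at 1).
#' @param keep which per-generation distributions to retain: `"all"`,
#'   `"last"` (default) or `"none"`.
#' @return a `gw_run` object; `tidy()` returns the trajectory tibble with
#'   columns `generation`, `phase` (`"M"` or `"S"`), `mean`, `sd`, `w0`.
#' @examples
#' run <- run_single(single_type_params(1, 2/3, 2, 16), generations = 5)
#' tidy(run)
#' @export
run_single <- function(params, generations, initial = NULL,
                       keep = c("last", "all", "none")) {
  keep <- match.arg(keep)
  stopifnot(generations >= 1)
  if (is.null(initial)) initial <- point_dist(params$n_max, 1L)
  check_capacity(initial, params)
  M <- mult_matrix_1d(params)
  S <- sel_matrix_1d(params$beta, params$n_max)
  state <- initial
  rows <- vector("list", 2L * generations + 1L)
  dists <- if (keep == "all") vector("list", 2L * generations + 1L) else NULL
  rows[[1]] <- traj_row_1d(0L, "S", state)
  if (keep == "all") dists[[1]] <- state
  for (n in seq_len(generations)) {
    wm <- apply_op_1d(state, M)
    state <- apply_op_1d(wm, S)
    rows[[2L * n]] <- traj_row_1d(n, "M", wm)
    rows[[2L * n + 1L]] <- traj_row_1d(n, "S", state)
    if (keep == "all") {
      dists[[2L * n]] <- wm
      dists[[2L * n + 1L]] <- state
    }
  }
  new_gw_run(kind = "single",
             trajectory = dplyr::bind_rows(rows),
             final = state,
             distributions = dists,
             params = params, generations = generations)
}

traj_row_1d <- function(n, phase, dist) {
  tibble::tibble(generation = n, phase = phase,
                 mean = dist_mean(dist), sd = dist_sd(dist),
                 w0 = extinction_mass(dist))
}

new_gw_run <- function(kind, trajectory, final, distributions, params,
                       generations, ...) {
  structure(list(kind = kind, trajectory = trajectory, final = final,
                 distributions = distributions, params = params,
                 generations = generations, ...),
            class = "gw_run")
}

#' @export
print.gw_run <- function(x, ...) {
  cat(sprintf("<gw_run> %s model, %d generations\n", x$kind, x$generations))
  last <- dplyr::slice_tail(x$trajectory, n = 1)
  cat("final state:\n")
  print(as.data.frame(last), row.names = FALSE)
  invisible(x)
}
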