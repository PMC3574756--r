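#' Carrying-capacity allocation under the nutrient cut-off
#'
#' Each type demands `rho_i * N_i` slots after multiplication. When the
#' total demand fits under `n_max` every type gets its full demand. When it
#' does not, capacity is allocated along the ray from the origin through the
#' demand vector: the capacities are the lattice point(s) on the hyperplane
#' `sum(mu) = n_max` nearest (Euclidean) to the intersection of that
#' hyperplane with the ray, subject to `N_i <= mu_i <= rho_i * N_i`
#' (existing individuals are never removed, and no type receives more slots
#' than its multiplication factor can use). When two or more lattice points
#' are equidistant the parent state's mass is split equally among them.
#'
#' @param counts integer vector of current counts per type.
#' @param rho integer vector of multiplication factors (recycled).
#' @param n_max carrying capacity.
#' @return list with `mu`: matrix of capacity vectors (one row per
#'   candidate) and `weight`: equal split weights summing to 1.
#' @examples
#' cutoff_capacities(c(2, 1), rho = c(3, 6), n_max = 32)  # no cut-off
#' cutoff_capacities(c(6, 3), rho = c(3, 6), n_max = 32)  # ray projection
#' @export
cutoff_capacities <- function(counts, rho, n_max) {
  counts <- as.numeric(counts)
  d <- length(counts)
  rho <- rep_len(as.numeric(rho), d)
  if (any(counts < 0) || sum(counts) > n_max) {
    stop("counts must be nonnegative with sum(counts) <= n_max", call. = FALSE)
  }
  demand <- rho * counts
  if (sum(demand) <= n_max) {
    return(list(mu = matrix(demand, nrow = 1), weight = 1))
  }
  target <- demand * n_max / sum(demand)  # ray / hyperplane intersection
  if (d == 2L) {
    lo <- max(counts[1], n_max - demand[2])
    hi <- min(demand[1], n_max - counts[2])
    cand1 <- unique(pmin(pmax(c(floor(target[1]), ceiling(target[1])), lo), hi))
    mu <- cbind(cand1, n_max - cand1)
  } else {
    mu <- bounded_compositions(n_max, lower = counts, upper = demand)
  }
  d2 <- rowSums((mu - rep(target, each = nrow(mu)))^2)
  keep <- which(d2 <= min(d2) + 1e-9)
  mu <- mu[keep, , drop = FALSE]
  dimnames(mu) <- NULL
  list(mu = mu, weight = rep(1 / nrow(mu), nrow(mu)))
}

# all integer vectors with sum = total and lower <= x <= upper
bounded_compositions <- function(total, lower, upper) {
  d <- length(lower)
  if (d == 1L) {
    if (total >= lower && total <= upper) return(matrix(total, 1, 1))
    return(matrix(numeric(0), 0, 1))
  }
  out <- list()
  rest_lo <- sum(lower[-1]); rest_hi <- sum(upper[-1])
  from <- max(lower[1], total - rest_hi)
  to <- min(upper[1], total - rest_lo)
  if (from > to) return(matrix(numeric(0), 0, d))
  for (x in from:to) {
    sub <- bounded_compositions(total - x, lower[-1], upper[-1])
    if (nrow(sub)) out[[length(out) + 1L]] <- cbind(x, sub)
  }
  do.call(rbind, out)
}
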