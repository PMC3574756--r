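#' Exact probability distributions over bounded population counts
#'
#' The simulator propagates whole probability distributions over integer
#' population counts `0..n_max` (one axis per entity type). A `gw_dist` is a
#' dense array with one dimension per type; mass outside the simplex
#' `sum(counts) <= n_max` is identically zero. The value at the all-zero
#' corner is the extinction probability W(0).
#'
#' @param probs numeric vector/matrix/array of probabilities, one dimension
#'   per entity type, each dimension of length `n_max + 1` (index 1 is
#'   count 0).
#' @param n_max integer carrying capacity (total count ceiling).
#' @return A `gw_dist` object.
#' @examples
#' d <- gw_dist(c(1/9, 4/9, 4/9), n_max = 2)
#' dist_mean(d)
#' extinction_mass(d)
#' @export
gw_dist <- function(probs, n_max) {
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 1)
  probs <- as.array(probs)
  if (any(dim(probs) != n_max + 1L)) {
    stop("every dimension of `probs` must have length n_max + 1", call. = FALSE)
  }
  d <- structure(list(probs = probs, n_max = n_max),
                 class = "gw_dist")
  validate_dist(d)
}

#' Point-mass distribution at a given count vector
#'
#' @param n_max carrying capacity.
#' @param at integer vector of counts, one per entity type (length 1, 2 or 4).
#' @return A `gw_dist` with all mass at `at`.
#' @export
point_dist <- function(n_max, at) {
  n_max <- as.integer(n_max)
  at <- as.integer(at)
  if (any(at < 0) || sum(at) > n_max) {
    stop("point mass must lie inside the simplex 0 <= sum(at) <= n_max",
         call. = FALSE)
  }
  probs <- array(0, dim = rep(n_max + 1L, length(at)))
  probs[matrix(at + 1L, nrow = 1)] <- 1
  gw_dist(probs, n_max)
}

#' @export
print.gw_dist <- function(x, ...) {
  nd <- dist_ndim(x)
  cat(sprintf("<gw_dist> %dD over counts 0..%d\n", nd, x$n_max))
  m <- dist_mean(x)
  cat("  mean:", paste(signif(m, 6), collapse = ", "),
      " W(0):", signif(extinction_mass(x), 6), "\n")
  invisible(x)
}

dist_ndim <- function(dist) length(dim(dist$probs))

#' @rdname gw_dist
#' @param dist a `gw_dist`.
#' @export
validate_dist <- function(dist) {
  p <- dist$probs
  if (any(p < -1e-12)) stop("negative probability mass", call. = FALSE)
  defect <- abs(1 - sum(p))
  if (defect > 1e-6) {
    stop(sprintf("probability mass defect %.3g exceeds 1e-6 (indexing bug?)",
                 defect), call. = FALSE)
  }
  # zero mass outside the simplex
  nd <- dist_ndim(dist)
  if (nd > 1L) {
    tot <- simplex_total_array(dist$n_max, nd)
    if (any(p[tot > dist$n_max] != 0)) {
      stop("nonzero mass outside the simplex sum(counts) <= n_max",
           call. = FALSE)
    }
  }
  dist
}

# array of total counts per cell, memoised per (n_max, ndim)
simplex_total_array <- local({
  cache <- new.env(parent = emptyenv())
  function(n_max, ndim) {
    key <- paste(n_max, ndim)
    if (is.null(cache[[key]])) {
      ax <- 0:n_max
      tot <- ax
      for (k in seq_len(ndim - 1L)) tot <- outer(tot, ax, `+`)
      cache[[key]] <- tot
    }
    cache[[key]]
  }
})

# Renormalize after a phase. Small drift (< 1e-6) is floating-point
# round-off and is folded back; anything larger aborts upstream in
# validate_dist().
renormalize_dist <- function(dist) {
  dist$probs[dist$probs < 0] <- 0   # clip round-off negatives (>-1e-12)
  validate_dist(dist)
  dist$probs <- dist$probs / sum(dist$probs)
  dist
}

#' Masked binomial probability mass
#'
#' Returns `choose(n, k) * p^k * (1-p)^(n-k)` for feasible `(k, n)` and 0 for
#' any out-of-range index combination (`k < 0`, `k > n`, `n < 0`). The
#' masking convention lets the nested convolution sums of the multiplication
#' and selection phases be written without enumerating their feasibility
#' constraints.
#'
#' @param k,n integers (vectorized).
#' @param p success probability in `[0, 1]` (scalar).
#' @return numeric vector of probabilities.
#' @examples
#' safe_binomial_pmf(1, 2, 2/3)  # 4/9
#' safe_binomial_pmf(3, 2, 0.5)  # 0, masked
#' @export
safe_binomial_pmf <- function(k, n, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  }
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  out <- numeric(len)
  ok <- k >= 0 & n >= 0 & k <= n
  if (any(ok)) out[ok] <- stats::dbinom(k[ok], n[ok], p)
  out
}

#' Moments and extinction mass of a distribution
#'
#' `dist_mean()` returns the unconditional mean count per axis, i.e.
#' `sum(N * W(N))` including the extinction mass at zero. `dist_sd()` is the
#' matching unconditional standard deviation. `extinction_mass()` returns
#' the probability that every type is extinct, `W(0, ..., 0)`.
#'
#' @param dist a `gw_dist`.
#' @param axis optional axis (1-based); default all axes.
#' @return numeric vector (one value per requested axis); for
#'   `extinction_mass()`, a single probability.
#' @export
dist_mean <- function(dist, axis = NULL) {
  nd <- dist_ndim(dist)
  axes <- if (is.null(axis)) seq_len(nd) else as.integer(axis)
  vapply(axes, function(a) {
    m <- marginal(dist, a)
    sum(0:dist$n_max * m$probs)
  }, numeric(1))
}

#' @rdname dist_mean
#' @export
dist_sd <- function(dist, axis = NULL) {
  nd <- dist_ndim(dist)
  axes <- if (is.null(axis)) seq_len(nd) else as.integer(axis)
  vapply(axes, function(a) {
    m <- marginal(dist, a)
    x <- 0:dist$n_max
    mu <- sum(x * m$probs)
    sqrt(max(sum(x^2 * m$probs) - mu^2, 0))
  }, numeric(1))
}

#' @rdname dist_mean
#' @export
extinction_mass <- function(dist) {
  nd <- dist_ndim(dist)
  dist$probs[matrix(1L, nrow = 1, ncol = nd)]
}

#' Marginal distribution along one axis
#'
#' Sums the joint distribution over all other axes.
#'
#' @param dist a `gw_dist` with 2 or more axes (1D inputs are returned
#'   unchanged when `axis = 1`).
#' @param axis which axis to keep (1-based).
#' @return a 1D `gw_dist`.
#' @export
marginal <- function(dist, axis = 1L) {
  nd <- dist_ndim(dist)
  axis <- as.integer(axis)
  stopifnot(axis >= 1, axis <= nd)
  if (nd == 1L) return(dist)
  m <- apply(dist$probs, axis, sum)
  structure(list(probs = as.array(m), n_max = dist$n_max), class = "gw_dist")
}

#' Total-variation distance between two distributions
#'
#' @param a,b `gw_dist` objects on the same support shape.
#' @return `0.5 * sum(abs(a - b))`, a number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  if (!identical(dim(a$probs), dim(b$probs))) {
    stop("distributions have different support shapes", call. = FALSE)
  }
  0.5 * sum(abs(a$probs - b$probs))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a distribution into a count/probability table
#'
#' @param x a `gw_dist`.
#' @param ... unused.
#' @param drop_zero drop cells with zero probability (default TRUE for
#'   multidimensional distributions).
#' @return a tibble with one count column per axis (`n1`, `n2`, ...) and a
#'   `probability` column.
#' @method as_tibble gw_dist
#' @export
as_tibble.gw_dist <- function(x, ..., drop_zero = dist_ndim(x) > 1L) {
  nd <- dist_ndim(x)
  grids <- rep(list(0:x$n_max), nd)
  names(grids) <- paste0("n", seq_len(nd))
  out <- do.call(tidyr::expand_grid, rev(grids))[, names(grids)]
  # expand_grid varies last column fastest; arrays vary first index fastest
  out <- tibble::as_tibble(out[do.call(order,
    lapply(rev(seq_len(nd)), function(i) out[[i]])), , drop = FALSE])
  out$probability <- as.vector(x$probs)
  if (drop_zero) out <- out[out$probability > 0, , drop = FALSE]
  out
}

## ---- simplex state indexing (shared by the transition-matrix builders) ----

# Enumerate all count vectors with sum <= n_max in `ndim` dimensions, and a
# lookup array mapping array cells to state ids (NA outside the simplex).
simplex_index <- local({
  cache <- new.env(parent = emptyenv())
  function(n_max, ndim) {
    key <- paste(n_max, ndim)
    if (is.null(cache[[key]])) {
      tot <- simplex_total_array(n_max, ndim)
      if (ndim == 1L) tot <- array(tot, dim = n_max + 1L)
      keep <- which(tot <= n_max)
      id <- array(NA_integer_, dim = dim(tot))
      id[keep] <- seq_along(keep)
      states <- arrayInd(keep, dim(tot)) - 1L
      cache[[key]] <- list(states = states, id = id, cells = keep,
                           n_states = length(keep))
    }
    cache[[key]]
  }
})

# distribution array -> state vector and back
dist_to_state_vec <- function(dist, idx) dist$probs[idx$cells]

state_vec_to_dist <- function(w, idx, n_max, ndim) {
  probs <- array(0, dim = rep(n_max + 1L, ndim))
  probs[idx$cells] <- w
  structure(list(probs = probs, n_max = as.integer(n_max)), class = "gw_dist")
}

## ---- serialization ----

#' Read and write distributions as TSV or JSON
#'
#' TSV files carry one row per support cell (count coordinates then
#' probability) at 17 significant digits, so write/read round-trips are
#' bit-identical. JSON carries the flattened probability array plus `n_max`
#' and the dimensionality.
#'
#' @param dist a `gw_dist`.
#' @param path file path.
#' @return `read_dist_tsv()` / `read_dist_json()` return a `gw_dist`;
#'   writers return `path` invisibly.
#' @export
write_dist_tsv <- function(dist, path) {
  tb <- as_tibble(dist, drop_zero = FALSE)
  tb$probability <- vapply(tb$probability, function(p)
    sprintf("%.17g", p), character(1))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  nd <- ncol(tb) - 1L
  n_max <- max(tb[[1]])
  probs <- array(0, dim = rep(n_max + 1L, nd))
  cells <- as.matrix(tb[, seq_len(nd), drop = FALSE]) + 1L
  probs[cells] <- tb$probability
  gw_dist(probs, n_max)
}

#' @rdname write_dist_tsv
#' @export
write_dist_json <- function(dist, path) {
  obj <- list(n_max = dist$n_max, ndim = dist_ndim(dist),
              probs = as.vector(dist$probs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gw_dist(array(obj$probs, dim = rep(obj$n_max + 1L, obj$ndim)), obj$n_max)
}
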