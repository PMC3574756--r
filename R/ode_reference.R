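#' Deterministic logistic comparator
#'
#' Closed-form solution of the logistic birth-death equation
#' `dN/dt = R*N - (R/K)*N^2`:
#' `N(t) = exp(R*t) * N0 * K / (K - N0 + N0 * exp(R*t))`.
#'
#' @param R net rate per generation (birth rate minus death rate).
#' @param K saturation (carrying capacity, counts), `K > 0`.
#' @param N0 initial count.
#' @param t time in generations (vectorized).
#' @return `N(t)`.
#' @export
logistic_solution <- function(R, K, N0, t) {
  stopifnot(K > 0, N0 >= 0)
  if (N0 == 0) return(rep(0, length(t)))
  # algebraically equal to exp(Rt)*N0*K / (K - N0 + N0*exp(Rt)), but stable
  # when exp(Rt) overflows
  K / (1 + (K - N0) / N0 * exp(-R * t))
}

#' Least-squares fit of the logistic growth rate to a mean trajectory
#'
#' Fits the closed-form logistic curve to an unconditional mean-count
#' trajectory (means must include the extinction mass at zero) with `N0`
#' fixed and `R`, `K` free. The fit is deterministic: `R` starts from the
#' early-generation log-slope (first ten points) and `K` from the final
#' mean, then both are refined by Levenberg-Marquardt least squares.
#'
#' @param trajectory a data frame with columns `n` (generation) and `mean`,
#'   or the tidy trajectory of a [run_single()] call (post-selection rows
#'   are used).
#' @param N0 fixed initial count (default 1).
#' @return a `gw_logistic_fit` with elements `R`, `K`, `residual` (sum of
#'   squares), `non_identifiable` flag, and `fitted` tibble.
#' @examples
#' tr <- tibble::tibble(n = 0:50, mean = logistic_solution(0.1, 50, 1, 0:50))
#' fit_logistic_R(tr)$R  # 0.1
#' @export
fit_logistic_R <- function(trajectory, N0 = 1) {
  tr <- as_mean_trajectory(trajectory)
  if (nrow(tr) < 3L) stop("need at least 3 trajectory points", call. = FALSE)
  if (all(tr$mean == 0)) {
    stop("degenerate all-zero trajectory: logistic rate undefined", call. = FALSE)
  }
  head_n <- utils::head(tr[tr$mean > 0, ], 10L)
  R0 <- if (nrow(head_n) >= 2L) {
    unname(stats::coef(stats::lm(log(mean) ~ n, data = head_n))[2])
  } else 0.1
  K0 <- max(tr$mean[nrow(tr)], N0 * 1.001, 1e-6)
  if (max(tr$mean) == min(tr$mean)) {
    # flat trajectory at K = N0: every R fits equally well
    return(new_logistic_fit(R = R0, K = K0, residual = 0,
                            non_identifiable = TRUE, tr = tr, N0 = N0))
  }
  fit <- minpack.lm::nlsLM(
    mean ~ logistic_solution(R, K, N0, n), data = tr,
    start = list(R = R0, K = K0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  cf <- stats::coef(fit)
  new_logistic_fit(R = unname(cf["R"]), K = unname(cf["K"]),
                   residual = sum(stats::resid(fit)^2),
                   non_identifiable = FALSE, tr = tr, N0 = N0)
}

new_logistic_fit <- function(R, K, residual, non_identifiable, tr, N0) {
  structure(list(R = R, K = K, N0 = N0, residual = residual,
                 non_identifiable = non_identifiable,
                 fitted = tibble::tibble(
                   n = tr$n, mean = tr$mean,
                   fitted = logistic_solution(R, K, N0, tr$n))),
            class = "gw_logistic_fit")
}

as_mean_trajectory <- function(trajectory) {
  tr <- tibble::as_tibble(trajectory)
  if ("phase" %in% names(tr)) tr <- dplyr::filter(tr, .data$phase == "S")
  if (!"n" %in% names(tr) && "generation" %in% names(tr)) {
    tr <- dplyr::rename(tr, n = "generation")
  }
  if (!all(c("n", "mean") %in% names(tr))) {
    stop("trajectory must have columns `n` (or `generation`) and `mean`",
         call. = FALSE)
  }
  dplyr::arrange(tr[, c("n", "mean")], .data$n)
}

#' @export
print.gw_logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic fit> R = %.4g, K = %.4g (N0 = %g, SSR = %.3g)%s\n",
              x$R, x$K, x$N0, x$residual,
              if (x$non_identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

#' Two-species deterministic comparator
#'
#' Integrates the coupled birth-death system for an initial form and a
#' mutant sharing one saturation level `K`:
#' `dNA/dt = Ra*NA - (Ra/K)*NA^2 - (Rb/K)*NA*NB` and symmetrically for
#' `NB`. With the `Rb` terms zeroed and `NB0 = 0` it reduces to the
#' logistic equation.
#'
#' @param Ra,Rb net rates of the initial form and the mutant.
#' @param K shared saturation, `K > 0`.
#' @param NA0,NB0 initial counts.
#' @param times numeric vector of output times.
#' @param rtol relative integrator tolerance.
#' @return tibble with columns `time`, `N_A`, `N_B`.
#' @export
two_species_ode <- function(Ra, Rb, K, NA0, NB0, times, rtol = 1e-8) {
  stopifnot(K > 0, NA0 >= 0, NB0 >= 0)
  deriv <- function(t, y, p) {
    list(c(Ra * y[1] - Ra / K * y[1]^2 - Rb / K * y[1] * y[2],
           Rb * y[2] - Rb / K * y[2]^2 - Ra / K * y[2] * y[1]))
  }
  out <- deSolve::ode(y = c(NA0, NB0), times = times, func = deriv,
                      parms = NULL, rtol = rtol, atol = 1e-10)
  tibble::tibble(time = out[, 1], N_A = pmax(out[, 2], 0),
                 N_B = pmax(out[, 3], 0))
}
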