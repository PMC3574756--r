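#' Plot a simulation run
#'
#' Draws the mean-count trajectories of every entity type (post-selection
#' rows for the phase-recording models) with the total extinction
#' probability as a secondary panel.
#'
#' @param object a `gw_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gw_run
#' @export
autoplot.gw_run <- function(object, ...) {
  tr <- object$trajectory
  if ("phase" %in% names(tr)) tr <- dplyr::filter(tr, .data$phase == "S")
  mean_cols <- grep("^(mean|p_mean|e_mean|m_mean|pA_mean|pB_mean|ea_mean|ma_mean|eb_mean|mb_mean)",
                    names(tr), value = TRUE)
  mean_cols <- mean_cols[!grepl("^sd", mean_cols)]
  w0_col <- intersect(c("w0", "w0_pathogen"), names(tr))[1]
  long <- tidyr::pivot_longer(tr[, c("generation", mean_cols)],
                              -"generation",
                              names_to = "series", values_to = "mean")
  long$panel <- "mean count"
  w0 <- tibble::tibble(generation = tr$generation, series = w0_col,
                       mean = tr[[w0_col]], panel = "extinction W(0)")
  dat <- dplyr::bind_rows(long, w0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$mean,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a probability distribution over counts
#'
#' 1D distributions are drawn as a bar profile; 2D distributions as a
#' probability heat map over the simplex.
#'
#' @param dist a `gw_dist` (1 or 2 axes).
#' @return a ggplot object.
#' @export
plot_distribution <- function(dist) {
  nd <- dist_ndim(dist)
  tb <- as_tibble(dist, drop_zero = FALSE)
  if (nd == 1L) {
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$n1, y = .data$probability)) +
      ggplot2::geom_col(width = 0.9) +
      ggplot2::labs(x = "count N", y = "W(N)") +
      ggplot2::theme_minimal()
  } else if (nd == 2L) {
    ggplot2::ggplot(dplyr::filter(tb, .data$n1 + .data$n2 <= dist$n_max),
                    ggplot2::aes(x = .data$n1, y = .data$n2,
                                 fill = .data$probability)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "count, type 1", y = "count, type 2") +
      ggplot2::theme_minimal()
  } else {
    stop("plot_distribution() draws 1D and 2D distributions; take a marginal",
         call. = FALSE)
  }
}

#' Plot a logistic fit against the mean trajectory it was fitted to
#'
#' @param object a `gw_logistic_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gw_logistic_fit
#' @export
autoplot.gw_logistic_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "generation",
                  y = "mean count",
                  title = sprintf("logistic fit: R = %.4g, K = %.4g",
                                  object$R, object$K)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
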