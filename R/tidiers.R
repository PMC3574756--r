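#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarise simulation runs
#'
#' `tidy()` returns the per-generation trajectory tibble; `glance()` a
#' one-row summary with the final means and extinction probabilities.
#'
#' @param x a `gw_run`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy gw_run
#' @export
tidy.gw_run <- function(x, ...) x$trajectory

#' @rdname tidy.gw_run
#' @method glance gw_run
#' @export
glance.gw_run <- function(x, ...) {
  last <- dplyr::slice_tail(x$trajectory, n = 1)
  out <- dplyr::select(last, -dplyr::any_of(c("phase")),
                       -dplyr::ends_with("_branch"))
  names(out)[names(out) != "generation"] <-
    paste0("final_", names(out)[names(out) != "generation"])
  dplyr::mutate(out, kind = x$kind, generations = x$generations,
                .before = 1)
}

#' @rdname tidy.gw_run
#' @method tidy gw_logistic_fit
#' @export
tidy.gw_logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("R", "K"), estimate = c(x$R, x$K))
}

#' @rdname tidy.gw_run
#' @method glance gw_logistic_fit
#' @export
glance.gw_logistic_fit <- function(x, ...) {
  tibble::tibble(R = x$R, K = x$K, N0 = x$N0, residual = x$residual,
                 non_identifiable = x$non_identifiable)
}
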