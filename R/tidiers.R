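#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted listener model
#'
#' @param x A `drex_fit` from [fit_listener()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter: `parameter`,
#'   `feature`, `value`.
#' @export
tidy.drex_fit <- function(x, ...) {
  out <- tibble::tibble(
    parameter = c("M", "M", "N", "N", "tau"),
    feature = c("f1", "f2", "f1", "f2", NA),
    value = c(x$M_f1, x$M_f2, x$N_f1, x$N_f2, x$tau)
  )
  if (!is.na(x$w)) {
    out <- dplyr::bind_rows(out, tibble::tibble(parameter = "w",
                                                feature = NA,
                                                value = x$w))
  }
  out
}

#' One-row summary of a fitted listener model
#'
#' @param x A `drex_fit` from [fit_listener()].
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `mse`, `hinge`, `n_trials`.
#' @export
glance.drex_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, mse = x$mse, hinge = x$hinge,
                 n_trials = x$n_trials)
}
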