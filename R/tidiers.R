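#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x a `decay_fit` from [fit_half_life()] or [bulk_half_life()].
#' @param ... unused.
#' @return a tibble with one row per regression term (`intercept`,
#'   `slope`) and its estimate.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a decay fit
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return a one-row tibble with `method`, `t_half`, `r_squared`,
#'   `n_points`, `n_excluded_zero`, `reason`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(method = x$method, t_half = x$t_half, r_squared = x$r_squared,
         n_points = x$n_points, n_excluded_zero = x$n_excluded_zero,
         reason = x$reason)
}
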