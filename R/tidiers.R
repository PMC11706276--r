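#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half", "k"), estimate = c(x$v_half, x$k))
}

#' @exportS3Method generics::glance
glance.boltzmann_fit <- function(x, ...) {
  tibble(v_half = x$v_half, k = x$k, direction = x$direction,
         residual = x$residual, n_points = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.recovery_fit <- function(x, ...) {
  tibble(term = c("tau", "amplitude"), estimate = c(x$tau, x$amplitude))
}

#' @exportS3Method generics::glance
glance.recovery_fit <- function(x, ...) {
  tibble(tau = x$tau, amplitude = x$amplitude, mode = x$mode,
         residual = x$residual, n_points = x$n_points)
}
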