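# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname tidiers
#' @param x A fitted object (`trap_calibration`, `step_fit`, `frap_fit` or
#'   `dsigma_fit`).
#' @param ... Unused.
tidy.trap_calibration <- function(x, ...) {
  tibble(term = "k_trap", estimate = x$k_trap, unit = "pN/um")
}

#' @export
#' @rdname tidiers
glance.trap_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble(k_trap = x$k_trap, r_squared = s$r.squared, n = nrow(x$records))
}

#' Tidiers for memtide fit objects
#'
#' [generics::tidy()] returns one row per parameter; [generics::glance()]
#' returns a one-row model summary.
#'
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
tidy.step_fit <- function(x, ...) {
  tibble(
    term = c("a1", "a2", "tau1", "tau2"),
    estimate = c(x$amplitudes, x$time_constants),
    unit = c("", "", "s", "s")
  )
}

#' @export
#' @rdname tidiers
glance.step_fit <- function(x, ...) {
  tibble(sigma = sd(stats::residuals(x$fit)), n = nrow(x$data))
}

#' @export
#' @rdname tidiers
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("F0", "F_inf", "t_half", "mobile_fraction", "D_t"),
    estimate = c(x$F0, x$F_inf, x$t_half, x$mobile_fraction, x$D_t),
    unit = c("", "", "s", "", "um^2/s")
  )
}

#' @export
#' @rdname tidiers
glance.frap_fit <- function(x, ...) {
  tibble(
    t_half = x$t_half, D_t = x$D_t, mobile_fraction = x$mobile_fraction,
    immobile_fraction = x$immobile_fraction,
    sigma = sd(stats::residuals(x$fit)), n = nrow(x$data)
  )
}

#' @export
#' @rdname tidiers
tidy.dsigma_fit <- function(x, ...) {
  tibble(
    term = c("D_sigma", "d_effective"),
    estimate = c(x$D_sigma_hat, x$d_hat),
    unit = c("um^2/s", "um")
  )
}

#' @export
#' @rdname tidiers
glance.dsigma_fit <- function(x, ...) {
  tibble(
    D_sigma_hat = x$D_sigma_hat, d_hat = x$d_hat,
    residual_ss = x$residual_ss, null_ss = x$null_ss,
    identifiable = x$identifiable, n = nrow(x$measured)
  )
}
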