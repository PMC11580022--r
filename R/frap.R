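# FRAP recovery analysis: normalization, hyperbolic recovery fit, tracer
# diffusivity and mobile/immobile fraction. The immobile fraction feeds the
# obstacle area fraction used by the tension-propagation model (see
# obstacle_fraction()).

#' Normalize a FRAP intensity trace
#'
#' \eqn{F = (f - f_o) / (f_{pre} - f_o)}, where \eqn{f_{pre}} and
#' \eqn{f_o} are the raw pre- and immediately post-bleach intensities
#' (background already subtracted). By construction F = 0 at the post-bleach
#' floor and F = 1 at the pre-bleach level.
#'
#' @param curve Data frame with columns `time_s` and `intensity_au`; time is
#'   measured from the end of the bleach.
#' @param f_pre Raw pre-bleach intensity (a.u.).
#' @param f_o Raw post-bleach intensity (a.u.); must differ from `f_pre`.
#' @return A `frap_curve` tibble with an added normalized column `F_norm`.
#' @export
normalize_frap <- function(curve, f_pre, f_o) {
  check_columns(curve, c("time_s", "intensity_au"), "curve")
  check_number(f_pre, "f_pre", allow_vector = FALSE)
  check_number(f_o, "f_o", allow_vector = FALSE)
  if (abs(f_pre - f_o) < sqrt(.Machine$double.eps) * max(1, abs(f_pre))) {
    abort("`f_pre` = `f_o`: no bleach depth to normalize against.",
          class = "memtide_domain_error")
  }
  res <- curve |>
    as_tibble() |>
    mutate(F_norm = (.data$intensity_au - f_o) / (f_pre - f_o))
  attr(res, "f_pre") <- f_pre
  attr(res, "f_o") <- f_o
  class(res) <- c("frap_curve", class(res))
  res
}

# hyperbolic recovery model
frap_model <- function(t, F0, F_inf, t_half) {
  (F0 + F_inf * (t / t_half)) / (1 + t / t_half)
}

#' Fit a FRAP recovery curve
#'
#' Fits the hyperbolic recovery model
#' \deqn{F(t) = \frac{F_0 + F_\infty (t/t_{1/2})}{1 + t/t_{1/2}}}
#' to a normalized post-bleach trace. Under the model
#' \eqn{F(t_{1/2}) = (F_0 + F_\infty)/2} exactly. The mobile fraction is
#' \eqn{F_\infty - F_0}, and the tracer diffusion constant is
#' \eqn{D_t = A_{bleach} / (4 t_{1/2})}.
#'
#' Initialization: `F0` from the first post-bleach point, `F_inf` from the
#' tail mean, `t_half` from the first crossing of their midpoint.
#'
#' @param curve A [normalize_frap()] result, or any data frame with `time_s`
#'   and `F_norm` (post-bleach, time from bleach end); at least 10 points.
#' @param A_bleach Photobleached membrane area (um^2); default
#'   2.4 x 0.85 = 2.04 (spot diameter x optical section).
#' @return A `frap_fit` object: list with `F0`, `F_inf`, `t_half`,
#'   `mobile_fraction`, `immobile_fraction`, `D_t`, `A_bleach`, the `nls`
#'   fit and the data. Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
#' @examples
#' t <- seq(0, 120, by = 1.29)
#' curve <- tibble::tibble(time_s = t, F_norm = (0.2 + 0.8 * (t / 10)) / (1 + t / 10))
#' fit_recovery(curve)
fit_recovery <- function(curve, A_bleach = memtide_constants()$A_bleach) {
  check_columns(curve, c("time_s", "F_norm"), "curve")
  check_number(A_bleach, "A_bleach", positive = TRUE, allow_vector = FALSE)
  if (nrow(curve) < 10) {
    abort("Need >= 10 post-bleach points to fit a recovery curve.",
          class = "memtide_fit_error")
  }
  dat <- tibble(t = curve$time_s - curve$time_s[1], F = curve$F_norm)
  F0_init <- dat$F[1]
  Finf_init <- mean(tail(dat$F, max(3L, ceiling(nrow(dat) / 10))))
  mid <- (F0_init + Finf_init) / 2
  cross <- which(dat$F >= mid & dat$t > 0)[1]
  t_half_init <- if (is.finite(cross) && !is.na(cross)) max(dat$t[cross], 1e-3) else max(dat$t) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ (F0 + F_inf * (t / t_half)) / (1 + t / t_half),
      data = dat,
      start = list(F0 = F0_init, F_inf = Finf_init, t_half = t_half_init),
      lower = c(-0.5, -0.5, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(
        sprintf(
          "FRAP recovery fit failed to converge (starting values F0=%.3g, F_inf=%.3g, t_half=%.3g): %s",
          F0_init, Finf_init, t_half_init, conditionMessage(e)
        ),
        class = "memtide_fit_error"
      )
    }
  )
  cf <- coef(fit)
  mobile <- cf[["F_inf"]] - cf[["F0"]]
  if (mobile < 0 || mobile > 1) {
    warn(sprintf("Mobile fraction %.3g outside [0, 1]; clipped.", mobile))
    mobile <- min(max(mobile, 0), 1)
  }
  structure(
    list(
      F0 = cf[["F0"]], F_inf = cf[["F_inf"]], t_half = cf[["t_half"]],
      mobile_fraction = mobile, immobile_fraction = 1 - mobile,
      D_t = diffusion_constant(cf[["t_half"]], A_bleach),
      A_bleach = A_bleach, fit = fit, data = dat
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>\n")
  cat(sprintf("  F0 = %.3g, F_inf = %.3g, t_half = %.4g s\n", x$F0, x$F_inf, x$t_half))
  cat(sprintf("  mobile = %.3g, immobile = %.3g\n", x$mobile_fraction, x$immobile_fraction))
  cat(sprintf("  D_t = %.4g um^2/s (A_bleach = %.3g um^2)\n", x$D_t, x$A_bleach))
  invisible(x)
}

#' Tracer diffusion constant from the recovery half-time
#'
#' \eqn{D_t = A_{bleach} / (4 t_{1/2})}; an exact quotient, no hidden
#' geometric factors.
#'
#' @param t_half Recovery half-time (s), > 0.
#' @param A_bleach Photobleached area (um^2); default 2.04.
#' @return Tracer diffusivity (um^2/s).
#' @export
#' @examples
#' diffusion_constant(26.84) # ~ 0.019 um^2/s
diffusion_constant <- function(t_half, A_bleach = memtide_constants()$A_bleach) {
  check_number(t_half, "t_half", positive = TRUE)
  check_number(A_bleach, "A_bleach", positive = TRUE, allow_vector = FALSE)
  A_bleach / (4 * t_half)
}

#' Mobile and immobile protein fractions
#'
#' The mobile fraction is \eqn{F_\infty - F_0}; the immobile fraction is its
#' complement. Values outside \[0, 1\] are flagged and clipped.
#'
#' @param fit A `frap_fit` (or list with `F0` and `F_inf`).
#' @return Tibble with columns `mobile` and `immobile`.
#' @export
mobile_immobile <- function(fit) {
  mobile <- fit$F_inf - fit$F0
  if (!is.finite(mobile)) abort("Invalid fit.", class = "memtide_domain_error")
  if (mobile < 0 || mobile > 1) {
    warn(sprintf("Mobile fraction %.3g outside [0, 1]; clipped.", mobile))
    mobile <- min(max(mobile, 0), 1)
  }
  tibble(mobile = mobile, immobile = 1 - mobile)
}
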