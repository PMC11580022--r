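# Internal argument checks and small numeric helpers.

check_number <- function(x, arg, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, allow_vector = TRUE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", arg), class = "memtide_domain_error")
  }
  if (!allow_vector && length(x) != 1L) {
    abort(sprintf("`%s` must be a single number.", arg), class = "memtide_domain_error")
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", arg), class = "memtide_domain_error")
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be > 0.", arg), class = "memtide_domain_error")
  }
  if (nonneg && any(x < 0)) {
    abort(sprintf("`%s` must be >= 0.", arg), class = "memtide_domain_error")
  }
  invisible(x)
}

check_fraction <- function(x, arg, open_lower = FALSE, open_upper = FALSE) {
  check_number(x, arg)
  lo_ok <- if (open_lower) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_upper) all(x < 1) else all(x <= 1)
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in [0, 1].", arg), class = "memtide_domain_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")),
      class = "memtide_schema_error"
    )
  }
  invisible(df)
}

check_time_monotone <- function(time, arg = "time") {
  if (any(!is.finite(time))) {
    abort(sprintf("`%s` contains non-finite values.", arg), class = "memtide_schema_error")
  }
  if (any(diff(time) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing.", arg), class = "memtide_schema_error")
  }
  invisible(time)
}

#' Round half-up to a number of significant figures
#'
#' Unlike [signif()], which rounds half to even, ties are rounded away from
#' zero. Used when comparing computed quantities to values printed at a fixed
#' number of significant figures.
#'
#' @param x Numeric vector.
#' @param digits Significant figures to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' signif_half_up(0.0925, 2) # 0.093
signif_half_up <- function(x, digits = 2) {
  check_number(x, "x")
  check_number(digits, "digits", positive = TRUE, allow_vector = FALSE)
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz]))) - (digits - 1)
  scaled <- abs(x[nz]) / 10^mag
  out[nz] <- sign(x[nz]) * floor(scaled + 0.5 + sqrt(.Machine$double.eps)) * 10^mag
  out
}

#' Gaussian smoothing of a uniformly sampled trace
#'
#' Discrete convolution with a Gaussian kernel truncated at 4 standard
#' deviations, with reflection padding at both ends.
#'
#' @param x Numeric vector, sampled at interval `dt`.
#' @param dt Sampling interval (s).
#' @param width Kernel width (s); interpreted as the Gaussian standard
#'   deviation when `kind = "sigma"` (default) or as full width at half
#'   maximum when `kind = "fwhm"`.
#' @param kind Interpretation of `width`.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, dt, width = 1, kind = c("sigma", "fwhm")) {
  kind <- match.arg(kind)
  check_number(x, "x", finite = TRUE)
  check_number(dt, "dt", positive = TRUE, allow_vector = FALSE)
  check_number(width, "width", nonneg = TRUE, allow_vector = FALSE)
  if (width == 0) return(x)
  sigma <- if (kind == "fwhm") width / (2 * sqrt(2 * log(2))) else width
  half <- max(1L, ceiling(4 * sigma / dt))
  kern <- exp(-0.5 * ((-half:half) * dt / sigma)^2)
  kern <- kern / sum(kern)
  n <- length(x)
  pad <- min(half, n - 1L)
  # point (odd) reflection about the end samples: preserves local trend, so
  # a steadily moving trace keeps its slope at the boundaries
  left <- 2 * x[1] - rev(x[seq_len(pad) + 1L])
  right <- 2 * x[n] - x[n - seq_len(pad)]
  if (half > pad) {
    left <- c(rep(left[1] %||% x[1], half - pad), left)
    right <- c(right, rep(right[length(right)] %||% x[n], half - pad))
  }
  xp <- c(left, x, right)
  as.numeric(stats::filter(xp, kern, sides = 2))[half + seq_len(n)]
}

# first-order low-pass filter (exponential relaxation toward the input)
lag_filter <- function(x, time, tau) {
  if (is.null(tau) || tau <= 0) return(x)
  y <- numeric(length(x))
  y[1] <- x[1]
  if (length(x) > 1) {
    a <- 1 - exp(-diff(time) / tau)
    for (i in seq_along(a)) y[i + 1] <- y[i] + a[i] * (x[i + 1] - y[i])
  }
  y
}
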