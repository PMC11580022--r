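# Activity-driven membrane tension dynamics: calcium dF/F processing, a
# minimal exo-endocytosis area-balance model of the stimulus-evoked tension
# drop and recovery, the recovered-fraction statistic, and calcium-tension
# anticorrelation.

#' Relative fluorescence change
#'
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0}, with the baseline \eqn{F_0} taken as
#' the mean intensity over a pre-stimulus window. Zero-mean over the
#' baseline by construction.
#'
#' @param trace Data frame with `time_s` and `intensity_au` (background
#'   already subtracted).
#' @param baseline_window Numeric length-2 `c(t0, t1)`: the pre-stimulus
#'   window over which the baseline is averaged.
#' @return Tibble: input plus `dF_over_F`.
#' @export
delta_f_over_f <- function(trace, baseline_window) {
  check_columns(trace, c("time_s", "intensity_au"), "trace")
  check_number(baseline_window, "baseline_window")
  if (length(baseline_window) != 2) {
    abort("`baseline_window` must be c(t0, t1).", class = "memtide_domain_error")
  }
  in_base <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  if (!any(in_base)) {
    abort("No samples inside `baseline_window`.", class = "memtide_domain_error")
  }
  f0 <- mean(trace$intensity_au[in_base])
  if (!is.finite(f0) || f0 <= 0) {
    abort("Baseline mean must be positive.", class = "memtide_domain_error")
  }
  trace |>
    as_tibble() |>
    mutate(dF_over_F = (.data$intensity_au - f0) / f0)
}

#' Exo-endocytosis model parameters
#'
#' Parameters of the minimal linear area-balance model behind
#' [simulate_exo_endo()]: stimulation adds membrane area (a fraction of the
#' terminal surface) over a short burst; a fraction `endo_efficiency` of the
#' added area is retrievable by first-order endocytosis with time constant
#' `endo_tau`; the tension readout through the tether lags with
#' `tether_lag_tau`.
#'
#' Defaults: 10% area added within 0.25 s (strong stimulation), endocytic
#' time constant 10 s (the observed tension recovery proceeds on a 10-20 s
#' time scale and is complete within 50 s; ~1 s applies to weak stimuli),
#' tether lag 1 s.
#'
#' @param area_added_fraction Added area as a fraction of terminal area.
#' @param add_duration Duration of the exocytic burst (s).
#' @param E 2D stretch modulus (pN/um) mapping fractional area excess to a
#'   tension change; shared with [membrane_model()].
#' @param endo_tau Endocytic time constant (s).
#' @param endo_efficiency Fraction of the added area that endocytosis can
#'   retrieve, in \[0, 1\]. Dynamin inhibition (MiTMAB) lowers it.
#' @param tether_lag_tau Tether response time constant (s).
#' @return An `exo_endo_params` list.
#' @export
exo_endo_params <- function(area_added_fraction = 0.10, add_duration = 0.25,
                            E = memtide_constants()$E, endo_tau = 10,
                            endo_efficiency = 1, tether_lag_tau = 1) {
  check_number(area_added_fraction, "area_added_fraction", positive = TRUE, allow_vector = FALSE)
  check_number(add_duration, "add_duration", positive = TRUE, allow_vector = FALSE)
  check_number(E, "E", positive = TRUE, allow_vector = FALSE)
  check_number(endo_tau, "endo_tau", positive = TRUE, allow_vector = FALSE)
  check_fraction(endo_efficiency, "endo_efficiency")
  check_number(tether_lag_tau, "tether_lag_tau", positive = TRUE, allow_vector = FALSE)
  structure(
    list(area_added_fraction = area_added_fraction, add_duration = add_duration,
         E = E, endo_tau = endo_tau, endo_efficiency = endo_efficiency,
         tether_lag_tau = tether_lag_tau),
    class = "exo_endo_params"
  )
}

#' Simulate stimulus-evoked tension dynamics
#'
#' Minimal area-balance model: exocytosis adds membrane area at a constant
#' rate during the burst; a fraction `endo_efficiency` of it enters a
#' retrievable pool removed by first-order endocytosis, the rest stays.
#' The fractional excess area e(t) maps to tension as
#' \eqn{\sigma(t) = \sigma_0 - E\, e(t)}, low-pass filtered by the tether
#' response time. Exact exponential stepping keeps the area bookkeeping
#' (added - endocytosed - residual = 0) at machine precision.
#'
#' @param params An [exo_endo_params()].
#' @param sigma0 Resting tension (pN/um).
#' @param duration Trace duration (s).
#' @param t_on Stimulus onset (s); default 10.
#' @param dt Sampling interval (s); default 0.05.
#' @return A `stimulus_trace` tibble with `time_s`, `tension_pN_per_um`,
#'   plus bookkeeping columns `area_added_cum`, `area_endocytosed_cum`,
#'   `area_excess` (all fractional, relative to terminal area); attributes
#'   `t_on`, `t_off`, `params`, `sigma0`.
#' @export
#' @examples
#' tr <- simulate_exo_endo(exo_endo_params(), sigma0 = 5, duration = 70)
#' recovered_fraction(tr)
simulate_exo_endo <- function(params, sigma0, duration, t_on = 10, dt = 0.05) {
  if (!inherits(params, "exo_endo_params")) params <- do.call(exo_endo_params, params)
  check_number(sigma0, "sigma0", positive = TRUE, allow_vector = FALSE)
  check_number(duration, "duration", positive = TRUE, allow_vector = FALSE)
  time <- seq(0, duration, by = dt)
  n <- length(time)
  eps <- params$endo_efficiency
  tau <- params$endo_tau
  rate <- params$area_added_fraction / params$add_duration
  p <- q <- added <- endo <- numeric(n) # retrievable pool, fixed pool, totals
  for (i in 2:n) {
    h <- time[i] - time[i - 1]
    # overlap of [t_{i-1}, t_i] with the exocytic burst
    burst <- max(0, min(time[i], t_on + params$add_duration) - max(time[i - 1], t_on))
    r_eff <- rate * burst / h
    decay <- exp(-h / tau)
    p[i] <- p[i - 1] * decay + eps * r_eff * tau * (1 - decay)
    q[i] <- q[i - 1] + (1 - eps) * r_eff * h
    added[i] <- added[i - 1] + r_eff * h
    endo[i] <- endo[i - 1] + (eps * r_eff * h - (p[i] - p[i - 1]))
  }
  excess <- p + q
  sigma <- sigma0 - params$E * excess
  if (min(sigma) <= 0) {
    warn("Tension reaches zero: area addition too large for the linear tension-area mapping.")
  }
  sigma <- lag_filter(sigma, time, params$tether_lag_tau)
  out <- tibble(
    time_s = time,
    tension_pN_per_um = sigma,
    area_added_cum = added,
    area_endocytosed_cum = endo,
    area_excess = excess
  )
  attr(out, "t_on") <- t_on
  attr(out, "t_off") <- t_on + params$add_duration
  attr(out, "params") <- params
  attr(out, "sigma0") <- sigma0
  class(out) <- c("stimulus_trace", class(out))
  out
}

#' Recovered fraction of membrane tension
#'
#' Fraction of the stimulus-induced tension drop regained within `window`
#' seconds of stimulus onset:
#' \deqn{\frac{\sigma(t_{on} + w) - \sigma_{min}}{\sigma_{baseline} - \sigma_{min}},}
#' clipped to \[0, 1.1\]. The baseline is the pre-stimulus mean. With
#' `smooth_width > 0` the trace is Gaussian-smoothed before the minimum and
#' endpoint are read off (recommended for noisy single-frame tension
#' estimates); set it to 0 to use the raw trace.
#'
#' Returns `NA` with a warning when the trace shows no dip beyond
#' `noise_factor` times the pre-stimulus standard deviation.
#'
#' @param trace A [simulate_exo_endo()] result or any data frame with
#'   `time_s`, `tension_pN_per_um`; stimulus onset from attribute `t_on` or
#'   the `t_on` argument.
#' @param window Recovery window (s); default 50.
#' @param t_on Stimulus onset (s); default from the trace attribute.
#' @param smooth_width Gaussian smoothing sigma (s); default 2.
#' @param noise_factor Dip-detection multiple of baseline noise; default 3.
#' @return Recovered fraction (dimensionless), or `NA` when no dip is
#'   discernible.
#' @export
recovered_fraction <- function(trace, window = 50, t_on = NULL,
                               smooth_width = 2, noise_factor = 3) {
  check_columns(trace, c("time_s", "tension_pN_per_um"), "trace")
  t_on <- t_on %||% attr(trace, "t_on")
  if (is.null(t_on)) abort("Provide the stimulus onset `t_on`.", class = "memtide_domain_error")
  time <- trace$time_s
  if (max(time) < t_on + window) {
    abort(sprintf("Trace must span t_on + window = %.3g s.", t_on + window),
          class = "memtide_domain_error")
  }
  sig <- trace$tension_pN_per_um
  if (smooth_width > 0 && length(time) > 4) {
    sig <- gaussian_smooth(sig, dt = median(diff(time)), width = smooth_width)
  }
  # keep the baseline clear of the smoothing kernel's reach into the dip
  pre <- time < t_on - 4 * smooth_width
  if (sum(pre) < 2) pre <- time < t_on
  if (sum(pre) < 2) abort("Need pre-stimulus samples for a baseline.", class = "memtide_domain_error")
  baseline <- mean(sig[pre])
  noise <- sd(trace$tension_pN_per_um[pre])
  post <- time >= t_on & time <= t_on + window
  i_min <- which(post)[which.min(sig[post])]
  sig_min <- sig[i_min]
  if ((baseline - sig_min) <= noise_factor * noise) {
    warn("No discernible tension dip beyond baseline noise; recovered fraction undefined.")
    return(NA_real_)
  }
  sig_end <- approx(time, sig, xout = t_on + window)$y
  rf <- (sig_end - sig_min) / (baseline - sig_min)
  min(max(rf, 0), 1.1)
}

#' Calcium-tension anticorrelation
#'
#' Pearson correlation between the calcium signal (\eqn{\Delta F/F}) and
#' membrane tension over the analysis window. Calcium-stimulated exocytosis
#' lowers tension, so coupled traces give strongly negative values.
#'
#' @param trace Data frame with `time_s`, `tension_pN_per_um` and
#'   `dF_over_F` on a common clock.
#' @param window Optional `c(t0, t1)` restricting the analysis window.
#' @return Pearson correlation coefficient, or `NA` (with a warning) when a
#'   channel is constant.
#' @export
calcium_tension_anticorrelation <- function(trace, window = NULL) {
  check_columns(trace, c("time_s", "tension_pN_per_um", "dF_over_F"), "trace")
  keep <- rep(TRUE, nrow(trace))
  if (!is.null(window)) {
    keep <- trace$time_s >= window[1] & trace$time_s <= window[2]
  }
  x <- trace$dF_over_F[keep]
  y <- trace$tension_pN_per_um[keep]
  if (sd(x) == 0 || sd(y) == 0 || !is.finite(sd(x)) || !is.finite(sd(y))) {
    warn("Constant channel: correlation undefined.")
    return(NA_real_)
  }
  cor(x, y)
}
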