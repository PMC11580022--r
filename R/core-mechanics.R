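# Tether and optical-trap mechanics.
#
# A membrane tether pulled from a cell held at force f reports the local
# membrane tension sigma through f = 2*pi*sqrt(2*kappa*sigma), where kappa is
# the membrane bending modulus. The tether radius satisfies f * r = 2*pi*kappa.

#' Membrane tension from tether force
#'
#' Inverts the tether force relation \eqn{f = 2\pi\sqrt{2\kappa\sigma}} to
#' give \eqn{\sigma = f^2 / (8\pi^2\kappa)}.
#'
#' @param force Tether force (pN), non-negative. Vectorized.
#' @param kappa Membrane bending modulus (pN um); default 0.27.
#' @return Membrane tension (pN/um).
#' @seealso [force_from_tension()], [radius_from_force()]
#' @export
#' @examples
#' tension_from_force(10.32) # ~ 5 pN/um
tension_from_force <- function(force, kappa = memtide_constants()$kappa) {
  check_number(force, "force", nonneg = TRUE)
  check_number(kappa, "kappa", positive = TRUE, allow_vector = FALSE)
  force^2 / (8 * pi^2 * kappa)
}

#' Tether force from membrane tension
#'
#' \eqn{f = 2\pi\sqrt{2\kappa\sigma}}; monotone increasing in `tension`.
#'
#' @param tension Membrane tension (pN/um), non-negative. Vectorized.
#' @inheritParams tension_from_force
#' @return Tether force (pN).
#' @export
#' @examples
#' force_from_tension(5) # ~ 10.32 pN
force_from_tension <- function(tension, kappa = memtide_constants()$kappa) {
  check_number(tension, "tension", nonneg = TRUE)
  check_number(kappa, "kappa", positive = TRUE, allow_vector = FALSE)
  2 * pi * sqrt(2 * kappa * tension)
}

#' Tether radius from tether force
#'
#' \eqn{r = 2\pi\kappa / f}, equivalently \eqn{r = \sqrt{\kappa/(2\sigma)}}.
#' Force and radius are inversely proportional at fixed bending modulus.
#'
#' @param force Tether force (pN), strictly positive. Vectorized.
#' @inheritParams tension_from_force
#' @return Tether radius (um).
#' @export
#' @examples
#' radius_from_force(10.32) # ~ 0.164 um
radius_from_force <- function(force, kappa = memtide_constants()$kappa) {
  check_number(force, "force", nonneg = TRUE)
  check_number(kappa, "kappa", positive = TRUE, allow_vector = FALSE)
  if (any(force == 0)) {
    abort("Tether radius is undefined at zero force.", class = "memtide_domain_error")
  }
  2 * pi * kappa / force
}

#' Bead force from trap displacement
#'
#' In the linear-spring regime of an optical trap, the force on the bead is
#' the trap stiffness times the deviation of the bead from its zero-force
#' position, \eqn{f_b = k_{trap} \Delta r}.
#'
#' @param dr Bead displacement from the zero-force position (um), >= 0.
#' @param k_trap Trap stiffness (pN/um).
#' @return Force on the bead (pN).
#' @export
#' @examples
#' force_from_displacement(0.017, 75) # ~ 1.3 pN: the tracking-error force floor
force_from_displacement <- function(dr, k_trap) {
  check_number(dr, "dr", nonneg = TRUE)
  check_number(k_trap, "k_trap", positive = TRUE, allow_vector = FALSE)
  k_trap * dr
}

#' Stokes drag coefficient of a bead
#'
#' \eqn{\gamma = 6\pi\eta R_{bead}}. Note `bead_radius` is a radius; bead
#' batches are usually quoted by diameter (1.9 or 3.2 um), so divide by two
#' before calling.
#'
#' @param fluid_viscosity 3D fluid viscosity (pN s/um^2); water is 1e-3.
#' @param bead_radius Bead radius (um), not diameter.
#' @return Drag coefficient (pN s/um).
#' @export
drag_coefficient <- function(fluid_viscosity = 1e-3, bead_radius = 1.5) {
  check_number(fluid_viscosity, "fluid_viscosity", positive = TRUE, allow_vector = FALSE)
  check_number(bead_radius, "bead_radius", positive = TRUE, allow_vector = FALSE)
  6 * pi * fluid_viscosity * bead_radius
}

#' Hydrodynamic force on an oscillated trapped bead
#'
#' During stage-oscillation calibration the bead experiences
#' \eqn{f_{hydro} = \gamma \omega_d A_{pp} / 2}, valid in the regime
#' \eqn{\omega_d \tau \ll 1} with \eqn{\tau = \gamma / k_{trap}}.
#' Linear in each argument.
#'
#' @param gamma Bead drag coefficient (pN s/um), see [drag_coefficient()].
#' @param w_d Angular drive frequency (rad/s), \eqn{2\pi f_d}.
#' @param A_pp Peak-to-peak stage oscillation amplitude (um).
#' @return Hydrodynamic force amplitude (pN).
#' @export
hydrodynamic_force <- function(gamma, w_d, A_pp) {
  check_number(gamma, "gamma", nonneg = TRUE)
  check_number(w_d, "w_d", nonneg = TRUE)
  check_number(A_pp, "A_pp", nonneg = TRUE)
  gamma * w_d * A_pp / 2
}

#' Reynolds number of a moving bead
#'
#' \eqn{Re = v\, D_{bead}\, \rho / \eta}. For micron beads in water at
#' um/s speeds this is ~1e-6, so inertial forces are negligible during
#' trap calibration.
#'
#' @param v_l Liquid (or bead) speed (um/s).
#' @param D_bead Bead diameter (um).
#' @param rho Fluid density (pN s^2/um^4); water is 1e-9.
#' @param eta 3D fluid viscosity (pN s/um^2); water is 1e-3.
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' reynolds_number(1, 1) # 1e-6
reynolds_number <- function(v_l, D_bead, rho = 1e-9, eta = 1e-3) {
  check_number(v_l, "v_l", nonneg = TRUE)
  check_number(D_bead, "D_bead", positive = TRUE)
  check_number(rho, "rho", positive = TRUE, allow_vector = FALSE)
  check_number(eta, "eta", positive = TRUE, allow_vector = FALSE)
  v_l * D_bead * rho / eta
}

#' Calibrate trap stiffness from oscillation records
#'
#' The stage is oscillated sinusoidally while a bead is held in the trap; in
#' the low-frequency regime the bead oscillation amplitude is
#' \eqn{A_{bead} = f_{hydro} / k_{trap}}. The stiffness is the reciprocal
#' slope of a linear fit of `A_bead` on `f_hydro`.
#'
#' @param records Data frame with columns `f_hydro_pN` and `A_bead_um`, one
#'   row per oscillation condition; at least two distinct `f_hydro_pN` values.
#' @param intercept Fit an intercept term (default `TRUE`)? With ideal data
#'   the line passes through the origin either way.
#' @return A `trap_calibration` object: list with `k_trap` (pN/um), the `lm`
#'   fit, and the records. Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' rec <- tibble::tibble(f_hydro_pN = c(2, 4, 8.88), A_bead_um = f_hydro_pN / 100)
#' calibrate_trap(rec)$k_trap # 100
calibrate_trap <- function(records, intercept = TRUE) {
  check_columns(records, c("f_hydro_pN", "A_bead_um"), "records")
  if (nrow(records) < 2 || length(unique(records$f_hydro_pN)) < 2) {
    abort("Trap calibration needs >= 2 records with distinct `f_hydro_pN`.",
          class = "memtide_fit_error")
  }
  fit <- if (intercept) {
    lm(A_bead_um ~ f_hydro_pN, data = records)
  } else {
    lm(A_bead_um ~ f_hydro_pN - 1, data = records)
  }
  slope <- coef(fit)[["f_hydro_pN"]]
  if (!is.finite(slope) || slope <= 0) {
    abort("Trap calibration fit produced a non-positive slope.",
          class = "memtide_fit_error")
  }
  structure(
    list(k_trap = 1 / slope, fit = fit, records = as_tibble(records),
         intercept = intercept),
    class = "trap_calibration"
  )
}

#' @export
print.trap_calibration <- function(x, ...) {
  cat("<trap_calibration>\n")
  cat(sprintf("  k_trap: %.4g pN/um (from %d oscillation records)\n",
              x$k_trap, nrow(x$records)))
  invisible(x)
}

#' Check the low-frequency trap-calibration regime
#'
#' The amplitude relation behind [calibrate_trap()] holds only when
#' \eqn{\omega_d \tau \ll 1}, \eqn{\tau = \gamma/k_{trap}}. Returns the
#' dimensionless product and warns when it exceeds `limit`.
#'
#' @param k_trap Trap stiffness (pN/um).
#' @param gamma Bead drag coefficient (pN s/um).
#' @param f_d Drive frequency (Hz).
#' @param limit Threshold above which the regime is flagged (default 0.1).
#' @return `w_d * tau` (invisibly flagged via warning when above `limit`).
#' @export
check_trap_regime <- function(k_trap, gamma, f_d, limit = 0.1) {
  check_number(k_trap, "k_trap", positive = TRUE, allow_vector = FALSE)
  check_number(gamma, "gamma", positive = TRUE, allow_vector = FALSE)
  check_number(f_d, "f_d", positive = TRUE, allow_vector = FALSE)
  wt <- 2 * pi * f_d * gamma / k_trap
  if (wt > limit) {
    warn(sprintf("w_d * tau = %.3g exceeds %.3g: outside the low-frequency calibration regime.",
                 wt, limit))
  }
  wt
}

#' Detection threshold for tension changes
#'
#' Propagates the single-frame force uncertainty `delta_f` through
#' \eqn{\sigma = f^2/(8\pi^2\kappa)}: at resting force f the smallest
#' detectable tension change is \eqn{\delta\sigma = f\,\delta f/(4\pi^2\kappa)}.
#'
#' @param force Resting tether force (pN).
#' @param delta_f Force uncertainty (pN); default 1.3 pN (17 nm tracking
#'   error at a 75 pN/um trap).
#' @inheritParams tension_from_force
#' @return Tension detection threshold (pN/um).
#' @export
tension_threshold <- function(force, delta_f = memtide_constants()$delta_f,
                              kappa = memtide_constants()$kappa) {
  check_number(force, "force", nonneg = TRUE)
  check_number(delta_f, "delta_f", positive = TRUE, allow_vector = FALSE)
  check_number(kappa, "kappa", positive = TRUE, allow_vector = FALSE)
  force * delta_f / (4 * pi^2 * kappa)
}

#' Membrane tension from tether fluorescence
#'
#' Tether fluorescence integrates over the tube circumference, so intensity
#' is proportional to tether radius; with \eqn{f \propto 1/r \propto \sigma^{1/2}}
#' this gives \eqn{\sigma \propto 1/I^2}. Anchored by a reference pair
#' measured at known tension: \eqn{\sigma = \sigma_{ref} (I_{ref}/I)^2}.
#'
#' @param intensity Background-corrected tether intensity (a.u.), > 0. Vectorized.
#' @param i_ref Reference intensity (a.u.), > 0.
#' @param sigma_ref Tension at the reference intensity (pN/um), > 0.
#' @return Membrane tension (pN/um).
#' @export
#' @examples
#' tension_from_fluorescence(50, i_ref = 100, sigma_ref = 2) # 8: half intensity, 4x tension
tension_from_fluorescence <- function(intensity, i_ref, sigma_ref) {
  check_number(intensity, "intensity", positive = TRUE)
  check_number(i_ref, "i_ref", positive = TRUE, allow_vector = FALSE)
  check_number(sigma_ref, "sigma_ref", positive = TRUE, allow_vector = FALSE)
  sigma_ref * (i_ref / intensity)^2
}

#' Build a force trace from tracked bead displacements
#'
#' Converts a displacement time series to force and tension columns and
#' validates the time base.
#'
#' @param trace Data frame with columns `time_s` and `dr_um` (bead deviation
#'   from the zero-force position).
#' @param k_trap Trap stiffness (pN/um).
#' @inheritParams tension_from_force
#' @return Tibble with `time_s`, `dr_um`, `force_pN`, `tension_pN_per_um`.
#' @export
force_trace <- function(trace, k_trap, kappa = memtide_constants()$kappa) {
  check_columns(trace, c("time_s", "dr_um"), "trace")
  check_time_monotone(trace$time_s, "time_s")
  check_number(k_trap, "k_trap", positive = TRUE, allow_vector = FALSE)
  trace |>
    as_tibble() |>
    mutate(
      force_pN = force_from_displacement(pmax(.data$dr_um, 0), k_trap),
      tension_pN_per_um = tension_from_force(.data$force_pN, kappa)
    )
}

#' Fit a double-exponential step response
#'
#' Characterizes the relaxation of tether force after a step-like tether
#' extension. The force trace is normalized to
#' \eqn{\tilde f = (f - f_0)/(f_{max} - f_0)} and fit with
#' \eqn{\tilde f(t) = 1 - A_1 e^{-t/\tau_1} - A_2 e^{-t/\tau_2}},
#' amplitudes constrained non-negative with \eqn{A_1 + A_2 \le 1.05}.
#' Initialization comes from a single-exponential fit of the tail.
#'
#' @param trace Data frame with columns `time_s` and `force_pN` (or an
#'   already normalized `f_norm` column), starting at the step (t = 0 at the
#'   first sample).
#' @param f0 Baseline force before the step; default the first sample.
#' @param f_max Plateau force; default the mean of the last 10% of samples.
#' @return A `step_fit` object with `amplitudes` and `time_constants`
#'   (sorted by increasing time constant), the `nls` fit and the normalized
#'   data. Supports `tidy()`/`glance()`.
#' @export
fit_step_response <- function(trace, f0 = NULL, f_max = NULL) {
  check_columns(trace, "time_s", "trace")
  t <- trace$time_s - trace$time_s[1]
  if ("f_norm" %in% names(trace)) {
    fn <- trace$f_norm
  } else {
    check_columns(trace, "force_pN", "trace")
    f <- trace$force_pN
    f0 <- f0 %||% f[1]
    f_max <- f_max %||% mean(tail(f, max(3L, ceiling(length(f) / 10))))
    if (abs(f_max - f0) < sqrt(.Machine$double.eps) * max(1, abs(f0))) {
      abort("Flat trace: f_max = f0, cannot normalize step response.",
            class = "memtide_fit_error")
    }
    fn <- (f - f0) / (f_max - f0)
  }
  # single-exponential initial guess from log-linear fit of 1 - fn
  resid1 <- pmax(1 - fn, 1e-6)
  ok <- resid1 > 1e-3 & t > 0
  tau0 <- if (sum(ok) >= 2) {
    sl <- unname(coef(lm(log(resid1[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  dat <- tibble(t = t, fn = fn)
  fit <- minpack.lm::nlsLM(
    fn ~ 1 - a1 * exp(-t / tau1) - a2 * exp(-t / tau2),
    data = dat,
    start = list(a1 = 0.5, a2 = 0.5, tau1 = tau0 / 3, tau2 = tau0 * 3),
    lower = c(0, 0, 1e-6, 1e-6),
    upper = c(1.05, 1.05, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  if (cf[["a1"]] + cf[["a2"]] > 1.05 + 1e-6) {
    warn("Step-response amplitudes sum above 1.05; fit may be ill-conditioned.")
  }
  ord <- order(c(cf[["tau1"]], cf[["tau2"]]))
  structure(
    list(
      amplitudes = unname(c(cf[["a1"]], cf[["a2"]])[ord]),
      time_constants = unname(c(cf[["tau1"]], cf[["tau2"]])[ord]),
      fit = fit,
      data = dat
    ),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat("<step_fit>\n")
  cat(sprintf("  amplitudes:     %s\n", paste(signif(x$amplitudes, 4), collapse = ", ")))
  cat(sprintf("  time constants: %s s\n", paste(signif(x$time_constants, 4), collapse = ", ")))
  invisible(x)
}
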