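# Diffusive membrane-tension propagation.
#
# When the plasma membrane flows past an array of immobile transmembrane
# obstacles, tension perturbations obey a diffusion equation
#   d(sigma)/dt = D_sigma * laplacian(sigma) + E * Q(t) * delta2(x),
# with tension diffusivity D_sigma = E * k / eta, where E is the 2D stretch
# modulus, eta the 2D membrane viscosity and k the Darcy permeability of the
# obstacle array. Pulling a tether at speed dL/dt extracts membrane area at
# rate Q(t) = 2*pi*r_t*dL/dt, acting as a point source (sink) of tension.

#' Dimensionless permeability factor of a random obstacle array
#'
#' Darcy permeability of 2D flow through a random array of fixed discs,
#' \eqn{k = a^2 f(\phi)}, with
#' \deqn{f(\phi) = \frac{-\ln\phi - 1.476 + 2\phi - 1.774\phi^2 + 4.076\phi^3}{8\phi}.}
#' A dilute-limit expansion for flow past random cylinders; rapidly decaying
#' and valid for area fractions up to about 0.3.
#'
#' @param phi Obstacle area fraction, in (0, 0.3]. Vectorized.
#' @return Dimensionless factor \eqn{f(\phi)}, strictly decreasing in `phi`.
#' @seealso [darcy_permeability()]
#' @export
#' @examples
#' permeability_factor(0.15) # ~ 0.579
permeability_factor <- function(phi) {
  check_number(phi, "phi")
  if (any(phi <= 0 | phi > 0.3)) {
    abort("`phi` must lie in (0, 0.3]: the dilute random-array permeability is not valid at higher packing.",
          class = "memtide_range_error")
  }
  (-log(phi) - 1.476 + 2 * phi - 1.774 * phi^2 + 4.076 * phi^3) / (8 * phi)
}

#' Darcy permeability of the obstacle array
#'
#' \eqn{k = a^2 f(\phi)} with `a` the obstacle radius. The default radius,
#' 2.3 nm, is a calibration constant chosen once so that typical measured
#' obstacle fractions map onto nm^2-scale permeabilities; it is not a
#' measured quantity.
#'
#' @inheritParams permeability_factor
#' @param a Obstacle radius (um); default 0.0023 um = 2.3 nm.
#' @return Darcy permeability (um^2).
#' @export
#' @examples
#' darcy_permeability(0.15) * 1e6 # ~ 3.06 nm^2
darcy_permeability <- function(phi, a = memtide_constants()$obstacle_radius) {
  check_number(a, "a", positive = TRUE, allow_vector = FALSE)
  a^2 * permeability_factor(phi)
}

#' Obstacle area fraction from the immobile protein fraction
#'
#' FRAP gives the fraction of membrane proteins that are immobile
#' (cytoskeleton-anchored). Assuming a fixed fraction of membrane area is
#' occupied by transmembrane proteins (default 25%), the obstacle area
#' fraction is their product.
#'
#' @param immobile_fraction Immobile protein fraction from FRAP, in \[0, 1\].
#' @param protein_area_coverage Fraction of membrane area occupied by
#'   transmembrane proteins; default 0.25.
#' @return Obstacle area fraction \eqn{\phi}.
#' @export
#' @examples
#' obstacle_fraction(0.60) # 0.150, chromaffin-like
#' obstacle_fraction(0.37) # 0.0925 ~ 0.093, soma-like
obstacle_fraction <- function(immobile_fraction,
                              protein_area_coverage = memtide_constants()$protein_area_coverage) {
  check_fraction(immobile_fraction, "immobile_fraction")
  check_fraction(protein_area_coverage, "protein_area_coverage")
  immobile_fraction * protein_area_coverage
}

#' Tension diffusion coefficient
#'
#' \eqn{D_\sigma = E k / \eta}: linear in the stretch modulus and the Darcy
#' permeability, inverse in the 2D membrane viscosity.
#'
#' @param E 2D membrane stretch modulus (pN/um).
#' @param k Darcy permeability (um^2).
#' @param eta 2D membrane viscosity (pN s/um).
#' @return Tension diffusivity (um^2/s).
#' @export
tension_diffusivity <- function(E, k, eta) {
  check_number(E, "E", positive = TRUE)
  check_number(k, "k", positive = TRUE)
  check_number(eta, "eta", positive = TRUE)
  E * k / eta
}

#' Membrane mechanical model
#'
#' Bundles the parameters tying FRAP-derived obstacle fractions to tension
#' diffusivity. `k` is derived from `a` and `phi` when not given; `D_sigma`
#' is derived as \eqn{Ek/\eta} when not given. Pass `D_sigma` directly to
#' bypass the permeability chain (e.g. for literature values).
#'
#' @param E 2D stretch modulus (pN/um); default 40. Order-of-magnitude
#'   config value: the cross-cell-type comparisons exposed by this package
#'   use only ratios in which E and eta cancel.
#' @param eta 2D membrane viscosity (pN s/um); default 1e-3.
#' @param a Obstacle radius (um); default 2.3 nm.
#' @param phi Obstacle area fraction; optional.
#' @param k Darcy permeability (um^2); derived from `a`, `phi` if omitted.
#' @param D_sigma Tension diffusivity (um^2/s); derived if omitted.
#' @return A `membrane_model` list with fields `E, eta, a, phi, k, D_sigma`.
#' @export
#' @examples
#' membrane_model(phi = 0.15)
#' membrane_model(D_sigma = 0.024) # HeLa-like literature value
membrane_model <- function(E = memtide_constants()$E,
                           eta = memtide_constants()$eta_membrane,
                           a = memtide_constants()$obstacle_radius,
                           phi = NULL, k = NULL, D_sigma = NULL) {
  check_number(E, "E", positive = TRUE, allow_vector = FALSE)
  check_number(eta, "eta", positive = TRUE, allow_vector = FALSE)
  check_number(a, "a", positive = TRUE, allow_vector = FALSE)
  if (is.null(k) && !is.null(phi)) k <- darcy_permeability(phi, a)
  if (is.null(D_sigma)) {
    if (is.null(k)) {
      abort("Provide `D_sigma`, `k`, or `phi` to define the model.",
            class = "memtide_domain_error")
    }
    D_sigma <- tension_diffusivity(E, k, eta)
  }
  check_number(D_sigma, "D_sigma", positive = TRUE, allow_vector = FALSE)
  structure(list(E = E, eta = eta, a = a, phi = phi, k = k, D_sigma = D_sigma),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("<membrane_model>\n")
  cat(sprintf("  E = %g pN/um, eta = %g pN s/um\n", x$E, x$eta))
  if (!is.null(x$phi)) cat(sprintf("  phi = %g, a = %g um\n", x$phi, x$a))
  if (!is.null(x$k)) cat(sprintf("  k = %g um^2 (%.3g nm^2)\n", x$k, x$k * 1e6))
  cat(sprintf("  D_sigma = %g um^2/s\n", x$D_sigma))
  invisible(x)
}

#' Pulling-tether motion program
#'
#' Piecewise-linear length program of the pulling tether: extend at
#' `extend_speed` for `extend_distance`, hold for `hold_time`, retract at
#' `retract_speed` back to the start. Defaults follow the standard
#' double-tether protocol (1 um/s out for 40 um, 30 s hold, 1 um/s back;
#' ~110 s total).
#'
#' @param extend_speed Extension speed (um/s).
#' @param extend_distance Extension distance (um).
#' @param hold_time Hold duration at full extension (s).
#' @param retract_speed Retraction speed (um/s).
#' @param tether_radius Tether radius used for the area-extraction source
#'   (um); default from [radius_from_force()] at a typical 10 pN tether force.
#' @param start_time Protocol start time (s); the length program is constant
#'   before it.
#' @return A `pull_protocol` list.
#' @export
pull_protocol <- function(extend_speed = 1, extend_distance = 40, hold_time = 30,
                          retract_speed = 1,
                          tether_radius = radius_from_force(10),
                          start_time = 0) {
  check_number(extend_speed, "extend_speed", nonneg = TRUE, allow_vector = FALSE)
  check_number(extend_distance, "extend_distance", nonneg = TRUE, allow_vector = FALSE)
  check_number(hold_time, "hold_time", nonneg = TRUE, allow_vector = FALSE)
  check_number(retract_speed, "retract_speed", nonneg = TRUE, allow_vector = FALSE)
  check_number(tether_radius, "tether_radius", positive = TRUE, allow_vector = FALSE)
  check_number(start_time, "start_time", nonneg = TRUE, allow_vector = FALSE)
  structure(
    list(extend_speed = extend_speed, extend_distance = extend_distance,
         hold_time = hold_time, retract_speed = retract_speed,
         tether_radius = tether_radius, start_time = start_time),
    class = "pull_protocol"
  )
}

#' @export
print.pull_protocol <- function(x, ...) {
  cat("<pull_protocol>\n")
  cat(sprintf("  extend %g um at %g um/s, hold %g s, retract at %g um/s\n",
              x$extend_distance, x$extend_speed, x$hold_time, x$retract_speed))
  cat(sprintf("  tether radius %g um, start %g s, duration %g s\n",
              x$tether_radius, x$start_time, protocol_duration(x)))
  invisible(x)
}

# constant-rate segments (absolute time): tibble(t0, t1, rate)
protocol_segments <- function(protocol) {
  p <- protocol
  t_ext <- if (p$extend_speed > 0) p$extend_distance / p$extend_speed else 0
  t_ret <- if (p$retract_speed > 0) p$extend_distance / p$retract_speed else 0
  ts <- p$start_time
  tibble(
    t0 = c(ts, ts + t_ext, ts + t_ext + p$hold_time),
    t1 = c(ts + t_ext, ts + t_ext + p$hold_time, ts + t_ext + p$hold_time + t_ret),
    rate = c(ifelse(t_ext > 0, p$extend_speed, 0), 0,
             ifelse(t_ret > 0, -p$retract_speed, 0))
  ) |> filter(.data$t1 > .data$t0)
}

#' Protocol duration
#'
#' Total duration of a [pull_protocol()] from its start time to the end of
#' retraction.
#'
#' @param protocol A [pull_protocol()].
#' @return Duration (s).
#' @export
protocol_duration <- function(protocol) {
  seg <- protocol_segments(protocol)
  if (nrow(seg) == 0) return(0)
  max(seg$t1) - protocol$start_time
}

#' Pulling-tether length program
#'
#' @param protocol A [pull_protocol()].
#' @param t Time (s). Vectorized.
#' @return Tether length above its initial value, L(t) (um); continuous and
#'   piecewise linear.
#' @export
protocol_length <- function(protocol, t) {
  seg <- protocol_segments(protocol)
  L <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    L <- L + seg$rate[i] * pmin(pmax(t - seg$t0[i], 0), seg$t1[i] - seg$t0[i])
  }
  L
}

#' Pulling-tether extension rate
#'
#' @inheritParams protocol_length
#' @return dL/dt (um/s), piecewise constant (right-continuous at kinks).
#' @export
protocol_rate <- function(protocol, t) {
  seg <- protocol_segments(protocol)
  r <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    r[t >= seg$t0[i] & t < seg$t1[i]] <- seg$rate[i]
  }
  r
}

#' Membrane-area extraction rate of the pulling tether
#'
#' \eqn{Q(t) = 2\pi r_t \, dL/dt} (um^2/s): the rate at which tether growth
#' removes membrane area at the tether base. Negative during retraction.
#'
#' @inheritParams protocol_length
#' @return Area extraction rate (um^2/s).
#' @export
extraction_rate <- function(protocol, t) {
  2 * pi * protocol$tether_radius * protocol_rate(protocol, t)
}

# ---- analytic plane kernel -------------------------------------------------
#
# On the infinite plane, the tension change at distance d from a point source
# of strength E*Q(t) is the time convolution with the 2D heat kernel:
#   dsigma(d, t) = int_0^t E*Q(t') / (4 pi D (t - t')) exp(-d^2/(4 D (t-t'))) dt'.
# For piecewise-constant Q the integral has the closed form
#   (E*Q / 4 pi D) * [E1(beta/s_hi) - E1(beta/s_lo)],  beta = d^2/(4D),
# with s = t - t' running over the segment and E1 the exponential integral.

# exponential integral E1, safe at 0+ and Inf (underflows to 0 beyond ~708)
e1_safe <- function(x) {
  out <- numeric(length(x))
  small <- is.finite(x) & x < 708
  if (any(small)) out[small] <- pracma::expint_E1(x[small])
  out
}

plane_response <- function(times, segments, r_t, D, E, d) {
  beta <- d^2 / (4 * D)
  out <- numeric(length(times))
  for (i in seq_len(nrow(segments))) {
    if (segments$rate[i] == 0) next
    Q <- 2 * pi * r_t * segments$rate[i]
    act <- which(times > segments$t0[i])
    if (length(act) == 0) next
    s_hi <- times[act] - segments$t0[i]
    s_lo <- pmax(times[act] - segments$t1[i], 0)
    e_hi <- e1_safe(beta / s_hi)
    e_lo <- e1_safe(ifelse(s_lo > 0, beta / s_lo, Inf))
    out[act] <- out[act] + E * Q / (4 * pi * D) * (e_hi - e_lo)
  }
  out
}

# ---- radial finite-difference backend --------------------------------------
#
# Reflecting disc of radius R with the source at the center. Finite-volume
# discretization in r (cell centers r_i = (i - 1/2) dr) conserves the area
# integral of sigma exactly; Crank-Nicolson time stepping; the source term
# injects E * (area extracted during the step) into the innermost cell.

disc_response <- function(times, protocol, D, E, d, disc_radius, dr, dt) {
  if (d >= disc_radius) {
    abort("Probe distance `d` must be smaller than `disc_radius`.",
          class = "memtide_domain_error")
  }
  N <- max(8L, ceiling(disc_radius / dr))
  dr <- disc_radius / N
  r_faces <- (0:N) * dr
  r_cent <- (seq_len(N) - 0.5) * dr
  vol <- 2 * pi * r_cent * dr
  # tridiagonal generator A: d sigma_i / dt = sum_j A_ij sigma_j
  wl <- D * r_faces[seq_len(N)] / (r_cent * dr^2)      # coupling to i-1
  wu <- D * r_faces[2:(N + 1)] / (r_cent * dr^2)       # coupling to i+1
  wl[1] <- 0
  wu[N] <- 0
  A <- Matrix::bandSparse(N, N,
    k = c(-1, 0, 1),
    diagonals = list(wl[-1], -(wl + wu), wu[-N])
  )
  I <- Matrix::Diagonal(N)
  t_end <- max(times)
  nsteps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / nsteps
  M1 <- I - (dt / 2) * A
  M2 <- I + (dt / 2) * A
  lu_fac <- Matrix::lu(M1)
  tg <- (0:nsteps) * dt
  L_tg <- protocol_length(protocol, tg)
  sig <- numeric(N)
  # probe readout by linear interpolation between neighbouring cell centers
  probe_at <- function(sig) approx(r_cent, sig, xout = d, rule = 2)$y
  out_grid <- numeric(nsteps + 1)
  out_grid[1] <- probe_at(sig)
  for (n in seq_len(nsteps)) {
    dA <- 2 * pi * protocol$tether_radius * (L_tg[n + 1] - L_tg[n])
    rhs <- M2 %*% sig
    rhs[1] <- rhs[1] + E * dA / vol[1]
    sig <- as.numeric(Matrix::solve(lu_fac, rhs))
    out_grid[n + 1] <- probe_at(sig)
  }
  list(
    delta_sigma = approx(tg, out_grid, xout = times, rule = 2)$y,
    final_field = tibble(r_um = r_cent, delta_sigma = sig, cell_area = vol),
    area_integral = sum(sig * vol),
    net_extracted_area = 2 * pi * protocol$tether_radius * L_tg[nsteps + 1]
  )
}

#' Simulate the probe-tether tension response
#'
#' Forward model of the double-tether experiment: the pulling tether extracts
#' membrane area according to its motion program, acting as a point source of
#' tension that spreads diffusively with diffusivity `D_sigma`; the probe
#' tether a distance `d` away reads out the local tension change.
#'
#' Two backends are available: the closed-form heat-kernel convolution on the
#' infinite plane (exact for the piecewise-linear protocol, via exponential
#' integrals) and a conservative radial finite-difference solver on a
#' reflecting disc (terminal-scale bounded geometry). The two bracket the
#' physical situation and agree closely when the disc is large compared to
#' the diffusion length.
#'
#' @param protocol A [pull_protocol()].
#' @param model A [membrane_model()] (its `D_sigma` and `E` are used).
#' @param d Probe-tether distance from the pulling tether (um), > 0.
#' @param geometry `"plane"` (analytic kernel, default) or `"disc"`
#'   (reflecting disc, finite differences).
#' @param times Output time grid (s); default 0 to protocol duration + 30 s
#'   at 10 Hz.
#' @param lag_tau Optional probe-tether response time constant (s); when
#'   given, the tension signal is passed through a first-order low-pass
#'   filter (default `NULL`, no lag).
#' @param disc_radius Disc radius R (um) for `geometry = "disc"`; default 5.
#' @param dr Radial grid step (um) for the disc backend; default
#'   `disc_radius / 200`.
#' @param dt Time step (s) for the disc backend; default 0.02.
#' @return A `probe_response` tibble with columns `time_s` and
#'   `delta_sigma_pN_per_um`, carrying attributes `d`, `D_sigma`, `geometry`
#'   and (for the disc backend) the final radial field and area bookkeeping.
#' @export
#' @examples
#' resp <- simulate_probe_response(pull_protocol(), membrane_model(D_sigma = 24), d = 8)
#' max_probe_amplitude(resp)
simulate_probe_response <- function(protocol, model, d,
                                    geometry = c("plane", "disc"),
                                    times = NULL, lag_tau = NULL,
                                    disc_radius = 5, dr = disc_radius / 200,
                                    dt = 0.02) {
  geometry <- match.arg(geometry)
  check_number(d, "d", positive = TRUE, allow_vector = FALSE)
  if (!inherits(model, "membrane_model")) model <- do.call(membrane_model, model)
  D <- model$D_sigma
  check_number(D, "D_sigma", positive = TRUE, allow_vector = FALSE)
  if (is.null(times)) {
    times <- seq(0, protocol$start_time + protocol_duration(protocol) + 30, by = 0.1)
  }
  check_time_monotone(times, "times")
  extra <- list()
  if (geometry == "plane") {
    seg <- protocol_segments(protocol)
    ds <- plane_response(times, seg, protocol$tether_radius, D, model$E, d)
  } else {
    sol <- disc_response(times, protocol, D, model$E, d, disc_radius, dr, dt)
    ds <- sol$delta_sigma
    extra <- sol[c("final_field", "area_integral", "net_extracted_area")]
  }
  if (!is.null(lag_tau)) ds <- lag_filter(ds, times, lag_tau)
  res <- tibble(time_s = times, delta_sigma_pN_per_um = ds)
  attr(res, "d") <- d
  attr(res, "D_sigma") <- D
  attr(res, "geometry") <- geometry
  attr(res, "protocol") <- protocol
  for (nm in names(extra)) attr(res, nm) <- extra[[nm]]
  class(res) <- c("probe_response", class(res))
  res
}

#' Probe response to an instantaneous area extraction
#'
#' Closed-form response at distance `d` to an impulse removing area `area`
#' at t = 0:
#' \deqn{\Delta\sigma(d,t) = \frac{E\,A_0}{4\pi D_\sigma t}
#'   \exp\!\left(-\frac{d^2}{4 D_\sigma t}\right),}
#' which peaks at \eqn{t = d^2/(4 D_\sigma)}. Useful as an oracle and for
#' asymptotic arguments.
#'
#' @param d Distance from the source (um).
#' @param times Output times (s), > 0 entries give nonzero response.
#' @param D_sigma Tension diffusivity (um^2/s).
#' @param E 2D stretch modulus (pN/um).
#' @param area Extracted area A0 (um^2).
#' @return A `probe_response` tibble as in [simulate_probe_response()].
#' @export
impulse_probe_response <- function(d, times, D_sigma,
                                   E = memtide_constants()$E, area = 1) {
  check_number(d, "d", positive = TRUE, allow_vector = FALSE)
  check_number(D_sigma, "D_sigma", positive = TRUE, allow_vector = FALSE)
  ds <- ifelse(times > 0,
               E * area / (4 * pi * D_sigma * times) * exp(-d^2 / (4 * D_sigma * times)),
               0)
  res <- tibble(time_s = times, delta_sigma_pN_per_um = ds)
  attr(res, "d") <- d
  attr(res, "D_sigma") <- D_sigma
  attr(res, "geometry") <- "plane"
  class(res) <- c("probe_response", class(res))
  res
}

#' Time to sense a tension change at the probe tether
#'
#' First time, measured from the protocol start, at which the probe-tether
#' tension change exceeds `threshold` (linear interpolation between
#' samples). `Inf` when never exceeded.
#'
#' @param response A `probe_response` (or any data frame with `time_s` and
#'   `delta_sigma_pN_per_um`).
#' @param threshold Detection threshold (pN/um). Default propagates the
#'   1.3 pN force uncertainty through the force-tension relation at a
#'   10 pN resting force, via [tension_threshold()].
#' @param smooth_width Optional Gaussian smoothing (s, as sigma) applied
#'   before thresholding; default 0 (none).
#' @return A `sense_result` tibble with `t_sense` (s), `threshold` and
#'   `max_amplitude` (pN/um).
#' @export
sense_time <- function(response, threshold = tension_threshold(10),
                       smooth_width = 0) {
  check_columns(response, c("time_s", "delta_sigma_pN_per_um"), "response")
  check_number(threshold, "threshold", positive = TRUE, allow_vector = FALSE)
  t <- response$time_s
  y <- response$delta_sigma_pN_per_um
  if (smooth_width > 0 && length(t) > 2) {
    y <- gaussian_smooth(y, dt = median(diff(t)), width = smooth_width)
  }
  start <- attr(response, "protocol")$start_time %||% 0
  max_amp <- max(y)
  if (max_amp < threshold) {
    t_sense <- Inf
  } else {
    i <- which(y >= threshold)[1]
    t_cross <- if (i == 1) t[1] else {
      t[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
    }
    t_sense <- max(t_cross - start, 0)
  }
  tibble(t_sense = t_sense, threshold = threshold, max_amplitude = max_amp)
}

#' Maximum probe-tether amplitude
#'
#' Maximum over time of the tension change at the probe tether.
#'
#' @inheritParams sense_time
#' @return Maximum \eqn{\Delta\sigma} (pN/um).
#' @export
max_probe_amplitude <- function(response) {
  check_columns(response, "delta_sigma_pN_per_um", "response")
  max(response$delta_sigma_pN_per_um)
}

#' Fit the tension diffusivity to a measured probe response
#'
#' Least-squares fit of the diffusive forward model (plane kernel) to a
#' measured probe-tether tension trace, over \eqn{\log_{10} D_\sigma}.
#' Optionally the tether separation is fit as an effective distance as well
#' (rapid, weakly distance-dependent propagation shows up as a best-fit
#' effective `d` much smaller than the geometric separation).
#'
#' A trace is reported as non-identifiable when fitting the model barely
#' improves on the null (flat zero) model; in that case the estimate should
#' not be interpreted.
#'
#' @param measured Data frame with `time_s` and `delta_sigma_pN_per_um`
#'   aligned to the protocol clock.
#' @param protocol The [pull_protocol()] that generated the perturbation.
#' @param model A [membrane_model()] supplying `E` (and the starting
#'   `D_sigma`, used to seed the search).
#' @param d Geometric tether separation (um). Required unless carried by
#'   `measured` as attribute `d`.
#' @param fit_effective_d Also fit an effective distance (default `FALSE`).
#' @param log10_D_range Search interval for log10(D_sigma); default (-3, 3).
#' @param lag_tau Optional probe response time constant passed to the
#'   forward model.
#' @return A `dsigma_fit` object: list with `D_sigma_hat`, `d_hat`,
#'   `residual_ss`, `null_ss`, `identifiable`, `fitted` (tibble) and inputs.
#'   Supports `tidy()`/`glance()`.
#' @export
fit_dsigma <- function(measured, protocol, model, d = NULL,
                       fit_effective_d = FALSE, log10_D_range = c(-3, 3),
                       lag_tau = NULL) {
  check_columns(measured, c("time_s", "delta_sigma_pN_per_um"), "measured")
  d <- d %||% attr(measured, "d")
  if (is.null(d)) abort("Provide the tether separation `d`.", class = "memtide_domain_error")
  if (!inherits(model, "membrane_model")) model <- do.call(membrane_model, model)
  times <- measured$time_s
  y <- measured$delta_sigma_pN_per_um
  seg <- protocol_segments(protocol)
  predict_ds <- function(D, dd) {
    p <- plane_response(times, seg, protocol$tether_radius, D, model$E, dd)
    if (!is.null(lag_tau)) p <- lag_filter(p, times, lag_tau) else p
  }
  sse <- function(pred) sum((y - pred)^2)
  null_ss <- sse(0 * y)
  if (fit_effective_d) {
    obj <- function(par) sse(predict_ds(10^par[1], exp(par[2])))
    init <- c(log10(model$D_sigma), log(d))
    opt <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    D_hat <- 10^opt$par[1]
    d_hat <- exp(opt$par[2])
    res_ss <- opt$value
  } else {
    obj <- function(l10D) sse(predict_ds(10^l10D, d))
    # coarse grid then local refinement: the objective can be multi-modal in
    # log D when the signal is weak
    grid <- seq(log10_D_range[1], log10_D_range[2], length.out = 25)
    v <- vapply(grid, obj, numeric(1))
    i0 <- which.min(v)
    lo <- grid[max(1, i0 - 1)]
    hi <- grid[min(length(grid), i0 + 1)]
    opt <- optimize(obj, lower = lo, upper = hi, tol = 1e-8)
    D_hat <- 10^opt$minimum
    d_hat <- d
    res_ss <- opt$objective
  }
  identifiable <- is.finite(res_ss) && null_ss > 0 &&
    (null_ss - res_ss) / null_ss > 0.05
  structure(
    list(
      D_sigma_hat = D_hat, d_hat = d_hat,
      residual_ss = res_ss, null_ss = null_ss,
      identifiable = identifiable,
      fit_effective_d = fit_effective_d,
      fitted = tibble(time_s = times,
                      delta_sigma_pN_per_um = predict_ds(D_hat, d_hat)),
      measured = as_tibble(measured), protocol = protocol, d = d
    ),
    class = "dsigma_fit"
  )
}

#' @export
print.dsigma_fit <- function(x, ...) {
  cat("<dsigma_fit>\n")
  cat(sprintf("  D_sigma_hat = %.4g um^2/s%s\n", x$D_sigma_hat,
              if (x$fit_effective_d) sprintf(", effective d = %.3g um", x$d_hat) else ""))
  cat(sprintf("  residual SS = %.4g (null %.4g); identifiable: %s\n",
              x$residual_ss, x$null_ss, x$identifiable))
  if (!x$identifiable) {
    cat("  ! fit barely improves on a flat trace; estimate not interpretable\n")
  }
  invisible(x)
}

#' Sum-of-squares profile over a diffusivity grid
#'
#' Evaluates the [fit_dsigma()] objective over a grid of `D_sigma` values;
#' a brute-force view of the fit landscape (and a cross-check on the
#' optimizer).
#'
#' @inheritParams fit_dsigma
#' @param D_grid Diffusivity grid (um^2/s).
#' @return Tibble with `D_sigma` and `sse`.
#' @export
dsigma_profile <- function(measured, protocol, model, d, D_grid, lag_tau = NULL) {
  check_columns(measured, c("time_s", "delta_sigma_pN_per_um"), "measured")
  if (!inherits(model, "membrane_model")) model <- do.call(membrane_model, model)
  seg <- protocol_segments(protocol)
  sse <- vapply(D_grid, function(D) {
    p <- plane_response(measured$time_s, seg, protocol$tether_radius, D, model$E, d)
    if (!is.null(lag_tau)) p <- lag_filter(p, measured$time_s, lag_tau)
    sum((measured$delta_sigma_pN_per_um - p)^2)
  }, numeric(1))
  tibble(D_sigma = D_grid, sse = sse)
}
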