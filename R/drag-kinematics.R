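# Tether-dragging analysis: from tracked cell contour, tether base and bead
# coordinates to the tether membrane angle, tangential force, base velocity
# and stall segments. The membrane contour is represented by a periodic
# parametric cubic spline; only the local tangent at the tether base is used.

# Periodic parametric spline through an ordered closed contour.
# Returns functions x(s), y(s) and derivatives over s in [0, 1].
contour_spline <- function(contour) {
  check_columns(contour, c("x_um", "y_um"), "contour")
  x <- contour$x_um
  y <- contour$y_um
  if (length(x) < 5) {
    abort("Contour needs >= 5 points.", class = "memtide_geometry_error")
  }
  # close the loop, parameterize by normalized cumulative chord length
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  s <- s / s[length(s)]
  keep <- !duplicated(s)
  fx <- splinefun(s[keep], x[keep], method = "periodic")
  fy <- splinefun(s[keep], y[keep], method = "periodic")
  list(fx = fx, fy = fy)
}

# Nearest point on the contour to a query point: dense scan then local
# refinement by optimize().
nearest_on_contour <- function(sp, px, py, n_scan = 400) {
  dist2 <- function(s) (sp$fx(s) - px)^2 + (sp$fy(s) - py)^2
  sg <- seq(0, 1, length.out = n_scan + 1)[-(n_scan + 1)]
  i0 <- which.min(dist2(sg))
  w <- 1.5 / n_scan
  opt <- optimize(dist2, lower = sg[i0] - w, upper = sg[i0] + w)
  s_star <- opt$minimum %% 1
  list(s = s_star, dist = sqrt(opt$objective))
}

#' Tether membrane angle
#'
#' Angle between the contour normal at the tether base and the base-to-bead
#' segment, folded into \eqn{[0, \pi/2]}. A bead pulled exactly along the
#' outward normal gives 0; a bead level with the surface gives
#' \eqn{\pi/2}. The contour is fit with a periodic spline and the tangent is
#' evaluated at the contour point nearest the tracked base.
#'
#' @param contour Ordered closed contour, data frame with `x_um`, `y_um`
#'   (>= 5 points).
#' @param base Tether base coordinates, numeric length-2 `c(x, y)` (um).
#' @param bead Bead-center coordinates, numeric length-2 (um).
#' @param tol Maximum allowed distance between `base` and the contour (um);
#'   default 0.5.
#' @return Angle theta (rad) in \eqn{[0, \pi/2]}.
#' @export
membrane_angle <- function(contour, base, bead, tol = 0.5) {
  membrane_angle_sp(contour_spline(contour), base, bead, tol)
}

# worker on a prebuilt contour spline (avoids refitting per frame)
membrane_angle_sp <- function(sp, base, bead, tol = 0.5) {
  np <- nearest_on_contour(sp, base[1], base[2])
  if (np$dist > tol) {
    abort(sprintf("Tether base is %.3g um from the contour (tolerance %.3g).",
                  np$dist, tol),
          class = "memtide_geometry_error")
  }
  tx <- sp$fx(np$s, deriv = 1)
  ty <- sp$fy(np$s, deriv = 1)
  tn <- sqrt(tx^2 + ty^2)
  if (tn == 0) abort("Degenerate contour tangent.", class = "memtide_geometry_error")
  # normal direction (sign irrelevant: angle folded below)
  nx <- -ty / tn
  ny <- tx / tn
  vx <- bead[1] - base[1]
  vy <- bead[2] - base[2]
  vn <- sqrt(vx^2 + vy^2)
  if (vn == 0) abort("Bead coincides with tether base.", class = "memtide_geometry_error")
  cosang <- abs(nx * vx / vn + ny * vy / vn)
  acos(pmin(pmax(cosang, 0), 1))
}

#' Tangential component of the tether force
#'
#' \eqn{f_\parallel = f \sin\theta}: the component of the total tether force
#' along the cell surface, which drives tether-base sliding.
#'
#' @param total_force Total tether force (pN). Vectorized.
#' @param theta Tether membrane angle (rad), in \eqn{[0, \pi/2]}. Vectorized.
#' @return Tangential force (pN), never exceeding `total_force`.
#' @export
tangential_force <- function(total_force, theta) {
  check_number(total_force, "total_force", nonneg = TRUE)
  check_number(theta, "theta")
  if (any(theta < 0 | theta > pi / 2 + 1e-9)) {
    abort("`theta` must lie in [0, pi/2]; fold angles first.",
          class = "memtide_domain_error")
  }
  total_force * sin(pmin(theta, pi / 2))
}

#' Tether-base kinematics
#'
#' Cumulative distance traveled by the tether base (running sum of
#' frame-to-frame displacements) and its velocity. The tracked base
#' positions are Gaussian-smoothed before differencing — summing raw
#' frame-to-frame displacements of a jittery but stationary point
#' accumulates spurious distance (~1 um/s at 17 nm jitter and 30 Hz),
#' swamping the 0.5 um/s stall criterion. The distance trace is then
#' smoothed with the same kernel and differentiated by central differences.
#'
#' @param frames Data frame with `time_s`, `base_x_um`, `base_y_um`
#'   (>= 3 frames, strictly increasing time).
#' @param smoothing_width Gaussian width (s); default 1.
#' @param width_kind `"sigma"` (default) or `"fwhm"`, see [gaussian_smooth()].
#' @return Tibble: input plus `cum_distance_um` (non-decreasing) and
#'   `v_t_um_per_s` (velocity of the smoothed distance trace).
#' @export
base_kinematics <- function(frames, smoothing_width = 1,
                            width_kind = c("sigma", "fwhm")) {
  width_kind <- match.arg(width_kind)
  check_columns(frames, c("time_s", "base_x_um", "base_y_um"), "frames")
  if (nrow(frames) < 3) {
    abort("Need >= 3 frames for kinematics.", class = "memtide_kinematics_error")
  }
  check_time_monotone(frames$time_s, "time_s")
  dt <- median(diff(frames$time_s))
  bx <- gaussian_smooth(frames$base_x_um, dt = dt, width = smoothing_width, kind = width_kind)
  by <- gaussian_smooth(frames$base_y_um, dt = dt, width = smoothing_width, kind = width_kind)
  step <- sqrt(diff(bx)^2 + diff(by)^2)
  cumd <- c(0, cumsum(step))
  cumd_s <- gaussian_smooth(cumd, dt = dt, width = smoothing_width, kind = width_kind)
  n <- length(cumd_s)
  v <- numeric(n)
  v[2:(n - 1)] <- (cumd_s[3:n] - cumd_s[1:(n - 2)]) /
    (frames$time_s[3:n] - frames$time_s[1:(n - 2)])
  v[1] <- (cumd_s[2] - cumd_s[1]) / (frames$time_s[2] - frames$time_s[1])
  v[n] <- (cumd_s[n] - cumd_s[n - 1]) / (frames$time_s[n] - frames$time_s[n - 1])
  frames |>
    as_tibble() |>
    mutate(cum_distance_um = cumd, v_t_um_per_s = v)
}

#' Assemble a drag track from frames and contours
#'
#' Per-frame pipeline: membrane angle at the tether base, tangential force,
#' then base kinematics. Accepts a single contour (applied to every frame)
#' or per-frame contours in long format.
#'
#' @param frames Data frame with `time_s`, `base_x_um`, `base_y_um`,
#'   `bead_x_um`, `bead_y_um`, `force_pN`.
#' @param contours Either a single contour data frame (`x_um`, `y_um`) or a
#'   long-format data frame with a `frame` column (1-based frame index)
#'   plus `x_um`, `y_um`.
#' @param smoothing_width Gaussian width (s) for [base_kinematics()].
#' @param tol Base-to-contour tolerance (um) for [membrane_angle()].
#' @return A `drag_track` tibble: `frames` plus `theta_rad`,
#'   `f_parallel_pN`, `cum_distance_um`, `v_t_um_per_s`; attribute
#'   `smoothing_width`.
#' @export
drag_track <- function(frames, contours, smoothing_width = 1, tol = 0.5) {
  check_columns(frames, c("time_s", "base_x_um", "base_y_um",
                          "bead_x_um", "bead_y_um", "force_pN"), "frames")
  per_frame <- "frame" %in% names(contours)
  n <- nrow(frames)
  theta <- numeric(n)
  if (!per_frame) {
    sp <- contour_spline(as_tibble(contours))
    for (i in seq_len(n)) {
      theta[i] <- membrane_angle_sp(
        sp,
        c(frames$base_x_um[i], frames$base_y_um[i]),
        c(frames$bead_x_um[i], frames$bead_y_um[i]),
        tol = tol
      )
    }
  } else {
    split_c <- split(as_tibble(contours), contours$frame)
    for (i in seq_len(n)) {
      ci <- split_c[[as.character(i)]]
      if (is.null(ci)) {
        abort(sprintf("No contour for frame %d.", i), class = "memtide_schema_error")
      }
      theta[i] <- membrane_angle(
        ci,
        c(frames$base_x_um[i], frames$base_y_um[i]),
        c(frames$bead_x_um[i], frames$bead_y_um[i]),
        tol = tol
      )
    }
  }
  out <- frames |>
    as_tibble() |>
    mutate(theta_rad = theta,
           f_parallel_pN = tangential_force(.data$force_pN, theta)) |>
    base_kinematics(smoothing_width = smoothing_width)
  attr(out, "smoothing_width") <- smoothing_width
  class(out) <- c("drag_track", class(out))
  out
}

#' Detect stall segments in a drag track
#'
#' Maximal contiguous runs where the tether-base speed stays below the
#' velocity noise floor while the tether sustains force. Reports the peak
#' tangential force per stall. Stalls shorter than three smoothing widths
#' are kept but flagged unreliable (the Gaussian smoothing can blur them).
#'
#' @param track A [drag_track()] (or data frame with `time_s`,
#'   `v_t_um_per_s` and `f_parallel_pN`).
#' @param v_noise Velocity noise floor (um/s); default 0.5.
#' @param min_reliable_duration Minimum duration (s) for a stall to be
#'   considered reliably resolved; default `3 * smoothing_width` of the
#'   track (or 3 s).
#' @return Tibble with one row per stall: `t_start`, `t_end`,
#'   `duration_s`, `f_parallel_max_pN`, `reliable`. Zero rows when the
#'   tether never stalls.
#' @export
stall_segments <- function(track, v_noise = memtide_constants()$v_noise,
                           min_reliable_duration = NULL) {
  check_columns(track, c("time_s", "v_t_um_per_s", "f_parallel_pN"), "track")
  check_number(v_noise, "v_noise", positive = TRUE, allow_vector = FALSE)
  sw <- attr(track, "smoothing_width") %||% 1
  min_reliable_duration <- min_reliable_duration %||% (3 * sw)
  stalled <- abs(track$v_t_um_per_s) < v_noise
  if (!any(stalled)) {
    return(tibble(t_start = numeric(), t_end = numeric(), duration_s = numeric(),
                  f_parallel_max_pN = numeric(), reliable = logical()))
  }
  r <- rle(stalled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  purrr::map(idx, function(j) {
    rows <- starts[j]:ends[j]
    tibble(
      t_start = track$time_s[starts[j]],
      t_end = track$time_s[ends[j]],
      f_parallel_max_pN = max(track$f_parallel_pN[rows])
    )
  }) |>
    bind_rows() |>
    mutate(duration_s = .data$t_end - .data$t_start,
           reliable = .data$duration_s >= min_reliable_duration) |>
    select("t_start", "t_end", "duration_s", "f_parallel_max_pN", "reliable")
}
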