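# ggplot2 autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a probe-tether tension response
#'
#' Time course of the tension change at the probe tether, with the pulling
#' protocol phases shaded when the protocol is attached.
#'
#' @param object A `probe_response` from [simulate_probe_response()] or
#'   [impulse_probe_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.probe_response <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$delta_sigma_pN_per_um)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(
      x = "time (s)",
      y = expression(Delta * sigma ~ "(pN/" * mu * "m)"),
      title = sprintf("Probe response: d = %.3g um, D_sigma = %.3g um^2/s",
                      attr(object, "d") %||% NA,
                      attr(object, "D_sigma") %||% NA)
    ) +
    ggplot2::theme_minimal()
  prot <- attr(object, "protocol")
  if (!is.null(prot)) {
    seg <- protocol_segments(prot)
    moving <- seg[seg$rate != 0, ]
    if (nrow(moving) > 0) {
      p <- p + ggplot2::geom_rect(
        data = moving,
        ggplot2::aes(xmin = .data$t0, xmax = .data$t1, ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.08, fill = "firebrick"
      )
    }
  }
  p
}

#' Plot a FRAP recovery fit
#'
#' Normalized recovery data overlaid with the fitted hyperbolic model; the
#' half-time is marked.
#'
#' @param object A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(t = seq(0, max(dat$t), length.out = 400))
  grid$F <- frap_model(grid$t, object$F0, object$F_inf, object$t_half)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$F)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "time since bleach (s)", y = "normalized fluorescence F",
      title = sprintf("FRAP: t_half = %.3g s, D_t = %.3g um^2/s, immobile = %.2f",
                      object$t_half, object$D_t, object$immobile_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a drag track
#'
#' Stacked time profiles of tangential force, cumulative base distance and
#' base velocity, with detected stall segments shaded and the velocity
#' noise floor marked.
#'
#' @param object A [drag_track()].
#' @param v_noise Velocity noise floor to display/detect (um/s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drag_track <- function(object, v_noise = memtide_constants()$v_noise, ...) {
  stalls <- stall_segments(object, v_noise = v_noise)
  long <- object |>
    select("time_s", "f_parallel_pN", "cum_distance_um", "v_t_um_per_s") |>
    pivot_longer(-"time_s", names_to = "channel", values_to = "value") |>
    mutate(channel = factor(.data$channel,
                            levels = c("f_parallel_pN", "cum_distance_um",
                                       "v_t_um_per_s"),
                            labels = c("f_par (pN)", "cum. distance (um)",
                                       "v_t (um/s)")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stalls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = stalls,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Plot a stimulation trace
#'
#' Membrane tension and calcium signal on a common time axis (free y
#' scales), stimulus onset marked.
#'
#' @param object A `stimulus_trace` (from [simulate_exo_endo()] or
#'   [gen_stimulus()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stimulus_trace <- function(object, ...) {
  cols <- intersect(c("tension_pN_per_um", "dF_over_F"), names(object))
  long <- object |>
    select(dplyr::all_of(c("time_s", cols))) |>
    pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  t_on <- attr(object, "t_on")
  if (!is.null(t_on)) {
    p <- p + ggplot2::geom_vline(xintercept = t_on, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Predicted sense time and amplitude versus distance
#'
#' Evaluates the diffusive forward model over a grid of tether separations
#' and returns the predicted time-to-sense and maximum probe amplitude per
#' distance — the model curves against which measured double-tether
#' responses are compared.
#'
#' @param protocol A [pull_protocol()].
#' @param model A [membrane_model()].
#' @param d_grid Tether separations (um).
#' @param threshold Detection threshold (pN/um); default from
#'   [tension_threshold()] at 10 pN.
#' @param times Evaluation time grid; default protocol span at 10 Hz.
#' @return Tibble with `d_um`, `t_sense_s`, `max_amplitude_pN_per_um`.
#' @export
sense_time_curve <- function(protocol, model, d_grid,
                             threshold = tension_threshold(10), times = NULL) {
  purrr::map(d_grid, function(dd) {
    resp <- simulate_probe_response(protocol, model, d = dd, times = times)
    st <- sense_time(resp, threshold = threshold)
    tibble(d_um = dd, t_sense_s = st$t_sense,
           max_amplitude_pN_per_um = st$max_amplitude)
  }) |> bind_rows()
}
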