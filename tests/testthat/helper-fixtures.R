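# Shared fixtures built in code.

# circular contour tibble, counter-clockwise
circle_contour <- function(radius = 5, n = 60, center = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  tibble::tibble(x_um = center[1] + radius * cos(phi),
                 y_um = center[2] + radius * sin(phi))
}

# independent numeric-quadrature oracle for the plane tension kernel:
# direct adaptive integration of the convolution integral, no exponential
# integrals involved
plane_kernel_quadrature <- function(t, d, D, E, protocol) {
  if (t <= protocol$start_time) return(0)
  r_t <- protocol$tether_radius
  integrand <- function(tp) {
    vapply(tp, function(x) {
      s <- t - x
      q <- 2 * pi * r_t * memtide::protocol_rate(protocol, x)
      if (s <= 0 || q == 0) return(0)
      arg <- d^2 / (4 * D * s)
      if (arg > 700) return(0)
      E * q / (4 * pi * D * s) * exp(-arg)
    }, numeric(1))
  }
  stats::integrate(integrand, protocol$start_time, t - 1e-12,
                   subdivisions = 5000L, rel.tol = 1e-10,
                   stop.on.error = FALSE)$value
}
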