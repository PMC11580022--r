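# Darcy permeability, tension diffusivity, the diffusive forward model and
# D_sigma fitting.

test_that("permeability factor matches direct evaluation and decays with packing", {
  f <- function(phi) (-log(phi) - 1.476 + 2 * phi - 1.774 * phi^2 + 4.076 * phi^3) / (8 * phi)
  expect_equal(permeability_factor(0.150), f(0.150))
  expect_equal(permeability_factor(0.150), 0.5791, tolerance = 1e-3)
  expect_equal(permeability_factor(0.096), 1.3628, tolerance = 1e-3)
  expect_equal(permeability_factor(0.093), 1.4423, tolerance = 1e-3)
  # strictly decreasing over the validity range
  phi <- seq(0.01, 0.3, by = 0.005)
  expect_true(all(diff(permeability_factor(phi)) < 0))
  expect_error(permeability_factor(0.35), class = "memtide_range_error")
  expect_error(permeability_factor(0), class = "memtide_range_error")
  expect_equal(darcy_permeability(0.15, a = 0.0023), 0.0023^2 * f(0.15))
})

test_that("obstacle fraction is the immobile fraction times protein coverage", {
  expect_equal(obstacle_fraction(0.60, 0.25), 0.150)
  expect_equal(obstacle_fraction(0.37, 0.25), 0.0925)
  expect_equal(signif_half_up(obstacle_fraction(0.37, 0.25), 2), 0.093)
  expect_equal(obstacle_fraction(0, 0.7), 0)
  expect_error(obstacle_fraction(1.2), class = "memtide_domain_error")
})

test_that("tension diffusivity is linear in E and k and inverse in eta", {
  expect_equal(tension_diffusivity(100, 2e-6, 1e-3), 0.2)
  expect_equal(tension_diffusivity(100, 4e-6, 1e-3),
               2 * tension_diffusivity(100, 2e-6, 1e-3))
  expect_equal(tension_diffusivity(200, 2e-6, 1e-3),
               2 * tension_diffusivity(100, 2e-6, 1e-3))
  expect_equal(tension_diffusivity(100, 2e-6, 2e-3),
               tension_diffusivity(100, 2e-6, 1e-3) / 2)
  expect_error(tension_diffusivity(0, 1, 1), class = "memtide_domain_error")
})

test_that("cell-type permeability contrast gives the ~2.4-fold diffusivity ratio", {
  # a, E, eta identical across cell types, so they cancel in the ratio
  ratio_soma <- permeability_factor(0.093) / permeability_factor(0.150)
  ratio_term <- permeability_factor(0.096) / permeability_factor(0.150)
  expect_true(ratio_soma > 2.3 && ratio_soma < 2.5)
  expect_true(ratio_term > 2.3 && ratio_term < 2.5)
  expect_equal(signif_half_up(mean(c(ratio_soma, ratio_term)), 2), 2.4)
})

test_that("membrane model derives k and D_sigma consistently", {
  m <- membrane_model(E = 40, eta = 1e-3, a = 0.0023, phi = 0.15)
  expect_equal(m$k, darcy_permeability(0.15, 0.0023))
  expect_equal(m$D_sigma, 40 * m$k / 1e-3)
  m2 <- membrane_model(D_sigma = 0.024)
  expect_equal(m2$D_sigma, 0.024)
  expect_error(membrane_model(), class = "memtide_domain_error")
})

test_that("protocol length program is continuous, piecewise linear and conservative", {
  p <- pull_protocol()
  expect_equal(protocol_duration(p), 110)
  t <- seq(0, 120, by = 0.01)
  L <- protocol_length(p, t)
  expect_equal(L[t == 0], 0)
  expect_equal(max(L), 40)
  expect_equal(L[t == 120], 0) # returns to start
  expect_true(max(abs(diff(L))) <= 1 * 0.01 + 1e-12) # speed bound
  expect_equal(protocol_rate(p, 20), 1)
  expect_equal(protocol_rate(p, 60), 0)
  expect_equal(protocol_rate(p, 90), -1)
  expect_equal(extraction_rate(p, 20), 2 * pi * p$tether_radius)
})

test_that("plane kernel matches an independent quadrature oracle", {
  p <- pull_protocol()
  m <- membrane_model(D_sigma = 2)
  times <- c(5, 20, 40, 60, 75, 100, 130)
  resp <- simulate_probe_response(p, m, d = 5, times = seq(0, 130, 0.5))
  for (t0 in times) {
    oracle <- plane_kernel_quadrature(t0, d = 5, D = 2, E = m$E, protocol = p)
    got <- resp$delta_sigma_pN_per_um[resp$time_s == t0]
    expect_equal(got, oracle, tolerance = 1e-6)
  }
  # zero before motion starts
  p2 <- pull_protocol(start_time = 10)
  resp2 <- simulate_probe_response(p2, m, d = 5, times = seq(0, 20, 0.1))
  expect_true(all(resp2$delta_sigma_pN_per_um[resp2$time_s <= 10] == 0))
  expect_true(any(resp2$delta_sigma_pN_per_um[resp2$time_s > 12] > 0))
})

test_that("impulse response has the heat-kernel form and peaks at d^2/(4D)", {
  d <- 5; D <- 2; E <- 40; A0 <- 1
  tt <- seq(0.01, 50, by = 0.01)
  r <- impulse_probe_response(d, tt, D, E = E, area = A0)
  t_peak <- r$time_s[which.max(r$delta_sigma_pN_per_um)]
  expect_equal(t_peak, d^2 / (4 * D), tolerance = 0.01)
  # closed form at an arbitrary time
  t1 <- 4
  expect_equal(r$delta_sigma_pN_per_um[r$time_s == t1],
               E * A0 / (4 * pi * D * t1) * exp(-d^2 / (4 * D * t1)))
})

test_that("finite-difference disc solver agrees with the plane kernel on a large disc", {
  p <- pull_protocol()
  m <- membrane_model(D_sigma = 2)
  times <- seq(0, 130, 0.5)
  plane <- simulate_probe_response(p, m, d = 5, times = times)
  disc <- simulate_probe_response(p, m, d = 5, geometry = "disc", times = times,
                                  disc_radius = 60, dr = 0.2, dt = 0.05)
  rel_err <- max(abs(disc$delta_sigma_pN_per_um - plane$delta_sigma_pN_per_um)) /
    max(abs(plane$delta_sigma_pN_per_um))
  expect_lt(rel_err, 0.01)
})

test_that("disc geometry conserves the area integral of the tension change", {
  p <- pull_protocol()
  m <- membrane_model(D_sigma = 2)
  # end of the hold phase: net extracted tether area is 2*pi*r_t*40
  disc <- simulate_probe_response(p, m, d = 3, geometry = "disc",
                                  times = seq(0, 70, 0.5),
                                  disc_radius = 20, dr = 0.1, dt = 0.05)
  expect_equal(attr(disc, "net_extracted_area"), 2 * pi * p$tether_radius * 40)
  expect_equal(attr(disc, "area_integral"),
               m$E * attr(disc, "net_extracted_area"),
               tolerance = 0.01)
  # after full retraction the net change is zero
  disc2 <- simulate_probe_response(p, m, d = 3, geometry = "disc",
                                   times = seq(0, 120, 0.5),
                                   disc_radius = 20, dr = 0.1, dt = 0.05)
  expect_equal(attr(disc2, "net_extracted_area"), 0, tolerance = 1e-10)
  expect_lt(abs(attr(disc2, "area_integral")), 1e-6)
})

test_that("bounded geometry reaches the uniform conservation limit at long times", {
  # extend 2 um and never retract; tension equilibrates to E*A_extracted/disc area
  p <- pull_protocol(extend_speed = 1, extend_distance = 2, hold_time = 300,
                     retract_speed = 0)
  m <- membrane_model(D_sigma = 1)
  disc <- simulate_probe_response(p, m, d = 2, geometry = "disc",
                                  times = seq(0, 300, 1),
                                  disc_radius = 5, dr = 0.05, dt = 0.05)
  field <- attr(disc, "final_field")
  uniform <- m$E * 2 * pi * p$tether_radius * 2 / (pi * 5^2)
  expect_equal(mean(field$delta_sigma), uniform, tolerance = 1e-6)
  expect_lt(stats::sd(field$delta_sigma) / abs(uniform), 1e-3)
})

test_that("sense time grows with distance and amplitude shrinks", {
  p <- pull_protocol()
  m <- membrane_model(D_sigma = 2.4)
  times <- seq(0, 140, 0.2)
  d_grid <- c(2, 4, 6, 8, 10)
  res <- lapply(d_grid, function(dd)
    sense_time(simulate_probe_response(p, m, d = dd, times = times)))
  ts <- vapply(res, function(r) r$t_sense, numeric(1))
  amp <- vapply(res, function(r) r$max_amplitude, numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_true(all(diff(amp) < 0))
  # default threshold is the tracking-error propagation at 10 pN
  expect_equal(res[[1]]$threshold, 10 * 1.3 / (4 * pi^2 * 0.27))
  # zero-speed protocol produces no response
  p0 <- pull_protocol(extend_speed = 0, extend_distance = 0, retract_speed = 0)
  r0 <- simulate_probe_response(p0, m, d = 5, times = seq(0, 50, 0.5))
  expect_equal(max_probe_amplitude(r0), 0)
  expect_true(is.infinite(sense_time(r0)$t_sense))
})

test_that("sense time scales as distance squared under pure diffusion", {
  # impulse source, threshold deep in the small-threshold asymptotic regime
  d_grid <- seq(2, 6, by = 0.5)
  ts <- vapply(d_grid, function(d) {
    tt <- exp(seq(log(1e-5), log(50), length.out = 5000))
    r <- impulse_probe_response(d, tt, D_sigma = 1, E = 40, area = 1)
    sense_time(r, threshold = 1e-9)$t_sense
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(log(ts) ~ log(d_grid)))[2])
  expect_gt(slope, 1.9)
  expect_lt(slope, 2.1)
})

test_that("D_sigma fitting recovers noiseless and noisy synthetic traces", {
  p <- pull_protocol()
  m <- membrane_model(D_sigma = 2.4)
  times <- seq(0, 140, 1 / 3)
  # noiseless self-consistency
  clean <- simulate_probe_response(p, m, d = 5, times = times)
  fit0 <- fit_dsigma(clean, p, m, d = 5)
  expect_equal(fit0$D_sigma_hat, 2.4, tolerance = 1e-3)
  expect_true(fit0$identifiable)

  # noisy: generator chain, recovery within 20%
  gen <- gen_double_tether(generator_config(seed = 41), D_sigma = 1, d = 5)
  meas <- tibble::tibble(
    time_s = gen$trace$time_s,
    delta_sigma_pN_per_um = gen$trace$tension_pN_per_um - gen$truth$sigma0
  )
  fit1 <- fit_dsigma(meas, p, membrane_model(D_sigma = 1), d = 5, lag_tau = 1)
  expect_equal(fit1$D_sigma_hat, 1, tolerance = 0.2)

  # effective-distance variant frees both parameters
  fit2 <- fit_dsigma(clean, p, m, d = 5, fit_effective_d = TRUE)
  expect_equal(fit2$D_sigma_hat, 2.4, tolerance = 0.05)
  expect_equal(fit2$d_hat, 5, tolerance = 0.05)

  # flat trace: reported non-identifiable, not a silent estimate
  set.seed(5)
  flat <- tibble::tibble(time_s = times,
                         delta_sigma_pN_per_um = stats::rnorm(length(times), 0, 1))
  fit3 <- fit_dsigma(flat, p, m, d = 5)
  expect_false(fit3$identifiable)

  g <- glance(fit1)
  expect_true(g$identifiable)
  expect_equal(g$D_sigma_hat, fit1$D_sigma_hat)
})

test_that("optimizer agrees with a brute-force grid search", {
  p <- pull_protocol()
  grid <- 10^seq(-2, 3, length.out = 120)
  for (s in 1:5) {
    gen <- gen_double_tether(generator_config(seed = 500 + s),
                             D_sigma = c(0.5, 1, 2.4, 8, 24)[s], d = 5)
    meas <- tibble::tibble(
      time_s = gen$trace$time_s,
      delta_sigma_pN_per_um = gen$trace$tension_pN_per_um - gen$truth$sigma0
    )
    prof <- dsigma_profile(meas, p, membrane_model(D_sigma = 1), d = 5, grid,
                           lag_tau = 1)
    fit <- fit_dsigma(meas, p, membrane_model(D_sigma = 1), d = 5, lag_tau = 1)
    D_grid_best <- prof$D_sigma[which.min(prof$sse)]
    # optimizer must land within one grid step of the brute-force argmin
    expect_equal(log10(fit$D_sigma_hat), log10(D_grid_best),
                 tolerance = 2 * 5 / 119)
  }
})
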