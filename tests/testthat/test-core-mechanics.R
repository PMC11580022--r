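# Tether force / tension / radius conversions and optical-trap physics.

test_that("force-tension conversions invert each other and match closed forms", {
  # forward evaluation: f = 2*pi*sqrt(2*kappa*sigma)
  expect_equal(force_from_tension(5, kappa = 0.27), 2 * pi * sqrt(2 * 0.27 * 5))
  expect_equal(force_from_tension(5, kappa = 0.27), 10.3243, tolerance = 1e-4)
  expect_equal(force_from_tension(0.01, kappa = 0.27), 0.4617, tolerance = 1e-3)
  expect_equal(force_from_tension(0), 0)
  expect_equal(tension_from_force(0), 0)
  expect_equal(tension_from_force(10.3243, kappa = 0.27), 5, tolerance = 1e-4)

  # roundtrip identity over eight decades, 1e-12 relative
  sigma <- 10^seq(-3, 2, length.out = 60)
  expect_equal(tension_from_force(force_from_tension(sigma)), sigma,
               tolerance = 1e-12)

  # monotone increasing in sigma
  expect_true(all(diff(force_from_tension(sigma)) > 0))

  expect_error(tension_from_force(-1), class = "memtide_domain_error")
  expect_error(force_from_tension(-0.1), class = "memtide_domain_error")
  expect_error(force_from_tension(1, kappa = 0), class = "memtide_domain_error")
})

test_that("tether radius is inversely proportional to force and consistent with tension", {
  kappa <- 0.27
  expect_equal(radius_from_force(2 * pi * kappa), 1) # algebraic identity
  expect_equal(radius_from_force(10.3243), 0.1644, tolerance = 1e-3)
  f <- c(1, 2, 5, 20)
  expect_equal(radius_from_force(2 * f), radius_from_force(f) / 2)
  # r * f = 2 * pi * kappa for all f
  expect_equal(radius_from_force(f) * f, rep(2 * pi * kappa, length(f)))
  # agreement with sqrt(kappa / (2 sigma)) for consistent pairs, 1e-10 relative
  sigma <- 10^seq(-2, 2, length.out = 30)
  expect_equal(radius_from_force(force_from_tension(sigma)),
               sqrt(kappa / (2 * sigma)), tolerance = 1e-10)
  expect_error(radius_from_force(0), class = "memtide_domain_error")
})

test_that("trap displacement force reproduces the printed tracking-error floor", {
  # 17 nm tracking error at k_trap = 75 pN/um -> 1.3 pN force uncertainty
  expect_equal(signif_half_up(force_from_displacement(0.017, 75), 2), 1.3)
  expect_equal(force_from_displacement(0, 75), 0)
  expect_equal(force_from_displacement(0.1, 271), 27.1)
})

test_that("hydrodynamic force and Reynolds number are linear in each argument", {
  gam <- drag_coefficient(1e-3, 1.5)
  expect_equal(gam, 6 * pi * 1e-3 * 1.5)
  f0 <- hydrodynamic_force(gam, 2 * pi * 5, 20)
  expect_equal(f0, gam * 2 * pi * 5 * 10) # = 8.88 pN
  expect_equal(f0, 8.883, tolerance = 1e-3)
  expect_equal(hydrodynamic_force(gam, 2 * pi * 5, 0), 0)

  expect_equal(reynolds_number(1, 1), 1e-6)   # the printed ~1e-6 regime check
  expect_equal(reynolds_number(10, 1), 1e-5)
  expect_equal(reynolds_number(0, 1), 0)

  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(1, 0.5, 4)
    x <- stats::runif(3, 0.1, 10)
    expect_equal(hydrodynamic_force(a * x[1], x[2], x[3]),
                 a * hydrodynamic_force(x[1], x[2], x[3]))
    expect_equal(hydrodynamic_force(x[1], a * x[2], x[3]),
                 a * hydrodynamic_force(x[1], x[2], x[3]))
    expect_equal(reynolds_number(a * x[1], x[2]), a * reynolds_number(x[1], x[2]))
    expect_equal(reynolds_number(x[1], a * x[2]), a * reynolds_number(x[1], x[2]))
  }
})

test_that("trap calibration recovers the generating stiffness", {
  # noiseless: exact
  rec <- tibble::tibble(f_hydro_pN = c(2, 4, 8.88),
                        A_bead_um = f_hydro_pN / 100)
  expect_equal(calibrate_trap(rec)$k_trap, 100, tolerance = 1e-12)
  expect_equal(calibrate_trap(rec, intercept = FALSE)$k_trap, 100, tolerance = 1e-12)

  # 5% multiplicative noise, n = 50: within 5%
  set.seed(202)
  f <- stats::runif(50, 1, 30)
  rec2 <- tibble::tibble(f_hydro_pN = f,
                         A_bead_um = f / 75 * (1 + stats::rnorm(50, 0, 0.05)))
  expect_equal(calibrate_trap(rec2)$k_trap, 75, tolerance = 0.05)

  # unbiased under zero-mean additive noise: mean of seeded replicates
  ks <- vapply(1:40, function(s) {
    set.seed(300 + s)
    f <- seq(2, 30, length.out = 20)
    rec3 <- tibble::tibble(f_hydro_pN = f,
                           A_bead_um = f / 100 + stats::rnorm(20, 0, 0.01))
    calibrate_trap(rec3)$k_trap
  }, numeric(1))
  expect_equal(mean(ks), 100, tolerance = 0.02)

  expect_error(calibrate_trap(rec[1, ]), class = "memtide_fit_error")
  expect_error(
    calibrate_trap(tibble::tibble(f_hydro_pN = c(5, 5, 5), A_bead_um = c(1, 1.1, 0.9))),
    class = "memtide_fit_error"
  )

  td <- tidy(calibrate_trap(rec))
  expect_equal(td$estimate[td$term == "k_trap"], 100, tolerance = 1e-10)
})

test_that("trap regime check flags fast driving", {
  gam <- drag_coefficient(1e-3, 1.5)
  expect_silent(check_trap_regime(75, gam, f_d = 5))
  expect_warning(check_trap_regime(0.5, gam, f_d = 100))
})

test_that("step-response fit recovers a known double exponential", {
  t <- seq(0, 12, by = 1 / 30)
  fn <- 1 - 0.6 * exp(-t / 0.2) - 0.4 * exp(-t / 2.0)
  fit <- fit_step_response(tibble::tibble(time_s = t, f_norm = fn))
  expect_equal(fit$amplitudes, c(0.6, 0.4), tolerance = 0.05)
  expect_equal(fit$time_constants, c(0.2, 2.0), tolerance = 0.05)
  expect_true(all(diff(fit$time_constants) >= 0))

  # from a raw force trace: normalization endpoints
  f_raw <- 2 + 8 * fn
  fit2 <- fit_step_response(tibble::tibble(time_s = t, force_pN = f_raw))
  expect_equal(fit2$data$fn[1], 0, tolerance = 1e-6)
  expect_equal(mean(tail(fit2$data$fn, 20)), 1, tolerance = 0.01)
  expect_equal(fit2$time_constants, c(0.2, 2.0), tolerance = 0.05)

  # Gaussian noise sd 0.02: time constants within 15%
  set.seed(77)
  fit3 <- fit_step_response(
    tibble::tibble(time_s = t, f_norm = fn + stats::rnorm(length(t), 0, 0.02))
  )
  expect_equal(fit3$time_constants, c(0.2, 2.0), tolerance = 0.15)

  expect_error(
    fit_step_response(tibble::tibble(time_s = t, force_pN = rep(3, length(t)))),
    class = "memtide_fit_error"
  )
})

test_that("fluorescence-based tension follows the inverse-square law", {
  expect_equal(tension_from_fluorescence(100, 100, 2), 2)
  expect_equal(tension_from_fluorescence(50, 100, 2), 8)
  expect_error(tension_from_fluorescence(0, 100, 2), class = "memtide_domain_error")

  # synthetic tether where intensity tracks radius: sigma = kappa / (2 r^2)
  kappa <- 0.27
  r <- seq(0.05, 0.3, length.out = 20)
  intensity <- 400 * r
  sigma_true <- kappa / (2 * r^2)
  i_ref <- intensity[10]
  sig <- tension_from_fluorescence(intensity, i_ref, sigma_true[10])
  expect_equal(sig, sigma_true, tolerance = 0.01)
  # and consistency with the force-based route
  expect_equal(sig, tension_from_force(2 * pi * kappa / r), tolerance = 0.01)
})

test_that("force traces validate their time base and propagate units", {
  tr <- tibble::tibble(time_s = seq(0, 1, 0.1), dr_um = seq(0, 0.1, 0.01))
  ft <- force_trace(tr, k_trap = 75)
  expect_equal(ft$force_pN, 75 * tr$dr_um)
  expect_equal(ft$tension_pN_per_um, tension_from_force(75 * tr$dr_um))
  bad <- tr
  bad$time_s <- rev(bad$time_s)
  expect_error(force_trace(bad, 75), class = "memtide_schema_error")
})
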