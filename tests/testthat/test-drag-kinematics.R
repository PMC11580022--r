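# Tether-drag geometry, kinematics and stall detection.

test_that("membrane angle is measured from the contour normal", {
  contour <- circle_contour(radius = 5, n = 80)
  base <- c(5, 0)
  # bead on the outward radial line: normal pull, theta = 0
  expect_equal(membrane_angle(contour, base, bead = c(7, 0)), 0, tolerance = 1e-3)
  # bead at 30 degrees from the normal
  bead30 <- base + 2 * c(cos(pi / 6), sin(pi / 6))
  expect_equal(membrane_angle(contour, base, bead30), pi / 6, tolerance = 1e-3)
  # bead level with the surface: theta = pi/2
  expect_equal(membrane_angle(contour, base, bead = c(5, 2)), pi / 2, tolerance = 1e-3)
  # folding: bead at 120 degrees from the outward normal folds to 60
  bead120 <- base + 2 * c(cos(2 * pi / 3), sin(2 * pi / 3))
  expect_equal(membrane_angle(contour, base, bead120), pi / 3, tolerance = 1e-3)
  # base far from the contour is a geometry error
  expect_error(membrane_angle(contour, base = c(8, 0), bead = c(9, 0)),
               class = "memtide_geometry_error")
})

test_that("tangential force is the sine projection and never exceeds the total", {
  expect_equal(tangential_force(10, pi / 6), 5)
  expect_equal(tangential_force(10, 0), 0)
  expect_equal(tangential_force(10, pi / 2), 10)
  set.seed(33)
  f <- stats::runif(100, 0, 50)
  th <- stats::runif(100, 0, pi / 2)
  expect_true(all(tangential_force(f, th) <= f + 1e-12))
  expect_error(tangential_force(10, 2), class = "memtide_domain_error")
})

test_that("base kinematics recover programmed speeds and respect the noise floor", {
  # straight-line motion at 2 um/s, 30 Hz
  t <- seq(0, 20, by = 1 / 30)
  frames <- tibble::tibble(time_s = t, base_x_um = 2 * t, base_y_um = 0)
  kin <- base_kinematics(frames)
  mid <- seq(100, length(t) - 100)
  expect_equal(stats::median(kin$v_t_um_per_s[mid]), 2, tolerance = 0.01)
  expect_equal(max(kin$cum_distance_um), 40, tolerance = 0.01)

  # constant speed on a circle: slight curvature attenuation from smoothing,
  # still within 10% of the programmed 2 um/s
  gen <- gen_drag_track(generator_config(seed = 61), motif = "free_slide",
                        noise_sd = 0)
  kin2 <- base_kinematics(gen$frames)
  expect_equal(stats::median(kin2$v_t_um_per_s), 2, tolerance = 0.1)

  # stationary base with 20 nm jitter stays under the 0.5 um/s noise floor
  set.seed(88)
  frames3 <- tibble::tibble(time_s = t,
                            base_x_um = stats::rnorm(length(t), 0, 0.02),
                            base_y_um = stats::rnorm(length(t), 0, 0.02))
  kin3 <- base_kinematics(frames3)
  expect_lt(max(abs(kin3$v_t_um_per_s)), 0.5)

  # zero displacement: cumulative distance identically zero
  frames4 <- tibble::tibble(time_s = t, base_x_um = 1, base_y_um = 2)
  expect_equal(max(base_kinematics(frames4)$cum_distance_um), 0)

  expect_error(base_kinematics(frames4[1:2, ]), class = "memtide_kinematics_error")
})

test_that("kinematics commute with time reversal up to the sign of velocity", {
  t <- seq(0, 10, by = 1 / 30)
  x <- cumsum(c(0, abs(stats::rnorm(length(t) - 1, 0.05, 0.02))))
  frames <- tibble::tibble(time_s = t, base_x_um = x, base_y_um = 0)
  fwd <- base_kinematics(frames)
  rev_frames <- tibble::tibble(time_s = t, base_x_um = rev(x), base_y_um = 0)
  bwd <- base_kinematics(rev_frames)
  expect_equal(max(fwd$cum_distance_um), max(bwd$cum_distance_um), tolerance = 1e-9)
  # cumulative distance accumulates unsigned steps, so the reversed track
  # traces the same speed profile backwards
  expect_equal(abs(fwd$v_t_um_per_s), rev(abs(bwd$v_t_um_per_s)), tolerance = 1e-6)
})

test_that("stall detection recovers programmed stick-slip stalls", {
  # noiseless ground truth: stall count and peak forces exact
  gen <- gen_drag_track(generator_config(seed = 71), motif = "stick_slip",
                        stall_peaks = c(8, 24), noise_sd = 0)
  track <- drag_track(gen$frames, gen$contour)
  stalls <- stall_segments(track)
  reliable <- stalls[stalls$reliable, ]
  expect_equal(nrow(reliable), 2)
  expect_equal(reliable$f_parallel_max_pN, c(8, 24), tolerance = 1e-3)
  # detected windows lie inside the programmed ones
  expect_true(all(reliable$t_start >= gen$truth$stall_windows$t_start - 0.5))
  expect_true(all(reliable$t_end <= gen$truth$stall_windows$t_end + 0.5))
  # f_parallel never exceeds the total force
  expect_true(all(track$f_parallel_pN <= track$force_pN + 1e-9))

  # with tracking noise the peaks are still recovered within a few percent
  gen2 <- gen_drag_track(generator_config(seed = 72), motif = "stick_slip")
  stalls2 <- stall_segments(drag_track(gen2$frames, gen2$contour))
  rel2 <- stalls2[stalls2$reliable, ]
  expect_equal(nrow(rel2), 2)
  expect_equal(rel2$f_parallel_max_pN, c(8, 24), tolerance = 0.1)

  # always-moving track: no stalls
  gen3 <- gen_drag_track(generator_config(seed = 73), motif = "free_slide")
  expect_equal(nrow(stall_segments(drag_track(gen3$frames, gen3$contour))), 0)

  # fully immobile track: one stall spanning the record
  gen4 <- gen_drag_track(generator_config(seed = 74), motif = "immobile")
  s4 <- stall_segments(drag_track(gen4$frames, gen4$contour))
  expect_equal(nrow(s4), 1)
  expect_equal(s4$t_start, 0)
  expect_equal(s4$t_end, max(gen4$frames$time_s))
})

test_that("stalls shorter than three smoothing widths are flagged, not merged", {
  t <- seq(0, 20, by = 1 / 30)
  v <- rep(2, length(t))
  v[t >= 5 & t < 6] <- 0     # 1 s stall, under the 3 s reliability bound
  v[t >= 10 & t < 15] <- 0   # 5 s stall
  track <- tibble::tibble(time_s = t, v_t_um_per_s = v,
                          f_parallel_pN = rep(4, length(t)))
  attr(track, "smoothing_width") <- 1
  stalls <- stall_segments(track)
  expect_equal(nrow(stalls), 2)
  expect_equal(stalls$reliable, c(FALSE, TRUE))
})

test_that("cell-type cohorts keep the terminal-below-chromaffin force ordering", {
  onset <- function(scenario, seed) {
    gen <- gen_drag_track(generator_config(seed = seed, scenario = scenario),
                          motif = "free_slide")
    track <- drag_track(gen$frames, gen$contour)
    stats::median(track$f_parallel_pN)
  }
  f_term <- onset("bipolar_terminal", 81)   # ~8 pN
  f_chrom <- onset("chromaffin", 82)        # ~24 pN
  expect_equal(f_term, 8, tolerance = 0.1)
  expect_equal(f_chrom, 24, tolerance = 0.1)
  expect_lt(f_term, f_chrom)
})
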