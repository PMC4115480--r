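test_that("kinetics objects validate and canonicalize", {
  k <- frap_kinetics(0.1, 0.3, 10, 0.5, 2)   # t1 > t2 on input
  expect_lte(k$t1, k$t2)
  expect_equal(k$A1, 0.5)                     # amplitudes follow their taus
  expect_equal(k$plateau, 0.9)
  expect_equal(k$immobile_fraction, 0.1, tolerance = 1e-12)

  expect_error(frap_kinetics(0.5, 0.4, 1, 0.2, 2), class = "frapkin_error_kinetics")
  expect_error(frap_kinetics(0.1, 0.3, -1, 0.2, 2), class = "frapkin_error_kinetics")
  expect_error(frap_kinetics(1.0, 0, 1, 0, 1), class = "frapkin_error_kinetics")
})

test_that("half-recovery time matches closed forms", {
  # pure single exponential: t-half = t1 * log(2)
  expect_equal(half_recovery_time(frap_kinetics(0, 1, 4, 0, 4)),
               4 * log(2), tolerance = 1e-6)
  # y0 offset does not shift the single-exponential half time
  expect_equal(half_recovery_time(frap_kinetics(0.3, 0.6, 4, 0, 4)),
               4 * log(2), tolerance = 1e-6)
  # equal time constants reduce to a single exponential
  expect_equal(half_recovery_time(frap_kinetics(0, 0.4, 7, 0.5, 7)),
               7 * log(2), tolerance = 1e-6)
})

test_that("half-recovery time matches the dense-grid oracle", {
  # frozen double-exponential case, oracle value from the grid search
  k <- frap_kinetics(0, 0.6, 2, 0.4, 10)
  expect_equal(half_recovery_time(k), grid_thalf(k), tolerance = 1e-4)
  expect_equal(half_recovery_time(k), 2.3623, tolerance = 1e-3)

  set.seed(101)
  for (i in 1:50) {
    k <- random_kinetics()
    expect_equal(half_recovery_time(k, t_upper_hint = 1), grid_thalf(k),
                 tolerance = 1e-4)
  }
})

test_that("half-recovery errors without recovering amplitude", {
  flat <- list(y0 = 0.5, A1 = 0, t1 = 1, A2 = 0, t2 = 1)
  expect_error(half_recovery_time(flat), class = "frapkin_error_no_recovery")
})

test_that("t-half is invariant to amplitude scaling and monotone in taus", {
  set.seed(202)
  for (i in 1:25) {
    k <- random_kinetics()
    s <- runif(1, 0.3, 1 / (k$y0 + k$A1 + k$A2))
    ks <- frap_kinetics(k$y0 * s, k$A1 * s, k$t1, k$A2 * s, k$t2)
    expect_equal(half_recovery_time(ks), half_recovery_time(k),
                 tolerance = 1e-5)
    # larger time constants never speed up recovery
    k_slow1 <- frap_kinetics(k$y0, k$A1, k$t1 * 1.3, k$A2,
                             max(k$t2, k$t1 * 1.3))
    k_slow2 <- frap_kinetics(k$y0, k$A1, k$t1, k$A2, k$t2 * 1.6)
    expect_gte(half_recovery_time(k_slow1), half_recovery_time(k) - 1e-6)
    expect_gte(half_recovery_time(k_slow2), half_recovery_time(k) - 1e-6)
  }
})

test_that("calibration hits the requested half time", {
  # closed form for a single exponential
  k1 <- calibrate_kinetics(5, amplitude_split = 1, plateau = 0.9, y0 = 0)
  expect_equal(k1$t1, 5 / log(2), tolerance = 1e-9)

  k <- calibrate_kinetics(6.3, amplitude_split = 0.6, t2_over_t1 = 5,
                          plateau = 0.95)
  expect_equal(half_recovery_time(k), 6.3, tolerance = 1e-4)
  expect_equal(k$plateau, 0.95, tolerance = 1e-12)

  for (target in c(1.1, 2.8, 3.6, 14.9, 20.7)) {
    k <- calibrate_kinetics(target)
    expect_equal(half_recovery_time(k), target, tolerance = 1e-4)
  }

  expect_error(calibrate_kinetics(0), class = "frapkin_error_calibrate")
  expect_error(calibrate_kinetics(5, plateau = 1.2),
               class = "frapkin_error_calibrate")
  expect_error(calibrate_kinetics(5, t2_over_t1 = 0.5),
               class = "frapkin_error_calibrate")
  expect_error(calibrate_kinetics(5, y0 = 0.95, plateau = 0.95),
               class = "frapkin_error_calibrate")
})
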