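test_that("noiseless double-exponential data are recovered exactly", {
  k <- frap_kinetics(0.2, 0.5, 2, 0.3, 15)
  x <- seq(0, 60, 0.25)
  fit <- fit_recovery(tibble::tibble(time_post_s = x,
                                     f_norm = recovery_value(k, x)))
  expect_true(fit$converged)
  for (p in c("y0", "A1", "t1", "A2", "t2")) {
    expect_equal(fit[[p]], k[[p]], tolerance = 1e-6)
  }
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$plateau, fit$y0 + fit$A1 + fit$A2, tolerance = 1e-12)
  expect_lte(fit$t1, fit$t2)
})

test_that("noisy fits agree with an independent unconstrained least-squares oracle", {
  k <- frap_kinetics(0.2, 0.5, 2, 0.3, 15)
  set.seed(404)
  x <- seq(0, 59.75, length.out = 120)
  y <- recovery_value(k, x) + rnorm(120, sd = 0.02)
  fit <- fit_recovery(tibble::tibble(time_post_s = x, f_norm = y))
  expect_true(fit$converged)
  # each parameter within 3 reported standard errors of truth
  for (p in c("y0", "A1", "t1", "A2", "t2")) {
    expect_lt(abs(fit[[p]] - k[[p]]), 3 * fit$se[[p]])
  }
  # oracle: plain unconstrained Gauss-Newton on the same points
  oracle <- stats::nls(
    y ~ y0 + A1 * (1 - exp(-x / t1)) + A2 * (1 - exp(-x / t2)),
    start = list(y0 = 0.2, A1 = 0.5, t1 = 2, A2 = 0.3, t2 = 15),
    algorithm = "port",
    control = stats::nls.control(maxiter = 200))
  oc <- coef(oracle)
  for (p in c("y0", "A1", "t1", "A2", "t2")) {
    expect_equal(fit[[p]], unname(oc[[p]]), tolerance = 1e-3)
  }
})

test_that("degenerate and deficient inputs are handled honestly", {
  # perfectly flat curve: amplitudes collapse, flagged for QC
  x <- seq(0, 30, 0.25)
  fit <- fit_recovery(tibble::tibble(time_post_s = x, f_norm = rep(1, length(x))))
  if (fit$converged) {
    expect_lt(fit$A1 + fit$A2, 1e-6)
    expect_true(any(grepl("no_recovery|zero_variance", fit$diagnostics)))
    expect_false(qc_filter(fit, qc_thresholds())$pass)
  } else {
    expect_false(qc_filter(fit, qc_thresholds())$pass)
  }

  # too few post-bleach points for a 5-parameter model
  expect_error(fit_recovery(tibble::tibble(time_post_s = 0:10 / 2,
                                           f_norm = runif(11))),
               class = "frapkin_error_fit_input")
})

test_that("near-equal time constants are canonicalized and diagnosed", {
  k <- frap_kinetics(0.1, 0.45, 5, 0.4, 5.05)
  x <- seq(0, 60, 0.25)
  fit <- fit_recovery(tibble::tibble(time_post_s = x,
                                     f_norm = recovery_value(k, x)))
  expect_true(fit$converged)
  expect_lte(fit$t1, fit$t2)
  if (fit$t2 / fit$t1 < 1.05) {
    expect_true(any(grepl("near_single_exponential", fit$diagnostics)))
  }
  # the half time is insensitive to the ambiguous split
  expect_equal(half_recovery_time(fit), half_recovery_time(k),
               tolerance = 1e-3)
})

test_that("tidy and glance expose the fit in broom shape", {
  k <- kin_brd4_like()
  x <- seq(0, 60, 0.25)
  fit <- fit_recovery(tibble::tibble(time_post_s = x,
                                     f_norm = recovery_value(k, x)))
  td <- tidy(fit)
  expect_equal(td$term, c("y0", "A1", "t1", "A2", "t2"))
  expect_equal(td$estimate[3], k$t1, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$adj.r.squared, 1, tolerance = 1e-9)
})
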