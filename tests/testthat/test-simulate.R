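test_that("simulation is deterministic under a fixed seed", {
  spec <- frap_sim_spec(n_cells = 3, seed = 9)
  a <- simulate_traces(spec)
  b <- simulate_traces(spec)
  expect_identical(a, b)
  c <- simulate_traces(frap_sim_spec(n_cells = 3, seed = 10))
  expect_false(identical(a$f_roi, c$f_roi))
})

test_that("corruption-free traces round-trip through normalization exactly", {
  k <- frap_kinetics(0.05, 0.55, 2, 0.4, 12)  # immobile fraction 0
  spec <- quiet_spec(kinetics = k, acq_bleach_rate = 0)
  tr <- simulate_recovery_trace(spec, 1)
  curve <- normalize_trace(tr)
  post <- curve[curve$phase == "post", ]
  expect_equal(post$f_norm, recovery_value(k, post$time_post_s),
               tolerance = 1e-12)
  # with no immobile fraction the curve tends to the prebleach level
  expect_equal(recovery_value(k, 1e6), 1, tolerance = 1e-12)
  expect_equal(curve$f_norm[curve$phase == "pre"], rep(1, 5))
})

test_that("acquisition bleaching cancels in the normalization", {
  spec <- quiet_spec(kinetics = kin_brd4_like(), acq_bleach_rate = 0.01,
                     background_level = 0)
  tr <- simulate_recovery_trace(spec, 1)
  post <- normalize_trace(tr)
  post <- post[post$phase == "post", ]
  truth <- attr(tr, "truth")
  k <- frap_kinetics(truth$y0, truth$A1, truth$t1, truth$A2, truth$t2)
  expect_lt(max(abs(post$f_norm - recovery_value(k, post$time_post_s))), 1e-9)
})

test_that("per-cell truth records the scattered kinetics and their t-half", {
  spec <- frap_sim_spec(n_cells = 25, cell_cv = 0.2, seed = 33)
  truth <- attr(simulate_traces(spec), "truth")
  expect_equal(nrow(truth), 25)
  expect_gt(stats::sd(truth$t1), 0)
  expect_equal(truth$t2 / truth$t1, rep(spec$kinetics$t2 / spec$kinetics$t1, 25),
               tolerance = 1e-9)
  for (i in c(1, 13, 25)) {
    k <- frap_kinetics(truth$y0[i], truth$A1[i], truth$t1[i],
                       truth$A2[i], truth$t2[i])
    expect_equal(truth$t_half_true_s[i], half_recovery_time(k),
                 tolerance = 1e-6)
  }
})

test_that("simulation spec rejects invalid parameters", {
  expect_error(frap_sim_spec(n_prebleach = 0), class = "frapkin_error_spec")
  expect_error(frap_sim_spec(frame_interval_s = 0), class = "frapkin_error_spec")
  expect_error(frap_sim_spec(roi_intensity_scale = -1),
               class = "frapkin_error_spec")
  expect_error(frap_sim_spec(kinetics = list(y0 = 0.9, A1 = 0.3, t1 = 1,
                                             A2 = 0, t2 = 1)),
               class = "frapkin_error_spec")
  # over-unity plateau rejected at the kinetics level
  expect_error(frap_kinetics(0.3, 0.5, 1, 0.3, 2),
               class = "frapkin_error_kinetics")
})

test_that("full pipeline recovers the group mean t-half from noisy traces", {
  spec <- frap_sim_spec(n_cells = 10, noise_sd = 20, cell_cv = 0.2, seed = 1)
  tr <- simulate_traces(spec)
  truth <- attr(tr, "truth")
  cells <- quantify_cells(tr)
  est <- mean(cells$t_half_s[cells$qc_pass])
  expect_lt(abs(est - mean(truth$t_half_true_s)) / mean(truth$t_half_true_s),
            0.10)
})
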