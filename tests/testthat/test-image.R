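small_image_spec <- function(sim = quiet_spec(duration_s = 20),
                             pixel_noise_sd = 0, ...) {
  frap_image_spec(sim, pixel_size_um = 0.15,
                  nucleus_semi_axes_um = c(6, 4.5), bleach_area_um2 = 13.6,
                  image_size_px = 96, pixel_noise_sd = pixel_noise_sd, ...)
}

test_that("ROI geometry realizes the requested bleach area", {
  spec <- small_image_spec()
  sim <- simulate_image_stack(spec, 1)
  px_area <- spec$pixel_size_um^2
  disc_area <- sum(sim$rois$roi) * px_area
  expect_lt(abs(disc_area - 13.6), px_area + 0.25)  # within ~one pixel ring
  # disc fully inside the nucleus; background fully outside
  expect_true(all(sim$rois$nucleus[sim$rois$roi]))
  expect_false(any(sim$rois$background & sim$rois$nucleus))

  # a 13.6 um2 disc in a nucleus sized so the disc is ~6% of the mask:
  # pixel counting agrees with the area ratio to < 0.5 percentage points
  nuc_area <- pi * prod(spec$nucleus_semi_axes_um)
  frac_expected <- 13.6 / nuc_area
  frac_pixels <- sum(sim$rois$roi) / sum(sim$rois$nucleus)
  expect_lt(abs(frac_pixels - frac_expected), 0.005)
})

test_that("without a bleach event or noise every extracted trace is constant", {
  sim0 <- quiet_spec(duration_s = 10,
                     kinetics = frap_kinetics(0.9999, 1e-6, 1, 0, 1),
                     bleach_fraction_of_total = 0, acq_bleach_rate = 0)
  sim <- simulate_image_stack(small_image_spec(sim0), 1)
  tr <- extract_traces(sim)
  for (col in c("f_roi", "f_total", "f_bg")) {
    expect_lt(diff(range(tr[[col]])), 1e-3 * mean(tr[[col]]))
  }
})

test_that("extraction reproduces known region means exactly", {
  # hand-built stack: uniform frames -> all three traces constant = v
  stack <- array(7.5, dim = c(20, 20, 4))
  rois <- list(roi = matrix(FALSE, 20, 20), nucleus = matrix(FALSE, 20, 20),
               background = matrix(FALSE, 20, 20))
  rois$roi[9:12, 9:12] <- TRUE
  rois$nucleus[5:16, 5:16] <- TRUE
  rois$background[1:3, 1:3] <- TRUE
  tr <- extract_traces(stack, rois, time_s = 0:3,
                       phase = c("pre", "post", "post", "post"))
  expect_equal(tr$f_roi, rep(7.5, 4))
  expect_equal(tr$f_total, rep(7.5, 4))
  expect_equal(tr$f_bg, rep(7.5, 4))

  # single-pixel ROI equals that pixel's time series
  rois$roi[] <- FALSE
  rois$roi[10, 11] <- TRUE
  series <- c(3, 1, 4, 1.5)
  for (f in 1:4) stack[10, 11, f] <- series[f]
  tr <- extract_traces(stack, rois, time_s = 0:3,
                       phase = c("pre", "post", "post", "post"))
  expect_equal(tr$f_roi, series)

  # known disc mean sequence reproduced without noise
  sim <- simulate_image_stack(small_image_spec(), 1)
  tr <- extract_traces(sim)
  manual <- vapply(seq_len(dim(sim$stack)[3]),
                   function(f) mean(sim$stack[, , f][sim$rois$roi]),
                   numeric(1))
  expect_equal(tr$f_roi, manual, tolerance = 1e-12)
})

test_that("extraction validates masks and frame metadata", {
  stack <- array(1, dim = c(10, 10, 3))
  rois <- list(roi = matrix(FALSE, 10, 10), nucleus = matrix(TRUE, 10, 10),
               background = matrix(TRUE, 10, 10))
  expect_error(extract_traces(stack, rois), class = "frapkin_error_empty_roi")
  rois$roi[1, 1] <- TRUE
  expect_error(extract_traces(stack, rois, time_s = 0:3),
               class = "frapkin_error_schema")
})

test_that("image-level and curve-level generators agree", {
  sim0 <- quiet_spec(duration_s = 20, seed = 19)
  # noiseless: normalized curves identical to machine precision
  curve_ref <- normalize_trace(simulate_recovery_trace(sim0, 1))
  img <- simulate_image_stack(small_image_spec(sim0), 1)
  curve_img <- normalize_trace(extract_traces(img))
  expect_lt(max(abs(curve_img$f_norm - curve_ref$f_norm)), 1e-9)

  # pixel noise averages down with the ROI pixel count
  sd_px <- 30
  img_n <- simulate_image_stack(small_image_spec(sim0, pixel_noise_sd = sd_px), 1)
  curve_n <- normalize_trace(extract_traces(img_n))
  n_px <- sum(img_n$rois$roi)
  rms <- sqrt(mean((curve_n$f_norm - curve_ref$f_norm)^2))
  # deviation in normalized units: ROI-mean noise over the ROI prebleach signal
  sim <- sim0
  tol <- 2 * sd_px / sqrt(n_px) / (sim$roi_intensity_scale *
                                     (1 - sim$bleach_fraction_of_total))
  expect_lt(rms, tol)
})

test_that("stacks round-trip through TIFF with sidecars", {
  sim <- simulate_image_stack(small_image_spec(), 1)
  dir <- withr::local_tempdir()
  write_image_stack(sim, dir, "s1")
  back <- read_image_stack(dir, "s1")
  expect_equal(dim(back$stack), dim(sim$stack))
  expect_lt(max(abs(back$stack - sim$stack)) / max(sim$stack), 1e-6)
  expect_identical(back$rois$roi, sim$rois$roi)
  expect_equal(back$time_s, sim$time_s)
  expect_equal(back$truth$t_half_true_s, sim$truth$t_half_true_s,
               tolerance = 1e-9)
  tr_a <- extract_traces(sim)
  tr_b <- extract_traces(back, cell_id = tr_a$cell_id[1])
  expect_equal(tr_b$f_roi, tr_a$f_roi, tolerance = 1e-5)
})

test_that("infeasible geometry is rejected", {
  expect_error(frap_image_spec(quiet_spec(), nucleus_semi_axes_um = c(2, 2),
                               bleach_area_um2 = 17.6),
               class = "frapkin_error_geometry")
  expect_error(frap_image_spec(quiet_spec(), bleach_area_um2 = 0),
               class = "frapkin_error_geometry")
})
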