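#' Specification of a synthetic FRAP experiment
#'
#' Bundles the acquisition and corruption parameters for the curve-level
#' simulator. Defaults reflect a typical bromodomain-protein FRAP protocol:
#' five prescans, ~0.25 s frame interval, a bleach event that removes a few
#' percent of the whole-nucleus signal, mild acquisition photobleaching from
#' the imaging laser, additive detector noise, and ~20% cell-to-cell scatter
#' in exchange kinetics.
#'
#' @param n_cells Number of cells to simulate.
#' @param kinetics Population-center kinetics, a [frap_kinetics()] object.
#' @param n_prebleach Number of prebleach scans (default 5).
#' @param frame_interval_s Frame interval, seconds (default 0.25).
#' @param duration_s Total post-bleach acquisition time, seconds.
#' @param cell_cv Coefficient of variation of the lognormal cell-to-cell
#'   factor applied multiplicatively to both time constants (one shared factor
#'   per cell, median 1, so each cell's true t-half scales by the factor).
#' @param noise_sd Additive Gaussian noise SD per channel per frame, in the
#'   same arbitrary units as the intensity scales.
#' @param acq_bleach_rate Fractional fluorescence loss per acquired frame
#'   caused by the imaging laser (applied to ROI and total channels, not to
#'   background), `>= 0`.
#' @param background_level Mean background intensity, arbitrary units.
#' @param roi_intensity_scale,total_intensity_scale Prebleach
#'   background-subtracted intensities of the bleached region and the whole
#'   nucleus, arbitrary units, `> 0`.
#' @param bleach_fraction_of_total Fraction of whole-nucleus fluorescent
#'   signal destroyed at the bleach event (both fluorescent channels drop by
#'   this factor, so it cancels in the normalization but lowers the
#'   signal-to-noise of post-bleach frames).
#' @param seed Integer seed; the same spec and seed give bit-identical output.
#' @return An object of class `frap_sim_spec` (a validated named list).
#' @seealso [simulate_traces()], [simulate_recovery_trace()]
#' @export
frap_sim_spec <- function(n_cells = 10,
                          kinetics = calibrate_kinetics(6.3),
                          n_prebleach = 5,
                          frame_interval_s = 0.25,
                          duration_s = 60,
                          cell_cv = 0.2,
                          noise_sd = 20,
                          acq_bleach_rate = 5e-4,
                          background_level = 50,
                          roi_intensity_scale = 1000,
                          total_intensity_scale = 1200,
                          bleach_fraction_of_total = 0.06,
                          seed = 1L) {
  if (!inherits(kinetics, "frap_kinetics")) {
    rlang::abort("`kinetics` must be a frap_kinetics object.",
                 class = "frapkin_error_spec")
  }
  if (n_cells < 1) {
    rlang::abort("`n_cells` must be at least 1.", class = "frapkin_error_spec")
  }
  if (n_prebleach < 1) {
    rlang::abort("`n_prebleach` must be at least 1.", class = "frapkin_error_spec")
  }
  if (frame_interval_s <= 0 || duration_s <= 0) {
    rlang::abort("`frame_interval_s` and `duration_s` must be positive.",
                 class = "frapkin_error_spec")
  }
  if (roi_intensity_scale <= 0 || total_intensity_scale <= 0) {
    rlang::abort("Intensity scales must be positive.", class = "frapkin_error_spec")
  }
  if (acq_bleach_rate < 0 || acq_bleach_rate >= 1) {
    rlang::abort("`acq_bleach_rate` must lie in [0, 1).", class = "frapkin_error_spec")
  }
  if (bleach_fraction_of_total < 0 || bleach_fraction_of_total >= 1) {
    rlang::abort("`bleach_fraction_of_total` must lie in [0, 1).",
                 class = "frapkin_error_spec")
  }
  if (cell_cv < 0 || noise_sd < 0 || background_level < 0) {
    rlang::abort("`cell_cv`, `noise_sd` and `background_level` must be non-negative.",
                 class = "frapkin_error_spec")
  }
  structure(
    list(n_cells = as.integer(n_cells), kinetics = kinetics,
         n_prebleach = as.integer(n_prebleach),
         frame_interval_s = frame_interval_s, duration_s = duration_s,
         cell_cv = cell_cv, noise_sd = noise_sd,
         acq_bleach_rate = acq_bleach_rate,
         background_level = background_level,
         roi_intensity_scale = roi_intensity_scale,
         total_intensity_scale = total_intensity_scale,
         bleach_fraction_of_total = bleach_fraction_of_total,
         seed = as.integer(seed)),
    class = "frap_sim_spec"
  )
}

# deterministic per-cell seed stream, independent across cells so adding a
# cell never perturbs earlier cells' draws
cell_seed <- function(seed, cell_index) {
  as.integer((as.double(seed) + 7919 * as.double(cell_index)) %% 2147483647)
}

# lognormal cell factor with median 1 and coefficient of variation cv
cell_kinetics_factor <- function(cv) {
  if (cv <= 0) return(1)
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(1, mean = 0, sd = sdlog))
}

#' Simulate one cell's FRAP trace
#'
#' Generates the raw three-channel intensity time series (bleached ROI, total
#' nucleus, background) for a single cell under the forward model: the
#' noise-free, corruption-free normalization of the trace equals the
#' double-exponential recovery curve of that cell's true kinetics exactly.
#' Prebleach frames sit at the unbleached level; the bleach event is
#' instantaneous between the last prescan and the first post-bleach frame (no
#' mid-bleach frame is emitted). Acquisition photobleaching multiplies both
#' fluorescent channels by `(1 - acq_bleach_rate)` per acquired frame; the
#' background channel is constant plus noise.
#'
#' @param spec A [frap_sim_spec()].
#' @param cell_index Cell number within the spec (1-based); determines the
#'   cell's private random stream.
#' @return A tibble with columns `cell_id`, `frame`, `time_s`, `phase`
#'   (`"pre"`/`"post"`), `f_roi`, `f_total`, `f_bg`, carrying the cell's true
#'   kinetics in attribute `"truth"` (a one-row tibble with the per-cell
#'   parameters and analytic t-half).
#' @export
simulate_recovery_trace <- function(spec, cell_index = 1L) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  set.seed(cell_seed(spec$seed, cell_index))
  k0 <- spec$kinetics
  fac <- cell_kinetics_factor(spec$cell_cv)
  k <- frap_kinetics(y0 = k0$y0, A1 = k0$A1, t1 = k0$t1 * fac,
                     A2 = k0$A2, t2 = k0$t2 * fac)

  n_post <- max(1L, floor(spec$duration_s / spec$frame_interval_s) + 1L)
  n_pre <- spec$n_prebleach
  n <- n_pre + n_post
  frame <- seq_len(n)
  time_s <- (frame - 1L) * spec$frame_interval_s
  phase <- rep(c("pre", "post"), c(n_pre, n_post))
  x <- c(rep(0, n_pre), time_s[(n_pre + 1L):n] - time_s[n_pre + 1L])

  g <- (1 - spec$acq_bleach_rate)^(frame - 1L)      # acquisition bleaching
  q <- c(rep(1, n_pre), rep(1 - spec$bleach_fraction_of_total, n_post))
  y <- c(rep(1, n_pre), recovery_value(k, x[(n_pre + 1L):n]))

  f_roi <- spec$background_level + spec$roi_intensity_scale * y * q * g
  f_total <- spec$background_level + spec$total_intensity_scale * q * g
  f_bg <- rep(spec$background_level, n)

  if (spec$noise_sd > 0) {
    f_roi <- f_roi + stats::rnorm(n, sd = spec$noise_sd)
    f_total <- f_total + stats::rnorm(n, sd = spec$noise_sd)
    f_bg <- f_bg + stats::rnorm(n, sd = spec$noise_sd)
  }

  truth <- tibble::tibble(
    cell_id = sprintf("cell_%03d", cell_index),
    y0 = k$y0, A1 = k$A1, t1 = k$t1, A2 = k$A2, t2 = k$t2,
    plateau = k$plateau,
    t_half_true_s = half_recovery_time(k, t_upper_hint = k$t2)
  )
  out <- tibble::tibble(
    cell_id = sprintf("cell_%03d", cell_index),
    frame = frame, time_s = time_s, phase = phase,
    f_roi = f_roi, f_total = f_total, f_bg = f_bg
  )
  attr(out, "truth") <- truth
  out
}

#' Simulate a group of FRAP traces
#'
#' Runs [simulate_recovery_trace()] for `spec$n_cells` cells and binds the
#' traces into one long tibble (the same layout written and read by
#' [write_frap_traces()] / [read_frap_traces()]).
#'
#' @param spec A [frap_sim_spec()].
#' @return A long tibble of traces with attribute `"truth"`: one row per cell
#'   with the true per-cell kinetics and analytic t-half.
#' @export
#' @examples
#' traces <- simulate_traces(frap_sim_spec(n_cells = 2, seed = 7))
#' dplyr::count(traces, cell_id)
#' attr(traces, "truth")
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  cells <- purrr::map(seq_len(spec$n_cells),
                      function(i) simulate_recovery_trace(spec, i))
  truth <- purrr::map(cells, attr, "truth") |> purrr::list_rbind()
  out <- purrr::list_rbind(cells)
  attr(out, "truth") <- truth
  out
}
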