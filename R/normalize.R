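#' Normalize a FRAP trace with acquisition-photobleach correction
#'
#' Converts one cell's raw three-channel trace to relative fluorescence using
#' double normalization: at each frame the background-subtracted ROI signal
#' is divided by the background-subtracted whole-nucleus signal (cancelling
#' fluorophore loss caused by the imaging laser, which affects both regions
#' equally), and the ratio is rescaled by the prebleach means so that the
#' prebleach level averages exactly 1:
#' \deqn{F_{norm}(t) = \frac{F_{ROI}(t) - F_{BG}(t)}{F_{total}(t) - F_{BG}(t)}
#'   \times \frac{\bar F^i_{total} - \bar F^i_{BG}}
#'               {\bar F^i_{ROI} - \bar F^i_{BG}},}
#' where the bars denote means over the prebleach scans.
#'
#' Time is re-zeroed at the first post-bleach frame (`time_post_s = 0` there);
#' prebleach frames keep their normalized values, at negative `time_post_s`,
#' as diagnostics. The normalization is invariant to common gain rescaling,
#' common additive offsets on all three channels, and (at zero background)
#' any common per-frame multiplicative decay of the two fluorescent channels.
#'
#' @param trace A single cell's trace: a tibble with columns `cell_id`,
#'   `time_s`, `phase`, `f_roi`, `f_total`, `f_bg` (one `cell_id` only).
#' @return A tibble with columns `cell_id`, `phase`, `time_post_s`, `f_norm`.
#' @seealso [normalize_traces()] for many cells at once.
#' @export
#' @examples
#' tr <- simulate_recovery_trace(frap_sim_spec(noise_sd = 0), 1)
#' curve <- normalize_trace(tr)
#' head(curve)
normalize_trace <- function(trace) {
  trace <- tibble::as_tibble(trace)
  if (length(unique(trace$cell_id)) != 1) {
    rlang::abort("`normalize_trace()` expects exactly one cell; use `normalize_traces()` for a collection.",
                 class = "frapkin_error_schema")
  }
  validate_traces(trace)
  id <- trace$cell_id[1]

  pre <- trace$phase == "pre"
  roi_i <- mean(trace$f_roi[pre] - trace$f_bg[pre])
  total_i <- mean(trace$f_total[pre] - trace$f_bg[pre])
  if (roi_i <= 0) {
    rlang::abort(paste0("Cell `", id,
                        "`: prebleach background-subtracted ROI signal is not positive."),
                 class = "frapkin_error_signal")
  }
  denom <- trace$f_total - trace$f_bg
  bad <- which(denom <= 0)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Cell `", id, "`: non-positive background-subtracted total signal at frame ",
             bad[1], " (time ", format(trace$time_s[bad[1]]), " s)."),
      class = "frapkin_error_denominator"
    )
  }
  f_norm <- (trace$f_roi - trace$f_bg) / denom * (total_i / roi_i)
  t0 <- trace$time_s[which(!pre)[1]]
  tibble::tibble(
    cell_id = id,
    phase = trace$phase,
    time_post_s = trace$time_s - t0,
    f_norm = f_norm
  )
}

#' Normalize a collection of FRAP traces
#'
#' Applies [normalize_trace()] to each cell of a long trace table. A failure
#' in any cell aborts with an error tagged with that cell's id.
#'
#' @param traces Long trace tibble (multiple cells).
#' @return A long tibble of normalized curves (`cell_id`, `phase`,
#'   `time_post_s`, `f_norm`).
#' @export
normalize_traces <- function(traces) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(normalize_trace) |>
    purrr::list_rbind()
}
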