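#' Quantify one cell: normalize, fit, half-recovery time, QC
#'
#' Runs the full per-cell quantification chain on one raw trace: Phair-style
#' normalization with acquisition-photobleach correction, constrained
#' double-exponential fit, half-recovery time by bisection, and
#' quality-control filtering on the fitted plateau and adjusted R-squared.
#' Stage errors are re-raised tagged with the cell id.
#'
#' @param trace A single cell's raw trace (see [normalize_trace()]).
#' @param thresholds A [qc_thresholds()] object.
#' @param constrain Passed to [fit_recovery()].
#' @return A one-row tibble: `cell_id`, `y0`, `A1`, `t1`, `A2`, `t2`,
#'   `plateau`, `adj_r2`, `converged`, `t_half_s`, `qc_pass`, `qc_reasons`
#'   (reasons collapsed with `";"`), plus the `frap_fit` object in the
#'   list-column `fit`. `t_half_s` is `NA` when the fit failed or no
#'   recovering amplitude was found.
#' @export
quantify_cell <- function(trace, thresholds = qc_thresholds(),
                          constrain = TRUE) {
  id <- as.character(trace$cell_id[1])
  res <- tryCatch({
    curve <- normalize_trace(trace)
    fit <- fit_recovery(curve, constrain = constrain)
    t_half <- NA_real_
    if (fit$converged && is.finite(fit$A1 + fit$A2) && fit$A1 + fit$A2 > 1e-6) {
      t_half <- half_recovery_time(fit, t_upper_hint = max(fit$t2, 1e-3))
    }
    qc <- qc_filter(fit, thresholds)
    tibble::tibble(
      cell_id = id, y0 = fit$y0, A1 = fit$A1, t1 = fit$t1, A2 = fit$A2,
      t2 = fit$t2, plateau = fit$plateau, adj_r2 = fit$adj_r2,
      converged = fit$converged, t_half_s = t_half,
      qc_pass = qc$pass,
      qc_reasons = paste(qc$reasons, collapse = ";"),
      fit = list(fit)
    )
  }, frapkin_error_schema = function(e) rlang::abort(
       paste0("Cell `", id, "`: ", rlang::cnd_message(e)), parent = e,
       class = class(e)[1]),
     frapkin_error_fit_input = function(e) rlang::abort(
       paste0("Cell `", id, "`: ", rlang::cnd_message(e)), parent = e,
       class = class(e)[1]))
  res
}

#' Quantify a collection of cells
#'
#' Applies [quantify_cell()] to every cell in a long trace table and binds
#' the per-cell results into one tibble (the per-cell results table of the
#' pipeline).
#'
#' @inheritParams quantify_cell
#' @param traces Long trace tibble with one or more cells.
#' @return A tibble with one row per cell (see [quantify_cell()]).
#' @export
#' @examples
#' traces <- simulate_traces(frap_sim_spec(n_cells = 3, seed = 11))
#' cells <- quantify_cells(traces)
#' cells[, c("cell_id", "t_half_s", "qc_pass")]
quantify_cells <- function(traces, thresholds = qc_thresholds(),
                           constrain = TRUE) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(quantify_cell, thresholds = thresholds, constrain = constrain) |>
    purrr::list_rbind()
}
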