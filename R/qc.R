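#' Quality-control verdict for a fitted recovery curve
#'
#' Marks a fitted cell for exclusion as an imaging artifact when the fitted
#' plateau exceeds the plateau threshold (focal drift can push apparent
#' recovery above the prebleach level) or the adjusted R-squared falls below
#' its threshold (cell movement or passing debris gives irregular recovery
#' profiles and poor fits), or when the fit did not converge. Inequalities
#' are strict: a plateau of exactly `plateau_max` or an adjusted R-squared of
#' exactly `adj_r2_min` passes.
#'
#' @param fit A [fit_recovery()] result.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing; values among `"no_fit"`, `"plateau"`, `"adj_r2"`).
#' @export
#' @examples
#' k <- frap_kinetics(0.05, 0.54, 2, 0.36, 12)
#' t <- seq(0, 60, 0.25)
#' fit <- fit_recovery(tibble::tibble(time_post_s = t,
#'                                    f_norm = recovery_value(k, t)))
#' qc_filter(fit, qc_thresholds())
qc_filter <- function(fit, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "frap_qc_thresholds"))
  reasons <- character()
  if (!isTRUE(fit$converged)) {
    reasons <- c(reasons, "no_fit")
  } else {
    if (is.na(fit$plateau) || fit$plateau > thresholds$plateau_max) {
      reasons <- c(reasons, "plateau")
    }
    if (is.na(fit$adj_r2) || fit$adj_r2 < thresholds$adj_r2_min) {
      reasons <- c(reasons, "adj_r2")
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}
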