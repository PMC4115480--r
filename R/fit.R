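#' Fit a double-exponential association model to a normalized recovery curve
#'
#' Least-squares fit of
#' `f_norm = y0 + A1 * (1 - exp(-t/t1)) + A2 * (1 - exp(-t/t2))`
#' to the post-bleach frames of a normalized curve, by Levenberg-Marquardt
#' with box constraints (`A1, A2 >= 0`, `t1, t2 > 0`); constraints guarantee
#' the fitted curve is non-decreasing, which the half-recovery bisection
#' relies on. Prebleach frames (`time_post_s < 0`) are excluded from the fit.
#'
#' Starting values: `y0` from the first post-bleach value, the plateau from
#' the mean of the final 10% of frames, and `(t1, t2)` at one tenth and one
#' half of the observed post-bleach span; on failure the time-constant starts
#' are rescaled through a fixed ladder of up to five restarts. Under the
#' constraints the time constants are additionally capped at ten times the
#' observed post-bleach span and the amplitudes at 2: past that the slow
#' component degenerates into a linear drift term with an unbounded plateau. Parameters are
#' reported in canonical order `t1 <= t2`; when the two fitted time constants
#' are within 5% of each other a `near_single_exponential` diagnostic is set
#' (the half-recovery time is unaffected). Adjusted R-squared uses p = 5 free
#' parameters: `1 - (1 - R2) * (n - 1) / (n - p - 1)`. A fit that does not
#' converge is reported as such, never silently replaced.
#'
#' @param curve A normalized curve from [normalize_trace()] (or any tibble
#'   with `time_post_s` and `f_norm`); only rows with `time_post_s >= 0`
#'   enter the fit. At least 12 post-bleach points are required.
#' @param constrain Fit under the non-negativity/positivity box constraints
#'   (default). `FALSE` fits unconstrained, for sensitivity checks only; the
#'   monotonicity that the half-recovery bisection assumes is then no longer
#'   guaranteed.
#' @param max_restarts Maximum number of jittered restarts after a failed
#'   attempt (default 5).
#' @return An object of class `frap_fit`: list with `y0`, `A1`, `t1`, `A2`,
#'   `t2`, `plateau`, `adj_r2`, `r2`, `converged`, `n_points`, `sigma`,
#'   standard errors in `se`, `diagnostics`, and the fitted data in `data`.
#' @seealso [tidy.frap_fit()], [glance.frap_fit()], [autoplot.frap_fit()]
#' @export
#' @examples
#' k <- frap_kinetics(0.2, 0.5, 2, 0.3, 15)
#' curve <- tibble::tibble(time_post_s = seq(0, 60, 0.25),
#'                         f_norm = recovery_value(k, seq(0, 60, 0.25)))
#' fit <- fit_recovery(curve)
#' glance(fit)
fit_recovery <- function(curve, constrain = TRUE, max_restarts = 5L) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("time_post_s", "f_norm") %in% names(curve))) {
    rlang::abort("`curve` needs columns `time_post_s` and `f_norm`.",
                 class = "frapkin_error_schema")
  }
  post <- curve[curve$time_post_s >= 0, c("time_post_s", "f_norm")]
  if (nrow(post) < 12) {
    rlang::abort("At least 12 post-bleach points are required for a 5-parameter fit.",
                 class = "frapkin_error_fit_input")
  }
  if (!all(is.finite(post$time_post_s)) || !all(is.finite(post$f_norm))) {
    rlang::abort("Non-finite values in the recovery curve.",
                 class = "frapkin_error_fit_input")
  }
  x <- post$time_post_s
  y <- post$f_norm
  n <- length(y)
  t_span <- max(x) - min(x)

  y0_start <- y[1]
  tail_n <- max(1L, ceiling(0.1 * n))
  plateau_start <- mean(utils::tail(y, tail_n))
  A_start <- max(plateau_start - y0_start, 0.05)

  # fixed restart ladder keeps the fit deterministic
  scale_ladder <- c(1, 0.4, 2.5, 0.15, 6)[seq_len(max_restarts + 1L)]
  lower <- if (constrain) c(y0 = -Inf, A1 = 0, t1 = 1e-6, A2 = 0, t2 = 1e-6) else NULL
  # time constants bounded by a multiple of the observed span: beyond that
  # the slow component is indistinguishable from a linear drift and the
  # plateau estimate degenerates
  upper <- if (constrain) c(y0 = 2, A1 = 2, t1 = 10 * t_span,
                            A2 = 2, t2 = 10 * t_span) else NULL
  fit <- NULL
  for (s in scale_ladder) {
    start <- list(y0 = y0_start, A1 = 0.6 * A_start, t1 = s * t_span / 10,
                  A2 = 0.4 * A_start, t2 = s * t_span / 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A1 * (1 - exp(-x / t1)) + A2 * (1 - exp(-x / t2)),
        data = list(x = x, y = y),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }

  if (is.null(fit)) {
    return(structure(
      list(y0 = NA_real_, A1 = NA_real_, t1 = NA_real_, A2 = NA_real_,
           t2 = NA_real_, plateau = NA_real_, r2 = NA_real_,
           adj_r2 = NA_real_, sigma = NA_real_, converged = FALSE,
           n_points = n, se = NULL,
           diagnostics = "no_fit: all restarts failed",
           data = post),
      class = "frap_fit"
    ))
  }

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  names(se) <- names(cf)
  # canonical order t1 <= t2
  if (cf[["t1"]] > cf[["t2"]]) {
    cf[c("A1", "t1", "A2", "t2")] <- cf[c("A2", "t2", "A1", "t1")]
    se[c("A1", "t1", "A2", "t2")] <- se[c("A2", "t2", "A1", "t1")]
  }

  resid <- y - recovery_value(as.list(cf), x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  adj_r2 <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 5 - 1)

  diagnostics <- character()
  if (cf[["A1"]] + cf[["A2"]] < 1e-6) {
    diagnostics <- c(diagnostics, "no_recovery: fitted amplitudes are ~0")
  } else if (cf[["t2"]] / cf[["t1"]] < 1.05) {
    diagnostics <- c(diagnostics, "near_single_exponential: t2/t1 < 1.05")
  }
  if (is.na(r2)) {
    diagnostics <- c(diagnostics, "zero_variance: flat curve, R2 undefined")
  }

  structure(
    list(y0 = unname(cf[["y0"]]), A1 = unname(cf[["A1"]]),
         t1 = unname(cf[["t1"]]), A2 = unname(cf[["A2"]]),
         t2 = unname(cf[["t2"]]),
         plateau = unname(cf[["y0"]] + cf[["A1"]] + cf[["A2"]]),
         r2 = r2, adj_r2 = adj_r2,
         sigma = sqrt(ss_res / max(n - 5, 1)),
         converged = TRUE, n_points = n, se = se,
         diagnostics = diagnostics, data = post),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<frap_fit> NOT converged;", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<frap_fit> y0 = %.4g, A1 = %.4g (t1 = %.4g s), A2 = %.4g (t2 = %.4g s)\n",
    x$y0, x$A1, x$t1, x$A2, x$t2))
  cat(sprintf("  plateau = %.4g, adjusted R2 = %.5g, n = %d\n",
              x$plateau, x$adj_r2, x$n_points))
  if (length(x$diagnostics) > 0) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a recovery fit
#'
#' @param x A [fit_recovery()] result.
#' @param ... Unused.
#' @return One row per model parameter with `term`, `estimate`, `std.error`.
#' @export
tidy.frap_fit <- function(x, ...) {
  terms <- c("y0", "A1", "t1", "A2", "t2")
  tibble::tibble(
    term = terms,
    estimate = unname(vapply(terms, function(t) x[[t]], numeric(1))),
    std.error = if (is.null(x$se)) rep(NA_real_, 5) else unname(x$se[terms])
  )
}

#' One-row summary of a recovery fit
#'
#' @param x A [fit_recovery()] result.
#' @param ... Unused.
#' @return A one-row tibble with `plateau`, `r.squared`, `adj.r.squared`,
#'   `sigma`, `n`, `converged`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    plateau = x$plateau, r.squared = x$r2, adj.r.squared = x$adj_r2,
    sigma = x$sigma, n = x$n_points, converged = x$converged
  )
}
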