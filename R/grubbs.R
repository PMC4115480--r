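#' Critical value of the two-sided Grubbs outlier test
#'
#' @param n Sample size.
#' @param alpha Significance level (two-sided).
#' @return The critical value
#'   \eqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}}} with
#'   \eqn{t = t_{1-\alpha/(2n),\,n-2}}.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) return(Inf)
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier elimination
#'
#' Removes, one value per pass, the single most extreme value of a treatment
#' group (largest studentized deviation from the mean,
#' `G = max |x - mean| / sd`) while `G` exceeds the two-sided critical value
#' at level `alpha`, stopping as soon as no value is extreme, fewer than three
#' values remain, or the spread is zero. The order of retained values is
#' preserved. This is the standard within-group outlier elimination applied
#' before computing group means.
#'
#' @param values Numeric vector of measurements (finite).
#' @param alpha Significance level per pass (default 0.05).
#' @return A list with `retained` (original order) and `removed` (in removal
#'   order).
#' @export
#' @examples
#' grubbs_outliers(c(5.1, 5.3, 5.0, 5.2, 9.8))$removed  # 9.8
grubbs_outliers <- function(values, alpha = 0.05) {
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite.", class = "frapkin_error_stats")
  }
  removed <- numeric()
  keep <- values
  repeat {
    n <- length(keep)
    if (n < 3) break
    s <- stats::sd(keep)
    if (s == 0) break
    dev <- abs(keep - mean(keep))
    G <- max(dev) / s
    if (G <= grubbs_critical(n, alpha)) break
    i <- which.max(dev)
    removed <- c(removed, keep[i])
    keep <- keep[-i]
  }
  list(retained = keep, removed = removed)
}
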