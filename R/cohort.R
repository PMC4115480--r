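#' Summarize one treatment group
#'
#' Grubbs outlier elimination at level `alpha`, then the arithmetic mean and
#' the standard error of the mean (sample SD with `n - 1` denominator divided
#' by `sqrt(n)`) of the retained values.
#'
#' @param values Numeric vector of half-recovery times (seconds) for
#'   QC-passed cells of one group.
#' @param alpha Grubbs significance level.
#' @return A one-row tibble: `n_before`, `n_after`, `mean_s`, `sem_s`
#'   (`NA` for a single value), `removed` (list-column).
#' @export
#' @examples
#' summarize_group(c(2, 4, 6))  # mean 4, SEM 2/sqrt(3)
summarize_group <- function(values, alpha = 0.05) {
  g <- grubbs_outliers(values, alpha)
  n <- length(g$retained)
  tibble::tibble(
    n_before = length(values),
    n_after = n,
    mean_s = if (n > 0) mean(g$retained) else NA_real_,
    sem_s = if (n > 1) stats::sd(g$retained) / sqrt(n) else NA_real_,
    removed = list(g$removed)
  )
}

#' Summarize all treatment groups of a results table
#'
#' @param data A tibble with one row per QC-passed cell, holding the group
#'   label and the half-recovery time.
#' @param group,value Column names (strings) of the group label and the
#'   t-half value; defaults `"group"` and `"t_half_s"`.
#' @param alpha Grubbs significance level.
#' @return A tibble with one row per group: `group`, `n_before`, `n_after`,
#'   `mean_s`, `sem_s`, `removed`. Groups with fewer than ten cells trigger a
#'   warning (group means are normally computed from at least ten cells).
#' @export
summarize_groups <- function(data, group = "group", value = "t_half_s",
                             alpha = 0.05) {
  data <- tibble::as_tibble(data)
  if (!all(c(group, value) %in% names(data))) {
    rlang::abort(paste0("`data` needs columns `", group, "` and `", value, "`."),
                 class = "frapkin_error_schema")
  }
  out <- data |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(summarize_group(.data[[value]], alpha = alpha),
                     .groups = "drop")
  small <- out$group[out$n_before < 10]
  if (length(small) > 0) {
    rlang::warn(paste0("Group(s) with fewer than 10 cells: ",
                       paste(small, collapse = ", ")),
                class = "frapkin_warning_small_group")
  }
  out
}

#' One-way ANOVA with Tukey-Kramer multiple comparisons
#'
#' Tests for differences in mean half-recovery time between treatment groups.
#' The overall one-way ANOVA F statistic uses the pooled within-group mean
#' square (MSE); each pair of groups is then compared with the Tukey-Kramer
#' studentized-range statistic
#' \deqn{q_{ij} = \frac{|\bar x_i - \bar x_j|}
#'   {\sqrt{\frac{MSE}{2}\left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' whose adjusted p-value comes from the studentized-range distribution with
#' `(k, N - k)` parameters; the Kramer form of the denominator handles
#' unequal group sizes. Values should already have passed QC and Grubbs
#' outlier elimination (see [summarize_groups()] and [run_frap_pipeline()]).
#'
#' Degenerate spread (MSE = 0) is flagged: pairs with unequal means are
#' reported significant with adjusted p = 0, pairs with equal means are not
#' significant.
#'
#' @inheritParams summarize_groups
#' @param alpha Familywise significance level for the `significant` flag.
#' @return An object of class `frap_anova`: list with `pairs` (tibble of
#'   `group_a`, `group_b`, `diff_s`, `q`, `p_adj`, `significant`), `f`,
#'   `p_value`, `df1`, `df2`, `mse`, `alpha`, `degenerate`, `group_stats`.
#' @seealso [tidy.frap_anova()], [glance.frap_anova()]
#' @export
anova_tukey <- function(data, group = "group", value = "t_half_s",
                        alpha = 0.05) {
  data <- tibble::as_tibble(data)
  if (!all(c(group, value) %in% names(data))) {
    rlang::abort(paste0("`data` needs columns `", group, "` and `", value, "`."),
                 class = "frapkin_error_schema")
  }
  labs <- as.character(data[[group]])
  x <- data[[value]]
  if (!all(is.finite(x))) {
    rlang::abort("Half-recovery values must be finite.",
                 class = "frapkin_error_stats")
  }
  stats_tbl <- tibble::tibble(label = labs, x = x) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$x),
                     ss = sum((.data$x - mean(.data$x))^2), .groups = "drop")
  k <- nrow(stats_tbl)
  if (k < 2) {
    rlang::abort("At least two groups are required for comparison.",
                 class = "frapkin_error_stats")
  }
  if (any(stats_tbl$n < 2)) {
    rlang::abort("Every group needs at least two values for the pooled variance.",
                 class = "frapkin_error_stats")
  }
  N <- sum(stats_tbl$n)
  df1 <- k - 1L
  df2 <- N - k
  mse <- sum(stats_tbl$ss) / df2
  grand <- sum(stats_tbl$n * stats_tbl$mean) / N
  msb <- sum(stats_tbl$n * (stats_tbl$mean - grand)^2) / df1
  degenerate <- mse == 0

  if (degenerate) {
    f <- if (msb > 0) Inf else NaN
    p_value <- if (msb > 0) 0 else 1
  } else {
    f <- msb / mse
    p_value <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  idx <- utils::combn(k, 2)
  pairs <- purrr::map(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    d <- stats_tbl$mean[i1] - stats_tbl$mean[i2]
    if (degenerate) {
      q <- if (d != 0) Inf else 0
      p <- if (d != 0) 0 else 1
    } else {
      se <- sqrt(mse / 2 * (1 / stats_tbl$n[i1] + 1 / stats_tbl$n[i2]))
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }
    tibble::tibble(group_a = stats_tbl$label[i1],
                   group_b = stats_tbl$label[i2],
                   diff_s = d, q = q, p_adj = p,
                   significant = p < alpha)
  }) |> purrr::list_rbind()

  structure(
    list(pairs = pairs, f = f, p_value = p_value, df1 = df1, df2 = df2,
         mse = mse, alpha = alpha, degenerate = degenerate,
         group_stats = stats_tbl),
    class = "frap_anova"
  )
}

#' @export
print.frap_anova <- function(x, ...) {
  cat(sprintf("<frap_anova> k = %d groups, F(%d, %d) = %.4g, p = %.4g%s\n",
              nrow(x$group_stats), x$df1, x$df2, x$f, x$p_value,
              if (x$degenerate) " [degenerate: MSE = 0]" else ""))
  print(x$pairs)
  invisible(x)
}

#' Tidy pairwise comparisons of a Tukey-Kramer analysis
#'
#' @param x A [anova_tukey()] result.
#' @param ... Unused.
#' @return The pairwise comparison tibble (`group_a`, `group_b`, `diff_s`,
#'   `q`, `p_adj`, `significant`).
#' @export
tidy.frap_anova <- function(x, ...) x$pairs

#' One-row summary of a Tukey-Kramer analysis
#'
#' @param x A [anova_tukey()] result.
#' @param ... Unused.
#' @return A one-row tibble with `statistic` (F), `p.value`, `df1`, `df2`,
#'   `mse`, `k`, `n`, `degenerate`.
#' @export
glance.frap_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, p.value = x$p_value, df1 = x$df1,
                 df2 = x$df2, mse = x$mse, k = nrow(x$group_stats),
                 n = sum(x$group_stats$n), degenerate = x$degenerate)
}

#' Percent-of-control selectivity profile
#'
#' Expresses each group's mean half-recovery time as a percentage of the
#' control group's mean (the wild-type control without inhibitor), the
#' presentation used to show that an inhibitor displaces only its intended
#' targets. Group means and SEMs are computed after Grubbs outlier
#' elimination; the SEM is scaled by the same factor as the mean (the
#' control mean is treated as a constant, matching the usual error-bar
#' convention; set `propagate_control_error = TRUE` to add the control
#' mean's relative variance in quadrature). Significance versus the control
#' is taken from the Tukey-Kramer comparisons over all groups.
#'
#' @inheritParams anova_tukey
#' @param control_label Label of the control group; must be present with at
#'   least two values.
#' @param propagate_control_error Also propagate the control mean's SEM into
#'   the percentage error bars (default `FALSE`).
#' @return A tibble with one row per group: `group`, `n`, `percent_of_control`,
#'   `sem_percent`, `significant_vs_control`. The control row is exactly 100%
#'   and not significant.
#' @export
selectivity_profile <- function(data, control_label, group = "group",
                                value = "t_half_s", alpha = 0.05,
                                propagate_control_error = FALSE) {
  data <- tibble::as_tibble(data)
  if (!control_label %in% as.character(data[[group]])) {
    rlang::abort(paste0("Control group \"", control_label,
                        "\" not present in the data."),
                 class = "frapkin_error_stats")
  }
  summ <- suppressWarnings(
    summarize_groups(data, group = group, value = value, alpha = alpha)
  )
  ctrl <- summ[summ$group == control_label, ]
  if (ctrl$n_after < 2) {
    rlang::abort("Control group needs at least two retained values.",
                 class = "frapkin_error_stats")
  }
  # significance from Tukey-Kramer on the Grubbs-retained values
  retained <- summ |>
    dplyr::select("group", "removed") |>
    dplyr::left_join(
      dplyr::rename(data, group = dplyr::all_of(group),
                    value = dplyr::all_of(value)),
      by = "group") |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(!.data$value %in% .data$removed[[1]]) |>
    dplyr::ungroup()
  cmp <- anova_tukey(retained, group = "group", value = "value", alpha = alpha)
  vs_ctrl <- cmp$pairs |>
    dplyr::filter(.data$group_a == control_label | .data$group_b == control_label) |>
    dplyr::mutate(other = ifelse(.data$group_a == control_label,
                                 .data$group_b, .data$group_a)) |>
    dplyr::select("other", "significant")

  summ |>
    dplyr::left_join(vs_ctrl, by = c(group = "other")) |>
    dplyr::mutate(
      percent_of_control = ifelse(.data$group == control_label, 100,
                                  .data$mean_s / ctrl$mean_s * 100),
      sem_percent = if (propagate_control_error) {
        .data$percent_of_control *
          sqrt((.data$sem_s / .data$mean_s)^2 + (ctrl$sem_s / ctrl$mean_s)^2)
      } else {
        .data$sem_s / ctrl$mean_s * 100
      },
      significant_vs_control = ifelse(.data$group == control_label, FALSE,
                                      .data$significant)
    ) |>
    dplyr::transmute(.data$group, n = .data$n_after,
                     .data$percent_of_control, .data$sem_percent,
                     .data$significant_vs_control)
}
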