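#' Plot mean normalized recovery per group
#'
#' Averages normalized curves over cells at matched frame indices within each
#' group (cells with unequal frame counts are truncated to the group's
#' shortest cell; no interpolation) and plots the per-time-point group means.
#'
#' @param norm A long normalized-curve tibble (from [normalize_traces()])
#'   with an added `group` column.
#' @param ribbon Draw a +/-1 SEM ribbon around each mean curve.
#' @return A ggplot object.
#' @export
plot_recovery_curves <- function(norm, ribbon = TRUE) {
  stopifnot(all(c("group", "cell_id", "time_post_s", "f_norm") %in% names(norm)))
  post <- norm |>
    dplyr::filter(.data$time_post_s >= 0) |>
    dplyr::group_by(.data$group, .data$cell_id) |>
    dplyr::arrange(.data$time_post_s, .by_group = TRUE) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup()
  max_idx <- post |>
    dplyr::group_by(.data$group, .data$cell_id) |>
    dplyr::summarise(n = max(.data$idx), .groups = "drop_last") |>
    dplyr::summarise(n = min(.data$n), .groups = "drop")
  means <- post |>
    dplyr::inner_join(max_idx, by = "group") |>
    dplyr::filter(.data$idx <= .data$n) |>
    dplyr::group_by(.data$group, .data$idx) |>
    dplyr::summarise(time_post_s = mean(.data$time_post_s),
                     mean_f = mean(.data$f_norm),
                     sem_f = stats::sd(.data$f_norm) /
                       sqrt(dplyr::n()), .groups = "drop")
  p <- ggplot2::ggplot(means,
                       ggplot2::aes(x = .data$time_post_s, y = .data$mean_f,
                                    colour = .data$group, fill = .data$group))
  if (ribbon) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_f - .data$sem_f,
                   ymax = .data$mean_f + .data$sem_f),
      alpha = 0.2, colour = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time after bleach (s)",
                  y = "Relative fluorescence",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of mean half-recovery time per group
#'
#' Bars show the group mean t-half with SEM error bars; groups significantly
#' different from the control (Tukey-Kramer) are marked with an asterisk.
#'
#' @param summary A group-summary tibble from [summarize_groups()].
#' @param comparison Optional [anova_tukey()] result used for the marks.
#' @param control_label Optional control group; marks are drawn for groups
#'   whose pair with the control is significant.
#' @return A ggplot object.
#' @export
plot_thalf_bars <- function(summary, comparison = NULL, control_label = NULL) {
  df <- summary
  df$mark <- ""
  if (!is.null(comparison) && !is.null(control_label)) {
    sig <- comparison$pairs |>
      dplyr::filter(.data$significant,
                    .data$group_a == control_label |
                      .data$group_b == control_label) |>
      dplyr::mutate(other = ifelse(.data$group_a == control_label,
                                   .data$group_b, .data$group_a))
    df$mark <- ifelse(df$group %in% sig$other, "*", "")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_s)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_s - .data$sem_s,
                   ymax = .data$mean_s + .data$sem_s), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean_s + 1.2 * dplyr::coalesce(.data$sem_s, 0),
                   label = .data$mark), size = 6, vjust = 0) +
    ggplot2::labs(x = NULL, y = expression(t[1/2] ~ "(s)")) +
    ggplot2::theme_minimal()
}

#' Bar chart of a percent-of-control selectivity profile
#'
#' @param profile A [selectivity_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_selectivity <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$group,
                               y = .data$percent_of_control,
                               fill = .data$significant_vs_control)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent_of_control - .data$sem_percent,
                   ymax = .data$percent_of_control + .data$sem_percent),
      width = 0.25) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick"),
                               name = "vs. control") +
    ggplot2::labs(x = NULL, y = "% of control t1/2") +
    ggplot2::theme_minimal()
}

#' Plot a fitted recovery curve over its data
#'
#' @param object A [fit_recovery()] result.
#' @param ... Unused.
#' @return A ggplot object showing the post-bleach points, the fitted
#'   double-exponential curve, and the half-recovery point.
#' @export
autoplot.frap_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_post_s, y = .data$f_norm)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "Time after bleach (s)", y = "Relative fluorescence") +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    grid <- tibble::tibble(
      time_post_s = seq(0, max(object$data$time_post_s), length.out = 400))
    grid$f_norm <- recovery_value(object, grid$time_post_s)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
    if (object$A1 + object$A2 > 1e-6) {
      th <- half_recovery_time(object, t_upper_hint = max(object$t2, 1e-3))
      p <- p + ggplot2::annotate("point", x = th,
                                 y = object$y0 + (object$A1 + object$A2) / 2,
                                 shape = 4, size = 3, colour = "firebrick")
    }
  }
  p
}
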