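#' Run the FRAP analysis pipeline from a config
#'
#' Orchestrates the full workflow from a single YAML config (or an equivalent
#' named list): optional seeded simulation of per-group traces, per-cell
#' quantification (normalize, fit, half-recovery, QC), and cohort analysis
#' (Grubbs outlier elimination, group summaries, one-way ANOVA with
#' Tukey-Kramer comparisons, and a percent-of-control selectivity profile
#' when a control is set). Output tables are written as TSV into the output
#' directory together with a run log recording the seed, thresholds, package
#' version and per-stage cell counts (parsed, fit-converged, QC-passed,
#' post-outlier).
#'
#' The config holds `mode` (`simulate`, `quantify`, `analyze` or `all`),
#' `seed`, an optional `out_dir`, the design fields of [read_frap_design()]
#' (`groups`, `control_label`, `thresholds`), and per-group either a `traces`
#' path (quantify/analyze) or a `simulation` block (`target_thalf_s` or
#' explicit kinetics plus any [frap_sim_spec()] field). One master seed
#' drives all groups through independent derived streams, so adding a group
#' leaves other groups' draws unchanged.
#'
#' @param config Path to a YAML config, or a named list with the same
#'   structure.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @param seed Master seed; overrides the config's `seed`.
#' @return Invisibly, a list of run artifacts: `traces`, `cells`, `groups`
#'   (summaries), `comparison`, `selectivity`, `counts`, `design`,
#'   `out_dir`.
#' @seealso [frap_report()]
#' @export
run_frap_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  mode <- cfg$mode %||% "all"
  if (!mode %in% c("simulate", "quantify", "analyze", "all")) {
    rlang::abort(paste0("Unknown mode: ", mode), class = "frapkin_error_config")
  }
  out_dir <- out_dir %||% cfg$out_dir %||%
    rlang::abort("No output directory given.", class = "frapkin_error_config")
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  flush_log <- function() writeLines(log_lines, log_path)

  say("frapkin %s | mode=%s seed=%d out=%s",
      as.character(utils::packageVersion("frapkin")), mode, seed, out_dir)

  th <- cfg$thresholds %||% list()
  thresholds <- qc_thresholds(th$plateau_max %||% 1.1, th$adj_r2_min %||% 0.95)
  alpha <- th$alpha %||% 0.05
  say("thresholds: plateau_max=%g adj_r2_min=%g alpha=%g",
      thresholds$plateau_max, thresholds$adj_r2_min, alpha)

  if (is.null(cfg$groups) || length(cfg$groups) == 0) {
    flush_log()
    rlang::abort("Config must define at least one group.",
                 class = "frapkin_error_config")
  }
  group_labels <- purrr::map_chr(cfg$groups, function(g) {
    g$label %||% rlang::abort("Every group needs a `label`.",
                              class = "frapkin_error_config")
  })
  if (anyDuplicated(group_labels)) {
    flush_log()
    rlang::abort("Duplicate group labels in config.",
                 class = "frapkin_error_config")
  }

  # --- simulate -------------------------------------------------------------
  traces_by_group <- list()
  if (mode %in% c("simulate", "all")) {
    for (i in seq_along(cfg$groups)) {
      g <- cfg$groups[[i]]
      sim <- g$simulation %||% list()
      kin <- if (!is.null(sim$target_thalf_s)) {
        calibrate_kinetics(sim$target_thalf_s,
                           amplitude_split = sim$amplitude_split %||% 0.6,
                           t2_over_t1 = sim$t2_over_t1 %||% 5,
                           plateau = sim$plateau %||% 0.95,
                           y0 = sim$y0 %||% 0.05)
      } else if (!is.null(sim$kinetics)) {
        do.call(frap_kinetics, sim$kinetics)
      } else {
        calibrate_kinetics(6.3)
      }
      spec <- frap_sim_spec(
        n_cells = sim$n_cells %||% 10,
        kinetics = kin,
        n_prebleach = sim$n_prebleach %||% 5,
        frame_interval_s = sim$frame_interval_s %||% 0.25,
        duration_s = sim$duration_s %||% max(20, 8 * half_recovery_time(kin, kin$t2)),
        cell_cv = sim$cell_cv %||% 0.2,
        noise_sd = sim$noise_sd %||% 20,
        acq_bleach_rate = sim$acq_bleach_rate %||% 0.005,
        background_level = sim$background_level %||% 50,
        roi_intensity_scale = sim$roi_intensity_scale %||% 1000,
        total_intensity_scale = sim$total_intensity_scale %||% 1200,
        bleach_fraction_of_total = sim$bleach_fraction_of_total %||% 0.06,
        seed = group_seed(seed, g$label)
      )
      tr <- simulate_traces(spec)
      tr$cell_id <- paste0(g$label, ":", tr$cell_id)
      truth <- attr(tr, "truth")
      truth$cell_id <- paste0(g$label, ":", truth$cell_id)
      traces_by_group[[g$label]] <- tr
      path <- file.path(out_dir, paste0("traces_", sanitize(g$label), ".tsv"))
      write_frap_traces(tr, path)
      readr::write_tsv(truth,
                       file.path(out_dir, paste0("truth_", sanitize(g$label), ".tsv")),
                       progress = FALSE)
      say("simulated group %s: %d cells -> %s", g$label, spec$n_cells, path)
      cfg$groups[[i]]$traces <- path
    }
  }

  if (mode == "simulate") {
    flush_log()
    return(invisible(list(traces = traces_by_group, out_dir = out_dir)))
  }

  # --- quantify -------------------------------------------------------------
  if (length(traces_by_group) == 0) {
    for (g in cfg$groups) {
      if (is.null(g$traces)) {
        flush_log()
        rlang::abort(paste0("Group `", g$label, "` has no trace file for mode ",
                            mode, "."), class = "frapkin_error_config")
      }
      path <- if (file.exists(g$traces)) g$traces else
        file.path(dirname(out_dir), g$traces)
      traces_by_group[[g$label]] <- read_frap_traces(path)
      say("read group %s: %d cells from %s", g$label,
          length(unique(traces_by_group[[g$label]]$cell_id)), g$traces)
    }
  }

  cells <- purrr::imap(traces_by_group, function(tr, label) {
    res <- quantify_cells(tr, thresholds = thresholds)
    res$group <- label
    res
  }) |> purrr::list_rbind()
  n_parsed <- nrow(cells)
  n_converged <- sum(cells$converged)
  n_qc <- sum(cells$qc_pass)
  say("cells: parsed=%d fit-converged=%d QC-passed=%d",
      n_parsed, n_converged, n_qc)
  per_cell <- dplyr::select(cells, "group", "cell_id", "y0", "A1", "t1",
                            "A2", "t2", "plateau", "adj_r2", "converged",
                            "t_half_s", "qc_pass", "qc_reasons")
  readr::write_tsv(per_cell, file.path(out_dir, "cells.tsv"), progress = FALSE)

  if (mode == "quantify") {
    flush_log()
    return(invisible(list(traces = traces_by_group, cells = per_cell,
                          counts = c(parsed = n_parsed,
                                     converged = n_converged, qc = n_qc),
                          out_dir = out_dir)))
  }

  # --- analyze --------------------------------------------------------------
  passed <- dplyr::filter(per_cell, .data$qc_pass, is.finite(.data$t_half_s))
  if (nrow(passed) == 0) {
    say("ERROR: no cells passed QC; nothing to analyze")
    readr::write_tsv(tibble::tibble(group = character(), n_before = integer(),
                                    n_after = integer(), mean_s = double(),
                                    sem_s = double()),
                     file.path(out_dir, "groups.tsv"), progress = FALSE)
    flush_log()
    rlang::abort("No cells passed QC; nothing to analyze.",
                 class = "frapkin_error_empty_run")
  }
  summaries <- withCallingHandlers(
    summarize_groups(passed, group = "group", value = "t_half_s",
                     alpha = alpha),
    frapkin_warning_small_group = function(w) {
      say("WARNING: %s", rlang::cnd_message(w))
      rlang::cnd_muffle(w)
    })
  n_post_outlier <- sum(summaries$n_after)
  say("cells after outlier removal: %d", n_post_outlier)
  readr::write_tsv(
    dplyr::mutate(summaries,
                  removed = purrr::map_chr(.data$removed, paste, collapse = ";")),
    file.path(out_dir, "groups.tsv"), progress = FALSE)

  comparison <- NULL
  selectivity <- NULL
  retained <- summaries |>
    dplyr::select("group", "removed") |>
    dplyr::inner_join(passed, by = "group") |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(!.data$t_half_s %in% .data$removed[[1]]) |>
    dplyr::ungroup() |>
    dplyr::select(-"removed")
  if (nrow(summaries) >= 2 && all(table(retained$group) >= 2)) {
    comparison <- anova_tukey(retained, group = "group", value = "t_half_s",
                              alpha = alpha)
    readr::write_tsv(comparison$pairs, file.path(out_dir, "comparisons.tsv"),
                     progress = FALSE)
    say("ANOVA: F(%d, %d) = %.4g, p = %.4g", comparison$df1, comparison$df2,
        comparison$f, comparison$p_value)
    if (!is.null(cfg$control_label) &&
        cfg$control_label %in% retained$group) {
      selectivity <- selectivity_profile(retained, cfg$control_label,
                                         group = "group", value = "t_half_s",
                                         alpha = alpha)
      readr::write_tsv(selectivity, file.path(out_dir, "selectivity.tsv"),
                       progress = FALSE)
      say("selectivity profile vs %s written", cfg$control_label)
    }
  } else {
    say("comparison skipped: need >= 2 groups with >= 2 retained cells each")
  }

  flush_log()
  invisible(list(
    traces = traces_by_group, cells = per_cell, groups = summaries,
    comparison = comparison, selectivity = selectivity,
    counts = c(parsed = n_parsed, converged = n_converged, qc = n_qc,
               post_outlier = n_post_outlier),
    design = cfg, out_dir = out_dir, thresholds = thresholds, alpha = alpha
  ))
}

sanitize <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

# group-level seed derived from the master seed and the group label, so the
# per-group streams are independent of group order and count
group_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003
  as.integer((as.double(seed) * 131 + h * 7907) %% 2147483647)
}

#' Generate summary plots for a pipeline run
#'
#' Produces the standard presentation of a FRAP comparison: mean normalized
#' recovery curves per group (per-time-point means over QC-passed cells), a
#' bar chart of mean t-half with SEM and significance marks, and the
#' percent-of-control selectivity bar chart when a control was set. Missing
#' optional sections (a single group, no control) are skipped.
#'
#' @param artifacts The list returned by [run_frap_pipeline()].
#' @param out_dir Directory for image files; defaults to the run's output
#'   directory. Plots are written as PDF.
#' @return Invisibly, a named list of ggplot objects (`recovery`, `thalf`,
#'   `selectivity` as applicable).
#' @export
frap_report <- function(artifacts, out_dir = artifacts$out_dir) {
  plots <- list()
  if (is.null(artifacts$cells) || nrow(artifacts$cells) == 0) {
    message("Empty run: no cells to plot.")
    return(invisible(plots))
  }
  passed_ids <- artifacts$cells$cell_id[artifacts$cells$qc_pass]
  groups_of <- stats::setNames(artifacts$cells$group, artifacts$cells$cell_id)
  norm <- purrr::imap(artifacts$traces, function(tr, label) {
    n <- normalize_traces(tr)
    n$group <- label
    n
  }) |> purrr::list_rbind() |>
    dplyr::filter(.data$cell_id %in% passed_ids)
  if (nrow(norm) > 0) {
    plots$recovery <- plot_recovery_curves(norm)
  }
  if (!is.null(artifacts$groups) && nrow(artifacts$groups) > 0) {
    plots$thalf <- plot_thalf_bars(artifacts$groups, artifacts$comparison,
                                   artifacts$design$control_label %||% NULL)
  }
  if (!is.null(artifacts$selectivity)) {
    plots$selectivity <- plot_selectivity(artifacts$selectivity)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(plots)) {
    ggplot2::ggsave(file.path(out_dir, paste0("plot_", nm, ".pdf")),
                    plots[[nm]], width = 7, height = 5)
  }
  invisible(plots)
}
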