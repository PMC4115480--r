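#' Read a FRAP trace table
#'
#' Reads a long-format tab-separated trace table: one row per cell and frame,
#' columns `cell_id`, `frame`, `time_s`, `phase` (`pre`/`post`), `f_roi`,
#' `f_total`, `f_bg`. `f_roi` is the mean intensity of the bleached region,
#' `f_total` of the whole nucleus and `f_bg` of a background region outside
#' the cell. Rows may arrive in any order; they are grouped by `cell_id` and
#' sorted by time within each cell. Each cell is validated: strictly
#' increasing times, at least one prebleach and one post-bleach frame, finite
#' intensities, positive background-subtracted total signal on prebleach
#' frames, no duplicate `(cell_id, time_s)` rows.
#'
#' @param path Path to a TSV trace table.
#' @return A long tibble of validated traces.
#' @seealso [write_frap_traces()]
#' @export
read_frap_traces <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Trace file not found: ", path),
                 class = "frapkin_error_io")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "frame", "time_s", "phase", "f_roi", "f_total", "f_bg")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Trace table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "frapkin_error_schema"
    )
  }
  tbl <- tbl |>
    dplyr::mutate(cell_id = as.character(.data$cell_id),
                  phase = as.character(.data$phase)) |>
    dplyr::arrange(.data$cell_id, .data$time_s) |>
    dplyr::select(dplyr::all_of(required))
  validate_traces(tbl)
  tbl
}

validate_traces <- function(tbl) {
  if (nrow(tbl) == 0) return(invisible(tbl))
  bad_phase <- setdiff(unique(tbl$phase), c("pre", "post"))
  if (length(bad_phase) > 0) {
    rlang::abort(paste0("Unknown phase value(s): ",
                        paste(bad_phase, collapse = ", ")),
                 class = "frapkin_error_schema")
  }
  for (col in c("time_s", "f_roi", "f_total", "f_bg")) {
    if (!all(is.finite(tbl[[col]]))) {
      rlang::abort(paste0("Non-finite values in column `", col, "`."),
                   class = "frapkin_error_schema")
    }
  }
  by_cell <- split(tbl, tbl$cell_id)
  for (cell in by_cell) {
    id <- cell$cell_id[1]
    if (anyDuplicated(cell$time_s)) {
      rlang::abort(paste0("Duplicate (cell_id, time_s) rows for cell `", id,
                          "`; duplicates are an error, never averaged."),
                   class = "frapkin_error_duplicate_time")
    }
    if (is.unsorted(cell$time_s, strictly = TRUE)) {
      rlang::abort(paste0("Time not strictly increasing for cell `", id, "`."),
                   class = "frapkin_error_time_order")
    }
    n_pre <- sum(cell$phase == "pre")
    if (n_pre < 1) {
      rlang::abort(paste0("Cell `", id, "` has no prebleach frames."),
                   class = "frapkin_error_no_prebleach")
    }
    if (n_pre >= nrow(cell)) {
      rlang::abort(paste0("Cell `", id, "` has no post-bleach frames."),
                   class = "frapkin_error_no_postbleach")
    }
    if (any(which(cell$phase == "pre") > n_pre)) {
      rlang::abort(paste0("Prebleach frames of cell `", id,
                          "` must precede all post-bleach frames."),
                   class = "frapkin_error_phase_order")
    }
    pre <- cell[cell$phase == "pre", ]
    if (mean(pre$f_total - pre$f_bg) <= 0) {
      rlang::abort(paste0("Cell `", id,
                          "`: prebleach background-subtracted total signal is not positive."),
                   class = "frapkin_error_signal")
    }
  }
  invisible(tbl)
}

#' Write a FRAP trace table
#'
#' Losslessly serializes traces to the tab-separated long format read by
#' [read_frap_traces()], at full double precision and stable column order.
#' An empty collection yields a header-only file.
#'
#' @param traces A long trace tibble (as from [simulate_traces()] or
#'   [read_frap_traces()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frap_traces <- function(traces, path) {
  cols <- c("cell_id", "frame", "time_s", "phase", "f_roi", "f_total", "f_bg")
  missing <- setdiff(cols, names(traces))
  if (length(missing) > 0) {
    rlang::abort(paste0("Traces are missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "frapkin_error_schema")
  }
  readr::write_tsv(dplyr::select(traces, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' Default quality-control thresholds
#'
#' Fitted cells are excluded as imaging artifacts when the fitted plateau
#' exceeds `plateau_max` or the adjusted R-squared falls below `adj_r2_min`
#' (strict inequalities: boundary values pass). Defaults are plateau 1.1 and
#' adjusted R-squared 0.95.
#'
#' @param plateau_max Maximum admissible fitted plateau (`> 1`).
#' @param adj_r2_min Minimum admissible adjusted R-squared (in `(0, 1)`).
#' @return An object of class `frap_qc_thresholds`.
#' @export
qc_thresholds <- function(plateau_max = 1.1, adj_r2_min = 0.95) {
  if (!is.finite(plateau_max) || plateau_max <= 1) {
    rlang::abort("`plateau_max` must be > 1.", class = "frapkin_error_spec")
  }
  if (!is.finite(adj_r2_min) || adj_r2_min <= 0 || adj_r2_min >= 1) {
    rlang::abort("`adj_r2_min` must lie in (0, 1).", class = "frapkin_error_spec")
  }
  structure(list(plateau_max = plateau_max, adj_r2_min = adj_r2_min),
            class = "frap_qc_thresholds")
}

#' Construct a study design
#'
#' A study design names the treatment groups of a FRAP comparison (construct,
#' genotype, SAHA co-treatment, inhibitor and dose, and where each group's
#' traces live) together with the control group and analysis thresholds.
#' Group sizes below ten cells trigger a warning, since group means are
#' normally computed from at least ten cells.
#'
#' @param groups A tibble (or data frame) with at least a `label` column;
#'   optional columns `construct`, `genotype`, `saha`, `saha_um`, `inhibitor`,
#'   `inhibitor_um`, `traces` (trace file reference) are filled with defaults.
#' @param control_label Label of the control group ("wild-type control
#'   without inhibitor"); must name an existing group.
#' @param plateau_max,adj_r2_min QC thresholds, see [qc_thresholds()].
#' @param alpha Significance level for outlier elimination and group
#'   comparisons.
#' @return An object of class `frap_design`.
#' @export
frap_design <- function(groups, control_label,
                        plateau_max = 1.1, adj_r2_min = 0.95, alpha = 0.05) {
  groups <- tibble::as_tibble(groups)
  if (!"label" %in% names(groups) || nrow(groups) == 0) {
    rlang::abort("`groups` must have a `label` column and at least one row.",
                 class = "frapkin_error_design")
  }
  groups$label <- as.character(groups$label)
  if (anyDuplicated(groups$label)) {
    rlang::abort("Duplicate group labels in design.",
                 class = "frapkin_error_design")
  }
  defaults <- list(construct = NA_character_, genotype = "wild-type",
                   saha = FALSE, saha_um = 0, inhibitor = NA_character_,
                   inhibitor_um = 0, traces = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(groups)) groups[[nm]] <- defaults[[nm]]
  }
  if (!control_label %in% groups$label) {
    rlang::abort(paste0("`control_label` \"", control_label,
                        "\" does not name a group in the design."),
                 class = "frapkin_error_design")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must lie in (0, 1).", class = "frapkin_error_design")
  }
  structure(
    list(groups = groups, control_label = control_label,
         thresholds = qc_thresholds(plateau_max, adj_r2_min), alpha = alpha),
    class = "frap_design"
  )
}

#' @export
print.frap_design <- function(x, ...) {
  cat(sprintf("<frap_design> %d group(s), control = \"%s\", alpha = %g\n",
              nrow(x$groups), x$control_label, x$alpha))
  cat(sprintf("  QC: plateau <= %g, adjusted R2 >= %g\n",
              x$thresholds$plateau_max, x$thresholds$adj_r2_min))
  print(x$groups)
  invisible(x)
}

#' Read a study design from a YAML config
#'
#' The config holds `control_label`, an optional `thresholds` block
#' (`plateau_max`, `adj_r2_min`, `alpha`; defaults 1.1 / 0.95 / 0.05) and a
#' `groups` list, each entry with `label` and optional `construct`,
#' `genotype`, `saha`, `saha_um`, `inhibitor`, `inhibitor_um`, `traces`.
#'
#' @param path Path to a YAML design file.
#' @return A [frap_design()] object.
#' @export
read_frap_design <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Design file not found: ", path),
                 class = "frapkin_error_io")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || length(cfg$groups) == 0) {
    rlang::abort("Design config must contain a non-empty `groups` list.",
                 class = "frapkin_error_design")
  }
  if (is.null(cfg$control_label)) {
    rlang::abort("Design config must name a `control_label`.",
                 class = "frapkin_error_design")
  }
  groups <- purrr::map(cfg$groups, function(g) {
    if (is.null(g$label)) {
      rlang::abort("Every design group needs a `label`.",
                   class = "frapkin_error_design")
    }
    tibble::tibble(
      label = as.character(g$label),
      construct = as.character(g$construct %||% NA_character_),
      genotype = as.character(g$genotype %||% "wild-type"),
      saha = isTRUE(g$saha) || (!is.null(g$saha_um) && g$saha_um > 0),
      saha_um = as.numeric(g$saha_um %||% 0),
      inhibitor = as.character(g$inhibitor %||% NA_character_),
      inhibitor_um = as.numeric(g$inhibitor_um %||% 0),
      traces = as.character(g$traces %||% NA_character_)
    )
  }) |> purrr::list_rbind()
  th <- cfg$thresholds %||% list()
  frap_design(groups, control_label = cfg$control_label,
              plateau_max = th$plateau_max %||% 1.1,
              adj_r2_min = th$adj_r2_min %||% 0.95,
              alpha = th$alpha %||% 0.05)
}
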