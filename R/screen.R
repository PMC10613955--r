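#' Screen functional/basis-set combinations against one assignment table
#'
#' Evaluates a grid of method combinations: for each cell (one functional
#' paired with one basis set) the per-group shieldings are regressed on the
#' experimental shifts ([fit_scaling()]), inverted to predicted shifts
#' ([apply_scaling()]), and summarised ([summarize_errors()]). Cells are
#' then ranked by ascending RMSE with a deterministic tie-break: lower
#' RMSE, then higher \eqn{r^2}, then lower maximum absolute deviation, then
#' lexicographic (functional, basis_set) order. Ranking is therefore
#' invariant under the insertion order of the grid.
#'
#' @param grid Long tibble with one row per (method, group): columns
#'   `functional`, `basis_set`, `group_id`, `isotropic_shielding_ppm`
#'   (ensemble- and equivalence-averaged; single-conformer global-minimum
#'   input is the usual screening mode) and optionally `delta_exp_ppm`.
#'   Every cell must cover every group.
#' @param assignments Assignment tibble supplying `delta_exp_ppm` per
#'   `group_id` (may be omitted when the grid carries `delta_exp_ppm`).
#' @param nucleus Nucleus label for the screen (`"1H"` or `"13C"`).
#' @return An object of class `screen_result`: list with `nucleus`,
#'   `cells` (one metrics row per method), `deviations` (per-group
#'   \eqn{|\Delta\delta|}, long), `ranking` (cells ordered best first, with
#'   a `rank` column), and `best_per_functional`.
#' @seealso [screen_from_metrics()] for ranking a table of already-computed
#'   metrics, [best_per_functional()], [select_top_k()]
#' @export
run_screen <- function(grid, assignments = NULL, nucleus = NULL) {
  grid <- as_tibble(grid)
  require_columns(grid, c("functional", "basis_set", "group_id",
                          "isotropic_shielding_ppm"), "grid")
  if (!"delta_exp_ppm" %in% names(grid)) {
    if (is.null(assignments)) {
      abort("format error: supply delta_exp_ppm in the grid or an assignments table")
    }
    require_columns(assignments, c("group_id", "delta_exp_ppm"),
                    "assignments")
    if (is.null(nucleus) && "nucleus" %in% names(assignments)) {
      nucleus <- unique(assignments$nucleus)
    }
    grid <- dplyr::inner_join(
      grid, as_tibble(assignments)[c("group_id", "delta_exp_ppm")],
      by = "group_id"
    )
  }
  if (is.null(nucleus) || length(nucleus) != 1) {
    abort("assignment inconsistency: screen one nucleus type at a time")
  }
  check_nucleus(nucleus)

  cells_groups <- grid |>
    dplyr::summarise(groups = list(sort(unique(.data$group_id))),
                     .by = c("functional", "basis_set"))
  if (!all(purrr::map_lgl(cells_groups$groups,
                          identical, cells_groups$groups[[1]]))) {
    abort("assignment inconsistency: ragged grid, cells do not share one set of group_ids")
  }

  evaluated <- grid |>
    tidyr::nest(cell = -c("functional", "basis_set")) |>
    dplyr::mutate(out = purrr::map(.data$cell, function(d) {
      fit <- fit_scaling(d, nucleus)
      devs <- d |>
        apply_scaling(fit) |>
        abs_deviations()
      list(metrics = summarize_errors(devs, r_squared = fit$r_squared,
                                      nucleus = nucleus),
           devs = devs, fit = glance(fit))
    }))

  cells <- dplyr::bind_cols(
    evaluated[c("functional", "basis_set")],
    purrr::map(evaluated$out, "metrics") |> dplyr::bind_rows()
  )
  deviations <- dplyr::bind_cols(
    evaluated[c("functional", "basis_set")] |>
      dplyr::slice(rep(seq_len(nrow(evaluated)),
                       purrr::map_int(evaluated$out, ~ nrow(.x$devs)))),
    purrr::map(evaluated$out, "devs") |> dplyr::bind_rows()
  )
  fits <- dplyr::bind_cols(
    evaluated[c("functional", "basis_set")],
    purrr::map(evaluated$out, "fit") |> dplyr::bind_rows()
  )

  new_screen_result(nucleus, cells, deviations = deviations, fits = fits)
}

#' Rank a table of already-computed screening metrics
#'
#' Published screening tables report \eqn{r^2} and RMSE per method
#' combination without the underlying shieldings. This ingestion mode
#' applies the same deterministic ranking and best-per-functional logic to
#' such a table, so selections can be reproduced (and audited) from printed
#' metrics alone.
#'
#' @param metrics Tibble with `functional`, `basis_set`, `rmse_ppm` and
#'   optionally `r_squared`, `mae_ppm`, `max_abs_dev_ppm`, `range_ppm`.
#' @param nucleus Nucleus label.
#' @return A `screen_result` (without per-group deviations).
#' @export
screen_from_metrics <- function(metrics, nucleus) {
  metrics <- as_tibble(metrics)
  require_columns(metrics, c("functional", "basis_set", "rmse_ppm"),
                  "metrics")
  check_nucleus(nucleus)
  if (anyDuplicated(metrics[c("functional", "basis_set")])) {
    abort("duplicate group: repeated (functional, basis_set) cell")
  }
  for (col in c("r_squared", "mae_ppm", "max_abs_dev_ppm", "range_ppm")) {
    if (!col %in% names(metrics)) metrics[[col]] <- NA_real_
  }
  if ("range_ppm" %in% names(metrics) && any(is.finite(metrics$range_ppm))) {
    metrics <- metrics |>
      dplyr::mutate(
        mae_pct = 100 * .data$mae_ppm / .data$range_ppm,
        rmse_pct = 100 * .data$rmse_ppm / .data$range_ppm
      )
  }
  metrics$nucleus <- nucleus
  new_screen_result(nucleus, metrics)
}

# internal constructor: attaches ranking and best-per-functional
new_screen_result <- function(nucleus, cells, deviations = NULL,
                              fits = NULL) {
  ranking <- rank_cells(cells)
  structure(
    list(
      nucleus = nucleus,
      cells = cells,
      deviations = deviations,
      fits = fits,
      ranking = ranking,
      best_per_functional = ranking |>
        dplyr::slice_min(.data$rank, n = 1, by = "functional") |>
        dplyr::arrange(.data$functional)
    ),
    class = "screen_result"
  )
}

# internal: deterministic ordering — RMSE asc, r^2 desc, |ddmax| asc,
# then canonical (functional, basis_set); NA metrics sort last within a tier
rank_cells <- function(cells) {
  cells |>
    dplyr::arrange(
      .data$rmse_ppm,
      dplyr::desc(dplyr::coalesce(.data$r_squared, -Inf)),
      dplyr::coalesce(.data$max_abs_dev_ppm, Inf),
      .data$functional,
      .data$basis_set
    ) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Best basis set for each functional
#'
#' @param result A `screen_result`.
#' @return Tibble with one row per functional: the cell minimising RMSE
#'   within that functional (ties broken as in [run_screen()]).
#' @export
best_per_functional <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  result$best_per_functional
}

#' Top-ranked method combinations
#'
#' @param result A `screen_result`.
#' @param k Number of combinations to keep (`k <=` number of cells).
#' @return The first `k` rows of the ranking.
#' @export
select_top_k <- function(result, k) {
  stopifnot(inherits(result, "screen_result"))
  if (k > nrow(result$ranking) || k < 1) {
    abort(paste0("invalid selection: k must be between 1 and ",
                 nrow(result$ranking)))
  }
  head(result$ranking, k)
}

#' Wide screening table (basis rows by functional columns)
#'
#' Reshapes a screen into the layout screening tables are usually printed
#' in: one row per basis set, one column per functional, cell value a
#' chosen metric. Best-per-functional cells are marked with an asterisk in
#' the formatted variant.
#'
#' @param result A `screen_result`.
#' @param metric Metric column to tabulate (default `"rmse_ppm"`).
#' @param mark_best Mark each functional's best cell with `*` (returns
#'   character columns).
#' @return A wide tibble.
#' @export
screen_table <- function(result, metric = "rmse_ppm", mark_best = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  cells <- result$cells
  require_columns(cells, metric, "cells")
  basis_order <- unique(cells$basis_set)
  if (mark_best) {
    best <- result$best_per_functional
    cells <- cells |>
      dplyr::mutate(
        .marked = paste0(
          format(.data[[metric]], digits = 4, trim = TRUE),
          ifelse(paste(.data$functional, .data$basis_set) %in%
                   paste(best$functional, best$basis_set), "*", "")
        )
      )
    metric <- ".marked"
  }
  cells |>
    dplyr::select("functional", "basis_set", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "functional",
                       values_from = dplyr::all_of(metric)) |>
    dplyr::arrange(match(.data$basis_set, basis_order))
}

#' @export
print.screen_result <- function(x, n = 6, ...) {
  cat("<screen_result> ", x$nucleus, "; ",
      nrow(x$cells), " method combination(s)\n", sep = "")
  cat("Top of ranking (RMSE ascending):\n")
  print(head(
    x$ranking[c("rank", "functional", "basis_set", "r_squared", "rmse_ppm")],
    n
  ))
  invisible(x)
}

#' Tidy and summarise a screen
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return `tidy()` returns the ranked per-cell metrics; `glance()` a
#'   one-row summary (nucleus, number of cells, best cell and its RMSE).
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  x$ranking
}

#' @rdname tidy.screen_result
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  best <- x$ranking[1, ]
  tibble(
    nucleus = x$nucleus,
    n_methods = nrow(x$cells),
    n_functionals = dplyr::n_distinct(x$cells$functional),
    n_basis_sets = dplyr::n_distinct(x$cells$basis_set),
    best_functional = best$functional,
    best_basis_set = best$basis_set,
    best_rmse_ppm = best$rmse_ppm
  )
}

#' Heatmap of a screening grid
#'
#' Tile plot of a metric over basis set (rows) and functional (columns);
#' each functional's best cell is outlined.
#'
#' @param object A `screen_result` (or, for the companion method, a
#'   `scaling_fit`).
#' @param metric Metric to fill by (default `"rmse_ppm"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, metric = "rmse_ppm", ...) {
  cells <- object$cells
  best <- object$best_per_functional
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$functional, y = .data$basis_set,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = best, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = metric,
                  title = paste0(object$nucleus,
                                 " method screen (outline = best per functional)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
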