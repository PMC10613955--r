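#' Absolute deviations of predicted from experimental shifts
#'
#' \eqn{|\Delta\delta| = |\delta_{cal} - \delta_{exp}|} per equivalence
#' group. Accepts either one tibble carrying both columns, or separate
#' prediction and experimental tibbles keyed by `group_id`.
#'
#' @param predictions Tibble with `group_id` and `delta_cal_ppm` (and
#'   optionally `delta_exp_ppm`, in which case `experimental` may be
#'   omitted).
#' @param experimental Tibble with `group_id` and `delta_exp_ppm`; must
#'   cover exactly the same groups.
#' @return Tibble with `group_id`, `delta_exp_ppm`, `delta_cal_ppm` and
#'   `abs_dev_ppm`.
#' @export
abs_deviations <- function(predictions, experimental = NULL) {
  predictions <- as_tibble(predictions)
  require_columns(predictions, c("group_id", "delta_cal_ppm"), "predictions")
  if (is.null(experimental)) {
    require_columns(predictions, "delta_exp_ppm", "predictions")
    joined <- predictions
  } else {
    experimental <- as_tibble(experimental)
    require_columns(experimental, c("group_id", "delta_exp_ppm"),
                    "experimental")
    if (!setequal(predictions$group_id, experimental$group_id) ||
        anyDuplicated(predictions$group_id) ||
        anyDuplicated(experimental$group_id)) {
      abort("assignment inconsistency: predictions and experimental must share one set of group_ids")
    }
    joined <- dplyr::inner_join(
      predictions,
      experimental[c("group_id", "delta_exp_ppm")],
      by = "group_id"
    )
  }
  joined |>
    dplyr::mutate(abs_dev_ppm = abs(.data$delta_cal_ppm - .data$delta_exp_ppm)) |>
    dplyr::select(dplyr::any_of(c("group_id", "nucleus")),
                  "delta_exp_ppm", "delta_cal_ppm", "abs_dev_ppm")
}

#' Error statistics of a prediction set
#'
#' Summarises per-group absolute deviations into the standard accuracy
#' metrics: mean absolute error
#' \eqn{MAE = \frac{1}{n}\sum |\Delta\delta|}, root-mean-square error
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum \Delta\delta^2}}, and the maximum
#' absolute deviation. Because 1H and 13C shifts live on very different
#' scales, each ppm metric is also expressed as a percentage of the spread
#' of the experimental shifts considered,
#' `100 * metric / (max(delta_exp) - min(delta_exp))`, which makes
#' accuracies comparable across nuclei.
#'
#' @param deviations Tibble from [abs_deviations()] (needs `abs_dev_ppm`
#'   and `delta_exp_ppm`).
#' @param r_squared Optional coefficient of determination of the underlying
#'   scaling fit, carried through for reporting.
#' @param nucleus Optional nucleus label; taken from a `nucleus` column when
#'   present.
#' @return A one-row tibble (a metrics report): `nucleus`, `n_groups`,
#'   `r_squared`, `mae_ppm`, `rmse_ppm`, `max_abs_dev_ppm`, `range_ppm`,
#'   `mae_pct`, `rmse_pct`. Always `mae_ppm <= rmse_ppm <= max_abs_dev_ppm`.
#' @examples
#' d <- tibble::tibble(group_id = c("C1", "C2"),
#'                     delta_exp_ppm = c(170, 20),
#'                     delta_cal_ppm = c(173, 16))
#' summarize_errors(abs_deviations(d))
#' @export
summarize_errors <- function(deviations, r_squared = NA_real_,
                             nucleus = NULL) {
  deviations <- as_tibble(deviations)
  require_columns(deviations, c("abs_dev_ppm", "delta_exp_ppm"), "deviations")
  if (nrow(deviations) == 0) abort("empty metrics")
  if (is.null(nucleus)) {
    nucleus <- if ("nucleus" %in% names(deviations)) {
      unique(deviations$nucleus)
    } else {
      NA_character_
    }
    if (length(nucleus) != 1) {
      abort("assignment inconsistency: summarise one nucleus type at a time")
    }
  }
  rng <- max(deviations$delta_exp_ppm) - min(deviations$delta_exp_ppm)
  if (rng <= 0) abort("degenerate regression: experimental shifts have zero range")
  tibble(
    nucleus = nucleus,
    n_groups = nrow(deviations),
    r_squared = r_squared,
    mae_ppm = mean(deviations$abs_dev_ppm),
    rmse_ppm = sqrt(mean(deviations$abs_dev_ppm^2)),
    max_abs_dev_ppm = max(deviations$abs_dev_ppm),
    range_ppm = rng,
    mae_pct = 100 * mean(deviations$abs_dev_ppm) / rng,
    rmse_pct = 100 * sqrt(mean(deviations$abs_dev_ppm^2)) / rng
  )
}

#' Per-group deviation averages across a set of methods
#'
#' For each equivalence group, averages its absolute deviation over several
#' method combinations (the per-atom view used to judge whether every
#' nucleus, not just the aggregate, is predicted reliably) and flags groups
#' whose average exceeds a threshold. Default thresholds are 1.50 ppm for
#' 13C and 0.100 ppm for 1H; flagging uses strict inequality.
#'
#' @param deviations Long tibble of per-group deviations with columns
#'   `group_id`, `abs_dev_ppm` and method identifiers (`functional`,
#'   `basis_set`); every method must cover the same groups.
#' @param threshold_ppm Flagging threshold in ppm; default by nucleus
#'   (1.50 for 13C, 0.100 for 1H).
#' @param nucleus Nucleus label used to pick the default threshold when no
#'   `nucleus` column is present.
#' @return Tibble with `group_id`, `n_methods`, `mean_abs_dev_ppm`,
#'   `threshold_ppm`, `flagged`.
#' @export
per_atom_summary <- function(deviations, threshold_ppm = NULL,
                             nucleus = NULL) {
  deviations <- as_tibble(deviations)
  require_columns(deviations, c("group_id", "abs_dev_ppm"), "deviations")
  method_cols <- intersect(c("functional", "basis_set"), names(deviations))
  if (length(method_cols) > 0) {
    per_method <- deviations |>
      dplyr::summarise(groups = list(sort(unique(.data$group_id))),
                       .by = dplyr::all_of(method_cols))
    if (nrow(per_method) > 1 &&
        !all(purrr::map_lgl(per_method$groups,
                            identical, per_method$groups[[1]]))) {
      abort("assignment inconsistency: methods do not share one set of group_ids")
    }
  }
  if (is.null(threshold_ppm)) {
    if (is.null(nucleus) && "nucleus" %in% names(deviations)) {
      nucleus <- unique(deviations$nucleus)
    }
    if (is.null(nucleus) || length(nucleus) != 1) {
      abort("per_atom_summary needs threshold_ppm or an unambiguous nucleus")
    }
    threshold_ppm <- c("13C" = 1.50, "1H" = 0.100)[[check_nucleus(nucleus)]]
  }
  deviations |>
    dplyr::summarise(
      n_methods = dplyr::n(),
      mean_abs_dev_ppm = mean(.data$abs_dev_ppm),
      .by = "group_id"
    ) |>
    dplyr::mutate(
      threshold_ppm = threshold_ppm,
      flagged = .data$mean_abs_dev_ppm > threshold_ppm
    )
}

#' Plot per-group deviation averages
#'
#' Column chart of [per_atom_summary()] output with the flagging threshold
#' as a dashed line; flagged groups are highlighted.
#'
#' @param summary Tibble from [per_atom_summary()].
#' @return A ggplot object.
#' @export
plot_deviation_summary <- function(summary) {
  require_columns(summary, c("group_id", "mean_abs_dev_ppm", "threshold_ppm",
                             "flagged"), "summary")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group_id,
                               y = .data$mean_abs_dev_ppm,
                               fill = .data$flagged)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = summary$threshold_ppm[1],
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL,
                  y = expression("mean |" * Delta * delta * "| (ppm)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
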