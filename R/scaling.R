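#' Fit the linear scaling between computed shieldings and experimental shifts
#'
#' GIAO shieldings carry a systematic, method-dependent error that is to a
#' good approximation linear in the chemical shift. It is removed
#' empirically by ordinary least squares of the computed shielding on the
#' experimental shift,
#' \eqn{\sigma_{cal} = a\,\delta_{exp} + b},
#' fitted separately per nucleus type and per functional/basis-set
#' combination. Predicted shifts are then obtained by inverting the fit
#' with [apply_scaling()]. The slope is near \eqn{-1} in practice (shielding
#' decreases as shift increases); the reported \eqn{r^2} is the coefficient
#' of determination of this regression.
#'
#' @param data Tibble with columns `delta_exp_ppm` and
#'   `isotropic_shielding_ppm` (one row per equivalence group, e.g. from
#'   [boltzmann_shieldings()]); a `nucleus` column, if present and uniform,
#'   tags the fit.
#' @param nucleus Optional nucleus label (`"1H"` or `"13C"`) overriding the
#'   `nucleus` column.
#' @return An object of class `scaling_fit` with elements `nucleus`, `a`
#'   (slope), `b` (intercept, ppm), `r_squared`, `n_points`, `sigma_resid`
#'   (residual standard deviation) and `data` (the points used).
#' @seealso [apply_scaling()], [tidy.scaling_fit()], [glance.scaling_fit()]
#' @examples
#' pts <- tibble::tibble(delta_exp_ppm = c(10, 20, 30),
#'                       isotropic_shielding_ppm = c(190, 180, 170))
#' fit_scaling(pts, "13C")
#' @export
fit_scaling <- function(data, nucleus = NULL) {
  data <- as_tibble(data)
  require_columns(data, c("delta_exp_ppm", "isotropic_shielding_ppm"),
                  "scaling data")
  if (is.null(nucleus)) {
    nucleus <- if ("nucleus" %in% names(data)) unique(data$nucleus) else NA_character_
    if (length(nucleus) != 1) {
      abort("assignment inconsistency: fit one nucleus type at a time")
    }
  }
  if (!is.na(nucleus)) check_nucleus(nucleus)

  n <- nrow(data)
  if (n < 2) abort("underdetermined: at least 2 points are required")
  if (sd(data$delta_exp_ppm) == 0) {
    abort("degenerate regression: delta_exp_ppm has zero variance")
  }

  fit <- lm(isotropic_shielding_ppm ~ delta_exp_ppm, data = data)
  a <- unname(coef(fit)[["delta_exp_ppm"]])
  b <- unname(coef(fit)[["(Intercept)"]])
  if (a == 0) abort("degenerate regression: fitted slope is zero")
  # r^2 of the regression = squared Pearson correlation of the point set
  r2 <- stats::cor(data$delta_exp_ppm, data$isotropic_shielding_ppm)^2

  structure(
    list(nucleus = nucleus, a = a, b = b, r_squared = r2, n_points = n,
         sigma_resid = sqrt(sum(fit$residuals^2) / (n - 2)),
         data = data, lm = fit),
    class = "scaling_fit"
  )
}

#' Convert shieldings to predicted chemical shifts with a fitted scaling
#'
#' Inverts the fitted line: \eqn{\delta_{cal} = (\sigma_{cal} - b)/a}.
#'
#' @param data Tibble with an `isotropic_shielding_ppm` column (rows are
#'   typically equivalence groups), or a bare numeric vector of shieldings.
#' @param fit A `scaling_fit` from [fit_scaling()].
#' @return The tibble with a `delta_cal_ppm` column appended (or a numeric
#'   vector if `data` was numeric).
#' @examples
#' pts <- tibble::tibble(delta_exp_ppm = c(10, 20, 30),
#'                       isotropic_shielding_ppm = c(190, 180, 170))
#' fit <- fit_scaling(pts, "13C")
#' apply_scaling(pts, fit)
#' @export
apply_scaling <- function(data, fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$a == 0) abort("degenerate regression: slope is zero")
  if (is.numeric(data)) {
    return((data - fit$b) / fit$a)
  }
  data <- as_tibble(data)
  require_columns(data, "isotropic_shielding_ppm", "prediction data")
  dplyr::mutate(
    data,
    delta_cal_ppm = (.data$isotropic_shielding_ppm - fit$b) / fit$a
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> ",
      if (!is.na(x$nucleus)) paste0(x$nucleus, "; ") else "",
      "sigma = ", format(x$a, digits = 6), " * delta + ",
      format(x$b, digits = 6), "; r^2 = ", format(x$r_squared, digits = 4),
      "; n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

#' Tidy a scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per coefficient (`slope`, `intercept`);
#'   `glance()` gives a one-row model summary (`nucleus`, `a`, `b`,
#'   `r_squared`, `sigma_resid`, `n_points`).
#' @method tidy scaling_fit
#' @export
tidy.scaling_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$b, x$a),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname tidy.scaling_fit
#' @method glance scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(nucleus = x$nucleus, a = x$a, b = x$b, r_squared = x$r_squared,
         sigma_resid = x$sigma_resid, n_points = x$n_points)
}

#' @rdname autoplot.screen_result
#' @method autoplot scaling_fit
#' @export
autoplot.scaling_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$delta_exp_ppm,
                               y = .data$isotropic_shielding_ppm)) +
    ggplot2::geom_abline(slope = object$a, intercept = object$b,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(delta[exp] ~ "(ppm)"),
      y = expression(sigma[cal] ~ "(ppm)"),
      title = sprintf("sigma = %.4f delta %+.2f   (r² = %.4f, n = %d)",
                      object$a, object$b, object$r_squared, object$n_points)
    ) +
    ggplot2::theme_minimal()
}
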