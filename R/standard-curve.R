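#' Convert a standard-curve slope to PCR efficiency
#'
#' For a regression of Cq on log10 relative concentration, the efficiency is
#' `E = 10^(-1/slope) - 1`: the fraction of template molecules copied per
#' cycle, 1 meaning perfect doubling. A 10-fold dilution series with E = 1
#' has slope `-1/log10(2)` (about -3.32 cycles per log10 unit).
#'
#' @param slope Standard-curve slope, cycles per log10 concentration unit
#'   (negative for any sensible dilution series).
#' @return Efficiency as a fraction. A positive slope yields a value with a
#'   warning: it almost always indicates inverted concentration coding, not
#'   a real super-efficient reaction.
#' @examples
#' efficiency_from_slope(-1 / log10(2)) # exactly 1
#' efficiency_from_slope(-3.59)
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) abort("slope must be nonzero")
  if (any(slope > 0)) {
    warn("positive slope: likely inverted concentration coding")
  }
  10^(-1 / slope) - 1
}

#' Convert PCR efficiency to a standard-curve slope
#'
#' Inverse of [efficiency_from_slope()]: `slope = -1/log10(1 + E)`.
#'
#' @param efficiency Efficiency as a positive fraction.
#' @return Slope in cycles per log10 concentration unit.
#' @examples
#' slope_from_efficiency(1) # -1/log10(2)
#' @export
slope_from_efficiency <- function(efficiency) {
  if (any(efficiency <= 0)) abort("efficiency must be > 0")
  -1 / log10(1 + efficiency)
}

#' Delta-method standard error of the efficiency estimate
#'
#' First-order propagation of the slope's standard error through the
#' slope-to-efficiency transform:
#' `SE(E) = SE(slope) * (1 + E) * ln(10) / slope^2`.
#'
#' @param se_slope Standard error of the fitted slope (cycles).
#' @param slope Fitted slope (cycles per log10 unit), nonzero.
#' @return Standard error of the efficiency, on the fraction scale.
#' @export
efficiency_se <- function(se_slope, slope) {
  if (any(slope == 0)) abort("slope must be nonzero")
  if (any(se_slope < 0, na.rm = TRUE)) abort("se_slope must be >= 0")
  e <- 10^(-1 / slope) - 1
  se_slope * (1 + e) * log(10) / slope^2
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 relative concentration over all
#' individual non-missing replicate reactions (never replicate means, never
#' imputed values). Using individual points gives the residual degrees of
#' freedom `n_points - 2` that the efficiency confidence interval relies on;
#' for balanced complete designs the slope is identical to a fit on
#' per-concentration means.
#'
#' @param data A [cq_table()] or compatible data frame, or a
#'   [simulate_dilution_series()] result.
#' @param target Optional target id to subset to; required when `data`
#'   contains several targets.
#' @param group Optional group level to subset to. When `NULL`, all groups
#'   are pooled.
#' @param quiet Suppress the warning that lists reactions excluded because
#'   their Cq is missing.
#' @return An object of class `curve_fit`: slope, intercept, their standard
#'   errors, `n_points`, `df` (`n_points - 2`), `r_squared`, `residual_sd`,
#'   plus the underlying `lm` fit and the points used. `tidy()` gives the
#'   coefficient table, `glance()` a one-row model summary including the
#'   point efficiency estimate.
#' @examples
#' tab <- cq_table(data.frame(
#'   target = "18S", dilution_step = rep(0:5, each = 2),
#'   replicate = rep(1:2, 6), cq = 15 + 3.4 * rep(0:5, each = 2)
#' ))
#' fit <- fit_standard_curve(tab)
#' glance(fit)
#' @export
fit_standard_curve <- function(data, target = NULL, group = NULL,
                               quiet = FALSE) {
  pts <- as_cq_data(data, target = target, group = group)
  miss <- pts[is.na(pts$cq), ]
  if (nrow(miss) > 0 && !quiet) {
    warn(sprintf(
      "excluding %d reaction(s) with missing Cq from the fit: %s",
      nrow(miss),
      paste(sprintf("(%s,%s,step %d,rep %d)", miss$target, miss$group,
                    miss$dilution_step, miss$replicate), collapse = " ")
    ))
  }
  pts <- pts[!is.na(pts$cq), ]
  n_conc <- dplyr::n_distinct(pts$log10_rel_conc)
  if (n_conc < 2) {
    abort("insufficient data: need >= 2 distinct concentrations with non-missing Cq")
  }
  if (var(pts$log10_rel_conc) == 0) {
    abort("degenerate design: zero variance in log10_rel_conc")
  }

  model <- lm(cq ~ log10_rel_conc, data = pts)
  # zero-residual fixtures are legitimate here; silence summary.lm's
  # "essentially perfect fit" warning
  sm <- suppressWarnings(summary(model))
  slope <- unname(coef(model)[["log10_rel_conc"]])
  n <- nrow(pts)
  se_slope <- if (n >= 3) sm$coefficients["log10_rel_conc", "Std. Error"] else NA_real_
  if (slope >= 0) {
    warn("fitted slope is non-negative: likely inverted concentration coding")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(model)[["(Intercept)"]]),
      se_slope = unname(se_slope),
      se_intercept = if (n >= 3) sm$coefficients["(Intercept)", "Std. Error"] else NA_real_,
      n_points = n,
      df = n - 2L,
      r_squared = sm$r.squared,
      residual_sd = sm$sigma,
      positive_slope = slope >= 0,
      target = target %||% paste(unique(pts$target), collapse = "+"),
      group = group %||% paste(unique(pts$group), collapse = "+"),
      n_excluded = nrow(miss),
      model = model,
      points = pts
    ),
    class = "curve_fit"
  )
}

#' Efficiency estimate with confidence interval from a fitted curve
#'
#' Converts the fitted slope to efficiency, propagates the slope's standard
#' error by the delta method ([efficiency_se()]), and forms a t interval
#' with `n_points - 2` degrees of freedom:
#' `E +/- t(level, df) * SE(E)`.
#'
#' The interval width is also expressed in efficiency percentage points
#' (`ci_width_pct = 100 * (ci_high - ci_low)`); the half-width is reported
#' alongside since both conventions circulate for quoting standard-curve
#' imprecision.
#'
#' @param fit A `curve_fit` from [fit_standard_curve()].
#' @param level Confidence level, in (0, 1).
#' @return An object of class `efficiency_estimate` (use `tidy()` for a
#'   one-row tibble): `efficiency`, `se_efficiency`, `ci_low`, `ci_high`,
#'   `ci_width_pct`, `ci_half_width_pct`, `df`, `level`.
#' @export
efficiency_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "curve_fit"), level > 0, level < 1)
  if (fit$df <= 0) abort("insufficient data: need n_points >= 3 for a confidence interval")
  e <- efficiency_from_slope(fit$slope)
  se_e <- efficiency_se(fit$se_slope, fit$slope)
  tq <- qt(1 - (1 - level) / 2, df = fit$df)
  lo <- e - tq * se_e
  hi <- e + tq * se_e
  structure(
    list(
      efficiency = e,
      se_efficiency = se_e,
      ci_low = lo,
      ci_high = hi,
      ci_width_pct = 100 * (hi - lo),
      ci_half_width_pct = 100 * tq * se_e,
      df = fit$df,
      level = level,
      slope = fit$slope,
      se_slope = fit$se_slope,
      target = fit$target,
      group = fit$group
    ),
    class = "efficiency_estimate"
  )
}

# Coerce supported inputs to a plain tibble of reactions, optionally
# subset by target/group.
as_cq_data <- function(data, target = NULL, group = NULL) {
  if (inherits(data, "simulated_series")) data <- data$table
  stopifnot(is.data.frame(data))
  pts <- tibble::as_tibble(data)
  if (!"group" %in% names(pts)) pts$group <- ""
  if (!is.null(target)) pts <- pts[pts$target == target, ]
  if (!is.null(group)) pts <- pts[pts$group == group, ]
  if (nrow(pts) == 0) abort("no reactions left after target/group subsetting")
  pts
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("Standard curve: %s%s, %d points (%d excluded as missing)\n",
              x$target,
              if (nzchar(x$group)) paste0(" / ", x$group) else "",
              x$n_points, x$n_excluded))
  cat(sprintf("  slope %.2f (SE %.3g), intercept %.2f, R^2 %.4f, residual SD %.2f\n",
              x$slope, x$se_slope, x$intercept, x$r_squared, x$residual_sd))
  cat(sprintf("  efficiency %.3f\n", efficiency_from_slope(x$slope)))
  invisible(x)
}

#' @export
tidy.curve_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "log10_rel_conc"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, se_slope = x$se_slope, intercept = x$intercept,
    r_squared = x$r_squared, residual_sd = x$residual_sd,
    n_points = x$n_points, df = x$df, n_excluded = x$n_excluded,
    efficiency = efficiency_from_slope(x$slope)
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "Efficiency %.2f%% (SE %.2f points), %d%% CI [%.2f%%, %.2f%%], df = %d\n",
    100 * x$efficiency, 100 * x$se_efficiency, round(100 * x$level),
    100 * x$ci_low, 100 * x$ci_high, x$df
  ))
  cat(sprintf("  CI width %.2f points (half-width %.2f)\n",
              x$ci_width_pct, x$ci_half_width_pct))
  invisible(x)
}

#' @export
tidy.efficiency_estimate <- function(x, ...) {
  tibble::tibble(
    target = x$target, group = x$group,
    efficiency = x$efficiency, se_efficiency = x$se_efficiency,
    ci_low = x$ci_low, ci_high = x$ci_high,
    ci_width_pct = x$ci_width_pct, ci_half_width_pct = x$ci_half_width_pct,
    df = x$df, level = x$level, slope = x$slope, se_slope = x$se_slope
  )
}

#' Plot a fitted standard curve
#'
#' Points are the individual replicate reactions used in the fit; the line
#' is the least-squares fit whose slope encodes the efficiency.
#'
#' @param object A `curve_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curve_fit <- function(object, ...) {
  e <- efficiency_from_slope(object$slope)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log10_rel_conc, y = .data$cq)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 relative concentration", y = "Cq",
      title = sprintf("%s: slope %.2f, E = %.1f%%",
                      object$target, object$slope, 100 * e)
    )
}
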