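#' Test efficiency homogeneity across a factor by ANCOVA
#'
#' Fits the separate-slopes analysis of covariance
#' `Cq = delta_i + beta_i * log10(conc) + e` — one intercept and one slope
#' per factor level (instrument, plate, reagent lot, ...) with no global
#' intercept — and tests each term with Type II sums of squares, i.e. by
#' comparing nested models while respecting marginality:
#'
#' * factor (intercepts): common-intercept + slope model vs
#'   per-level-intercepts + common slope;
#' * covariate (log10 concentration): per-level intercepts with vs without
#'   the common slope;
#' * interaction (per-level slopes): common-slope ANCOVA vs the full
#'   separate-slopes model.
#'
#' The interaction is the scientifically relevant test: factor-specific
#' slopes mean factor-specific amplification efficiencies. F statistics use
#' the full-model residual mean square with `n - 2L` degrees of freedom for
#' `L` levels. Missing Cq values are excluded listwise (degrees of freedom
#' adjust; nothing is imputed).
#'
#' @inheritParams fit_standard_curve
#' @param factor_field Name of the column holding the factor (default
#'   `"group"`).
#' @return An object of class `ancova_fit`: `terms` (term, sum of squares,
#'   df, F, p), `sse_full`, `df_residual`, and `per_level` — per-level
#'   slope, standard error, intercept and fit size from independent
#'   per-level regressions (identical to the full-model slopes). `tidy()`
#'   returns the term table, `glance()` a one-row summary.
#' @seealso [per_level_efficiencies()] to turn the per-level slopes into
#'   efficiency estimates with confidence intervals.
#' @export
fit_ancova <- function(data, target = NULL, factor_field = "group",
                       quiet = FALSE) {
  pts <- as_cq_data(data, target = target)
  if (!factor_field %in% names(pts)) {
    abort(sprintf("factor column '%s' not found", factor_field))
  }
  n_miss <- sum(is.na(pts$cq))
  if (n_miss > 0 && !quiet) {
    warn(sprintf("excluding %d reaction(s) with missing Cq from the ANCOVA", n_miss))
  }
  pts <- pts[!is.na(pts$cq), ]
  d <- tibble::tibble(
    cq = pts$cq,
    x = pts$log10_rel_conc,
    g = factor(pts[[factor_field]])
  )
  L <- nlevels(d$g)
  if (L < 2) abort("need >= 2 factor levels for ANCOVA")
  for (lev in levels(d$g)) {
    dl <- d[d$g == lev, ]
    if (nrow(dl) < 3 || dplyr::n_distinct(dl$x) < 2) {
      abort(sprintf(
        "level '%s' needs >= 3 points spanning >= 2 concentrations", lev))
    }
  }

  m_full <- lm(cq ~ 0 + g + g:x, data = d)
  if (anyNA(coef(m_full))) {
    abort(sprintf("rank-deficient design: could not estimate %s",
                  paste(names(coef(m_full))[is.na(coef(m_full))], collapse = ", ")))
  }
  m_cs   <- lm(cq ~ 0 + g + x, data = d)  # common slope
  m_g    <- lm(cq ~ 0 + g, data = d)      # intercepts only
  m_x    <- lm(cq ~ x, data = d)          # single intercept + slope

  sse <- function(m) sum(stats::residuals(m)^2)
  sse_full <- sse(m_full)
  df_res <- nrow(d) - 2L * L
  mse <- sse_full / df_res

  ss <- c(factor      = sse(m_x) - sse(m_cs),
          covariate   = sse(m_g) - sse(m_cs),
          interaction = sse(m_cs) - sse_full)
  df <- c(L - 1L, 1L, L - 1L)
  f  <- (ss / df) / mse
  terms <- tibble::tibble(
    term = c(factor_field, "log10_rel_conc",
             paste0(factor_field, ":log10_rel_conc")),
    role = c("factor", "covariate", "interaction"),
    ss = unname(ss), df = df, f_stat = unname(f),
    p_value = pf(unname(f), df, df_res, lower.tail = FALSE)
  )

  per_level <- purrr::map_dfr(levels(d$g), function(lev) {
    dl <- d[d$g == lev, ]
    fit <- lm(cq ~ x, data = dl)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      level = lev,
      slope = unname(coef(fit)[["x"]]),
      se_slope = unname(sm["x", "Std. Error"]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      n_points = nrow(dl),
      df = nrow(dl) - 2L
    )
  })

  structure(
    list(
      terms = terms,
      sse_full = sse_full,
      df_residual = df_res,
      per_level = per_level,
      factor_field = factor_field,
      target = target %||% paste(unique(pts$target), collapse = "+"),
      n = nrow(d),
      n_excluded = n_miss
    ),
    class = "ancova_fit"
  )
}

#' Per-level efficiency estimates from an ANCOVA fit
#'
#' Converts each level's slope to an efficiency with a delta-method
#' standard error and a t confidence interval using that level's own
#' residual error and degrees of freedom — the error bars of an
#' instrument-comparison plot.
#'
#' @param result An `ancova_fit`.
#' @param level_conf Confidence level.
#' @return A tibble with one row per factor level: `efficiency`,
#'   `se_efficiency`, `ci_low`, `ci_high`, `ci_width_pct`, `df`.
#' @export
per_level_efficiencies <- function(result, level_conf = 0.95) {
  stopifnot(inherits(result, "ancova_fit"))
  result$per_level |>
    dplyr::rowwise() |>
    dplyr::mutate(
      efficiency = 10^(-1 / .data$slope) - 1,
      se_efficiency = efficiency_se(.data$se_slope, .data$slope),
      t_crit = qt(1 - (1 - level_conf) / 2, df = .data$df),
      ci_low = .data$efficiency - .data$t_crit * .data$se_efficiency,
      ci_high = .data$efficiency + .data$t_crit * .data$se_efficiency,
      ci_width_pct = 100 * (.data$ci_high - .data$ci_low),
      level_conf = level_conf
    ) |>
    dplyr::ungroup() |>
    dplyr::select("level", "slope", "se_slope", "efficiency",
                  "se_efficiency", "ci_low", "ci_high", "ci_width_pct",
                  "df", "level_conf")
}

format_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA of Cq on log10 concentration by %s (%s): %d reactions, %d excluded\n",
              x$factor_field, x$target, x$n, x$n_excluded))
  tab <- x$terms
  cat(sprintf("  %-28s %10s %4s %10s %10s\n", "term", "SS", "df", "F", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s %10.3f %4d %10.2f %10s\n", tab$term[i], tab$ss[i],
                tab$df[i], tab$f_stat[i], format_p(tab$p_value[i])))
  }
  cat(sprintf("  residual SSE %.3f on %d df\n", x$sse_full, x$df_residual))
  invisible(x)
}

#' @export
tidy.ancova_fit <- function(x, ...) {
  tibble::tibble(
    term = x$terms$term, sumsq = x$terms$ss, df = x$terms$df,
    statistic = x$terms$f_stat, p.value = x$terms$p_value
  )
}

#' @export
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse_full, df.residual = x$df_residual, nobs = x$n,
    n_levels = nrow(x$per_level),
    p_interaction = x$terms$p_value[x$terms$role == "interaction"]
  )
}

#' Plot per-level efficiencies from an ANCOVA fit
#'
#' Bar-and-error-bar view of the efficiency estimated for each factor
#' level; non-overlapping intervals across levels echo a significant
#' slope-by-factor interaction.
#'
#' @param object An `ancova_fit`.
#' @param level_conf Confidence level of the error bars.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ancova_fit <- function(object, level_conf = 0.95, ...) {
  eff <- per_level_efficiencies(object, level_conf = level_conf)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$level, y = .data$efficiency)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::labs(
      x = object$factor_field, y = "PCR efficiency",
      title = sprintf("Efficiency by %s (interaction p %s)",
                      object$factor_field,
                      format_p(object$terms$p_value[3]))
    )
}
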