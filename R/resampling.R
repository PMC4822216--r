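#' Monte Carlo subsampling of technical replicates
#'
#' Quantifies how the precision of the standard-curve efficiency estimate
#' depends on the number of technical replicates: at each concentration,
#' `k` of the available non-missing replicates are drawn without
#' replacement (independently across concentrations), a standard curve is
#' fitted to the pooled draw, and the efficiency recorded. Repeating this
#' `n_resamples` times yields an empirical distribution of the efficiency
#' an experimenter running only `k` replicates could have obtained.
#'
#' Duplicate subsets across resamples are allowed (simple Monte Carlo); use
#' [enumerate_all_subsets()] for the exact, exhaustive version. Concentrations
#' with fewer than `k` non-missing replicates contribute all they have, so
#' designs with dropout are handled without imputation.
#'
#' @inheritParams fit_standard_curve
#' @param k Replicates to draw per concentration.
#' @param n_resamples Number of Monte Carlo draws.
#' @param seed Master seed; per-resample substreams are derived from it
#'   deterministically, so results are reproducible.
#' @return A tibble of class `efficiency_distribution` with one row per
#'   resample: `resample`, `efficiency`, `slope`, `n_points`, and a `draw`
#'   list-column recording, per concentration, which replicate rows were
#'   used (every efficiency is reproducible from its draw). Attributes:
#'   `k`, `seed`, `exhaustive = FALSE`.
#' @examples
#' tab <- cq_table(data.frame(
#'   target = "18S", dilution_step = rep(0:5, each = 4),
#'   replicate = rep(1:4, 6),
#'   cq = 15 + 3.4 * rep(0:5, each = 4) + rnorm(24, sd = 0.2)
#' ))
#' d <- subsample_efficiencies(tab, k = 2, n_resamples = 200, seed = 1)
#' summarize_distribution(d)
#' @export
subsample_efficiencies <- function(data, target = NULL, group = NULL, k,
                                   n_resamples = 1000, seed = 1) {
  stopifnot(k >= 1, n_resamples >= 1)
  des <- subsample_design(data, target, group)
  k_max <- max(des$m)
  if (k > k_max) {
    warn(sprintf("k = %d exceeds the %d available replicates; capped", k, k_max))
    k <- k_max
  }
  k_c <- pmin(k, des$m)
  C <- length(des$x)

  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, n_resamples)
  draws <- vector("list", n_resamples)
  sums <- matrix(0, n_resamples, C)
  for (i in seq_len(n_resamples)) {
    set.seed(substreams[i])
    idx <- lapply(seq_len(C), function(c) sort(sample.int(des$m[c], k_c[c])))
    draws[[i]] <- setNames(idx, names(des$y))
    sums[i, ] <- vapply(seq_len(C), function(c) sum(des$y[[c]][idx[[c]]]),
                        numeric(1))
  }
  slopes <- slopes_from_sums(sums, des$x, k_c)
  new_efficiency_distribution(
    tibble::tibble(
      resample = seq_len(n_resamples),
      efficiency = 10^(-1 / slopes) - 1,
      slope = slopes,
      n_points = sum(k_c),
      draw = draws
    ),
    k = k, seed = seed, exhaustive = FALSE, design = des
  )
}

#' Exhaustively enumerate all replicate subsets
#'
#' Exact counterpart of [subsample_efficiencies()]: fits a standard curve to
#' every distinct combination of per-concentration `k`-subsets of the
#' non-missing replicates. For a 6-concentration, 4-replicate design this is
#' `choose(4,k)^6` fits (4096 for k = 1 or 3, 46656 for k = 2); the slope of
#' each fit is computed in closed form, vectorized over combinations.
#'
#' @inheritParams subsample_efficiencies
#' @param cap Refuse (with the count reported) when the number of
#'   combinations exceeds this.
#' @return An `efficiency_distribution` with one row per combination and
#'   attribute `exhaustive = TRUE`; the `draw` column again records the
#'   replicate rows behind each efficiency.
#' @export
enumerate_all_subsets <- function(data, target = NULL, group = NULL, k,
                                  cap = 1e6) {
  stopifnot(k >= 1)
  des <- subsample_design(data, target, group)
  k_c <- pmin(k, des$m)
  n_comb <- prod(choose(des$m, k_c))
  if (n_comb > cap) {
    abort(sprintf("exhaustive enumeration needs %.0f combinations (cap %.0f)",
                  n_comb, cap))
  }
  C <- length(des$x)
  subsets <- lapply(seq_len(C), function(c) {
    m <- combn(des$m[c], k_c[c])
    list(idx = m, sums = colSums(matrix(des$y[[c]][m], nrow = k_c[c])))
  })
  grid <- as.matrix(expand.grid(lapply(subsets, function(s) seq_along(s$sums)),
                                KEEP.OUT.ATTRS = FALSE))
  sums <- vapply(seq_len(C), function(c) subsets[[c]]$sums[grid[, c]],
                 numeric(nrow(grid)))
  if (nrow(grid) == 1) sums <- matrix(sums, nrow = 1)
  slopes <- slopes_from_sums(sums, des$x, k_c)
  draws <- lapply(seq_len(nrow(grid)), function(i) {
    setNames(lapply(seq_len(C), function(c) subsets[[c]]$idx[, grid[i, c]]),
             names(des$y))
  })
  new_efficiency_distribution(
    tibble::tibble(
      resample = seq_len(nrow(grid)),
      efficiency = 10^(-1 / slopes) - 1,
      slope = slopes,
      n_points = sum(k_c),
      draw = draws
    ),
    k = k, seed = NA_integer_, exhaustive = TRUE, design = des
  )
}

#' Summarise an efficiency distribution
#'
#' Mean, sample standard deviation (n - 1 denominator) and a percentile
#' interval (linear interpolation between order statistics, quantile type 7)
#' of the resampled or enumerated efficiencies. The min-max range is
#' reported alongside the percentile interval.
#'
#' @param dist An `efficiency_distribution`.
#' @param level Coverage of the percentile interval.
#' @return A one-row tibble: `mean_e`, `sd_e`, `ci_low`, `ci_high`,
#'   `ci_width_pct` (percentage points), `min_e`, `max_e`, `level`, `k`,
#'   `n_resamples`, `exhaustive`, `degenerate` (TRUE when only one
#'   efficiency value was available, in which case `sd_e` is 0 by
#'   convention).
#' @export
summarize_distribution <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "efficiency_distribution"), level > 0, level < 1)
  e <- dist$efficiency
  if (length(e) == 0) abort("empty efficiency distribution")
  degenerate <- length(e) == 1
  qs <- quantile(e, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  tibble::tibble(
    mean_e = mean(e),
    sd_e = if (degenerate) 0 else sd(e),
    ci_low = qs[1],
    ci_high = qs[2],
    ci_width_pct = 100 * (qs[2] - qs[1]),
    min_e = min(e),
    max_e = max(e),
    level = level,
    k = attr(dist, "k"),
    n_resamples = nrow(dist),
    exhaustive = attr(dist, "exhaustive"),
    degenerate = degenerate,
    quantile_type = 7L
  )
}

# Per-concentration design extracted once: x values, non-missing Cq vectors
# (named by concentration), available replicate counts, and the original row
# ids so draws can be audited.
subsample_design <- function(data, target = NULL, group = NULL) {
  pts <- as_cq_data(data, target = target, group = group)
  pts <- pts[order(pts$log10_rel_conc, decreasing = TRUE), ]
  by_conc <- split(pts, factor(pts$log10_rel_conc,
                               levels = unique(pts$log10_rel_conc)))
  y <- lapply(by_conc, function(d) d$cq[!is.na(d$cq)])
  m <- vapply(y, length, integer(1))
  if (any(m == 0)) {
    abort(sprintf("insufficient data: concentration log10 = %s has no non-missing Cq",
                  names(y)[which(m == 0)[1]]))
  }
  if (length(y) < 2) abort("insufficient data: need >= 2 distinct concentrations")
  list(x = as.numeric(names(y)), y = y, m = m)
}

# OLS slope for many subsets of a fixed design: `sums` has one row per
# subset and one column per concentration holding the sum of the chosen Cq
# values; k_c chosen points at concentration x_c.
slopes_from_sums <- function(sums, x, k_c) {
  n <- sum(k_c)
  sx <- sum(k_c * x)
  sxx <- sum(k_c * x^2) - sx^2 / n
  sy <- rowSums(sums)
  sxy <- as.numeric(sums %*% x) - sx * sy / n
  sxy / sxx
}

new_efficiency_distribution <- function(tbl, k, seed, exhaustive, design) {
  structure(
    tbl,
    k = k, seed = seed, exhaustive = exhaustive, design = design,
    class = c("efficiency_distribution", class(tbl))
  )
}

# Refit one entry of an efficiency distribution from its recorded draw;
# used to audit that every resampled efficiency is reproducible.
refit_from_draw <- function(dist, i) {
  des <- attr(dist, "design")
  draw <- dist$draw[[i]]
  y <- unlist(lapply(seq_along(des$y), function(c) des$y[[c]][draw[[c]]]))
  x <- rep(des$x, lengths(draw))
  unname(coef(lm(y ~ x))[["x"]])
}

#' Plot a resampled efficiency distribution
#'
#' Histogram of the efficiencies with the percentile-interval bounds.
#'
#' @param object An `efficiency_distribution`.
#' @param level Coverage of the percentile interval drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.efficiency_distribution <- function(object, level = 0.95, ...) {
  s <- summarize_distribution(object, level = level)
  ggplot2::ggplot(tibble::tibble(efficiency = object$efficiency),
                  ggplot2::aes(x = .data$efficiency)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(s$ci_low, s$ci_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(
      x = "efficiency", y = "count",
      title = sprintf("k = %d replicates: mean E = %.3f, SD = %.3f",
                      s$k, s$mean_e, s$sd_e)
    )
}
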