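#' Configuration for the serial-dilution simulator
#'
#' Bundles the physical truth behind a simulated dilution series. The
#' simulator reproduces the three error mechanisms that degrade real
#' standard curves: multiplicative pipetting error on every transferred
#' volume (compounding down the series — the carry-over that makes serial
#' dilutions risky), Poisson sampling of the molecules in each transferred
#' aliquot, and Poisson sampling of the molecules in each reaction aliquot.
#' A reaction that receives zero template molecules yields no Cq (dropout),
#' which is why small transfer volumes inflate missing data at the diluted
#' end of a series.
#'
#' @param true_efficiency Amplification efficiency generating the data, in
#'   (0, 1].
#' @param stock_copies Expected template copies in one reaction aliquot of
#'   the undiluted stock.
#' @param dilution_factor Nominal fold-dilution per step (default 10).
#' @param n_steps Number of dilution steps below the stock (default 5,
#'   i.e. 6 concentrations).
#' @param transfer_volume_ul Volume carried tube-to-tube when building the
#'   series.
#' @param total_volume_ul Total volume per tube (transfer + diluent);
#'   defaults to `transfer_volume_ul * dilution_factor` so the nominal
#'   dilution factor is honoured.
#' @param reaction_volume_ul Template aliquot pipetted into each reaction.
#' @param pipette_cv Relative SD of each transferred volume. Conventional
#'   air-displacement pipettes hold a few percent at small volumes; 0.02 is
#'   a realistic default.
#' @param cq_noise_sd SD (cycles) of Gaussian measurement noise added to
#'   each Cq, absorbing early-cycle stochasticity and instrument read
#'   noise.
#' @param threshold_copies Amplicon copy number at the fluorescence
#'   threshold. The fluorescence-per-amplicon constant cancels when all
#'   reactions of an assay are read at the same threshold, so a single copy
#'   number suffices.
#' @param n_replicates Technical qPCR replicates per concentration.
#' @param single_stranded If `TRUE` (cDNA), the first cycle synthesises the
#'   complement rather than doubling, shifting Cq by one cycle.
#' @param poisson_sampling If `FALSE`, molecule counts are replaced by
#'   their expectations: the deterministic limit in which (with
#'   `pipette_cv = 0` and `cq_noise_sd = 0`) the simulated Cq values are
#'   exactly linear in log10 concentration.
#' @param target Target id written into the simulated table.
#' @param stock_log10 log10 relative concentration assigned to the stock.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(true_efficiency = 0.95,
                              stock_copies = 1e6,
                              dilution_factor = 10,
                              n_steps = 5,
                              transfer_volume_ul = 50,
                              total_volume_ul = NULL,
                              reaction_volume_ul = 2,
                              pipette_cv = 0.02,
                              cq_noise_sd = 0.15,
                              threshold_copies = 1e10,
                              n_replicates = 4,
                              single_stranded = TRUE,
                              poisson_sampling = TRUE,
                              target = "sim",
                              stock_log10 = 6) {
  total_volume_ul <- total_volume_ul %||% (transfer_volume_ul * dilution_factor)
  cfg <- list(
    true_efficiency = true_efficiency, stock_copies = stock_copies,
    dilution_factor = dilution_factor, n_steps = as.integer(n_steps),
    transfer_volume_ul = transfer_volume_ul, total_volume_ul = total_volume_ul,
    reaction_volume_ul = reaction_volume_ul, pipette_cv = pipette_cv,
    cq_noise_sd = cq_noise_sd, threshold_copies = threshold_copies,
    n_replicates = as.integer(n_replicates),
    single_stranded = isTRUE(single_stranded),
    poisson_sampling = isTRUE(poisson_sampling),
    target = target, stock_log10 = stock_log10
  )
  stopifnot(
    cfg$true_efficiency > 0, cfg$true_efficiency <= 1,
    cfg$stock_copies > 0, cfg$dilution_factor > 1, cfg$n_steps >= 1,
    cfg$transfer_volume_ul > 0, cfg$reaction_volume_ul > 0,
    cfg$pipette_cv >= 0, cfg$cq_noise_sd >= 0, cfg$threshold_copies > 0,
    cfg$n_replicates >= 1
  )
  if (cfg$transfer_volume_ul >= cfg$total_volume_ul) {
    abort("transfer_volume_ul must be smaller than total_volume_ul")
  }
  structure(cfg, class = "simulation_config")
}

# Poisson draws that stay exact for small means and switch to the normal
# approximation where rpois's integer range would overflow.
rpois_big <- function(n, lambda) {
  out <- numeric(n)
  small <- lambda < 1e7
  if (any(small)) out[small] <- rpois(sum(small), lambda[small])
  if (any(!small)) {
    out[!small] <- round(rnorm(sum(!small), lambda[!small], sqrt(lambda[!small])))
  }
  out
}

#' Simulate a serial-dilution qPCR series
#'
#' Builds the dilution series tube by tube, then "runs" the qPCR. At each
#' step the realized transferred volume is `transfer * (1 + eps)` with
#' `eps ~ Normal(0, pipette_cv)`, so the realized dilution factor is
#' `total / (transfer * (1 + eps))` and volume errors compound down the
#' series. The number of molecules actually carried over is Poisson with
#' mean concentration x realized volume, and each reaction receives a
#' Poisson number of template molecules from its tube. A reaction with `m`
#' molecules crosses threshold at
#' `Cq = [single-stranded offset] + log(threshold / m) / log(1 + E)`
#' plus Gaussian noise; a reaction with zero molecules drops out (missing
#' Cq). The table's `log10_rel_conc` is the *nominal* concentration — what
#' the experimenter believes — which is exactly why transfer errors bias
#' the fitted curve.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the whole series is reproducible from it.
#' @param group Group label written into the table (used to tag independent
#'   series).
#' @return An object of class `simulated_series`: `table` (a [cq_table()]
#'   with extra `copies` and `dropout` columns), `truth` (the config),
#'   `per_step_mean_copies` (realized Poisson mean per step) and
#'   `dropout_flags`.
#' @examples
#' s <- simulate_dilution_series(simulation_config(), seed = 1)
#' summarize_series(s)
#' @export
simulate_dilution_series <- function(config, seed, group = "") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  n_steps <- config$n_steps
  diluent <- config$total_volume_ul - config$transfer_volume_ul

  conc <- numeric(n_steps + 1)                      # copies per ul, per tube
  conc[1] <- config$stock_copies / config$reaction_volume_ul
  for (s in seq_len(n_steps)) {
    eps <- rnorm(1, 0, config$pipette_cv)
    v_real <- config$transfer_volume_ul * (1 + eps)
    if (v_real <= 0) v_real <- .Machine$double.eps  # pathological CV guard
    mu_transfer <- conc[s] * v_real
    n_trans <- if (config$poisson_sampling) rpois_big(1, mu_transfer) else mu_transfer
    conc[s + 1] <- n_trans / (v_real + diluent)
  }
  lambda <- conc * config$reaction_volume_ul        # expected copies/reaction

  steps <- rep(0:n_steps, each = config$n_replicates)
  lam_r <- lambda[steps + 1]
  m <- if (config$poisson_sampling) rpois_big(length(lam_r), lam_r) else lam_r
  dropout <- m <= 0
  cq <- rep(NA_real_, length(m))
  off <- if (config$single_stranded) 1 else 0
  cq[!dropout] <- off +
    log(config$threshold_copies / m[!dropout]) / log1p(config$true_efficiency) +
    rnorm(sum(!dropout), 0, config$cq_noise_sd)

  tab <- cq_table(
    tibble::tibble(
      target = config$target,
      group = group,
      dilution_step = steps,
      log10_rel_conc = config$stock_log10 -
        steps * log10(config$dilution_factor),
      replicate = rep(seq_len(config$n_replicates), n_steps + 1),
      cq = cq,
      copies = m,
      dropout = dropout
    )
  )
  structure(
    list(table = tab, truth = config, per_step_mean_copies = lambda,
         dropout_flags = dropout, seed = as.integer(seed)),
    class = "simulated_series"
  )
}

#' Per-step missing-data and replicate-scatter summary
#'
#' The two indicators of sampling error at the diluted end of a series:
#' the percentage of reactions with no Cq and the sample SD of the
#' non-missing replicate Cq values at each dilution step, pooled across
#' groups/series when several are present.
#'
#' @param data A `simulated_series`, [cq_table()] or compatible data frame.
#' @param target Optional target subset.
#' @return A tibble with one row per (target, dilution step): `n_total`,
#'   `n_missing`, `missing_pct`, `replicate_sd` (NA with `sd_flag = TRUE`
#'   when fewer than 2 non-missing values are available).
#' @export
summarize_series <- function(data, target = NULL) {
  pts <- as_cq_data(data, target = target)
  pts |>
    dplyr::group_by(.data$target, .data$dilution_step, .data$log10_rel_conc) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_missing = sum(is.na(.data$cq)),
      missing_pct = 100 * sum(is.na(.data$cq)) / dplyr::n(),
      replicate_sd = if (sum(!is.na(.data$cq)) >= 2) {
        sd(.data$cq[!is.na(.data$cq)])
      } else NA_real_,
      sd_flag = sum(!is.na(.data$cq)) < 2,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$target, .data$dilution_step)
}

#' Compare transfer volumes for building a dilution series
#'
#' Simulates `n_series` independent dilution series at each candidate
#' transfer volume (total volume scaled to hold the dilution factor
#' constant), pools them, and reports the indicators an experimenter would
#' use to choose a volume: missing-data percentage and replicate Cq SD at
#' the most diluted step, the fitted efficiency on the pooled data, and
#' its confidence-interval width.
#'
#' @param base_config A [simulation_config()]; its `transfer_volume_ul` and
#'   `total_volume_ul` are overridden per candidate volume.
#' @param volumes Transfer volumes (ul) to compare.
#' @param n_series Independent dilution series per volume.
#' @param seed Master seed; per-series seeds are derived from it.
#' @param level Confidence level for the efficiency interval.
#' @return A tibble of class `volume_comparison`, one row per volume:
#'   `missing_pct_last`, `missing_se` (binomial Monte Carlo SE, percentage
#'   points), `replicate_sd_last`, `fitted_e`, `ci_width_pct`.
#' @export
compare_transfer_volumes <- function(base_config, volumes = c(2, 5, 10),
                                     n_series = 4, seed = 1, level = 0.95) {
  stopifnot(inherits(base_config, "simulation_config"), length(volumes) >= 1)
  set.seed(as.integer(seed))
  series_seeds <- matrix(sample.int(.Machine$integer.max,
                                    length(volumes) * n_series),
                         nrow = length(volumes))
  out <- purrr::map_dfr(seq_along(volumes), function(vi) {
    v <- volumes[vi]
    cfg <- base_config
    cfg$transfer_volume_ul <- v
    cfg$total_volume_ul <- v * cfg$dilution_factor
    tabs <- purrr::map(seq_len(n_series), function(si) {
      simulate_dilution_series(cfg, seed = series_seeds[vi, si],
                               group = paste0("S", si))$table
    })
    pooled <- dplyr::bind_rows(tabs)
    smry <- summarize_series(pooled)
    last <- smry[smry$dilution_step == max(smry$dilution_step), ]
    fit <- fit_standard_curve(pooled, quiet = TRUE)
    est <- efficiency_ci(fit, level = level)
    p_hat <- last$missing_pct / 100
    tibble::tibble(
      transfer_volume_ul = v,
      n_reactions = nrow(pooled),
      missing_pct_last = last$missing_pct,
      missing_se = 100 * sqrt(p_hat * (1 - p_hat) / last$n_total),
      replicate_sd_last = last$replicate_sd,
      fitted_e = est$efficiency,
      ci_width_pct = est$ci_width_pct
    )
  })
  structure(out, class = c("volume_comparison", class(out)))
}

#' Plot a transfer-volume comparison
#'
#' Missing-data percentage (with Monte Carlo error bars) and replicate Cq
#' SD at the most diluted step, against transfer volume.
#'
#' @param object A `volume_comparison` from [compare_transfer_volumes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.volume_comparison <- function(object, ...) {
  long <- tibble::tibble(
    transfer_volume_ul = rep(object$transfer_volume_ul, 2),
    metric = rep(c("missing data at last step (%)", "replicate Cq SD (cycles)"),
                 each = nrow(object)),
    value = c(object$missing_pct_last, object$replicate_sd_last),
    se = c(object$missing_se, rep(NA_real_, nrow(object)))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$transfer_volume_ul,
                                     y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                          ymax = .data$value + .data$se),
                             na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "transfer volume (ul)", y = NULL,
                  title = "Sampling error vs transfer volume")
}

#' @export
print.simulated_series <- function(x, ...) {
  cat(sprintf(
    "Simulated dilution series: E = %.3f, %d steps x %d replicates, %d dropout(s)\n",
    x$truth$true_efficiency, x$truth$n_steps + 1, x$truth$n_replicates,
    sum(x$dropout_flags)
  ))
  invisible(x)
}
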