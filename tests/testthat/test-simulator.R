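test_that("the deterministic limit gives exactly linear Cq and exact recovery", {
  cfg <- simulation_config(true_efficiency = 1, pipette_cv = 0,
                           cq_noise_sd = 0, poisson_sampling = FALSE,
                           n_replicates = 2)
  sim <- simulate_dilution_series(cfg, seed = 1)
  per_step <- unique(sim$table[c("dilution_step", "cq")])
  expect_equal(nrow(per_step), 6)  # replicates identical
  incr <- diff(per_step$cq[order(per_step$dilution_step)])
  expect_equal(incr, rep(log(10) / log(2), 5), tolerance = 1e-10)
  fit <- fit_standard_curve(sim, quiet = TRUE)
  expect_equal(efficiency_from_slope(fit$slope), 1, tolerance = 1e-10)

  # same limit at imperfect efficiency: slope recovers E exactly
  cfg2 <- simulation_config(true_efficiency = 0.87, pipette_cv = 0,
                            cq_noise_sd = 0, poisson_sampling = FALSE)
  fit2 <- fit_standard_curve(simulate_dilution_series(cfg2, seed = 1),
                             quiet = TRUE)
  expect_equal(efficiency_from_slope(fit2$slope), 0.87, tolerance = 1e-10)
})

test_that("expected copies fall by the dilution factor and dropout follows the Poisson zero class", {
  cfg <- simulation_config(stock_copies = 1e5, n_steps = 5,
                           n_replicates = 16, transfer_volume_ul = 10)
  n_drop <- 0; n_tot <- 0; p_pred <- numeric(0)
  for (s in 1:200) {
    sim <- simulate_dilution_series(cfg, seed = 1000 + s)
    lam <- sim$per_step_mean_copies
    expect_equal(length(lam), 6)
    expect_true(all(diff(log10(lam)) < 0))
    last <- sim$table[sim$table$dilution_step == 5, ]
    n_drop <- n_drop + sum(is.na(last$cq))
    n_tot <- n_tot + nrow(last)
    p_pred <- c(p_pred, exp(-lam[6]))
  }
  # realized last-step mean is ~1 copy/reaction; dropout matches exp(-lambda)
  p_hat <- n_drop / n_tot
  p_exp <- mean(p_pred)
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(p_hat - p_exp), 3 * se)
  expect_gt(p_hat, 0.2)  # in the vicinity of exp(-1) = 0.368
  expect_lt(p_hat, 0.55)
  # zero-copy reactions, and only those, are missing
  expect_true(all(is.na(sim$table$cq) == (sim$table$copies == 0)))
})

test_that("nominal dilution is honoured in expectation across the series", {
  cfg <- simulation_config(stock_copies = 1e6)
  lam <- rowMeans(sapply(1:100, function(s)
    simulate_dilution_series(cfg, seed = 2000 + s)$per_step_mean_copies))
  ratios <- lam[-6] / lam[-1]
  expect_equal(ratios, rep(10, 5), tolerance = 0.1)
})

test_that("replicate Cq scatter grows as copy numbers shrink", {
  cfg <- simulation_config(stock_copies = 1e5, n_replicates = 16,
                           cq_noise_sd = 0.1, transfer_volume_ul = 10)
  sds <- sapply(1:60, function(s) {
    smry <- summarize_series(simulate_dilution_series(cfg, seed = 3000 + s))
    smry$replicate_sd
  })
  avg <- rowMeans(sds, na.rm = TRUE)
  expect_lt(avg[1], avg[5])  # stock vs second-most-diluted
  expect_lt(avg[2], avg[6])
})

test_that("per-step summaries count missing data as simple arithmetic", {
  df <- make_cq_df(n_reps = 16, noise_sd = 0.2, seed = 61)
  df$cq[df$dilution_step == 5][1:5] <- NA
  smry <- summarize_series(cq_table(df))
  expect_equal(smry$missing_pct[smry$dilution_step == 5], 100 * 5 / 16)
  expect_equal(smry$missing_pct[smry$dilution_step == 0], 0)

  same <- make_cq_df(steps = 0:1, n_reps = 4)
  expect_equal(summarize_series(cq_table(same))$replicate_sd, c(0, 0))

  df$cq[df$dilution_step == 5][6:15] <- NA  # single survivor
  smry2 <- summarize_series(cq_table(df))
  expect_true(smry2$sd_flag[smry2$dilution_step == 5])
  expect_true(is.na(smry2$replicate_sd[smry2$dilution_step == 5]))
})

test_that("transfer volume does not matter when its error mechanisms are off", {
  cfg <- simulation_config(pipette_cv = 0, cq_noise_sd = 0,
                           poisson_sampling = FALSE, stock_copies = 1e8)
  vc <- compare_transfer_volumes(cfg, volumes = c(2, 5, 10), n_series = 2,
                                 seed = 4)
  expect_equal(vc$missing_pct_last, rep(0, 3))
  expect_equal(diff(vc$fitted_e), rep(0, 2), tolerance = 1e-12)

  # abundant target: no dropout at any volume even with sampling on
  cfg2 <- simulation_config(stock_copies = 1e9)  # >= 1e4 copies at the last step
  vc2 <- compare_transfer_volumes(cfg2, volumes = c(2, 5, 10), n_series = 2,
                                  seed = 5)
  expect_equal(vc2$missing_pct_last, rep(0, 3))
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(true_efficiency = 1.2))
  expect_error(simulation_config(true_efficiency = 0))
  expect_error(simulation_config(transfer_volume_ul = 60, total_volume_ul = 50),
               "smaller than total")
  cfg <- simulation_config(transfer_volume_ul = 5)
  expect_equal(cfg$total_volume_ul, 50)  # derived to honour the factor
})

test_that("a simulated series is reproducible from its seed", {
  cfg <- simulation_config()
  s1 <- simulate_dilution_series(cfg, seed = 99)
  s2 <- simulate_dilution_series(cfg, seed = 99)
  expect_equal(s1$table$cq, s2$table$cq)
  expect_equal(s1$per_step_mean_copies, s2$per_step_mean_copies)
})
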