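test_that("a noiseless dilution series is fitted exactly", {
  # cq = 30 - 3.3219 * x at x in 6..1, two replicates per concentration
  tab <- make_cq_tab(slope = -3.3219, intercept = 30, n_reps = 2)
  fit <- fit_standard_curve(tab)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-10)
  expect_equal(fit$se_slope, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 12L)
})

test_that("lm-based fit agrees with the closed-form OLS oracle to 1e-10", {
  tab <- make_cq_tab(n_reps = 2, noise_sd = 0.2, seed = 21)
  fit <- fit_standard_curve(tab)
  oracle <- ols_oracle(tab$log10_rel_conc, tab$cq)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$se_slope, oracle$se_slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
})

test_that("slope-efficiency conversions match their closed forms and invert", {
  expect_equal(efficiency_from_slope(-1 / log10(2)), 1, tolerance = 1e-12)
  expect_equal(round(efficiency_from_slope(-3.33), 2), 1.00)
  expect_equal(efficiency_from_slope(-3.59), 0.899, tolerance = 5e-4)
  expect_equal(slope_from_efficiency(1), -1 / log10(2), tolerance = 1e-12)
  expect_equal(round(slope_from_efficiency(0.9966), 3), -3.330)

  slopes <- seq(-5, -2.5, length.out = 41)
  round_trip <- slope_from_efficiency(efficiency_from_slope(slopes))
  expect_lt(max(abs(round_trip - slopes)), 1e-10)
  expect_equal(efficiency_from_slope(slope_from_efficiency(0.87)), 0.87,
               tolerance = 1e-12)

  expect_error(efficiency_from_slope(0), "nonzero")
  expect_error(slope_from_efficiency(0), "> 0")
  expect_warning(efficiency_from_slope(3.3), "inverted")
})

test_that("delta-method SE matches hand arithmetic and a finite-difference check", {
  expect_equal(efficiency_se(0, -3.5), 0)
  expect_equal(efficiency_se(0.05, -3.3219), 0.0209, tolerance = 5e-3)

  # numerical delta method: |dE/dslope| * se_slope
  for (slope in c(-4.2, -3.6, -3.32, -2.9)) {
    h <- 1e-6
    deriv <- (efficiency_from_slope(slope + h) -
                efficiency_from_slope(slope - h)) / (2 * h)
    expect_equal(efficiency_se(0.04, slope), abs(deriv) * 0.04,
                 tolerance = 1e-6)
  }
})

test_that("t-based confidence intervals follow E +/- t(df) * SE(E)", {
  # construct a fit whose delta-method SE(E) is exactly 0.01 at E = 0.95
  slope <- slope_from_efficiency(0.95)
  se_slope <- 0.01 / ((1 + 0.95) * log(10) / slope^2)
  fit <- structure(list(slope = slope, se_slope = se_slope, n_points = 24L,
                        df = 22L, target = "t", group = ""),
                   class = "curve_fit")
  est <- efficiency_ci(fit, level = 0.95)
  tq <- qt(0.975, 22)
  expect_equal(tq, 2.0739, tolerance = 1e-4)
  expect_equal(est$ci_low, 0.95 - tq * 0.01, tolerance = 1e-10)
  expect_equal(est$ci_high, 0.95 + tq * 0.01, tolerance = 1e-10)
  expect_equal(round(est$ci_low, 4), 0.9293)
  expect_equal(round(est$ci_high, 4), 0.9707)
  expect_equal(est$ci_width_pct, 100 * (est$ci_high - est$ci_low))
  expect_true(est$ci_low <= est$efficiency && est$efficiency <= est$ci_high)

  # zero SE collapses the interval onto the point estimate
  fit0 <- fit_standard_curve(make_cq_tab(slope = -3.5, n_reps = 2))
  est0 <- efficiency_ci(fit0)
  expect_equal(est0$ci_width_pct, 0, tolerance = 1e-6)
})

test_that("CI width shrinks as replicates are added, all else fixed", {
  x1 <- rep(6:1, 1)
  sxx1 <- sum((x1 - mean(x1))^2)
  sigma <- 0.2
  widths <- sapply(1:5, function(r) {
    n <- 6 * r
    se_slope <- sigma / sqrt(r * sxx1)
    fit <- structure(list(slope = -3.5, se_slope = se_slope,
                          n_points = n, df = n - 2L, target = "t", group = ""),
                     class = "curve_fit")
    efficiency_ci(fit)$ci_width_pct
  })
  expect_true(all(diff(widths) < 0))
})

test_that("replicate means give the same slope as all points on balanced designs", {
  df <- make_cq_df(n_reps = 4, noise_sd = 0.3, seed = 8)
  fit_all <- fit_standard_curve(cq_table(df))
  means <- aggregate(cq ~ log10_rel_conc, df, mean)
  oracle <- ols_oracle(means$log10_rel_conc, means$cq)
  expect_equal(fit_all$slope, oracle$slope, tolerance = 1e-10)
})

test_that("missing Cq values are excluded with a warning, never imputed", {
  df <- make_cq_df(n_reps = 4, noise_sd = 0.2, seed = 9)
  df$cq[c(3, 17)] <- NA
  expect_warning(fit <- fit_standard_curve(cq_table(df)),
                 "excluding 2 reaction")
  expect_equal(fit$n_points, 22L)
  expect_equal(fit$n_excluded, 2L)
  # same answer as fitting the complete cases directly
  cc <- df[!is.na(df$cq), ]
  oracle <- ols_oracle(cc$log10_rel_conc, cc$cq)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
})

test_that("degenerate designs are refused with informative errors", {
  one_conc <- make_cq_df(steps = 0, n_reps = 4)
  expect_error(fit_standard_curve(cq_table(one_conc)), "2 distinct concentrations")
  two_conc <- make_cq_df(steps = 0:1, n_reps = 2, noise_sd = 0.1, seed = 2)
  two_conc$cq[3:4] <- NA
  expect_warning(
    expect_error(fit_standard_curve(cq_table(two_conc)), "2 distinct concentrations")
  )
  flipped <- make_cq_df(n_reps = 2)
  flipped$cq <- rev(flipped$cq)
  expect_warning(fit_standard_curve(cq_table(flipped)), "inverted")
})
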