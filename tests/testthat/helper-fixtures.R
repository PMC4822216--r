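# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Long-format Cq data on a straight line with optional Gaussian noise.
make_cq_df <- function(slope = -3.4, intercept = 36, steps = 0:5,
                       n_reps = 4, noise_sd = 0, seed = NULL,
                       target = "18S", group = "", stock_log10 = 6) {
  if (!is.null(seed)) set.seed(seed)
  x <- stock_log10 - rep(steps, each = n_reps)
  data.frame(
    target = target, group = group,
    dilution_step = rep(steps, each = n_reps),
    log10_rel_conc = x,
    replicate = rep(seq_len(n_reps), length(steps)),
    cq = intercept + slope * x + rnorm(length(x), sd = noise_sd)
  )
}

make_cq_tab <- function(...) cq_table(make_cq_df(...))

# Closed-form OLS oracle (sum-of-products form), independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       r_squared = 1 - sum(resid^2) / (sum(y^2) - sum(y)^2 / n))
}

# Two-level ANCOVA fixture with distinct slopes per level.
make_two_level_df <- function(slope_a = -3.32, slope_b = -3.60,
                              noise_sd = 0.1, seed = 42, n_reps = 4) {
  rbind(
    make_cq_df(slope = slope_a, intercept = 40, n_reps = n_reps,
               noise_sd = noise_sd, seed = seed, target = "t", group = "A"),
    make_cq_df(slope = slope_b, intercept = 41, n_reps = n_reps,
               noise_sd = noise_sd, seed = seed + 1, target = "t", group = "B")
  )
}
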