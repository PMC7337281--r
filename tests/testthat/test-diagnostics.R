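make_counts_trial <- function(obs_c, n_c, obs_t, n_t) {
  trial_dataset(
    outcome = c(rep(1, obs_c), rep(NA, n_c - obs_c),
                rep(1, obs_t), rep(NA, n_t - obs_t)),
    treatment = rep(c(0, 1), c(n_c, n_t)))
}

test_that("observation proportions and trimming share follow the indicator sums", {
  # the trial report's own arithmetic: 86/97 control vs 56/96 treated
  ar <- attrition_rates(make_counts_trial(86, 97, 56, 96))
  expect_equal(ar$q_control, 86 / 97)
  expect_equal(ar$q_treated, 56 / 96)
  expect_equal(ar$trim_share, (86 / 97 - 56 / 96) / (86 / 97))
  expect_equal(round(ar$trim_share, 2), 0.34)
  expect_identical(ar$trimmed_arm, "control")
  # hand arithmetic: 4/4 control, 2/4 treated
  ar2 <- attrition_rates(make_counts_trial(4, 4, 2, 4))
  expect_equal(ar2$q_control, 1)
  expect_equal(ar2$q_treated, 0.5)
  expect_equal(ar2$trim_share, 0.5)
  # equal rates: share exactly zero
  expect_equal(attrition_rates(make_counts_trial(3, 4, 3, 4))$trim_share, 0)
})

test_that("attrition accounting is permutation-invariant and rejects empty arms", {
  ds <- make_counts_trial(5, 8, 3, 7)
  perm <- with_seed_local(11, sample(ds$n))
  ds_p <- trial_dataset(ds$y[perm], ds$treat[perm])
  expect_identical(attrition_rates(ds)[c("trim_share", "trimmed_arm")],
                   attrition_rates(ds_p)[c("trim_share", "trimmed_arm")])
  all_missing <- trial_dataset(c(1, 2, NA, NA), c(0, 0, 1, 1))
  expect_error(attrition_rates(all_missing),
               class = "rflb_degenerate_attrition_error")
})

test_that("power after attrition matches the linear formula benchmarks", {
  p <- power_after_attrition(75, 100)
  expect_equal(p$theta, 0.14, tolerance = 1e-12)
  expect_equal(round(100 * p$power), 56)
  full <- power_after_attrition(100, 100)
  expect_equal(full$theta, 0.84)
  expect_equal(full$power, 0.80, tolerance = 0.005)
  # normal CDF evaluation at ratio 0.9
  p9 <- power_after_attrition(90, 100)
  expect_equal(p9$theta, 0.56)
  expect_equal(p9$power, pnorm(0.56))
  expect_error(power_after_attrition(101, 100), class = "rflb_argument_error")
})

test_that("power is strictly increasing and theta linear in the ratio", {
  ratios <- seq(10, 100, by = 5)
  pw <- sapply(ratios, function(r) power_after_attrition(r, 100)$power)
  th <- sapply(ratios, function(r) power_after_attrition(r, 100)$theta)
  expect_true(all(diff(pw) > 0))
  expect_equal(diff(th) / diff(ratios / 100), rep(2.8, length(ratios) - 1))
  # the square-root sensitivity variant agrees at the no-attrition point
  expect_equal(power_after_attrition(100, 100, form = "sqrt")$theta, 0.84)
})

test_that("the unadjusted ATE equals the difference in observed arm means", {
  expect_equal(estimate_ate(trial_dataset(c(1, 3, 0, 2),
                                          c(1, 1, 0, 0)))$beta, 1.0)
  ds <- with_seed_local(3, trial_dataset(
    outcome = ifelse(rbinom(100, 1, 0.8) == 1, rnorm(100), NA),
    treatment = rep(c(1, 0), 50)))
  est <- estimate_ate(ds)
  md <- mean(ds$y[ds$treat == 1], na.rm = TRUE) -
        mean(ds$y[ds$treat == 0], na.rm = TRUE)
  expect_equal(est$beta, md, tolerance = 1e-10)
  expect_equal(est$n_used, sum(ds$obs))
})

test_that("adjusted ATE matches the normal-equations solution on a 6-point toy", {
  y <- c(3, 5, 4, 1, 2, 6); tr <- c(1, 1, 1, 0, 0, 0)
  x <- c(0, 1, 1, 0, 1, 0)
  ds <- trial_dataset(y, tr, covariates = data.frame(x = x))
  est <- estimate_ate(ds, adjusted = TRUE)
  # independent oracle: solve X'X b = X'y directly
  M <- cbind(1, tr, x)
  b <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(est$beta, unname(b[2, 1]), tolerance = 1e-12)
  expect_equal(est$covariate_coefficients$estimate, unname(b[3, 1]),
               tolerance = 1e-12)
})

test_that("groups with the published observed means give a -26.22 point effect", {
  ds <- trial_dataset(outcome = c(38.46, 58.46, 64.68, 84.68),
                      treatment = c(1, 1, 0, 0))
  expect_equal(estimate_ate(ds)$beta, -26.22, tolerance = 1e-10)
})

test_that("collinear adjustment sets are rejected with the offending column named", {
  ds <- trial_dataset(rnorm(10), rep(c(1, 0), 5),
                      covariates = data.frame(a = 1:10, b = 2 * (1:10)))
  expect_error(estimate_ate(ds, adjusted = TRUE),
               class = "rflb_collinearity_error", regexp = "b")
})

test_that("balance test is exact under perfect balance and flags perfect prediction", {
  ds <- trial_dataset(rnorm(6), c(1, 1, 1, 0, 0, 0),
                      covariates = data.frame(x = c(1, 2, 3, 1, 2, 3)))
  bt <- balance_test(ds, "full")
  expect_equal(bt$p_value, 1, tolerance = 1e-6)
  expect_equal(bt$coefficients$estimate, 0, tolerance = 1e-10)
  # covariate identical to treatment: perfect prediction, p ~ 0
  ds2 <- trial_dataset(rnorm(8), rep(c(1, 0), each = 4),
                       covariates = data.frame(x = rep(c(1, 0), each = 4)))
  bt2 <- balance_test(ds2, "full")
  expect_true(bt2$perfect_prediction)
  expect_equal(bt2$p_value, 0)
  # constant covariates are dropped with reduced df
  ds3 <- trial_dataset(rnorm(8), rep(c(1, 0), 4),
                       covariates = data.frame(c1 = rep(1, 8), x = rnorm(8)))
  expect_warning(bt3 <- balance_test(ds3, "full"), "constant")
  expect_equal(bt3$df, 1)
})

test_that("balance test holds its nominal size on randomized trials", {
  rej <- 0L
  reps <- 1000L
  for (r in seq_len(reps)) {
    ds <- with_seed_local(7000 + r, {
      n <- 500
      trial_dataset(rnorm(n), sample(rep(0:1, each = n / 2)),
                    covariates = data.frame(a = rnorm(n), b = rnorm(n),
                                            g = factor(sample(c("m", "f"), n,
                                                              TRUE))))
    })
    rej <- rej + (balance_test(ds, "full")$p_value < 0.05)
  }
  band <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej / reps, 0.05 - band)
  expect_lt(rej / reps, 0.05 + band)
})

test_that("adjusted-vs-unadjusted comparison is null under orthogonal covariates", {
  # perfectly balanced binary covariate, unrelated to the outcome
  ds <- trial_dataset(rep(c(1, 2, 3, 4), 4), rep(c(1, 0), each = 8),
                      covariates = data.frame(x = rep(c(0, 1), 8)))
  cmp <- mcar_mar_comparison(ds, config = analysis_config(seed = 5,
                                                          n_bootstrap = 100))
  expect_equal(cmp$difference, 0, tolerance = 1e-10)
})

test_that("the comparison flags attrition driven by an outcome-related covariate", {
  sc_mar <- trial_scenario(
    500, 500, control_mean = 0, outcome_sd = 1, effect = 0.5,
    covariates = list(pre = list(type = "continuous", mean = 0, sd = 1)),
    loadings = c(pre = 0.8),
    attrition = list(mechanism = "MAR", rate_treated = 0.7,
                     rate_control = 0.95, coef_x = c(pre = 2.5),
                     monotone = TRUE, direction = "treated-attrites-more"))
  sc_mcar <- trial_scenario(
    500, 500, control_mean = 0, outcome_sd = 1, effect = 0.5,
    covariates = list(pre = list(type = "continuous", mean = 0, sd = 1)),
    loadings = c(pre = 0.8),
    attrition = list(mechanism = "MCAR", rate_treated = 0.7,
                     rate_control = 0.95))
  flag <- function(sc, r) {
    g <- generate_trial(sc, seed = 400 + r)
    cmp <- mcar_mar_comparison(g$dataset,
                               config = analysis_config(seed = r,
                                                        n_bootstrap = 150))
    abs(cmp$difference) > 2 * cmp$se_difference
  }
  mar_hits <- sum(vapply(1:10, function(r) flag(sc_mar, r), logical(1)))
  mcar_hits <- sum(vapply(1:10, function(r) flag(sc_mcar, r), logical(1)))
  expect_gte(mar_hits, 6)   # majority flagged under MAR attrition
  expect_lte(mcar_hits, 2)  # rarely flagged under MCAR
})

test_that("with no trimming the monotonicity check equals the observed-sample balance test", {
  ds <- with_seed_local(21, trial_dataset(
    outcome = ifelse(rbinom(80, 1, 0.8) == 1, rnorm(80), NA),
    treatment = rep(c(1, 0), 40),
    covariates = data.frame(x = rnorm(80))))
  b <- lee_bounds(ds, trim_share = 0)
  mono <- monotonicity_check(ds, b$trimmed_rows$lower)
  ref <- balance_test(ds, "observed")
  expect_equal(mono$wald_statistic, ref$wald_statistic)
  expect_equal(mono$p_value, ref$p_value)
  # passing the bounds result checks both retained sets
  both <- monotonicity_check(ds, b)
  expect_named(both, c("lower", "upper"))
  expect_equal(both$upper$p_value, ref$p_value)
})
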