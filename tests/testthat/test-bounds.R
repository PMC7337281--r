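test_that("trimmed means match hand arithmetic in both modes", {
  expect_equal(trimmed_mean(c(1, 2, 3, 4), 0.5, "lower"), 3.5)
  expect_equal(trimmed_mean(c(1, 2, 3, 4, 5), 0.3, "upper"),
               (1 + 2 + 3 + 0.5 * 4) / 3.5)
  v <- c(2.5, -1, 7, 0)
  expect_equal(trimmed_mean(v, 0, "lower"), mean(v))
  # integer mode removes whole observations (ceiling)
  expect_equal(trimmed_mean(c(1, 2, 3, 4), 0.5, "lower", "integer"), 3.5)
  expect_equal(trimmed_mean(1:5, 0.3, "upper", "integer"), 2)
  expect_error(trimmed_mean(numeric(0), 0.2), class = "rflb_argument_error")
})

test_that("fractional trimming is permutation-invariant under ties", {
  x <- c(3, 1, 3, 3, 2)
  for (tail in c("lower", "upper"))
    expect_equal(trimmed_mean(x, 0.35, tail),
                 trimmed_mean(rev(sort(x)), 0.35, tail))
})

test_that("fractional trimming agrees with the mass-discretization oracle", {
  for (r in 1:50) {
    x <- with_seed_local(900 + r, rnorm(sample(3:40, 1), sd = 2))
    p <- with_seed_local(1900 + r, runif(1, 0, 0.9))
    for (tail in c("lower", "upper"))
      expect_lt(abs(trimmed_mean(x, p, tail) -
                      trimmed_mean_oracle(x, p, tail)), 1e-3)
  }
})

test_that("worst-case bounds fill missing outcomes with the support extremes", {
  ds <- trial_dataset(c(50, NA, 60, 80), c(1, 1, 0, 0))
  hm <- horowitz_manski_bounds(ds, outcome_support(0, 100))
  expect_equal(hm$lower, -45)
  expect_equal(hm$upper, 5)
  # no missing outcomes: bounds collapse to the mean difference
  full <- trial_dataset(c(5, 7, 1, 3), c(1, 1, 0, 0))
  hm2 <- horowitz_manski_bounds(full, outcome_support(0, 10))
  expect_equal(hm2$lower, hm2$upper)
  expect_equal(hm2$lower, 4)
  # widening the support strictly widens the interval when outcomes are missing
  wide <- horowitz_manski_bounds(ds, outcome_support(-50, 150))
  expect_lt(wide$lower, hm$lower)
  expect_gt(wide$upper, hm$upper)
  expect_error(horowitz_manski_bounds(ds, outcome_support(55, 100)),
               class = "rflb_support_error")
})

test_that("Lee bounds on the hand-computable toy equal [11.5, 13.5]", {
  b <- lee_bounds(toy_lee_trial())
  expect_equal(b$trim_share, 0.5)
  expect_identical(b$trimmed_arm, "control")
  expect_equal(b$lower, 11.5)
  expect_equal(b$upper, 13.5)
  # retained sets: upper bound trims the lower tail of the control outcomes
  expect_setequal(b$trimmed_rows$lower, c("P5", "P6", "P3", "P4"))
  expect_setequal(b$trimmed_rows$upper, c("P5", "P6", "P1", "P2"))
})

test_that("equal attrition collapses the Lee interval to the point estimate", {
  ds <- trial_dataset(c(1, 2, NA, 4, 3, 5, NA, 6),
                      c(0, 0, 0, 0, 1, 1, 1, 1))
  b <- lee_bounds(ds)
  expect_equal(b$trim_share, 0)
  expect_equal(b$lower, b$upper)
  expect_equal(b$lower, b$estimate)
})

test_that("the interval widens weakly as the trim fraction grows", {
  ds <- rand_bounded_trial(77)
  grid <- seq(0, 0.8, by = 0.05)
  res <- t(vapply(grid, function(p) {
    b <- lee_bounds(ds, trim_share = p)
    c(b$lower, b$upper)
  }, numeric(2)))
  expect_true(all(diff(res[, 1]) <= 1e-12))
  expect_true(all(diff(res[, 2]) >= -1e-12))
})

test_that("the Lee interval nests inside the worst-case interval", {
  for (r in 1:20) {
    ds <- rand_bounded_trial(3000 + r)
    hm <- horowitz_manski_bounds(ds, outcome_support(0, 100))
    lee <- lee_bounds(ds)
    expect_gte(lee$lower, hm$lower - 1e-9)
    expect_lte(lee$upper, hm$upper + 1e-9)
  }
})

test_that("trimming bounds target never-attriters and can exceed worst-case bounds at the boundary", {
  # The two procedures bound different estimands (never-attriter vs full
  # population), so when observed outcomes span the whole support and the
  # attrition differential is extreme, the trimming interval can poke
  # outside the worst-case interval: treated fully observed with high
  # outcomes, control half-attrited with low observed outcomes.
  ds <- trial_dataset(c(60, 80, 10, 20, NA, NA), c(1, 1, 0, 0, 0, 0))
  hm <- horowitz_manski_bounds(ds, outcome_support(0, 100))
  lee <- lee_bounds(ds)
  expect_equal(lee$upper, 65)   # trimmed treated mean 80 minus control 15
  expect_equal(hm$upper, 62.5)  # control missing filled with the support min
  expect_gt(lee$upper, hm$upper)
})

test_that("a single cell reproduces the unconditional bounds", {
  ds <- toy_lee_trial()
  cb <- conditional_lee_bounds(ds, rep("all", ds$n))
  b <- lee_bounds(ds)
  expect_equal(cb$lower, b$lower)
  expect_equal(cb$upper, b$upper)
  expect_equal(nrow(cb$cells), 1)
  expect_equal(cb$cells$weight, 1)
})

test_that("exchangeable cells reproduce the unconditional bounds", {
  base <- toy_lee_trial()
  dup <- trial_dataset(rep(base$y, 2), rep(base$treat, 2))
  cells <- rep(c("A", "B"), each = base$n)
  cb <- conditional_lee_bounds(dup, cells)
  b <- lee_bounds(dup)
  expect_equal(cb$lower, b$lower)
  expect_equal(cb$upper, b$upper)
  expect_equal(cb$cells$weight, c(0.5, 0.5))
})

test_that("conditioning on the attrition-bearing group tightens the interval", {
  # attrition confined to females in the treated arm; female control
  # outcomes sit mid-distribution, so unconditional trimming discards male
  # extremes while conditional trimming only touches the (central) female
  # values -- the interval must then fall strictly inside
  y_c_male <- c(10, 20, 80, 90)
  y_c_female <- c(44, 48, 52, 56)
  y_t_male <- c(40, 45, 50, 55)
  y_t_female <- c(30, 70, NA, NA)
  ds <- trial_dataset(
    outcome = c(y_c_male, y_c_female, y_t_male, y_t_female),
    treatment = rep(c(0, 1), each = 8),
    covariates = data.frame(sex = rep(c("m", "m", "m", "m",
                                        "f", "f", "f", "f"), 2)))
  uncond <- lee_bounds(ds)
  cond <- conditional_lee_bounds(ds, as.character(ds$X$sex))
  # direct hand computation: male cell has no attrition differential
  # (point -2.5), female cell trims half of {44,48,52,56}; weights 2/3, 1/3
  expect_equal(cond$lower, (2 / 3) * -2.5 + (1 / 3) * -4)
  expect_equal(cond$upper, (2 / 3) * -2.5 + (1 / 3) * 4)
  expect_gt(cond$lower, uncond$lower)
  expect_lt(cond$upper, uncond$upper)
  expect_true(all(cond$cells$weight > 0))
  expect_equal(sum(cond$cells$weight), 1)
})

test_that("undersized cells are pooled and empty-arm cells are rejected", {
  ds <- toy_lee_trial()
  # a 1-member cell pools into ".other" under a min count of 2
  cells <- c("big", "big", "big", "tiny", "big", "big", "big", "big")
  cb <- conditional_lee_bounds(ds, cells, min_per_arm = 2)
  expect_equal(nrow(cb$cells), 1)
  # without pooling, a cell lacking observed outcomes in an arm is infeasible
  bad <- c("a", "a", "a", "a", "b", "b", "a", "a")  # cell a: only NA treated
  expect_error(conditional_lee_bounds(ds, bad, merge_undersized = FALSE),
               class = "rflb_conditioning_infeasible_error")
  expect_error(conditional_lee_bounds(ds, cells[-1]),
               class = "rflb_argument_error")
})

test_that("bootstrap intervals are deterministic, contain the bounds, and drop bad replicates", {
  ds <- rand_bounded_trial(55, n_per_arm = 60)
  cfg <- analysis_config(seed = 99, n_bootstrap = 120)
  b1 <- bounds_ci(ds, "lee", cfg)
  b2 <- bounds_ci(ds, "lee", cfg)
  expect_identical(b1$ci_outer, b2$ci_outer)
  expect_identical(b1$se_lower, b2$se_lower)
  expect_lte(b1$ci_outer[1], b1$lower)
  expect_gte(b1$ci_outer[2], b1$upper)
  expect_lte(b1$n_dropped, 0.2 * cfg$n_bootstrap)
  # a single replicate is reproducible bit-identically
  one <- analysis_config(seed = 4, n_bootstrap = 1)
  expect_identical(bounds_ci(ds, "lee", one)$ci_outer,
                   bounds_ci(ds, "lee", one)$ci_outer)
})

test_that("without attrition the outer interval approaches the classical CI", {
  sc <- trial_scenario(1000, 1000, control_mean = 0, outcome_sd = 1,
                       effect = 0.3)
  g <- generate_trial(sc, seed = 9)
  b <- bounds_ci(g$dataset, "lee", analysis_config(seed = 9,
                                                   n_bootstrap = 300))
  expect_equal(b$lower, b$upper)  # no attrition: point identification
  fit <- stats::lm(y ~ treat, data = as.data.frame(g$dataset))
  cls <- stats::confint(fit)["treat", ]
  expect_equal(unname(b$ci_outer[1]), unname(cls[1]), tolerance = 0.05)
  expect_equal(unname(b$ci_outer[2]), unname(cls[2]), tolerance = 0.05)
})

test_that("the adjusted interval is narrower than the outer interval but covers the set", {
  ds <- rand_bounded_trial(31, n_per_arm = 60)
  cfg <- analysis_config(seed = 13, n_bootstrap = 150)
  outer <- bounds_ci(ds, "lee", cfg)
  im <- bounds_ci(ds, "lee", cfg, ci_method = "imbens-manski")
  expect_lte(diff(im$ci_outer), diff(outer$ci_outer) + 1e-12)
  expect_lte(im$ci_outer[1], im$lower)
  expect_gte(im$ci_outer[2], im$upper)
})
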