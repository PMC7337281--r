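#' Define a synthetic two-arm trial scenario
#'
#' A scenario fixes the data-generating process for [generate_trial()]:
#' arm sizes, the outcome model (control mean/SD, additive treatment effect,
#' covariate loadings), the covariate distributions, and the attrition
#' mechanism. Attrition follows a logistic index on per-arm base observation
#' rates, standardized covariates, treatment-by-covariate interactions and
#' (for MNAR) the standardized latent control outcome:
#' \deqn{P(S=1 | T=t) = logit^{-1}(logit(r_t) + X'c_x + t \cdot X'c_{tx} + c_y z_{y_0}).}
#' Mechanism labels constrain the coefficients: MCAR forces all of them to
#' zero (attrition may still differ by arm through the base rates), MAR
#' allows covariate and interaction terms, and MNAR additionally allows
#' dependence on the latent outcome.
#'
#' With `monotone = TRUE`, both potential observation indicators are drawn
#' from one uniform per participant and the treated-arm probability is
#' clamped to the enforced direction, so treatment shifts attrition in a
#' single direction for every participant by construction (a coefficient
#' sign condition cannot guarantee this once continuous covariates enter the
#' index).
#'
#' @param n_treated,n_control Arm sizes.
#' @param control_mean,outcome_sd Mean and total SD of the control-arm
#'   outcome (loadings included).
#' @param effect Additive treatment effect `beta_true` in outcome units.
#' @param outcome_sd_treated Optional total SD for the treated arm; when
#'   given, treated outcomes get their own residual draw (mean-preserving
#'   heterogeneous increments, independent of attrition).
#' @param covariates Named list of distribution specs:
#'   `list(type = "continuous", mean =, sd =)` or
#'   `list(type = "categorical", levels =, probs =)`.
#' @param loadings Named numeric: outcome loading per covariate, applied to
#'   the standardized covariate (continuous) or the indicator of a
#'   non-reference level (categorical).
#' @param attrition List: `mechanism` in `{"MCAR","MAR","MNAR"}`,
#'   `rate_treated`, `rate_control` (base observation probabilities in
#'   (0,1]), `coef_x`, `coef_tx` (named numerics), `coef_y` (scalar),
#'   `monotone` flag, optional `direction`
#'   (`"treated-attrites-more"`/`"control-attrites-more"`; inferred from the
#'   base rates when they differ).
#' @param seed Default seed for [generate_trial()].
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(n_treated, n_control,
                           control_mean, outcome_sd, effect,
                           outcome_sd_treated = NULL,
                           covariates = list(), loadings = numeric(0),
                           attrition = list(), seed = 1L) {
  if (!is_count(n_treated) || !is_count(n_control))
    stop_rflb("rflb_scenario_error", "arm sizes must be positive counts")
  if (!is.numeric(outcome_sd) || outcome_sd <= 0)
    stop_rflb("rflb_scenario_error", "outcome_sd must be positive")
  at <- utils::modifyList(
    list(mechanism = "MCAR", rate_treated = 1, rate_control = 1,
         coef_x = numeric(0), coef_tx = numeric(0), coef_y = 0,
         monotone = TRUE, direction = NULL),
    attrition)
  if (!at$mechanism %in% c("MCAR", "MAR", "MNAR"))
    stop_rflb("rflb_scenario_error", "mechanism must be MCAR, MAR or MNAR")
  for (r in c(at$rate_treated, at$rate_control))
    if (!(is.numeric(r) && r > 0 && r <= 1))
      stop_rflb("rflb_scenario_error", "base observation rates must be in (0,1]")
  any_coef <- any(c(at$coef_x, at$coef_tx, at$coef_y) != 0)
  if (at$mechanism == "MCAR" && any_coef)
    stop_rflb("rflb_scenario_error",
              "MCAR requires all attrition coefficients to be zero")
  if (at$mechanism == "MAR" && at$coef_y != 0)
    stop_rflb("rflb_scenario_error",
              "MAR cannot load on the latent outcome (coef_y)")
  bad <- setdiff(c(names(at$coef_x), names(at$coef_tx), names(loadings)),
                 names(covariates))
  if (length(bad))
    stop_rflb("rflb_scenario_error", "coefficients on unknown covariates: %s",
              paste(bad, collapse = ", "))
  structure(
    list(n_treated = as.integer(n_treated), n_control = as.integer(n_control),
         control_mean = control_mean, outcome_sd = outcome_sd,
         effect = effect, outcome_sd_treated = outcome_sd_treated,
         covariates = covariates, loadings = loadings, attrition = at,
         seed = as.integer(seed)),
    class = "trial_scenario")
}

## Standardized covariate scores used by loadings and attrition coefficients.
covariate_scores <- function(scenario, X) {
  vapply(names(scenario$covariates), function(nm) {
    spec <- scenario$covariates[[nm]]
    if (spec$type == "continuous") (X[[nm]] - spec$mean) / spec$sd
    else as.numeric(X[[nm]] != spec$levels[1])
  }, numeric(nrow(X)))
}

loading_variance <- function(scenario) {
  if (!length(scenario$loadings)) return(0)
  sum(vapply(names(scenario$loadings), function(nm) {
    spec <- scenario$covariates[[nm]]
    v <- if (spec$type == "continuous") 1
         else { p <- 1 - spec$probs[1]; p * (1 - p) }
    scenario$loadings[[nm]]^2 * v
  }, numeric(1)))
}

#' Generate a synthetic trial with hidden truth
#'
#' Draws covariates, potential outcomes, a fixed-margin treatment assignment
#' (exact arm sizes) and potential observation indicators `S(T=1)`, `S(T=0)`
#' from the scenario's attrition mechanism. The hidden truth record labels
#' the never-attriters (observed under either assignment) and their average
#' treatment effect -- the estimand the trimming bounds identify.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Seed override (defaults to the scenario seed).
#' @return A list: `dataset` (a [trial_dataset()]) and `truth` (`y0`, `y1`,
#'   `s_treated`, `s_control`, `never_attriter`, `ate_never`, `beta_true`).
#' @export
generate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  seed <- seed %||% scenario$seed
  n <- scenario$n_treated + scenario$n_control
  at <- scenario$attrition
  with_seed(seed, {
    X <- as.data.frame(lapply(scenario$covariates, function(spec) {
      if (spec$type == "continuous") stats::rnorm(n, spec$mean, spec$sd)
      else factor(sample(spec$levels, n, replace = TRUE, prob = spec$probs),
                  levels = spec$levels)
    }))
    z <- if (length(scenario$covariates))
      covariate_scores(scenario, X) else matrix(0, n, 0)
    load_part <- if (length(scenario$loadings))
      drop(z[, names(scenario$loadings), drop = FALSE] %*%
             unname(scenario$loadings)) else rep(0, n)
    resid_var <- scenario$outcome_sd^2 - loading_variance(scenario)
    if (resid_var <= 0)
      stop_rflb("rflb_scenario_error",
                "covariate loadings exceed the stated total outcome SD")
    y0 <- scenario$control_mean + load_part + stats::rnorm(n, 0, sqrt(resid_var))
    if (is.null(scenario$outcome_sd_treated)) {
      y1 <- y0 + scenario$effect
    } else {
      rv_t <- scenario$outcome_sd_treated^2 - loading_variance(scenario)
      if (rv_t <= 0)
        stop_rflb("rflb_scenario_error",
                  "covariate loadings exceed the treated-arm outcome SD")
      y1 <- scenario$control_mean + scenario$effect + load_part +
        stats::rnorm(n, 0, sqrt(rv_t))
    }
    treat <- sample(rep(c(1L, 0L), c(scenario$n_treated, scenario$n_control)))
    idx_sum <- function(coefs) {
      if (!length(coefs)) rep(0, n)
      else drop(z[, names(coefs), drop = FALSE] %*% unname(coefs))
    }
    zy <- (y0 - scenario$control_mean) / scenario$outcome_sd
    lp0 <- stats::qlogis(at$rate_control) + idx_sum(at$coef_x) + at$coef_y * zy
    lp1 <- stats::qlogis(at$rate_treated) + idx_sum(at$coef_x) +
      idx_sum(at$coef_tx) + at$coef_y * zy
    p0 <- stats::plogis(lp0); p1 <- stats::plogis(lp1)
    if (anyNA(p0) || anyNA(p1))
      stop_rflb("rflb_scenario_error",
                "attrition index is numerically infeasible")
    if (isTRUE(at$monotone)) {
      dir <- at$direction %||% {
        if (at$rate_treated < at$rate_control) "treated-attrites-more"
        else if (at$rate_treated > at$rate_control) "control-attrites-more"
        else if (any(c(at$coef_tx, at$coef_y) != 0))
          stop_rflb("rflb_scenario_error",
                    "monotone attrition with equal base rates needs an explicit direction")
        else "treated-attrites-more"
      }
      if (dir == "treated-attrites-more") p1 <- pmin(p1, p0)
      else p1 <- pmax(p1, p0)
    }
    u <- stats::runif(n)
    s1 <- as.integer(u <= p1); s0 <- as.integer(u <= p0)
    s <- ifelse(treat == 1L, s1, s0)
    y_obs <- ifelse(s == 1L, ifelse(treat == 1L, y1, y0), NA_real_)
    never <- s1 == 1L & s0 == 1L
    list(dataset = trial_dataset(outcome = y_obs, treatment = treat,
                                 covariates = if (ncol(X)) X else NULL),
         truth = list(y0 = y0, y1 = y1, s_treated = s1, s_control = s0,
                      never_attriter = never,
                      ate_never = mean((y1 - y0)[never]),
                      beta_true = scenario$effect,
                      p_obs_treated = p1, p_obs_control = p0))
  })
}

#' ZeroPhobia-calibrated trial preset
#'
#' A scenario emulating the acrophobia VR-CBT trial used throughout the
#' package: 96 treated / 97 control participants, observed AQ-Total outcome
#' moments of 48.46 (24.33) treated and 74.68 (21.55) control, and attrition
#' of 40/96 treated versus 11/97 control -- a trimming share of about 0.34.
#' Baseline covariates are gender, age and the AQ pre-score, with the
#' pre-score loaded on the outcome (correlation about 0.5); in this preset
#' attrition depends on assignment only (coefficients zero), mirroring the
#' trial's importance graph where no background characteristic beat the
#' random benchmark.
#'
#' @param equal_rates Use the pooled observation rate in both arms (an MCAR
#'   variant with expected trimming share 0).
#' @param seed Default generation seed.
#' @return A [trial_scenario()].
#' @export
zerophobia_preset <- function(equal_rates = FALSE, seed = 2019L) {
  pooled <- (56 + 86) / 193
  trial_scenario(
    n_treated = 96L, n_control = 97L,
    control_mean = 74.68, outcome_sd = 21.55, effect = -26.22,
    outcome_sd_treated = 24.33,
    covariates = list(
      female = list(type = "categorical", levels = c("male", "female"),
                    probs = c(0.5, 0.5)),
      age = list(type = "continuous", mean = 41.3, sd = 13.0),
      aq_pre = list(type = "continuous", mean = 85.0, sd = 18.0)),
    loadings = c(aq_pre = 10.8),
    attrition = list(
      mechanism = "MCAR",
      rate_treated = if (equal_rates) pooled else 56 / 96,
      rate_control = if (equal_rates) pooled else 86 / 97,
      monotone = TRUE, direction = "treated-attrites-more"),
    seed = seed)
}

#' Selective-attrition preset (interaction-driven missingness)
#'
#' The ZeroPhobia-calibrated trial with attrition re-simulated to be jointly
#' associated with treatment status, gender and the (continuous) pre-score
#' through treatment-interaction terms, while leaving the average treatment
#' effect unaffected (attrition is independent of the treatment-effect
#' increment). This is the setting in which conditioning can tighten Lee
#' bounds and the RFLB screen should select gender and the pre-score.
#'
#' @param n_treated,n_control Arm sizes (trial scale by default).
#' @param seed Default generation seed.
#' @return A [trial_scenario()].
#' @export
selective_attrition_preset <- function(n_treated = 96L, n_control = 97L,
                                       seed = 2020L) {
  base <- zerophobia_preset(seed = seed)
  trial_scenario(
    n_treated = n_treated, n_control = n_control,
    control_mean = base$control_mean, outcome_sd = base$outcome_sd,
    effect = base$effect, outcome_sd_treated = base$outcome_sd_treated,
    covariates = base$covariates, loadings = base$loadings,
    attrition = list(
      mechanism = "MNAR", rate_treated = 0.65, rate_control = 0.90,
      coef_tx = c(female = -1.0, aq_pre = -2.0),
      monotone = TRUE, direction = "treated-attrites-more"),
    seed = seed)
}

#' Monotone outcome-dependent attrition preset
#'
#' A larger trial whose attrition index loads on the latent control outcome
#' (genuine MNAR) as well as on assignment, with monotone selection and a
#' homogeneous additive effect, so the never-attriter average treatment
#' effect equals `beta_true` exactly -- the recovery target for coverage
#' checks of the trimming bounds.
#'
#' @param n_treated,n_control Arm sizes.
#' @param seed Default generation seed.
#' @return A [trial_scenario()].
#' @export
mnar_outcome_preset <- function(n_treated = 1000L, n_control = 1000L,
                                seed = 7L) {
  trial_scenario(
    n_treated = n_treated, n_control = n_control,
    control_mean = 50, outcome_sd = 10, effect = -5,
    covariates = list(
      female = list(type = "categorical", levels = c("male", "female"),
                    probs = c(0.5, 0.5)),
      pre = list(type = "continuous", mean = 50, sd = 10)),
    loadings = c(pre = 5),
    attrition = list(
      mechanism = "MNAR", rate_treated = 0.65, rate_control = 0.9,
      coef_y = 0.8, monotone = TRUE, direction = "treated-attrites-more"),
    seed = seed)
}

#' Rescale a scenario to a standardized effect size
#'
#' Sets `beta_true = d * SD(control outcome)`, leaving everything else
#' unchanged -- the harness for small/medium/large effect-size experiments
#' (d = 0.2, 0.4, 0.8).
#'
#' @param scenario A [trial_scenario()].
#' @param d Standardized effect size (Cohen's d; sign preserved).
#' @return The modified [trial_scenario()].
#' @export
scale_effect <- function(scenario, d) {
  stopifnot(inherits(scenario, "trial_scenario"), is.numeric(d))
  scenario$effect <- d * scenario$outcome_sd
  scenario$effect_size_d <- d
  scenario
}

#' Run a replicated bounding simulation study
#'
#' Generates `n_reps` independent trials from a scenario (sub-seeded from
#' the configuration seed) and computes the requested bound estimators on
#' each, recording per-replication bounds, widths, optional bootstrap CIs,
#' and whether the interval covers that replication's true never-attriter
#' average treatment effect. Aggregates mirror the usual bounding-results
#' table: mean lower/upper bound, mean width, and the percent width
#' reduction of each conditional method relative to unconditional Lee
#' bounds.
#'
#' @param scenario A [trial_scenario()].
#' @param methods Subset of `c("lee", "lee-conditional", "rflb")`.
#' @param n_reps Number of replications.
#' @param config An [analysis_config()]; its seed drives all replication
#'   sub-seeds.
#' @param conditioning Covariate names (categorical) whose level
#'   combinations define the cells for `"lee-conditional"`.
#' @param ci Also compute bootstrap outer CIs per replication (slower).
#' @param trim_mode Passed to the estimators.
#' @return An object of class `simulation_summary` with `$replications` and
#'   `$aggregate` tables.
#' @export
run_simulation_study <- function(scenario, methods = "lee", n_reps = 50L,
                                 config = analysis_config(),
                                 conditioning = NULL, ci = FALSE,
                                 trim_mode = c("fractional", "integer")) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(is_count(n_reps))
  methods <- match.arg(methods, c("lee", "lee-conditional", "rflb"),
                       several.ok = TRUE)
  if ("lee-conditional" %in% methods && is.null(conditioning))
    stop_rflb("rflb_argument_error",
              "conditioning covariates required for lee-conditional")
  rows <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- derive_seed(config$seed, 1000L + r)
    gen <- generate_trial(scenario, seed = seed_r)
    ds <- gen$dataset
    cfg_r <- config; cfg_r$seed <- seed_r
    for (m in methods) {
      res <- tryCatch({
        b <- switch(m,
          lee = if (ci) bounds_ci(ds, "lee", cfg_r, trim_mode = trim_mode)
                else lee_bounds(ds, trim_mode),
          `lee-conditional` = {
            cells <- interaction(ds$X[conditioning], drop = TRUE)
            if (ci) bounds_ci(ds, "lee-conditional", cfg_r, cells = cells,
                              trim_mode = trim_mode)
            else conditional_lee_bounds(ds, cells, trim_mode)
          },
          rflb = rflb_bounds(ds, cfg_r, trim_mode, ci = ci)$bounds)
        b
      }, error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(res)) {
        data.frame(rep = r, method = m, lower = NA_real_, upper = NA_real_,
                   width = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                   ci_width = NA_real_, covered = NA, failed = TRUE)
      } else {
        data.frame(
          rep = r, method = m, lower = res$lower, upper = res$upper,
          width = res$upper - res$lower,
          ci_lower = if (!is.null(res$ci_outer)) res$ci_outer[1] else NA_real_,
          ci_upper = if (!is.null(res$ci_outer)) res$ci_outer[2] else NA_real_,
          ci_width = if (!is.null(res$ci_outer)) diff(res$ci_outer) else NA_real_,
          covered = gen$truth$ate_never >= res$lower &
                    gen$truth$ate_never <= res$upper,
          failed = FALSE)
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(methods, function(m) {
    d <- reps[reps$method == m & !reps$failed, ]
    data.frame(method = m,
               lower = mean(d$lower), upper = mean(d$upper),
               width = mean(d$width), ci_width = mean(d$ci_width),
               coverage = mean(d$covered),
               n_ok = nrow(d), n_failed = sum(reps$method == m) - nrow(d))
  }))
  if ("lee" %in% methods) {
    w0 <- agg$width[agg$method == "lee"]
    cw0 <- agg$ci_width[agg$method == "lee"]
    agg$gain_pct <- 100 * (w0 - agg$width) / w0
    agg$ci_gain_pct <- 100 * (cw0 - agg$ci_width) / cw0
  } else {
    agg$gain_pct <- NA_real_; agg$ci_gain_pct <- NA_real_
  }
  structure(list(replications = reps, aggregate = agg, n_reps = n_reps,
                 scenario = scenario),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("Bounding simulation: %d replications, beta_true = %.3f\n",
              x$n_reps, x$scenario$effect))
  a <- x$aggregate
  cat(sprintf("%-18s %8s %8s %8s %8s %9s %9s\n", "method", "lower", "upper",
              "width", "%-gain", "CI width", "coverage"))
  for (i in seq_len(nrow(a)))
    cat(sprintf("%-18s %8.3f %8.3f %8.3f %8.3f %9.3f %9.3f\n",
                a$method[i], a$lower[i], a$upper[i], a$width[i],
                a$gain_pct[i], a$ci_width[i], a$coverage[i]))
  invisible(x)
}
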