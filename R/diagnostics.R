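#' Per-arm observation proportions and trimming share
#'
#' Computes the proportion of observed outcomes in each arm,
#' \eqn{q_{T=1} = \sum_i 1(T_i=1, S_i=1) / \sum_i 1(T_i=1)} and likewise for
#' the control arm, the trimming share
#' \eqn{q = (\max(q_0,q_1) - \min(q_0,q_1)) / \max(q_0,q_1)}, and the arm to
#' be trimmed in a Lee-bounds run: the less-attrited arm, i.e. the one with
#' the larger observed proportion. When the two proportions are equal, `q`
#' is 0, trimming is vacuous, and `trimmed_arm` is reported as `"control"`
#' by convention.
#'
#' @param ds A [trial_dataset()].
#' @return An object of class `attrition_summary` with fields `n_fs`, `n_os`,
#'   `q_treated`, `q_control`, `trim_share`, `trimmed_arm`.
#' @export
#' @examples
#' # 86/97 control and 56/96 treated outcomes observed -> q ~ 0.34
#' ds <- trial_dataset(
#'   outcome = c(rep(1, 86), rep(NA, 11), rep(1, 56), rep(NA, 40)),
#'   treatment = rep(c(0, 1), c(97, 96)))
#' attrition_rates(ds)
attrition_rates <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  n_t <- sum(ds$treat == 1L); n_c <- sum(ds$treat == 0L)
  o_t <- sum(ds$obs[ds$treat == 1L]); o_c <- sum(ds$obs[ds$treat == 0L])
  if (o_t == 0L || o_c == 0L)
    stop_rflb("rflb_degenerate_attrition_error",
              "an arm has zero observed outcomes; bounds are undefined")
  q_t <- o_t / n_t; q_c <- o_c / n_c
  structure(
    list(n_fs = n_t + n_c, n_os = o_t + o_c,
         q_treated = q_t, q_control = q_c,
         trim_share = (max(q_t, q_c) - min(q_t, q_c)) / max(q_t, q_c),
         trimmed_arm = if (q_t > q_c) "treated" else "control"),
    class = "attrition_summary")
}

#' @export
print.attrition_summary <- function(x, ...) {
  cat(sprintf("Attrition: %d of %d outcomes observed\n", x$n_os, x$n_fs))
  cat(sprintf("  observed proportion, treated: %.4f  control: %.4f\n",
              x$q_treated, x$q_control))
  cat(sprintf("  trimming share q = %.4f (trimmed arm: %s)\n",
              x$trim_share, x$trimmed_arm))
  invisible(x)
}

#' Statistical power retained after attrition
#'
#' For a trial designed for 80% power on the full randomized sample, the
#' power retained when only `n_os` of `n_fs` outcomes are observed is
#' \eqn{\Phi(\theta)} with \eqn{\theta = 2.8 \cdot N_{os}/N_{fs} - 1.96}. At
#' a ratio of 1 this recovers \eqn{\theta = 0.84} and 80% power; at a ratio
#' of 0.75 it gives \eqn{\theta = 0.14} and 56% power. The default is this
#' linear-in-the-ratio form; `form = "sqrt"` replaces the ratio by its square
#' root, the variant implied by the usual \eqn{\sqrt{n}} scaling of the test
#' statistic, exposed for sensitivity analysis.
#'
#' @param n_os Observed-outcome count (0 < n_os <= n_fs).
#' @param n_fs Full randomized count.
#' @param form `"linear"` (default) or `"sqrt"`.
#' @return An object of class `power_loss` with fields `ratio`, `theta`,
#'   `power`.
#' @export
power_after_attrition <- function(n_os, n_fs, form = c("linear", "sqrt")) {
  form <- match.arg(form)
  if (!is_count(n_os) || !is_count(n_fs) || n_os > n_fs)
    stop_rflb("rflb_argument_error", "need 0 < n_os <= n_fs")
  ratio <- n_os / n_fs
  theta <- 2.8 * switch(form, linear = ratio, sqrt = sqrt(ratio)) - 1.96
  structure(list(ratio = ratio, theta = theta, power = stats::pnorm(theta),
                 form = form),
            class = "power_loss")
}

#' @export
print.power_loss <- function(x, ...) {
  cat(sprintf("Observed/full sample ratio %.3f -> theta = %.2f, power = %.0f%%\n",
              x$ratio, x$theta, 100 * x$power))
  invisible(x)
}

## Complete-case analysis frame: observed outcomes, and (when covariates are
## used) rows with complete covariate values.
cc_rows <- function(ds, covariates = NULL) {
  keep <- ds$obs == 1L
  if (length(covariates))
    keep <- keep & stats::complete.cases(ds$X[covariates])
  which(keep)
}

robust_vcov <- function(fit) sandwich::vcovHC(fit, type = "HC1")

#' Average treatment effect by ordinary least squares
#'
#' Fits \eqn{y_i = \alpha + \beta T_i + \epsilon_i} (unadjusted) or
#' \eqn{y_i = \alpha + \beta T_i + X_i'\delta + \epsilon_i} (adjusted) on the
#' complete-case sample of observed outcomes. The unadjusted \eqn{\beta} is
#' exactly the difference in observed arm means. Standard errors are
#' heteroskedasticity-robust (HC1): trimmed and selected samples are not
#' homoskedastic by construction.
#'
#' @param ds A [trial_dataset()].
#' @param adjusted Include baseline covariates?
#' @param covariates Covariate names to adjust for; defaults to all.
#' @return An object of class `ate_estimate`: `beta`, `se`, `adjusted`,
#'   `covariate_coefficients` (estimate + robust SE per adjusted term),
#'   `n_used`.
#' @export
estimate_ate <- function(ds, adjusted = FALSE, covariates = NULL) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (adjusted && is.null(covariates)) covariates <- covariate_names(ds)
  rows <- cc_rows(ds, if (adjusted) covariates)
  treat <- ds$treat[rows]
  if (sum(treat == 1L) < 2L || sum(treat == 0L) < 2L)
    stop_rflb("rflb_degenerate_design_error",
              "need at least 2 observed outcomes per arm")
  dat <- data.frame(y = ds$y[rows], treat = treat)
  if (adjusted && length(covariates))
    dat <- cbind(dat, ds$X[rows, covariates, drop = FALSE])
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_rflb("rflb_collinearity_error",
              "collinear terms in adjustment set: %s",
              paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(robust_vcov(fit)))
  keep <- setdiff(names(cf), c("(Intercept)", "treat"))
  structure(
    list(beta = unname(cf["treat"]), se = unname(se["treat"]),
         adjusted = adjusted,
         covariate_coefficients = if (length(keep))
           data.frame(term = keep, estimate = unname(cf[keep]),
                      se = unname(se[keep])) else NULL,
         n_used = nrow(dat)),
    class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE (%s, n = %d): beta = %.3f (robust SE %.3f)\n",
              if (x$adjusted) "covariate-adjusted" else "unadjusted",
              x$n_used, x$beta, x$se))
  invisible(x)
}

#' Covariate balance test by linear probability model
#'
#' Regresses treatment status on the baseline covariates,
#' \eqn{T_i = \alpha + X_i'\delta + \epsilon_i}, on the requested sample and
#' tests \eqn{\delta = 0} jointly with a heteroskedasticity-robust Wald test.
#' If randomization (and, on trimmed samples, monotone selection) holds,
#' treatment status should not be predictable from the covariates. Constant
#' covariates on the sample are dropped with a warning and the degrees of
#' freedom reduced.
#'
#' @param ds A [trial_dataset()].
#' @param sample `"observed"` (complete cases, default), `"full"`, or
#'   `"trimmed"` (requires `trimmed_rows`).
#' @param trimmed_rows Participant ids retained after trimming (for
#'   `sample = "trimmed"`).
#' @param covariates Covariate names to test; defaults to all.
#' @return An object of class `balance_test`: `coefficients`,
#'   `wald_statistic`, `df`, `p_value`, `sample`, `n`.
#' @export
balance_test <- function(ds, sample = c("observed", "full", "trimmed"),
                         trimmed_rows = NULL, covariates = NULL) {
  sample <- match.arg(sample)
  covariates <- covariates %||% covariate_names(ds)
  if (!length(covariates))
    stop_rflb("rflb_argument_error", "no covariates to test")
  rows <- switch(sample,
    full = seq_len(ds$n),
    observed = which(ds$obs == 1L),
    trimmed = {
      if (is.null(trimmed_rows))
        stop_rflb("rflb_argument_error", "trimmed_rows required for sample = 'trimmed'")
      which(ds$id %in% trimmed_rows)
    })
  if (!length(rows))
    stop_rflb("rflb_argument_error", "requested sample is empty")
  X <- ds$X[rows, covariates, drop = FALSE]
  keep <- stats::complete.cases(X)
  rows <- rows[keep]; X <- X[keep, , drop = FALSE]
  constant <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  if (any(constant)) {
    warning(sprintf("dropping constant covariate(s) on this sample: %s",
                    paste(names(X)[constant], collapse = ", ")))
    X <- X[!constant]
  }
  if (!ncol(X))
    stop_rflb("rflb_argument_error", "all covariates degenerate on this sample")
  dat <- cbind(data.frame(treat = ds$treat[rows]), X)
  fit <- stats::lm(treat ~ ., data = dat)
  cf <- stats::coef(fit)
  cf <- cf[!is.na(cf)]
  terms <- setdiff(names(cf), "(Intercept)")
  b <- cf[terms]
  perfect <- max(abs(stats::resid(fit))) < 1e-10
  if (perfect) {
    wald <- Inf; p <- 0
  } else {
    V <- robust_vcov(fit)[terms, terms, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
    wald <- drop(t(b) %*% Vi %*% b)
    p <- stats::pchisq(wald, df = length(b), lower.tail = FALSE)
  }
  structure(
    list(coefficients = data.frame(term = terms, estimate = unname(b)),
         wald_statistic = wald, df = length(b), p_value = p,
         sample = sample, n = nrow(dat), perfect_prediction = perfect),
    class = "balance_test")
}

#' @export
print.balance_test <- function(x, ...) {
  cat(sprintf("Balance test (%s sample, n = %d): Wald = %.3f on %d df, p = %.4g\n",
              x$sample, x$n, x$wald_statistic, x$df, x$p_value))
  if (x$perfect_prediction)
    cat("  (treatment perfectly predicted by covariates)\n")
  invisible(x)
}

#' Compare adjusted and unadjusted treatment-effect estimates
#'
#' Under MCAR, adding baseline covariates to the outcome regression must not
#' change the estimated treatment effect beyond sampling noise; a systematic
#' shift indicates that missingness is related to the covariates. Both fits
#' use the same complete-case rows, and the difference
#' \eqn{\beta_{adj} - \beta_{unadj}} gets a paired-bootstrap standard error
#' (resampling rows within arm and recomputing both fits on each replicate).
#'
#' @param ds A [trial_dataset()].
#' @param covariates Covariates for the adjusted fit; defaults to all.
#' @param config An [analysis_config()] (bootstrap size and seed).
#' @return An object of class `mcar_mar_comparison`: `beta_unadjusted`,
#'   `beta_adjusted`, `difference`, `se_difference`, `z`, `p_value`.
#' @export
mcar_mar_comparison <- function(ds, covariates = NULL,
                                config = analysis_config()) {
  covariates <- covariates %||% covariate_names(ds)
  rows <- cc_rows(ds, covariates)
  sub <- subset_trial(ds, rows)
  fit_pair <- function(d) {
    c(estimate_ate(d, adjusted = FALSE)$beta,
      estimate_ate(d, adjusted = TRUE, covariates = covariates)$beta)
  }
  base <- fit_pair(sub)
  diffs <- with_seed(derive_seed(config$seed, 31L), {
    vapply(seq_len(config$n_bootstrap), function(b) {
      idx <- resample_within_arm(sub$treat)
      bb <- tryCatch(fit_pair(subset_trial(sub, idx)),
                     error = function(e) c(NA_real_, NA_real_))
      bb[2] - bb[1]
    }, numeric(1))
  })
  diffs <- diffs[is.finite(diffs)]
  se <- stats::sd(diffs)
  d <- base[2] - base[1]
  z <- if (se > 0) d / se else Inf * sign(d)
  structure(
    list(beta_unadjusted = base[1], beta_adjusted = base[2], difference = d,
         se_difference = se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         n_bootstrap = length(diffs)),
    class = "mcar_mar_comparison")
}

#' @export
print.mcar_mar_comparison <- function(x, ...) {
  cat(sprintf("beta unadjusted %.3f, adjusted %.3f; difference %.3f (bootstrap SE %.3f, p = %.3g)\n",
              x$beta_unadjusted, x$beta_adjusted, x$difference,
              x$se_difference, x$p_value))
  invisible(x)
}

## Within-arm resampling indices for the nonparametric bootstrap.
resample_within_arm <- function(treat) {
  idx_t <- which(treat == 1L); idx_c <- which(treat == 0L)
  c(idx_t[sample.int(length(idx_t), replace = TRUE)],
    idx_c[sample.int(length(idx_c), replace = TRUE)])
}

#' Monotone-selection check on the trimmed sample
#'
#' After trimming, the retained sample should not allow treatment status to
#' be predicted from the covariates if the monotone-selection assumption
#' holds for observables: this is [balance_test()] run on the post-trimming
#' analysis set and reported alongside the bounds.
#'
#' @param ds A [trial_dataset()].
#' @param trimmed_rows Either a vector of retained participant ids, or a
#'   `bounds_result` (then both trimmed tails are checked and a list of two
#'   tests is returned).
#' @param covariates Covariate names to test; defaults to all.
#' @return A `balance_test`, or a named list of two for a `bounds_result`.
#' @export
monotonicity_check <- function(ds, trimmed_rows, covariates = NULL) {
  if (inherits(trimmed_rows, "bounds_result")) {
    return(lapply(trimmed_rows$trimmed_rows, function(ids)
      balance_test(ds, "trimmed", trimmed_rows = ids, covariates = covariates)))
  }
  balance_test(ds, "trimmed", trimmed_rows = trimmed_rows,
               covariates = covariates)
}
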