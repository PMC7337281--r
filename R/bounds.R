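#' Outcome support for worst-case bounds
#'
#' The logical range of the outcome scale, used to fill in missing outcomes
#' with best- and worst-case values.
#'
#' @param y_min,y_max Support endpoints, `y_min < y_max`.
#' @return An object of class `outcome_support`.
#' @export
outcome_support <- function(y_min, y_max) {
  if (!is.numeric(y_min) || !is.numeric(y_max) || !(y_min < y_max))
    stop_rflb("rflb_argument_error", "need y_min < y_max")
  structure(list(y_min = y_min, y_max = y_max), class = "outcome_support")
}

new_bounds_result <- function(lower, upper, method, estimate,
                              trim_share = 0, trimmed_arm = NA_character_,
                              trimmed_rows = NULL, attrition = NULL,
                              cells = NULL, support = NULL, fallback = FALSE) {
  structure(
    list(lower = lower, upper = upper, estimate = estimate, method = method,
         trim_share = trim_share, trimmed_arm = trimmed_arm,
         se_lower = NA_real_, se_upper = NA_real_, ci_outer = NULL,
         ci_level = NA_real_, ci_method = NA_character_,
         n_bootstrap = 0L, n_dropped = 0L,
         cells = cells, trimmed_rows = trimmed_rows, attrition = attrition,
         support = support, fallback = fallback),
    class = "bounds_result")
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf("%s bounds%s\n", x$method,
              if (isTRUE(x$fallback)) " (fallback to unconditional Lee)" else ""))
  cat(sprintf("  point estimate (unadjusted beta): %.3f\n", x$estimate))
  cat(sprintf("  lower %.3f  upper %.3f  width %.3f  (trim share %.3f, trimmed arm %s)\n",
              x$lower, x$upper, x$upper - x$lower, x$trim_share,
              x$trimmed_arm))
  if (!is.null(x$ci_outer))
    cat(sprintf("  %.0f%% outer CI [%.3f, %.3f]  width %.3f  (%s, %d bootstrap replicates, %d dropped)\n",
                100 * x$ci_level, x$ci_outer[1], x$ci_outer[2],
                diff(x$ci_outer), x$ci_method, x$n_bootstrap, x$n_dropped))
  if (!is.null(x$cells)) {
    cat("  per-cell detail:\n")
    print(x$cells, row.names = FALSE)
  }
  invisible(x)
}

## Retention weights, in ascending order of the values, after removing mass
## `p` from one tail. Fractional mode puts partial weight on the order
## statistic straddling the p-quantile (permutation-invariant under ties);
## integer mode removes ceiling(p*n) whole observations.
trim_weights <- function(n, p, tail = c("lower", "upper"),
                         mode = c("fractional", "integer")) {
  tail <- match.arg(tail); mode <- match.arg(mode)
  if (mode == "integer") {
    m <- if (p == 0) 0L else min(ceiling(p * n), n - 1L)
    w <- rep(1, n)
    if (m > 0) {
      if (tail == "lower") w[seq_len(m)] <- 0 else w[n + 1L - seq_len(m)] <- 0
    }
    return(w)
  }
  k <- p * n
  i <- seq_len(n)
  w <- pmax(0, i - k) - pmax(0, i - 1 - k)
  if (tail == "upper") rev(w) else w
}

#' Tail-trimmed mean
#'
#' Mean of an empirical distribution after removing probability mass `p`
#' from one tail. In `"fractional"` mode each observation carries mass `1/n`
#' and the order statistic straddling the `p`-quantile keeps fractional
#' weight, matching the population trimming formula exactly; in `"integer"`
#' mode `ceiling(p*n)` whole observations are removed, for replicating
#' implementations that round.
#'
#' @param values Numeric vector (non-empty).
#' @param p Trim fraction in `[0, 1)`.
#' @param tail `"lower"` or `"upper"`: the tail that is removed.
#' @param mode `"fractional"` (default) or `"integer"`.
#' @return The trimmed mean (the plain mean when `p = 0`).
#' @export
#' @examples
#' trimmed_mean(c(1, 2, 3, 4), 0.5, "lower")        # mean of {3, 4} = 3.5
#' trimmed_mean(c(1, 2, 3, 4, 5), 0.3, "upper")     # (1+2+3+0.5*4)/3.5
trimmed_mean <- function(values, p, tail = c("lower", "upper"),
                         mode = c("fractional", "integer")) {
  if (!length(values) || anyNA(values))
    stop_rflb("rflb_argument_error", "values must be non-empty and complete")
  if (!is_prob(p, open = FALSE) || p >= 1)
    stop_rflb("rflb_argument_error", "p must be in [0, 1)")
  x <- sort(values)
  w <- trim_weights(length(x), p, tail, mode)
  sum(w * x) / sum(w)
}

#' Horowitz-Manski worst-case bounds
#'
#' Assumption-free bounds on the average treatment effect: every missing
#' outcome is replaced by the best- or worst-case value on the outcome
#' support. The lower bound sets missing treated outcomes to `y_min` and
#' missing control outcomes to `y_max`; the upper bound is the mirror image.
#' No trimming is involved, so the bounds apply to the full randomized
#' sample.
#'
#' @param ds A [trial_dataset()].
#' @param support An [outcome_support()] covering every observed outcome.
#' @return A `bounds_result` with `method = "horowitz-manski"`.
#' @export
horowitz_manski_bounds <- function(ds, support) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(support, "outcome_support"))
  yobs <- ds$y[ds$obs == 1L]
  if (any(yobs < support$y_min | yobs > support$y_max))
    stop_rflb("rflb_support_error",
              "observed outcomes fall outside the stated support")
  fill_mean <- function(arm, value) {
    y <- ds$y[ds$treat == arm]
    y[is.na(y)] <- value
    mean(y)
  }
  lower <- fill_mean(1L, support$y_min) - fill_mean(0L, support$y_max)
  upper <- fill_mean(1L, support$y_max) - fill_mean(0L, support$y_min)
  est <- mean(ds$y[ds$treat == 1L & ds$obs == 1L]) -
         mean(ds$y[ds$treat == 0L & ds$obs == 1L])
  new_bounds_result(lower, upper, "horowitz-manski", estimate = est,
                    trimmed_rows = list(lower = ds$id, upper = ds$id),
                    support = support)
}

## Core Lee computation shared by the unconditional and per-cell paths.
## Returns both tail candidates (as treated-minus-control differences), the
## retained ids per candidate, and the untrimmed mean difference.
lee_core <- function(ds, rows, p, trimmed_arm, trim_mode) {
  arm_code <- if (trimmed_arm == "treated") 1L else 0L
  trim_obs <- rows[ds$treat[rows] == arm_code & ds$obs[rows] == 1L]
  other_obs <- rows[ds$treat[rows] != arm_code & ds$obs[rows] == 1L]
  y_trim <- ds$y[trim_obs]
  mu_other <- mean(ds$y[other_obs])
  signed <- function(m) if (arm_code == 1L) m - mu_other else mu_other - m
  ord <- order(y_trim)
  ids_sorted <- ds$id[trim_obs][ord]
  retained <- function(tail)
    c(ds$id[other_obs],
      ids_sorted[trim_weights(length(y_trim), p, tail, trim_mode) > 1e-12])
  cand <- c(lower_tail = signed(trimmed_mean(y_trim, p, "lower", trim_mode)),
            upper_tail = signed(trimmed_mean(y_trim, p, "upper", trim_mode)))
  lo_tail <- names(which.min(cand)); up_tail <- setdiff(names(cand), lo_tail)
  list(lower = min(cand), upper = max(cand),
       estimate = signed(mean(y_trim)),
       trimmed_rows = list(lower = retained(sub("_tail", "", lo_tail)),
                           upper = retained(sub("_tail", "", up_tail))))
}

#' Lee trimming bounds for the average treatment effect
#'
#' Under monotone sample selection, trims the outcome distribution of the
#' less-attrited arm by the trimming share `q` from each tail in turn; the
#' two resulting mean differences bracket the average treatment effect for
#' the never-attriters (participants whose outcome would be observed under
#' either assignment). Bounds are computed as the two tail-trimmed
#' differences and sorted, so no outcome sign convention is assumed.
#'
#' @param ds A [trial_dataset()].
#' @param trim_mode `"fractional"` (default) or `"integer"`; see
#'   [trimmed_mean()].
#' @param trim_share,trimmed_arm Optional overrides of the values from
#'   [attrition_rates()], for sensitivity analysis.
#' @return A `bounds_result` with `method = "lee"`; `trimmed_rows` holds the
#'   retained participant ids behind each bound, for
#'   [monotonicity_check()].
#' @export
lee_bounds <- function(ds, trim_mode = c("fractional", "integer"),
                       trim_share = NULL, trimmed_arm = NULL) {
  trim_mode <- match.arg(trim_mode)
  ar <- attrition_rates(ds)
  p <- trim_share %||% ar$trim_share
  arm <- trimmed_arm %||% ar$trimmed_arm
  core <- lee_core(ds, seq_len(ds$n), p, arm, trim_mode)
  new_bounds_result(core$lower, core$upper, "lee", estimate = core$estimate,
                    trim_share = p, trimmed_arm = arm,
                    trimmed_rows = core$trimmed_rows, attrition = ar)
}

## Pool cells that violate the minimum per-arm observed count: undersized
## cells are pooled into ".other"; a still-undersized pool is merged into the
## largest remaining cell.
merge_cells <- function(ds, cells, min_per_arm) {
  cells <- factor(as.character(cells))
  min_obs <- function(f) {
    vapply(levels(f), function(l) {
      r <- f == l
      min(sum(ds$obs[r & ds$treat == 1L]), sum(ds$obs[r & ds$treat == 0L]))
    }, numeric(1))
  }
  m <- min_obs(cells)
  und <- names(m)[m < min_per_arm]
  if (length(und) && length(und) < nlevels(cells)) {
    x <- as.character(cells)
    x[x %in% und] <- ".other"
    cells <- factor(x)
    if (nlevels(cells) > 1L) {
      m <- min_obs(cells)
      if (".other" %in% names(m) && m[".other"] < min_per_arm) {
        big <- names(which.max(table(cells[cells != ".other"])))
        x[x == ".other"] <- big
        cells <- factor(x)
      }
    }
  } else if (length(und) && nlevels(cells) > 1L) {
    cells <- factor(rep("all", length(cells)))
  }
  cells
}

#' Conditional Lee bounds on discrete cells
#'
#' Performs the Lee trimming procedure separately within each cell of a
#' discrete partition (e.g. levels of a baseline factor, or the leaves of a
#' conditioning tree) and aggregates the per-cell bounds with weights
#' proportional to each cell's share of observed participants in the
#' globally untrimmed arm -- the reference population of never-attriters.
#' Each cell is trimmed in the direction of its own attrition differential;
#' cells whose differential flips sign relative to the global one are
#' retained (their trim applies to the other arm) and flagged in the
#' per-cell table. Cells violating the minimum per-arm observed count are
#' pooled into an `".other"` cell.
#'
#' @param ds A [trial_dataset()].
#' @param cells Vector of cell labels, one per row (no missing entries).
#' @param trim_mode `"fractional"` or `"integer"`.
#' @param min_per_arm Minimum observed outcomes per arm per cell before
#'   pooling (default 1).
#' @param merge_undersized Pool undersized cells (default `TRUE`); with
#'   `FALSE`, any cell violating the minimum count raises a
#'   conditioning-infeasible error instead.
#' @return A `bounds_result` with `method = "lee-conditional"` and a
#'   per-cell detail table in `$cells`.
#' @export
conditional_lee_bounds <- function(ds, cells,
                                   trim_mode = c("fractional", "integer"),
                                   min_per_arm = 1L,
                                   merge_undersized = TRUE) {
  trim_mode <- match.arg(trim_mode)
  if (length(cells) != ds$n || anyNA(cells))
    stop_rflb("rflb_argument_error",
              "cells must assign every row to exactly one cell")
  ar <- attrition_rates(ds)
  cells <- if (merge_undersized) merge_cells(ds, cells, min_per_arm)
           else factor(as.character(cells))
  untrim_code <- if (ar$trimmed_arm == "treated") 0L else 1L
  lv <- levels(cells)
  rows_of <- lapply(lv, function(l) which(cells == l))
  names(rows_of) <- lv
  detail <- vector("list", length(lv))
  trimmed_lower <- trimmed_upper <- character(0)
  for (i in seq_along(lv)) {
    rows <- rows_of[[i]]
    o_t <- sum(ds$obs[rows][ds$treat[rows] == 1L])
    o_c <- sum(ds$obs[rows][ds$treat[rows] == 0L])
    if (o_t == 0L || o_c == 0L)
      stop_rflb("rflb_conditioning_infeasible_error",
                "cell '%s' has no observed outcomes in one arm", lv[i])
    n_t <- sum(ds$treat[rows] == 1L); n_c <- sum(ds$treat[rows] == 0L)
    q_t <- o_t / n_t; q_c <- o_c / n_c
    p_cell <- (max(q_t, q_c) - min(q_t, q_c)) / max(q_t, q_c)
    arm_cell <- if (q_t > q_c) "treated" else "control"
    core <- lee_core(ds, rows, p_cell, arm_cell, trim_mode)
    w <- sum(ds$obs[rows][ds$treat[rows] == untrim_code])
    detail[[i]] <- data.frame(
      cell = lv[i], n_treated = n_t, n_control = n_c,
      obs_treated = o_t, obs_control = o_c,
      trim_share = p_cell, trimmed_arm = arm_cell,
      flipped = p_cell > 0 && arm_cell != ar$trimmed_arm,
      weight = w, lower = core$lower, upper = core$upper,
      stringsAsFactors = FALSE)
    trimmed_lower <- c(trimmed_lower, core$trimmed_rows$lower)
    trimmed_upper <- c(trimmed_upper, core$trimmed_rows$upper)
  }
  detail <- do.call(rbind, detail)
  detail$weight <- detail$weight / sum(detail$weight)
  est <- mean(ds$y[ds$treat == 1L & ds$obs == 1L]) -
         mean(ds$y[ds$treat == 0L & ds$obs == 1L])
  new_bounds_result(
    lower = sum(detail$weight * detail$lower),
    upper = sum(detail$weight * detail$upper),
    method = "lee-conditional", estimate = est,
    trim_share = sum(detail$weight * detail$trim_share),
    trimmed_arm = ar$trimmed_arm,
    trimmed_rows = list(lower = trimmed_lower, upper = trimmed_upper),
    attrition = ar, cells = detail)
}

#' Bootstrap uncertainty for bound estimates
#'
#' Nonparametric bootstrap over participants: rows are resampled with
#' replacement within arm and the full bounding procedure -- including the
#' trimming shares and, for conditional methods, the fixed cell assignment
#' -- is recomputed on every replicate. `se_lower`/`se_upper` are the
#' bootstrap standard deviations of the two bounds. The default outer
#' confidence interval extends each bound outward by `z` times its own
#' standard error, covering the whole identified set;
#' `ci_method = "imbens-manski"` instead uses the adjusted critical value
#' that gives `ci_level` coverage for the parameter rather than the set.
#' Replicates with degenerate attrition are dropped and counted; more than
#' 20% dropped raises an instability error. Results are deterministic under
#' the configuration seed.
#'
#' @param ds A [trial_dataset()].
#' @param method `"lee"`, `"horowitz-manski"`, or `"lee-conditional"`.
#' @param config An [analysis_config()].
#' @param support Required for `method = "horowitz-manski"`.
#' @param cells Required for `method = "lee-conditional"`.
#' @param trim_mode,min_per_arm Passed to the underlying estimator.
#' @param ci_method `"outer"` (default) or `"imbens-manski"`.
#' @return The full-sample `bounds_result` with `se_lower`, `se_upper`,
#'   `ci_outer` filled in.
#' @export
bounds_ci <- function(ds, method = c("lee", "horowitz-manski",
                                     "lee-conditional"),
                      config = analysis_config(), support = NULL,
                      cells = NULL, trim_mode = c("fractional", "integer"),
                      min_per_arm = 1L,
                      ci_method = c("outer", "imbens-manski")) {
  method <- match.arg(method)
  trim_mode <- match.arg(trim_mode)
  ci_method <- match.arg(ci_method)
  est <- switch(method,
    lee = function(d, cl) lee_bounds(d, trim_mode),
    `horowitz-manski` = function(d, cl) horowitz_manski_bounds(d, support),
    `lee-conditional` = function(d, cl)
      conditional_lee_bounds(d, cl, trim_mode, min_per_arm))
  if (method == "lee-conditional" && is.null(cells))
    stop_rflb("rflb_argument_error", "cells required for lee-conditional")
  base <- est(ds, cells)
  B <- config$n_bootstrap
  lows <- ups <- rep(NA_real_, B)
  with_seed(derive_seed(config$seed, 47L), {
    for (b in seq_len(B)) {
      idx <- resample_within_arm(ds$treat)
      r <- tryCatch(est(subset_trial(ds, idx),
                        if (!is.null(cells)) cells[idx]),
                    error = function(e) NULL)
      if (!is.null(r)) { lows[b] <- r$lower; ups[b] <- r$upper }
    }
  })
  ok <- is.finite(lows) & is.finite(ups)
  n_drop <- B - sum(ok)
  if (n_drop > 0.2 * B)
    stop_rflb("rflb_instability_error",
              "%d of %d bootstrap replicates failed", n_drop, B)
  se_l <- stats::sd(lows[ok]); se_u <- stats::sd(ups[ok])
  if (B == 1L) { se_l <- 0; se_u <- 0 }
  z <- switch(ci_method,
    outer = stats::qnorm(1 - (1 - config$ci_level) / 2),
    `imbens-manski` = imbens_manski_cv(base$upper - base$lower,
                                       max(se_l, se_u), config$ci_level))
  base$se_lower <- se_l; base$se_upper <- se_u
  base$ci_outer <- c(base$lower - z * se_l, base$upper + z * se_u)
  base$ci_level <- config$ci_level
  base$ci_method <- ci_method
  base$n_bootstrap <- B
  base$n_dropped <- n_drop
  base
}

## Imbens-Manski critical value: c solves
## pnorm(c + width/se_max) - pnorm(-c) = level.
imbens_manski_cv <- function(width, se_max, level) {
  two_sided <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.finite(se_max) || se_max <= 0) return(two_sided)
  delta <- width / se_max
  f <- function(c) stats::pnorm(c + delta) - stats::pnorm(-c) - level
  stats::uniroot(f, lower = 0, upper = two_sided + 1, tol = 1e-10)$root
}
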