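#' Analysis configuration
#'
#' Bundles the tunable settings shared across the bounding and RFLB
#' procedures. Forest defaults are standard practice (500 trees, sqrt(p)
#' variables per split, minimum node size 5, 5-fold cross-validation);
#' conditioning-tree defaults (at most 4 leaves, at least 20 observed
#' outcomes per arm per cell) keep every cell large enough to support its own
#' trimmed means.
#'
#' @param alpha Significance level for diagnostic tests, in (0,1).
#' @param ci_level Confidence level for bound confidence intervals, in (0,1).
#' @param n_bootstrap Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; every source of randomness in a run flows from
#'   it.
#' @param rf_settings List: `num_trees`, `mtry` (`NULL` = sqrt of the feature
#'   count), `min_node_size`, `cv_folds`, `n_perm` (permutation repeats per
#'   fold), `benchmark_mode` (`"single"` uniform draw, or `"median5"`, the
#'   elementwise median of five draws for a lower-noise benchmark),
#'   `selection_rule` (`"both"`: a covariate must beat the benchmark on both
#'   its main and its treatment-interaction importance; `"main"`:
#'   main-effect screen only).
#' @param tree_settings List: `max_leaves`, `min_cell_obs` (minimum observed
#'   outcomes per arm in every conditioning cell).
#' @param covariate_missing_policy `"missing-indicator"` or `"drop-row"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, ci_level = 0.95,
                            n_bootstrap = 500L, seed = 1L,
                            rf_settings = list(),
                            tree_settings = list(),
                            covariate_missing_policy = c("missing-indicator",
                                                         "drop-row")) {
  if (!is_prob(alpha)) stop_rflb("rflb_config_error", "alpha must be in (0,1)")
  if (!is_prob(ci_level)) stop_rflb("rflb_config_error", "ci_level must be in (0,1)")
  if (!is_count(n_bootstrap)) stop_rflb("rflb_config_error", "n_bootstrap must be >= 1")
  if (!is_count(abs(seed) + 1)) stop_rflb("rflb_config_error", "seed must be an integer")
  rf <- utils::modifyList(
    list(num_trees = 500L, mtry = NULL, min_node_size = 5L, cv_folds = 5L,
         n_perm = 3L, benchmark_mode = "single", selection_rule = "both"),
    rf_settings)
  tr <- utils::modifyList(list(max_leaves = 4L, min_cell_obs = 20L),
                          tree_settings)
  for (v in c("num_trees", "min_node_size", "cv_folds", "n_perm"))
    if (!is_count(rf[[v]]))
      stop_rflb("rflb_config_error", "rf_settings$%s must be a count >= 1", v)
  for (v in c("max_leaves", "min_cell_obs"))
    if (!is_count(tr[[v]]))
      stop_rflb("rflb_config_error", "tree_settings$%s must be a count >= 1", v)
  structure(
    list(alpha = alpha, ci_level = ci_level,
         n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
         rf_settings = rf, tree_settings = tr,
         covariate_missing_policy = match.arg(covariate_missing_policy)),
    class = "analysis_config")
}
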