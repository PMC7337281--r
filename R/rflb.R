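## ---- cross-validated permutation importance ------------------------------

## Permutation importance of each column of `X` for predicting the binary
## factor `y`, measured as the held-out Brier-score increase when the column
## is permuted, averaged over k cross-validation folds (and `n_perm`
## permutations per fold). Out-of-fold scoring avoids the optimism of
## in-sample impurity importance, which is also biased toward continuous
## variables and would rig the comparison against a continuous uniform
## benchmark.
cv_perm_importance <- function(X, y, rf, seed) {
  n <- nrow(X)
  k <- max(2L, min(rf$cv_folds, n))
  pos <- levels(y)[2]
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(k), n))
    imp <- matrix(NA_real_, k, ncol(X), dimnames = list(NULL, names(X)))
    for (f in seq_len(k)) {
      tr <- folds != f
      dat <- cbind(data.frame(.s = y), X)
      fit <- ranger::ranger(
        dependent.variable.name = ".s", data = dat[tr, , drop = FALSE],
        probability = TRUE, num.trees = rf$num_trees,
        mtry = rf$mtry %||% max(1L, floor(sqrt(ncol(X)))),
        min.node.size = rf$min_node_size,
        respect.unordered.factors = "order",
        seed = derive_seed(seed, f), num.threads = 1L)
      Xte <- X[!tr, , drop = FALSE]
      yte <- as.numeric(y[!tr] == pos)
      brier <- function(Xp) {
        pr <- stats::predict(fit, data = Xp, num.threads = 1L)$predictions
        mean((pr[, pos] - yte)^2)
      }
      base <- brier(Xte)
      m <- nrow(Xte)
      for (j in seq_len(ncol(X))) {
        losses <- vapply(seq_len(rf$n_perm), function(r) {
          Xp <- Xte
          Xp[[j]] <- Xp[[j]][sample.int(m)]
          brier(Xp)
        }, numeric(1))
        imp[f, j] <- mean(losses) - base
      }
    }
    colMeans(imp)
  })
}

## Normalize raw importances so the maximum equals 1; negative values (the
## permuted model predicted better, i.e. pure noise) clip to 0. If nothing
## improves the held-out score, all values are 0 and nothing can be selected.
normalize_importance <- function(raw) {
  mx <- max(raw)
  if (!is.finite(mx) || mx <= 0) return(stats::setNames(rep(0, length(raw)), names(raw)))
  pmax(raw, 0) / mx
}

#' Random-forest attrition importance with a random benchmark
#'
#' Steps 1-2 of the RFLB procedure. A random-forest classifier of the
#' observation indicator `S` is fit on treatment, the baseline covariates,
#' and an injected pure-noise benchmark column (a seeded uniform draw per
#' participant). Importances are permutation importances on held-out
#' cross-validation folds, normalized so the most important feature scores
#' 1. A covariate is *selected* only if its importance strictly exceeds the
#' benchmark's. A second forest scores explicit treatment-interaction
#' features `T*X_j` (per-level indicators for factors) against the
#' `T*benchmark` feature: attrition that is merely covariate-related is
#' necessary but not sufficient for tightening -- the covariation between
#' attrition and *treatment assignment* must be conditional on the covariate
#' too, which is what the interaction screen confirms. The default
#' conditioning set is the intersection of the two screens
#' (`rf_settings$selection_rule = "both"`).
#'
#' @param ds A [trial_dataset()] with at least one covariate and both
#'   attrition classes present.
#' @param config An [analysis_config()].
#' @return An object of class `importance_report` with normalized
#'   `importances`, `benchmark_importance`, `treatment_importance`,
#'   `interaction_importances`, `interaction_benchmark`, the `selected`,
#'   `interaction_selected` and `conditioning_set` covariate sets, `seed`
#'   and `cv_folds`.
#' @export
attrition_importance <- function(ds, config = analysis_config()) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (!ncol(ds$X))
    stop_rflb("rflb_argument_error", "at least one covariate is required")
  if (all(ds$obs == 1L) || all(ds$obs == 0L))
    stop_rflb("rflb_no_attrition_error",
              "attrition is all-0 or all-1; an attrition model is undefined")
  if (anyNA(ds$X))
    ds <- apply_covariate_missing_policy(ds, config$covariate_missing_policy)
  rf <- config$rf_settings
  n <- ds$n
  bench <- with_seed(derive_seed(config$seed, 11L), {
    if (identical(rf$benchmark_mode, "median5"))
      apply(matrix(stats::runif(5L * n), n, 5L), 1L, stats::median)
    else stats::runif(n)
  })
  y <- factor(ds$obs, levels = c(0L, 1L))

  main <- cbind(data.frame(.treat = ds$treat, .benchmark = bench), ds$X)
  raw_main <- cv_perm_importance(main, y, rf, derive_seed(config$seed, 12L))
  norm_main <- normalize_importance(raw_main)

  ## interaction features: T * X_j, with T * benchmark as their own yardstick
  int_frame <- data.frame(.treat = ds$treat,
                          .benchmark.T = ds$treat * bench)
  feat_of <- character(0)
  for (nm in names(ds$X)) {
    col <- ds$X[[nm]]
    if (is.numeric(col)) {
      fn <- paste0(nm, ".T")
      int_frame[[fn]] <- ds$treat * col
      feat_of[fn] <- nm
    } else {
      for (lv in levels(factor(col))[-1]) {
        fn <- paste0(nm, ".", lv, ".T")
        int_frame[[fn]] <- ds$treat * as.integer(col == lv)
        feat_of[fn] <- nm
      }
    }
  }
  int_frame <- cbind(int_frame, ds$X)
  raw_int <- cv_perm_importance(int_frame, y, rf,
                                derive_seed(config$seed, 13L))
  norm_int <- normalize_importance(raw_int)
  int_imp <- vapply(names(ds$X), function(nm) {
    f <- names(feat_of)[feat_of == nm]
    if (length(f)) max(norm_int[f]) else 0
  }, numeric(1))
  bench_imp <- unname(norm_main[".benchmark"])
  bench_int <- unname(norm_int[".benchmark.T"])
  covs <- names(ds$X)
  selected <- covs[norm_main[covs] > bench_imp]
  interaction_selected <- covs[int_imp[covs] > bench_int]
  conditioning_set <- if (identical(rf$selection_rule, "main")) selected
                      else intersect(selected, interaction_selected)
  structure(
    list(importances = norm_main[covs],
         treatment_importance = unname(norm_main[".treat"]),
         benchmark_importance = bench_imp,
         interaction_importances = int_imp,
         interaction_benchmark = bench_int,
         selected = selected, interaction_selected = interaction_selected,
         conditioning_set = conditioning_set,
         selection_rule = rf$selection_rule,
         seed = config$seed, cv_folds = rf$cv_folds),
    class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  bar <- function(v) strrep("#", round(40 * max(0, min(1, v))))
  cat("Attrition importance (normalized, max = 1):\n")
  ord <- order(-x$importances)
  cat(sprintf("  %-20s %5.2f %s\n", "[treatment]", x$treatment_importance,
              bar(x$treatment_importance)))
  for (nm in names(x$importances)[ord])
    cat(sprintf("  %-20s %5.2f %s\n", nm, x$importances[[nm]],
                bar(x$importances[[nm]])))
  cat(sprintf("  %-20s %5.2f %s  <- benchmark\n", "[random benchmark]",
              x$benchmark_importance, bar(x$benchmark_importance)))
  cat(sprintf("Selected (main): %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  cat(sprintf("Selected (interaction): %s\n",
              if (length(x$interaction_selected))
                paste(x$interaction_selected, collapse = ", ") else "(none)"))
  cat(sprintf("Conditioning set (rule '%s'): %s\n", x$selection_rule,
              if (length(x$conditioning_set))
                paste(x$conditioning_set, collapse = ", ") else "(none)"))
  invisible(x)
}

## ---- conditioning tree ----------------------------------------------------

entropy2 <- function(s) {
  p <- mean(s)
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

## Best admissible binary split of `rows` on one variable. Candidates:
## midpoints between consecutive unique values (continuous; capped at a
## 64-point quantile grid) or ordered level groupings by attrition rate
## (categorical, the optimal search order for a binary outcome). A split is
## admissible only when both children keep at least `min_cell` observed
## outcomes per arm, which enforces cell feasibility at construction time.
best_split_var <- function(ds, rows, var, min_cell) {
  x <- ds$X[[var]][rows]
  s <- ds$obs[rows]; tr <- ds$treat[rows]
  h0 <- entropy2(s)
  n <- length(rows)
  admissible <- function(side) {
    min(sum(s[side & tr == 1L]), sum(s[side & tr == 0L])) >= min_cell &&
      min(sum(s[!side & tr == 1L]), sum(s[!side & tr == 0L])) >= min_cell
  }
  gain_of <- function(side) {
    nl <- sum(side)
    h0 - (nl * entropy2(s[side]) + (n - nl) * entropy2(s[!side])) / n
  }
  best <- NULL
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) < 2L) return(NULL)
    mids <- (ux[-1] + ux[-length(ux)]) / 2
    if (length(mids) > 64L)
      mids <- unique(stats::quantile(x, probs = seq_len(64L) / 65, names = FALSE))
    for (t in mids) {
      side <- x <= t
      if (!admissible(side)) next
      g <- gain_of(side)
      if (is.null(best) || g > best$gain + 1e-12)
        best <- list(var = var, type = "numeric", threshold = t,
                     levels_left = NULL, gain = g)
    }
  } else {
    xl <- as.character(x)
    lv <- names(sort(tapply(s, xl, mean)))
    if (length(lv) < 2L) return(NULL)
    for (l in seq_len(length(lv) - 1L)) {
      left_levels <- lv[seq_len(l)]
      side <- xl %in% left_levels
      if (!admissible(side)) next
      g <- gain_of(side)
      if (is.null(best) || g > best$gain + 1e-12)
        best <- list(var = var, type = "factor", threshold = NA_real_,
                     levels_left = left_levels, gain = g)
    }
  }
  best
}

split_side <- function(split, x) {
  if (split$type == "numeric") x <= split$threshold
  else as.character(x) %in% split$levels_left
}

split_label <- function(split, left) {
  if (split$type == "numeric")
    sprintf("%s %s %.4g", split$var, if (left) "<=" else ">", split$threshold)
  else
    sprintf("%s %s {%s}", split$var, if (left) "in" else "not in",
            paste(split$levels_left, collapse = ","))
}

#' Build a conditioning scheme from the selected covariates
#'
#' Steps 3-4 of the RFLB procedure: a single depth-limited classification
#' tree predicting the observation indicator from the selected covariates
#' (treatment is excluded from the splits), grown greedily on entropy gain.
#' Leaves become the discrete conditioning cells. A split is admitted only
#' when both children retain at least `tree_settings$min_cell_obs` observed
#' outcomes per arm, so every cell can support its own trimmed means; growth
#' stops at `tree_settings$max_leaves` leaves or when no admissible split
#' improves purity. Fully deterministic given the data.
#'
#' @param ds A [trial_dataset()].
#' @param report An [attrition_importance()] report with a non-empty
#'   conditioning set.
#' @param config An [analysis_config()].
#' @return An object of class `conditioning_scheme`: the split `nodes`, a
#'   `cells` table (id, rule, per-arm assigned and observed counts) and the
#'   training-row `assignment`.
#' @export
build_conditioning_scheme <- function(ds, report, config = analysis_config()) {
  vars <- report$conditioning_set
  if (!length(vars))
    stop_rflb("rflb_empty_conditioning_error",
              "conditioning set is empty; fall back to unconditional lee_bounds()")
  ts <- config$tree_settings
  nodes <- list(list(id = 1L, rows = seq_len(ds$n), split = NULL,
                     left = NA_integer_, right = NA_integer_,
                     rule = "all"))
  leaves <- 1L
  while (length(leaves) < ts$max_leaves) {
    cand <- lapply(leaves, function(nd) {
      rows <- nodes[[nd]]$rows
      bests <- lapply(vars, function(v)
        best_split_var(ds, rows, v, ts$min_cell_obs))
      bests <- bests[!vapply(bests, is.null, logical(1))]
      if (!length(bests)) return(NULL)
      bests[[which.max(vapply(bests, `[[`, numeric(1), "gain"))]]
    })
    gains <- vapply(cand, function(cc) if (is.null(cc)) -Inf else cc$gain,
                    numeric(1))
    if (all(gains <= 1e-12)) break
    pick <- which.max(gains)
    nd <- leaves[pick]; sp <- cand[[pick]]
    rows <- nodes[[nd]]$rows
    side <- split_side(sp, ds$X[[sp$var]][rows])
    lid <- length(nodes) + 1L; rid <- length(nodes) + 2L
    parent_rule <- nodes[[nd]]$rule
    join <- function(lbl) if (parent_rule == "all") lbl
                          else paste(parent_rule, "&", lbl)
    nodes[[lid]] <- list(id = lid, rows = rows[side], split = NULL,
                         left = NA_integer_, right = NA_integer_,
                         rule = join(split_label(sp, TRUE)))
    nodes[[rid]] <- list(id = rid, rows = rows[!side], split = NULL,
                         left = NA_integer_, right = NA_integer_,
                         rule = join(split_label(sp, FALSE)))
    nodes[[nd]]$split <- sp
    nodes[[nd]]$left <- lid; nodes[[nd]]$right <- rid
    leaves <- c(setdiff(leaves, nd), lid, rid)
  }
  leaves <- sort(leaves)
  cell_id <- function(leaf) sprintf("cell_%d", match(leaf, leaves))
  assignment <- character(ds$n)
  cells <- do.call(rbind, lapply(leaves, function(nd) {
    rows <- nodes[[nd]]$rows
    assignment[rows] <<- cell_id(nd)
    data.frame(cell = cell_id(nd), rule = nodes[[nd]]$rule,
               n_treated = sum(ds$treat[rows] == 1L),
               n_control = sum(ds$treat[rows] == 0L),
               obs_treated = sum(ds$obs[rows][ds$treat[rows] == 1L]),
               obs_control = sum(ds$obs[rows][ds$treat[rows] == 0L]),
               stringsAsFactors = FALSE)
  }))
  structure(list(nodes = nodes, leaves = leaves, vars = vars,
                 cells = cells, assignment = assignment,
                 settings = ts),
            class = "conditioning_scheme")
}

#' Assign rows of a dataset to conditioning cells
#'
#' Applies a fitted [build_conditioning_scheme()] tree to (possibly new)
#' data, e.g. bootstrap resamples.
#'
#' @param scheme A `conditioning_scheme`.
#' @param ds A [trial_dataset()] containing the scheme's covariates.
#' @return Character vector of cell ids, one per row.
#' @export
predict_cells <- function(scheme, ds) {
  out <- character(ds$n)
  for (i in seq_len(ds$n)) {
    nd <- 1L
    repeat {
      node <- scheme$nodes[[nd]]
      if (is.null(node$split)) break
      nd <- if (split_side(node$split, ds$X[[node$split$var]][i]))
        node$left else node$right
    }
    out[i] <- sprintf("cell_%d", match(nd, scheme$leaves))
  }
  out
}

#' @export
print.conditioning_scheme <- function(x, ...) {
  cat(sprintf("Conditioning scheme on {%s}: %d cell(s)\n",
              paste(x$vars, collapse = ", "), nrow(x$cells)))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

## ---- the full pipeline ----------------------------------------------------

#' Random Forest Lee Bounds
#'
#' The full four-step procedure: (1) a random-forest attrition model over
#' treatment, covariates and a random benchmark; (2) a cross-validated
#' permutation-importance screen, with treatment-interaction confirmation,
#' against the benchmark; (3) an entropy decision tree that discretizes the
#' selected (possibly continuous) covariates into cells; (4) cell-wise
#' conditional Lee bounds with bootstrap uncertainty. When the screen
#' selects nothing -- or the tree cannot form more than one feasible cell --
#' the procedure falls back to unconditional Lee bounds (flagged, never
#' silent): with no covariate conditioning the two coincide, so the
#' identified set is never widened.
#'
#' @param ds A [trial_dataset()] with covariates.
#' @param config An [analysis_config()].
#' @param trim_mode `"fractional"` or `"integer"`.
#' @param ci Compute bootstrap standard errors and the outer confidence
#'   interval (default `TRUE`; skip for speed in simulation studies).
#' @return An object of class `rflb_result`: `$bounds` (a `bounds_result`
#'   with `method = "rflb"`), `$importance` (the screen report), `$scheme`
#'   (the conditioning tree, `NULL` on fallback) and `$fallback`.
#' @export
rflb_bounds <- function(ds, config = analysis_config(),
                        trim_mode = c("fractional", "integer"), ci = TRUE) {
  trim_mode <- match.arg(trim_mode)
  if (anyNA(ds$X))
    ds <- apply_covariate_missing_policy(ds, config$covariate_missing_policy)
  report <- attrition_importance(ds, config)
  scheme <- NULL
  fallback <- length(report$conditioning_set) == 0L
  if (!fallback) {
    scheme <- build_conditioning_scheme(ds, report, config)
    if (nrow(scheme$cells) < 2L) {
      scheme <- NULL
      fallback <- TRUE
    }
  }
  if (fallback) {
    message("RFLB: no covariate passed the benchmark screen with a feasible partition; falling back to unconditional Lee bounds")
    bounds <- if (ci) bounds_ci(ds, "lee", config, trim_mode = trim_mode)
              else lee_bounds(ds, trim_mode)
  } else {
    cells <- scheme$assignment
    bounds <- if (ci) bounds_ci(ds, "lee-conditional", config, cells = cells,
                                trim_mode = trim_mode)
              else conditional_lee_bounds(ds, cells, trim_mode)
  }
  bounds$method <- "rflb"
  bounds$fallback <- fallback
  structure(list(bounds = bounds, importance = report, scheme = scheme,
                 fallback = fallback),
            class = "rflb_result")
}

#' @export
print.rflb_result <- function(x, ...) {
  print(x$importance)
  if (!is.null(x$scheme)) print(x$scheme)
  print(x$bounds)
  invisible(x)
}

#' Export importance-graph data
#'
#' Writes the normalized importance bars (sorted descending, benchmark
#' marked) as JSON or CSV for plotting; `format = "json"` round-trips the
#' report values exactly.
#'
#' @param report An `importance_report`.
#' @param path Destination path.
#' @param format `"json"` or `"csv"`.
#' @param include_treatment Include the treatment indicator bar? Only
#'   background characteristics are candidates for tightening, so graphs for
#'   conditioning decisions typically exclude it.
#' @return Invisibly, `path`.
#' @export
export_importance_graph <- function(report, path, format = c("json", "csv"),
                                    include_treatment = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(report, "importance_report"))
  bars <- data.frame(
    variable = c(if (include_treatment) "[treatment]",
                 names(report$importances), "[random benchmark]"),
    importance = c(if (include_treatment) report$treatment_importance,
                   unname(report$importances), report$benchmark_importance),
    benchmark = c(if (include_treatment) FALSE,
                  rep(FALSE, length(report$importances)), TRUE),
    stringsAsFactors = FALSE)
  bars <- bars[order(-bars$importance), ]
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(bars, path, row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(bars = bars,
             importances = as.list(report$importances),
             treatment_importance = report$treatment_importance,
             benchmark_importance = report$benchmark_importance,
             interaction_importances = as.list(report$interaction_importances),
             interaction_benchmark = report$interaction_benchmark,
             selected = report$selected,
             interaction_selected = report$interaction_selected,
             conditioning_set = report$conditioning_set),
        path, auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_rflb("rflb_io_error", "cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Plot an importance graph
#'
#' Horizontal bar chart of normalized importances with the random benchmark
#' marked, in the style of an attrition importance graph.
#'
#' @param report An `importance_report`.
#' @param include_treatment Include the treatment bar?
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar data.
#' @export
plot_importance <- function(report, include_treatment = TRUE, ...) {
  vars <- c(if (include_treatment) "[treatment]",
            names(report$importances), "[random benchmark]")
  vals <- c(if (include_treatment) report$treatment_importance,
            unname(report$importances), report$benchmark_importance)
  ord <- order(vals)
  cols <- ifelse(vars[ord] == "[random benchmark]", "firebrick", "grey40")
  graphics::barplot(vals[ord], names.arg = vars[ord], horiz = TRUE,
                    las = 1, col = cols, xlim = c(0, 1),
                    xlab = "normalized importance", ...)
  invisible(data.frame(variable = vars, importance = vals))
}
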