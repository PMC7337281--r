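#' Construct a trial dataset
#'
#' The universal input container of the package: one row per randomized
#' participant, holding the (possibly missing) endpoint outcome, the binary
#' treatment assignment, and baseline covariates. The observation indicator
#' `S` is derived from outcome missingness and is, by construction, 1 exactly
#' when the outcome is present.
#'
#' Covariates are baseline (pre-assignment) quantities by contract: nothing in
#' the package ever derives a covariate from the outcome.
#'
#' @param outcome Numeric vector of trial outcomes; `NA` marks an unobserved
#'   (attrited) outcome.
#' @param treatment Vector codable to {0,1}: numeric 0/1, logical, or a
#'   two-level factor/character together with `treated_level`.
#' @param covariates Optional `data.frame` of baseline covariates (continuous
#'   or factor), one row per participant; entries may be missing.
#' @param id Optional vector of unique participant labels; generated when
#'   omitted.
#' @param treated_level For factor/character `treatment`, the level that
#'   denotes the treated arm. Never inferred from the data: a silent arm flip
#'   would invert every bound.
#'
#' @return An object of class `trial_dataset`: a list with elements `id`,
#'   `y`, `treat`, `obs` (the indicator `S`), `X` (covariate data.frame) and
#'   `n`.
#' @export
#' @examples
#' ds <- trial_dataset(outcome = c(5, NA, 3, 7),
#'                     treatment = c(1, 1, 0, 0))
#' sum(ds$obs)  # 3 observed outcomes
trial_dataset <- function(outcome, treatment, covariates = NULL, id = NULL,
                          treated_level = NULL) {
  n <- length(outcome)
  treat <- code_treatment(treatment, treated_level)
  if (length(treat) != n)
    stop_rflb("rflb_validation_error", "outcome and treatment lengths differ")
  if (sum(treat == 1L) == 0L || sum(treat == 0L) == 0L)
    stop_rflb("rflb_degenerate_design_error", "both arms must be non-empty")
  if (is.null(id)) id <- sprintf("P%0*d", nchar(n), seq_len(n))
  id <- as.character(id)
  if (length(id) != n)
    stop_rflb("rflb_validation_error", "id length differs from outcome length")
  if (anyDuplicated(id))
    stop_rflb("rflb_validation_error", "duplicate participant_id: %s",
              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop_rflb("rflb_validation_error", "covariate row count differs from outcome length")
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
  }
  rownames(covariates) <- NULL
  structure(
    list(id = id, y = as.numeric(outcome), treat = treat,
         obs = as.integer(!is.na(outcome)), X = covariates, n = n),
    class = "trial_dataset"
  )
}

code_treatment <- function(treatment, treated_level = NULL) {
  if (is.logical(treatment)) return(as.integer(treatment))
  if (is.numeric(treatment)) {
    bad <- setdiff(unique(treatment), c(0, 1))
    if (length(bad))
      stop_rflb("rflb_coding_error",
                "unmappable treatment codes: %s (expected 0/1)",
                paste(bad, collapse = ", "))
    return(as.integer(treatment))
  }
  lev <- unique(as.character(treatment))
  lev <- lev[!is.na(lev)]
  if (length(lev) != 2L)
    stop_rflb("rflb_coding_error",
              "treatment must have exactly two levels, found: %s",
              paste(lev, collapse = ", "))
  if (is.null(treated_level))
    stop_rflb("rflb_coding_error",
              "treated_level is required for factor/character treatment (levels: %s); the treated arm is never inferred",
              paste(lev, collapse = ", "))
  if (!treated_level %in% lev)
    stop_rflb("rflb_coding_error", "treated_level '%s' not among levels %s",
              treated_level, paste(lev, collapse = ", "))
  as.integer(as.character(treatment) == treated_level)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Two-arm trial dataset: %d participants (%d treated / %d control)\n",
              x$n, sum(x$treat == 1), sum(x$treat == 0)))
  cat(sprintf("Observed outcomes: %d treated, %d control; covariates: %s\n",
              sum(x$obs[x$treat == 1]), sum(x$obs[x$treat == 0]),
              if (ncol(x$X)) paste(names(x$X), collapse = ", ") else "(none)"))
  invisible(x)
}

#' @export
as.data.frame.trial_dataset <- function(x, ...) {
  cbind(data.frame(id = x$id, y = x$y, treat = x$treat,
                   stringsAsFactors = FALSE),
        x$X)
}

covariate_names <- function(ds) names(ds$X)

## Row subset preserving validity; ids de-duplicated for bootstrap resamples.
subset_trial <- function(ds, idx) {
  trial_dataset(outcome = ds$y[idx], treatment = ds$treat[idx],
                covariates = if (ncol(ds$X)) ds$X[idx, , drop = FALSE] else NULL,
                id = make.unique(ds$id[idx], sep = "#"))
}

#' Read a trial table from delimited text or a Stata file
#'
#' Delimited input is CSV with a header row; empty fields and `"NA"` are both
#' read as missing outcomes. The Stata dialect is a thin adapter over
#' [foreign::read.dta()]; value labels become factor levels.
#'
#' @param path Path to the file.
#' @param column_map Named list mapping roles to column names:
#'   `outcome`, `treatment`, optional `id`, optional `covariates` (character
#'   vector; defaults to all remaining columns), optional `treated_level`
#'   (required when the treatment column is not coded 0/1).
#' @param dialect `"delimited"` (default) or `"stata"`.
#' @return A validated [trial_dataset()].
#' @export
read_trial_table <- function(path,
                             column_map = list(outcome = "y", treatment = "treat"),
                             dialect = c("delimited", "stata")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_rflb("rflb_io_error", "file not found: %s", path)
  df <- switch(dialect,
    delimited = utils::read.csv(path, na.strings = c("", "NA"),
                                stringsAsFactors = FALSE),
    stata = foreign::read.dta(path, convert.factors = TRUE)
  )
  need <- c(column_map$outcome, column_map$treatment, column_map$id,
            column_map$covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_rflb("rflb_validation_error", "mapped columns absent from table: %s",
              paste(missing_cols, collapse = ", "))
  covs <- column_map$covariates
  if (is.null(covs))
    covs <- setdiff(names(df), c(column_map$outcome, column_map$treatment,
                                 column_map$id))
  trial_dataset(
    outcome = df[[column_map$outcome]],
    treatment = df[[column_map$treatment]],
    covariates = if (length(covs)) df[covs] else NULL,
    id = if (!is.null(column_map$id)) df[[column_map$id]] else NULL,
    treated_level = column_map$treated_level
  )
}

#' Write a trial table as delimited text
#'
#' Writes CSV with a header row; missing outcomes are written as empty
#' fields. `read_trial_table()` on the result reproduces the dataset.
#'
#' @param ds A [trial_dataset()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_trial_table <- function(ds, path) {
  ok <- tryCatch({
    utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_rflb("rflb_io_error", "cannot write %s: %s", path,
              conditionMessage(ok))
  invisible(path)
}

#' Resolve missing covariate values
#'
#' The missing-indicator policy gives each covariate with any missing value a
#' companion 0/1 indicator column (`<name>_missing`) and fills the holes with
#' the covariate's observed mean (continuous) or a dedicated `"(missing)"`
#' level (categorical); the indicator carries the missingness information.
#' The drop-row policy removes every row with any missing covariate and
#' reports the count.
#'
#' @param ds A [trial_dataset()].
#' @param policy `"missing-indicator"` (default) or `"drop-row"`.
#' @return A [trial_dataset()] with complete covariates.
#' @export
apply_covariate_missing_policy <- function(ds,
    policy = c("missing-indicator", "drop-row")) {
  policy <- match.arg(policy)
  X <- ds$X
  if (!ncol(X) || !anyNA(X)) return(ds)
  all_missing <- vapply(X, function(col) all(is.na(col)), logical(1))
  if (any(all_missing))
    stop_rflb("rflb_config_error", "covariate(s) entirely missing: %s",
              paste(names(X)[all_missing], collapse = ", "))
  if (policy == "drop-row") {
    keep <- stats::complete.cases(X)
    message(sprintf("drop-row policy removed %d of %d rows", sum(!keep), ds$n))
    return(subset_trial(ds, which(keep)))
  }
  for (nm in names(X)) {
    col <- X[[nm]]
    if (!anyNA(col)) next
    ind <- as.integer(is.na(col))
    if (is.numeric(col)) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
    } else {
      col <- factor(col, levels = c(levels(col), "(missing)"))
      col[is.na(col)] <- "(missing)"
    }
    X[[nm]] <- col
    X[[paste0(nm, "_missing")]] <- ind
  }
  out <- ds
  out$X <- X
  out
}
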