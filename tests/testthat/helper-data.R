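# Fixture builders shared across test files; everything is generated in code.

# 4 control (all observed) vs 4 treated (2 observed): trim share 0.5,
# hand-computable Lee bounds [11.5, 13.5].
toy_lee_trial <- function() {
  trial_dataset(outcome = c(1, 2, 3, 4, 10, 20, NA, NA),
                treatment = c(0, 0, 0, 0, 1, 1, 1, 1))
}

# Bounded-support trial for containment properties against worst-case
# bounds: outcomes are scores on an instrument whose logical range [0, 100]
# strictly contains the observed spread (scores rarely hit a scale's
# extremes), which is the regime in which worst-case bounds are used.
rand_bounded_trial <- function(seed, n_per_arm = 40) {
  with_seed_local(seed, {
    n <- 2 * n_per_arm
    treat <- rep(c(1L, 0L), each = n_per_arm)
    y <- runif(n, 20, 80)
    p_obs <- ifelse(treat == 1L, runif(1, 0.5, 0.95), runif(1, 0.5, 0.95))
    s <- rbinom(n, 1, p_obs)
    # guarantee both arms keep observed outcomes
    s[c(1, n_per_arm + 1)] <- 1L
    y[s == 0L] <- NA
    trial_dataset(outcome = y, treatment = treat)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force trimmed-mean oracle: expand each observation into 1,000
# equal-mass atoms and discard exactly p of the total mass from the tail
# (whole atoms plus a fractional piece of the straddling atom).
trimmed_mean_oracle <- function(x, p, tail) {
  atoms <- rep(sort(x), each = 1000L)
  if (tail == "upper") atoms <- rev(atoms)
  N <- length(atoms)
  k <- p * N
  w <- numeric(N)
  for (i in seq_len(N)) w[i] <- min(max(i - k, 0), 1)
  sum(w * atoms) / sum(w)
}

# Small analysis config for unit tests that exercise the forest machinery
# without needing full-size ensembles.
fast_config <- function(seed = 1L, ...) {
  analysis_config(seed = seed, n_bootstrap = 50L,
                  rf_settings = list(num_trees = 150L, cv_folds = 3L,
                                     n_perm = 2L), ...)
}

# Minimal importance report carrying just a conditioning set, for driving
# the tree builder directly.
fake_report <- function(vars) {
  structure(list(conditioning_set = vars), class = "importance_report")
}
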