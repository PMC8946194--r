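# Small shared fixtures; everything is generated in code at test time.

small_spec <- function(n_participants = 2, rng_seed = 42L, ...) {
  design_spec(n_participants = n_participants, rng_seed = rng_seed, ...)
}

# A one-condition cohort with the default clock cells, small enough for
# fast unit tests but with every (task, interval) cell populated.
small_cohort <- function(n_participants = 4, seed = 7L,
                         conditions = "sitting", ...) {
  d <- generate_design(design_spec(n_participants = n_participants,
                                   conditions = conditions,
                                   rng_seed = seed, ...))
  linear_clock_model(d, seed = seed + 1L)
}

# Identity clock: e = d exactly, no noise, no contamination.
identity_params <- function() {
  cp <- default_clock_params(cv = 0, outlier_rate = 0)
  cp$offset <- 0
  cp$gain <- 1
  cp
}

# Brute-force Walsh-average pseudomedian (independent oracle).
hl_oracle <- function(x) {
  w <- c()
  for (i in seq_along(x)) {
    for (j in i:length(x)) w <- c(w, (x[i] + x[j]) / 2)
  }
  median(w)
}

# Brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments (independent oracle, n <= ~14).
wilcoxon_oracle_p <- function(x, mu0 = 0) {
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}
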