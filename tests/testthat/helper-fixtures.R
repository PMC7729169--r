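# Shared toy-data builders for the test suite.

# Balanced two-factor table with optional planted main/interaction effects
# and Gaussian noise; factors A (a levels) x B (b levels) x nrep replicates.
toy_factorial <- function(a = 2, b = 3, nrep = 6, main_a = 0, main_b = 0,
                          inter = 0, sd = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(A = factor(seq_len(a)), B = factor(seq_len(b)),
                   rep = seq_len(nrep))
  mu <- main_a * as.integer(g$A) + main_b * as.integer(g$B) +
    inter * as.integer(g$A) * as.integer(g$B)
  g$y <- mu + rnorm(nrow(g), 0, sd)
  g
}

# Continuous-input regression table with independent uniform inputs.
toy_regression <- function(n = 80, k = 5, seed = 1, fun = function(X) 3 * X[, 1],
                           sd = 0.01) {
  set.seed(seed)
  X <- matrix(runif(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  d <- as.data.frame(X)
  d$y <- fun(X) + rnorm(n, 0, sd)
  d
}

# Independent ridge solve (plain base R), used as an oracle against
# fit_weights and in the exhaustive-enumeration tests.
oracle_ridge <- function(X, y, lambda) {
  solve(t(X) %*% X + lambda * diag(ncol(X)), t(X) %*% y)[, 1]
}

# Independent MDL score of a submodel-structure candidate, with the same
# coefficient bookkeeping (intercept absorbed from the second block on).
oracle_mdl <- function(mse, p, n) (n / 2) * log(mse) + (p / 2) * log(n)
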