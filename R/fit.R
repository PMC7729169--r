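#' Ridge-regularized least-squares weights
#'
#' Minimizes ||y - Xw||^2 + ridge * ||w||^2. The tiny default ridge (1e-6)
#' makes the tensor-product design solvable even though each submodel block
#' spans the constant function (the normal-equations matrix is otherwise
#' rank-deficient by one per extra submodel).
#'
#' @param X design matrix.
#' @param y response vector.
#' @param ridge_factor ridge penalty (> 0).
#' @return weight vector of length ncol(X).
#' @export
fit_weights <- function(X, y, ridge_factor = 1e-6) {
  stopifnot(nrow(X) == length(y), ridge_factor > 0)
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + ridge_factor
  drop(solve(XtX, crossprod(X, y)))
}

#' Fit-quality statistics of a trained submodel set
#'
#' MSE is the mean squared prediction error; Train-Set R2 is the percentage
#' of response variance explained. The f-ratio is the regression mean square
#' over the residual mean square, `(R2/df1) / ((100 - R2)/df2)` with
#' df1 = p - 1 and df2 = n - p, compared against the F critical value at
#' `alpha`. The quality gate accepts models with R2 > 70% and f-ratio above
#' both 4 and the critical value, and rejects R2 > 99.9% as over-fitting.
#'
#' @param y observed response.
#' @param y_pred model predictions (same length).
#' @param p number of model coefficients (see [asmod_search()] bookkeeping).
#' @param alpha significance level for the F comparison (default 0.05).
#' @return a `fit_stats` list: `n`, `p`, `mse`, `r2_percent`, `f_ratio`,
#'   `df1`, `df2`, `f_critical`, `quality`.
#' @export
fit_stats <- function(y, y_pred, p, alpha = 0.05) {
  n <- length(y)
  stopifnot(length(y_pred) == n)
  if (n <= p) stop("insufficient-df: need n > p (n = ", n, ", p = ", p, ")")
  sse <- sum((y - y_pred)^2)
  sst <- sum((y - mean(y))^2)
  mse <- sse / n
  if (sst == 0) stop("degenerate-response: constant y")
  r2 <- (1 - sse / sst) * 100
  df1 <- p - 1
  df2 <- n - p
  f_ratio <- if (r2 >= 100) Inf else (r2 / df1) / ((100 - r2) / df2)
  fc <- f_critical(alpha, max(df1, 1), df2)
  quality <- if (r2 > 99.9) "rejected_overfit"
             else if (r2 > 70 && f_ratio > 4 && f_ratio > fc) "accepted"
             else "rejected_low"
  structure(list(n = n, p = p, mse = mse, r2_percent = r2, f_ratio = f_ratio,
                 df1 = df1, df2 = df2, f_critical = fc, quality = quality),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("MSE %.4g | Train Set R2 %.2f%% | f ratio %.2f | df %d, %d | f crit %.2f | %s\n",
              x$mse, x$r2_percent, x$f_ratio, x$df1, x$df2, x$f_critical, x$quality))
  invisible(x)
}

#' Model-selection criterion score
#'
#' Lower is better for every criterion. `SRM` uses the guaranteed-risk bound
#' `MSE / (1 - sqrt(eps))` with `eps = C1 * (p * (ln(2n/p) + 1) + C2) / n`,
#' returning `+Inf` when the capacity term reaches or exceeds 1 (the model is
#' too complex for the sample); the denominator is floored at 1e-6. `MDL` is
#' `(n/2) ln MSE + (p/2) ln n`, `BIC` is `n ln MSE + p ln n`. The
#' resampling criteria `CV` (k-fold) and `LOOCV` need the design matrix and
#' response and score held-out MSE.
#'
#' @param mse training mean squared error.
#' @param p coefficient count.
#' @param n number of observations.
#' @param config a [training_config()].
#' @param X,y design matrix and response; required for `CV`/`LOOCV`.
#' @param folds optional integer fold assignment for `CV` (computed seeded
#'   from `config$random_seed`, stratified if a `strata` factor is given).
#' @param strata optional stratification factor for fold assignment.
#' @return numeric score.
#' @export
criterion_score <- function(mse, p, n, config = training_config(),
                            X = NULL, y = NULL, folds = NULL, strata = NULL) {
  stopifnot(n > 0, p >= 1)
  switch(config$model_selection,
    SRM = {
      eps <- config$srm_c1 * (p * (log(2 * n / p) + 1) + config$srm_c2) / n
      denom <- 1 - sqrt(eps)
      if (denom <= 0) Inf else mse / max(denom, 1e-6)
    },
    MDL = (n / 2) * log(mse) + (p / 2) * log(n),
    BIC = n * log(mse) + p * log(n),
    CV = {
      if (is.null(X) || is.null(y)) stop("CV criterion needs X and y")
      if (p >= n) stop("infeasible-fold: p >= n")
      if (is.null(folds)) folds <- make_folds(n, config$cv_folds, strata,
                                              config$random_seed)
      err <- 0
      for (f in sort(unique(folds))) {
        tr <- folds != f
        w <- fit_weights(X[tr, , drop = FALSE], y[tr], config$ridge_factor)
        err <- err + sum((y[!tr] - X[!tr, , drop = FALSE] %*% w)^2)
      }
      err / n
    },
    LOOCV = {
      if (is.null(X) || is.null(y)) stop("LOOCV criterion needs X and y")
      if (p >= n) stop("infeasible-fold: p >= n")
      XtX <- crossprod(X)
      diag(XtX) <- diag(XtX) + config$ridge_factor
      H <- X %*% solve(XtX, t(X))
      h <- pmin(diag(H), 1 - 1e-8)
      res <- (y - H %*% y) / (1 - h)
      mean(res^2)
    })
}

# Seeded, optionally stratified k-fold assignment (balanced within strata).
make_folds <- function(n, k, strata = NULL, seed = 1L) {
  rs <- sample_with_seed(seed, function() {
    folds <- integer(n)
    if (is.null(strata)) strata <- factor(rep(1, n))
    for (s in levels(factor(strata))) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
  rs
}

# Run fn() under a local RNG state seeded with `seed`, restoring the global
# state afterwards, so training perturbs no user RNG stream.
sample_with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
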