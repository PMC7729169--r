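#' Factorial ANOVA for a treatment table
#'
#' Fixed-effects factorial decomposition of one response over the design
#' factors, with p-values from the F distribution. Sequential (Type I) sums
#' of squares are used; on the balanced full-factorial designs this package
#' targets they coincide with Type III.
#'
#' @param table data frame with factor and response columns.
#' @param response name of the response column.
#' @param factors character vector of factor column names.
#' @param interactions logical: include all interactions among `factors`
#'   (`TRUE`, the default) or main effects only.
#' @return data frame with one row per term (plus residuals): `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`. Attribute `degenerate` is set
#'   when the response is constant.
#' @export
factorial_anova <- function(table, response, factors = c("genotype", "subculture", "medium"),
                            interactions = TRUE) {
  if (!response %in% names(table)) stop("missing-column: response '", response, "' not in table")
  missing_f <- setdiff(factors, names(table))
  if (length(missing_f)) stop("missing-column: ", paste(missing_f, collapse = ", "))
  y <- table[[response]]
  for (f in factors) {
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2) stop("factor '", f, "' needs >= 2 levels")
  }
  if (stats::var(y) == 0) {
    out <- data.frame(term = factors, df = NA_integer_, sumsq = 0, meansq = 0,
                      statistic = NA_real_, p.value = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  op <- if (interactions) "*" else "+"
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = op)))
  fit <- stats::aov(fml, data = table)
  sm <- summary(fit)[[1]]
  nt <- nrow(sm)
  fv <- if (is.null(sm[["F value"]])) rep(NA_real_, nt) else sm[["F value"]]
  pv <- if (is.null(sm[["Pr(>F)"]])) rep(NA_real_, nt) else sm[["Pr(>F)"]]
  out <- data.frame(term = trimws(rownames(sm)), df = sm[["Df"]],
                    sumsq = sm[["Sum Sq"]], meansq = sm[["Mean Sq"]],
                    statistic = fv, p.value = pv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}

#' Tukey HSD compact letter display
#'
#' Groups are compared pairwise with the studentized-range (Tukey HSD)
#' criterion at level `alpha` on the pooled one-way residual mean square,
#' then letters are assigned by a greedy insert-absorb sweep over groups
#' ordered by mean: groups sharing no letter differ significantly.
#'
#' @param table data frame.
#' @param response response column name.
#' @param grouping one or more grouping column names (crossed if several).
#' @param alpha significance level (default 0.01 as in factorial screens).
#' @return data frame `group`, `mean`, `n`, `letters`, ordered by mean.
#' @export
tukey_hsd <- function(table, response, grouping, alpha = 0.01) {
  if (!response %in% names(table)) stop("missing-column: ", response)
  g <- interaction(table[grouping], sep = ":", drop = TRUE)
  y <- table[[response]]
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  k <- length(means)
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  if (k == 1)
    return(data.frame(group = names(means), mean = as.numeric(means),
                      n = as.integer(ns), letters = "a", stringsAsFactors = FALSE))
  df_err <- length(y) - k
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_err
  # significance matrix from the studentized range distribution
  sig <- matrix(FALSE, k, k)
  if (mse > 0) {
    qcrit <- stats::qtukey(1 - alpha, k, df_err)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) / se > qcrit
    }
  } else {
    sig[] <- outer(means, means, function(a, b) abs(a - b) > 0)
    diag(sig) <- FALSE
  }
  letters_for <- cld_insert_absorb(sig)
  data.frame(group = names(means), mean = as.numeric(means), n = as.integer(ns),
             letters = letters_for, stringsAsFactors = FALSE)
}

# Greedy insert-absorb compact letter display over a symmetric significance
# matrix whose rows/cols are ordered by group mean. Each letter is a maximal
# run of mean-consecutive groups containing no significant pair; runs
# contained in another run are absorbed. Ties are broken by group order.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  run_end <- function(i) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    j
  }
  runs <- unique(lapply(seq_len(k), function(i) i:run_end(i)))
  contained <- vapply(seq_along(runs), function(a)
    any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[!contained]
  runs <- runs[order(vapply(runs, min, numeric(1)))]
  labs <- rep(letters, length.out = length(runs))
  vapply(seq_len(k), function(g)
    paste0(labs[vapply(runs, function(r) g %in% r, logical(1))], collapse = ""),
    character(1))
}

#' Upper-alpha critical value of the F distribution
#'
#' @param alpha tail probability (0 < alpha < 1).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return the upper-`alpha` quantile of F(df1, df2), unrounded (reports
#'   round it to two decimals).
#' @export
f_critical <- function(alpha, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("invalid-df: df1 and df2 must be >= 1")
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must lie in (0, 1)")
  stats::qf(1 - alpha, df1, df2)
}

#' Normality and homoscedasticity checks
#'
#' Kolmogorov-Smirnov test on the (group-centred, standardised) residuals and
#' Levene's test of equal variances across groups.
#'
#' @param table data frame.
#' @param response response column name.
#' @param grouping grouping column name(s) for Levene and residual centring.
#' @return list with elements `normality` (statistic, p.value, method) and
#'   `homoscedasticity` (statistic, p.value, method); `degenerate = TRUE`
#'   replaces both when the response is constant.
#' @export
distribution_checks <- function(table, response, grouping = "genotype") {
  y <- table[[response]]
  if (is.null(y)) stop("missing-column: ", response)
  if (length(y) < 3) stop("need >= 3 observations")
  g <- interaction(table[grouping], sep = ":", drop = TRUE)
  if (nlevels(g) < 2) stop("invalid-grouping: Levene needs >= 2 groups")
  if (stats::var(y) == 0) return(list(degenerate = TRUE))
  res <- y - stats::ave(y, g)
  s <- stats::sd(res)
  ks <- suppressWarnings(stats::ks.test(res / s, "pnorm"))
  lv <- car::leveneTest(y, g)
  list(
    degenerate = FALSE,
    normality = list(statistic = unname(ks$statistic), p.value = ks$p.value,
                     method = "Kolmogorov-Smirnov"),
    homoscedasticity = list(statistic = lv[["F value"]][1],
                            p.value = lv[["Pr(>F)"]][1], method = "Levene")
  )
}
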