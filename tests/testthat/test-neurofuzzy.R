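make_cont_basis <- function(peaks) list(kind = "continuous", input = "x", peaks = peaks)

test_that("order-2 B-spline activations reproduce the triangular endpoints", {
  sm <- nutrifuzz:::new_submodel(list(make_cont_basis(c(0, 1))))
  A <- basis_activations(sm, data.frame(x = c(0, 1, 0.5)))
  expect_equal(A, rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  sm3 <- nutrifuzz:::new_submodel(list(make_cont_basis(c(0, 0.5, 1))))
  expect_equal(basis_activations(sm3, data.frame(x = 0.25))[1, ], c(0.5, 0.5, 0))
  cat3 <- nutrifuzz:::new_submodel(list(list(kind = "categorical", input = "g",
                                             levels = c("a", "b", "c"))))
  expect_equal(basis_activations(cat3, data.frame(g = "b"))[1, ], c(0, 1, 0))
})

test_that("activations are a partition of unity, including tensor products", {
  set.seed(41)
  for (i in 1:10) {
    peaks <- sort(unique(c(0, runif(sample(0:6, 1)), 1)))
    x <- runif(50)
    sm <- nutrifuzz:::new_submodel(list(make_cont_basis(peaks)))
    expect_equal(rowSums(basis_activations(sm, data.frame(x = x))),
                 rep(1, 50), tolerance = 1e-12)
  }
  # tensor of continuous x continuous x categorical
  sm <- nutrifuzz:::new_submodel(list(
    make_cont_basis(c(0, 0.3, 1)),
    list(kind = "continuous", input = "z", peaks = c(0, 0.5, 0.75, 1)),
    list(kind = "categorical", input = "g", levels = c("a", "b"))))
  d <- data.frame(x = runif(30), z = runif(30), g = sample(c("a", "b"), 30, TRUE))
  expect_equal(rowSums(basis_activations(sm, d)), rep(1, 30), tolerance = 1e-12)
})

test_that("input normalization maps the observed range onto [0, 1]", {
  tab <- build_factor_table(c("BD", "BH"), ms_media_table(), 1:2)
  specs <- input_specs(tab, c("genotype", "NH4"))
  nt <- normalize_inputs(tab, specs)
  expect_equal(min(nt$NH4), 0)
  expect_equal(max(nt$NH4), 1)
  # NH4 at half its maximum maps to 0.5 (its minimum is 0)
  mid <- tab[which.min(abs(tab$NH4 - max(tab$NH4) / 2))[1], ]
  expect_equal(normalize_inputs(mid, specs)$NH4, 0.5, tolerance = 0.01)
  tab$const <- 5
  expect_warning(sp2 <- input_specs(tab, c("const", "NH4")), "constant")
  expect_named(sp2, "NH4")
})

test_that("ridge weights match least squares in the small-ridge limit", {
  set.seed(51)
  X <- cbind(1, matrix(rnorm(200), 50, 4))
  beta <- c(2, -1, 0.5, 3, 0)
  y <- drop(X %*% beta)
  w <- fit_weights(X, y, 1e-10)
  expect_equal(max(abs(X %*% w - y)), 0, tolerance = 1e-6)
  expect_equal(w, unname(coef(lm(y ~ X - 1))), tolerance = 1e-5)
  expect_equal(fit_weights(X, rep(0, 50), 1e-6), rep(0, 5), tolerance = 1e-9)
  # agrees with an independent ridge solve at moderate ridge
  yn <- y + rnorm(50)
  expect_equal(fit_weights(X, yn, 0.3), oracle_ridge(X, yn, 0.3), tolerance = 1e-10)
})

test_that("fit statistics reproduce the published SL-row bookkeeping", {
  set.seed(61)
  y <- rnorm(108)
  # construct predictions with an exact explained-variance fraction
  r2_target <- 74.97
  cc <- 1 - sqrt(1 - r2_target / 100)
  y_pred <- mean(y) + cc * (y - mean(y))
  st <- fit_stats(y, y_pred, p = 8)
  expect_equal(st$r2_percent, 74.97, tolerance = 1e-10)
  expect_equal(st$df1, 7)
  expect_equal(st$df2, 100)
  expect_equal(round(st$f_ratio, 2), 42.79)
  expect_equal(round(st$f_critical, 2), 2.10)
  expect_equal(st$quality, "accepted")
  # perfect fit is flagged as over-fitting; mean-only prediction gives R2 = 0
  expect_equal(fit_stats(y, y, p = 8)$quality, "rejected_overfit")
  expect_equal(fit_stats(y, rep(mean(y), 108), p = 8)$r2_percent, 0)
  expect_error(fit_stats(y[1:5], y[1:5] * 0.9, p = 8), "insufficient-df")
})

test_that("SRM criterion matches direct arithmetic and is monotone in p", {
  cfg <- training_config()
  # independent hand evaluation of the stated guaranteed-risk formula
  eps <- 0.95 * (8 * (log(2 * 108 / 8) + 1) + 4.8) / 108
  expect_equal(criterion_score(1, 8, 108, cfg), 1 / (1 - sqrt(eps)), tolerance = 1e-12)
  scores <- vapply(1:30, function(p) criterion_score(1, p, 108, cfg), numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_equal(criterion_score(0, 17, 108, cfg), 0)
  # capacity term at or beyond 1 yields an infinite score
  expect_identical(criterion_score(1, 90, 108, cfg), Inf)
  # MDL and BIC closed forms
  mdl <- training_config(model_selection = "MDL")
  bic <- training_config(model_selection = "BIC")
  expect_equal(criterion_score(2, 5, 40, mdl), 20 * log(2) + 2.5 * log(40))
  expect_equal(criterion_score(2, 5, 40, bic), 40 * log(2) + 5 * log(40))
  expect_error(criterion_score(1, 5, 40, training_config(model_selection = "CV")),
               "needs X and y")
})

test_that("LOOCV closed form matches explicit leave-one-out refits", {
  set.seed(71)
  X <- cbind(1, matrix(runif(60), 20, 3))
  y <- rnorm(20)
  cfg <- training_config(model_selection = "LOOCV", ridge_factor = 1e-4)
  fast <- criterion_score(mean(y^2), 4, 20, cfg, X = X, y = y)
  slow <- mean(vapply(1:20, function(i) {
    w <- oracle_ridge(X[-i, ], y[-i], 1e-4)
    (y[i] - sum(X[i, ] * w))^2
  }, numeric(1)))
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("inserting a node never increases the training MSE", {
  set.seed(81)
  d <- data.frame(x = runif(60))
  y <- sin(2 * pi * d$x)
  mse_of <- function(peaks) {
    sm <- nutrifuzz:::new_submodel(list(make_cont_basis(peaks)))
    X <- cbind(1, basis_activations(sm, d))
    w <- fit_weights(X, y, 1e-8)
    mean((y - X %*% w)^2)
  }
  peaks <- c(0, 1)
  prev <- mse_of(peaks)
  for (i in 1:6) {
    widths <- diff(peaks)
    w <- which.max(widths)
    peaks <- sort(c(peaks, (peaks[w] + peaks[w + 1]) / 2))
    cur <- mse_of(peaks)
    expect_lte(cur, prev + 1e-10)
    prev <- cur
  }
})
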