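test_that("parameter bookkeeping reproduces the published df pairs", {
  geno <- list(kind = "categorical", input = "genotype", levels = c("BD", "BH", "BT"))
  subc <- list(kind = "categorical", input = "subculture", levels = as.character(1:4))
  b2 <- function(nm) list(kind = "continuous", input = nm, peaks = c(0, 1))
  b3 <- function(nm) list(kind = "continuous", input = nm, peaks = c(0, 0.5, 1))
  sm <- nutrifuzz:::new_submodel
  p <- nutrifuzz:::model_p
  # genotype(3) x Cu(2) plus NH4(2): p = 8 -> df 7, 100 at n = 108
  expect_equal(p(list(sm(list(geno, b2("Cu"))), sm(list(b2("NH4"))))), 8)
  # genotype(3) x SO4(2) x MoO4(3) plus subculture(4) x Na(2): p = 26 -> 25, 82
  expect_equal(p(list(sm(list(geno, b2("SO4"), b3("MoO4"))),
                      sm(list(subc, b2("Na"))))), 26)
  # single submodel keeps its explicit bias: genotype(3) x NH4(2) -> p = 7
  expect_equal(p(list(sm(list(geno, b2("NH4"))))), 7)
  expect_equal(p(list()), 1)
})

test_that("search recovers a planted univariate effect without spurious inputs", {
  d <- toy_regression(n = 80, k = 5, seed = 101, fun = function(X) 3 * X[, 1],
                      sd = 0.01)
  m <- asmod_search(d, "y", paste0("x", 1:5), training_config(random_seed = 1))
  expect_false(m$uninformative)
  expect_equal(unique(unlist(lapply(m$submodels, `[[`, "inputs"))), "x1")
  expect_gt(m$stats$r2_percent, 99)
})

test_that("search recovers a planted two-way interaction as one tensor submodel", {
  d <- toy_regression(n = 100, k = 4, seed = 102,
                      fun = function(X) X[, 1] * X[, 2] + 0.5 * X[, 1], sd = 0.01)
  m <- asmod_search(d, "y", paste0("x", 1:4), training_config(random_seed = 1))
  sel <- lapply(m$submodels, `[[`, "inputs")
  expect_true(any(vapply(sel, function(s) setequal(s, c("x1", "x2")), logical(1))))
  expect_false(any(c("x3", "x4") %in% unlist(sel)))
})

test_that("a constant response yields the bias-only model flagged uninformative", {
  d <- data.frame(x1 = runif(20), x2 = runif(20), y = 2)
  m <- asmod_search(d, "y", c("x1", "x2"))
  expect_true(m$uninformative)
  expect_length(m$submodels, 0)
  expect_equal(unname(m$fitted), rep(2, 20), tolerance = 1e-6)
})

test_that("greedy search matches exhaustive enumeration on two-input toys", {
  # all structures reachable under the move set with node adaptation off:
  # bias-only, each univariate, both univariate, and the 2x2 tensor
  enumerate_best <- function(d, y, cfg) {
    b <- function(nm) list(kind = "continuous", input = nm, peaks = c(0, 1))
    sm <- nutrifuzz:::new_submodel
    structs <- list(list(), list(sm(list(b("x1")))), list(sm(list(b("x2")))),
                    list(sm(list(b("x1"))), sm(list(b("x2")))),
                    list(sm(list(b("x1"), b("x2")))))
    scores <- vapply(structs, function(s) {
      p <- nutrifuzz:::model_p(s)
      if (p >= length(y)) return(Inf)
      X <- nutrifuzz:::design_matrix(s, d)
      w <- oracle_ridge(X, y, cfg$ridge_factor)
      oracle_mdl(mean((y - X %*% w)^2), p, length(y))
    }, numeric(1))
    min(scores)
  }
  cfg <- training_config(model_selection = "MDL", adapt_nodes = FALSE)
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(x1 = runif(8), x2 = runif(8))
    d$y <- 1 + d$x1 + 0.8 * d$x2 + 1.5 * d$x1 * d$x2 + rnorm(8, 0, 0.05)
    nt <- normalize_inputs(d, input_specs(d, c("x1", "x2")))
    m <- asmod_search(d, "y", c("x1", "x2"), cfg)
    expect_equal(m$score, enumerate_best(nt, d$y, cfg), tolerance = 1e-9)
  }
})

test_that("training is bit-reproducible under a fixed seed and config", {
  ds <- generate_dataset(sim_config(seed = 9))
  run <- function() {
    m <- asmod_search(ds$data, "SL", config = training_config(random_seed = 5))
    list(lbl = vapply(m$submodels, nutrifuzz:::submodel_label, character(1)),
         w = m$weights, mse = m$mse, score = m$score)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
})

test_that("per-output failures do not abort sibling outputs", {
  d <- toy_regression(n = 40, k = 3, seed = 104, fun = function(X) 2 * X[, 2],
                      sd = 0.05)
  d$bad <- NA_real_
  res <- train_all_outputs(d, c("y", "bad"), training_config(random_seed = 1),
                           candidate_inputs = paste0("x", 1:3))
  expect_null(res$y$error)
  expect_gt(res$y$stats$r2_percent, 95)
  expect_match(res$bad$error, "missing")
  st <- stats_table(res)
  expect_true(any(grepl("ERROR", st$inputs)))
})
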