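#' Training configuration for the ASMOD neurofuzzy learner
#'
#' Defaults follow the standard training set-up for adaptive B-spline
#' neurofuzzy modeling of factorial tissue-culture data: ridge factor 1e-6,
#' structural risk minimization with C1 = 0.95, C2 = 4.8, an initial
#' two-set fuzzy partition per continuous input, node adaptation enabled,
#' at most 3 inputs per submodel and at most 15 nodes per input, order-2
#' (piecewise-linear, i.e. triangular-membership) B-splines.
#'
#' @param ridge_factor ridge penalty added to the normal equations (> 0).
#' @param model_selection one of `"SRM"`, `"MDL"`, `"BIC"`, `"CV"`, `"LOOCV"`.
#' @param srm_c1,srm_c2 constants of the SRM guaranteed-risk bound.
#' @param initial_set_density number of fuzzy sets a continuous input starts
#'   with (2 = endpoints only).
#' @param adapt_nodes allow knot insertion/removal on continuous inputs.
#' @param max_inputs_per_submodel cap on tensor-product dimensionality.
#' @param max_nodes_per_input cap on basis functions per continuous input.
#' @param spline_order only order 2 is supported (triangular fuzzy sets).
#' @param cv_folds folds for `"CV"` selection.
#' @param random_seed seed for the (only) stochastic step, CV fold assignment.
#' @return a `training_config` list.
#' @export
training_config <- function(ridge_factor = 1e-6, model_selection = "SRM",
                            srm_c1 = 0.95, srm_c2 = 4.8,
                            initial_set_density = 2, adapt_nodes = TRUE,
                            max_inputs_per_submodel = 3, max_nodes_per_input = 15,
                            spline_order = 2, cv_folds = 5, random_seed = 1L) {
  model_selection <- match.arg(model_selection, c("SRM", "MDL", "BIC", "CV", "LOOCV"))
  stopifnot(ridge_factor > 0, max_inputs_per_submodel >= 1,
            initial_set_density >= 2, initial_set_density <= max_nodes_per_input,
            spline_order == 2)
  structure(list(ridge_factor = ridge_factor, model_selection = model_selection,
                 srm_c1 = srm_c1, srm_c2 = srm_c2,
                 initial_set_density = initial_set_density,
                 adapt_nodes = adapt_nodes,
                 max_inputs_per_submodel = max_inputs_per_submodel,
                 max_nodes_per_input = max_nodes_per_input,
                 spline_order = spline_order, cv_folds = cv_folds,
                 random_seed = as.integer(random_seed)),
            class = "training_config")
}

#' Describe candidate inputs of a table
#'
#' Numeric columns become continuous inputs with their observed range as
#' domain; factor/character columns become categorical inputs. Constant
#' continuous columns are dropped with a warning (they carry no information
#' and cannot be normalized).
#'
#' @param table data frame.
#' @param candidates column names to consider.
#' @return named list of input specs (`name`, `kind`, `domain`/`levels`).
#' @export
input_specs <- function(table, candidates) {
  specs <- list()
  for (nm in candidates) {
    x <- table[[nm]]
    if (is.null(x)) stop("missing-column: ", nm)
    if (is.numeric(x)) {
      rng <- range(x)
      if (diff(rng) == 0) {
        warning("dropping constant continuous input: ", nm)
        next
      }
      specs[[nm]] <- list(name = nm, kind = "continuous", domain = rng)
    } else {
      lv <- levels(factor(x))
      if (length(lv) < 2) {
        warning("dropping single-level categorical input: ", nm)
        next
      }
      specs[[nm]] <- list(name = nm, kind = "categorical", levels = lv)
    }
  }
  specs
}

#' Normalize inputs to the unit interval
#'
#' Continuous inputs are affinely mapped onto [0, 1] over their spec domain
#' (observed range at spec construction); categorical inputs are returned as
#' factors with the spec's level set. Values outside the domain are clamped.
#'
#' @param table data frame.
#' @param specs list from [input_specs()].
#' @return data frame with one column per spec, normalized.
#' @export
normalize_inputs <- function(table, specs) {
  out <- lapply(specs, function(sp) {
    x <- table[[sp$name]]
    if (sp$kind == "continuous") {
      z <- (x - sp$domain[1]) / diff(sp$domain)
      pmin(pmax(z, 0), 1)
    } else factor(x, levels = sp$levels)
  })
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

# A per-input fuzzy basis: for continuous inputs an order-2 clamped B-spline
# basis is identified by its node (peak) positions in [0,1], boundary nodes
# included; for categorical inputs, by the level set (indicator basis).
new_basis <- function(spec, set_density = 2) {
  if (spec$kind == "continuous")
    list(kind = "continuous", input = spec$name,
         peaks = seq(0, 1, length.out = set_density))
  else
    list(kind = "categorical", input = spec$name, levels = spec$levels)
}

basis_size <- function(basis) {
  if (basis$kind == "continuous") length(basis$peaks) else length(basis$levels)
}

# Activation matrix (n x basis size) of one per-input basis. Order-2
# B-splines over clamped knots are the triangular "hat" functions peaking at
# each node; they form a partition of unity on [0,1]. Out-of-range values
# are clamped.
basis_matrix <- function(basis, x) {
  if (basis$kind == "categorical") {
    x <- factor(x, levels = basis$levels)
    if (anyNA(x)) stop("categorical value outside basis levels for ", basis$input)
    A <- matrix(0, length(x), length(basis$levels))
    A[cbind(seq_along(x), as.integer(x))] <- 1
    return(A)
  }
  p <- basis$peaks
  x <- pmin(pmax(as.numeric(x), 0), 1)
  k <- length(p)
  A <- matrix(0, length(x), k)
  i <- findInterval(x, p, all.inside = TRUE)  # interval [p_i, p_{i+1}]
  w <- (x - p[i]) / (p[i + 1] - p[i])
  A[cbind(seq_along(x), i)] <- 1 - w
  A[cbind(seq_along(x), i + 1)] <- A[cbind(seq_along(x), i + 1)] + w
  A
}

# A submodel: 1..max_inputs inputs with one basis each; its design block is
# the row-wise tensor (Khatri-Rao) product of the per-input activations,
# columns ordered with the *last* input varying fastest.
new_submodel <- function(bases) {
  list(inputs = vapply(bases, `[[`, character(1), "input"), bases = bases)
}

submodel_size <- function(sm) prod(vapply(sm$bases, basis_size, numeric(1)))

#' Tensor-product basis activations of a submodel
#'
#' @param submodel internal submodel object (see [asmod_search()] results).
#' @param rows data frame of normalized inputs covering the submodel's inputs.
#' @return matrix of activations, rows summing to 1 (partition of unity).
#' @export
basis_activations <- function(submodel, rows) {
  mats <- lapply(submodel$bases, function(b) basis_matrix(b, rows[[b$input]]))
  Reduce(function(A, B) {
    a <- ncol(A); b <- ncol(B)
    A[, rep(seq_len(a), each = b), drop = FALSE] *
      B[, rep(seq_len(b), times = a), drop = FALSE]
  }, mats)
}

# Full design matrix: explicit intercept plus each submodel's tensor block.
# attr "blocks" maps submodel index -> column indices.
design_matrix <- function(submodels, ntab) {
  n <- nrow(ntab)
  X <- matrix(1, n, 1)
  blocks <- list()
  for (sm in submodels) {
    B <- basis_activations(sm, ntab)
    blocks[[length(blocks) + 1]] <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
  }
  attr(X, "blocks") <- blocks
  X
}

# Coefficient count of the additive model. Every tensor-product B-spline (or
# indicator) basis spans the constant function, so from the second submodel
# on, one coefficient per submodel is redundant with the global bias and is
# not double-counted: p = 1 + sum(sizes) - max(0, m - 1). This bookkeeping
# yields df pairs such as (7, 100) for a 3x2 + 2 structure at n = 108.
model_p <- function(submodels) {
  m <- length(submodels)
  if (m == 0) return(1L)
  as.integer(1 + sum(vapply(submodels, submodel_size, numeric(1))) - max(0, m - 1))
}
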