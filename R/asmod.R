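#' ASMOD structure search for one output
#'
#' Builds an additive model of low-dimensional tensor-product B-spline
#' submodels by stepwise refinement. Starting from the bias-only model, each
#' iteration proposes every legal move — add a univariate submodel on an
#' unused input at the initial set density; merge two submodels into a
#' tensor product (combined inputs capped); insert one node at the midpoint
#' of the widest inter-knot interval of a continuous input; or prune by
#' deleting a submodel, splitting a tensor submodel into its marginals, or
#' removing a node — ridge-fits every candidate and accepts the best
#' strictly-improving move under the selection criterion. The search stops
#' when no move improves.
#'
#' Coefficient bookkeeping: each submodel block spans the constant function,
#' so p = 1 + total basis size - (number of submodels - 1) for multi-submodel
#' structures; df1 = p - 1 and df2 = n - p feed the f-ratio gate.
#'
#' @param table data frame of inputs (and the response column).
#' @param output response column name.
#' @param candidate_inputs columns offered to the learner; default: every
#'   column except the responses and the `medium` identifier.
#' @param config a [training_config()].
#' @return an `asmod_model` with elements `submodels` (ordered by criterion
#'   contribution), `weights`, `fitted`, `stats` (a [fit_stats()] object),
#'   `score`, `uninformative`, and the input `specs` used for normalization.
#' @export
asmod_search <- function(table, output, candidate_inputs = NULL,
                         config = training_config()) {
  if (!output %in% names(table)) stop("output column '", output, "' not in table")
  if (is.null(candidate_inputs))
    candidate_inputs <- setdiff(names(table), c(response_names(), "medium"))
  candidate_inputs <- setdiff(candidate_inputs, output)
  if (length(candidate_inputs) == 0) stop("need >= 1 candidate input")
  y <- table[[output]]
  if (anyNA(y)) stop("response '", output, "' contains missing values")
  n <- length(y)
  specs <- input_specs(table, candidate_inputs)
  ntab <- normalize_inputs(table, specs)
  strata <- if ("genotype" %in% names(table)) factor(table$genotype) else NULL
  folds <- if (config$model_selection == "CV")
    make_folds(n, config$cv_folds, strata, config$random_seed) else NULL

  evaluate <- function(submodels) {
    p <- model_p(submodels)
    if (p >= n) return(NULL)
    X <- design_matrix(submodels, ntab)
    w <- fit_weights(X, y, config$ridge_factor)
    fitted <- drop(X %*% w)
    mse <- mean((y - fitted)^2)
    score <- criterion_score(mse, p, n, config, X = X, y = y,
                             folds = folds, strata = strata)
    list(submodels = submodels, p = p, X = X, weights = w,
         fitted = fitted, mse = mse, score = score)
  }

  cur <- evaluate(list())
  if (stats::var(y) == 0) {
    return(finish_model(output, cur, y, specs, config, uninformative = TRUE))
  }
  for (iter in seq_len(300)) {
    moves <- propose_moves(cur$submodels, specs, config)
    if (length(moves) == 0) break
    cands <- list()
    for (mv in moves) {
      ev <- evaluate(mv$submodels)
      if (!is.null(ev)) { ev$key <- mv$key; cands[[length(cands) + 1]] <- ev }
    }
    if (length(cands) == 0) break
    scores <- vapply(cands, `[[`, numeric(1), "score")
    ps <- vapply(cands, `[[`, numeric(1), "p")
    keys <- vapply(cands, `[[`, character(1), "key")
    best <- cands[[order(scores, ps, keys)[1]]]
    tol <- 1e-12 * max(1, abs(cur$score))
    if (!is.finite(best$score) || best$score >= cur$score - tol) break
    cur <- best
  }

  uninformative <- length(cur$submodels) == 0
  if (!uninformative && length(cur$submodels) > 1) {
    # order submodels by criterion contribution (drop-one score increase)
    contrib <- vapply(seq_along(cur$submodels), function(j) {
      ev <- evaluate(cur$submodels[-j])
      if (is.null(ev)) Inf else ev$score - cur$score
    }, numeric(1))
    cur <- evaluate(cur$submodels[order(-contrib)])
  }
  finish_model(output, cur, y, specs, config, uninformative)
}

response_names <- function() c("SL", "RL", "PN", "LN", "AFW", "RFW")

finish_model <- function(output, ev, y, specs, config, uninformative) {
  stats <- if (stats::var(y) > 0 && length(y) > ev$p)
    fit_stats(y, ev$fitted, ev$p) else NULL
  blocks <- attr(ev$X, "blocks")
  contrib_means <- vapply(seq_along(ev$submodels), function(j)
    mean(ev$X[, blocks[[j]], drop = FALSE] %*% ev$weights[blocks[[j]]]),
    numeric(1))
  structure(list(output = output, submodels = ev$submodels, weights = ev$weights,
                 specs = specs, config = config, n = length(y), p = ev$p,
                 mse = ev$mse, score = ev$score,
                 criterion = config$model_selection, fitted = ev$fitted,
                 contrib_means = contrib_means,
                 y_range = range(y), stats = stats,
                 uninformative = uninformative),
            class = "asmod_model")
}

# All legal moves from the current structure. Keys give the deterministic
# tie-break order: criterion, then parameter count, then this label.
propose_moves <- function(submodels, specs, config) {
  moves <- list()
  add_move <- function(sms, key) moves[[length(moves) + 1]] <<- list(submodels = sms, key = key)
  used <- unlist(lapply(submodels, `[[`, "inputs"))
  for (nm in names(specs)) {
    if (nm %in% used) next
    sm <- new_submodel(list(new_basis(specs[[nm]], config$initial_set_density)))
    add_move(c(submodels, list(sm)), paste0("add:", nm))
  }
  m <- length(submodels)
  if (m >= 2) for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ins <- c(submodels[[i]]$inputs, submodels[[j]]$inputs)
    if (length(ins) > config$max_inputs_per_submodel) next
    bases <- c(submodels[[i]]$bases, submodels[[j]]$bases)
    bases <- bases[order(match(vapply(bases, `[[`, character(1), "input"), names(specs)))]
    add_move(c(submodels[-c(i, j)], list(new_submodel(bases))),
             paste0("merge:", paste(sort(ins), collapse = "*")))
  }
  # tensor-expand an existing submodel with a fresh input (the classical
  # ASMOD refinement; reaches interactions whose marginal effect alone is
  # too weak to earn a univariate submodel first)
  for (i in seq_along(submodels)) {
    sm <- submodels[[i]]
    if (length(sm$inputs) >= config$max_inputs_per_submodel) next
    for (nm in setdiff(names(specs), used)) {
      bases <- c(sm$bases, list(new_basis(specs[[nm]], config$initial_set_density)))
      bases <- bases[order(match(vapply(bases, `[[`, character(1), "input"), names(specs)))]
      add_move(`[[<-`(submodels, i, new_submodel(bases)),
               paste0("expand:", paste(sort(c(sm$inputs, nm)), collapse = "*")))
    }
  }
  for (i in seq_along(submodels)) {
    sm <- submodels[[i]]
    if (config$adapt_nodes) for (b in seq_along(sm$bases)) {
      bs <- sm$bases[[b]]
      if (bs$kind != "continuous") next
      if (length(bs$peaks) < config$max_nodes_per_input) {
        widths <- diff(bs$peaks)
        w <- which.max(widths)  # first maximum = lower interval on ties
        sm2 <- sm
        sm2$bases[[b]]$peaks <- sort(c(bs$peaks, (bs$peaks[w] + bs$peaks[w + 1]) / 2))
        add_move(`[[<-`(submodels, i, sm2), paste0("node+:", bs$input, ":", w))
      }
      if (length(bs$peaks) > 2) for (kn in 2:(length(bs$peaks) - 1)) {
        sm2 <- sm
        sm2$bases[[b]]$peaks <- bs$peaks[-kn]
        add_move(`[[<-`(submodels, i, sm2), paste0("node-:", bs$input, ":", kn))
      }
    }
    add_move(submodels[-i], paste0("del:", paste(sort(sm$inputs), collapse = "*")))
    if (length(sm$inputs) >= 2) {
      parts <- lapply(sm$bases, function(b) new_submodel(list(b)))
      add_move(c(submodels[-i], parts),
               paste0("split:", paste(sort(sm$inputs), collapse = "*")))
    }
  }
  moves
}

#' @export
print.asmod_model <- function(x, ...) {
  cat("ASMOD neurofuzzy model for", x$output,
      sprintf("(criterion %s, score %.4g)\n", x$criterion, x$score))
  if (x$uninformative) cat("  <uninformative: bias-only model>\n")
  for (j in seq_along(x$submodels))
    cat(sprintf("  submodel %d: %s\n", j, submodel_label(x$submodels[[j]])))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

submodel_label <- function(sm) {
  paste(vapply(sm$bases, function(b)
    sprintf("%s(%d)", b$input, basis_size(b)), character(1)), collapse = " x ")
}

#' Predict from an ASMOD model
#'
#' @param object an `asmod_model`.
#' @param newdata data frame with the model's input columns (original units;
#'   values outside the training domain are clamped).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.asmod_model <- function(object, newdata, ...) {
  ntab <- normalize_inputs(newdata, object$specs)
  X <- design_matrix(object$submodels, ntab)
  drop(X %*% object$weights)
}

#' Train one ASMOD model per output
#'
#' Outputs are trained independently; the seed stream is split
#' deterministically per output so per-output results do not depend on which
#' other outputs are requested. A failure on one output is captured and does
#' not abort the remaining ones.
#'
#' @param table data frame with inputs and response columns.
#' @param outputs character vector of response column names.
#' @param config a [training_config()].
#' @param candidate_inputs optional explicit candidate set (default as in
#'   [asmod_search()]).
#' @return named list; per output either `list(model, stats)` or
#'   `list(error = <message>)`.
#' @export
train_all_outputs <- function(table, outputs, config = training_config(),
                              candidate_inputs = NULL) {
  missing_out <- setdiff(outputs, names(table))
  if (length(missing_out)) stop("missing-column: ", paste(missing_out, collapse = ", "))
  res <- list()
  for (k in seq_along(outputs)) {
    cfg <- config
    cfg$random_seed <- as.integer((config$random_seed + 7919 * k) %% 2147483647)
    res[[outputs[k]]] <- tryCatch({
      m <- asmod_search(table, outputs[k], candidate_inputs, cfg)
      list(model = m, stats = m$stats, error = NULL)
    }, error = function(e) list(model = NULL, stats = NULL,
                                error = conditionMessage(e)))
  }
  res
}

#' Fit-statistics table across trained outputs
#'
#' One row per (output, submodel) in the layout of a model-quality table:
#' significant inputs, MSE, Train-Set R2, f-ratio, df pair and f-critical
#' are reported on the first row of each output.
#'
#' @param results list from [train_all_outputs()].
#' @return data frame.
#' @export
stats_table <- function(results) {
  rows <- list()
  for (out in names(results)) {
    r <- results[[out]]
    if (!is.null(r$error)) {
      rows[[length(rows) + 1]] <- data.frame(
        output = out, submodel = NA_integer_, inputs = paste("ERROR:", r$error),
        mse = NA_real_, r2_percent = NA_real_, f_ratio = NA_real_,
        df = NA_character_, f_critical = NA_real_, quality = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    m <- r$model; s <- r$stats
    nsub <- max(1, length(m$submodels))
    for (j in seq_len(nsub)) {
      first <- j == 1
      rows[[length(rows) + 1]] <- data.frame(
        output = out, submodel = j,
        inputs = if (length(m$submodels) == 0) "(bias only)"
                 else paste(m$submodels[[j]]$inputs, collapse = " x "),
        mse = if (first && !is.null(s)) s$mse else NA_real_,
        r2_percent = if (first && !is.null(s)) s$r2_percent else NA_real_,
        f_ratio = if (first && !is.null(s)) s$f_ratio else NA_real_,
        df = if (first && !is.null(s)) paste0(s$df1, ", ", s$df2) else NA_character_,
        f_critical = if (first && !is.null(s)) s$f_critical else NA_real_,
        quality = if (first && !is.null(s)) s$quality else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
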