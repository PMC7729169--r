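#' Linguistic partition of one submodel input
#'
#' Each basis function of an order-2 B-spline partition is a triangular
#' fuzzy set; sets are labelled in knot order as Low/High (2 sets),
#' Low/Mid/High (3 sets) or Low, Mid1..Midk, High (more). Peaks and support
#' intervals are reported in the input's original units. Categorical inputs
#' use their level names as labels.
#'
#' @param basis a per-input basis from a trained submodel.
#' @param spec the matching input spec (provides the domain for
#'   denormalization); optional for categorical inputs.
#' @return data frame `label`, `index`, `peak`, `support_lo`, `support_hi`
#'   (numeric columns NA for categorical inputs).
#' @export
linguistic_partition <- function(basis, spec = NULL) {
  k <- basis_size(basis)
  if (k < 2) stop("no-partition: basis has a single function")
  if (basis$kind == "categorical") {
    return(data.frame(label = basis$levels, index = seq_len(k),
                      peak = NA_real_, support_lo = NA_real_,
                      support_hi = NA_real_, stringsAsFactors = FALSE))
  }
  labels <- fuzzy_labels(k)
  denorm <- function(z) if (is.null(spec)) z else spec$domain[1] + z * diff(spec$domain)
  p <- basis$peaks
  data.frame(label = labels, index = seq_len(k),
             peak = denorm(p),
             support_lo = denorm(p[pmax(seq_len(k) - 1, 1)]),
             support_hi = denorm(p[pmin(seq_len(k) + 1, k)]),
             stringsAsFactors = FALSE)
}

fuzzy_labels <- function(k) {
  if (k == 2) c("Low", "High")
  else if (k == 3) c("Low", "Mid", "High")
  else c("Low", paste0("Mid", seq_len(k - 2)), "High")
}

#' Extract linguistic IF-THEN rules from a trained model
#'
#' For every submodel and every combination of antecedent labels (one fuzzy
#' set or categorical level per input), the submodel is evaluated at the
#' combination's characteristic point — the basis-function peak, where that
#' tensor coefficient is the submodel output — plus the model bias and the
#' other submodels' average contribution. The value is normalized against
#' the model's fitted-value range, m = (v - v_min) / (v_max - v_min),
#' clamped to [0, 1], and emitted as consequent High with membership m when
#' m >= 0.5 (ties High) or Low with membership 1 - m otherwise, so the Low
#' and High memberships of each combination sum to 1.
#'
#' @param model an `asmod_model`.
#' @return a `rule_set` data frame: `output`, `submodel`, one column per
#'   antecedent input (NA where an input is not in the rule's submodel),
#'   `consequent`, `membership`, `value`. Attribute `partitions` holds the
#'   linguistic partitions per (submodel, input); attribute `flat_submodels`
#'   flags submodels whose combinations do not vary.
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "asmod_model"))
  v_rng <- range(model$fitted)
  if (diff(v_rng) == 0) {
    flat_all <- TRUE
  } else flat_all <- FALSE
  intercept <- model$weights[1]
  sizes <- vapply(model$submodels, submodel_size, numeric(1))
  # design matrix is [intercept | block 1 | block 2 | ...]
  offsets <- 2 + c(0, cumsum(sizes))[seq_along(sizes)]
  all_inputs <- unique(unlist(lapply(model$submodels, `[[`, "inputs")))
  frames <- list()
  partitions <- list()
  flat_submodels <- integer(0)
  for (j in seq_along(model$submodels)) {
    sm <- model$submodels[[j]]
    wj <- model$weights[offsets[j] + seq_len(sizes[j]) - 1]
    bias_share <- intercept + sum(model$contrib_means[-j])
    ks <- vapply(sm$bases, basis_size, numeric(1))
    labs <- lapply(seq_along(sm$bases), function(b)
      linguistic_partition(sm$bases[[b]],
                           model$specs[[sm$inputs[b]]])$label)
    for (b in seq_along(sm$bases))
      partitions[[paste0(j, ":", sm$inputs[b])]] <-
        linguistic_partition(sm$bases[[b]], model$specs[[sm$inputs[b]]])
    combos <- expand.grid(lapply(rev(ks), seq_len), KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_along(ks)), drop = FALSE]  # first input slowest
    names(combos) <- sm$inputs
    # tensor column of a combo: last input varies fastest
    col <- rep(0L, nrow(combos))
    for (b in seq_along(ks)) col <- col * ks[b] + (combos[[b]] - 1L)
    v <- bias_share + wj[col + 1L]
    if (diff(range(v)) == 0 || flat_all) flat_submodels <- c(flat_submodels, j)
    m <- if (flat_all) rep(0.5, length(v))
         else pmin(pmax((v - v_rng[1]) / diff(v_rng), 0), 1)
    fr <- data.frame(output = rep(model$output, nrow(combos)),
                     submodel = rep(j, nrow(combos)), stringsAsFactors = FALSE)
    for (inp in all_inputs)
      fr[[inp]] <- if (inp %in% sm$inputs)
        labs[[match(inp, sm$inputs)]][combos[[inp]]] else NA_character_
    fr$consequent <- ifelse(m >= 0.5, "High", "Low")
    fr$membership <- ifelse(m >= 0.5, m, 1 - m)
    fr$value <- v
    frames[[j]] <- fr
  }
  rules <- if (length(frames)) do.call(rbind, frames) else
    data.frame(output = character(0), submodel = integer(0),
               consequent = character(0), membership = numeric(0),
               value = numeric(0), stringsAsFactors = FALSE)
  rownames(rules) <- NULL
  structure(rules, partitions = partitions, flat_submodels = flat_submodels,
            class = c("rule_set", "data.frame"))
}

#' Filter a rule set to its dominant rules
#'
#' @param rules a `rule_set` from [extract_rules()] (or a row-bound table of
#'   several).
#' @param min_membership keep rules with membership >= this threshold.
#' @return the filtered rules, in stable (output, submodel, antecedent) order.
#' @export
dominant_rules <- function(rules, min_membership = 0.7) {
  stopifnot(min_membership >= 0, min_membership <= 1)
  keep <- rules$membership >= min_membership
  out <- rules[keep, , drop = FALSE]
  out <- out[order(out$output, out$submodel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rule tables for all trained outputs
#'
#' @param results list from [train_all_outputs()].
#' @return single data frame of rules across outputs (all-NA antecedent
#'   columns unioned), or an empty data frame when nothing was trainable.
#' @export
rules_table <- function(results) {
  sets <- list()
  for (out in names(results)) {
    r <- results[[out]]
    if (is.null(r$model) || r$model$uninformative) next
    sets[[out]] <- as.data.frame(extract_rules(r$model))
  }
  if (length(sets) == 0) return(data.frame())
  cols <- unique(unlist(lapply(sets, names)))
  sets <- lapply(sets, function(s) {
    for (cl in setdiff(cols, names(s))) s[[cl]] <- NA_character_
    s[, cols, drop = FALSE]
  })
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}
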