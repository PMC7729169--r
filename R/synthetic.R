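#' Catalog of planted effect surfaces
#'
#' Effect functions are piecewise-linear in normalized inputs, so a
#' triangular-membership B-spline learner can represent them exactly:
#' `ramp_up` (x), `ramp_down` (1 - x) and `peak_mid` (triangle peaking at
#' 0.5). Genotype- or subculture-dependent surfaces combine these with a
#' per-level coefficient.
#'
#' @name effect_catalog
NULL

ramp_up <- function(x) x
ramp_down <- function(x) 1 - x
peak_mid <- function(x) 1 - 2 * abs(x - 0.5)

#' A planted effect for the synthetic generator
#'
#' @param output response name the effect contributes to.
#' @param inputs 1-3 input column names.
#' @param fun function of a data frame of normalized inputs (continuous in
#'   [0,1], categoricals as character) returning values in roughly [0, 1].
#' @param weight relative amplitude of this effect within its output.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(output, inputs, fun, weight = 1) {
  stopifnot(length(inputs) >= 1, length(inputs) <= 3, weight >= 0)
  structure(list(output = output, inputs = inputs, fun = fun, weight = weight),
            class = "planted_effect")
}

#' Default planted interaction structure
#'
#' Mirrors the interaction structure a neurofuzzy screen detects on this
#' design — genotype x Cu and NH4 for shoot length; genotype x SO4 x MoO4
#' plus subculture x Na for root length and plantlet number (plantlet number
#' additionally gated to zero on media lacking a whole nutrient group);
#' genotype x NH4 for leaf number; genotype x SO4 x MoO4 for aerial fresh
#' weight; genotype x Cu x SO4 plus a monotone-negative molybdate term for
#' root fresh weight — with the qualitative directions of the corresponding
#' rule summaries (e.g. BT benefits from low Cu; high Na raises rooting at
#' every subculture).
#'
#' @param scales named list of `c(baseline, amplitude)` per output, in
#'   output units.
#' @return list of [planted_effect()]s plus a `scales` attribute.
#' @export
default_planted_effects <- function(scales = list(
    SL = c(2, 4), RL = c(1, 4), PN = c(0, 40),
    LN = c(4, 20), AFW = c(0.2, 1.5), RFW = c(0.05, 0.4))) {
  gcoef <- function(g, bd, bh, bt) c(BD = bd, BH = bh, BT = bt)[as.character(g)]
  cu_geno <- function(d) gcoef(d$genotype, 0.1, 0.4, 1.0) * ramp_down(d$Cu) +
    gcoef(d$genotype, 0.05, 0.2, 0) * ramp_up(d$Cu)
  # genotype-dependent sulfate x molybdate response; the molybdate factor of
  # the first term saturates at 0.4 (not 0) at full strength so the sulfate
  # ramp stays active across the whole design
  so4_mo_geno <- function(d) {
    a <- gcoef(d$genotype, 0.9, 1.0, 0.45)
    b <- gcoef(d$genotype, 0.5, 0.1, 1.0)
    a * ramp_up(d$SO4) * (1 - 0.6 * d$MoO4) +
      b * (1 - 0.5 * ramp_up(d$SO4)) * peak_mid(d$MoO4)
  }
  sub_na <- function(d) {
    s <- c(`1` = 0.8, `2` = 0.9, `3` = 1.0, `4` = 1.0)[as.character(d$subculture)]
    s * ramp_up(d$Na)
  }
  nh4_geno <- function(d) gcoef(d$genotype, 0.05, 0.15, 1.0) * ramp_up(d$NH4)
  # "either nutrient high" response, soft enough not to saturate where one
  # of the two ions sits at full strength
  cu_so4_geno <- function(d) {
    g <- gcoef(d$genotype, 0.7, 1.0, 0.5)
    g * (0.5 * ramp_up(d$SO4) + 0.8 * ramp_up(d$Cu) -
           0.45 * ramp_up(d$SO4) * ramp_up(d$Cu))
  }
  eff <- list(
    planted_effect("SL", c("genotype", "Cu"), cu_geno, 1.0),
    planted_effect("SL", "NH4", function(d) ramp_up(d$NH4), 0.4),
    planted_effect("RL", c("genotype", "SO4", "MoO4"), so4_mo_geno, 1.0),
    planted_effect("RL", c("subculture", "Na"), sub_na, 0.35),
    planted_effect("PN", c("genotype", "SO4", "MoO4"), so4_mo_geno, 1.0),
    planted_effect("PN", c("subculture", "Na"), sub_na, 0.35),
    planted_effect("LN", c("genotype", "NH4"), nh4_geno, 1.0),
    planted_effect("AFW", c("genotype", "SO4", "MoO4"), so4_mo_geno, 1.0),
    planted_effect("RFW", c("genotype", "Cu", "SO4"), cu_so4_geno, 1.0),
    planted_effect("RFW", "MoO4", function(d) ramp_down(d$MoO4), 0.25)
  )
  attr(eff, "scales") <- scales
  eff
}

#' Simulation configuration
#'
#' The defaults are the study conditions of the factorial nutrition
#' experiment this generator emulates: 3 genotypes x the nine MS dilution
#' media x 4 subcultures (108 treatments), 20 replicates collapsed to
#' treatment means, the default planted interaction structure, and Gaussian
#' noise with standard deviation equal to `noise_fraction` of each output's
#' deterministic signal range.
#'
#' @param genotypes genotype codes.
#' @param media media table (salts x media, mg/L).
#' @param subcultures subculture labels.
#' @param replicates replicates per treatment when `means_only = FALSE`.
#' @param means_only generate one (noisy) treatment-mean row per treatment.
#' @param effects list of [planted_effect()]s (with a `scales` attribute).
#' @param noise_fraction noise SD as a fraction of the signal range (>= 0).
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genotypes = c("BD", "BH", "BT"),
                       media = ms_media_table(), subcultures = 1:4,
                       replicates = 20, means_only = TRUE,
                       effects = default_planted_effects(),
                       noise_fraction = 0.10, seed = 42L) {
  stopifnot(noise_fraction >= 0, replicates >= 1)
  structure(list(genotypes = genotypes, media = media,
                 subcultures = subcultures, replicates = as.integer(replicates),
                 means_only = means_only, effects = effects,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic factorial dataset
#'
#' Builds the full treatment crossing with ion columns, evaluates each
#' output's planted surfaces on normalized inputs, rescales to output units
#' (baseline + amplitude), adds Gaussian noise and rounds count-like outputs
#' (PN, LN) to nonnegative integers. Plantlet number is additionally forced
#' to zero on media where a whole nutrient group is absent, emulating the
#' total inhibition of plantlet formation on mineral-free media.
#'
#' @param config a [sim_config()].
#' @param registry salt registry used for the ion split.
#' @return list with `data` (factor table + response columns) and `truth`
#'   (per output: planted inputs, alias classes of the design, and the
#'   noise-free surface).
#' @export
generate_dataset <- function(config = sim_config(), registry = ms_salt_registry()) {
  tab <- build_factor_table(config$genotypes, config$media, config$subcultures,
                            registry)
  ions <- ion_columns(tab)
  design_cols <- c("genotype", "subculture", ions)
  specs <- input_specs(tab, design_cols)
  ntab <- normalize_inputs(tab, specs)
  ntab$genotype <- as.character(ntab$genotype)
  ntab$subculture <- as.character(ntab$subculture)
  outputs <- unique(vapply(config$effects, `[[`, character(1), "output"))
  scales <- attr(config$effects, "scales")
  for (e in config$effects) {
    bad <- setdiff(e$inputs, names(ntab))
    if (length(bad)) stop("planted effect for ", e$output,
                          " references absent input(s): ", paste(bad, collapse = ", "))
  }
  # nutrient-group gate for count-like organogenesis outputs
  gate <- rep(1, nrow(tab))
  if (all(c("NH4", "Mn") %in% names(tab)))
    gate <- as.numeric(tab$NH4 > 0 & tab$Mn > 0)
  surfaces <- list()
  for (out in outputs) {
    sc <- scales[[out]]
    s <- rep(0, nrow(tab))
    for (e in config$effects) if (e$output == out)
      s <- s + e$weight * unname(e$fun(ntab))
    rng <- diff(range(s))
    s <- if (rng > 0) (s - min(s)) / rng else s * 0
    surf <- sc[1] + sc[2] * s
    if (out == "PN") surf <- surf * gate
    surfaces[[out]] <- surf
  }
  draws <- sample_with_seed(config$seed, function() {
    out_draws <- lapply(outputs, function(out) {
      surf <- surfaces[[out]]
      noise_sd <- config$noise_fraction * diff(range(surf))
      nrep <- if (config$means_only) 1L else config$replicates
      y <- rep(surf, each = nrep) + stats::rnorm(length(surf) * nrep, 0, noise_sd)
      if (out %in% c("PN", "LN")) y <- pmax(0, round(y))
      y
    })
    names(out_draws) <- outputs
    out_draws
  })
  if (config$means_only) {
    data <- tab
  } else {
    data <- tab[rep(seq_len(nrow(tab)), each = config$replicates), , drop = FALSE]
    data$replicate <- rep(seq_len(config$replicates), times = nrow(tab))
    rownames(data) <- NULL
  }
  for (out in outputs) data[[out]] <- draws[[out]]
  truth <- lapply(outputs, function(out) list(
    inputs = unique(unlist(lapply(config$effects,
             function(e) if (e$output == out) e$inputs))),
    surface = surfaces[[out]]))
  names(truth) <- outputs
  attr(data, "ion_columns") <- ions
  truth$alias_classes <- alias_classes(ntab, ions)
  structure(list(data = data, truth = truth, config = config),
            class = "nf_dataset")
}

# Groups of design columns that are (near-)exactly collinear after
# normalization: in a grouped dilution design every pure-macro ion carries
# the same column, likewise every pure-micro ion. Planted-input recovery is
# only meaningful up to these classes.
alias_classes <- function(ntab, ions) {
  num <- ntab[, intersect(ions, names(ntab)), drop = FALSE]
  cls <- list()
  assigned <- character(0)
  for (a in names(num)) {
    if (a %in% assigned) next
    grp <- a
    for (b in setdiff(names(num), c(assigned, a))) {
      if (abs(stats::cor(num[[a]], num[[b]])) >= 0.999) grp <- c(grp, b)
    }
    cls[[length(cls) + 1]] <- grp
    assigned <- c(assigned, grp)
  }
  cls
}

#' Recovery metrics of trained models against the generator truth
#'
#' In a grouped dilution design the ion columns are heavily collinear (every
#' pure-macronutrient ion carries the same normalized column, likewise every
#' pure-micronutrient ion, and mixed ions such as sulfate are linear
#' combinations of the two dose axes), so individual planted ions are
#' identifiable only up to the linear span of the selected columns. A
#' planted continuous input therefore counts as recovered when its
#' normalized design column is reproduced (R-squared >= `span_r2`) by the
#' columns the model selected; categorical inputs must be selected
#' themselves. `false_inputs` counts selected inputs not reproducible from
#' the planted columns. Also reported: the correlation between model
#' predictions and the noise-free surface, and agreement of the dominant
#' rule direction with the planted surface (the top High-membership rule
#' must sit at a higher point of the true surface than the top Low rule).
#'
#' @param results list from [train_all_outputs()].
#' @param dataset the `nf_dataset` the models were trained on.
#' @param span_r2 reconstruction threshold for span-based recovery.
#' @return data frame, one row per output.
#' @export
recovery_report <- function(results, dataset, span_r2 = 0.995) {
  truth <- dataset$truth
  outputs <- setdiff(names(truth), "alias_classes")
  if (!all(names(results) %in% outputs))
    stop("report error: trained outputs not present in truth")
  tmean <- dataset$data[!duplicated(dataset$data[c("genotype", "subculture", "medium")]), ]
  ions <- ion_columns(dataset$data)
  nspecs <- input_specs(tmean, c("genotype", "subculture", ions))
  ncols <- normalize_inputs(tmean, nspecs)
  in_span <- function(target, have) {
    if (target %in% have) return(TRUE)
    if (!is.numeric(ncols[[target]])) return(FALSE)
    have_num <- have[vapply(have, function(h) is.numeric(ncols[[h]]), logical(1))]
    if (length(have_num) == 0) return(FALSE)
    X <- as.matrix(ncols[have_num])
    fit <- stats::lm.fit(cbind(1, X), ncols[[target]])
    1 - sum(fit$residuals^2) / sum((ncols[[target]] - mean(ncols[[target]]))^2) >= span_r2
  }
  rows <- lapply(names(results), function(out) {
    r <- results[[out]]
    planted <- truth[[out]]$inputs
    if (!is.null(r$error) || is.null(r$model))
      return(data.frame(output = out, recall = NA_real_, false_inputs = NA_integer_,
                        surface_cor = NA_real_, direction_ok = NA,
                        r2_percent = NA_real_, stringsAsFactors = FALSE))
    sel <- unique(unlist(lapply(r$model$submodels, `[[`, "inputs")))
    recall <- mean(vapply(planted, in_span, logical(1), have = sel))
    false_in <- sum(!vapply(sel, in_span, logical(1), have = planted))
    surf <- truth[[out]]$surface
    pred <- if (nrow(dataset$data) == length(surf)) r$model$fitted else
      predict(r$model, dataset$data[!duplicated(dataset$data[c("genotype", "subculture", "medium")]), ])
    sc <- if (stats::sd(surf) > 0 && stats::sd(pred) > 0) stats::cor(pred, surf) else NA_real_
    data.frame(output = out, recall = recall, false_inputs = as.integer(false_in),
               surface_cor = sc, direction_ok = direction_agreement(r$model, dataset, out),
               r2_percent = if (is.null(r$stats)) NA_real_ else r$stats$r2_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Does the dominant High rule of submodel 1 point at a higher region of the
# planted surface than the dominant Low rule?
direction_agreement <- function(model, dataset, out) {
  if (model$uninformative || length(model$submodels) == 0) return(NA)
  rules <- tryCatch(extract_rules(model), error = function(e) NULL)
  if (is.null(rules)) return(NA)
  r1 <- rules[rules$submodel == 1, , drop = FALSE]
  hi <- r1[r1$consequent == "High", , drop = FALSE]
  lo <- r1[r1$consequent == "Low", , drop = FALSE]
  if (nrow(hi) == 0 || nrow(lo) == 0) return(NA)
  hi <- hi[which.max(hi$membership), ]
  lo <- lo[which.max(lo$membership), ]
  surf <- dataset$truth[[out]]$surface
  tmean <- dataset$data[!duplicated(dataset$data[c("genotype", "subculture", "medium")]), ]
  at_rule <- function(rule) {
    sm <- model$submodels[[1]]
    keep <- rep(TRUE, length(surf))
    for (b in seq_along(sm$bases)) {
      inp <- sm$inputs[b]
      part <- linguistic_partition(sm$bases[[b]], model$specs[[inp]])
      lab <- rule[[inp]]
      if (sm$bases[[b]]$kind == "categorical") {
        keep <- keep & (as.character(tmean[[inp]]) == lab)
      } else {
        pk <- part$peak[part$label == lab]
        keep <- keep & (abs(tmean[[inp]] - pk) ==
                          min(abs(unique(tmean[[inp]]) - pk)))
      }
    }
    mean(surf[keep])
  }
  isTRUE(at_rule(hi) > at_rule(lo))
}
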