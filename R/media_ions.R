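#' Salt registry and ion arithmetic for MS-based culture media
#'
#' A salt registry maps each mineral salt of a culture-medium formulation to
#' its molar mass and the ions it dissociates into. Converting a medium from
#' salt amounts (mg/L) to ion molar concentrations (mM) removes the
#' confounding between ions that share a salt, so that downstream models see
#' one column per chemical species rather than per reagent.
#'
#' @name media_ions
NULL

#' Read a salt registry from a delimited file
#'
#' The file has columns `salt`, `group` (macro/micro/iron), `molar_mass`
#' (g/mol) and `ions`, the latter encoded as `ion:count;ion:count` with the
#' stoichiometric count of each ion per formula unit.
#'
#' @param path path to a tab- or comma-delimited registry file.
#' @param sep field separator, default tab.
#' @return a `salt_registry` data frame with a parsed `ions` list column.
#' @export
read_salt_registry <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("salt", "group", "molar_mass", "ions")
  if (!all(need %in% names(df)))
    stop("salt registry must have columns: ", paste(need, collapse = ", "))
  df$ions <- lapply(df$ions, parse_ion_spec)
  validate_salt_registry(df)
}

parse_ion_spec <- function(spec) {
  parts <- strsplit(trimws(spec), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(counts) <- vapply(kv, `[[`, character(1), 1)
  counts
}

validate_salt_registry <- function(df) {
  if (anyDuplicated(df$salt)) stop("duplicate salt names in registry")
  if (any(df$molar_mass <= 0)) stop("molar_mass must be > 0 for every salt")
  for (i in seq_len(nrow(df))) {
    ions <- df$ions[[i]]
    if (length(ions) == 0 || any(ions < 1))
      stop("salt ", df$salt[i], ": ion list must be non-empty with counts >= 1")
  }
  class(df) <- c("salt_registry", "data.frame")
  df
}

#' The Murashige & Skoog salt registry shipped with the package
#'
#' Molar masses use the hydrate identity of each reagent as supplied
#' (e.g. CaCl2.2H2O at 147.01 g/mol) and anhydrous Na2EDTA (336.21 g/mol),
#' the convention under which the full-MS sodium concentration works out to
#' 0.223 mM.
#'
#' @return a `salt_registry` data frame.
#' @export
ms_salt_registry <- function() {
  read_salt_registry(system.file("extdata", "ms_salt_registry.tsv",
                                 package = "nutrifuzz"))
}

#' Read a media-definition table (salts x media, mg/L)
#'
#' @param path CSV with a `salt` column followed by one column per medium.
#' @return data frame with rownames = salt names, one numeric column per medium.
#' @export
read_media_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "salt") stop("first column of a media table must be 'salt'")
  if (anyDuplicated(names(df)[-1])) stop("duplicate medium names in media table")
  rownames(df) <- df$salt
  df$salt <- NULL
  if (any(as.matrix(df) < 0, na.rm = TRUE)) stop("salt amounts must be >= 0")
  df
}

#' The nine MS-based media of the dilution-series design
#'
#' Full MS plus half/quarter/eighth/zero strength of either the macronutrient
#' group (1/2MSM ... 0MSM) or the micronutrient group (1/2MSu ... 0MSu), with
#' the EDTA-chelated iron source held constant throughout.
#'
#' @return data frame, salts in rows (rownames), media in columns, mg/L.
#' @export
ms_media_table <- function() {
  read_media_table(system.file("extdata", "ms_media.csv", package = "nutrifuzz"))
}

#' Convert one medium formulation to an ion profile
#'
#' For each ion, the molar concentration is the sum over salts of
#' (mg/L / molar mass) x stoichiometric count, in mM. Ions contributed by no
#' salt of the medium are absent from the profile (to be read as 0 mM).
#'
#' @param medium named numeric vector of salt amounts in mg/L (names = salts),
#'   or a single-column data frame with salt rownames.
#' @param registry a `salt_registry`.
#' @param name provenance label for the medium.
#' @return named numeric vector of ion concentrations in mM, with attributes
#'   `medium` (provenance) and class `ion_profile`.
#' @export
ion_profile <- function(medium, registry = ms_salt_registry(), name = NULL) {
  if (is.data.frame(medium)) {
    if (is.null(name) && ncol(medium) == 1) name <- colnames(medium)[1]
    medium <- stats::setNames(medium[[1]], rownames(medium))
  }
  if (is.null(names(medium)) || any(names(medium) == ""))
    stop("medium must be a named vector of salt amounts")
  unknown <- setdiff(names(medium), registry$salt)
  if (length(unknown) > 0)
    stop("unresolved salt name(s): ", paste(unknown, collapse = ", "))
  if (any(medium < 0)) stop("salt amounts must be >= 0")
  conc <- numeric(0)
  for (s in names(medium)) {
    i <- match(s, registry$salt)
    mmol <- medium[[s]] / registry$molar_mass[i]  # mg/L / g/mol = mmol/L
    for (ion in names(registry$ions[[i]])) {
      add <- mmol * registry$ions[[i]][[ion]]
      conc[ion] <- if (ion %in% names(conc)) conc[[ion]] + add else add
    }
  }
  structure(conc, medium = name, class = c("ion_profile", class(conc)))
}

#' @export
print.ion_profile <- function(x, ...) {
  med <- attr(x, "medium")
  cat("Ion profile", if (!is.null(med)) paste0("(", med, ")"), "\n")
  macro <- x[x >= 0.5]
  micro <- x[x < 0.5]
  if (length(macro))
    print(round(macro, 2))
  if (length(micro)) {
    cat("micro (uM):\n")
    print(round(micro * 1000, 2))
  }
  invisible(x)
}

# Round half-up to two significant figures but never coarser than one
# decimal: the precision at which the dilution-series tables are printed.
round_printed <- function(x) {
  out <- x
  pos <- !is.na(x) & x > 0
  d <- pmax(1, 1 - floor(log10(x[pos])))
  out[pos] <- floor(x[pos] * 10^d + 0.5) / 10^d
  out
}

#' Build a dilution series of one salt group
#'
#' Scales only the salts of the requested group (macro or micro) by each
#' factor, leaving the iron/EDTA source (and any other group) untouched, and
#' rounds the scaled amounts to printed precision (two significant figures,
#' at most one decimal place of coarseness).
#'
#' @param base named numeric vector (or 1-column data frame) of the full-
#'   strength formulation in mg/L.
#' @param group `"macro"` or `"micro"`.
#' @param factors numeric vector of dilution fractions in [0, 1].
#' @param registry a `salt_registry` (supplies the group membership).
#' @param names optional names for the resulting media.
#' @return data frame, salts in rows, one column per factor.
#' @export
dilution_series <- function(base, group, factors,
                            registry = ms_salt_registry(), names = NULL) {
  if (is.data.frame(base)) base <- stats::setNames(base[[1]], rownames(base))
  if (any(factors < 0 | factors > 1)) stop("invalid-factor: factors must lie in [0, 1]")
  if (!group %in% registry$group)
    stop("group must identify a declared salt group: ",
         paste(unique(registry$group), collapse = ", "))
  in_group <- names(base) %in% registry$salt[registry$group == group]
  out <- sapply(factors, function(f) {
    v <- base
    v[in_group] <- round_printed(v[in_group] * f)
    v
  })
  out <- as.data.frame(out, row.names = names(base))
  colnames(out) <- if (!is.null(names)) names else paste0(group, "_x", factors)
  out
}

#' Ions that vary across a set of media
#'
#' Species whose molar concentration is the same in every medium (the
#' EDTA-chelated iron source contributes constant Fe and EDTA) are excluded;
#' the remainder are the candidate inputs of the factorial design.
#'
#' @param media data frame, salts in rows, media in columns (mg/L).
#' @param registry a `salt_registry`.
#' @param tol absolute tolerance (mM) below which variation is ignored.
#' @return character vector of ion ids, in first-appearance order.
#' @export
variable_ions <- function(media, registry = ms_salt_registry(), tol = 1e-9) {
  if (is.null(media) || ncol(media) == 0) stop("invalid-input: empty media list")
  profs <- lapply(colnames(media), function(m)
    ion_profile(stats::setNames(media[[m]], rownames(media)), registry, name = m))
  all_ions <- unique(unlist(lapply(profs, names)))
  mat <- sapply(profs, function(p) {
    v <- stats::setNames(numeric(length(all_ions)), all_ions)
    v[names(p)] <- p
    v
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(all_ions))
  varying <- apply(mat, 1, function(r) diff(range(r)) > tol)
  all_ions[varying]
}

#' Build the full-factorial treatment table
#'
#' Crosses genotypes x media x subcultures and attaches one column per
#' variable ion (mM, from [ion_profile()]). Genotype and subculture are
#' categorical factors; the medium name is kept as an identifier column.
#'
#' @param genotypes character vector of genotype codes.
#' @param media data frame of media (salts x media, mg/L).
#' @param subcultures vector of subculture labels (coerced to factor).
#' @param registry a `salt_registry`.
#' @return a data frame with columns `genotype`, `subculture`, `medium` and
#'   the variable-ion concentrations; one row per treatment.
#' @export
build_factor_table <- function(genotypes, media, subcultures,
                               registry = ms_salt_registry()) {
  if (length(genotypes) == 0 || ncol(media) == 0 || length(subcultures) == 0)
    stop("genotypes, media and subcultures must all be non-empty")
  if (anyDuplicated(colnames(media)))
    stop("ambiguous design: duplicate medium names")
  ions <- if (ncol(media) >= 2) variable_ions(media, registry) else character(0)
  prof <- matrix(vapply(colnames(media), function(m) {
    p <- ion_profile(stats::setNames(media[[m]], rownames(media)), registry, m)
    v <- stats::setNames(numeric(length(ions)), ions)
    v[intersect(names(p), ions)] <- p[intersect(names(p), ions)]
    v
  }, numeric(length(ions))), nrow = length(ions), ncol = ncol(media),
  dimnames = list(ions, colnames(media)))
  grid <- expand.grid(subculture = subcultures, medium = colnames(media),
                      genotype = genotypes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "subculture", "medium")]
  tab <- cbind(
    data.frame(genotype = factor(grid$genotype, levels = unique(genotypes)),
               subculture = factor(grid$subculture, levels = unique(subcultures)),
               medium = grid$medium, stringsAsFactors = FALSE),
    as.data.frame(t(prof[, grid$medium, drop = FALSE]), row.names = FALSE)
  )
  rownames(tab) <- NULL
  attr(tab, "ion_columns") <- ions
  tab
}

#' Ion columns of a factor table
#' @param table a factor table from [build_factor_table()] or
#'   [generate_dataset()].
#' @return character vector of ion column names.
#' @export
ion_columns <- function(table) {
  ic <- attr(table, "ion_columns")
  if (!is.null(ic)) return(ic)
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("SL", "RL", "PN", "LN", "AFW", "RFW"))
}
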