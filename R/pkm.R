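# Prior-knowledge model (PKM): a linear group-contribution (GC) fish-toxicity
# model composed with a linear interspecies fish->daphnia map, bridged onto
# the data-set toxicity scale -ln(LC50 mg/L).
#
# All composition happens on a declared scale graph (quantity + units);
# silent unit coercion is forbidden because mg/L vs mmol/L confusion is the
# dominant failure mode with these models.

.scale_quantities <- c("neg_log10_lc50", "neg_ln_lc50", "lc50")
.scale_units <- c("mmol_per_l", "mg_per_l")

#' Declare a toxicity scale
#'
#' @param quantity one of `"neg_log10_lc50"`, `"neg_ln_lc50"`, `"lc50"`.
#' @param units one of `"mmol_per_l"`, `"mg_per_l"`.
#' @return list of class `tox_scale`.
#' @export
tox_scale <- function(quantity, units) {
  assert_that(quantity %in% .scale_quantities,
              paste0("quantity must be one of: ",
                     paste(.scale_quantities, collapse = ", ")),
              class = "toxhybrid_unit_error")
  assert_that(units %in% .scale_units,
              paste0("units must be one of: ",
                     paste(.scale_units, collapse = ", ")),
              class = "toxhybrid_unit_error")
  structure(list(quantity = quantity, units = units), class = "tox_scale")
}

scale_eq <- function(a, b) a$quantity == b$quantity && a$units == b$units

#' Convert a toxicity value between declared scales
#'
#' Converts via the concentration domain. Moving between mmol/L and mg/L
#' requires the molar mass (g/mol); omitting it raises a data error.
#'
#' @param value numeric vector on scale `from`.
#' @param from,to [tox_scale()] declarations.
#' @param molar_mass numeric vector of molar masses (g/mol), needed only for
#'   unit changes.
#' @return numeric vector on scale `to`.
#' @export
convert_scale <- function(value, from, to, molar_mass = NULL) {
  stopifnot(inherits(from, "tox_scale"), inherits(to, "tox_scale"))
  if (scale_eq(from, to)) return(value)
  # to concentration in `from` units
  conc <- switch(from$quantity,
                 neg_log10_lc50 = 10^(-value),
                 neg_ln_lc50 = exp(-value),
                 lc50 = value)
  if (from$units != to$units) {
    if (is.null(molar_mass)) {
      th_stop("molar mass required to convert between mmol/L and mg/L",
              "toxhybrid_data_error")
    }
    conc <- if (from$units == "mmol_per_l") conc * molar_mass  # -> mg/L
            else conc / molar_mass                             # -> mmol/L
  }
  switch(to$quantity,
         neg_log10_lc50 = -log10(conc),
         neg_ln_lc50 = -log(conc),
         lc50 = conc)
}

#' Group-contribution model
#'
#' Linear fragment model `intercept + sum(count_i * coef_i)`. A term's
#' `pattern` is either a SMARTS substructure expression (counted with the
#' substructure engine) or `"desc:<name>"`, referencing a descriptor column
#' so descriptor-linear prior models (e.g. baseline narcosis on logP) fit the
#' same interface.
#'
#' @param fragments data.frame with columns `pattern` and `coef` (may have
#'   zero rows).
#' @param intercept numeric intercept.
#' @param output_scale [tox_scale()] of the model output.
#' @return list of class `gc_model`.
#' @export
gc_model <- function(fragments, intercept, output_scale) {
  if (is.null(fragments)) {
    fragments <- data.frame(pattern = character(0), coef = numeric(0))
  }
  assert_that(is.data.frame(fragments) &&
                all(c("pattern", "coef") %in% colnames(fragments)),
              "fragments needs pattern and coef columns",
              class = "toxhybrid_config_error")
  assert_that(is_number(intercept), "intercept must be a number",
              class = "toxhybrid_config_error")
  stopifnot(inherits(output_scale, "tox_scale"))
  structure(list(fragments = fragments, intercept = intercept,
                 output_scale = output_scale),
            class = "gc_model")
}

#' Linear interspecies map
#'
#' `daphnia = slope * fish + intercept`, with declared input and output
#' scales (typically both a log-toxicity quantity).
#'
#' @param slope,intercept numeric coefficients.
#' @param input_scale,output_scale [tox_scale()] declarations.
#' @return list of class `interspecies_map`.
#' @export
interspecies_map <- function(slope = 1, intercept = 0,
                             input_scale = tox_scale("neg_log10_lc50", "mmol_per_l"),
                             output_scale = input_scale) {
  assert_that(is_number(slope) && is_number(intercept),
              "slope and intercept must be numbers",
              class = "toxhybrid_config_error")
  structure(list(slope = slope, intercept = intercept,
                 input_scale = input_scale, output_scale = output_scale),
            class = "interspecies_map")
}

#' Apply an interspecies map
#'
#' @param map an [interspecies_map()].
#' @param fish_value numeric vector on `map$input_scale`.
#' @return numeric vector on `map$output_scale`.
#' @export
interspecies <- function(map, fish_value) {
  stopifnot(inherits(map, "interspecies_map"))
  map$slope * fish_value + map$intercept
}

#' Compose the prior-knowledge model
#'
#' Chains a GC fish model through an interspecies map onto the data-set
#' toxicity scale (-ln LC50 mg/L). Scale compatibility is validated at
#' construction: the GC output scale must equal the map input scale.
#'
#' @param gc a [gc_model()].
#' @param map an [interspecies_map()].
#' @param target_scale the data-set scale; fixed default
#'   `tox_scale("neg_ln_lc50", "mg_per_l")`.
#' @return list of class `pk_model`.
#' @export
pk_model <- function(gc, map = interspecies_map(input_scale = gc$output_scale),
                     target_scale = tox_scale("neg_ln_lc50", "mg_per_l")) {
  stopifnot(inherits(gc, "gc_model"), inherits(map, "interspecies_map"))
  if (!scale_eq(gc$output_scale, map$input_scale)) {
    th_stop("GC output scale does not match interspecies input scale",
            "toxhybrid_unit_error")
  }
  structure(list(gc = gc, map = map, target_scale = target_scale),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Prior-knowledge toxicity model\n")
  cat("  GC terms: ", nrow(x$gc$fragments), " (+ intercept ",
      format(x$gc$intercept), ") on ", x$gc$output_scale$quantity, " [",
      x$gc$output_scale$units, "]\n", sep = "")
  cat("  interspecies: slope ", format(x$map$slope), ", intercept ",
      format(x$map$intercept), "\n", sep = "")
  cat("  target scale: ", x$target_scale$quantity, " [",
      x$target_scale$units, "]\n", sep = "")
  invisible(x)
}

# Evaluate GC terms for a set of molecules. `descriptors` supplies the
# columns used by desc:-typed terms; SMARTS terms are counted on the parsed
# structures.
gc_terms_matrix <- function(gc, smiles, descriptors = NULL) {
  n <- length(smiles)
  if (nrow(gc$fragments) == 0) return(matrix(0, n, 0))
  pat <- gc$fragments$pattern
  out <- matrix(0, n, length(pat))
  desc_idx <- grepl("^desc:", pat)
  if (any(desc_idx)) {
    nms <- sub("^desc:", "", pat[desc_idx])
    assert_that(!is.null(descriptors),
                "GC model uses descriptor terms but no descriptors were supplied",
                class = "toxhybrid_feature_error")
    miss <- setdiff(nms, colnames(descriptors))
    assert_that(length(miss) == 0,
                paste0("descriptor(s) absent: ", paste(miss, collapse = ", ")),
                class = "toxhybrid_feature_error")
    out[, desc_idx] <- descriptors[, nms, drop = FALSE]
  }
  if (any(!desc_idx)) {
    p <- parse_smiles(smiles)
    assert_that(all(p$ok), "all SMILES must parse", class = "toxhybrid_parse_error")
    for (j in which(!desc_idx)) {
      cnt <- tryCatch(smarts_count(p$sdf, pat[j]),
                      error = function(e) th_stop(
                        paste0("SMARTS pattern failed to compile: ", pat[j]),
                        "toxhybrid_config_error"))
      out[, j] <- as.numeric(cnt)
    }
  }
  out
}

#' Evaluate the GC model
#'
#' @param gc a [gc_model()].
#' @param smiles character vector of SMILES.
#' @param descriptors optional descriptor matrix (rows follow `smiles`) for
#'   `desc:`-typed terms.
#' @return numeric vector on `gc$output_scale`.
#' @export
gc_predict <- function(gc, smiles, descriptors = NULL) {
  stopifnot(inherits(gc, "gc_model"))
  tm <- gc_terms_matrix(gc, smiles, descriptors)
  rep(gc$intercept, length(smiles)) +
    if (ncol(tm) > 0) drop(tm %*% gc$fragments$coef) else 0
}

#' Predict toxicity with the prior-knowledge model
#'
#' Evaluates the GC fish model, maps it to daphnia via the interspecies
#' equation, and converts the result through the declared unit bridge onto
#' the data-set scale. Molar masses are computed from the structures when
#' the bridge changes units.
#'
#' @param object a [pk_model()].
#' @param newdata character vector of SMILES, or a data.frame with a
#'   `smiles` column.
#' @param descriptors optional descriptor matrix for `desc:`-typed GC terms.
#' @param ... unused.
#' @return numeric vector of tox values on `-ln(LC50 mg/L)`.
#' @export
predict.pk_model <- function(object, newdata, descriptors = NULL, ...) {
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  assert_that(is.character(smiles) && length(smiles) > 0,
              "newdata must supply SMILES")
  fish <- gc_predict(object$gc, smiles, descriptors)
  daph <- interspecies(object$map, fish)
  mm <- NULL
  if (object$map$output_scale$units != object$target_scale$units) {
    mm <- molar_mass(smiles)
  }
  convert_scale(daph, object$map$output_scale, object$target_scale, mm)
}

#' Molar mass from structure
#'
#' Sum of standard atomic masses (implicit hydrogens included), g/mol.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector.
#' @export
molar_mass <- function(smiles) {
  p <- parse_smiles(smiles)
  assert_that(all(p$ok), "all SMILES must parse", class = "toxhybrid_parse_error")
  vapply(seq_along(p$ids), function(i) {
    g <- mol_graph(p$sdf[[i]])
    f <- expand_hydrogens(g)
    sum(.atom_props[f$element, "mass"])
  }, numeric(1))
}

#' Shipped default prior-knowledge model
#'
#' A baseline-narcosis fish model, `-log10(LC50 mmol/L) = 0.85 * logP + 1.39`
#' (a placeholder calibration on the classic hydrophobicity relationship for
#' nonpolar narcotics), composed with an identity interspecies map. Intended
#' as a runnable default; substitute fitted GC and interspecies coefficients
#' via [read_pkm_config()] for real use.
#'
#' @return a [pk_model()].
#' @export
default_pk_model <- function() {
  gc <- gc_model(
    fragments = data.frame(pattern = "desc:MolLogP", coef = 0.85),
    intercept = 1.39,
    output_scale = tox_scale("neg_log10_lc50", "mmol_per_l")
  )
  pk_model(gc)
}

#' Read a prior-knowledge model from a YAML config
#'
#' Schema:
#' ```yaml
#' gc:
#'   intercept: 1.39
#'   scale: {quantity: neg_log10_lc50, units: mmol_per_l}
#'   fragments:
#'     - {pattern: "desc:MolLogP", coef: 0.85}
#'     - {pattern: "[CH3][#7]",    coef: -0.2}
#' interspecies:
#'   slope: 1.0
#'   intercept: 0.0
#' ```
#' The interspecies scales default to the GC output scale.
#'
#' @param path YAML file.
#' @return a [pk_model()].
#' @export
read_pkm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$gc), "config lacks a gc block",
              class = "toxhybrid_config_error")
  sc <- cfg$gc$scale
  assert_that(!is.null(sc$quantity) && !is.null(sc$units),
              "gc scale must declare quantity and units",
              class = "toxhybrid_config_error")
  out_scale <- tox_scale(sc$quantity, sc$units)
  frags <- if (length(cfg$gc$fragments) > 0) {
    data.frame(pattern = vapply(cfg$gc$fragments, `[[`, "", "pattern"),
               coef = vapply(cfg$gc$fragments, function(f) as.numeric(f$coef), 0))
  } else NULL
  gc <- gc_model(frags, intercept = as.numeric(cfg$gc$intercept %||% 0),
                 output_scale = out_scale)
  is <- cfg$interspecies
  map <- interspecies_map(
    slope = as.numeric(is$slope %||% 1), intercept = as.numeric(is$intercept %||% 0),
    input_scale = if (!is.null(is$input_scale))
      tox_scale(is$input_scale$quantity, is$input_scale$units) else out_scale,
    output_scale = if (!is.null(is$output_scale))
      tox_scale(is$output_scale$quantity, is$output_scale$units) else out_scale
  )
  pk_model(gc, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
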