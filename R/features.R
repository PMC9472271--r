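# FeatureSet container: named descriptor matrix and/or binary fingerprint
# matrix for an ordered molecule list.

#' Construct a feature set
#'
#' Container pairing an ordered molecule list with a descriptor matrix and/or
#' a binary fingerprint matrix. Row order of all matrices matches `mol_ids`.
#'
#' @param mol_ids character vector of unique molecule ids.
#' @param smiles optional SMILES aligned with `mol_ids`.
#' @param descriptors numeric matrix (molecules x descriptors) or NULL.
#' @param fingerprints 0/1 matrix (molecules x bits) or NULL.
#' @param fp_params list describing the fingerprint (`type`, `n_bits`).
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(mol_ids, smiles = NULL, descriptors = NULL,
                        fingerprints = NULL, fp_params = NULL) {
  assert_that(length(mol_ids) > 0 && !anyDuplicated(mol_ids),
              "mol_ids must be unique and non-empty")
  if (!is.null(descriptors)) {
    assert_that(nrow(descriptors) == length(mol_ids),
                "descriptor rows must match mol_ids")
    assert_that(!anyNA(descriptors), "descriptors must not contain missing values")
    assert_that(!anyDuplicated(colnames(descriptors)),
                "descriptor names must be unique")
    rownames(descriptors) <- mol_ids
  }
  if (!is.null(fingerprints)) {
    assert_that(nrow(fingerprints) == length(mol_ids),
                "fingerprint rows must match mol_ids")
    storage.mode(fingerprints) <- "integer"
    assert_that(all(fingerprints %in% c(0L, 1L)), "fingerprints must be binary")
    rownames(fingerprints) <- mol_ids
  }
  structure(list(mol_ids = as.character(mol_ids), smiles = smiles,
                 descriptors = descriptors, fingerprints = fingerprints,
                 fp_params = fp_params),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", length(x$mol_ids), " molecules\n", sep = "")
  if (!is.null(x$descriptors))
    cat("  descriptors: ", ncol(x$descriptors), " (",
        paste(utils::head(colnames(x$descriptors), 4), collapse = ", "),
        if (ncol(x$descriptors) > 4) ", ..." else "", ")\n", sep = "")
  if (!is.null(x$fingerprints))
    cat("  fingerprints: ", x$fp_params$type, ", ", ncol(x$fingerprints),
        " bits\n", sep = "")
  invisible(x)
}

#' Subset a feature set to named descriptor columns
#'
#' @param fs a [feature_set] with descriptors.
#' @param names descriptor columns to keep, in the requested order.
#' @return A new `feature_set` restricted to those columns.
#' @export
subset_descriptors <- function(fs, names) {
  stopifnot(inherits(fs, "feature_set"))
  assert_that(!is.null(fs$descriptors), "feature set has no descriptors")
  missing <- setdiff(names, colnames(fs$descriptors))
  if (length(missing) > 0) {
    th_stop(paste0("descriptor(s) absent from feature set: ",
                   paste(missing, collapse = ", ")),
            "toxhybrid_feature_error")
  }
  feature_set(fs$mol_ids, fs$smiles,
              descriptors = fs$descriptors[, names, drop = FALSE],
              fingerprints = fs$fingerprints, fp_params = fs$fp_params)
}

#' Fingerprint parameters
#'
#' @param type OpenBabel fingerprint name; default `"ECFP4"` (circular,
#'   radius 2).
#' @param n_bits target length; `NULL` keeps the provider's native length.
#'   If smaller, the fingerprint is folded (OR of halves), so `n_bits` must
#'   divide the native length by a power of two. Minimum 64.
#' @return list of class `fp_params`.
#' @export
fp_params <- function(type = "ECFP4", n_bits = NULL) {
  if (!is.null(n_bits)) {
    assert_that(is_count(n_bits) && n_bits >= 64, "n_bits must be >= 64",
                class = "toxhybrid_config_error")
  }
  structure(list(type = type, n_bits = n_bits), class = "fp_params")
}

#' Compute binary fingerprints
#'
#' One fixed-length binary vector per molecule; identical structures (same
#' canonical SMILES) give identical vectors.
#'
#' @param smiles character vector of valid SMILES, or a data.frame with a
#'   `smiles` column.
#' @param params a [fp_params()] object.
#' @param ids optional molecule ids.
#' @return A [feature_set] with the fingerprint matrix filled in.
#' @export
compute_fingerprints <- function(smiles, params = fp_params(), ids = NULL) {
  if (is.data.frame(smiles)) {
    if (is.null(ids) && "mol_id" %in% colnames(smiles)) ids <- smiles$mol_id
    smiles <- smiles$smiles
  }
  assert_that(inherits(params, "fp_params"), "params must come from fp_params()",
              class = "toxhybrid_config_error")
  p <- parse_smiles(smiles, ids)
  assert_that(all(p$ok), "all SMILES must parse; validate with load_dataset() first",
              class = "toxhybrid_parse_error")
  fps <- ChemmineR::fingerprintOB(p$sdf, params$type)
  m <- fps@fpma
  storage.mode(m) <- "integer"
  if (!is.null(params$n_bits) && params$n_bits != ncol(m)) {
    assert_that(params$n_bits < ncol(m) &&
                  ncol(m) %% params$n_bits == 0 &&
                  log2(ncol(m) / params$n_bits) %% 1 == 0,
                "n_bits must be the native length folded by a power of two",
                class = "toxhybrid_config_error")
    while (ncol(m) > params$n_bits) {
      half <- ncol(m) / 2
      m <- (m[, 1:half, drop = FALSE] | m[, (half + 1):(2 * half), drop = FALSE]) * 1L
    }
  }
  params$n_bits <- ncol(m)
  feature_set(p$ids, p$smiles, fingerprints = m, fp_params = params)
}

#' Featurize molecules with descriptors and fingerprints
#'
#' Convenience wrapper computing both representation types into a single
#' [feature_set].
#'
#' @inheritParams compute_descriptors
#' @param fp [fp_params()] or `NULL` to skip fingerprints.
#' @param descriptors descriptor names or `NULL` to skip descriptors.
#' @return A [feature_set].
#' @export
featurize <- function(smiles, descriptors = default_descriptor_panel(),
                      fp = fp_params(), ids = NULL) {
  assert_that(!is.null(descriptors) || !is.null(fp),
              "at least one representation must be requested")
  ds <- if (!is.null(descriptors)) compute_descriptors(smiles, descriptors, ids)
  fs <- if (!is.null(fp)) compute_fingerprints(smiles, fp, ids)
  if (is.null(ds)) return(fs)
  if (is.null(fs)) return(ds)
  feature_set(ds$mol_ids, ds$smiles, descriptors = ds$descriptors,
              fingerprints = fs$fingerprints, fp_params = fs$fp_params)
}

#' Count trend-rule fragments for one molecule
#'
#' Counts the structural features used by the scoped trend rules: carbon
#' atoms, amine-nitrogen presence, ether/methoxy oxygen presence, and
#' N-bonded methyl groups.
#'
#' @param smiles a single SMILES string.
#' @return named numeric vector with `nC`, `has_amine`, `has_methoxy`,
#'   `n_NCH3`.
#' @export
count_rule_fragments <- function(smiles) {
  assert_that(is.character(smiles) && length(smiles) == 1L,
              "smiles must be a single string")
  p <- parse_smiles(smiles)
  assert_that(all(p$ok), "SMILES must parse", class = "toxhybrid_parse_error")
  fc <- fragment_counts_sdf(p$sdf)
  g <- mol_graph(p$sdf[[1]])
  c(nC = sum(g$element == "C"),
    has_amine = as.numeric(fc[1, "nAmine"] > 0),
    has_methoxy = as.numeric(fc[1, "nEther"] > 0),
    n_NCH3 = unname(fc[1, "n_NCH3"]))
}
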