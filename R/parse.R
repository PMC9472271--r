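# SMILES parsing and canonicalization via ChemmineR/ChemmineOB (OpenBabel).
# All structure handling in the package funnels through parse_smiles() so the
# provider is swappable in one place.

#' Parse SMILES strings into an SDF container
#'
#' Parses a character vector of SMILES with OpenBabel (via
#' [ChemmineR::smiles2sdf()]). Unparseable entries are reported per molecule
#' rather than failing the batch.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional molecule identifiers (defaults to `m1`, `m2`, ...).
#' @return A list with elements:
#'   \describe{
#'     \item{sdf}{`SDFset` of the successfully parsed molecules.}
#'     \item{ok}{logical vector over the input, `TRUE` where parsed.}
#'     \item{ids}{ids of the parsed molecules, aligned with `sdf`.}
#'     \item{smiles}{input SMILES of the parsed molecules.}
#'   }
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  assert_that(is.character(smiles) && length(smiles) > 0,
              "smiles must be a non-empty character vector")
  if (is.null(ids)) {
    ids <- if (!is.null(names(smiles)) && all(nzchar(names(smiles)))) {
      names(smiles)
    } else paste0("m", seq_along(smiles))
  }
  assert_that(length(ids) == length(smiles) && !anyDuplicated(ids),
              "ids must be unique and match smiles in length")
  names(smiles) <- ids

  batch <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                    error = function(e) NULL)
  if (!is.null(batch) && length(batch) == length(smiles)) {
    ok <- rep(TRUE, length(smiles))
  } else {
    # Fall back to per-molecule parsing to locate the failures.
    ok <- vapply(seq_along(smiles), function(i) {
      !is.null(tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
                        error = function(e) NULL))
    }, logical(1))
    if (!any(ok)) {
      return(list(sdf = NULL, ok = ok, ids = character(0), smiles = character(0)))
    }
    batch <- suppressWarnings(ChemmineR::smiles2sdf(smiles[ok]))
  }
  list(sdf = batch, ok = ok, ids = ids[ok], smiles = unname(smiles[ok]))
}

#' Canonical SMILES
#'
#' Returns the OpenBabel canonical SMILES for each input, used to recognise
#' identical structures written differently (e.g. `CCO` vs `OCC`).
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  p <- parse_smiles(smiles)
  assert_that(all(p$ok), "all SMILES must parse for canonicalization",
              class = "toxhybrid_parse_error")
  pr <- ob_properties(p$sdf)
  as.character(pr$cansmiNS)
}

# Count SMARTS matches per molecule over an SDFset. `unique_sets` collapses
# matches that involve the same atom set (e.g. C-O-C matched in both
# directions); directional counting is wanted for e.g. N-CH3 enumeration.
smarts_count <- function(sdf, smarts, unique_sets = TRUE) {
  ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = unique_sets)
}

# OpenBabel bulk properties for an SDFset: cansmi, formula, logP, MR, MW,
# TPSA, HBD, HBA1/2 ...
ob_properties <- function(sdf) {
  ChemmineR::propOB(sdf)
}
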