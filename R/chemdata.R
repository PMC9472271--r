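# Molecule-table handling: CSV I/O, the -ln(LC50) toxicity transform,
# ECHA-style T/PT/NT hazard labelling and the saturated-C/H/O/N structural
# filter that defines the modelling domain.

#' Toxicity transform
#'
#' Converts an acute L(E)C50 in mg/L to the modelling scale
#' `tox = -ln(LC50)`. Strictly decreasing: lower effect concentrations
#' (more toxic) map to larger tox values.
#'
#' @param lc50 positive numeric vector, mg/L.
#' @return numeric vector of tox values.
#' @export
tox_transform <- function(lc50) {
  assert_that(is.numeric(lc50) && all(is.finite(lc50)),
              "lc50 must be finite numeric", class = "toxhybrid_domain_error")
  if (any(lc50 <= 0)) {
    th_stop("lc50 must be strictly positive (mg/L)", "toxhybrid_domain_error")
  }
  -log(lc50)
}

#' Hazard threshold configuration
#'
#' Screening cutoffs on the raw LC50 scale (mg/L): substances below `t_cut`
#' are Toxic (T), below `pt_cut` Potentially Toxic (PT), otherwise Not
#' Toxic (NT) at the screening level.
#'
#' @param t_cut T cutoff in mg/L (default 0.01).
#' @param pt_cut PT cutoff in mg/L (default 0.1).
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(t_cut = 0.01, pt_cut = 0.1) {
  assert_that(is_number(t_cut) && is_number(pt_cut) && t_cut > 0 && t_cut < pt_cut,
              "need 0 < t_cut < pt_cut", class = "toxhybrid_config_error")
  structure(list(t_cut = t_cut, pt_cut = pt_cut), class = "threshold_config")
}

#' Classify hazard category from LC50
#'
#' @param lc50 positive numeric vector, mg/L.
#' @param cfg a [threshold_config()].
#' @return factor with levels `T`, `PT`, `NT`. `T` iff `lc50 < t_cut`;
#'   `PT` iff `t_cut <= lc50 < pt_cut`; `NT` iff `lc50 >= pt_cut`.
#' @export
classify_hazard <- function(lc50, cfg = threshold_config()) {
  assert_that(inherits(cfg, "threshold_config"),
              "cfg must come from threshold_config()",
              class = "toxhybrid_config_error")
  assert_that(is.numeric(lc50) && all(is.finite(lc50)) && all(lc50 > 0),
              "lc50 must be positive", class = "toxhybrid_domain_error")
  lab <- ifelse(lc50 < cfg$t_cut, "T", ifelse(lc50 < cfg$pt_cut, "PT", "NT"))
  factor(lab, levels = c("T", "PT", "NT"))
}

#' Load a molecule table
#'
#' Reads a CSV table of molecules with SMILES and acute LC50/EC50 (mg/L),
#' canonicalizes the structures, and drops rows whose SMILES do not parse or
#' whose LC50 is not strictly positive (each drop is reported via a warning
#' and in the `dropped` attribute).
#'
#' @param path CSV file path.
#' @param column_map named list mapping roles to column names; defaults to
#'   `list(smiles = "SMILES", lc50 = "LC50_mgL", id = NULL)` (`id = NULL`
#'   generates `m1`, `m2`, ...).
#' @param thresholds [threshold_config()] used for hazard labels.
#' @return data.frame with columns `mol_id`, `smiles` (canonical), `smiles_in`,
#'   `lc50_mg_per_l`, `tox`, `hazard`; attribute `dropped` is a data.frame of
#'   removed rows with reason codes.
#' @export
load_dataset <- function(path,
                         column_map = list(smiles = "SMILES", lc50 = "LC50_mgL",
                                           id = NULL),
                         thresholds = threshold_config()) {
  assert_that(file.exists(path), paste0("no such file: ", path),
              class = "toxhybrid_io_error")
  raw <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    assert_that(requireNamespace("readxl", quietly = TRUE),
                "reading Excel files requires the readxl package",
                class = "toxhybrid_io_error")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c(column_map$smiles, column_map$lc50)
  miss <- setdiff(need, colnames(raw))
  if (length(miss) > 0) {
    th_stop(paste0("missing column(s): ", paste(miss, collapse = ", ")),
            "toxhybrid_schema_error")
  }
  ids <- if (!is.null(column_map$id) && column_map$id %in% colnames(raw)) {
    as.character(raw[[column_map$id]])
  } else paste0("m", seq_len(nrow(raw)))
  build_dataset(smiles = as.character(raw[[column_map$smiles]]),
                lc50 = suppressWarnings(as.numeric(raw[[column_map$lc50]])),
                ids = ids, thresholds = thresholds)
}

#' Build a validated molecule table from vectors
#'
#' In-memory equivalent of [load_dataset()]; used by the synthetic generator
#' and by tests.
#'
#' @param smiles character vector.
#' @param lc50 numeric vector, mg/L.
#' @param ids optional ids.
#' @param thresholds [threshold_config()].
#' @return See [load_dataset()].
#' @export
build_dataset <- function(smiles, lc50, ids = NULL,
                          thresholds = threshold_config()) {
  assert_that(length(smiles) == length(lc50), "smiles and lc50 lengths differ")
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  reason <- rep(NA_character_, length(smiles))
  bad_lc <- !is.finite(lc50) | lc50 <= 0
  reason[bad_lc] <- "nonpositive_or_missing_lc50"
  p <- parse_smiles(ifelse(is.na(smiles) | smiles == "", "?", smiles), ids)
  reason[!p$ok & is.na(reason)] <- "unparseable_smiles"
  keep <- is.na(reason)
  if (!all(keep)) {
    warning(sprintf("dropped %d of %d rows (%s)", sum(!keep), length(keep),
                    paste(unique(reason[!keep]), collapse = ", ")))
  }
  if (!any(keep)) th_stop("no valid rows in dataset", "toxhybrid_empty_error")
  kp <- parse_smiles(smiles[keep], ids[keep])
  cans <- as.character(ob_properties(kp$sdf)$cansmiNS)
  out <- data.frame(
    mol_id = ids[keep],
    smiles = cans,
    smiles_in = smiles[keep],
    lc50_mg_per_l = lc50[keep],
    tox = tox_transform(lc50[keep]),
    hazard = classify_hazard(lc50[keep], thresholds),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- data.frame(mol_id = ids[!keep],
                                     smiles = smiles[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Write a molecule table
#'
#' Canonical CSV output with the derived `tox` and `hazard` columns appended.
#'
#' @param records data.frame from [load_dataset()]/[build_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Filter to saturated aliphatic C/H/O/N compounds
#'
#' Keeps molecules whose element set is within {C, H, O, N}, that contain no
#' aromatic atoms and no carbon-carbon double or triple bonds. Carbonyl and
#' other heteroatom multiple bonds are allowed ("saturated" refers to the
#' carbon skeleton), so aliphatic acids, amides and ketones stay in domain.
#'
#' @param records data.frame with a `smiles` column of valid SMILES.
#' @return list with `kept` (subset of `records`) and `rejected` (data.frame
#'   with `mol_id`, `smiles`, `reason` in
#'   {`element`, `aromatic`, `cc_multiple_bond`}).
#' @export
filter_chon_saturated <- function(records) {
  assert_that(is.data.frame(records) && "smiles" %in% colnames(records),
              "records must have a smiles column")
  if (nrow(records) == 0) {
    return(list(kept = records,
                rejected = data.frame(mol_id = character(0), smiles = character(0),
                                      reason = character(0))))
  }
  ids <- if ("mol_id" %in% colnames(records)) records$mol_id
         else paste0("m", seq_len(nrow(records)))
  p <- parse_smiles(records$smiles, ids)
  assert_that(all(p$ok), "all SMILES must parse", class = "toxhybrid_parse_error")
  sdf <- p$sdf
  n <- length(sdf)
  bad_el <- vapply(seq_len(n), function(i) {
    el <- unique(sub("_.*$", "", rownames(ChemmineR::atomblock(sdf[[i]]))))
    !all(el %in% c("C", "H", "O", "N"))
  }, logical(1))
  aromatic <- as.numeric(smarts_count(sdf, "[a]")) > 0
  cc_mult <- as.numeric(smarts_count(sdf, "[#6]=,#[#6]")) > 0
  reason <- rep(NA_character_, n)
  reason[cc_mult] <- "cc_multiple_bond"
  reason[aromatic] <- "aromatic"
  reason[bad_el] <- "element"
  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       rejected = data.frame(mol_id = ids[!keep],
                             smiles = records$smiles[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
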