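# Prior-knowledge hybridization schemes wrapped around the kNN and PK
# models:
#   H0 - molecular-weight outlier removal before training;
#   H1 - knowledge-driven descriptor selection before training;
#   H2 - logP-routed switch between the fingerprint kNN and the PKM;
#   H3 - PKM-guided neighbour selection.

#' Hybridization configuration
#'
#' @param mw_threshold H0 outlier cutoff in g/mol; molecules strictly above
#'   it are removed (default 300).
#' @param pk_descriptors H1 descriptor subset; defaults to the six
#'   knowledge-selected descriptors LogP (here `MolLogP`), `AATSC0p`,
#'   `TPSA`, `ETA_dEpsilon_A`, `SHBd`, `Mi`.
#' @param logp_low,logp_high H2 routing band (closed interval, defaults 1.5
#'   and 4.0): queries with logP inside it go to the fingerprint kNN, the
#'   rest to the PKM.
#' @param k neighbour count for the wrapped kNN.
#' @return list of class `hybrid_config`.
#' @export
hybrid_config <- function(mw_threshold = 300,
                          pk_descriptors = c("MolLogP", "AATSC0p", "TPSA",
                                             "ETA_dEpsilon_A", "SHBd", "Mi"),
                          logp_low = 1.5, logp_high = 4.0, k = 5) {
  assert_that(is_number(mw_threshold) && mw_threshold > 0,
              "mw_threshold must be positive", class = "toxhybrid_config_error")
  assert_that(length(pk_descriptors) > 0, "pk_descriptors must be non-empty",
              class = "toxhybrid_config_error")
  assert_that(is_number(logp_low) && is_number(logp_high) && logp_low < logp_high,
              "need logp_low < logp_high", class = "toxhybrid_config_error")
  assert_that(is_count(k), "k must be a positive integer",
              class = "toxhybrid_config_error")
  structure(list(mw_threshold = mw_threshold, pk_descriptors = pk_descriptors,
                 logp_low = logp_low, logp_high = logp_high, k = as.integer(k)),
            class = "hybrid_config")
}

#' H0: molecular-weight outlier removal
#'
#' Splits molecules into kept (MW <= threshold) and outliers (MW strictly
#' above). The downstream model is retrained on `kept`. An optional
#' `extra_predicate` hook can refine the outlier rule with further
#' descriptors.
#'
#' @param records data.frame of molecules.
#' @param mw numeric vector of molecular weights (g/mol) aligned with
#'   `records` (e.g. the `MW` descriptor column).
#' @param cfg a [hybrid_config()].
#' @param extra_predicate optional `function(records) logical` marking
#'   additional outliers.
#' @return list with `kept`, `outliers` (row subsets) and logical `is_outlier`.
#' @export
h0_filter <- function(records, mw, cfg = hybrid_config(),
                      extra_predicate = NULL) {
  assert_that(is.numeric(mw) && length(mw) == nrow(records) && !anyNA(mw),
              "mw must be numeric, complete, aligned with records",
              class = "toxhybrid_feature_error")
  out <- mw > cfg$mw_threshold
  if (!is.null(extra_predicate)) out <- out | extra_predicate(records)
  list(kept = records[!out, , drop = FALSE],
       outliers = records[out, , drop = FALSE],
       is_outlier = out)
}

#' H1: knowledge-driven descriptor selection
#'
#' Restricts a feature set to the configured prior-knowledge descriptors, in
#' config order; the descriptor kNN is then trained in the reduced space.
#'
#' @param features a [feature_set] with descriptors.
#' @param cfg a [hybrid_config()].
#' @return the column-restricted [feature_set].
#' @export
h1_select <- function(features, cfg = hybrid_config()) {
  subset_descriptors(features, cfg$pk_descriptors)
}

#' H2: logP-routed kNN / PKM switch
#'
#' Builds the routed predictor: queries with computed logP inside the closed
#' band route to the fingerprint kNN model, all others to the
#' prior-knowledge model. The router adds no arithmetic of its own.
#'
#' @param knn_model a fitted fingerprint-mode [tox_knn()].
#' @param pkm a [pk_model()].
#' @param cfg a [hybrid_config()].
#' @return object of class `hybrid_h2`.
#' @export
hybrid_h2 <- function(knn_model, pkm, cfg = hybrid_config()) {
  stopifnot(inherits(knn_model, "tox_knn"), inherits(pkm, "pk_model"))
  assert_that(knn_model$mode == "fingerprint",
              "H2 wraps the fingerprint-based kNN model",
              class = "toxhybrid_config_error")
  structure(list(knn = knn_model, pkm = pkm, cfg = cfg), class = "hybrid_h2")
}

#' Predict with the H2 routed model
#'
#' @param object a [hybrid_h2()].
#' @param newdata a [feature_set] carrying fingerprints and a `MolLogP`
#'   descriptor column (plus SMILES for the PKM route).
#' @param descriptors optional descriptor matrix for `desc:`-typed GC terms;
#'   defaults to the feature set's own descriptors.
#' @param ... unused.
#' @return data.frame with `tox` and `route` (`"knn"` or `"pkm"`).
#' @export
predict.hybrid_h2 <- function(object, newdata, descriptors = NULL, ...) {
  stopifnot(inherits(newdata, "feature_set"))
  assert_that(!is.null(newdata$descriptors) &&
                "MolLogP" %in% colnames(newdata$descriptors),
              "newdata must carry a MolLogP descriptor column",
              class = "toxhybrid_feature_error")
  assert_that(!is.null(newdata$fingerprints) && !is.null(newdata$smiles),
              "newdata must carry fingerprints and SMILES",
              class = "toxhybrid_feature_error")
  logp <- newdata$descriptors[, "MolLogP"]
  use_knn <- logp >= object$cfg$logp_low & logp <= object$cfg$logp_high
  n <- length(logp)
  tox <- numeric(n)
  if (any(use_knn)) {
    tox[use_knn] <- predict(object$knn,
                            newdata$fingerprints[use_knn, , drop = FALSE],
                            k = object$cfg$k)
  }
  if (any(!use_knn)) {
    dsc <- descriptors
    if (is.null(dsc)) dsc <- newdata$descriptors
    tox[!use_knn] <- predict(object$pkm, newdata$smiles[!use_knn],
                             descriptors = dsc[!use_knn, , drop = FALSE])
  }
  data.frame(mol_id = newdata$mol_ids, tox = tox,
             route = ifelse(use_knn, "knn", "pkm"),
             stringsAsFactors = FALSE)
}

#' @export
print.hybrid_h2 <- function(x, ...) {
  cat("H2 hybrid: fingerprint kNN for logP in [",
      x$cfg$logp_low, ", ", x$cfg$logp_high, "], PKM otherwise\n", sep = "")
  print(x$knn)
  invisible(x)
}

#' H3: prior-knowledge-guided neighbour selection
#'
#' Neighbours of a query are the k training molecules whose PKM predictions
#' are closest to the query's PKM prediction (ties broken by ascending
#' training index); the estimate is the mean of those neighbours' observed
#' tox values.
#'
#' @param query_pkm numeric vector of PKM predictions for the queries.
#' @param train_pkm numeric vector of PKM predictions for the training set.
#' @param train_tox observed tox values of the training set.
#' @param k neighbour count.
#' @return numeric vector of predictions, one per query.
#' @export
h3_predict <- function(query_pkm, train_pkm, train_tox, k) {
  assert_that(length(train_pkm) == length(train_tox),
              "train_pkm and train_tox lengths differ")
  assert_that(is_count(k) && k <= length(train_pkm),
              "k exceeds the number of training molecules",
              class = "toxhybrid_parameter_error")
  vapply(query_pkm, function(q) {
    d <- abs(train_pkm - q)
    mean(train_tox[order(d, seq_along(d))[seq_len(k)]])
  }, numeric(1))
}
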