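# Rule-based post-assessment (the "H4" audit): literature toxicity-trend
# rules, Spearman compliance matrix of rule features vs model predictions,
# the min-max rule-affinity score, and the regression/classification metrics
# used to summarize model performance.

#' Literature trend rule set
#'
#' The 16 descriptor-level toxicity trends collected from the acute-aquatic-
#' toxicity literature: each rule names a feature, an expected sign of its
#' correlation with toxicity, and (for the chain-length and N-methyl rules)
#' a scope predicate restricting which molecules are correlated.
#'
#' Scope predicates are feature-resolved: `contains_amine` (nAmine > 0),
#' `contains_methoxy` (nEther > 0), `contains_N` (nN > 0).
#'
#' @return data.frame with columns `rule_id`, `feature`, `expected_sign`,
#'   `scope`, `source_note`.
#' @export
default_rules <- function() {
  data.frame(
    rule_id = c("logp_up", "mr_up", "gats1p_down", "aatsc0p_up", "tpsa_down",
                "shbd_down", "maxhbint2_down", "eta_deps_a_down", "mi_down",
                "gats1i_down", "mw_up", "eta_alpha_up", "eta_etap_b_down",
                "nc_amine_up", "nc_methoxy_up", "nch3_down"),
    feature = c("MolLogP", "MR", "GATS1p", "AATSC0p", "TPSA",
                "SHBd", "maxHBint2", "ETA_dEpsilon_A", "Mi",
                "GATS1i", "MW", "ETA_Alpha", "ETA_EtaP_B",
                "nC", "nC", "n_NCH3"),
    expected_sign = c(+1, +1, -1, +1, -1,
                      -1, -1, -1, -1,
                      -1, +1, +1, -1,
                      +1, +1, -1),
    scope = c(NA, NA, NA, NA, NA,
              NA, NA, NA, NA,
              NA, NA, NA, NA,
              "contains_amine", "contains_methoxy", "contains_N"),
    source_note = c(
      "toxicity increases with hydrophobicity",
      "toxicity increases with polarizability (molar refractivity)",
      "toxicity decreases with GATS1p",
      "toxicity increases with AATSC0p",
      "toxicity decreases with topological polar surface area",
      "most-toxic compounds are H-bond acceptors, not donors (SHBd low)",
      "most-toxic compounds are H-bond acceptors, not donors (maxHBint2 low)",
      "unsaturation/electronegative-atom effect via ETA_dEpsilon_A",
      "toxicity decreases with ionization potential (Mi)",
      "toxicity decreases with GATS1i",
      "toxicity increases with molecular weight",
      "toxicity increases with molecular bulk (ETA_Alpha)",
      "branching decreases toxicity (ETA_EtaP_B)",
      "amine toxicity increases with chain length",
      "ethoxylate/methoxy toxicity increases with alkyl chain length",
      "N-methylation reduces amine toxicity"
    ),
    stringsAsFactors = FALSE
  )
}

# Resolve a scope predicate name to a logical vector over molecules, using
# descriptor columns.
scope_mask <- function(scope, descriptors) {
  if (is.na(scope)) return(rep(TRUE, nrow(descriptors)))
  need <- switch(scope,
                 contains_amine = "nAmine",
                 contains_methoxy = "nEther",
                 contains_N = "nN",
                 th_stop(paste0("unknown scope predicate: ", scope),
                         "toxhybrid_config_error"))
  assert_that(need %in% colnames(descriptors),
              paste0("scope predicate needs descriptor ", need),
              class = "toxhybrid_feature_error")
  descriptors[, need] > 0
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged). Undefined (NA, with
#' a warning suppressed) when either vector is constant after ranking or
#' fewer than 3 pairs are available.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    th_stop("vector lengths differ", "toxhybrid_dimension_error")
  }
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Compliance matrix of rules against model predictions
#'
#' For every rule and every prediction column, the Spearman correlation
#' between the rule's feature and the predictions, restricted to the rule's
#' scope. Cells with fewer than 3 in-scope molecules are undefined (NA),
#' not zero. Include the measured tox values as a column named `"Data"` to
#' show the reference trends alongside the models.
#'
#' @param predictions named list of numeric vectors (one per model, equal
#'   lengths, same molecule order) -- e.g.
#'   `list(Data = records$tox, DESC_5 = pred)`.
#' @param features a [feature_set] whose descriptors contain every rule
#'   feature and scope column.
#' @param rules rule data.frame as from [default_rules()].
#' @return object of class `compliance_matrix`: list with `rho`
#'   (rules x models), `n_used` (matching sample sizes), `rules`, `models`.
#' @export
compliance_matrix <- function(predictions, features, rules = default_rules()) {
  assert_that(is.list(predictions) && length(predictions) >= 1 &&
                !is.null(names(predictions)) && all(nzchar(names(predictions))),
              "predictions must be a named list")
  stopifnot(inherits(features, "feature_set"))
  desc <- features$descriptors
  assert_that(!is.null(desc), "features must carry descriptors",
              class = "toxhybrid_feature_error")
  n <- nrow(desc)
  lens <- vapply(predictions, length, 0L)
  assert_that(all(lens == n), "all prediction vectors must match the molecule set")
  missing <- setdiff(rules$feature, colnames(desc))
  assert_that(length(missing) == 0,
              paste0("rule feature(s) absent: ", paste(missing, collapse = ", ")),
              class = "toxhybrid_feature_error")
  nr <- nrow(rules); nm <- length(predictions)
  rho <- matrix(NA_real_, nr, nm, dimnames = list(rules$rule_id, names(predictions)))
  n_used <- matrix(0L, nr, nm, dimnames = dimnames(rho))
  for (r in seq_len(nr)) {
    mask <- scope_mask(rules$scope[r], desc)
    feat <- desc[mask, rules$feature[r]]
    for (m in seq_len(nm)) {
      pred <- predictions[[m]][mask]
      n_used[r, m] <- sum(mask)
      if (sum(mask) >= 3) rho[r, m] <- spearman_rho(feat, pred)
    }
  }
  structure(list(rho = rho, n_used = n_used, rules = rules,
                 models = names(predictions)),
            class = "compliance_matrix")
}

#' @export
print.compliance_matrix <- function(x, digits = 2, ...) {
  cat("Rule-compliance matrix (Spearman rho, rules x models)\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Plot a compliance heatmap
#'
#' Base-graphics heatmap of the compliance matrix: red positive, blue
#' negative correlation with toxicity.
#'
#' @param x a [compliance_matrix()].
#' @param ... passed to [graphics::image()].
#' @export
plot.compliance_matrix <- function(x, ...) {
  z <- t(x$rho)[, rev(seq_len(nrow(x$rho))), drop = FALSE]
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 1,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Rule affinity of models
#'
#' Compliance score per model: each rule's correlations are sign-adjusted by
#' the rule's expected direction (`s = expected_sign * rho`), min-max
#' normalized across models within the rule (degenerate ranges map to 0.5),
#' and summed over rules. Scores lie in `[0, n_scored_rules]`; a model that
#' is the best-complying model under every rule scores the maximum.
#'
#' Rules with any undefined correlation among the scored models are dropped
#' (recorded in `dropped_rules`). A reference column (e.g. `"Data"`) can be
#' excluded from normalization via `exclude`.
#'
#' @param cm a [compliance_matrix()].
#' @param exclude model columns to leave out of scoring (default `"Data"`).
#' @return list with `affinity` (named numeric), `normalized` (rules x
#'   models matrix of u-scores), `dropped_rules`.
#' @export
rule_affinity <- function(cm, exclude = "Data") {
  stopifnot(inherits(cm, "compliance_matrix"))
  keep_models <- setdiff(colnames(cm$rho), exclude)
  if (length(keep_models) < 2) {
    th_stop("rule affinity needs at least two models to normalize across",
            "toxhybrid_parameter_error")
  }
  rho <- cm$rho[, keep_models, drop = FALSE]
  sgn <- cm$rules$expected_sign
  s <- rho * sgn
  defined <- apply(s, 1, function(r) all(is.finite(r)))
  dropped <- rownames(rho)[!defined]
  s <- s[defined, , drop = FALSE]
  u <- t(apply(s, 1, function(r) {
    rng <- max(r) - min(r)
    if (rng == 0) rep(0.5, length(r)) else (r - min(r)) / rng
  }))
  colnames(u) <- keep_models
  list(affinity = colSums(u), normalized = u, dropped_rules = dropped)
}

#' Regression performance metrics
#'
#' @param y_true observed values.
#' @param y_pred predicted values, same length (>= 2).
#' @return named vector `r2` (1 - SS_res/SS_tot) and `spearman`. `r2` is
#'   undefined (error) for constant `y_true`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred) && length(y_true) >= 2,
              "need equal lengths >= 2", class = "toxhybrid_dimension_error")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    th_stop("r2 undefined for constant y_true", "toxhybrid_domain_error")
  }
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  c(r2 = r2, spearman = spearman_rho(y_true, y_pred))
}

#' Classification metrics for hazard labels
#'
#' Three-label (T/PT/NT) metrics that account for label imbalance: balanced
#' accuracy is the unweighted mean of per-class recalls over the classes
#' present in `labels_true`; precision and recall are support-weighted
#' averages of the per-class values; classes absent from the truth carry no
#' support weight.
#'
#' @param labels_true,labels_pred factors or characters with values in
#'   {T, PT, NT}.
#' @return named vector `balanced_accuracy`, `precision`, `recall`, all in
#'   \[0, 1\].
#' @export
classification_metrics <- function(labels_true, labels_pred) {
  assert_that(length(labels_true) > 0, "empty input",
              class = "toxhybrid_dimension_error")
  assert_that(length(labels_true) == length(labels_pred),
              "label vectors differ in length", class = "toxhybrid_dimension_error")
  lev <- c("T", "PT", "NT")
  t_ <- factor(as.character(labels_true), levels = lev)
  p_ <- factor(as.character(labels_pred), levels = lev)
  assert_that(!anyNA(t_) && !anyNA(p_), "labels must be in {T, PT, NT}",
              class = "toxhybrid_domain_error")
  cmx <- table(t_, p_)
  present <- lev[rowSums(cmx) > 0]
  rec <- vapply(present, function(cl) cmx[cl, cl] / sum(cmx[cl, ]), 0)
  prec <- vapply(present, function(cl) {
    pp <- sum(cmx[, cl])
    if (pp == 0) 0 else cmx[cl, cl] / pp
  }, 0)
  support <- vapply(present, function(cl) sum(cmx[cl, ]), 0)
  w <- support / sum(support)
  c(balanced_accuracy = mean(rec),
    precision = sum(w * prec),
    recall = sum(w * rec))
}
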