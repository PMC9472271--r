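# k-nearest-neighbour toxicity predictors.
#
# Two neighbourhood definitions:
#   * fingerprint mode: descending Tanimoto similarity on binary fingerprints;
#   * descriptor mode: ascending Manhattan distance on z-scaled descriptors
#     (scaling fitted on the training rows only).
# Ties are broken by ascending training index so results are reproducible.

#' Tanimoto similarity between binary vectors
#'
#' `|a AND b| / |a OR b|` over on-bits. By documented convention the
#' similarity of two all-zero vectors is 1 (identical empty structures).
#'
#' @param a,b binary vectors (0/1 or logical) of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    th_stop("fingerprint lengths differ", "toxhybrid_dimension_error")
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1.0)
  sum(a & b) / un
}

#' Manhattan distance between numeric vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sum(|x - y|)`.
#' @export
manhattan <- function(x, y) {
  if (length(x) != length(y)) {
    th_stop("vector lengths differ", "toxhybrid_dimension_error")
  }
  sum(abs(x - y))
}

# Similarity of every query fingerprint row to every training row.
# qa: nq x bits, tr: nt x bits (0/1 integer). Returns nq x nt matrix.
tanimoto_matrix <- function(qa, tr) {
  inter <- qa %*% t(tr)
  na <- rowSums(qa); nb <- rowSums(tr)
  un <- outer(na, nb, "+") - inter
  out <- ifelse(un == 0, 1.0, inter / pmax(un, 1))
  out
}

manhattan_matrix <- function(qx, tx) {
  nq <- nrow(qx); nt <- nrow(tx)
  out <- matrix(0, nq, nt)
  for (i in seq_len(nq)) {
    out[i, ] <- colSums(abs(t(tx) - qx[i, ]))
  }
  out
}

#' Fit a kNN toxicity model
#'
#' Stores the training representation and targets; prediction averages the
#' targets of the k nearest training molecules. In descriptor mode the
#' training columns are z-scaled (zero-variance columns are dropped and
#' recorded) and queries are scaled with the training parameters.
#'
#' @param x training features: a [feature_set], or a numeric matrix
#'   (descriptor mode) / 0-1 matrix (fingerprint mode).
#' @param y numeric vector of training tox values (`-ln` LC50 mg/L).
#' @param mode `"descriptor"` (Manhattan) or `"fingerprint"` (Tanimoto).
#' @param k number of neighbours (default 5).
#' @param weight `"uniform"` (arithmetic mean, default) or `"distance"`
#'   (inverse-distance / similarity weighted mean).
#' @return Object of class `tox_knn`.
#' @seealso [predict.tox_knn()], [select_k()]
#' @export
tox_knn <- function(x, y, mode = c("descriptor", "fingerprint"), k = 5,
                    weight = c("uniform", "distance")) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  m <- knn_matrix(x, mode)
  assert_that(is.numeric(y) && length(y) == nrow(m) && all(is.finite(y)),
              "y must be finite numeric matching rows of x")
  assert_that(is_count(k) && k <= nrow(m),
              "k must be a positive integer <= number of training molecules",
              class = "toxhybrid_parameter_error")
  scaler <- NULL
  if (mode == "descriptor") {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    keep <- sd > 0
    scaler <- list(mean = mu[keep], sd = sd[keep],
                   dropped = colnames(m)[!keep], columns = colnames(m)[keep])
    m <- scale(m[, keep, drop = FALSE], center = mu[keep], scale = sd[keep])
  }
  structure(list(mode = mode, k = as.integer(k), weight = weight,
                 train = m, y = y, scaler = scaler, n_train = nrow(m)),
            class = "tox_knn")
}

# Extract the matrix for the model's mode from flexible input.
knn_matrix <- function(x, mode) {
  if (inherits(x, "feature_set")) {
    x <- if (mode == "descriptor") x$descriptors else x$fingerprints
    assert_that(!is.null(x), paste0("feature set lacks ", mode, " data"),
                class = "toxhybrid_feature_error")
  }
  assert_that(is.matrix(x) && nrow(x) > 0, "x must be a non-empty matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  storage.mode(x) <- if (mode == "fingerprint") "integer" else "double"
  x
}

# Scale query descriptors with the training scaler.
scale_query <- function(object, m) {
  sc <- object$scaler
  miss <- setdiff(sc$columns, colnames(m))
  assert_that(length(miss) == 0,
              paste0("query lacks descriptor(s): ", paste(miss, collapse = ", ")),
              class = "toxhybrid_feature_error")
  scale(m[, sc$columns, drop = FALSE], center = sc$mean, scale = sc$sd)
}

#' Find nearest training neighbours
#'
#' @param object a fitted [tox_knn()] model.
#' @param newdata query features (matrix or [feature_set]).
#' @param k neighbourhood size; defaults to the model's k.
#' @param exclude_self integer vector (one per query row) of training indices
#'   to exclude, for leave-one-out evaluation on the training set; `NULL` for
#'   none.
#' @return integer matrix (queries x k) of training indices, nearest first;
#'   ties broken by ascending training index.
#' @export
find_neighbors <- function(object, newdata, k = object$k, exclude_self = NULL) {
  stopifnot(inherits(object, "tox_knn"))
  m <- knn_matrix(newdata, object$mode)
  n_avail <- object$n_train - as.integer(!is.null(exclude_self))
  assert_that(is_count(k) && k <= n_avail,
              "k exceeds the number of available training molecules",
              class = "toxhybrid_parameter_error")
  if (object$mode == "descriptor") {
    d <- manhattan_matrix(scale_query(object, m), object$train)
  } else {
    if (ncol(m) != ncol(object$train)) {
      th_stop("fingerprint lengths differ", "toxhybrid_dimension_error")
    }
    d <- -tanimoto_matrix(m, object$train)   # negate: smaller is nearer
  }
  if (!is.null(exclude_self)) {
    assert_that(length(exclude_self) == nrow(d),
                "exclude_self must have one index per query row")
    d[cbind(seq_len(nrow(d)), exclude_self)] <- Inf
  }
  idx <- matrix(0L, nrow(d), k)
  for (i in seq_len(nrow(d))) {
    # order() is stable; secondary key = training index for tie-breaks
    idx[i, ] <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
  }
  attr(idx, "distance") <- d
  idx
}

#' Predict toxicity with a kNN model
#'
#' @inheritParams find_neighbors
#' @param ... unused.
#' @return numeric vector of predicted tox values (`-ln` LC50 mg/L).
#' @export
predict.tox_knn <- function(object, newdata, k = object$k,
                            exclude_self = NULL, ...) {
  idx <- find_neighbors(object, newdata, k = k, exclude_self = exclude_self)
  knn_aggregate(object, idx, attr(idx, "distance"))
}

# Average neighbour targets given an index matrix and the (signed) distance
# matrix produced by find_neighbors.
knn_aggregate <- function(object, idx, d) {
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    yy <- object$y[idx[i, ]]
    if (object$weight == "uniform") {
      out[i] <- mean(yy)
    } else {
      dd <- d[i, idx[i, ]]
      if (object$mode == "fingerprint") dd <- 1 + dd  # back to 1 - similarity
      w <- 1 / pmax(dd, .Machine$double.eps)
      out[i] <- sum(w * yy) / sum(w)
    }
  }
  out
}

#' @export
print.tox_knn <- function(x, ...) {
  cat("kNN toxicity model (", x$mode, " mode)\n", sep = "")
  cat("  k = ", x$k, ", weighting: ", x$weight,
      ", training molecules: ", x$n_train, "\n", sep = "")
  if (!is.null(x$scaler) && length(x$scaler$dropped) > 0)
    cat("  constant descriptor columns dropped: ",
        length(x$scaler$dropped), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tox_knn <- function(object, ...) {
  # leave-one-out over the stored (already scaled) training matrix
  d <- if (object$mode == "descriptor") {
    manhattan_matrix(object$train, object$train)
  } else {
    -tanimoto_matrix(object$train, object$train)
  }
  diag(d) <- Inf
  idx <- t(apply(d, 1, function(r) order(r, seq_along(r))[seq_len(object$k)]))
  pred <- knn_aggregate(object, idx, d)
  res <- regression_metrics(object$y, pred)
  cat("Leave-one-out performance on training data:\n")
  cat(sprintf("  r2 = %.3f, Spearman = %.3f\n", res["r2"], res["spearman"]))
  invisible(res)
}

#' Cross-validation plan for neighbour-count selection
#'
#' @param validation_ratios fractions of the data held out, each in
#'   \[0.05, 0.30\].
#' @param candidate_ks neighbour counts to score, ascending.
#' @param repeats random splits per ratio.
#' @param seed RNG seed making the plan deterministic.
#' @param score `"r2"` or `"spearman"`.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(validation_ratios = c(0.05, 0.10, 0.20, 0.30),
                    candidate_ks = 1:15, repeats = 10, seed = 1,
                    score = c("r2", "spearman")) {
  score <- match.arg(score)
  assert_that(all(validation_ratios >= 0.05 & validation_ratios <= 0.30),
              "validation ratios must lie in [0.05, 0.30]",
              class = "toxhybrid_config_error")
  assert_that(all(diff(candidate_ks) > 0) && all(candidate_ks >= 1),
              "candidate_ks must be ascending positive integers",
              class = "toxhybrid_config_error")
  assert_that(is_count(repeats), "repeats must be a positive integer",
              class = "toxhybrid_config_error")
  structure(list(validation_ratios = validation_ratios,
                 candidate_ks = as.integer(candidate_ks),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 score = score),
            class = "cv_plan")
}

#' Select the neighbour count by cross-validation
#'
#' For every (ratio, repeat) pair a seeded random split is drawn; each
#' candidate k is fitted on the training part and scored on the validation
#' part. The k with the best mean score wins (ties go to the smaller k).
#'
#' @param x training features (matrix or [feature_set]).
#' @param y training tox values.
#' @param mode `"descriptor"` or `"fingerprint"`.
#' @param plan a [cv_plan()].
#' @return list with `best_k` and `score_table` (one row per
#'   ratio/repeat/k with the validation score).
#' @export
select_k <- function(x, y, mode = c("descriptor", "fingerprint"),
                     plan = cv_plan()) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "cv_plan"))
  m <- knn_matrix(x, mode)
  n <- nrow(m)
  max_ratio <- max(plan$validation_ratios)
  assert_that(max(plan$candidate_ks) <= floor(n * (1 - max_ratio)),
              "largest candidate k infeasible for the smallest training split",
              class = "toxhybrid_parameter_error")
  grid <- expand.grid(ratio = plan$validation_ratios,
                      rep = seq_len(plan$repeats))
  rows <- vector("list", nrow(grid) * length(plan$candidate_ks))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    ratio <- grid$ratio[g]; rep_i <- grid$rep[g]
    n_val <- max(1L, round(n * ratio))
    val <- with_seed(sub_seed(plan$seed, g), sample.int(n, n_val))
    tr <- setdiff(seq_len(n), val)
    fit <- tox_knn(m[tr, , drop = FALSE], y[tr], mode = mode,
                   k = min(plan$candidate_ks[1], length(tr)))
    for (k in plan$candidate_ks) {
      pred <- predict(fit, m[val, , drop = FALSE], k = k)
      sc <- if (plan$score == "r2") {
        unname(regression_metrics(y[val], pred)["r2"])
      } else {
        suppressWarnings(stats::cor(y[val], pred, method = "spearman"))
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(ratio = ratio, rep = rep_i, k = k, score = sc)
    }
  }
  tab <- do.call(rbind, rows)
  mean_by_k <- tapply(tab$score, tab$k, mean, na.rm = TRUE)
  ks <- as.integer(names(mean_by_k))
  best_k <- ks[which.max(mean_by_k)]   # which.max takes first (smallest k) on ties
  list(best_k = best_k, score_table = tab,
       mean_scores = data.frame(k = ks, score = as.numeric(mean_by_k)))
}

#' Final neighbour counts used by the published standard models
#'
#' Named presets: the neighbour counts retained for the final
#' descriptor-based (`"desc"`: 2, 4, 5, 6, 8) and fingerprint-based
#' (`"fpn"`: 2, 5, 7, 12, 14) standard models.
#'
#' @param mode `"desc"` or `"fpn"`.
#' @return integer vector of k values.
#' @export
preset_k <- function(mode = c("desc", "fpn")) {
  mode <- match.arg(mode)
  switch(mode, desc = c(2L, 4L, 5L, 6L, 8L), fpn = c(2L, 5L, 7L, 12L, 14L))
}
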