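test_that("the trend rule set encodes the sixteen literature rules", {
  r <- default_rules()
  expect_equal(nrow(r), 16)
  expect_true(all(r$expected_sign %in% c(-1, 1)))
  expect_equal(r$expected_sign[r$feature == "TPSA"], -1)
  expect_equal(r$expected_sign[r$feature == "MW"], +1)
  expect_equal(r$expected_sign[r$feature == "MolLogP"], +1)
  expect_equal(r$expected_sign[r$rule_id == "nch3_down"], -1)
  expect_equal(sum(!is.na(r$scope)), 3)   # the scoped fragment rules
})

test_that("Spearman correlation equals rank-Pearson with averaged ties", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1.0)
  expect_equal(spearman_rho(1:10, -(1:10)), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  expect_true(is.na(spearman_rho(1:2, 2:1)))          # fewer than 3 pairs
  set.seed(51)
  for (i in 1:10) {
    x <- sample(1:8, 20, replace = TRUE)   # ties included
    y <- rnorm(20)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
    # invariance under strictly monotone transforms
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, 3 * y - 2), spearman_rho(x, y))
  }
})

# A small numeric fixture exercising compliance and affinity without any
# chemistry: three rule features and synthetic model predictions.
audit_fixture <- function() {
  set.seed(52)
  n <- 20
  desc <- cbind(MolLogP = rnorm(n), TPSA = runif(n, 0, 80), MW = runif(n, 40, 400),
                nAmine = rbinom(n, 1, 0.5), nEther = rbinom(n, 1, 0.4),
                nN = rbinom(n, 2, 0.5), nC = sample(2:10, n, TRUE),
                n_NCH3 = rbinom(n, 2, 0.3))
  fs <- feature_set(paste0("m", 1:n), descriptors = desc)
  rules <- default_rules()[c(1, 5, 11, 16), ]   # MolLogP+, TPSA-, MW+, n_NCH3-
  tox <- desc[, "MolLogP"] - 0.02 * desc[, "TPSA"] + 0.005 * desc[, "MW"]
  preds <- list(Data = tox,
                A = tox + rnorm(n, 0, 0.1),
                B = -0.5 * desc[, "TPSA"],
                C = rnorm(n))
  list(fs = fs, rules = rules, preds = preds, desc = desc)
}

test_that("the compliance matrix is the scoped Spearman of features vs predictions", {
  fx <- audit_fixture()
  cm <- compliance_matrix(fx$preds, fx$fs, fx$rules)
  expect_true(all(cm$rho[is.finite(cm$rho)] >= -1 & cm$rho[is.finite(cm$rho)] <= 1))
  # cellwise against the independent oracle
  for (r in seq_len(nrow(fx$rules))) {
    mask <- if (is.na(fx$rules$scope[r])) rep(TRUE, 20) else fx$desc[, "nN"] > 0
    for (m in names(fx$preds)) {
      expect_equal(cm$rho[r, m],
                   oracle_spearman(fx$desc[mask, fx$rules$feature[r]],
                                   fx$preds[[m]][mask]),
                   tolerance = 1e-12)
    }
  }
  # a model identical to the data reproduces the Data column
  cm2 <- compliance_matrix(list(Data = fx$preds$Data, Copy = fx$preds$Data),
                           fx$fs, fx$rules)
  expect_equal(cm2$rho[, "Copy"], cm2$rho[, "Data"])
  # predictions equal to a rule feature give rho = 1 on that rule
  cm3 <- compliance_matrix(list(Data = fx$preds$Data,
                                M = fx$desc[, "MolLogP"]),
                           fx$fs, fx$rules)
  expect_equal(unname(cm3$rho["logp_up", "M"]), 1.0)
})

test_that("under-sized scope subsets give undefined cells, not zero", {
  fx <- audit_fixture()
  d2 <- fx$desc; d2[, "nN"] <- c(1, 1, rep(0, 18))   # two in-scope molecules
  fs2 <- feature_set(paste0("m", 1:20), descriptors = d2)
  cm <- compliance_matrix(fx$preds, fs2, fx$rules)
  expect_true(is.na(cm$rho["nch3_down", "A"]))
  expect_equal(cm$n_used["nch3_down", "A"], 2L)
})

test_that("rule affinity min-max normalizes sign-adjusted correlations across models", {
  fx <- audit_fixture()
  cm <- compliance_matrix(fx$preds, fx$fs, fx$rules)
  aff <- rule_affinity(cm)
  expect_setequal(names(aff$affinity), c("A", "B", "C"))
  n_scored <- nrow(aff$normalized)
  expect_true(all(aff$affinity >= 0 & aff$affinity <= n_scored))
  # spreadsheet-style oracle
  rho <- cm$rho[, c("A", "B", "C")]
  s <- rho * fx$rules$expected_sign
  ok <- apply(s, 1, function(r) all(is.finite(r)))
  u <- t(apply(s[ok, ], 1, function(r) {
    if (max(r) == min(r)) rep(0.5, 3) else (r - min(r)) / (max(r) - min(r))
  }))
  expect_equal(aff$affinity, colSums(u))
  # per-rule endpoints: best-complying model scores 1, worst 0
  expect_true(all(apply(aff$normalized, 1, max) == 1 |
                    apply(aff$normalized, 1, function(r) all(r == 0.5))))
})

test_that("degenerate and two-model endpoint cases behave as documented", {
  n <- 10
  feat <- cbind(MolLogP = 1:10, nAmine = 1, nEther = 1, nN = 1, nC = 1:10,
                n_NCH3 = 0:9, TPSA = 10:1, MW = 1:10)
  fs <- feature_set(paste0("m", 1:n), descriptors = feat)
  rules <- default_rules()[1, ]               # MolLogP, sign +1
  # rho = +1 and -1 on a +1 rule -> u = 1 and 0
  cm <- compliance_matrix(list(up = as.numeric(1:10), down = as.numeric(10:1)),
                          fs, rules)
  aff <- rule_affinity(cm, exclude = character(0))
  expect_equal(unname(aff$normalized[1, ]), c(1, 0))
  # identical models -> all u = 0.5
  cm2 <- compliance_matrix(list(a = as.numeric(1:10), b = as.numeric(1:10)),
                           fs, rules)
  aff2 <- rule_affinity(cm2, exclude = character(0))
  expect_equal(unname(aff2$normalized[1, ]), c(0.5, 0.5))
  expect_error(rule_affinity(cm, exclude = "down"),
               class = "toxhybrid_parameter_error")
})

test_that("affinity is invariant to model order and coherent under negation", {
  fx <- audit_fixture()
  cm <- compliance_matrix(fx$preds, fx$fs, fx$rules)
  aff <- rule_affinity(cm)
  perm <- fx$preds[c("Data", "C", "A", "B")]
  aff_p <- rule_affinity(compliance_matrix(perm, fx$fs, fx$rules))
  expect_equal(aff_p$affinity[names(aff$affinity)], aff$affinity)
  # negating every model flips s, reversing each rule's ordering of u
  neg <- lapply(fx$preds, function(p) -p)
  cm_n <- compliance_matrix(neg, fx$fs, fx$rules)
  aff_n <- rule_affinity(cm_n)
  common <- intersect(rownames(aff$normalized), rownames(aff_n$normalized))
  for (r in common) {
    expect_equal(order(aff$normalized[r, ]),
                 rev(order(aff_n$normalized[r, ])))
  }
})

test_that("regression metrics follow the sum-of-squares definitions", {
  y <- c(3, 1, 4, 1, 5, 9, 2.6)
  expect_equal(unname(regression_metrics(y, y)), c(1, 1))
  m <- regression_metrics(y, rep(mean(y), length(y)))
  expect_equal(unname(m["r2"]), 0)
  set.seed(53)
  p <- y + rnorm(7, 0, 0.5)
  expect_equal(unname(regression_metrics(y, p)["r2"]),
               1 - sum((y - p)^2) / sum((y - mean(y))^2))
  expect_error(regression_metrics(rep(2, 5), rnorm(5)),
               class = "toxhybrid_domain_error")
})

test_that("classification metrics use macro recall and support-weighted averages", {
  perfect <- classification_metrics(c("T", "PT", "NT"), c("T", "PT", "NT"))
  expect_equal(unname(perfect), c(1, 1, 1))
  m <- classification_metrics(c("T", "T", "PT", "NT"), c("T", "PT", "PT", "NT"))
  expect_equal(unname(m["balanced_accuracy"]), (0.5 + 1 + 1) / 3)
  # support-weighted recall: (2*0.5 + 1*1 + 1*1)/4
  expect_equal(unname(m["recall"]), 3 / 4)
  # precision: T 1/1, PT 1/2, NT 1/1 weighted by true support 2,1,1
  expect_equal(unname(m["precision"]), (2 * 1 + 1 * 0.5 + 1 * 1) / 4)
  expect_equal(unname(classification_metrics(rep("NT", 4), rep("NT", 4))["balanced_accuracy"]),
               1.0)
  expect_error(classification_metrics(character(0), character(0)),
               class = "toxhybrid_dimension_error")
  expect_error(classification_metrics(c("T", "X"), c("T", "T")),
               class = "toxhybrid_domain_error")
})
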