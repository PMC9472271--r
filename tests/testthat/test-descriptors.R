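fs_fix <- function() cached("fs_fix", compute_descriptors(fixture_smiles,
                                                          ids = names(fixture_smiles)))

test_that("the default panel has 93 uniquely named descriptors covering the rule set", {
  panel <- default_descriptor_panel()
  expect_length(panel, 93)
  expect_false(anyDuplicated(panel) > 0)
  rule_feats <- setdiff(default_rules()$feature, "nC")
  expect_true(all(rule_feats %in% panel))
})

test_that("whole-molecule properties match reference values", {
  d <- fs_fix()$descriptors
  expect_equal(d["etoh", "MW"], 46.07, tolerance = 0.01 / 46)
  expect_equal(d["but", "TPSA"], 0.0)       # no polar atoms in butane
  expect_equal(d["dme", "nC"], 2)
  expect_equal(d["tma", "n_NCH3"], 3)       # three methyls on nitrogen
  expect_equal(d["etoh", "n_NCH3"], 0)
  expect_equal(d["etoh", "nHBDon"], 1)
})

test_that("descriptor computation is deterministic and permutation-equivariant", {
  smi <- fixture_smiles[1:6]
  a <- compute_descriptors(smi, ids = names(smi))
  b <- compute_descriptors(smi, ids = names(smi))
  expect_identical(a$descriptors, b$descriptors)
  perm <- c(4, 2, 6, 1, 3, 5)
  c_ <- compute_descriptors(smi[perm], ids = names(smi)[perm])
  expect_equal(c_$descriptors, a$descriptors[perm, ], tolerance = 1e-12)
})

test_that("unknown descriptor names fail loudly", {
  expect_error(compute_descriptors("CCO", names = c("MW", "NotADescriptor")),
               class = "toxhybrid_provider_error")
  expect_error(descriptor_provider("Bogus42"), class = "toxhybrid_provider_error")
})

test_that("centered autocorrelation AATSC0p matches a hand computation for ethanol", {
  # ethanol C2H6O, all atoms with hydrogens: polarizabilities
  w <- c(1.76, 1.76, 0.802, rep(0.667, 6))
  expected <- sum((w - mean(w))^2) / length(w)
  expect_equal(fs_fix()$descriptors["etoh", "AATSC0p"], expected, tolerance = 1e-9)
})

test_that("Geary autocorrelation GATS1p matches a hand computation for ethanol", {
  # bonds: C1-C2, C2-O, C1-H x3, C2-H x2, O-H
  w <- c(C1 = 1.76, C2 = 1.76, O = 0.802, H = 0.667)
  pairs <- rbind(c("C1", "C2"), c("C2", "O"),
                 c("C1", "H"), c("C1", "H"), c("C1", "H"),
                 c("C2", "H"), c("C2", "H"), c("O", "H"))
  wfull <- c(1.76, 1.76, 0.802, rep(0.667, 6))
  num <- sum((w[pairs[, 1]] - w[pairs[, 2]])^2) / (2 * nrow(pairs))
  den <- sum((wfull - mean(wfull))^2) / (length(wfull) - 1)
  expect_equal(fs_fix()$descriptors["etoh", "GATS1p"], num / den, tolerance = 1e-9)
})

test_that("E-state hydrogen-bond-donor sum matches the Kier-Hall arithmetic for ethanol", {
  # intrinsic states: CH3 (dv=1,d=1) I=2; CH2 (dv=2,d=2) I=1.5; OH (dv=5,d=1) I=6
  # S(O) = 6 + (6-1.5)/2^2 + (6-2)/3^2
  expect_equal(fs_fix()$descriptors["etoh", "SHBd"],
               6 + 4.5 / 4 + 4 / 9, tolerance = 1e-9)
})

test_that("ETA alpha sums the published valence-electron contributions", {
  # C: (6-4)/4 = 0.5 each; O: (8-6)/6 = 1/3
  expect_equal(fs_fix()$descriptors["etoh", "ETA_Alpha"], 0.5 + 0.5 + 1 / 3,
               tolerance = 1e-9)
  # pure alkane: butane = 4 x 0.5
  expect_equal(fs_fix()$descriptors["but", "ETA_Alpha"], 2.0, tolerance = 1e-9)
})

test_that("topological indices match hand counts on butane and isobutane", {
  d <- compute_descriptors(c(b = "CCCC", ib = "CC(C)C"))$descriptors
  # butane path graph: Wiener = 1+2+3+1+2+1 = 10; isobutane star: 9
  expect_equal(d[1, "Wiener"], 10)
  expect_equal(d[2, "Wiener"], 9)
  expect_equal(d[1, "nBranch"], 0)
  expect_equal(d[2, "nBranch"], 1)
  expect_equal(d[1, "Zagreb1"], 1 + 4 + 4 + 1)
  expect_equal(d[2, "Zagreb1"], 9 + 3)
  # Kier chi1: butane 0.5 + 1/sqrt(2)*2 ... = 1.914; isobutane 3/sqrt(3)
  expect_equal(d[1, "Chi1"], 2 / sqrt(2) + 1 / 2, tolerance = 1e-9)
  expect_equal(d[2, "Chi1"], 3 / sqrt(3), tolerance = 1e-9)
})

test_that("fragment counting follows the documented substructure definitions", {
  expect_equal(unname(count_rule_fragments("CN(C)C")["n_NCH3"]), 3)
  expect_equal(unname(count_rule_fragments("CCO")["n_NCH3"]), 0)
  fr <- count_rule_fragments("COC")
  expect_equal(unname(fr["has_methoxy"]), 1)
  expect_equal(unname(fr["nC"]), 2)
  # amide nitrogen is not an amine
  d <- compute_descriptors(c(acam = "CC(N)=O", buta = "CCCCN"))$descriptors
  expect_equal(d["acam", "nAmine"], 0)
  expect_equal(d["buta", "nAmine"], 1)
})

test_that("fingerprints are canonical-structure invariants of fixed length", {
  fp <- compute_fingerprints(c(a = "CCO", b = "OCC", c = "CCCO"))
  expect_identical(fp$fingerprints["a", ], fp$fingerprints["b", ])
  expect_false(all(fp$fingerprints["a", ] == fp$fingerprints["c", ]))
  expect_true(all(fp$fingerprints %in% c(0L, 1L)))
  # folding halves the length while keeping binarity
  fp2 <- compute_fingerprints("CCO", fp_params("ECFP4", n_bits = 1024))
  expect_equal(ncol(fp2$fingerprints), 1024)
  expect_error(fp_params(n_bits = 32), class = "toxhybrid_config_error")
  expect_error(compute_fingerprints("CCO", fp_params("ECFP4", n_bits = 1000)),
               class = "toxhybrid_config_error")
})
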