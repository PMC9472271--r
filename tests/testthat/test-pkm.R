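ds_scale <- function() tox_scale("neg_ln_lc50", "mg_per_l")

test_that("group-contribution prediction is intercept plus counted fragments", {
  gc0 <- gc_model(NULL, intercept = 2.5, output_scale = ds_scale())
  expect_equal(gc_predict(gc0, c("CCO", "CCCC")), c(2.5, 2.5))
  gcc <- gc_model(data.frame(pattern = "C", coef = 0.5), intercept = 1.0,
                  output_scale = ds_scale())
  expect_equal(gc_predict(gcc, "CCC"), 3 * 0.5 + 1.0)   # propane: 3 carbons
  # molecule without the fragment falls back to the intercept
  gcn <- gc_model(data.frame(pattern = "[NX3]", coef = 2), intercept = -1,
                  output_scale = ds_scale())
  expect_equal(gc_predict(gcn, "CCO"), -1)
  expect_error(gc_predict(gc_model(data.frame(pattern = "[[bad", coef = 1),
                                   intercept = 0, output_scale = ds_scale()),
                          "CCO"),
               class = "toxhybrid_config_error")
})

test_that("the interspecies map is the declared affine function", {
  id <- interspecies_map(1, 0)
  expect_equal(interspecies(id, c(-2, 0, 3.7)), c(-2, 0, 3.7))
  expect_equal(interspecies(interspecies_map(1, 0.5), 2.0), 2.5)
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1); x <- rnorm(1)
    expect_equal(interspecies(interspecies_map(a, b), x), a * x + b)
  }
})

test_that("scale conversion round-trips and demands molar mass across units", {
  sc_log_mmol <- tox_scale("neg_log10_lc50", "mmol_per_l")
  v <- c(-1, 0.5, 3)
  back <- convert_scale(convert_scale(v, sc_log_mmol, ds_scale(), molar_mass = 46.07),
                        ds_scale(), sc_log_mmol, molar_mass = 46.07)
  expect_equal(back, v, tolerance = 1e-9)
  expect_error(convert_scale(1, sc_log_mmol, ds_scale()),
               class = "toxhybrid_data_error")
  expect_error(tox_scale("bogus", "mg_per_l"), class = "toxhybrid_unit_error")
})

test_that("the composed model lands on the data-set scale", {
  # trivial chain: gc already on the data-set scale, identity map
  pk0 <- pk_model(gc_model(NULL, intercept = 3, output_scale = ds_scale()),
                  interspecies_map(1, 0, input_scale = ds_scale(),
                                   output_scale = ds_scale()))
  expect_equal(predict(pk0, c("CCO", "CCCC")), c(3, 3))

  # hand-computed chain on ethanol: one hydroxyl fragment, log-molar scale
  gcy <- gc_model(data.frame(pattern = "[OX2H]", coef = 0.7), intercept = 1.2,
                  output_scale = tox_scale("neg_log10_lc50", "mmol_per_l"))
  pk <- pk_model(gcy, interspecies_map(1.1, 0.2, input_scale = gcy$output_scale,
                                       output_scale = gcy$output_scale))
  got <- predict(pk, "CCO")
  y <- 1.1 * (1.2 + 0.7 * 1) + 0.2          # -log10 LC50 in mmol/L
  mw <- 2 * 12.011 + 6 * 1.008 + 15.999
  expect_equal(got, -log(10^(-y) * mw), tolerance = 1e-9)

  # identical canonical structures predict identically
  expect_equal(predict(pk, "CCO"), predict(pk, "OCC"))
})

test_that("prediction is affine in each GC coefficient", {
  mk <- function(coef) {
    gc_model(data.frame(pattern = c("C", "[OX2H]"), coef = c(coef, 0.3)),
             intercept = 0.4,
             output_scale = tox_scale("neg_log10_lc50", "mmol_per_l"))
  }
  at <- function(coef) predict(pk_model(mk(coef)), "CCCO")
  # finite differences: slope constant in coef (3 carbon matches scale by ln 10)
  d1 <- at(1) - at(0)
  d2 <- at(2) - at(1)
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1, 3 * log(10), tolerance = 1e-9)
})

test_that("descriptor-typed terms drive the baseline-narcosis default monotonically", {
  pk <- default_pk_model()
  alcohols <- paste0(vapply(2:10, function(n) paste(rep("C", n), collapse = ""), ""), "O")
  fs <- compute_descriptors(alcohols, names = c("MolLogP", "MW"))
  pred <- predict(pk, alcohols, descriptors = fs$descriptors)
  expect_true(all(diff(fs$descriptors[, "MolLogP"]) > 0))
  expect_true(all(diff(pred) > 0))
  # the descriptor reference must be supplied
  expect_error(predict(pk, "CCO"), class = "toxhybrid_feature_error")
})

test_that("a YAML config reproduces the programmatic model", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "gc:",
    "  intercept: 1.39",
    "  scale: {quantity: neg_log10_lc50, units: mmol_per_l}",
    "  fragments:",
    "    - {pattern: 'desc:MolLogP', coef: 0.85}",
    "interspecies:",
    "  slope: 1.0",
    "  intercept: 0.0"
  ), path)
  pk <- read_pkm_config(path)
  ref <- default_pk_model()
  smi <- c("CCO", "CCCCCO")
  fs <- compute_descriptors(smi, names = "MolLogP")
  expect_equal(predict(pk, smi, descriptors = fs$descriptors),
               predict(ref, smi, descriptors = fs$descriptors))
  # scale mismatches are rejected at composition time
  expect_error(
    pk_model(gc_model(NULL, 0, tox_scale("neg_log10_lc50", "mmol_per_l")),
             interspecies_map(1, 0, input_scale = ds_scale())),
    class = "toxhybrid_unit_error")
})
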