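# toxhybrid

Prior-knowledge hybrid k-nearest-neighbour models for screening-level
prediction of acute aquatic toxicity.

## The problem

Early chemical screening (hazard assessment, computer-aided molecular
design) needs acute aquatic toxicity estimates — the L(E)C50, the
concentration in mg/L affecting 50% of test organisms in an acute exposure
(96 h fish or 48 h *Daphnia magna*) — for many candidate structures that
have never been tested. Data-driven QSAR models fill the gap, but training
data are scarce, noisy and heterogeneous. One remedy is to fold *prior
knowledge* — trends and relationships reported across the ecotoxicology
literature — into the modelling workflow: before training (data and
predictor selection), during prediction (model switching and neighbour
guidance), and after (auditing predictions against known trends).

`toxhybrid` implements that workflow end-to-end for saturated aliphatic
C/H/O/N compounds:

* **Sentence mining** (`mine_corpus()`, `extract_relevant()`): pulls the
  literature sentences that carry toxicity trends, by co-occurrence of
  *main terms* (`toxicity`, `acute`, `lc50`, `ec50`) and *connection-word*
  stems (`increase`, `decreas`, `relat`, ...), after cleaning and sentence
  segmentation; RAKE-style key-phrase extraction summarizes each article.
* **Molecule handling** (`load_dataset()`, `filter_chon_saturated()`,
  `compute_descriptors()`, `compute_fingerprints()`): CSV in, canonical
  SMILES, the toxicity transform `tox = -ln(LC50 mg/L)`, ECHA-style
  screening labels (T < 0.01 mg/L, PT < 0.1 mg/L, NT otherwise), a
  93-descriptor panel and circular fingerprints.
* **Standard kNN models** (`tox_knn()`, `select_k()`): Tanimoto similarity
  on fingerprints or Manhattan distance on z-scaled descriptors; the
  estimate is the mean toxicity of the k nearest training molecules, with
  cross-validated choice of k.
* **Prior-knowledge model** (`pk_model()`): a configurable linear
  group-contribution fish model composed with a linear interspecies
  fish-to-daphnia map on a declared unit/scale graph
  (mg/L vs mmol/L conversions are explicit, never silent).
* **Hybrid schemes** (`h0_filter()`, `h1_select()`, `hybrid_h2()`,
  `h3_predict()`): molecular-weight outlier removal, knowledge-driven
  descriptor selection, logP-routed switching between kNN and the
  prior-knowledge model, and prior-knowledge-guided neighbour selection.
* **Rule audit** (`default_rules()`, `compliance_matrix()`,
  `rule_affinity()`): sixteen literature trend rules (toxicity rises with
  logP, MW, polarizability; falls with TPSA, H-bond-donor character,
  N-methylation, ...) scored against any model's predictions by scoped
  Spearman correlation, then min-max normalized across models and summed
  into a single *rule affinity* per model.
* **Synthetic benchmark** (`gen_spec()`, `make_benchmark()`): a generator
  of saturated C/H/O/N molecules with trend-consistent toxicity
  (`tox = -2 + 0.8*logP + 0.01*MW - 0.8*n_NCH3` plus Gaussian noise), so
  the entire pipeline runs and is tested without any external data.

## Worked example

```r
library(toxhybrid)

# a seeded synthetic benchmark: 500 molecules, 80/20 split
bm  <- make_benchmark(gen_spec(n_molecules = 500, seed = 2024), test_frac = 0.2)
rec <- rbind(bm$train, bm$test)
fs  <- compute_descriptors(rec)                  # 93-descriptor panel
tr  <- match(bm$train$mol_id, fs$mol_ids)
te  <- match(bm$test$mol_id,  fs$mol_ids)

# standard descriptor-based kNN, k = 5
m <- tox_knn(fs$descriptors[tr, ], bm$train$tox, "descriptor", k = 5)
regression_metrics(bm$test$tox, predict(m, fs$descriptors[te, ]))
#>        r2  spearman
#> 0.8969377 0.9533352

# audit the model against the literature trend rules
te_fs <- feature_set(fs$mol_ids[te], descriptors = fs$descriptors[te, ])
cm  <- compliance_matrix(list(Data = bm$test$tox,
                              DESC = predict(m, fs$descriptors[te, ])),
                         te_fs)
round(cm$rho[c("logp_up", "mw_up", "tpsa_down"), ], 2)
#>            Data  DESC
#> logp_up    0.92  0.91
#> mw_up      0.71  0.67
#> tpsa_down -0.07 -0.12
```

The r² of ~0.90 says the held-out toxicity is recovered almost completely
under the benchmark's noise level; the compliance rows show both the data
and the model following the expected directions (strongly positive for
logP and MW; TPSA, which the generative law touches only indirectly, is
weakly negative).

## Command line

A thin CLI over the same functions ships in `inst/cli/toxhybrid.R`:

```sh
Rscript inst/cli/toxhybrid.R simulate --n 500 --seed 1 --out synth.csv
Rscript inst/cli/toxhybrid.R predict  --train synth.csv --test q.csv --mode desc --k 5 --out pred.csv
Rscript inst/cli/toxhybrid.R mine     --in corpus_dir/ --out sentences.csv
```

## Limitations

The shipped prior-knowledge coefficients are a baseline-narcosis
placeholder (`-log10(LC50 mmol/L) = 0.85 logP + 1.39`, identity
interspecies map); substitute fitted group-contribution and interspecies
coefficients through `read_pkm_config()` for real screening use. The
descriptor panel's autocorrelation, E-state and ETA columns are native
graph-based implementations of those descriptor families; see the methods
vignette for definitions and deviations.
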