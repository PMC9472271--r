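# Shared fixtures and independent oracles. Everything is built in code;
# expensive featurizations are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small, chemically varied set of saturated C/H/O/N molecules.
fixture_smiles <- c(
  etoh = "CCO", prop = "CCC", but = "CCCC", tba = "CC(C)(C)N",
  dea = "CCNCC", tma = "CN(C)C", dme = "COC", gly = "OCC(O)CO",
  meac = "COC(C)=O", urea = "NC(N)=O", hexol = "CCCCCCO",
  dmae = "CN(C)CCO", ipa = "CC(C)O", actn = "CC(C)=O",
  mea = "NCCO", buta = "CCCCN", peth = "CCOCC", acam = "CC(N)=O",
  octol = "CCCCCCCCO", nnd = "CCCCCCN(C)C"
)

# --- independent kNN oracle (plain loops, no shared code with R/) ----------

oracle_tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  i <- 0L; u <- 0L
  for (k in seq_along(a)) {
    if (a[k] && b[k]) i <- i + 1L
    if (a[k] || b[k]) u <- u + 1L
  }
  if (u == 0L) return(1.0)
  i / u
}

oracle_manhattan <- function(x, y) {
  s <- 0
  for (k in seq_along(x)) s <- s + abs(x[k] - y[k])
  s
}

# Exhaustive neighbour search: distance to every training row, full sort with
# index tie-break, first k.
oracle_neighbors <- function(train, query, k, mode) {
  d <- numeric(nrow(train))
  for (i in seq_len(nrow(train))) {
    d[i] <- if (mode == "descriptor") oracle_manhattan(query, train[i, ])
            else -oracle_tanimoto(query, train[i, ])
  }
  ord <- order(d, seq_along(d))
  ord[seq_len(k)]
}

oracle_knn_predict <- function(train, y, query, k, mode) {
  mean(y[oracle_neighbors(train, query, k, mode)])
}

# z-scale with training moments (for descriptor-mode oracle comparisons)
oracle_scale <- function(train, query) {
  mu <- colMeans(train); sd <- apply(train, 2, sd)
  keep <- sd > 0
  list(train = scale(train[, keep, drop = FALSE], mu[keep], sd[keep]),
       query = scale(query[, keep, drop = FALSE], mu[keep], sd[keep]))
}

# --- independent Spearman oracle (rank-Pearson by hand) --------------------

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# --- mined-article fixture -------------------------------------------------

fixture_article <- function() {
  paste(
    "Acute toxicity of aliphatic amines",
    "Abstract We study amines. Introduction",
    "Toxicity increases with chain length.",            # relevant
    "The fish were fed daily.",                         # no main term
    "Water temperature was held at 20 degrees.",        # no main term
    "The LC50 values depend on hydrophobicity.",        # relevant
    "Several compounds were purchased from a supplier.",# no main term
    "Acute exposure lasted for a long time in tanks.",  # main term, no stem
    "References [1] Someone et al. 2001."
  , sep = " ")
}

fixture_sentences <- function() {
  split_sentences(clean_text(fixture_article()))
}
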