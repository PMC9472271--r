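# Synthetic-molecule benchmark generator.
#
# Produces saturated aliphatic C/H/O/N molecules (branched alkyl skeletons
# decorated with hydroxyl, ether/methoxy, primary-amine and
# dimethylamino groups) together with toxicity values that follow the
# literature trend directions: toxicity rises with hydrophobicity (logP) and
# molecular weight and falls with the number of N-bonded methyl groups.
# An optional contamination fraction gives the highest-MW molecules a flat
# (trend-free) toxicity, emulating the weak MW-toxicity correlation observed
# above the outlier threshold, so the H0 scheme has a testable purpose.

#' Synthetic-data generation specification
#'
#' @param n_molecules number of molecules (default 500).
#' @param seed RNG seed; every draw is derived from it.
#' @param chain_length_range carbon-skeleton size range, within \[2, 20\]
#'   (default 2-12).
#' @param group_probs per-molecule decoration probabilities for `hydroxyl`,
#'   `ether` (methoxy), `primary_amine`, `tert_amine_NCH3` (dimethylamino).
#' @param gen_model coefficients of the generative toxicity law
#'   `tox = intercept + logp_coef*logP + mw_coef*MW + nNCH3_coef*n_NCH3`;
#'   `logp_coef > 0`, `mw_coef >= 0`, `nNCH3_coef <= 0`.
#' @param noise_sd Gaussian noise added to the true toxicity (default 0.3).
#' @param contamination_frac fraction in \[0, 1) of highest-MW molecules
#'   whose true toxicity is replaced by a flat value (default 0).
#' @return list of class `gen_spec`.
#' @export
gen_spec <- function(n_molecules = 500, seed = 1,
                     chain_length_range = c(2, 12),
                     group_probs = c(hydroxyl = 0.30, ether = 0.20,
                                     primary_amine = 0.20, tert_amine_NCH3 = 0.15),
                     gen_model = list(logp_coef = 0.8, mw_coef = 0.01,
                                      nNCH3_coef = -0.8, intercept = -2.0),
                     noise_sd = 0.3, contamination_frac = 0) {
  assert_that(is_count(n_molecules), "n_molecules must be a positive integer",
              class = "toxhybrid_config_error")
  assert_that(length(chain_length_range) == 2 &&
                chain_length_range[1] >= 2 && chain_length_range[2] <= 20 &&
                chain_length_range[1] <= chain_length_range[2],
              "chain_length_range must lie within [2, 20]",
              class = "toxhybrid_config_error")
  need <- c("hydroxyl", "ether", "primary_amine", "tert_amine_NCH3")
  assert_that(all(need %in% names(group_probs)) &&
                all(group_probs >= 0 & group_probs <= 1),
              "group_probs must name all four groups with probabilities in [0,1]",
              class = "toxhybrid_config_error")
  assert_that(gen_model$logp_coef > 0 && gen_model$mw_coef >= 0 &&
                gen_model$nNCH3_coef <= 0,
              "gen_model signs: logp_coef > 0, mw_coef >= 0, nNCH3_coef <= 0",
              class = "toxhybrid_config_error")
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0",
              class = "toxhybrid_config_error")
  assert_that(is_number(contamination_frac) &&
                contamination_frac >= 0 && contamination_frac < 1,
              "contamination_frac must be in [0, 1)",
              class = "toxhybrid_config_error")
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 chain_length_range = as.integer(chain_length_range),
                 group_probs = group_probs[need], gen_model = gen_model,
                 noise_sd = noise_sd, contamination_frac = contamination_frac),
            class = "gen_spec")
}

# Build one random branched alkane skeleton as an adjacency list, then a
# SMILES string by depth-first traversal. Decorations are substituents on
# carbons with free valence.
random_molecule <- function(n_c, groups) {
  # skeleton: attach each new carbon to a uniformly chosen existing carbon
  # with free valence (< 4 connections)
  children <- rep(list(integer(0)), n_c)
  nconn <- integer(n_c)
  for (v in seq_len(n_c)[-1]) {
    open <- which(nconn[seq_len(v - 1)] < 4L)
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    children[[parent]] <- c(children[[parent]], v)
    nconn[parent] <- nconn[parent] + 1L
    nconn[v] <- nconn[v] + 1L
  }
  # decorations: substituent SMILES fragments on carbons with free valence
  deco <- rep(list(character(0)), n_c)
  add_group <- function(frag, deco) {
    open <- which(nconn + vapply(deco, length, 0L) < 4L)
    if (length(open) == 0) return(deco)
    at <- if (length(open) == 1L) open else sample(open, 1L)
    deco[[at]] <- c(deco[[at]], frag)
    deco
  }
  if (stats::runif(1) < groups["hydroxyl"])        deco <- add_group("O", deco)
  if (stats::runif(1) < groups["ether"])           deco <- add_group("OC", deco)
  if (stats::runif(1) < groups["primary_amine"])   deco <- add_group("N", deco)
  if (stats::runif(1) < groups["tert_amine_NCH3"]) deco <- add_group("N(C)C", deco)
  smiles_of <- function(v) {
    subs <- c(deco[[v]], vapply(children[[v]], smiles_of, ""))
    if (length(subs) == 0) return("C")
    paste0("C",
           paste0("(", subs[-length(subs)], ")", collapse = ""),
           subs[length(subs)])
  }
  smiles_of(1L)
}

#' Generate synthetic molecules
#'
#' Deterministic for a fixed spec seed. Every generated SMILES is a valid,
#' saturated aliphatic C/H/O/N structure (passes [filter_chon_saturated()]).
#'
#' @param spec a [gen_spec()].
#' @return character vector of `spec$n_molecules` SMILES.
#' @export
generate_molecules <- function(spec = gen_spec()) {
  stopifnot(inherits(spec, "gen_spec"))
  with_seed(sub_seed(spec$seed, 1L), {
    sizes <- seq(spec$chain_length_range[1], spec$chain_length_range[2])
    vapply(seq_len(spec$n_molecules), function(i) {
      n_c <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      random_molecule(n_c, spec$group_probs)
    }, character(1))
  })
}

#' Generate toxicity values for synthetic molecules
#'
#' Features each molecule (logP, MW, N-CH3 count), evaluates the generative
#' law, optionally flattens the top-MW contamination fraction, adds seeded
#' Gaussian noise, and converts to LC50 via `LC50 = exp(-tox)` (mg/L).
#'
#' @param smiles character vector from [generate_molecules()].
#' @param spec the [gen_spec()] used.
#' @return list with `lc50` (mg/L), `tox` (noisy), `truth` (noiseless),
#'   `features` (data.frame logP/MW/n_NCH3), `contaminated` (logical).
#' @export
generate_toxicity <- function(smiles, spec = gen_spec()) {
  stopifnot(inherits(spec, "gen_spec"))
  p <- parse_smiles(smiles)
  assert_that(all(p$ok), "generated SMILES must parse")
  pr <- ob_properties(p$sdf)
  logp <- as.numeric(pr$logP)
  mw <- as.numeric(pr$MW)
  nch3 <- as.numeric(smarts_count(p$sdf, "[CH3][#7]"))
  gm <- spec$gen_model
  truth <- gm$intercept + gm$logp_coef * logp + gm$mw_coef * mw +
    gm$nNCH3_coef * nch3
  contaminated <- rep(FALSE, length(truth))
  if (spec$contamination_frac > 0) {
    n_cont <- ceiling(spec$contamination_frac * length(truth))
    idx <- order(mw, decreasing = TRUE)[seq_len(n_cont)]
    contaminated[idx] <- TRUE
    truth[idx] <- mean(truth[!contaminated])
  }
  tox <- truth + with_seed(sub_seed(spec$seed, 2L),
                           stats::rnorm(length(truth), 0, spec$noise_sd))
  list(lc50 = exp(-tox), tox = tox, truth = truth,
       features = data.frame(logP = logp, MW = mw, n_NCH3 = nch3),
       contaminated = contaminated)
}

#' Generate a complete synthetic dataset
#'
#' @param spec a [gen_spec()].
#' @return A validated molecule table (see [build_dataset()]) with extra
#'   columns `truth` (noiseless tox) and `contaminated`.
#' @export
generate_dataset <- function(spec = gen_spec()) {
  smi <- generate_molecules(spec)
  gt <- generate_toxicity(smi, spec)
  rec <- build_dataset(smi, gt$lc50, ids = sprintf("s%04d", seq_along(smi)))
  assert_that(nrow(rec) == length(smi), "all synthetic molecules must validate")
  rec$truth <- gt$truth
  rec$contaminated <- gt$contaminated
  rec
}

#' Split a synthetic dataset into train and test benchmarks
#'
#' @param spec a [gen_spec()].
#' @param test_frac fraction held out, in (0, 0.5).
#' @param seed split seed (defaults to the generator seed).
#' @return list with `train` and `test` molecule tables (disjoint,
#'   exhaustive) and the `spec`.
#' @export
make_benchmark <- function(spec = gen_spec(), test_frac = 0.2,
                           seed = spec$seed) {
  assert_that(is_number(test_frac) && test_frac > 0 && test_frac < 0.5,
              "test_frac must be in (0, 0.5)", class = "toxhybrid_config_error")
  rec <- generate_dataset(spec)
  n <- nrow(rec)
  n_test <- round(n * test_frac)
  assert_that(n_test >= 1 && n_test < n, "dataset too small for the split",
              class = "toxhybrid_parameter_error")
  test_idx <- with_seed(sub_seed(seed, 3L), sample.int(n, n_test))
  list(train = rec[-test_idx, , drop = FALSE],
       test = rec[test_idx, , drop = FALSE],
       spec = spec)
}
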