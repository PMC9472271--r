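# Molecular descriptor panel.
#
# Two providers stand behind the panel:
#  * "openbabel" -- whole-molecule properties (logP, molar refractivity,
#    TPSA, H-bond donor/acceptor counts) from OpenBabel via ChemmineR.
#  * "native"    -- graph-based descriptors computed here: constitutional
#    means, topological indices, Kier-Hall connectivity/shape, E-state,
#    extended-topochemical-atom (ETA) measures, 2D autocorrelations, and
#    SMARTS-defined fragment counts.
#
# The audit layer only requires named numeric columns; every descriptor named
# in the trend rule set is present in the default panel.

.w_cols <- c(m = "mass", p = "polar", i = "ion", e = "eneg")

#' Default descriptor panel
#'
#' The 93 descriptor names computed by the built-in providers. Includes every
#' descriptor referenced by [default_rules()] (MolLogP, MR, GATS1p, AATSC0p,
#' TPSA, SHBd, maxHBint2, ETA_dEpsilon_A, Mi, GATS1i, MW, ETA_Alpha,
#' ETA_EtaP_B) and the fragment counts used by scoped rules.
#'
#' @return character vector of descriptor names.
#' @export
default_descriptor_panel <- function() {
  auto <- as.vector(outer(
    c("ATS0", "ATS1", "ATS2", "ATSC1", "AATSC0", "AATSC1", "MATS1", "GATS1", "GATS2"),
    names(.w_cols), paste0))
  c(
    # constitutional
    "MW", "AMW", "nAtom", "nHeavyAtom", "nH", "nC", "nN", "nO", "nBonds",
    "Mi", "Mp", "Me",
    # fragment counts
    "n_NCH3", "nAmine", "nEther", "nHydroxyl", "nCarbonyl", "nNH2", "nBranch",
    # OpenBabel whole-molecule properties
    "MolLogP", "MR", "TPSA", "nHBDon", "nHBAcc",
    # topological
    "Wiener", "Zagreb1", "Zagreb2", "Radius", "Diameter", "MeanDistance",
    "ECCEN", "BalabanJ",
    # Kier-Hall connectivity and shape
    "Chi0", "Chi1", "Chi2", "Chi0v", "Chi1v", "Chi2v",
    "Kappa1", "Kappa2", "Kappa3",
    # E-state
    "sumEState", "maxEState", "minEState", "SHBd", "SHBa", "maxHBint2",
    "SsOH", "SssO", "SsNH2",
    # extended topochemical atom
    "ETA_Alpha", "ETA_AlphaP", "ETA_Epsilon_1", "ETA_Epsilon_2",
    "ETA_dEpsilon_A", "ETA_Eta_B", "ETA_EtaP_B",
    # 2D autocorrelation, weights m/p/i/e
    auto
  )
}

.ob_descriptors <- c("MolLogP", "MR", "TPSA", "nHBDon", "nHBAcc")
.fragment_descriptors <- c("n_NCH3", "nAmine", "nEther", "nHydroxyl",
                           "nCarbonyl", "nNH2")

#' Provider responsible for each descriptor
#'
#' @param names descriptor names.
#' @return character vector, `"openbabel"` or `"native"` per name; errors on
#'   names no provider computes.
#' @export
descriptor_provider <- function(names) {
  known <- default_descriptor_panel()
  bad <- setdiff(names, known)
  if (length(bad) > 0) {
    th_stop(paste0("no provider for descriptor(s): ", paste(bad, collapse = ", ")),
            "toxhybrid_provider_error")
  }
  ifelse(names %in% .ob_descriptors, "openbabel", "native")
}

# ---- native per-molecule computation -------------------------------------

estate_indices <- function(g, d_heavy) {
  el <- g$element
  pqn <- .atom_props[el, "pqn"]
  zv <- .atom_props[el, "zval"]
  delta <- pmax(g$degree, 1)          # isolated heavy atom guard
  deltav <- pmax(zv - g$nh, 0)
  I <- ((2 / pqn)^2 * deltav + 1) / delta
  n <- g$n
  S <- I
  if (n > 1) {
    for (i in seq_len(n)) {
      S[i] <- I[i] + sum((I[i] - I[-i]) / (d_heavy[i, -i] + 1)^2)
    }
  }
  S
}

native_descriptors <- function(g) {
  el <- g$element
  n <- g$n
  d_heavy <- graph_distances(g$adj)
  if (any(is.infinite(d_heavy))) {
    th_stop("disconnected structure: native topological descriptors undefined",
            "toxhybrid_provider_error")
  }
  f <- expand_hydrogens(g)
  d_full <- graph_distances(f$adj)
  out <- c()

  # constitutional
  mass_full <- .atom_props[f$element, "mass"]
  out["MW"] <- sum(mass_full)
  out["nAtom"] <- f$n
  out["AMW"] <- out["MW"] / f$n
  out["nHeavyAtom"] <- n
  out["nH"] <- f$n - n
  out["nC"] <- sum(el == "C")
  out["nN"] <- sum(el == "N")
  out["nO"] <- sum(el == "O")
  out["nBonds"] <- sum(g$adj) / 2 + (f$n - n)
  # mean atomic properties scaled on carbon, all atoms incl. H
  out["Mi"] <- mean(.atom_props[f$element, "ion"]) / .atom_props["C", "ion"]
  out["Mp"] <- mean(.atom_props[f$element, "polar"]) / .atom_props["C", "polar"]
  out["Me"] <- mean(.atom_props[f$element, "eneg"]) / .atom_props["C", "eneg"]
  out["nBranch"] <- sum(g$degree >= 3)

  # topological (heavy-atom graph)
  deg <- g$degree
  if (n > 1) {
    ecc <- apply(d_heavy, 1, max)
    out["Wiener"] <- sum(d_heavy) / 2
    out["Radius"] <- min(ecc)
    out["Diameter"] <- max(ecc)
    out["MeanDistance"] <- sum(d_heavy) / (n * (n - 1))
    out["ECCEN"] <- sum(ecc * deg)
  } else {
    out[c("Wiener", "Radius", "Diameter", "MeanDistance", "ECCEN")] <- 0
  }
  out["Zagreb1"] <- sum(deg^2)
  edges <- which(upper.tri(g$adj) & g$adj > 0, arr.ind = TRUE)
  out["Zagreb2"] <- if (NROW(edges)) sum(deg[edges[, 1]] * deg[edges[, 2]]) else 0
  nb <- NROW(edges)
  if (nb > 0 && n > 1) {
    s <- rowSums(d_heavy)
    cyc <- nb - n + 1
    out["BalabanJ"] <- nb / (cyc + 1) *
      sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]]))
  } else out["BalabanJ"] <- 0

  # Kier-Hall connectivity (simple and valence)
  zv <- .atom_props[el, "zval"]
  deltav <- pmax(zv - g$nh, 0)
  chi_terms <- function(dd) {
    dd <- pmax(dd, 0)
    chi0 <- sum(ifelse(dd > 0, 1 / sqrt(dd), 0))
    chi1 <- if (nb > 0) {
      di <- dd[edges[, 1]]; dj <- dd[edges[, 2]]
      ok <- di > 0 & dj > 0
      sum(1 / sqrt(di[ok] * dj[ok]))
    } else 0
    chi2 <- 0
    for (j in seq_len(n)) {
      nbrs <- which(g$adj[j, ] > 0)
      if (length(nbrs) >= 2 && dd[j] > 0) {
        pr <- utils::combn(nbrs, 2)
        di <- dd[pr[1, ]]; dk <- dd[pr[2, ]]
        ok <- di > 0 & dk > 0
        chi2 <- chi2 + sum(1 / sqrt(di[ok] * dd[j] * dk[ok]))
      }
    }
    c(chi0, chi1, chi2)
  }
  ch <- chi_terms(deg)
  chv <- chi_terms(deltav)
  out["Chi0"] <- ch[1]; out["Chi1"] <- ch[2]; out["Chi2"] <- ch[3]
  out["Chi0v"] <- chv[1]; out["Chi1v"] <- chv[2]; out["Chi2v"] <- chv[3]

  # Kier shape
  p1 <- nb
  p2 <- sum(choose(deg, 2))
  tri <- sum(diag(g$adj %*% g$adj %*% g$adj)) / 6
  p3 <- if (nb > 0) sum((deg[edges[, 1]] - 1) * (deg[edges[, 2]] - 1)) - 3 * tri else 0
  out["Kappa1"] <- if (p1 > 0) n * (n - 1)^2 / p1^2 else 0
  out["Kappa2"] <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  out["Kappa3"] <- if (p3 > 0) {
    if (n %% 2 == 1) (n - 1) * (n - 3)^2 / p3^2 else (n - 3) * (n - 2)^2 / p3^2
  } else 0

  # E-state
  S <- estate_indices(g, d_heavy)
  out["sumEState"] <- sum(S)
  out["maxEState"] <- max(S)
  out["minEState"] <- min(S)
  donor <- el %in% c("N", "O") & g$nh >= 1
  acceptor <- el %in% c("N", "O")
  out["SHBd"] <- if (any(donor)) sum(S[donor]) else 0
  out["SHBa"] <- if (any(acceptor)) sum(S[acceptor]) else 0
  out["SsOH"] <- sum(S[el == "O" & deg == 1 & g$nh == 1])
  out["SssO"] <- sum(S[el == "O" & deg == 2 & g$nh == 0])
  out["SsNH2"] <- sum(S[el == "N" & deg == 1 & g$nh == 2])
  hb2 <- 0
  if (any(donor) && any(acceptor)) {
    for (di in which(donor)) {
      for (ai in which(acceptor)) {
        if (di != ai && d_heavy[di, ai] == 2) hb2 <- max(hb2, S[di] * S[ai])
      }
    }
  }
  out["maxHBint2"] <- hb2

  # ETA
  z <- .atom_props[el, "z"]
  pqn <- .atom_props[el, "pqn"]
  alpha <- ifelse(pqn > 1, (z - zv) / zv / (pqn - 1), 0)
  eps <- -alpha + 0.3 * zv
  eps_full <- c(eps, rep(-0 + 0.3 * 1, f$n - n))   # H: alpha 0, zval 1
  out["ETA_Alpha"] <- sum(alpha)
  out["ETA_AlphaP"] <- mean(alpha)
  out["ETA_Epsilon_1"] <- mean(eps)
  out["ETA_Epsilon_2"] <- mean(eps_full)
  out["ETA_dEpsilon_A"] <- out["ETA_Epsilon_2"] - out["ETA_Epsilon_1"]
  out["ETA_Eta_B"] <- sum(pmax(0, deg - 2))
  out["ETA_EtaP_B"] <- out["ETA_Eta_B"] / n

  # 2D autocorrelation, H included (keeps pure alkanes non-degenerate)
  for (wk in names(.w_cols)) {
    w <- .atom_props[f$element, .w_cols[[wk]]]
    wc <- w - mean(w)
    var0 <- sum(wc^2)
    nfull <- f$n
    pairs_at <- function(lag) which(upper.tri(d_full) & d_full == lag, arr.ind = TRUE)
    p1m <- pairs_at(1); p2m <- pairs_at(2)
    out[paste0("ATS0", wk)] <- sum(w^2)
    out[paste0("ATS1", wk)] <- if (NROW(p1m)) sum(w[p1m[, 1]] * w[p1m[, 2]]) else 0
    out[paste0("ATS2", wk)] <- if (NROW(p2m)) sum(w[p2m[, 1]] * w[p2m[, 2]]) else 0
    atsc1 <- if (NROW(p1m)) sum(wc[p1m[, 1]] * wc[p1m[, 2]]) else 0
    out[paste0("ATSC1", wk)] <- atsc1
    out[paste0("AATSC0", wk)] <- var0 / nfull
    out[paste0("AATSC1", wk)] <- if (NROW(p1m)) atsc1 / NROW(p1m) else 0
    out[paste0("MATS1", wk)] <- if (var0 > 0 && NROW(p1m)) {
      (atsc1 / NROW(p1m)) / (var0 / nfull)
    } else 0
    gats_at <- function(pm) {
      if (var0 > 0 && NROW(pm) && nfull > 1) {
        (sum((w[pm[, 1]] - w[pm[, 2]])^2) / (2 * NROW(pm))) / (var0 / (nfull - 1))
      } else 0
    }
    out[paste0("GATS1", wk)] <- gats_at(p1m)
    out[paste0("GATS2", wk)] <- gats_at(p2m)
  }
  out
}

# ---- panel assembly -------------------------------------------------------

fragment_counts_sdf <- function(sdf) {
  pats <- c(
    n_NCH3    = "[CH3][#7]",
    nAmine    = "[NX3;!$([NX3][#6X3]=[OX1])]",
    nEther    = "[#6][OX2H0][#6]",
    nHydroxyl = "[OX2H]",
    nCarbonyl = "[CX3]=[OX1]",
    nNH2      = "[NX3H2]"
  )
  res <- vapply(pats, function(p) as.numeric(smarts_count(sdf, p)),
                numeric(length(sdf)))
  if (length(sdf) == 1L) res <- matrix(res, nrow = 1, dimnames = list(NULL, names(pats)))
  res
}

#' Compute a descriptor matrix
#'
#' Computes the requested descriptors for a set of molecules. Descriptors are
#' routed to their provider ([descriptor_provider()]); unknown names fail
#' loudly rather than being imputed. Columns that are constant across all
#' molecules are flagged in the result (attribute `constant_columns`).
#'
#' @param smiles character vector of valid SMILES (or a data.frame with a
#'   `smiles` column, e.g. from [load_dataset()]).
#' @param names descriptor names; defaults to the full 93-descriptor panel.
#' @param ids optional molecule ids (taken from a `mol_id` column if present).
#' @return A [feature_set] with the descriptor matrix filled in.
#' @export
compute_descriptors <- function(smiles, names = default_descriptor_panel(),
                                ids = NULL) {
  if (is.data.frame(smiles)) {
    if (is.null(ids) && "mol_id" %in% colnames(smiles)) ids <- smiles$mol_id
    smiles <- smiles$smiles
  }
  assert_that(length(names) > 0 && !anyDuplicated(names),
              "descriptor names must be unique and non-empty")
  descriptor_provider(names)   # validates
  p <- parse_smiles(smiles, ids)
  assert_that(all(p$ok), "all SMILES must parse; validate with load_dataset() first",
              class = "toxhybrid_parse_error")
  n <- length(p$ids)

  full <- matrix(NA_real_, n, length(names), dimnames = list(p$ids, names))

  ob_needed <- intersect(names, .ob_descriptors)
  if (length(ob_needed) > 0) {
    pr <- ob_properties(p$sdf)
    map <- c(MolLogP = "logP", MR = "MR", TPSA = "TPSA",
             nHBDon = "HBD", nHBAcc = "HBA1")
    for (nm in ob_needed) full[, nm] <- as.numeric(pr[[map[[nm]]]])
  }
  frag_needed <- intersect(names, .fragment_descriptors)
  if (length(frag_needed) > 0) {
    fc <- fragment_counts_sdf(p$sdf)
    for (nm in frag_needed) full[, nm] <- fc[, nm]
  }
  native_needed <- setdiff(names, c(.ob_descriptors, .fragment_descriptors))
  if (length(native_needed) > 0) {
    for (i in seq_len(n)) {
      nd <- native_descriptors(mol_graph(p$sdf[[i]]))
      full[i, native_needed] <- nd[native_needed]
    }
  }
  if (anyNA(full)) {
    th_stop("descriptor computation produced missing values",
            "toxhybrid_provider_error")
  }
  feature_set(mol_ids = p$ids, smiles = p$smiles,
              descriptors = full)
}
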