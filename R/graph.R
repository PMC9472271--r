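# Lightweight molecular-graph representation extracted from an SDF molecule.
# Native topological descriptors (autocorrelation, E-state, ETA, chi/kappa)
# are computed from this structure; element-level properties come from the
# tables below.

# Standard atomic property tables. Sources: CRC-style standard atomic
# weights, static dipole polarizabilities (A^3), first ionization energies
# (eV), Pauling electronegativities. Valence electrons and principal quantum
# number follow the usual Kier-Hall usage.
.atom_props <- local({
  el <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  data.frame(
    element = el,
    mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45, 79.904, 126.904),
    polar   = c(0.667, 1.76, 1.10, 0.802, 2.90, 3.63, 0.557, 2.18, 3.05, 5.35),
    ion     = c(13.598, 11.260, 14.534, 13.618, 10.360, 10.487, 17.423, 12.968, 11.814, 10.451),
    eneg    = c(2.20, 2.55, 3.04, 3.44, 2.58, 2.19, 3.98, 3.16, 2.96, 2.66),
    zval    = c(1L, 4L, 5L, 6L, 6L, 5L, 7L, 7L, 7L, 7L),
    z       = c(1L, 6L, 7L, 8L, 16L, 15L, 9L, 17L, 35L, 53L),
    pqn     = c(1L, 2L, 2L, 2L, 3L, 3L, 2L, 3L, 4L, 5L),
    stdval  = c(1L, 4L, 3L, 2L, 2L, 3L, 1L, 1L, 1L, 1L),
    row.names = el
  )
})

#' Molecular graph of one molecule
#'
#' Extracts the heavy-atom graph (elements, adjacency, bond orders) from one
#' molecule of an `SDFset` and derives implicit hydrogen counts from standard
#' valences. Basis for the package's native topological descriptors.
#'
#' @param sdf_one a single `SDF` object (one element of an `SDFset`).
#' @return A list: `element` (character), `adj` (0/1 matrix), `border`
#'   (bond-order matrix), `nh` (implicit H per heavy atom), `degree`
#'   (heavy-atom degree), `n` (number of heavy atoms).
#' @export
mol_graph <- function(sdf_one) {
  ab <- ChemmineR::atomblock(sdf_one)
  bb <- ChemmineR::bondblock(sdf_one)
  el <- sub("_.*$", "", rownames(ab))
  unknown <- setdiff(unique(el), rownames(.atom_props))
  assert_that(length(unknown) == 0,
              paste0("unsupported element(s): ", paste(unknown, collapse = ", ")),
              class = "toxhybrid_provider_error")
  n <- length(el)
  adj <- matrix(0L, n, n)
  bo <- matrix(0, n, n)
  if (NROW(bb) > 0) {
    for (r in seq_len(NROW(bb))) {
      i <- bb[r, 1]; j <- bb[r, 2]; o <- bb[r, 3]
      adj[i, j] <- adj[j, i] <- 1L
      # OpenBabel writes kekulized molfiles; treat aromatic order 4 as 1.5
      bo[i, j] <- bo[j, i] <- if (o == 4) 1.5 else o
    }
  }
  valence_used <- rowSums(bo)
  nh <- pmax(0L, .atom_props[el, "stdval"] - as.integer(round(valence_used)))
  # Explicit hydrogens present in the atom block carry no implicit H
  nh[el == "H"] <- 0L
  list(element = el, adj = adj, border = bo, nh = nh,
       degree = rowSums(adj), n = n)
}

# Topological (bond-count) distance matrix by iterated boolean reachability;
# fast enough for molecules of a few dozen atoms and fully vectorized.
graph_distances <- function(adj) {
  n <- nrow(adj)
  if (n == 1L) return(matrix(0, 1, 1))
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  reach <- adj > 0
  step <- adj > 0
  k <- 1L
  while (any(is.infinite(d)) && k < n) {
    step <- (step %*% adj) > 0
    k <- k + 1L
    new <- step & is.infinite(d)
    d[new] <- k
  }
  d
}

# Expand the heavy-atom graph with implicit hydrogens as explicit pendant
# vertices (needed for H-inclusive autocorrelation and mean-property
# descriptors). Returns element vector and adjacency.
expand_hydrogens <- function(g) {
  nh_total <- sum(g$nh)
  n <- g$n + nh_total
  el <- c(g$element, rep("H", nh_total))
  adj <- matrix(0L, n, n)
  adj[seq_len(g$n), seq_len(g$n)] <- g$adj
  if (nh_total > 0) {
    hidx <- g$n
    for (i in seq_len(g$n)) {
      if (g$nh[i] > 0) {
        for (h in seq_len(g$nh[i])) {
          hidx <- hidx + 1L
          adj[i, hidx] <- adj[hidx, i] <- 1L
        }
      }
    }
  }
  list(element = el, adj = adj, n = n)
}
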