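#' @importFrom rlang .data
NULL

# Atomic numbers for the elements the parsers accept.
ELEMENT_Z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
  I = 53
)

atomic_number <- function(element) {
  z <- ELEMENT_Z[element]
  if (anyNA(z)) {
    stop("unknown element(s): ", paste(unique(element[is.na(z)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(z)
}

# Construct a molecule object from parsed atom/bond tables and precompute the
# graph-derived atom properties every downstream stage queries (degree,
# hydrogen counts, ring membership, smallest ring size).
new_molecule <- function(atoms, bonds, id = NA_character_, source = NA_character_) {
  n <- nrow(atoms)
  atoms$deg <- integer(n)
  if (nrow(bonds) > 0) {
    tab <- table(factor(c(bonds$a1, bonds$a2), levels = seq_len(n)))
    atoms$deg <- as.integer(tab)
  }
  h_nbrs <- integer(n)
  if (nrow(bonds) > 0) {
    is_h <- atoms$element == "H"
    for (k in seq_len(nrow(bonds))) {
      if (is_h[bonds$a2[k]]) h_nbrs[bonds$a1[k]] <- h_nbrs[bonds$a1[k]] + 1L
      if (is_h[bonds$a1[k]]) h_nbrs[bonds$a2[k]] <- h_nbrs[bonds$a2[k]] + 1L
    }
  }
  atoms$h_total <- atoms$nH + h_nbrs
  # total connections (X primitive): explicit neighbours + implicit hydrogens
  atoms$conn <- atoms$deg + atoms$nH
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$aromatic, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ord[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ord[k]
    }
  }
  atoms$valence <- as.integer(round(bsum + atoms$nH))

  ring <- ring_membership(n, bonds)
  atoms$in_ring <- ring$atom_in_ring
  bonds$in_ring <- ring$bond_in_ring
  atoms$min_ring <- ring$min_ring

  structure(
    list(atoms = atoms, bonds = bonds, id = id, source = source),
    class = "nsfp_molecule"
  )
}

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("a1", "a2")] else data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# Ring membership via bridge detection: an edge lies on a cycle iff it is not
# a bridge; an atom is in a ring iff one of its edges is. Smallest-ring size
# per atom is the shortest cycle through any incident non-bridge edge.
ring_membership <- function(n, bonds) {
  atom_in_ring <- logical(n)
  bond_in_ring <- logical(nrow(bonds))
  min_ring <- rep(NA_integer_, n)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_data_frame(
      d = bonds[, c("a1", "a2")], directed = FALSE,
      vertices = data.frame(name = seq_len(n))
    )
    br <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    for (k in which(bond_in_ring)) {
      a <- bonds$a1[k]
      b <- bonds$a2[k]
      atom_in_ring[a] <- TRUE
      atom_in_ring[b] <- TRUE
      g2 <- igraph::delete_edges(g, k)
      d <- igraph::distances(g2, v = as.character(a), to = as.character(b))[1, 1]
      if (is.finite(d)) {
        sz <- as.integer(d + 1)
        if (is.na(min_ring[a]) || sz < min_ring[a]) min_ring[a] <- sz
        if (is.na(min_ring[b]) || sz < min_ring[b]) min_ring[b] <- sz
      }
    }
  }
  list(
    atom_in_ring = atom_in_ring, bond_in_ring = bond_in_ring,
    min_ring = min_ring
  )
}

#' Count non-hydrogen atoms of a molecule
#'
#' The heavy-atom count is independent of whether hydrogens were written
#' explicitly: explicit `[H]` atoms are excluded and implicit hydrogens were
#' never atoms to begin with. Compound-size prefilters in selectivity
#' screening (e.g. requiring 22 or more heavy atoms so a ligand can span both
#' the orthosteric and the secondary binding pocket of a GPCR) are expressed
#' in this count.
#'
#' @param mol A molecule object as returned by [parse_molecules()] (the
#'   elements of the `mol` list-column) or [smiles_to_molecule()].
#' @return A single non-negative integer.
#' @examples
#' heavy_atom_count(smiles_to_molecule("CCO")) # 3
#' heavy_atom_count(smiles_to_molecule("[H]OC([H])([H])[H]")) # 2
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "nsfp_molecule"))
  sum(mol$atoms$element != "H")
}

#' @export
print.nsfp_molecule <- function(x, ...) {
  cat(
    "<molecule ", if (is.na(x$id)) "?" else x$id, ": ",
    heavy_atom_count(x), " heavy atoms, ", nrow(x$bonds), " bonds>\n",
    sep = ""
  )
  invisible(x)
}

# Keep the largest organic (carbon-containing, ties broken by heavy-atom
# count then input order) connected component. Screening-library convention
# for salts and mixtures.
largest_fragment <- function(mol) {
  g <- mol_graph(mol)
  comp <- igraph::components(g)$membership
  if (max(comp) == 1L) {
    return(mol)
  }
  heavy <- mol$atoms$element != "H"
  carbon <- mol$atoms$element == "C"
  score <- vapply(seq_len(max(comp)), function(cc) {
    idx <- comp == cc
    sum(heavy[idx]) + ifelse(any(carbon[idx]), 1000, 0)
  }, numeric(1))
  keep <- which(comp == which.max(score))
  sub_molecule(mol, keep)
}

sub_molecule <- function(mol, keep) {
  keep <- sort(keep)
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  atoms <- mol$atoms[keep, c("element", "charge", "aromatic", "nH"), drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  sel <- b$a1 %in% keep & b$a2 %in% keep
  bonds <- data.frame(
    a1 = remap[b$a1[sel]], a2 = remap[b$a2[sel]],
    order = b$order[sel], aromatic = b$aromatic[sel],
    stringsAsFactors = FALSE
  )
  new_molecule(atoms, bonds, id = mol$id, source = mol$source)
}

# Topological (bond-count) distance matrix over all atoms.
mol_distances <- function(mol) {
  g <- mol_graph(mol)
  d <- igraph::distances(g)
  ord <- order(as.integer(rownames(d)))
  d[ord, ord, drop = FALSE]
}
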