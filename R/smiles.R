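# SMILES reader. Covers the grammar screening libraries actually use:
# organic-subset and bracket atoms (isotope, chirality marks, H count,
# charge, atom map -- stereo and isotopes are parsed and discarded), bond
# symbols - = # : / \, branches, dot-separated fragments, ring closures
# including %nn. Aromaticity is taken from lowercase atom notation, and
# additionally perceived for kekulized six-membered rings so that C1=CC=CC=C1
# and c1ccccc1 yield the same molecule.

SMILES_ORGANIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
SMILES_AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
SMILES_BOND_CHARS <- c("-", "=", "#", ":", "/", "\\")

read_smiles_atom <- function(x, i) {
  ch <- substr(x, i, i)
  if (ch == "[") {
    j <- regexpr("]", substr(x, i + 1, nchar(x)), fixed = TRUE)
    if (j < 0) stop("unclosed '[' in '", x, "'", call. = FALSE)
    content <- substr(x, i + 1, i + j - 1)
    atom <- parse_bracket_atom(content, x)
    return(list(atom = atom, next_i = i + j + 1))
  }
  two <- substr(x, i, i + 1)
  if (two %in% SMILES_ORGANIC) {
    return(list(
      atom = list(element = two, aromatic = FALSE, charge = 0L, nH = NA_integer_),
      next_i = i + 2
    ))
  }
  if (ch %in% SMILES_ORGANIC) {
    return(list(
      atom = list(element = ch, aromatic = FALSE, charge = 0L, nH = NA_integer_),
      next_i = i + 1
    ))
  }
  if (ch %in% SMILES_AROMATIC_ORGANIC) {
    return(list(
      atom = list(element = toupper(ch), aromatic = TRUE, charge = 0L, nH = NA_integer_),
      next_i = i + 1
    ))
  }
  NULL
}

parse_bracket_atom <- function(content, full) {
  s <- content
  eat <- function(pattern) {
    m <- regmatches(s, regexpr(paste0("^", pattern), s))
    if (length(m) == 1) s <<- substr(s, nchar(m) + 1, nchar(s))
    if (length(m) == 1) m else NULL
  }
  eat("[0-9]+") # isotope, ignored
  sym <- eat("\\*|se|as|[A-Z][a-z]?|[bcnops]")
  if (is.null(sym)) stop("bad bracket atom [", content, "] in '", full, "'", call. = FALSE)
  aromatic <- sym %in% c(SMILES_AROMATIC_ORGANIC, "se", "as")
  element <- if (sym == "*") {
    "*"
  } else if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2))
  } else {
    sym
  }
  if (element != "*" && !(element %in% names(ELEMENT_Z))) {
    stop("unknown element '", element, "' in '", full, "'", call. = FALSE)
  }
  eat("@@|@") # chirality, ignored (connectivity-only downstream)
  nH <- 0L
  h <- eat("H[0-9]*")
  if (!is.null(h)) nH <- if (nchar(h) == 1) 1L else as.integer(substr(h, 2, nchar(h)))
  charge <- 0L
  cg <- eat("\\+[0-9]+|-[0-9]+|\\++|-+")
  if (!is.null(cg)) {
    charge <- if (grepl("[0-9]", cg)) {
      as.integer(cg)
    } else if (substr(cg, 1, 1) == "+") {
      nchar(cg)
    } else {
      -nchar(cg)
    }
  }
  eat(":[0-9]+") # atom map, ignored
  if (nchar(s) > 0) stop("bad bracket atom [", content, "] in '", full, "'", call. = FALSE)
  list(element = element, aromatic = aromatic, charge = as.integer(charge), nH = nH)
}

# Smallest allowed valences of the organic subset (Daylight convention):
# implicit H fill up to the smallest normal valence >= current bond-order sum.
ORGANIC_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a single SMILES string into a molecule
#'
#' @param smiles A SMILES string.
#' @param id Optional identifier stored on the molecule.
#' @param desalt Keep only the largest organic fragment of multi-fragment
#'   (salt) inputs. Default `TRUE`, the screening-library convention.
#' @return An object of class `nsfp_molecule`: a list with an `atoms` table
#'   (element, formal charge, aromatic flag, hydrogen counts, ring
#'   membership) and a `bonds` table (atom indices, bond order, aromatic
#'   flag).
#' @examples
#' m <- smiles_to_molecule("c1ccccc1C(=O)N", id = "benzamide")
#' heavy_atom_count(m)
#' @export
smiles_to_molecule <- function(smiles, id = NA_character_, desalt = TRUE) {
  sc <- chain_scan(smiles, read_smiles_atom, SMILES_BOND_CHARS)
  atoms <- data.frame(
    element = vapply(sc$atoms, `[[`, character(1), "element"),
    charge = vapply(sc$atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(sc$atoms, `[[`, logical(1), "aromatic"),
    nH = vapply(sc$atoms, `[[`, integer(1), "nH"),
    stringsAsFactors = FALSE
  )
  if (any(atoms$element == "*")) {
    stop("wildcard atoms are not allowed in molecule SMILES: '", smiles, "'",
      call. = FALSE
    )
  }
  bonds <- resolve_smiles_bonds(atoms, sc$bonds, smiles)
  ar <- perceive_kekulized_aromaticity(atoms, bonds)
  atoms <- ar$atoms
  bonds <- ar$bonds
  atoms$nH <- implicit_hydrogens(atoms, bonds, smiles)
  mol <- new_molecule(atoms, bonds, id = id, source = smiles)
  if (desalt) mol <- largest_fragment(mol)
  mol
}

resolve_smiles_bonds <- function(atoms, raw, smiles) {
  n <- nrow(raw)
  order <- numeric(n)
  aromatic <- logical(n)
  if (n == 0) {
    return(data.frame(
      a1 = integer(0), a2 = integer(0), order = numeric(0),
      aromatic = logical(0)
    ))
  }
  # an unspecified bond between two aromatic atoms is aromatic only inside a
  # ring (biphenyl's central bond is single)
  rm <- ring_membership(nrow(atoms), data.frame(
    a1 = raw$a1, a2 = raw$a2,
    order = rep(1, n), aromatic = rep(FALSE, n)
  ))
  for (k in seq_len(n)) {
    sym <- raw$sym[k]
    both_ar <- atoms$aromatic[raw$a1[k]] && atoms$aromatic[raw$a2[k]]
    if (sym == "=") {
      order[k] <- 2
    } else if (sym == "#") {
      order[k] <- 3
    } else if (sym == ":") {
      order[k] <- 1
      aromatic[k] <- TRUE
    } else if (sym %in% c("-", "/", "\\")) {
      order[k] <- 1
    } else { # unspecified
      order[k] <- 1
      aromatic[k] <- both_ar && rm$bond_in_ring[k]
    }
  }
  dup <- duplicated(cbind(pmin(raw$a1, raw$a2), pmax(raw$a1, raw$a2)))
  if (any(dup)) stop("duplicate bond in '", smiles, "'", call. = FALSE)
  data.frame(
    a1 = raw$a1, a2 = raw$a2, order = order, aromatic = aromatic,
    stringsAsFactors = FALSE
  )
}

# Upgrade kekulized aromatic rings written in uppercase: a ring of size 5-7
# whose bonds alternate so every ring atom carries exactly one double bond
# within the ring (pyridine/benzene pattern) is marked aromatic. Conservative
# on purpose; lowercase notation is the canonical input.
perceive_kekulized_aromaticity <- function(atoms, bonds) {
  if (nrow(bonds) == 0) {
    return(list(atoms = atoms, bonds = bonds))
  }
  ring_bonds <- which(ring_membership(nrow(atoms), bonds)$bond_in_ring)
  if (length(ring_bonds) == 0) {
    return(list(atoms = atoms, bonds = bonds))
  }
  g <- igraph::graph_from_data_frame(
    d = bonds[ring_bonds, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(atoms)))
  )
  # enumerate chordless cycles up to size 7 via per-edge shortest cycles
  for (kk in seq_along(ring_bonds)) {
    k <- ring_bonds[kk]
    a <- bonds$a1[k]
    b <- bonds$a2[k]
    g2 <- igraph::delete_edges(g, kk)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2,
      from = as.character(a), to = as.character(b)
    )$vpath[[1]])
    cyc <- as.integer(igraph::as_ids(sp))
    if (length(cyc) < 5 || length(cyc) > 7) next
    if (any(atoms$aromatic[cyc])) next
    if (!all(atoms$element[cyc] %in% c("C", "N"))) next
    in_cyc <- function(i, j) {
      w <- which((bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i))
      w[1]
    }
    eidx <- vapply(seq_along(cyc), function(t) {
      in_cyc(cyc[t], cyc[if (t == length(cyc)) 1 else t + 1])
    }, integer(1))
    if (anyNA(eidx)) next
    ords <- bonds$order[eidx]
    # perfect alternation: every ring atom touches exactly one ring double bond
    dbl <- eidx[ords == 2]
    touch <- table(factor(c(bonds$a1[dbl], bonds$a2[dbl]), levels = cyc))
    if (length(dbl) * 2 == length(cyc) && all(touch == 1)) {
      atoms$aromatic[cyc] <- TRUE
      bonds$aromatic[eidx] <- TRUE
      bonds$order[eidx] <- 1
    }
  }
  list(atoms = atoms, bonds = bonds)
}

implicit_hydrogens <- function(atoms, bonds, smiles) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$aromatic, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ord[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ord[k]
    }
  }
  deg <- integer(n)
  if (nrow(bonds) > 0) {
    deg <- as.integer(table(factor(c(bonds$a1, bonds$a2), levels = seq_len(n))))
  }
  nH <- atoms$nH
  for (i in seq_len(n)) {
    if (!is.na(nH[i])) next # bracket atom: explicit H count is authoritative
    el <- atoms$element[i]
    if (atoms$aromatic[i]) {
      nH[i] <- if (el == "C") max(0L, 3L - deg[i]) else 0L
    } else {
      v <- ORGANIC_VALENCES[[el]]
      if (is.null(v)) {
        nH[i] <- 0L
      } else {
        fit <- v[v >= ceiling(bsum[i])]
        nH[i] <- if (length(fit) == 0) 0L else as.integer(fit[1] - round(bsum[i]))
      }
    }
  }
  nH
}


#' Write molecules back to SMILES
#'
#' Emits a (non-canonical) SMILES via depth-first traversal: aromatic atoms
#' lowercase, charges and non-default hydrogen counts in brackets.
#' Round-tripping through [smiles_to_molecule()] preserves atom count, bond
#' count and the NSFP fingerprint.
#'
#' @param mol A molecule object.
#' @return A SMILES string.
#' @export
molecule_to_smiles <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  nb <- nrow(bonds)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other_end <- function(k, i) if (bonds$a1[k] == i) bonds$a2[k] else bonds$a1[k]
  bond_sym <- function(k) {
    if (nb == 0) return("")
    if (bonds$aromatic[k]) "" else if (bonds$order[k] == 2) "=" else if (bonds$order[k] == 3) "#" else ""
  }

  # pass 1: spanning forest; leftover bonds become ring closures
  visited <- logical(n)
  tree <- logical(nb)
  children <- vector("list", n) # per atom: bond indices, in visit order
  roots <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    roots <- c(roots, s)
    stack <- s
    visited[s] <- TRUE
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (k in adj[[i]]) {
        o <- other_end(k, i)
        if (!visited[o]) {
          visited[o] <- TRUE
          tree[k] <- TRUE
          children[[i]] <- c(children[[i]], k)
          stack <- c(stack, o)
        }
      }
    }
  }
  ring_bonds <- which(!tree)
  ring_lab <- vapply(seq_along(ring_bonds), function(d) {
    if (d > 9) paste0("%", d) else as.character(d)
  }, character(1))
  digits_at <- vector("list", n)
  for (d in seq_along(ring_bonds)) {
    k <- ring_bonds[d]
    tag <- paste0(bond_sym(k), ring_lab[d])
    digits_at[[bonds$a1[k]]] <- c(digits_at[[bonds$a1[k]]], tag)
    digits_at[[bonds$a2[k]]] <- c(digits_at[[bonds$a2[k]]], tag)
  }

  # expected implicit-H count under the plain-atom reading rules
  bsum <- numeric(n)
  for (k in seq_len(nb)) {
    o <- if (bonds$aromatic[k]) 1.5 else bonds$order[k]
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + o
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + o
  }
  deg <- vapply(adj, length, integer(1))
  atom_tok <- function(i) {
    el <- atoms$element[i]
    if (el == "H") return("[H]")
    sym <- if (atoms$aromatic[i]) tolower(el) else el
    plain_ok <- FALSE
    if (el %in% SMILES_ORGANIC && atoms$charge[i] == 0L) {
      expected <- if (atoms$aromatic[i]) {
        if (el == "C") max(0L, 3L - deg[i]) else 0L
      } else {
        v <- ORGANIC_VALENCES[[el]]
        fit <- v[v >= ceiling(bsum[i])]
        if (length(fit) == 0) 0L else as.integer(fit[1] - round(bsum[i]))
      }
      plain_ok <- expected == atoms$nH[i] &&
        (!atoms$aromatic[i] || tolower(el) %in% SMILES_AROMATIC_ORGANIC)
    }
    if (plain_ok) return(sym)
    h <- if (atoms$nH[i] == 0) "" else if (atoms$nH[i] == 1) "H" else paste0("H", atoms$nH[i])
    cg <- if (atoms$charge[i] == 0) {
      ""
    } else if (atoms$charge[i] > 0) {
      paste0("+", if (atoms$charge[i] > 1) atoms$charge[i] else "")
    } else {
      paste0("-", if (atoms$charge[i] < -1) -atoms$charge[i] else "")
    }
    paste0("[", sym, h, cg, "]")
  }

  emit <- function(i) {
    out <- paste0(atom_tok(i), paste0(digits_at[[i]], collapse = ""))
    ch <- children[[i]]
    for (t in seq_along(ch)) {
      k <- ch[t]
      sub <- paste0(bond_sym(k), emit(other_end(k, i)))
      out <- paste0(out, if (t < length(ch)) paste0("(", sub, ")") else sub)
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}
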