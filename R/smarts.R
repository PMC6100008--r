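# SMARTS compiler and matcher. Supports the pattern vocabulary that
# substructure key sets (Klekota-Roth style) are written in: atom primitives
# *, A, a, #n, element symbols (aliphatic uppercase / aromatic lowercase),
# D, X, H, h, R, r, v, +/- charges; logical operators ! (not), & and
# juxtaposition (high-precedence and), , (or), ; (low-precedence and); bond
# symbols - / \ = # : ~ @ and the default single-or-aromatic bond; branches
# and ring closures. Recursive SMARTS ($(...)) and stereo primitives are not
# supported and are rejected at compile time with a clear error.

SMARTS_BOND_CHARS <- c("-", "=", "#", ":", "~", "@", "/", "\\")

#' Compile a SMARTS pattern
#'
#' @param smarts A SMARTS string (see the package vignette for the supported
#'   subset).
#' @return An object of class `nsfp_smarts` holding the query graph.
#' @examples
#' q <- smarts_compile("[OX2H]")
#' smarts_match_sets(smiles_to_molecule("OCCN"), q)
#' @export
smarts_compile <- function(smarts) {
  if (grepl("$", smarts, fixed = TRUE)) {
    stop("recursive SMARTS ($(...)) are not supported: '", smarts, "'",
      call. = FALSE
    )
  }
  sc <- chain_scan(smarts, read_smarts_atom, SMARTS_BOND_CHARS)
  bonds <- sc$bonds
  bonds$kind <- vapply(bonds$sym, function(sym) {
    switch(sym,
      "-" = "single", "/" = "single", "\\" = "single",
      "=" = "double", "#" = "triple", ":" = "aromatic",
      "~" = "any", "@" = "ring", "default"
    )
  }, character(1), USE.NAMES = FALSE)
  q <- structure(
    list(atoms = sc$atoms, bonds = bonds, pattern = smarts),
    class = "nsfp_smarts"
  )
  # queries must be connected: NSFP keys describe single substructures
  if (length(sc$atoms) > 1) {
    g <- igraph::graph_from_data_frame(
      d = bonds[, c("a1", "a2")], directed = FALSE,
      vertices = data.frame(name = seq_along(sc$atoms))
    )
    if (igraph::components(g)$no != 1) {
      stop("disconnected SMARTS pattern: '", smarts, "'", call. = FALSE)
    }
  }
  q
}

#' @export
print.nsfp_smarts <- function(x, ...) {
  cat("<smarts ", x$pattern, ": ", length(x$atoms), " atoms>\n", sep = "")
  invisible(x)
}

read_smarts_atom <- function(x, i) {
  ch <- substr(x, i, i)
  if (ch == "[") {
    j <- regexpr("]", substr(x, i + 1, nchar(x)), fixed = TRUE)
    if (j < 0) stop("unclosed '[' in '", x, "'", call. = FALSE)
    content <- substr(x, i + 1, i + j - 1)
    expr <- parse_smarts_expr(content, x)
    return(list(atom = expr, next_i = i + j + 1))
  }
  two <- substr(x, i, i + 1)
  if (two %in% c("Cl", "Br")) {
    return(list(atom = prim("elem_aliph", two), next_i = i + 2))
  }
  if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
    return(list(atom = prim("elem_aliph", ch), next_i = i + 1))
  }
  if (ch %in% c("b", "c", "n", "o", "p", "s")) {
    return(list(atom = prim("elem_arom", toupper(ch)), next_i = i + 1))
  }
  if (ch == "*") {
    return(list(atom = prim("any", NA), next_i = i + 1))
  }
  if (ch == "a") {
    return(list(atom = prim("aromatic", NA), next_i = i + 1))
  }
  if (ch == "A") {
    return(list(atom = prim("aliphatic", NA), next_i = i + 1))
  }
  NULL
}

prim <- function(kind, val) list(op = "prim", kind = kind, val = val)

# Operator precedence (loosest to tightest): ';' (and) < ',' (or) < '&' or
# juxtaposition (and) < '!' (not).
parse_smarts_expr <- function(content, full) {
  pos <- 1L
  n <- nchar(content)
  peek <- function() if (pos <= n) substr(content, pos, pos) else ""
  fail <- function() {
    stop("unsupported SMARTS atom expression [", content, "] in '", full, "'",
      call. = FALSE
    )
  }

  parse_low <- function() {
    terms <- list(parse_or())
    while (peek() == ";") {
      pos <<- pos + 1L
      terms[[length(terms) + 1L]] <- parse_or()
    }
    if (length(terms) == 1) terms[[1]] else list(op = "and", args = terms)
  }
  parse_or <- function() {
    terms <- list(parse_and())
    while (peek() == ",") {
      pos <<- pos + 1L
      terms[[length(terms) + 1L]] <- parse_and()
    }
    if (length(terms) == 1) terms[[1]] else list(op = "or", args = terms)
  }
  parse_and <- function() {
    terms <- list(parse_not())
    repeat {
      ch <- peek()
      if (ch == "&") {
        pos <<- pos + 1L
        terms[[length(terms) + 1L]] <- parse_not()
      } else if (ch != "" && !(ch %in% c(";", ","))) {
        terms[[length(terms) + 1L]] <- parse_not()
      } else {
        break
      }
    }
    if (length(terms) == 1) terms[[1]] else list(op = "and", args = terms)
  }
  parse_not <- function() {
    if (peek() == "!") {
      pos <<- pos + 1L
      return(list(op = "not", arg = parse_not()))
    }
    parse_prim()
  }
  take <- function(pattern) {
    m <- regmatches(
      substr(content, pos, n),
      regexpr(paste0("^", pattern), substr(content, pos, n))
    )
    if (length(m) == 1) {
      pos <<- pos + nchar(m)
      m
    } else {
      NULL
    }
  }
  parse_prim <- function() {
    t <- take("#[0-9]+")
    if (!is.null(t)) {
      return(prim("atomic_number", as.integer(substr(t, 2, nchar(t)))))
    }
    t <- take("\\*")
    if (!is.null(t)) {
      return(prim("any", NA))
    }
    t <- take("[DXHhRrvx][0-9]*")
    if (!is.null(t)) {
      letter <- substr(t, 1, 1)
      num <- if (nchar(t) > 1) as.integer(substr(t, 2, nchar(t))) else NA_integer_
      if (letter == "x") fail()
      # H with no digit means exactly one hydrogen; R/r with no digit mean
      # "in a ring"; D/X/h/v default to 1
      if (letter %in% c("D", "X", "h", "v") && is.na(num)) num <- 1L
      if (letter == "H" && is.na(num)) num <- 1L
      return(prim(switch(letter,
        D = "degree", X = "connections", H = "total_h", h = "implicit_h",
        R = "ring_count", r = "ring_size", v = "valence"
      ), num))
    }
    t <- take("\\+[0-9]+|-[0-9]+|\\++|--+|\\+|-")
    if (!is.null(t)) {
      chg <- if (grepl("[0-9]", t)) {
        as.integer(t)
      } else if (substr(t, 1, 1) == "+") {
        nchar(t)
      } else {
        -nchar(t)
      }
      return(prim("charge", as.integer(chg)))
    }
    t <- take("se|as|[bcnops]")
    if (!is.null(t)) {
      el <- paste0(toupper(substr(t, 1, 1)), substr(t, 2, 2))
      return(prim("elem_arom", el))
    }
    t <- take("[A-Z][a-z]?")
    if (!is.null(t)) {
      if (t == "A") {
        return(prim("aliphatic", NA))
      }
      if (t %in% names(ELEMENT_Z)) {
        return(prim("elem_aliph", t))
      }
      # single-letter fallback when a two-letter read grabbed the next primitive
      t1 <- substr(t, 1, 1)
      if (t1 %in% names(ELEMENT_Z)) {
        pos <<- pos - 1L
        return(prim("elem_aliph", t1))
      }
      fail()
    }
    t <- take("a")
    if (!is.null(t)) {
      return(prim("aromatic", NA))
    }
    fail()
  }

  expr <- parse_low()
  if (pos <= n) fail()
  expr
}

# Evaluate an atom expression against atom `i` of a molecule.
smarts_atom_ok <- function(expr, mol, i) {
  a <- mol$atoms
  switch(expr$op,
    "and" = all(vapply(expr$args, smarts_atom_ok, logical(1), mol = mol, i = i)),
    "or" = any(vapply(expr$args, smarts_atom_ok, logical(1), mol = mol, i = i)),
    "not" = !smarts_atom_ok(expr$arg, mol, i),
    "prim" = {
      switch(expr$kind,
        any = TRUE,
        aromatic = a$aromatic[i],
        aliphatic = !a$aromatic[i],
        atomic_number = !is.na(ELEMENT_Z[a$element[i]]) &&
          ELEMENT_Z[[a$element[i]]] == expr$val,
        elem_aliph = a$element[i] == expr$val && !a$aromatic[i],
        elem_arom = a$element[i] == expr$val && a$aromatic[i],
        degree = a$deg[i] == expr$val,
        connections = a$conn[i] == expr$val,
        total_h = a$h_total[i] == expr$val,
        implicit_h = a$nH[i] == expr$val,
        ring_count = if (is.na(expr$val)) {
          a$in_ring[i]
        } else if (expr$val == 0L) {
          !a$in_ring[i]
        } else {
          a$in_ring[i] # ring-count >= 1 approximated by ring membership
        },
        ring_size = if (is.na(expr$val)) {
          a$in_ring[i]
        } else {
          !is.na(a$min_ring[i]) && a$min_ring[i] == expr$val
        },
        valence = a$valence[i] == expr$val,
        charge = a$charge[i] == expr$val,
        stop("unknown primitive kind ", expr$kind, call. = FALSE)
      )
    },
    stop("unknown op ", expr$op, call. = FALSE)
  )
}

smarts_bond_ok <- function(kind, mol, bond_idx) {
  b <- mol$bonds
  switch(kind,
    single = b$order[bond_idx] == 1 && !b$aromatic[bond_idx],
    double = b$order[bond_idx] == 2 && !b$aromatic[bond_idx],
    triple = b$order[bond_idx] == 3 && !b$aromatic[bond_idx],
    aromatic = b$aromatic[bond_idx],
    any = TRUE,
    ring = b$in_ring[bond_idx],
    default = b$aromatic[bond_idx] ||
      (b$order[bond_idx] == 1 && !b$aromatic[bond_idx])
  )
}

#' Find all embeddings of a SMARTS query in a molecule
#'
#' Backtracking subgraph matching. `smarts_match_all()` returns every
#' embedding as a vector of molecule atom indices in query-atom order;
#' `smarts_match_sets()` collapses symmetry-equivalent embeddings to unique
#' atom-index sets (the deduplication the NSFP uses: benzene matched against
#' a six-membered aromatic ring key yields twelve embeddings but one atom
#' set).
#'
#' @param mol A molecule.
#' @param query A compiled SMARTS (`nsfp_smarts`) or a SMARTS string.
#' @return `smarts_match_all()`: list of integer vectors.
#'   `smarts_match_sets()`: list of sorted unique integer vectors.
#' @export
smarts_match_all <- function(mol, query) {
  if (is.character(query)) query <- smarts_compile(query)
  stopifnot(inherits(mol, "nsfp_molecule"), inherits(query, "nsfp_smarts"))
  nq <- length(query$atoms)
  nm <- nrow(mol$atoms)
  if (nm == 0) {
    return(list())
  }
  cand <- lapply(query$atoms, function(expr) {
    which(vapply(seq_len(nm), function(i) smarts_atom_ok(expr, mol, i), logical(1)))
  })
  if (any(vapply(cand, length, integer(1)) == 0)) {
    return(list())
  }

  # molecule adjacency: bond index lookup
  bond_at <- matrix(0L, nm, nm)
  for (k in seq_len(nrow(mol$bonds))) {
    bond_at[mol$bonds$a1[k], mol$bonds$a2[k]] <- k
    bond_at[mol$bonds$a2[k], mol$bonds$a1[k]] <- k
  }

  # query traversal order: start at the rarest atom, grow connectedly
  qadj <- vector("list", nq)
  for (k in seq_len(nrow(query$bonds))) {
    a <- query$bonds$a1[k]
    b <- query$bonds$a2[k]
    qadj[[a]] <- rbind(qadj[[a]], c(b, k))
    qadj[[b]] <- rbind(qadj[[b]], c(a, k))
  }
  ord <- integer(0)
  placed <- logical(nq)
  repeat {
    if (length(ord) == 0) {
      nxt <- which.min(vapply(cand, length, integer(1)))
    } else {
      frontier <- setdiff(unlist(lapply(ord, function(q) qadj[[q]][, 1])), ord)
      if (length(frontier) == 0) break
      nxt <- frontier[which.min(vapply(cand[frontier], length, integer(1)))]
    }
    ord <- c(ord, nxt)
    placed[nxt] <- TRUE
    if (length(ord) == nq) break
  }

  results <- list()
  assign <- integer(nq)
  used <- logical(nm)
  recurse <- function(step) {
    if (step > nq) {
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    q <- ord[step]
    anchors <- if (is.null(qadj[[q]])) {
      matrix(integer(0), 0, 2)
    } else {
      qadj[[q]][placed_now[qadj[[q]][, 1]], , drop = FALSE]
    }
    for (m in cand[[q]]) {
      if (used[m]) next
      ok <- TRUE
      for (r in seq_len(nrow(anchors))) {
        ma <- assign[anchors[r, 1]]
        bk <- bond_at[ma, m]
        if (bk == 0L || !smarts_bond_ok(query$bonds$kind[anchors[r, 2]], mol, bk)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[q] <<- m
      used[m] <<- TRUE
      placed_now[q] <<- TRUE
      recurse(step + 1L)
      used[m] <<- FALSE
      placed_now[q] <<- FALSE
    }
  }
  placed_now <- logical(nq)
  recurse(1L)
  results
}

#' @rdname smarts_match_all
#' @export
smarts_match_sets <- function(mol, query) {
  hits <- smarts_match_all(mol, query)
  if (length(hits) == 0) {
    return(list())
  }
  sets <- lapply(hits, function(v) sort(unique(v)))
  keys <- vapply(sets, paste, character(1), collapse = ",")
  sets[!duplicated(keys)]
}
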