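# Internal scanner for SMILES-style chain grammars (atoms, bonds, branches,
# ring-bond closures). Both the SMILES reader and the SMARTS compiler walk
# their strings with this engine; they differ only in how an atom token is
# read and which bond symbols are legal.

chain_scan <- function(x, read_atom, bond_chars) {
  n <- nchar(x)
  atoms <- list()
  bonds_a1 <- integer(0)
  bonds_a2 <- integer(0)
  bonds_sym <- character(0)
  prev <- NA_integer_
  pending <- ""
  stack <- integer(0)
  ring <- list() # closure label -> list(atom, sym)

  add_bond <- function(a, b, sym) {
    if (a == b) stop("self-bond in '", x, "'", call. = FALSE)
    bonds_a1 <<- c(bonds_a1, a)
    bonds_a2 <<- c(bonds_a2, b)
    bonds_sym <<- c(bonds_sym, sym)
  }

  i <- 1
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in '", x, "'", call. = FALSE)
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unmatched ')' in '", x, "'", call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1
    } else if (ch %in% bond_chars) {
      pending <- ch
      i <- i + 1
    } else if (grepl("^[0-9%]$", ch)) {
      if (ch == "%") {
        lab <- substr(x, i + 1, i + 2)
        if (!grepl("^[0-9]{2}$", lab)) {
          stop("bad %-ring closure in '", x, "'", call. = FALSE)
        }
        i <- i + 3
      } else {
        lab <- ch
        i <- i + 1
      }
      if (is.na(prev)) stop("ring closure before any atom in '", x, "'", call. = FALSE)
      if (!is.null(ring[[lab]])) {
        op <- ring[[lab]]
        sym <- if (nzchar(pending)) pending else op$sym
        add_bond(op$atom, prev, sym)
        ring[[lab]] <- NULL
      } else {
        ring[[lab]] <- list(atom = prev, sym = pending)
      }
      pending <- ""
    } else {
      res <- read_atom(x, i)
      if (is.null(res)) {
        stop("unexpected character '", ch, "' at position ", i, " in '", x, "'",
          call. = FALSE
        )
      }
      atoms[[length(atoms) + 1L]] <- res$atom
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- ""
      prev <- idx
      i <- res$next_i
    }
  }
  if (length(stack) > 0) stop("unclosed branch in '", x, "'", call. = FALSE)
  open <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open) > 0) {
    stop("unclosed ring bond(s) ", paste(open, collapse = ","), " in '", x, "'",
      call. = FALSE
    )
  }
  if (length(atoms) == 0) stop("no atoms in '", x, "'", call. = FALSE)
  list(
    atoms = atoms,
    bonds = data.frame(
      a1 = bonds_a1, a2 = bonds_a2, sym = bonds_sym,
      stringsAsFactors = FALSE
    )
  )
}
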