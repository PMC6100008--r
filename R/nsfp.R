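# Neighbouring Substructures Fingerprint (NSFP). A key-based substructure
# fingerprint augmented with connectivity: instead of recording which SMARTS
# keys occur, the NSFP records which *pairs* (and optionally triples) of key
# matches are neighbours in the molecular graph, so that two substructures
# only count when they jointly constitute a larger fragment.

#' Match every key of a key set against a molecule
#'
#' Each match is a distinct (key_id, atom set) pair: symmetry-equivalent
#' embeddings of the same key on the same atoms are collapsed to one match,
#' while matches of the same key on different atom sets stay distinct.
#'
#' @param mol A molecule object.
#' @param keys An `nsfp_keyset`.
#' @return A tibble with columns `key_id` and `atom_set` (list-column of
#'   sorted integer vectors); zero rows when nothing matches.
#' @export
match_keys <- function(mol, keys) {
  stopifnot(inherits(mol, "nsfp_molecule"), inherits(keys, "nsfp_keyset"))
  res <- purrr::map2(keys$key_id, keys$query, function(kid, q) {
    sets <- smarts_match_sets(mol, q)
    if (length(sets) == 0) {
      return(NULL)
    }
    tibble::tibble(key_id = kid, atom_set = sets)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(key_id = character(0), atom_set = list()))
  }
  out
}

#' Adjacency between substructure matches
#'
#' Two matches are neighbours when their atom sets touch under the chosen
#' definition: `overlap` — the sets share an atom; `bonded` — they share an
#' atom or a bond joins them (the default NSFP notion: the two substructures
#' form one connected fragment); `path` — the shortest topological distance
#' between the sets is at most `d` bonds (`d = 0` reduces to `overlap`,
#' `d = 1` to `bonded`).
#'
#' @param matches A match tibble from [match_keys()].
#' @param mol The molecule the matches came from.
#' @param mode `"overlap"`, `"bonded"` or `"path"`.
#' @param d Maximum topological distance for `mode = "path"`.
#' @return Integer matrix with two columns (`i`, `j`), each row an unordered
#'   pair of row indices into `matches`; zero rows when no pair is adjacent.
#' @export
match_adjacency <- function(matches, mol, mode = c("bonded", "overlap", "path"),
                            d = 1L) {
  mode <- match.arg(mode)
  if (mode == "path" && d < 0) stop("d must be >= 0", call. = FALSE)
  m <- nrow(matches)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (m < 2) {
    return(empty)
  }
  dist <- mol_distances(mol)
  limit <- switch(mode, overlap = 0, bonded = 1, path = d)
  pairs <- utils::combn(m, 2)
  keep <- vapply(seq_len(ncol(pairs)), function(p) {
    a <- matches$atom_set[[pairs[1, p]]]
    b <- matches$atom_set[[pairs[2, p]]]
    min(dist[a, b, drop = FALSE]) <= limit
  }, logical(1))
  out <- t(pairs[, keep, drop = FALSE])
  colnames(out) <- c("i", "j")
  out
}

#' Compute the Neighbouring Substructures Fingerprint of a molecule
#'
#' Doublet features are counted once per adjacent pair of key matches;
#' triplet features once per connected triple in the match-adjacency graph
#' (any three matches whose induced adjacency subgraph is connected). A
#' feature tuple is canonicalized by sorting its key ids lexicographically;
#' tuples of repeated keys (two distinct matches of the same key) are
#' retained, e.g. `KR007|KR007`.
#'
#' @param mol A molecule object.
#' @param keys An `nsfp_keyset`.
#' @param order `"2"` for doublets only or `"2+3"` to add triplets.
#' @param mode,d Neighbour definition, see [match_adjacency()].
#' @param distinct_keys_only Drop tuples whose keys are all identical
#'   (default `FALSE`: self-tuples from distinct matches are kept).
#' @param counts Store occurrence counts (default) rather than clamping to
#'   presence; kernels consume the binarized view either way.
#' @return An object of class `nsfp_fingerprint`: named integer vector of
#'   feature counts (names are `key|key[|key]` tuples) with attributes
#'   `keyset_name` and `order`.
#' @examples
#' keys <- make_keyset(c("[OX2H]", "[NX3;H2]"), c("K_O", "K_N"))
#' nsfp_fingerprint(smiles_to_molecule("OCCN"), keys, mode = "path", d = 3)
#' @export
nsfp_fingerprint <- function(mol, keys, order = c("2", "2+3"),
                             mode = c("bonded", "overlap", "path"), d = 1L,
                             distinct_keys_only = FALSE, counts = TRUE) {
  order <- match.arg(order)
  mode <- match.arg(mode)
  if (!inherits(keys, "nsfp_keyset") || nrow(keys) == 0) {
    stop("empty or invalid key set", call. = FALSE)
  }
  matches <- match_keys(mol, keys)
  adj <- match_adjacency(matches, mol, mode = mode, d = d)
  feats <- character(0)
  if (nrow(adj) > 0) {
    kid <- matches$key_id
    feats <- vapply(seq_len(nrow(adj)), function(p) {
      paste(sort(c(kid[adj[p, 1]], kid[adj[p, 2]])), collapse = "|")
    }, character(1))
    if (order == "2+3" && nrow(matches) >= 3) {
      feats <- c(feats, nsfp_triplets(matches, adj))
    }
    if (distinct_keys_only) {
      keep <- vapply(strsplit(feats, "|", fixed = TRUE), function(v) {
        length(unique(v)) > 1
      }, logical(1))
      feats <- feats[keep]
    }
  }
  counts_vec <- if (length(feats) == 0) {
    integer(0)
  } else {
    tab <- table(feats)
    stats::setNames(as.integer(tab), names(tab))
  }
  if (!counts && length(counts_vec) > 0) counts_vec[] <- 1L
  new_fingerprint(counts_vec, attr(keys, "keyset_name"), order)
}

nsfp_triplets <- function(matches, adj) {
  m <- nrow(matches)
  amat <- matrix(FALSE, m, m)
  amat[adj] <- TRUE
  amat[adj[, c(2, 1), drop = FALSE]] <- TRUE
  kid <- matches$key_id
  trips <- utils::combn(m, 3)
  out <- character(0)
  for (p in seq_len(ncol(trips))) {
    a <- trips[1, p]
    b <- trips[2, p]
    cc <- trips[3, p]
    ne <- amat[a, b] + amat[a, cc] + amat[b, cc]
    # a 3-node graph is connected iff it has >= 2 edges
    if (ne >= 2) {
      out <- c(out, paste(sort(c(kid[a], kid[b], kid[cc])), collapse = "|"))
    }
  }
  out
}

new_fingerprint <- function(counts, keyset_name, order) {
  structure(counts,
    keyset_name = keyset_name, order = order,
    class = "nsfp_fingerprint"
  )
}

#' @export
print.nsfp_fingerprint <- function(x, ...) {
  cat("<nsfp fingerprint: ", length(x), " features, keyset '",
    attr(x, "keyset_name"), "'>\n",
    sep = ""
  )
  if (length(x) > 0) print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Binarized (presence) view of a fingerprint
#'
#' @param fp An `nsfp_fingerprint`.
#' @return Character vector of present feature tuples (count >= 1).
#' @export
binarize <- function(fp) {
  stopifnot(inherits(fp, "nsfp_fingerprint"))
  names(fp)[as.integer(fp) >= 1L]
}

#' Fingerprint a whole molecule table
#'
#' @param mol_tbl A molecule tibble from [parse_molecules()].
#' @param keys An `nsfp_keyset`.
#' @param ... Passed to [nsfp_fingerprint()].
#' @return The input tibble with a `fingerprint` list-column added.
#' @export
nsfp_fingerprints <- function(mol_tbl, keys, ...) {
  stopifnot(is.data.frame(mol_tbl), "mol" %in% names(mol_tbl))
  mol_tbl$fingerprint <- purrr::map(mol_tbl$mol, nsfp_fingerprint, keys = keys, ...)
  mol_tbl
}

#' Write fingerprints as JSON lines
#'
#' One JSON object per molecule per line:
#' `{"id": ..., "features": {"KR001|KR007": 2, ...}}`.
#'
#' @param fp_tbl A tibble with `id` and `fingerprint` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_jsonl <- function(fp_tbl, path) {
  lines <- purrr::map2_chr(fp_tbl$id, fp_tbl$fingerprint, function(id, fp) {
    feats <- if (length(fp) == 0) {
      stats::setNames(list(), character(0))
    } else {
      as.list(stats::setNames(as.integer(fp), names(fp)))
    }
    jsonlite::toJSON(list(id = id, features = feats), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Dense 0/1 feature matrix over an ordered feature vocabulary
#'
#' @param fingerprints List of `nsfp_fingerprint` objects.
#' @param vocabulary Optional character vector fixing the column order;
#'   defaults to the sorted union of observed features.
#' @return 0/1 integer matrix, one row per fingerprint.
#' @export
fingerprint_matrix <- function(fingerprints, vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(fingerprints, names))))
  }
  m <- matrix(0L, length(fingerprints), length(vocabulary),
    dimnames = list(NULL, vocabulary)
  )
  for (i in seq_along(fingerprints)) {
    present <- intersect(names(fingerprints[[i]]), vocabulary)
    m[i, present] <- 1L
  }
  m
}
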