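#' Read a molecule library from a SMILES or SDF file
#'
#' SMILES files carry one record per line, `SMILES[ whitespace id]`; ids are
#' auto-assigned (`mol_<line>`) when absent. SDF v2000 records are read from
#' their fixed-width connection tables (elements, bonds, `M  CHG` formal
#' charges). Records that fail to parse are skipped, counted, and reported
#' in a message; a file with zero valid records is an error.
#'
#' @param path Path to the input file.
#' @param format `"smiles"` or `"sdf"`.
#' @param desalt Keep only the largest organic fragment of each record
#'   (default `TRUE`).
#' @return A tibble with one row per valid record: `id`, `mol` (list-column
#'   of molecule objects), `heavy_atoms`, `source`. The number of skipped
#'   records is attached as attribute `skipped` together with their ids in
#'   attribute `skipped_ids`.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), f)
#' parse_molecules(f)
#' @export
parse_molecules <- function(path, format = c("smiles", "sdf"), desalt = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- which(keep)
    if (length(lines) == 0) stop("no records in ", path, call. = FALSE)
    parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
    smiles <- parts[, 1]
    ids <- ifelse(nzchar(parts[, 2]), parts[, 2], paste0("mol_", lineno))
    mols <- purrr::map2(smiles, ids, function(s, id) {
      tryCatch(smiles_to_molecule(s, id = id, desalt = desalt),
        error = function(e) NULL
      )
    })
  } else {
    sdf <- read_sdf_records(path)
    ids <- ifelse(nzchar(sdf$id), sdf$id, paste0("mol_", seq_along(sdf$id)))
    mols <- purrr::map2(sdf$records, ids, function(rec, id) {
      tryCatch(
        {
          m <- sdf_record_to_molecule(rec, id = id)
          if (desalt) m <- largest_fragment(m)
          m
        },
        error = function(e) NULL
      )
    })
  }
  bad <- vapply(mols, is.null, logical(1))
  if (all(bad)) stop("no valid molecule records in ", path, call. = FALSE)
  if (any(bad)) {
    message(sum(bad), " record(s) skipped in ", path, ": ",
      paste(utils::head(ids[bad], 10), collapse = ", "),
      if (sum(bad) > 10) ", ..." else ""
    )
  }
  out <- tibble::tibble(
    id = ids[!bad],
    mol = mols[!bad],
    heavy_atoms = vapply(mols[!bad], heavy_atom_count, integer(1)),
    source = vapply(mols[!bad], function(m) m$source, character(1))
  )
  attr(out, "skipped") <- sum(bad)
  attr(out, "skipped_ids") <- ids[bad]
  out
}

# Minimal SDF record splitter; per-record parsing is delegated to
# sdf_record_to_molecule (atom/bond blocks of the V2000 connection table).
read_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  records <- purrr::map2(starts, ends, function(s, e) lines[s:e])
  records <- records[vapply(records, function(r) any(nzchar(trimws(r))), logical(1))]
  ids <- vapply(records, function(r) trimws(r[1]), character(1))
  list(records = records, id = ids)
}

sdf_record_to_molecule <- function(rec, id) {
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("bad SDF counts line", call. = FALSE)
  atom_lines <- rec[5:(4 + na)]
  element <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(
    as.numeric(substr(atom_lines, 1, 10)),
    as.numeric(substr(atom_lines, 11, 20)),
    as.numeric(substr(atom_lines, 21, 30))
  )
  bonds <- if (nb > 0) {
    bl <- rec[(5 + na):(4 + na + nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      type = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), type = integer(0))
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nc <- flds[1]
    for (t in seq_len(nc)) {
      charge[flds[2 * t]] <- flds[2 * t + 1]
    }
  }
  aromatic_bond <- bonds$type == 4L
  atoms <- data.frame(
    element = element, charge = charge,
    aromatic = FALSE, nH = NA_integer_, stringsAsFactors = FALSE
  )
  atoms$aromatic[unique(c(bonds$a1[aromatic_bond], bonds$a2[aromatic_bond]))] <- TRUE
  b <- data.frame(
    a1 = bonds$a1, a2 = bonds$a2,
    order = ifelse(aromatic_bond, 1L, pmin(bonds$type, 3L)),
    aromatic = aromatic_bond, stringsAsFactors = FALSE
  )
  ar <- perceive_kekulized_aromaticity(atoms, b)
  atoms <- ar$atoms
  b <- ar$bonds
  atoms$nH <- implicit_hydrogens(atoms, b, id)
  mol <- new_molecule(atoms, b, id = id, source = "sdf")
  attr(mol, "xyz") <- xyz
  mol
}

#' Load a SMARTS substructure key set
#'
#' Key files are tab-separated `key_id<TAB>SMARTS`, or a bare one-pattern-
#' per-line list (ids auto-numbered `K0001`, `K0002`, ...). Every pattern is
#' compiled at load time; the key order in the file is preserved and defines
#' the feature indexing of all fingerprints built from the set.
#'
#' @param path Path to the key file.
#' @param name Name recorded on the key set (defaults to the file name).
#' @return An object of class `nsfp_keyset`: tibble of `key_id`, `smarts`,
#'   and a list-column `query` of compiled patterns.
#' @export
load_keyset <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read key file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("no keys in ", path, call. = FALSE)
  has_tab <- grepl("\t", lines)
  if (any(has_tab) && !all(has_tab)) {
    stop("mixed key-file format in ", path, call. = FALSE)
  }
  if (all(has_tab)) {
    parts <- stringr::str_split_fixed(lines, "\t", 2)
    key_id <- trimws(parts[, 1])
    smarts <- trimws(parts[, 2])
  } else {
    smarts <- trimws(lines)
    key_id <- sprintf("K%04d", seq_along(smarts))
  }
  dup <- key_id[duplicated(key_id)]
  if (length(dup) > 0) {
    stop("duplicate key id(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  query <- vector("list", length(smarts))
  for (i in seq_along(smarts)) {
    query[[i]] <- tryCatch(smarts_compile(smarts[i]), error = function(e) {
      stop("key ", key_id[i], ": cannot compile SMARTS '", smarts[i], "': ",
        conditionMessage(e),
        call. = FALSE
      )
    })
  }
  keyset(key_id, smarts, query, name)
}

keyset <- function(key_id, smarts, query, name) {
  out <- tibble::tibble(key_id = key_id, smarts = smarts, query = query)
  attr(out, "keyset_name") <- name
  class(out) <- c("nsfp_keyset", class(out))
  out
}

#' Build a key set from a character vector of SMARTS
#'
#' @param smarts Character vector of SMARTS patterns.
#' @param key_id Optional ids (default `K0001`, ...).
#' @param name Key set name.
#' @return An `nsfp_keyset` (see [load_keyset()]).
#' @export
make_keyset <- function(smarts, key_id = sprintf("K%04d", seq_along(smarts)),
                        name = "adhoc") {
  stopifnot(length(smarts) == length(key_id), !anyDuplicated(key_id))
  keyset(key_id, smarts, lapply(smarts, smarts_compile), name)
}

#' Path to the demo substructure key file shipped with the package
#'
#' A small Klekota-Roth-flavoured key list (~40 SMARTS) used by the examples
#' and tests. Production screening should load a full published key set via
#' [load_keyset()].
#'
#' @return File path.
#' @export
demo_keyset_path <- function() {
  system.file("extdata", "demo_keys.tsv", package = "nsfpscreen", mustWork = TRUE)
}
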