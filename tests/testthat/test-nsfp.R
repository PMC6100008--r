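test_that("match adjacency respects overlap, bonded and path modes", {
  mol <- smiles_to_molecule("OCCN")
  keys <- make_keyset(c("[OX2H]", "[NX3;H2]"), c("K_O", "K_N"))
  matches <- match_keys(mol, keys)
  expect_equal(nrow(matches), 2)
  # O(1) and N(4) are three bonds apart
  expect_equal(nrow(match_adjacency(matches, mol, mode = "bonded")), 0)
  expect_equal(nrow(match_adjacency(matches, mol, mode = "path", d = 2)), 0)
  expect_equal(nrow(match_adjacency(matches, mol, mode = "path", d = 3)), 1)
  expect_error(match_adjacency(matches, mol, mode = "path", d = -1), "d must be")
})

test_that("overlapping matches are adjacent in every mode", {
  mol <- smiles_to_molecule("CC(=O)N") # amide: carbonyl and N-C=O share atoms
  keys <- make_keyset(c("[CX3]=[OX1]", "[NX3][CX3]=[OX1]"), c("K_CO", "K_AMIDE"))
  matches <- match_keys(mol, keys)
  expect_equal(nrow(matches), 2)
  for (mode in c("overlap", "bonded")) {
    expect_equal(nrow(match_adjacency(matches, mol, mode = mode)), 1)
  }
  single <- matches[1, , drop = FALSE]
  expect_equal(nrow(match_adjacency(single, mol)), 0)
})

test_that("doublet fingerprints count adjacent match pairs once", {
  keys <- make_keyset(c("[OX2H]", "[NX3;H2]"), c("K_O", "K_N"))
  fp <- nsfp_fingerprint(smiles_to_molecule("OCCN"), keys, mode = "path", d = 3)
  expect_equal(fp_as_named_int(fp), c("K_N|K_O" = 1L))
  # a molecule with one match total has no pairs
  fp1 <- nsfp_fingerprint(smiles_to_molecule("OCC"), keys)
  expect_length(fp1, 0)
  expect_error(
    nsfp_fingerprint(smiles_to_molecule("OCC"), structure(list(), class = "x")),
    "key set"
  )
})

test_that("triplets require a connected three-match subgraph", {
  keys <- make_keyset(c("[OX2H]", "[CX4]", "[NX3;H2]"), c("K_O", "K_C", "K_N"))
  fp <- nsfp_fingerprint(smiles_to_molecule("OCN"), keys,
    order = "2+3", mode = "bonded"
  )
  expect_equal(unname(fp[["K_C|K_N|K_O"]]), 1L)
  # path-connected through the shared carbon even though O and N are not bonded
  expect_equal(unname(fp[["K_C|K_O"]]), 1L)
  expect_equal(unname(fp[["K_C|K_N"]]), 1L)
  expect_false("K_N|K_O" %in% names(fp))
})

test_that("self-tuples of one key on distinct atom sets are retained and switchable", {
  keys <- make_keyset("[OX2H]", "K_O")
  diol <- smiles_to_molecule("OCO")
  fp <- nsfp_fingerprint(diol, keys, mode = "path", d = 2)
  expect_equal(fp_as_named_int(fp), c("K_O|K_O" = 1L))
  fp2 <- nsfp_fingerprint(diol, keys, mode = "path", d = 2, distinct_keys_only = TRUE)
  expect_length(fp2, 0)
})

test_that("binarize reduces counts to presence", {
  fp <- structure(c("a|b" = 3L, "b|b" = 2L),
    keyset_name = "t", order = "2",
    class = "nsfp_fingerprint"
  )
  expect_setequal(binarize(fp), c("a|b", "b|b"))
  empty <- structure(integer(0),
    keyset_name = "t", order = "2",
    class = "nsfp_fingerprint"
  )
  expect_length(binarize(empty), 0)
})

test_that("fingerprints equal the independent brute-force enumerator", {
  keys <- oracle_keyset()
  smiles <- random_small_smiles(40, seed = 11)
  for (smi in smiles) {
    mol <- smiles_to_molecule(smi)
    if (heavy_atom_count(mol) > 14) next
    for (ord in c("2", "2+3")) {
      expect_equal(
        fp_as_named_int(nsfp_fingerprint(mol, keys, order = ord, mode = "bonded")),
        fp_as_named_int(brute_force_nsfp(mol, keys, order = ord, mode = "bonded")),
        info = paste(smi, ord)
      )
    }
    expect_equal(
      fp_as_named_int(nsfp_fingerprint(mol, keys, mode = "path", d = 3)),
      fp_as_named_int(brute_force_nsfp(mol, keys, mode = "path", d = 3)),
      info = smi
    )
  }
})

test_that("fingerprints are invariant under atom renumbering", {
  keys <- oracle_keyset()
  set.seed(5)
  for (smi in c("CC(=O)Nc1ccccc1", "OCC(N)C=O", "N#CCCO")) {
    mol <- smiles_to_molecule(smi)
    base <- fp_as_named_int(nsfp_fingerprint(mol, keys, order = "2+3"))
    for (rep in 1:3) {
      perm <- sample(nrow(mol$atoms))
      atoms <- mol$atoms[perm, c("element", "charge", "aromatic", "nH")]
      rownames(atoms) <- NULL
      inv <- order(perm)
      bonds <- data.frame(
        a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
        order = mol$bonds$order, aromatic = mol$bonds$aromatic
      )
      shuffled <- nsfpscreen:::new_molecule(atoms, bonds, id = mol$id)
      expect_equal(
        fp_as_named_int(nsfp_fingerprint(shuffled, keys, order = "2+3")),
        base,
        info = paste(smi, rep)
      )
    }
  }
})

test_that("growing the path threshold never removes features or decreases counts", {
  keys <- oracle_keyset()
  for (smi in random_small_smiles(15, seed = 23)) {
    mol <- smiles_to_molecule(smi)
    prev <- integer(0)
    for (d in 0:4) {
      cur <- fp_as_named_int(nsfp_fingerprint(mol, keys, mode = "path", d = d))
      expect_true(all(names(prev) %in% names(cur)), info = paste(smi, d))
      if (length(prev) > 0) {
        expect_true(all(cur[names(prev)] >= prev), info = paste(smi, d))
      }
      prev <- cur
    }
  }
})

test_that("doublet totals are bounded by match-pair combinatorics", {
  keys <- oracle_keyset()
  for (smi in random_small_smiles(15, seed = 31)) {
    mol <- smiles_to_molecule(smi)
    m <- nrow(match_keys(mol, keys))
    fp <- nsfp_fingerprint(mol, keys, mode = "path", d = 10)
    expect_lte(sum(fp), choose(m, 2) + m, label = smi)
  }
})

test_that("fingerprint JSON lines round-trip ids and features", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("OCCN amine", "CCCC butane"), f)
  tbl <- nsfp_fingerprints(
    parse_molecules(f),
    make_keyset(c("[OX2H]", "[NX3;H2]"), c("KO", "KN")),
    mode = "path", d = 3
  )
  out <- withr::local_tempfile(fileext = ".jsonl")
  write_fingerprints_jsonl(tbl, out)
  lines <- readLines(out)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$id, "amine")
  expect_equal(rec$features[["KN|KO"]], 1L)
  rec2 <- jsonlite::fromJSON(lines[2])
  expect_length(rec2$features, 0)
  m <- fingerprint_matrix(tbl$fingerprint)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(m[, "KN|KO"], c(1L, 0L))
})
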