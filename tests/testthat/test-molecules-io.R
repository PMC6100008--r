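test_that("SMILES libraries parse with id assignment and skip bookkeeping", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO m1", "C(", "c1ccccc1"), f)
  expect_message(tbl <- parse_molecules(f), "skipped")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$id, c("m1", "mol_3"))
  expect_equal(tbl$heavy_atoms, c(3L, 6L))
  expect_equal(attr(tbl, "skipped"), 1L)
  expect_equal(attr(tbl, "skipped_ids"), "mol_2")
})

test_that("unreadable files and all-invalid libraries are fatal", {
  expect_error(parse_molecules(tempfile()), "cannot read")
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C(", ")("), f)
  expect_error(parse_molecules(f), "no valid molecule records")
})

test_that("heavy atom count ignores hydrogen notation", {
  expect_equal(heavy_atom_count(smiles_to_molecule("CCO")), 3L)
  expect_equal(heavy_atom_count(smiles_to_molecule("[H]OC([H])([H])[H]")), 2L)
  expect_equal(heavy_atom_count(smiles_to_molecule("c1ccccc1")), 6L)
})

test_that("heavy atom count is invariant under kekulization and explicit-H rewriting", {
  pairs <- list(
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("c1ccncc1", "C1=CC=NC=C1"),
    c("Cc1ccccc1", "CC1=CC=CC=C1"),
    c("CN", "C([H])([H])([H])N([H])[H]"),
    c("O", "[H]O[H]")
  )
  for (p in pairs) {
    expect_equal(
      heavy_atom_count(smiles_to_molecule(p[1])),
      heavy_atom_count(smiles_to_molecule(p[2])),
      info = paste(p, collapse = " vs ")
    )
  }
})

test_that("kekulized aromatic rings are perceived as aromatic", {
  kek <- smiles_to_molecule("C1=CC=CC=C1")
  arom <- smiles_to_molecule("c1ccccc1")
  expect_true(all(kek$atoms$aromatic))
  q <- smarts_compile("c1ccccc1")
  expect_length(smarts_match_sets(kek, q), 1)
  expect_equal(
    fp_as_named_int(nsfp_fingerprint(kek, demo_keys())),
    fp_as_named_int(nsfp_fingerprint(arom, demo_keys()))
  )
})

test_that("multi-fragment salts keep the largest organic fragment by default", {
  m <- smiles_to_molecule("CCN.Cl")
  expect_equal(heavy_atom_count(m), 3L)
  m2 <- smiles_to_molecule("CCN.Cl", desalt = FALSE)
  expect_equal(heavy_atom_count(m2), 4L)
})

test_that("parse -> write -> parse preserves structure and fingerprint", {
  keys <- demo_keys()
  for (row in seq_len(nrow(fixture_molecules()))) {
    smi <- fixture_molecules()$smiles[row]
    m1 <- smiles_to_molecule(smi)
    m2 <- smiles_to_molecule(molecule_to_smiles(m1))
    expect_equal(nrow(m2$atoms), nrow(m1$atoms), info = smi)
    expect_equal(nrow(m2$bonds), nrow(m1$bonds), info = smi)
    expect_equal(
      fp_as_named_int(nsfp_fingerprint(m2, keys)),
      fp_as_named_int(nsfp_fingerprint(m1, keys)),
      info = smi
    )
  }
})

test_that("SDF records parse to the same molecules as their SMILES", {
  sdf_benzamide <- c(
    "benzamide", "  synthetic", "",
    "  9  9  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.0000    0.0000    0.0000 C   0  0",
    "    2.0000    0.0000    0.0000 C   0  0",
    "    2.0000    1.0000    0.0000 C   0  0",
    "    1.0000    1.0000    0.0000 C   0  0",
    "    0.0000    1.0000    0.0000 C   0  0",
    "    3.0000    1.5000    0.0000 C   0  0",
    "    4.0000    1.0000    0.0000 O   0  0",
    "    3.0000    2.5000    0.0000 N   0  0",
    "  1  2  2  0", "  2  3  1  0", "  3  4  2  0", "  4  5  1  0",
    "  5  6  2  0", "  6  1  1  0", "  4  7  1  0", "  7  8  2  0",
    "  7  9  1  0",
    "M  END", "$$$$"
  )
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_benzamide, f)
  tbl <- parse_molecules(f, format = "sdf")
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$id, "benzamide")
  expect_equal(tbl$heavy_atoms, 9L)
  ref <- smiles_to_molecule("NC(=O)c1ccccc1")
  expect_equal(
    fp_as_named_int(nsfp_fingerprint(tbl$mol[[1]], demo_keys())),
    fp_as_named_int(nsfp_fingerprint(ref, demo_keys()))
  )
})

test_that("key sets load with order preserved and loud failures", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("K1\t[OX2H]", "K2\t[NX3]"), f)
  ks <- load_keyset(f)
  expect_s3_class(ks, "nsfp_keyset")
  expect_equal(ks$key_id, c("K1", "K2"))

  writeLines(c("K1\t[OX2H]", "K1\t[NX3]"), f)
  expect_error(load_keyset(f), "duplicate key id.*K1")

  writeLines(c("K9\t[C("), f)
  expect_error(load_keyset(f), "K9")

  writeLines(c("[OX2H]", "[NX3]"), f)
  ks2 <- load_keyset(f)
  expect_equal(ks2$key_id, c("K0001", "K0002"))
})

test_that("the shipped demo key file compiles completely", {
  ks <- demo_keys()
  expect_gte(nrow(ks), 40)
  expect_true(all(vapply(ks$query, inherits, logical(1), "nsfp_smarts")))
})
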