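rec <- function(id, target, value, unit = "nM", measure = "Ki", relation = "=") {
  tibble::tibble(
    compound_id = id, target_id = target, value = value,
    unit = unit, measure = measure, relation = relation
  )
}

test_that("affinities normalize to Ki in nM across units and measures", {
  records <- dplyr::bind_rows(
    rec("a", "R2B", 6.0, measure = "pKi"),
    rec("b", "R2B", 0.5, unit = "uM"),
    rec("c", "R2B", 2e-6, unit = "M"),
    rec("d", "R2B", 120, measure = "Kd")
  )
  out <- normalize_to_ki(records)
  expect_equal(out$ki_nM, c(1000, 500, 2000, 120))
  expect_true(all(is.na(out$reject_reason)))
})

test_that("censored records are rejected only when they straddle a threshold", {
  records <- dplyr::bind_rows(
    rec("a", "R2B", 800, relation = ">"), # could be < or > 1000: ambiguous
    rec("b", "R2B", 5000, relation = ">"), # surely inactive
    rec("c", "R2B", 100, relation = "<"), # surely active
    rec("d", "R2B", 800, relation = "<") # could be active or ambiguous
  )
  out <- normalize_to_ki(records)
  expect_equal(out$reject_reason[1], "ambiguous vs thresholds")
  expect_true(is.na(out$reject_reason[2]))
  expect_true(is.na(out$reject_reason[3]))
  expect_equal(out$reject_reason[4], "ambiguous vs thresholds")
})

test_that("non-positive values are flagged, not propagated", {
  out <- normalize_to_ki(rec("a", "R2B", -5))
  expect_equal(out$reject_reason, "non-positive value")
  expect_true(is.na(out$ki_nM))
})

test_that("activity labels use inclusive 500/1000 nM thresholds", {
  expect_equal(
    label_activity(c(500, 1000, 750, 1, 1e6)),
    c("active", "inactive", "ambiguous", "active", "inactive")
  )
  expect_error(label_activity(100, t_active = 1000, t_inactive = 500), "smaller")
})

test_that("the seven sets assemble with the documented memberships", {
  # selective example: active at target, inactive at antitarget
  records <- dplyr::bind_rows(
    rec("sel", "R2B", 50), rec("sel", "R1B", 5000),
    rec("non", "R2B", 100), rec("non", "R1B", 200),
    rec("inv", "R1B", 30), rec("inv", "R2B", 8000),
    rec("single", "R2B", 10)
  )
  sets <- build_sets(records, molecules = NULL, target = "R2B", antitarget = "R1B")
  member <- function(s) sets$compound_id[sets$set == s]
  expect_setequal(member("2B_active"), c("sel", "non", "single"))
  expect_setequal(member("1B_inactive"), "sel")
  expect_setequal(member("2B_selective"), "sel")
  expect_setequal(member("nonselective"), "non")
  expect_setequal(member("1B_selective"), "inv")
  expect_false("single" %in% member("2B_selective"))
})

test_that("the heavy-atom floor removes small compounds from every set", {
  lib <- tibble::tibble(
    id = c("big", "small"),
    mol = list(
      smiles_to_molecule(strrep("C", 25), id = "big"),
      smiles_to_molecule(strrep("C", 21), id = "small")
    )
  )
  lib$heavy_atoms <- vapply(lib$mol, heavy_atom_count, integer(1))
  records <- dplyr::bind_rows(
    rec("big", "R2B", 1), rec("big", "R1B", 9000),
    rec("small", "R2B", 1), rec("small", "R1B", 9000)
  )
  sets <- build_sets(records, lib, target = "R2B", antitarget = "R1B")
  expect_false("small" %in% sets$compound_id)
  expect_true("big" %in% sets$compound_id)
  expect_error(
    build_sets(dplyr::bind_rows(records, rec("ghost", "R2B", 1), rec("ghost", "R1B", 1)),
      lib,
      target = "R2B", antitarget = "R1B"
    ),
    "not resolvable"
  )
})

test_that("replicates aggregate by geometric mean and conflicts drop out", {
  # geometric mean of 100 and 2500 is 500 -> active (boundary inclusive)
  records <- dplyr::bind_rows(
    rec("gm", "R2B", 100), rec("gm", "R2B", 2500),
    rec("gm", "R1B", 9000)
  )
  expect_message(
    sets <- build_sets(records, NULL, target = "R2B", antitarget = "R1B"),
    "conflicting"
  )
  # both active-side and inactive-side evidence at R2B: dropped (conservative)
  expect_false("gm" %in% sets$compound_id)

  records2 <- dplyr::bind_rows(
    rec("gm2", "R2B", 100), rec("gm2", "R2B", 400),
    rec("gm2", "R1B", 9000)
  )
  sets2 <- build_sets(records2, NULL, target = "R2B", antitarget = "R1B")
  expect_true("gm2" %in% sets2$compound_id[sets2$set == "2B_active"])
})

test_that("set construction is order-independent and idempotent", {
  cfg <- generator_config(seed = 3, n_molecules = 60)
  lib <- generate_library(cfg)
  records <- generate_activity_table(lib, cfg)
  s1 <- build_sets(records, NULL, target = "R2B", antitarget = "R1B")
  s2 <- build_sets(records[sample(nrow(records)), ], NULL,
    target = "R2B", antitarget = "R1B"
  )
  expect_equal(
    dplyr::arrange(s1, set, compound_id),
    dplyr::arrange(s2, set, compound_id),
    ignore_attr = TRUE
  )
  expect_equal(attr(s1, "counts"), attr(s2, "counts"))
})

test_that("noise-free synthetic tables recover the planted sets exactly", {
  cfg <- generator_config(seed = 9, n_molecules = 80, noise = 0)
  lib <- generate_library(cfg)
  records <- generate_activity_table(lib, cfg)
  sets <- build_sets(records, NULL, target = "R2B", antitarget = "R1B")
  member <- function(s) sort(sets$compound_id[sets$set == s])
  expect_equal(member("2B_active"), sort(lib$id[lib$motif1]))
  expect_equal(member("2B_selective"), sort(lib$id[lib$motif1 & !lib$motif2]))
  expect_equal(member("nonselective"), sort(lib$id[lib$motif1 & lib$motif2]))
  expect_equal(member("1B_selective"), sort(lib$id[lib$motif2 & !lib$motif1]))
})

test_that("set files and manifest are written", {
  cfg <- generator_config(seed = 3, n_molecules = 40, noise = 0)
  lib <- generate_library(cfg)
  sets <- build_sets(generate_activity_table(lib, cfg), NULL,
    target = "R2B", antitarget = "R1B"
  )
  dir <- withr::local_tempdir()
  write_sets(sets, dir)
  expect_true(file.exists(file.path(dir, "2B_selective.ids")))
  manifest <- jsonlite::fromJSON(file.path(dir, "sets_manifest.json"))
  expect_equal(manifest$counts$`2B_active`, unname(attr(sets, "counts")["2B_active"]))
})
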