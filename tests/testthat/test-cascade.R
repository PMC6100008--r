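stub_model <- function(pass_ids) {
  structure(list(pass_ids = pass_ids), class = "stub_model")
}
# predict method for stubs: fingerprints are tagged with their compound id
predict.stub_model <- function(object, newdata, ...) {
  vapply(newdata, function(fp) attr(fp, "cid") %in% object$pass_ids, logical(1))
}
.S3method("predict", "stub_model", predict.stub_model)

test_that("each cascade stage passes exactly one flag combination", {
  combos <- expand.grid(t = c(TRUE, FALSE), a = c(TRUE, FALSE))
  s1 <- stage1(combos$t, combos$a)
  s2 <- stage2(combos$t, combos$a)
  expect_equal(sum(s1 == "stage1_selective"), 1)
  expect_equal(sum(s2 == "stage2_selective"), 1)
  expect_equal(s1[combos$t & !combos$a], "stage1_selective")
  expect_equal(s2[combos$t & !combos$a], "stage2_selective")
  expect_true(all(s1[!(combos$t & !combos$a)] == "rejected_stage1"))
  expect_true(all(s2[!(combos$t & !combos$a)] == "rejected_stage2"))
})

test_that("screening a library yields the constructed funnel counts", {
  cfg <- generator_config(seed = 21, n_molecules = 10)
  lib <- generate_library(cfg)
  keys <- demo_keys()
  # stub models pass 3 compounds at stage 1, of which 2 survive stage 2
  s1_ids <- lib$id[1:3]
  s2_ids <- lib$id[1:2]
  models <- list(
    a_target = stub_model(s1_ids),
    a_antitarget = stub_model(character(0)),
    s_target = stub_model(s2_ids),
    s_antitarget = stub_model(character(0))
  )
  # tag fingerprints with compound ids via a wrapper keyset-compatible call
  with_mocked_bindings(
    nsfp_fingerprint = function(mol, keys, ...) {
      structure(integer(0),
        keyset_name = attr(keys, "keyset_name"), order = "2",
        cid = mol$id, class = "nsfp_fingerprint"
      )
    },
    {
      decisions <- suppressWarnings(suppressMessages(
        screen_database(lib, models, keys)
      ))
      expect_equal(unname(attr(decisions, "funnel")), c(10L, 3L, 2L))
      expect_equal(sum(decisions$verdict == "stage2_selective"), 2)
      expect_true(all(is.na(decisions$s_target[decisions$verdict == "rejected_stage1"])))
    }
  )
})

test_that("empty input yields an empty decision table with zero counts", {
  lib <- generate_library(generator_config(seed = 1, n_molecules = 0))
  models <- list(
    a_target = stub_model("x"), a_antitarget = stub_model("x"),
    s_target = stub_model("x"), s_antitarget = stub_model("x")
  )
  decisions <- screen_database(lib, models, demo_keys())
  expect_equal(nrow(decisions), 0)
  expect_equal(unname(attr(decisions, "funnel")), c(0L, 0L, 0L))
})

test_that("verdict counts are monotone along the funnel", {
  cfg <- generator_config(seed = 22, n_molecules = 40)
  lib <- generate_library(cfg)
  records <- generate_activity_table(lib, cfg)
  sets <- build_sets(records, NULL, target = "R2B", antitarget = "R1B")
  keys <- demo_keys()
  fps <- purrr::map(lib$mol, nsfp_fingerprint, keys = keys)
  names(fps) <- lib$id
  pick <- function(s) fps[intersect(sets$compound_id[sets$set == s], names(fps))]
  spec <- classifier_spec("naive_bayes", alpha = 1)
  models <- list(
    a_target = train_classifier(spec, pick("2B_active"), pick("2B_inactive")),
    a_antitarget = train_classifier(spec, pick("1B_active"), pick("1B_inactive")),
    s_target = train_classifier(spec, pick("2B_selective"), pick("nonselective")),
    s_antitarget = train_classifier(spec, pick("1B_selective"), pick("nonselective"))
  )
  decisions <- suppressMessages(screen_database(lib, models, keys))
  funnel <- attr(decisions, "funnel")
  expect_lte(funnel["stage2"], funnel["stage1"])
  expect_lte(funnel["stage1"], funnel["input"])
})

test_that("swapping target and antitarget roles mirrors the verdicts", {
  cfg <- generator_config(seed = 23, n_molecules = 12)
  lib <- generate_library(cfg)
  keys <- demo_keys()
  ids_a <- lib$id[1:4]
  ids_b <- lib$id[5:8]
  fwd <- list(
    a_target = stub_model(ids_a), a_antitarget = stub_model(ids_b),
    s_target = stub_model(ids_a), s_antitarget = stub_model(ids_b)
  )
  rev <- list(
    a_target = stub_model(ids_b), a_antitarget = stub_model(ids_a),
    s_target = stub_model(ids_b), s_antitarget = stub_model(ids_a)
  )
  with_mocked_bindings(
    nsfp_fingerprint = function(mol, keys, ...) {
      structure(integer(0),
        keyset_name = attr(keys, "keyset_name"), order = "2",
        cid = mol$id, class = "nsfp_fingerprint"
      )
    },
    {
      d_fwd <- suppressWarnings(suppressMessages(screen_database(lib, fwd, keys)))
      d_rev <- suppressWarnings(suppressMessages(screen_database(lib, rev, keys)))
      expect_setequal(
        d_fwd$compound_id[d_fwd$verdict == "stage2_selective"], ids_a
      )
      expect_setequal(
        d_rev$compound_id[d_rev$verdict == "stage2_selective"], ids_b
      )
    }
  )
})

test_that("a keyset mismatch between models and keys is fatal", {
  cfg <- generator_config(seed = 24, n_molecules = 6)
  lib <- generate_library(cfg)
  keys <- demo_keys()
  other <- make_keyset("[OX2H]", "KO", name = "other")
  fp_other <- purrr::map(lib$mol[1:3], nsfp_fingerprint, keys = other)
  model <- train_classifier(
    classifier_spec("naive_bayes"),
    fp_other[1:2], fp_other[3]
  )
  models <- list(
    a_target = model, a_antitarget = model,
    s_target = model, s_antitarget = model
  )
  expect_error(screen_database(lib, models, keys), "key set")
})
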