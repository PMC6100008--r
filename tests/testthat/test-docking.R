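test_that("the distance criterion is boundary-inclusive at 5.0 A", {
  ps <- generate_pose_set("boundary_5A", seed = 7)
  spec <- ps$specs$T2B
  sbp <- "M218^5.39"
  sat <- lapply(seq_len(nrow(ps$poses)), function(i) {
    detect_interactions(ps$poses[i, ], spec)
  })
  expect_true(sbp %in% sat[[1]]) # 4.9 A
  expect_true(sbp %in% sat[[2]]) # exactly 5.0 A: inclusive
  expect_false(sbp %in% sat[[3]]) # 5.1 A
})

test_that("hydrogen bonds and salt bridges follow their geometric cutoffs", {
  spec <- nsfpscreen:::toy_receptor("T2B", "target")
  asp <- "D135^3.32"
  pose_at <- function(d) nsfpscreen:::probe_pose("c", "T2B", 1L, -9, asp_d = d)
  expect_true(asp %in% detect_interactions(pose_at(3.4)[1, ], spec)) # hbond
  expect_true(asp %in% detect_interactions(pose_at(3.8)[1, ], spec)) # salt bridge
  expect_false(asp %in% detect_interactions(pose_at(4.2)[1, ], spec)) # beyond both
})

test_that("a neutral donor nitrogen forms hydrogen bonds but no salt bridge", {
  spec <- nsfpscreen:::toy_receptor("T2B", "target")
  pose <- nsfpscreen:::probe_pose("c", "T2B", 1L, -9, asp_d = 3.8)
  pose$atoms[[1]]$charge[1] <- 0L # de-protonate: 3.8 A is now too far
  expect_false("D135^3.32" %in% detect_interactions(pose[1, ], spec))
})

test_that("missing residue coordinates are fatal and named", {
  crit <- tibble::tibble(
    residue = "D135^3.32", site = "OBP", criterion = "hbond",
    threshold = NA_real_
  )
  atoms <- tibble::tibble(
    residue = "OTHER", atom = "O", element = "O",
    x = 0, y = 0, z = 0, donor = FALSE, acceptor = TRUE,
    carboxylate_o = FALSE
  )
  expect_error(receptor_spec("X", "target", crit, atoms), "D135")
})

test_that("pose filtering implements both modes over the packaged scenarios", {
  for (scen in c("asp_only", "boundary_5A", "water_rescue")) {
    ps <- generate_pose_set(scen, seed = 7)
    spec <- ps$specs$T2B
    kept_strict <- pose_filter(ps$poses, spec, mode = "obp_and_sbp")
    kept_water <- pose_filter(ps$poses, spec, mode = "asp_or_water")
    expect_setequal(
      kept_strict$compound_id,
      ps$expected$compound_id[ps$expected$pass_obp_and_sbp]
    )
    expect_setequal(
      kept_water$compound_id,
      ps$expected$compound_id[ps$expected$pass_asp_or_water]
    )
  }
})

test_that("strict filtering is a subset of the aspartate-only relaxation", {
  for (scen in c("asp_only", "boundary_5A", "water_rescue", "planted_selectives_10")) {
    ps <- generate_pose_set(scen, seed = 7)
    spec <- ps$specs$T2B
    poses <- ps$poses[ps$poses$receptor_id == "T2B", ]
    strict <- pose_filter(poses, spec, mode = "obp_and_sbp")
    asp_only_pass <- poses$compound_id[vapply(seq_len(nrow(poses)), function(i) {
      "D135^3.32" %in% detect_interactions(poses[i, ], spec)
    }, logical(1))]
    expect_true(all(strict$compound_id %in% asp_only_pass))
  }
})

test_that("interaction detection is invariant under rigid motion", {
  ps <- generate_pose_set("boundary_5A", seed = 7)
  spec <- ps$specs$T2B
  base <- lapply(seq_len(nrow(ps$poses)), function(i) {
    detect_interactions(ps$poses[i, ], spec)
  })
  # rotate everything jointly by a fixed rotation + translation
  theta <- 0.73
  rot <- matrix(c(
    cos(theta), -sin(theta), 0,
    sin(theta), cos(theta), 0,
    0, 0, 1
  ), 3, 3, byrow = TRUE)
  shift <- c(11.2, -3.4, 5.6)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  spec2 <- spec
  spec2$atoms <- move(spec$atoms)
  poses2 <- ps$poses
  poses2$atoms <- lapply(poses2$atoms, move)
  for (i in seq_len(nrow(poses2))) {
    expect_equal(detect_interactions(poses2[i, ], spec2), base[[i]])
  }
})

test_that("compound ranking uses best pose score with lexicographic ties", {
  poses <- tibble::tibble(
    compound_id = c("A", "A", "B", "C"),
    receptor_id = "R1",
    pose_index = c(1L, 2L, 1L, 1L),
    score = c(-9.2, -8.0, -7.1, -8.0)
  )
  ranks <- rank_compounds(poses)
  expect_equal(ranks$compound_id[ranks$rank], c("A", "C", "B"))
  # tie at -8.0 between A(-9.2 best kept) and C: A already rank 1; C beats B
  expect_equal(ranks$rank[ranks$compound_id == "C"], 2L)
  tie <- rank_compounds(tibble::tibble(
    compound_id = c("B", "A"), receptor_id = "R", pose_index = 1L,
    score = c(-8, -8)
  ))
  expect_equal(tie$rank[tie$compound_id == "A"], 1L)
})

test_that("pose SDF input round-trips scores, ids and donor flags", {
  sdf <- c(
    "lig1_pose1", "  synthetic", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  0",
    "    1.4000    0.0000    0.0000 C   0  0",
    "    2.1000    1.2000    0.0000 O   0  0",
    "  1  2  1  0", "  2  3  2  0",
    "M  CHG  1   1   1",
    "M  END",
    "> <r_i_docking_score>", "-9.25", "",
    "$$$$",
    "lig1_pose2", "  synthetic", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "M  END",
    "> <r_i_docking_score>", "-8.5", "",
    "$$$$"
  )
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  poses <- read_poses_sdf(f, "T2B")
  expect_equal(nrow(poses), 2)
  expect_equal(poses$compound_id, c("lig1", "lig1"))
  expect_equal(poses$pose_index, c(1L, 2L))
  expect_equal(poses$score, c(-9.25, -8.5))
  a <- poses$atoms[[1]]
  expect_equal(a$charge[1], 1L)
  expect_true(a$donor[1]) # charged N
  expect_true(a$acceptor[3]) # carbonyl O
  expect_error(read_poses_sdf(f, "T2B", score_property = "nope"), "score property")
})

test_that("receptor YAML plus PDB subset load into annotated specs", {
  skip_if_not_installed("bio3d")
  dir <- withr::local_tempdir()
  pdb <- c(
    "ATOM      1  N   ASP A 135      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  OD1 ASP A 135       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  OD2 ASP A 135       1.000   0.800   0.000  1.00  0.00           O",
    "ATOM      4  SD  MET A 218       8.000   0.000   0.000  1.00  0.00           S",
    "HETATM    5  O   HOH A2004       3.000   3.000   0.000  1.00  0.00           O",
    "END"
  )
  writeLines(pdb, file.path(dir, "rec.pdb"))
  yml <- c(
    "receptors:",
    "  - receptor_id: T2B",
    "    role: target",
    "    pdb: rec.pdb",
    "    criteria:",
    "      - {residue: 'D135^3.32', site: OBP, criterion: hbond_or_salt_bridge, resno: 135}",
    "      - {residue: 'M218^5.39', site: SBP, criterion: distance, threshold: 5.0, resno: 218}",
    "      - {residue: 'HOH2004', site: water, criterion: hbond, resno: 2004}"
  )
  writeLines(yml, file.path(dir, "receptors.yaml"))
  specs <- load_receptor_specs(file.path(dir, "receptors.yaml"))
  spec <- specs$T2B
  expect_s3_class(spec, "receptor_spec")
  expect_true(all(spec$atoms$carboxylate_o[spec$atoms$atom %in% c("OD1", "OD2")]))
  expect_true(spec$atoms$donor[spec$atoms$atom == "N"])
  water <- spec$atoms[spec$atoms$residue == "HOH2004", ]
  expect_true(water$donor && water$acceptor)
  # the loaded spec behaves like the in-code toy receptor
  pose <- nsfpscreen:::probe_pose("c", "T2B", 1L, -9, asp_d = 2.8, sbp_d = 4.0)
  sat <- detect_interactions(pose[1, ], spec)
  expect_true(all(c("D135^3.32", "M218^5.39") %in% sat))
})
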