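test_that("delta_max reproduces the rank-sum difference and strict selection", {
  ranks <- tibble::tibble(
    receptor_id = c("4IB4", "4NC3", "4IAQ", "4IAR"),
    compound_id = "cmpd",
    rank = c(2L, 3L, 10L, 12L)
  )
  out <- delta_max(ranks, c("4IB4", "4NC3"), c("4IAQ", "4IAR"))
  expect_equal(out$delta_max, -17)
  expect_true(out$selected)

  even <- tibble::tibble(
    receptor_id = c("T", "A"), compound_id = "c", rank = c(4L, 4L)
  )
  out2 <- delta_max(even, "T", "A")
  expect_equal(out2$delta_max, 0)
  expect_false(out2$selected) # strict inequality at the boundary

  expect_error(delta_max(ranks, character(0), "4IAQ"), "non-empty")
})

test_that("delta_max negates under target/antitarget swap", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    ids <- sprintf("c%02d", seq_len(n))
    ranks <- dplyr::bind_rows(lapply(c("T1", "T2", "A1", "A2"), function(r) {
      tibble::tibble(receptor_id = r, compound_id = ids, rank = sample(n))
    }))
    fwd <- delta_max(ranks, c("T1", "T2"), c("A1", "A2"))
    rev <- delta_max(ranks, c("A1", "A2"), c("T1", "T2"))
    expect_equal(
      fwd$delta_max[order(fwd$compound_id)],
      -rev$delta_max[order(rev$compound_id)]
    )
  }
})

test_that("compounds missing a rank at any receptor are excluded with a note", {
  ranks <- tibble::tibble(
    receptor_id = c("T", "T", "A"),
    compound_id = c("a", "b", "a"),
    rank = c(1L, 2L, 1L)
  )
  expect_message(out <- delta_max(ranks, "T", "A"), "excluded")
  expect_equal(out$compound_id, "a")
  expect_equal(attr(out, "excluded"), "b")
})

test_that("top-fraction selection floors and validates", {
  big <- tibble::tibble(
    compound_id = sprintf("c%03d", 1:181),
    delta_max = sort(stats::rnorm(181)) - 10,
    selected = TRUE
  )
  expect_equal(nrow(select_top_fraction(big, 0.10)), 18)
  small <- big[1:10, ]
  expect_equal(nrow(select_top_fraction(small, 0.10)), 1)
  expect_equal(nrow(select_top_fraction(big[1:5, ], 1.0)), 5)
  expect_error(select_top_fraction(big, 0), "fraction")
  expect_error(select_top_fraction(big, 1.5), "fraction")
  shuffled <- big[sample(181), ]
  expect_error(select_top_fraction(shuffled, 0.1), "sorted")
})

test_that("diversity selection collapses similars and keeps distant groups", {
  # identical fingerprints: one centroid regardless of n_out
  same <- lapply(1:8, function(i) c("a|b", "c|d"))
  out <- diversity_select(sprintf("c%d", 1:8), same, n_out = 50)
  expect_equal(attr(out, "centroids"), "c1")
  expect_true(all(out$cluster == 1))

  # two far-apart groups (zero cross-similarity, verified by brute force)
  g1 <- lapply(1:4, function(i) c("a1", "a2", "a3", sprintf("g1f%d", i)))
  g2 <- lapply(1:4, function(i) c("x1", "x2", "x3", sprintf("g2f%d", i)))
  cross <- outer(seq_along(g1), seq_along(g2), Vectorize(function(i, j) {
    tanimoto_kernel(g1[[i]], g2[[j]])
  }))
  expect_true(all(cross < 0.6))
  out2 <- diversity_select(sprintf("c%d", 1:8), c(g1, g2),
    n_out = 50,
    sim_threshold = 0.6
  )
  expect_length(attr(out2, "centroids"), 2)

  # n_out caps the returned leaders
  distinct <- lapply(1:6, function(i) sprintf("only%d", i))
  out3 <- diversity_select(sprintf("c%d", 1:6), distinct, n_out = 3)
  expect_length(attr(out3, "centroids"), 3)
  out4 <- diversity_select(character(0), list(), n_out = 5)
  expect_equal(nrow(out4), 0)
})

test_that("the planted-selectives scenario yields the intended consensus head", {
  ps <- generate_pose_set("planted_selectives_10", seed = 7)
  surviving <- dplyr::bind_rows(lapply(names(ps$specs), function(rid) {
    pose_filter(
      ps$poses[ps$poses$receptor_id == rid, ],
      ps$specs[[rid]], "obp_and_sbp"
    )
  }))
  ranks <- rank_compounds(surviving)
  cons <- delta_max(ranks, "T2B", "T1B")
  expect_setequal(utils::head(cons$compound_id, 10), ps$expected$planted_ids)
  expect_true(all(utils::head(cons$selected, 10)))
})
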