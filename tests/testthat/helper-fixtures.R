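# Shared fixtures and independent oracles.

fixture_molecules <- function() {
  path <- test_path("fixtures", "fixture_molecules.smi")
  lines <- readLines(path)
  parts <- do.call(rbind, strsplit(lines, " "))
  tibble::tibble(name = parts[, 2], smiles = parts[, 1])
}

demo_keys <- function() load_keyset(demo_keyset_path())

# Small random molecules (<= 14 heavy atoms) assembled from tiny fragments;
# every string the grammar emits is parseable by construction.
random_small_smiles <- function(n, seed) {
  frags <- c("C", "N", "O", "CC", "CO", "CN", "C(=O)", "c1ccccc1", "C=C", "C#N")
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    paste(sample(frags, k, replace = TRUE, prob = c(3, 2, 2, 2, 1, 1, 1, 1, 1, 1)),
      collapse = ""
    )
  }, character(1))
}

# Ten-key set used by the fingerprint oracle checks.
oracle_keyset <- function() {
  make_keyset(
    c(
      "[OX2H]", "[NX3;H2]", "[NX3;H1]", "c1ccccc1", "[CX3]=[OX1]",
      "[CX4H3]", "[CX2]#[NX1]", "[CX3]=[CX3]", "[OX2H0]", "[CX4H2]"
    ),
    name = "oracle10"
  )
}

# Independent brute-force NSFP: enumerates every match pair/triple and tests
# adjacency with its own breadth-first-search distances (no igraph, no
# match_adjacency). Returns a named count vector comparable to
# nsfp_fingerprint output.
brute_force_nsfp <- function(mol, keys, order = "2", mode = "bonded", d = 1L) {
  matches <- match_keys(mol, keys)
  m <- nrow(matches)
  if (m < 2) {
    return(integer(0))
  }
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]
    b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs_dist <- function(src) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    dist
  }
  dmat <- t(vapply(seq_len(n), bfs_dist, numeric(n)))
  limit <- switch(mode, overlap = 0, bonded = 1, path = d)
  set_dist <- function(i, j) {
    min(dmat[matches$atom_set[[i]], matches$atom_set[[j]]])
  }
  near <- function(i, j) set_dist(i, j) <= limit
  feats <- character(0)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (near(i, j)) {
        feats <- c(feats, paste(sort(c(
          matches$key_id[i],
          matches$key_id[j]
        )), collapse = "|"))
      }
    }
  }
  if (order == "2+3" && m >= 3) {
    for (i in seq_len(m - 2)) {
      for (j in (i + 1):(m - 1)) {
        for (k in (j + 1):m) {
          edges <- near(i, j) + near(i, k) + near(j, k)
          if (edges >= 2) {
            feats <- c(feats, paste(sort(c(
              matches$key_id[i], matches$key_id[j], matches$key_id[k]
            )), collapse = "|"))
          }
        }
      }
    }
  }
  if (length(feats) == 0) {
    return(integer(0))
  }
  tab <- table(feats)
  stats::setNames(as.integer(tab), names(tab))
}

fp_as_named_int <- function(fp) {
  if (length(fp) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  out <- stats::setNames(as.integer(fp), names(fp))
  out[order(names(out))]
}

# Deterministic random fingerprints over a toy vocabulary.
random_bitviews <- function(n, seed, vocab_size = 40, mean_bits = 8) {
  set.seed(seed)
  vocab <- sprintf("f%02d", seq_len(vocab_size))
  lapply(seq_len(n), function(i) {
    sample(vocab, min(vocab_size, 1 + stats::rpois(1, mean_bits)))
  })
}
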