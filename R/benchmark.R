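#' Assemble the seeded synthetic selectivity benchmark
#'
#' The standard end-to-end validation problem: a synthetic library whose
#' target activity is planted on an NSFP-visible motif, an affinity table
#' with 5% label noise, and balanced 400/400 positive/negative classes for
#' the target-activity classification task. Fingerprints use the packaged
#' demo key set with default (bonded doublet) settings.
#'
#' @param seed Integer seed (default 7, the reference benchmark).
#' @param n_per_class Examples per activity class (default 400).
#' @param noise Label-flip rate (default 0.05).
#' @return List: `lib` (the selected molecules with motif truth and a
#'   `fingerprint` column), `records` (their affinity table), `pos`/`neg`
#'   (fingerprint lists for the target-activity task, noisy labels),
#'   `planted_selective` (ids with motif 1 and not motif 2 -- the true
#'   target-selectives), `keys`.
#' @export
synthetic_benchmark <- function(seed = 7L, n_per_class = 400L, noise = 0.05) {
  cfg <- generator_config(
    seed = seed, n_molecules = 4L * n_per_class,
    noise = noise
  )
  lib <- generate_library(cfg)
  records <- generate_activity_table(lib, cfg)
  truth <- attr(records, "truth")
  lab <- truth$active_R2B[match(lib$id, truth$compound_id)]
  pos_ids <- lib$id[lab][seq_len(n_per_class)]
  neg_ids <- lib$id[!lab][seq_len(n_per_class)]
  if (anyNA(c(pos_ids, neg_ids))) {
    stop("library too small for ", n_per_class, " examples per class",
      call. = FALSE
    )
  }
  keep <- lib$id %in% c(pos_ids, neg_ids)
  lib <- lib[keep, , drop = FALSE]
  records <- records[records$compound_id %in% lib$id, , drop = FALSE]
  attr(records, "truth") <- truth[truth$compound_id %in% lib$id, , drop = FALSE]
  keys <- load_keyset(demo_keyset_path())
  lib <- nsfp_fingerprints(lib, keys)
  fps <- stats::setNames(lib$fingerprint, lib$id)
  list(
    lib = lib,
    records = records,
    pos = fps[pos_ids],
    neg = fps[neg_ids],
    planted_selective = lib$id[lib$motif1 & !lib$motif2],
    keys = keys
  )
}
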