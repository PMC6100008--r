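# Two-stage prospective classification cascade: an activity stage (target
# model positive AND antitarget model negative) followed by a selectivity
# stage (target-selectivity model positive AND antitarget-selectivity model
# negative). Every other flag combination is rejected at its stage.

#' Stage-1 (activity) cascade rule
#'
#' A compound passes iff it is classified active at the target and inactive
#' at the antitarget; any other combination is rejected.
#'
#' @param a_target,a_antitarget Logical vectors of activity-model calls.
#' @return Character vector: `"stage1_selective"` or `"rejected_stage1"`.
#' @export
stage1 <- function(a_target, a_antitarget) {
  ifelse(a_target & !a_antitarget, "stage1_selective", "rejected_stage1")
}

#' Stage-2 (selectivity) cascade rule
#'
#' Applied to stage-1 survivors: pass iff the target-selectivity model is
#' positive and the antitarget-selectivity model negative.
#'
#' @param s_target,s_antitarget Logical vectors of selectivity-model calls.
#' @return Character vector: `"stage2_selective"` or `"rejected_stage2"`.
#' @export
stage2 <- function(s_target, s_antitarget) {
  ifelse(s_target & !s_antitarget, "stage2_selective", "rejected_stage2")
}

#' Screen a molecule library through the four-model cascade
#'
#' Fingerprints are computed once per molecule and shared across the four
#' models. Stage-2 models are only consulted for stage-1 survivors, matching
#' the funnel: a compound's verdict is `rejected_stage1`,
#' `rejected_stage2`, or `stage2_selective`.
#'
#' @param mol_tbl Molecule tibble from [parse_molecules()] or
#'   [generate_library()].
#' @param models Named list with elements `a_target`, `a_antitarget`,
#'   `s_target`, `s_antitarget`, each a `trained_classifier` (or any object
#'   with a compatible [predict()] method) trained on fingerprints over
#'   `keys`.
#' @param keys The `nsfp_keyset` shared by all four models.
#' @param fingerprints Optional list of precomputed `nsfp_fingerprint`s
#'   aligned with `mol_tbl` rows (e.g. a `fingerprint` column from
#'   [nsfp_fingerprints()]); computed from `mol_tbl$mol` when `NULL`.
#' @param ... Fingerprint options passed to [nsfp_fingerprint()].
#' @return A tibble: `compound_id`, the four flags (`NA` where a stage was
#'   not reached), `verdict`. Funnel counts (input, stage-1 pass, stage-2
#'   pass) are attached as attribute `funnel` and reported in a message.
#' @export
screen_database <- function(mol_tbl, models, keys, fingerprints = NULL, ...) {
  need <- c("a_target", "a_antitarget", "s_target", "s_antitarget")
  if (!all(need %in% names(models))) {
    stop("models must be named ", paste(need, collapse = ", "), call. = FALSE)
  }
  ks_name <- attr(keys, "keyset_name")
  for (nm in need) {
    mdl <- models[[nm]]
    if (inherits(mdl, "trained_classifier") && !is.null(mdl$keyset_name) &&
      !identical(mdl$keyset_name, ks_name)) {
      stop("model '", nm, "' was trained on key set '", mdl$keyset_name,
        "', not '", ks_name, "'",
        call. = FALSE
      )
    }
  }
  n <- nrow(mol_tbl)
  if (n == 0) {
    out <- tibble::tibble(
      compound_id = character(0), a_target = logical(0),
      a_antitarget = logical(0), s_target = logical(0),
      s_antitarget = logical(0), verdict = character(0)
    )
    attr(out, "funnel") <- c(input = 0L, stage1 = 0L, stage2 = 0L)
    return(out)
  }
  fps <- fingerprints %||% purrr::map(mol_tbl$mol, nsfp_fingerprint, keys = keys, ...)
  stopifnot(length(fps) == n)
  empty_fp <- vapply(fps, length, integer(1)) == 0
  if (any(empty_fp)) {
    warning(sum(empty_fp), " molecule(s) have an empty fingerprint and are ",
      "classified on the all-absent feature vector",
      call. = FALSE
    )
  }
  a_t <- predict(models$a_target, fps)
  a_a <- predict(models$a_antitarget, fps)
  v1 <- stage1(a_t, a_a)
  pass1 <- v1 == "stage1_selective"
  s_t <- rep(NA, n)
  s_a <- rep(NA, n)
  verdict <- v1
  if (any(pass1)) {
    s_t[pass1] <- predict(models$s_target, fps[pass1])
    s_a[pass1] <- predict(models$s_antitarget, fps[pass1])
    verdict[pass1] <- stage2(s_t[pass1], s_a[pass1])
  }
  out <- tibble::tibble(
    compound_id = mol_tbl$id,
    a_target = a_t, a_antitarget = a_a,
    s_target = as.logical(s_t), s_antitarget = as.logical(s_a),
    verdict = verdict
  )
  funnel <- c(
    input = n, stage1 = sum(pass1),
    stage2 = sum(verdict == "stage2_selective")
  )
  attr(out, "funnel") <- funnel
  message(
    "cascade: ", funnel["input"], " in, ", funnel["stage1"],
    " passed stage 1, ", funnel["stage2"], " passed stage 2"
  )
  out
}
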