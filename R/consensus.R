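# Docking post-processing, part 2: per-receptor compound ranking from
# docking scores, rank-difference consensus (delta-max) across target and
# antitarget structures, top-fraction selection and leader-clustering
# diversity selection.

#' Rank compounds per receptor from surviving poses
#'
#' A compound's score at a receptor is its best (minimum, docking-score
#' convention) surviving pose score; compounds are ranked ascending so rank
#' 1 is the best score. Score ties break lexicographically by compound id
#' (deterministic).
#'
#' @param poses Pose tibble (typically [pose_filter()] output) with
#'   `compound_id`, `receptor_id`, `score`.
#' @return Rank tibble: `receptor_id`, `compound_id`, `score`, `rank`;
#'   ranks form a permutation of `1..n` within each receptor.
#' @export
rank_compounds <- function(poses) {
  poses |>
    dplyr::group_by(.data$receptor_id, .data$compound_id) |>
    dplyr::summarise(score = min(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$receptor_id) |>
    dplyr::arrange(.data$score, .data$compound_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Rank-difference consensus selectivity score
#'
#' For every compound ranked at all listed receptors,
#' `delta_max = sum(ranks at target receptors) - sum(ranks at antitarget
#' receptors)`. Because better docking scores earn numerically lower ranks,
#' a compound is called target-selective iff `delta_max < 0` (strict);
#' output is sorted ascending so the most target-selective compounds come
#' first. Compounds missing a rank at any listed receptor are excluded and
#' reported in attribute `excluded`.
#'
#' @param ranks Rank tibble from [rank_compounds()].
#' @param target_receptors,antitarget_receptors Non-empty character vectors
#'   of receptor ids.
#' @return Consensus tibble: `compound_id`, `delta_max`, `selected`.
#' @examples
#' ranks <- tibble::tibble(
#'   receptor_id = c("4IB4", "4NC3", "4IAQ", "4IAR"),
#'   compound_id = "cmpd", rank = c(2, 3, 10, 12)
#' )
#' delta_max(ranks, c("4IB4", "4NC3"), c("4IAQ", "4IAR")) # delta_max -17
#' @export
delta_max <- function(ranks, target_receptors, antitarget_receptors) {
  if (length(target_receptors) == 0 || length(antitarget_receptors) == 0) {
    stop("receptor sets must be non-empty", call. = FALSE)
  }
  all_rec <- c(target_receptors, antitarget_receptors)
  missing_rec <- setdiff(all_rec, unique(ranks$receptor_id))
  if (length(missing_rec) > 0) {
    stop("no ranks for receptor(s): ", paste(missing_rec, collapse = ", "),
      call. = FALSE
    )
  }
  wide <- ranks |>
    dplyr::filter(.data$receptor_id %in% all_rec) |>
    dplyr::select("compound_id", "receptor_id", "rank") |>
    tidyr::pivot_wider(names_from = "receptor_id", values_from = "rank")
  complete <- stats::complete.cases(wide[all_rec])
  excluded <- wide$compound_id[!complete]
  if (length(excluded) > 0) {
    message(
      length(excluded), " compound(s) lack ranks at some receptor and ",
      "are excluded from the consensus"
    )
  }
  wide <- wide[complete, , drop = FALSE]
  out <- tibble::tibble(
    compound_id = wide$compound_id,
    delta_max = rowSums(wide[, target_receptors, drop = FALSE]) -
      rowSums(wide[, antitarget_receptors, drop = FALSE])
  ) |>
    dplyr::mutate(selected = .data$delta_max < 0) |>
    dplyr::arrange(.data$delta_max, .data$compound_id)
  attr(out, "excluded") <- excluded
  out
}

#' Keep the top fraction of a sorted consensus list
#'
#' Takes the first `floor(n * fraction)` entries of a consensus table
#' already sorted ascending by `delta_max` (a ranked list of 181 compounds
#' at the conventional 10% cut keeps 18).
#'
#' @param consensus Consensus tibble sorted ascending by `delta_max`.
#' @param fraction Fraction in (0, 1\].
#' @return The retained head of `consensus`.
#' @export
select_top_fraction <- function(consensus, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(consensus$delta_max)) {
    stop("consensus must be sorted ascending by delta_max", call. = FALSE)
  }
  utils::head(consensus, floor(nrow(consensus) * fraction))
}

#' Diversity selection by sphere-exclusion (leader) clustering
#'
#' Compounds are processed in the given order (ascending delta-max when fed
#' from [delta_max()], making selection deterministic); a compound whose
#' Tanimoto similarity to every existing leader is below the threshold
#' founds a new cluster, others join the nearest leader. The first `n_out`
#' leaders (cluster centroids) are returned.
#'
#' @param compound_ids Character vector, in processing order.
#' @param fingerprints List of fingerprints/bit views aligned with
#'   `compound_ids`.
#' @param n_out Number of centroids wanted (all leaders if fewer exist).
#' @param sim_threshold Tanimoto similarity at or above which a compound
#'   joins an existing cluster (default 0.6).
#' @return Tibble `compound_id`, `cluster`, `is_centroid`; attribute
#'   `centroids` holds the selected centroid ids in order.
#' @export
diversity_select <- function(compound_ids, fingerprints, n_out = 50L,
                             sim_threshold = 0.6) {
  stopifnot(length(compound_ids) == length(fingerprints))
  if (n_out < 1) stop("n_out must be >= 1", call. = FALSE)
  if (sim_threshold < 0 || sim_threshold > 1) {
    stop("sim_threshold must be in [0, 1]", call. = FALSE)
  }
  n <- length(compound_ids)
  if (n == 0) {
    out <- tibble::tibble(
      compound_id = character(0), cluster = integer(0),
      is_centroid = logical(0)
    )
    attr(out, "centroids") <- character(0)
    return(out)
  }
  bits <- lapply(fingerprints, as_bitview)
  leaders <- integer(0)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    sims <- vapply(leaders, function(l) tanimoto_kernel(bits[[i]], bits[[l]]),
      numeric(1)
    )
    if (length(leaders) > 0 && any(sims >= sim_threshold)) {
      cluster[i] <- which.max(sims)
    } else {
      leaders <- c(leaders, i)
      cluster[i] <- length(leaders)
    }
  }
  centroid_idx <- leaders[seq_len(min(n_out, length(leaders)))]
  out <- tibble::tibble(
    compound_id = compound_ids,
    cluster = cluster,
    is_centroid = seq_len(n) %in% centroid_idx
  )
  attr(out, "centroids") <- compound_ids[centroid_idx]
  out
}
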