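# Training-set construction from raw affinity tables. Mirrors the standard
# ChEMBL-style workflow: normalize heterogeneous affinity records to Ki in
# nM, label actives/inactives by thresholds, and assemble the seven sets a
# target/antitarget selectivity study needs (per-target actives and
# inactives, per-target selectives, and nonselectives).

ACTIVITY_SET_NAMES <- c(
  "1B_active", "1B_inactive", "2B_active", "2B_inactive",
  "1B_selective", "2B_selective", "nonselective"
)

#' Normalize affinity records to Ki in nM
#'
#' Unit scaling (`uM` x1000, `M` x1e9), p-measures via `10^(9 - value)` nM;
#' Kd is accepted as a Ki proxy, IC50 likewise with a one-time warning
#' (Cheng-Prusoff conversion applies when `policy` supplies the radioligand
#' concentration and Kd). Records with a non-`=` relation are kept only when
#' the bound falls unambiguously on one side of both labelling thresholds;
#' a `> 800 nM` record, for instance, straddles a 1000 nM inactivity
#' threshold and is rejected.
#'
#' @param records Tibble with columns `compound_id`, `target_id`, `value`,
#'   `unit` (`nM`/`uM`/`M`; ignored for p-measures), `measure` (`Ki`, `pKi`,
#'   `IC50`, `pIC50`, `Kd`), `relation` (`=`, `<`, `>`, `<=`, `>=`).
#' @param t_active,t_inactive Labelling thresholds in nM used to judge
#'   whether censored records are ambiguous.
#' @param policy List; `allow_ic50` (default `TRUE`), `allow_kd` (default
#'   `TRUE`), optional `cheng_prusoff = list(L, Kd)` with radioligand
#'   concentration and dissociation constant in nM.
#' @return The input tibble with `ki_nM` (NA when rejected) and
#'   `reject_reason` columns added.
#' @export
normalize_to_ki <- function(records, t_active = 500, t_inactive = 1000,
                            policy = list()) {
  stopifnot(is.data.frame(records))
  allow_ic50 <- !isFALSE(policy$allow_ic50)
  allow_kd <- !isFALSE(policy$allow_kd)
  cp <- policy$cheng_prusoff

  to_nM <- function(value, unit, measure) {
    p_measure <- measure %in% c("pKi", "pIC50")
    scale <- dplyr::case_when(
      p_measure ~ NA_real_,
      unit == "nM" ~ 1,
      unit == "uM" ~ 1e3,
      unit == "M" ~ 1e9,
      TRUE ~ NA_real_
    )
    ifelse(p_measure, 10^(9 - value), value * scale)
  }

  out <- records
  out$ki_nM <- to_nM(records$value, records$unit, records$measure)
  out$reject_reason <- NA_character_

  bad_value <- !is.finite(records$value) | records$value <= 0
  out$reject_reason[bad_value] <- "non-positive value"

  bad_unit <- is.na(out$ki_nM) & !bad_value
  out$reject_reason[bad_unit] <- "unknown unit"

  is_ic50 <- records$measure %in% c("IC50", "pIC50")
  if (any(is_ic50) && !allow_ic50) {
    out$reject_reason[is_ic50] <- "IC50 not accepted by policy"
  } else if (any(is_ic50) && is.null(cp)) {
    warning("treating ", sum(is_ic50),
      " IC50/pIC50 record(s) as Ki (no Cheng-Prusoff parameters supplied)",
      call. = FALSE
    )
  } else if (any(is_ic50) && !is.null(cp)) {
    out$ki_nM[is_ic50] <- out$ki_nM[is_ic50] / (1 + cp$L / cp$Kd)
  }
  is_kd <- records$measure == "Kd"
  if (any(is_kd) && !allow_kd) {
    out$reject_reason[is_kd] <- "Kd not accepted by policy"
  }

  # censored records: usable only when the bound clears both thresholds
  rel <- records$relation
  lower_bound <- rel %in% c(">", ">=") # true value above reported
  upper_bound <- rel %in% c("<", "<=")
  ambiguous <- (lower_bound & out$ki_nM < t_inactive) |
    (upper_bound & out$ki_nM > t_active)
  ambiguous[is.na(ambiguous)] <- FALSE
  set <- ambiguous & is.na(out$reject_reason)
  out$reject_reason[set] <- "ambiguous vs thresholds"

  out$ki_nM[!is.na(out$reject_reason)] <- NA_real_
  out
}

#' Label a Ki value as active, inactive or ambiguous
#'
#' Actives are compounds with Ki at or below `t_active`; inactives at or
#' above `t_inactive`; values strictly between are ambiguous and excluded
#' from every training set.
#'
#' @param ki_nM Numeric vector of Ki values in nM.
#' @param t_active Activity threshold, default 500 nM (inclusive).
#' @param t_inactive Inactivity threshold, default 1000 nM (inclusive).
#' @return Character vector: `"active"`, `"inactive"` or `"ambiguous"`.
#' @examples
#' label_activity(c(500, 1000, 750))
#' @export
label_activity <- function(ki_nM, t_active = 500, t_inactive = 1000) {
  if (t_active >= t_inactive) {
    stop("t_active must be smaller than t_inactive", call. = FALSE)
  }
  stopifnot(all(is.na(ki_nM) | ki_nM > 0))
  dplyr::case_when(
    is.na(ki_nM) ~ NA_character_,
    ki_nM <= t_active ~ "active",
    ki_nM >= t_inactive ~ "inactive",
    TRUE ~ "ambiguous"
  )
}

#' Build the seven selectivity-study training sets
#'
#' Per compound and target, replicate measurements are aggregated by
#' geometric mean of Ki (binding affinities are log-normally distributed)
#' before labelling. Compounds below the heavy-atom floor are dropped from
#' all sets; compounds whose aggregated evidence at one target straddles
#' both thresholds are dropped there and logged. The returned sets satisfy:
#' active and inactive sets of a target are disjoint; `selective(T)` is the
#' intersection of `active(T)` with `inactive(other)`; `nonselective` is the
#' intersection of the two active sets.
#'
#' @param records Affinity tibble (see [normalize_to_ki()]); `target_id`
#'   must take exactly two values.
#' @param molecules A molecule tibble from [parse_molecules()] resolving
#'   every `compound_id`, or `NULL` to skip the size filter.
#' @param min_heavy Minimum heavy-atom count, default 22 (ligands must be
#'   able to span both the orthosteric and the secondary binding pocket).
#' @param t_active,t_inactive Labelling thresholds in nM.
#' @param policy Normalization policy, see [normalize_to_ki()].
#' @param target,antitarget Which `target_id` plays the target (mapped to
#'   the `2B` set names) and which the antitarget (`1B`). Default: sorted
#'   unique targets, second as target.
#' @return A tibble `set`, `compound_id` covering the seven sets, with a
#'   `counts` attribute (named integer vector) and a `dropped` attribute
#'   listing compounds removed for conflicting evidence.
#' @export
build_sets <- function(records, molecules = NULL, min_heavy = 22L,
                       t_active = 500, t_inactive = 1000, policy = list(),
                       target = NULL, antitarget = NULL) {
  targets <- sort(unique(records$target_id))
  if (length(targets) != 2) {
    stop("expected exactly two targets, got: ", paste(targets, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(target)) target <- setdiff(targets, antitarget)[length(setdiff(targets, antitarget))]
  if (is.null(antitarget)) antitarget <- setdiff(targets, target)
  stopifnot(target %in% targets, antitarget %in% targets, target != antitarget)

  norm <- normalize_to_ki(records,
    t_active = t_active, t_inactive = t_inactive,
    policy = policy
  )
  norm <- dplyr::filter(norm, !is.na(.data$ki_nM))

  if (!is.null(molecules)) {
    heavy <- stats::setNames(molecules$heavy_atoms, molecules$id)
    unresolved <- setdiff(unique(norm$compound_id), names(heavy))
    if (length(unresolved) > 0) {
      stop("compound id(s) not resolvable to molecules: ",
        paste(utils::head(unresolved, 5), collapse = ", "),
        call. = FALSE
      )
    }
    norm <- dplyr::filter(norm, heavy[.data$compound_id] >= min_heavy)
  }

  agg <- norm |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(
      # evidence flags must see the raw replicate values, so they are
      # computed before ki_nM is overwritten by the aggregate
      any_active = any(.data$ki_nM <= t_active),
      any_inactive = any(.data$ki_nM >= t_inactive),
      ki_nM = exp(mean(log(.data$ki_nM))),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = label_activity(.data$ki_nM, t_active, t_inactive))

  # conflicting duplicates: evidence on both sides of the threshold band
  conflict <- agg$any_active & agg$any_inactive
  dropped <- unique(agg$compound_id[conflict])
  if (length(dropped) > 0) {
    message(
      length(dropped), " compound(s) dropped for conflicting replicate ",
      "evidence: ", paste(utils::head(dropped, 5), collapse = ", ")
    )
    agg <- dplyr::filter(agg, !(.data$compound_id %in% dropped))
  }

  lab <- function(tgt, lbl) {
    sort(unique(agg$compound_id[agg$target_id == tgt & agg$label == lbl]))
  }
  t_act <- lab(target, "active")
  t_inact <- lab(target, "inactive")
  a_act <- lab(antitarget, "active")
  a_inact <- lab(antitarget, "inactive")

  sets <- list(
    "1B_active" = a_act,
    "1B_inactive" = a_inact,
    "2B_active" = t_act,
    "2B_inactive" = t_inact,
    "1B_selective" = intersect(a_act, t_inact),
    "2B_selective" = intersect(t_act, a_inact),
    "nonselective" = intersect(t_act, a_act)
  )
  check_set_invariants(sets)

  out <- tibble::tibble(
    set = rep(names(sets), lengths(sets)),
    compound_id = unlist(sets, use.names = FALSE)
  )
  attr(out, "counts") <- vapply(sets, length, integer(1))
  attr(out, "dropped") <- dropped
  attr(out, "targets") <- c(target = target, antitarget = antitarget)
  out
}

check_set_invariants <- function(sets) {
  stopifnot(
    length(intersect(sets[["1B_active"]], sets[["1B_inactive"]])) == 0,
    length(intersect(sets[["2B_active"]], sets[["2B_inactive"]])) == 0,
    all(sets[["2B_selective"]] %in% sets[["2B_active"]]),
    all(sets[["2B_selective"]] %in% sets[["1B_inactive"]]),
    all(sets[["1B_selective"]] %in% sets[["1B_active"]]),
    all(sets[["1B_selective"]] %in% sets[["2B_inactive"]]),
    all(sets[["nonselective"]] %in% sets[["1B_active"]]),
    all(sets[["nonselective"]] %in% sets[["2B_active"]])
  )
  invisible(TRUE)
}

#' Write one id-list file per training set plus a JSON manifest
#'
#' @param sets Output of [build_sets()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_sets <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_set <- split(sets$compound_id, sets$set)
  for (nm in names(by_set)) {
    writeLines(by_set[[nm]], file.path(dir, paste0(nm, ".ids")))
  }
  manifest <- file.path(dir, "sets_manifest.json")
  jsonlite::write_json(
    list(
      counts = as.list(attr(sets, "counts")),
      dropped = attr(sets, "dropped"),
      targets = as.list(attr(sets, "targets"))
    ),
    manifest,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read an activity table from delimited text
#'
#' Accepts CSV or TSV with the canonical columns (`compound_id`,
#' `target_id`, `value`, `unit`, `measure`, `relation`); ChEMBL-style
#' export headers can be mapped via `col_map`.
#'
#' @param path File path.
#' @param col_map Named character vector mapping canonical names to file
#'   column names, e.g. `c(compound_id = "molecule_chembl_id")`.
#' @return A tibble of activity records.
#' @export
read_activity_table <- function(path, col_map = NULL) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(tab)[names(tab) == col_map[[canon]]] <- canon
    }
  }
  need <- c("compound_id", "target_id", "value", "unit", "measure", "relation")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("activity table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(tab[need])
}
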