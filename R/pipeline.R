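# Whole-funnel orchestration: training sets -> four classifiers -> cascade
# screen -> docking post-processing -> top-fraction and diversity selection,
# from a single YAML configuration, with a run manifest recording funnel
# counts, seeds and outputs.

#' Fast model grid used by the pipeline default
#'
#' One representative specification per classifier family; swap in
#' [default_model_grid()] (or any list of [classifier_spec()]) through the
#' `grid` config entry for a full search.
#'
#' @return List of [classifier_spec()] objects.
#' @export
fast_model_grid <- function() {
  list(
    classifier_spec("naive_bayes", alpha = 1),
    classifier_spec("svm", "tanimoto", C = 1),
    classifier_spec("eem", "tanimoto", m = 64L, eps = 1e-2)
  )
}

#' Run the full screening pipeline from a YAML configuration
#'
#' Configuration sections (all thresholds surfaced as named parameters with
#' the conventional defaults: 500/1000 nM activity thresholds, 22 heavy
#' atoms, 10% top fraction, 50 centroids):
#' \describe{
#'   \item{seed}{Integer; drives every stochastic stage.}
#'   \item{synthetic}{`n_molecules`, `noise`, ... ([generator_config()]
#'     fields); mutually exclusive with `library`/`activity` file inputs.}
#'   \item{library / activity}{Paths to a SMILES library and an activity
#'     table.}
#'   \item{keys}{Key file path; default the packaged demo set.}
#'   \item{fingerprint}{`order`, `mode`, `d`.}
#'   \item{thresholds}{`t_active`, `t_inactive`, `min_heavy`.}
#'   \item{grid}{`"fast"` (default) or `"default"`.}
#'   \item{docking}{`scenario` (packaged pose scenario) or
#'     `poses_target`/`poses_antitarget`/`receptors` paths; `mode`,
#'     `top_fraction`, `n_centroids`, `sim_threshold`. Omit the section to
#'     skip the docking stage.}
#'   \item{out_dir}{Where outputs and the manifest are written.}
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` under `out_dir`. Funnel counts are monotone
#'   non-increasing along input, stage-1, stage-2, pose-filtered,
#'   consensus-selected, top-fraction, diversity centroids.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_pipeline_config(cfg)
  seed <- cfg$seed %||% 7L
  out_dir <- cfg$out_dir %||% tempfile("nsfp_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- cfg$thresholds %||% list()
  t_active <- thr$t_active %||% 500
  t_inactive <- thr$t_inactive %||% 1000
  min_heavy <- thr$min_heavy %||% 22L
  fp <- cfg$fingerprint %||% list()
  fp_args <- list(
    order = fp$order %||% "2", mode = fp$mode %||% "bonded",
    d = fp$d %||% 1L
  )

  t_start <- Sys.time()
  keys <- if (is.null(cfg$keys)) {
    load_keyset(demo_keyset_path())
  } else {
    load_keyset(cfg$keys)
  }

  # ---- inputs
  if (!is.null(cfg$synthetic)) {
    gen_args <- cfg$synthetic
    gen_args$seed <- seed
    gcfg <- do.call(generator_config, gen_args)
    lib <- generate_library(gcfg)
    records <- generate_activity_table(lib, gcfg)
  } else {
    lib <- parse_molecules(cfg$library, format = cfg$library_format %||% "smiles")
    records <- read_activity_table(cfg$activity, col_map = cfg$activity_col_map)
  }

  # ---- training sets
  sets <- build_sets(records, lib,
    min_heavy = min_heavy,
    t_active = t_active, t_inactive = t_inactive,
    target = cfg$target, antitarget = cfg$antitarget
  )
  write_sets(sets, file.path(out_dir, "sets"))

  # ---- fingerprints (computed once, shared by training and screening)
  fps <- purrr::map(lib$mol, function(m) {
    do.call(nsfp_fingerprint, c(list(mol = m, keys = keys), fp_args))
  })
  names(fps) <- lib$id

  grid <- if (identical(cfg$grid, "default")) {
    default_model_grid()
  } else if (is.list(cfg$grid)) {
    cfg$grid
  } else {
    fast_model_grid()
  }
  pair_fps <- function(set_name) {
    ids <- sets$compound_id[sets$set == set_name]
    fps[intersect(ids, names(fps))]
  }
  train_pair <- function(pos_set, neg_set) {
    pos <- pair_fps(pos_set)
    neg <- pair_fps(neg_set)
    sel <- select_best_model(grid, pos, neg, k = 5L, seed = seed)
    model <- train_classifier(sel$spec, pos, neg, seed = seed)
    list(model = model, cv = sel$cv, audit = sel$audit)
  }
  trained <- list(
    a_target = train_pair("2B_active", "2B_inactive"),
    a_antitarget = train_pair("1B_active", "1B_inactive"),
    s_target = train_pair("2B_selective", "nonselective"),
    s_antitarget = train_pair("1B_selective", "nonselective")
  )
  models <- purrr::map(trained, "model")
  model_mcc <- purrr::map_dbl(trained, function(t) t$cv$mcc)

  # ---- cascade screen
  decisions <- screen_database(lib, models, keys, fingerprints = unname(fps))
  readr::write_tsv(
    dplyr::select(decisions, -dplyr::any_of("mol")),
    file.path(out_dir, "decisions.tsv")
  )
  funnel <- attr(decisions, "funnel")

  # ---- docking post-processing (optional)
  docking_counts <- c(
    pose_filtered = NA_integer_, consensus_selected = NA_integer_,
    top_fraction = NA_integer_, centroids = NA_integer_
  )
  docking_skipped <- is.null(cfg$docking)
  if (!docking_skipped) {
    dk <- cfg$docking
    mode <- dk$mode %||% "obp_and_sbp"
    if (!is.null(dk$scenario)) {
      # packaged scenarios stand in for an external docking engine: their
      # probe poses are assigned to the stage-2 survivors so the docking
      # sub-funnel continues the cascade funnel
      ps <- generate_pose_set(dk$scenario, seed = seed)
      stage2_ids <- decisions$compound_id[decisions$verdict == "stage2_selective"]
      scen_ids <- unique(ps$poses$compound_id)
      n_map <- min(length(scen_ids), length(stage2_ids))
      id_map <- stats::setNames(stage2_ids[seq_len(n_map)], scen_ids[seq_len(n_map)])
      poses <- ps$poses[ps$poses$compound_id %in% names(id_map), , drop = FALSE]
      poses$compound_id <- unname(id_map[poses$compound_id])
      specs <- ps$specs
    } else {
      specs <- load_receptor_specs(dk$receptors)
      read_many <- function(paths, ids) {
        dplyr::bind_rows(purrr::map2(paths, ids, function(p, id) {
          read_poses_sdf(p, id, score_property = dk$score_property %||% "r_i_docking_score")
        }))
      }
      roles <- vapply(specs, `[[`, character(1), "role")
      poses <- dplyr::bind_rows(
        read_many(dk$poses_target, names(specs)[roles == "target"]),
        read_many(dk$poses_antitarget, names(specs)[roles == "antitarget"])
      )
    }
    surviving <- dplyr::bind_rows(lapply(names(specs), function(rid) {
      pose_filter(
        poses[poses$receptor_id == rid, , drop = FALSE],
        specs[[rid]], mode
      )
    }))
    ranks <- rank_compounds(surviving)
    roles <- vapply(specs, `[[`, character(1), "role")
    cons <- delta_max(
      ranks,
      target_receptors = names(specs)[roles == "target"],
      antitarget_receptors = names(specs)[roles == "antitarget"]
    )
    sel <- dplyr::filter(cons, .data$selected)
    top <- select_top_fraction(sel, dk$top_fraction %||% 0.10)
    div_fps <- fps[top$compound_id]
    missing_fp <- vapply(div_fps, is.null, logical(1))
    div <- diversity_select(
      top$compound_id[!missing_fp], div_fps[!missing_fp],
      n_out = dk$n_centroids %||% 50L,
      sim_threshold = dk$sim_threshold %||% 0.6
    )
    readr::write_tsv(cons, file.path(out_dir, "consensus.tsv"))
    writeLines(attr(div, "centroids"), file.path(out_dir, "centroids.ids"))
    docking_counts <- c(
      pose_filtered = length(unique(surviving$compound_id)),
      consensus_selected = nrow(sel),
      top_fraction = nrow(top),
      centroids = length(attr(div, "centroids"))
    )
  }

  manifest <- list(
    config_hash = rlang::hash(cfg),
    seed = seed,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    keyset = attr(keys, "keyset_name"),
    set_counts = as.list(attr(sets, "counts")),
    model_mcc = as.list(model_mcc),
    funnel = list(
      input = unname(funnel["input"]),
      stage1 = unname(funnel["stage1"]),
      stage2 = unname(funnel["stage2"]),
      pose_filtered = unname(docking_counts["pose_filtered"]),
      consensus_selected = unname(docking_counts["consensus_selected"]),
      top_fraction = unname(docking_counts["top_fraction"]),
      centroids = unname(docking_counts["centroids"])
    ),
    docking = if (docking_skipped) "skipped" else "run",
    out_dir = out_dir
  )
  check_funnel_monotone(manifest$funnel)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or YAML path", call. = FALSE)
  has_syn <- !is.null(cfg$synthetic)
  has_files <- !is.null(cfg$library) && !is.null(cfg$activity)
  if (!has_syn && !has_files) {
    stop("config needs either a 'synthetic' section or 'library' + 'activity'",
      call. = FALSE
    )
  }
  if (has_syn && has_files) {
    stop("'synthetic' and file inputs are mutually exclusive", call. = FALSE)
  }
  for (p in c(cfg$library, cfg$activity, cfg$keys)) {
    if (!file.exists(p)) stop("config references missing file: ", p, call. = FALSE)
  }
  invisible(TRUE)
}

check_funnel_monotone <- function(funnel) {
  chain <- c(
    funnel$input, funnel$stage1, funnel$stage2,
    funnel$pose_filtered, funnel$consensus_selected,
    funnel$top_fraction, funnel$centroids
  )
  chain <- chain[!is.na(chain)]
  if (is.unsorted(rev(chain))) {
    stop("funnel counts are not monotone non-increasing: ",
      paste(chain, collapse = " -> "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
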