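# Docking post-processing, part 1: receptor interaction criteria and pose
# filtering. This package never runs docking; it consumes pose coordinate
# files (SDF with a score property, or a delimited table) produced by an
# external engine, plus receptor residue coordinates and a residue-criterion
# configuration, and keeps only poses whose protein-ligand interactions
# match the selectivity hypothesis: an anchoring contact to the conserved
# orthosteric aspartate (Asp 3.32 in Ballesteros-Weinstein numbering) plus
# contacts to the non-conserved secondary-binding-pocket residues, or, in
# the water-mediated variant, a hydrogen bond to either the aspartate or a
# structural water.

HBOND_MAX_A <- 3.5
SALT_BRIDGE_MAX_A <- 4.0
DISTANCE_CRITERION_A <- 5.0

#' Build a receptor interaction specification
#'
#' @param receptor_id Receptor structure identifier (e.g. a PDB id).
#' @param role `"target"` or `"antitarget"`.
#' @param criteria Tibble/data frame with columns `residue` (label, e.g.
#'   `"D135^3.32"`), `site` (`"OBP"`, `"SBP"` or `"water"`), `criterion`
#'   (`"hbond"`, `"distance"`, `"hbond_or_salt_bridge"`), `threshold`
#'   (Angstrom; `NA` takes the criterion default: 3.5 for hydrogen bonds,
#'   5.0 for distance contacts).
#' @param atoms Tibble with residue atom coordinates: `residue`, `atom`
#'   (name), `element`, `x`, `y`, `z`, and logical `donor`, `acceptor`,
#'   `carboxylate_o` flags.
#' @return A `receptor_spec` object.
#' @export
receptor_spec <- function(receptor_id, role = c("target", "antitarget"),
                          criteria, atoms) {
  role <- match.arg(role)
  criteria <- tibble::as_tibble(criteria)
  atoms <- tibble::as_tibble(atoms)
  stopifnot(
    all(c("residue", "site", "criterion", "threshold") %in% names(criteria)),
    all(c("residue", "atom", "element", "x", "y", "z") %in% names(atoms))
  )
  if (anyDuplicated(criteria$residue)) {
    stop("duplicate residue labels in criteria", call. = FALSE)
  }
  bad <- !criteria$criterion %in% c("hbond", "distance", "hbond_or_salt_bridge")
  if (any(bad)) {
    stop("unknown criterion: ", paste(criteria$criterion[bad], collapse = ", "),
      call. = FALSE
    )
  }
  criteria$threshold <- ifelse(
    is.na(criteria$threshold),
    ifelse(criteria$criterion == "distance", DISTANCE_CRITERION_A, HBOND_MAX_A),
    criteria$threshold
  )
  if (any(criteria$threshold <= 0)) stop("thresholds must be > 0", call. = FALSE)
  missing_coords <- setdiff(criteria$residue, atoms$residue)
  if (length(missing_coords) > 0) {
    stop("no coordinates for residue(s): ",
      paste(missing_coords, collapse = ", "),
      call. = FALSE
    )
  }
  for (flag in c("donor", "acceptor", "carboxylate_o")) {
    if (is.null(atoms[[flag]])) atoms[[flag]] <- FALSE
  }
  structure(
    list(
      receptor_id = receptor_id, role = role, criteria = criteria,
      atoms = atoms
    ),
    class = "receptor_spec"
  )
}

#' @export
print.receptor_spec <- function(x, ...) {
  cat("<receptor_spec ", x$receptor_id, " (", x$role, "): ",
    nrow(x$criteria), " criteria, ", nrow(x$atoms), " atoms>\n",
    sep = ""
  )
  invisible(x)
}

#' Load receptor specifications from a YAML criteria file plus PDB coordinates
#'
#' The YAML lists one entry per receptor: `receptor_id`, `role`, `pdb`
#' (path, resolved relative to the YAML file), and `criteria` (list of
#' `residue`, `site`, `criterion`, optional `threshold`, and `resno` /
#' optional `chain` used to pull the residue's atoms out of the PDB).
#' Donor/acceptor/carboxylate flags are assigned from standard amino-acid
#' atom chemistry (backbone N donor / O acceptor, Ser/Thr/Tyr hydroxyls
#' both, Asp/Glu carboxylate oxygens acceptor + salt-bridge capable, water
#' oxygen both).
#'
#' @param path Path to the YAML file.
#' @return List of `receptor_spec` objects, named by receptor id.
#' @export
load_receptor_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  out <- list()
  for (entry in cfg$receptors) {
    crit <- dplyr::bind_rows(lapply(entry$criteria, function(cr) {
      tibble::tibble(
        residue = cr$residue, site = cr$site, criterion = cr$criterion,
        threshold = if (is.null(cr$threshold)) NA_real_ else cr$threshold,
        resno = cr$resno,
        chain = if (is.null(cr$chain)) NA_character_ else cr$chain
      )
    }))
    pdb_path <- entry$pdb
    if (!file.exists(pdb_path)) pdb_path <- file.path(base, entry$pdb)
    atoms <- read_residue_atoms(pdb_path, crit)
    out[[entry$receptor_id]] <- receptor_spec(
      entry$receptor_id, entry$role,
      crit[, c("residue", "site", "criterion", "threshold")], atoms
    )
  }
  out
}

# Pull the atoms of the criterion residues out of a PDB file (bio3d) and
# annotate donor/acceptor/salt-bridge chemistry by residue + atom name.
read_residue_atoms <- function(pdb_path, crit) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB receptor files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  rows <- list()
  for (i in seq_len(nrow(crit))) {
    sel <- at$resno == crit$resno[i]
    if (!is.na(crit$chain[i])) sel <- sel & at$chain == crit$chain[i]
    if (!any(sel)) {
      stop("residue ", crit$residue[i], " (resno ", crit$resno[i],
        ") not found in ", pdb_path,
        call. = FALSE
      )
    }
    sub <- at[sel, , drop = FALSE]
    rows[[i]] <- tibble::tibble(
      residue = crit$residue[i],
      atom = sub$elety,
      element = ifelse(nzchar(trimws(sub$elesy)), trimws(sub$elesy),
        substr(trimws(sub$elety), 1, 1)
      ),
      x = sub$x, y = sub$y, z = sub$z,
      resid = sub$resid
    )
  }
  atoms <- dplyr::bind_rows(rows)
  annotate_protein_atom_chemistry(atoms)
}

annotate_protein_atom_chemistry <- function(atoms) {
  nm <- atoms$atom
  res <- toupper(atoms$resid %||% "")
  is_water <- res %in% c("HOH", "WAT", "H2O")
  atoms$donor <- (nm == "N") |
    (res %in% c("SER", "THR", "TYR") & nm %in% c("OG", "OG1", "OH")) |
    (res %in% c("ASN", "GLN") & nm %in% c("ND2", "NE2")) |
    (res %in% c("LYS") & nm == "NZ") |
    (res %in% c("ARG") & nm %in% c("NE", "NH1", "NH2")) |
    (res %in% c("TRP") & nm == "NE1") |
    (res %in% c("HIS") & nm %in% c("ND1", "NE2")) |
    (is_water & atoms$element == "O")
  atoms$acceptor <- (nm == "O") |
    (res %in% c("SER", "THR", "TYR") & nm %in% c("OG", "OG1", "OH")) |
    (res %in% c("ASN", "GLN") & nm %in% c("OD1", "OE1")) |
    (res %in% c("ASP") & nm %in% c("OD1", "OD2")) |
    (res %in% c("GLU") & nm %in% c("OE1", "OE2")) |
    (res %in% c("HIS") & nm %in% c("ND1", "NE2")) |
    (is_water & atoms$element == "O")
  atoms$carboxylate_o <- (res == "ASP" & nm %in% c("OD1", "OD2")) |
    (res == "GLU" & nm %in% c("OE1", "OE2"))
  atoms
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect which residue criteria a docking pose satisfies
#'
#' Distance criterion: the minimum ligand-atom-to-residue-atom Euclidean
#' distance is at or below the threshold (default 5.0 Angstrom, boundary
#' inclusive). Hydrogen bond: a ligand donor or acceptor heavy atom lies
#' within the hydrogen-bond threshold (default 3.5 Angstrom) of a
#' complementary residue acceptor/donor heavy atom. Salt-bridge extension:
#' additionally satisfied when a positively charged ligand nitrogen lies
#' within 4.0 Angstrom of a carboxylate oxygen. Water sites are a single
#' oxygen acting as both donor and acceptor.
#'
#' @param pose A pose record: list/row with `atoms`, a tibble of `element`,
#'   `x`, `y`, `z`, `charge`, `donor`, `acceptor`.
#' @param spec A `receptor_spec`.
#' @return Character vector of satisfied residue labels.
#' @export
detect_interactions <- function(pose, spec) {
  stopifnot(inherits(spec, "receptor_spec"))
  lig <- pose$atoms
  if (is.list(lig) && !is.data.frame(lig)) lig <- lig[[1]]
  satisfied <- character(0)
  for (i in seq_len(nrow(spec$criteria))) {
    cr <- spec$criteria[i, ]
    ratoms <- spec$atoms[spec$atoms$residue == cr$residue, , drop = FALSE]
    ok <- switch(cr$criterion,
      distance = min_cross_distance(lig, ratoms) <= cr$threshold,
      hbond = hbond_satisfied(lig, ratoms, cr$threshold),
      hbond_or_salt_bridge = hbond_satisfied(lig, ratoms, cr$threshold) ||
        salt_bridge_satisfied(lig, ratoms)
    )
    if (isTRUE(ok)) satisfied <- c(satisfied, cr$residue)
  }
  satisfied
}

min_cross_distance <- function(a, b) {
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  sqrt(min(d2))
}

hbond_satisfied <- function(lig, ratoms, threshold = HBOND_MAX_A) {
  heavy <- lig$element != "H"
  # donor-to-acceptor and acceptor-to-donor pairings
  pairs <- list(
    list(l = heavy & lig$donor, r = ratoms$acceptor),
    list(l = heavy & lig$acceptor, r = ratoms$donor)
  )
  for (p in pairs) {
    if (any(p$l) && any(p$r)) {
      d <- min_cross_distance(lig[p$l, , drop = FALSE], ratoms[p$r, , drop = FALSE])
      if (d <= threshold) {
        return(TRUE)
      }
    }
  }
  FALSE
}

salt_bridge_satisfied <- function(lig, ratoms) {
  cation <- lig$element == "N" & lig$charge > 0
  anion <- ratoms$carboxylate_o
  if (!any(cation) || !any(anion)) {
    return(FALSE)
  }
  min_cross_distance(
    lig[cation, , drop = FALSE],
    ratoms[anion, , drop = FALSE]
  ) <= SALT_BRIDGE_MAX_A
}

#' Filter docking poses by interaction criteria
#'
#' Two modes. `obp_and_sbp`: keep a pose iff the orthosteric aspartate
#' hydrogen bond is satisfied AND at least one secondary-binding-pocket
#' criterion is satisfied. `asp_or_water`: keep iff the aspartate hydrogen
#' bond / salt bridge OR the structural-water hydrogen bond is satisfied.
#' Compounds whose every pose fails drop out of the funnel.
#'
#' @param poses A pose tibble (see [read_poses_sdf()] /
#'   [generate_pose_set()]): columns `compound_id`, `receptor_id`,
#'   `pose_index`, `score`, `atoms` (list-column).
#' @param spec The matching `receptor_spec`.
#' @param mode `"obp_and_sbp"` or `"asp_or_water"`.
#' @return The surviving rows of `poses`, with a `satisfied` list-column of
#'   residue labels.
#' @export
pose_filter <- function(poses, spec, mode = c("obp_and_sbp", "asp_or_water")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "receptor_spec"))
  cr <- spec$criteria
  asp <- cr$residue[cr$site == "OBP" & grepl("3\\.32", cr$residue)]
  if (length(asp) == 0) asp <- cr$residue[cr$site == "OBP"][1]
  if (mode == "obp_and_sbp") {
    sbp <- cr$residue[cr$site == "SBP"]
    if (length(sbp) == 0) {
      stop("mode 'obp_and_sbp' needs SBP criteria in the receptor spec",
        call. = FALSE
      )
    }
  } else {
    water <- cr$residue[cr$site == "water"]
    if (length(water) == 0) {
      stop("mode 'asp_or_water' needs a water criterion in the receptor spec",
        call. = FALSE
      )
    }
  }
  if (nrow(poses) == 0) {
    poses$satisfied <- list()
    return(poses)
  }
  mismatch <- poses$receptor_id != spec$receptor_id
  if (any(mismatch)) {
    stop("pose/receptor mismatch: poses for ",
      paste(unique(poses$receptor_id[mismatch]), collapse = ", "),
      " given spec ", spec$receptor_id,
      call. = FALSE
    )
  }
  sat <- lapply(seq_len(nrow(poses)), function(i) {
    detect_interactions(poses[i, ], spec)
  })
  keep <- vapply(seq_along(sat), function(i) {
    s <- sat[[i]]
    if (mode == "obp_and_sbp") {
      any(asp %in% s) && any(sbp %in% s)
    } else {
      any(asp %in% s) || any(water %in% s)
    }
  }, logical(1))
  out <- poses[keep, , drop = FALSE]
  out$satisfied <- sat[keep]
  out
}

#' Read docking poses from a multi-record SDF file
#'
#' Each record is one pose; the compound id is the record title (an optional
#' `_pose<k>` suffix is split off as the pose index) and the docking score
#' is taken from the named data field.
#'
#' @param path SDF file path.
#' @param receptor_id Receptor these poses were docked into.
#' @param score_property Name of the SDF data field holding the docking
#'   score (default `"r_i_docking_score"`).
#' @return Pose tibble: `compound_id`, `receptor_id`, `pose_index`, `score`,
#'   `atoms` (list-column of element/x/y/z/charge/donor/acceptor tibbles).
#' @export
read_poses_sdf <- function(path, receptor_id, score_property = "r_i_docking_score") {
  recs <- read_sdf_records(path)
  rows <- purrr::map2(recs$records, recs$id, function(rec, title) {
    score <- sdf_property(rec, score_property)
    if (is.na(score)) {
      stop("pose record '", title, "' lacks score property '",
        score_property, "'",
        call. = FALSE
      )
    }
    mol <- sdf_record_to_molecule(rec, id = title)
    xyz <- attr(mol, "xyz")
    atoms <- pose_atoms_from_molecule(mol, xyz)
    pose_index <- 1L
    compound_id <- title
    m <- regmatches(title, regexec("^(.*)_pose([0-9]+)$", title))[[1]]
    if (length(m) == 3) {
      compound_id <- m[2]
      pose_index <- as.integer(m[3])
    }
    tibble::tibble(
      compound_id = compound_id, receptor_id = receptor_id,
      pose_index = pose_index, score = score, atoms = list(atoms)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::mutate(pose_index = make_unique_pose_index(.data$pose_index)) |>
    dplyr::ungroup()
  out
}

make_unique_pose_index <- function(idx) {
  if (anyDuplicated(idx)) seq_along(idx) else idx
}

sdf_property <- function(rec, name) {
  hit <- grep(paste0("^> *<", name, ">"), rec)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  as.numeric(trimws(rec[hit[1] + 1]))
}

# Ligand donor/acceptor perception from the connection table: N/O acceptors;
# N/O bearing a hydrogen (explicit or implied by valence) donors; positive
# charge recorded for salt-bridge detection.
pose_atoms_from_molecule <- function(mol, xyz) {
  a <- mol$atoms
  tibble::tibble(
    element = a$element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = a$charge,
    donor = a$element %in% c("N", "O") & (a$h_total > 0 | a$charge > 0),
    acceptor = a$element %in% c("N", "O")
  )
}

#' Read docking poses from a delimited score table
#'
#' A TSV/CSV alternative to SDF input: one row per ligand atom with columns
#' `compound_id`, `receptor_id`, `pose_index`, `score`, `element`, `x`,
#' `y`, `z`, and optional `charge`, `donor`, `acceptor`.
#'
#' @param path File path.
#' @return Pose tibble as in [read_poses_sdf()].
#' @export
read_poses_table <- function(path) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c(
    "compound_id", "receptor_id", "pose_index", "score",
    "element", "x", "y", "z"
  )
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("pose table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(tab$charge)) tab$charge <- 0L
  if (is.null(tab$donor)) tab$donor <- tab$element %in% c("N", "O")
  if (is.null(tab$acceptor)) tab$acceptor <- tab$element %in% c("N", "O")
  tab |>
    dplyr::group_by(.data$compound_id, .data$receptor_id, .data$pose_index, .data$score) |>
    tidyr::nest(atoms = c(
      "element", "x", "y", "z", "charge",
      "donor", "acceptor"
    )) |>
    dplyr::ungroup()
}
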