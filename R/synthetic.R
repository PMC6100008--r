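# Seeded synthetic data with planted ground truth. The generator emulates
# the *shape* of a selectivity-screening study's inputs -- a druglike
# molecule library, a heterogeneous affinity table for a target/antitarget
# pair, docking pose sets with interaction geometry -- while keeping the
# truth (which compounds carry which activity-defining motif, which poses
# satisfy which criterion, the intended consensus ordering) known by
# construction. Fragments are serotonergic-flavoured (arylpiperazines,
# piperidines, azoles) purely for realism; the ground truth is the planted
# motifs, not pharmacology.

#' Configuration for the synthetic generators
#'
#' @param seed Integer seed; all generators are bit-reproducible given
#'   (seed, config).
#' @param n_molecules Library size.
#' @param p_motif1,p_motif2 Independent insertion probabilities of the two
#'   planted motifs (chlorophenyl and arylsulfonyl fragments). Motif 1
#'   drives activity at the target, motif 2 at the antitarget, so molecules
#'   with motif 1 only are the planted target-selectives.
#' @param noise Label-flip rate in \[0, 0.5) applied when affinities are
#'   drawn.
#' @param unit_mix Proportions (summing to 1) of records emitted as nM Ki,
#'   uM Ki, and pKi.
#' @param n_fragments Range (length-2 integer vector) of backbone fragments
#'   per molecule; the default spans the 22-heavy-atom boundary.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 7L, n_molecules = 1000L,
                             p_motif1 = 0.35, p_motif2 = 0.35,
                             noise = 0.05,
                             unit_mix = c(nM = 0.5, uM = 0.25, pKi = 0.25),
                             n_fragments = c(3L, 6L)) {
  stopifnot(
    noise >= 0, noise < 0.5,
    abs(sum(unit_mix) - 1) < 1e-9,
    length(n_fragments) == 2, n_fragments[1] >= 1
  )
  cfg <- list(
    seed = as.integer(seed), n_molecules = as.integer(n_molecules),
    p_motif1 = p_motif1, p_motif2 = p_motif2, noise = noise,
    unit_mix = unit_mix, n_fragments = n_fragments,
    fragments = c(
      "C" = 3, "CC" = 3, "CCC" = 2, "CCN" = 2, "CCO" = 2, "CO" = 1,
      "CN" = 1, "C(=O)" = 1, "c1ccccc1" = 3, "c1ccncc1" = 2,
      "C1CCNCC1" = 2, "N1CCNCC1" = 2, "C1CCCCC1" = 1, "c1cc[nH]c1" = 1
    ),
    motif1 = "c1ccc(Cl)cc1", # halogen adjacent to benzene
    motif2 = "S(=O)(=O)c1ccccc1" # sulfonyl adjacent to benzene
  )
  # the grammar must only emit parseable SMILES: fail here, not mid-run
  for (f in c(names(cfg$fragments), cfg$motif1, cfg$motif2)) {
    tryCatch(smiles_to_molecule(f), error = function(e) {
      stop("fragment grammar produces unparseable SMILES '", f, "': ",
        conditionMessage(e),
        call. = FALSE
      )
    })
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic molecule library
#'
#' Molecules are chains of weighted backbone fragments; each planted motif
#' is inserted independently with its configured probability at a random
#' chain position. Heavy-atom sizes span the 22-atom screening boundary.
#'
#' @param cfg A [generator_config()].
#' @return Molecule tibble (as from [parse_molecules()]) with logical
#'   `motif1`, `motif2` annotation columns.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_molecules
  if (n == 0) {
    return(tibble::tibble(
      id = character(0), mol = list(), heavy_atoms = integer(0),
      source = character(0), motif1 = logical(0), motif2 = logical(0)
    ))
  }
  frag_names <- names(cfg$fragments)
  frag_w <- cfg$fragments / sum(cfg$fragments)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(cfg$n_fragments[1]:cfg$n_fragments[2], 1)
    parts <- sample(frag_names, k, replace = TRUE, prob = frag_w)
    m1 <- stats::runif(1) < cfg$p_motif1
    m2 <- stats::runif(1) < cfg$p_motif2
    if (m1) parts <- append(parts, cfg$motif1, after = sample(0:length(parts), 1))
    if (m2) parts <- append(parts, cfg$motif2, after = sample(0:length(parts), 1))
    smi <- paste(parts, collapse = "")
    rows[[i]] <- list(smiles = smi, motif1 = m1, motif2 = m2)
  }
  ids <- sprintf("SYN%05d", seq_len(n))
  mols <- purrr::map2(rows, ids, function(r, id) smiles_to_molecule(r$smiles, id = id))
  tibble::tibble(
    id = ids,
    mol = mols,
    heavy_atoms = vapply(mols, heavy_atom_count, integer(1)),
    source = vapply(rows, `[[`, character(1), "smiles"),
    motif1 = vapply(rows, `[[`, logical(1), "motif1"),
    motif2 = vapply(rows, `[[`, logical(1), "motif2")
  )
}

#' Generate a synthetic affinity table for a target/antitarget pair
#'
#' Target `R2B` activity is planted on motif 1, antitarget `R1B` activity
#' on motif 2 (so motif-1-only molecules are the planted target-selectives).
#' Actives draw Ki log-uniformly from 5-200 nM, inactives from 2000-50000
#' nM; labels flip with the configured noise rate before the draw; records
#' are emitted in a seeded mix of units/measures (nM Ki, uM Ki, pKi) with
#' relation `"="`.
#'
#' @param mols Library tibble from [generate_library()].
#' @param cfg The same [generator_config()].
#' @return Activity record tibble; the post-noise truth is attached as
#'   attribute `truth` (tibble `compound_id`, `active_R2B`, `active_R1B`,
#'   `flipped_R2B`, `flipped_R1B`).
#' @export
generate_activity_table <- function(mols, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(mols)
  plan <- tidyr::expand_grid(
    compound_id = mols$id,
    target_id = c("R2B", "R1B")
  )
  motif <- ifelse(plan$target_id == "R2B",
    mols$motif1[match(plan$compound_id, mols$id)],
    mols$motif2[match(plan$compound_id, mols$id)]
  )
  flip <- stats::runif(nrow(plan)) < cfg$noise
  active <- xor(motif, flip)
  ki <- ifelse(active,
    exp(stats::runif(nrow(plan), log(5), log(200))),
    exp(stats::runif(nrow(plan), log(2000), log(50000)))
  )
  form <- sample(names(cfg$unit_mix), nrow(plan),
    replace = TRUE,
    prob = cfg$unit_mix
  )
  records <- tibble::tibble(
    compound_id = plan$compound_id,
    target_id = plan$target_id,
    value = dplyr::case_when(
      form == "nM" ~ ki,
      form == "uM" ~ ki / 1e3,
      form == "pKi" ~ 9 - log10(ki)
    ),
    unit = ifelse(form == "uM", "uM", "nM"),
    measure = ifelse(form == "pKi", "pKi", "Ki"),
    relation = "="
  )
  truth <- tibble::tibble(
    compound_id = plan$compound_id,
    target_id = plan$target_id,
    active = active, flipped = flip
  ) |>
    tidyr::pivot_wider(
      names_from = "target_id",
      values_from = c("active", "flipped")
    )
  attr(records, "truth") <- truth
  records
}

# ---- pose scenarios --------------------------------------------------------

toy_receptor <- function(receptor_id, role) {
  asp_label <- if (role == "target") "D135^3.32" else "D129^3.32"
  sbp_label <- if (role == "target") "M218^5.39" else "M337^6.58"
  water_label <- if (role == "target") "HOH2004" else "HOH2020"
  criteria <- tibble::tibble(
    residue = c(asp_label, sbp_label, water_label),
    site = c("OBP", "SBP", "water"),
    criterion = c("hbond_or_salt_bridge", "distance", "hbond"),
    threshold = c(NA_real_, 5.0, NA_real_)
  )
  atoms <- tibble::tibble(
    residue = c(asp_label, asp_label, sbp_label, water_label),
    atom = c("OD1", "OD2", "SD", "O"),
    element = c("O", "O", "S", "O"),
    x = c(0, -1.0, 8, 3),
    y = c(0, 0.8, 0, 3),
    z = c(0, 0, 0, 0),
    donor = c(FALSE, FALSE, FALSE, TRUE),
    acceptor = c(TRUE, TRUE, FALSE, TRUE),
    carboxylate_o = c(TRUE, TRUE, FALSE, FALSE)
  )
  receptor_spec(receptor_id, role, criteria, atoms)
}

# A three-atom probe ligand: protonated amine (donor/cation), carbon,
# carbonyl-like oxygen (acceptor). Coordinates place it relative to the toy
# receptor: `asp_d` = N+ distance to Asp OD1, `sbp_d` = C distance to the
# SBP sulfur, `water_d` = O distance to the water oxygen.
probe_pose <- function(compound_id, receptor_id, pose_index, score,
                       asp_d = 2.8, sbp_d = 4.0, water_d = 8.0) {
  atoms <- tibble::tibble(
    element = c("N", "C", "O"),
    x = c(asp_d, 8 - sbp_d, 3),
    y = c(0, 0, 3 + water_d),
    z = c(0, 0, 0),
    charge = c(1L, 0L, 0L),
    donor = c(TRUE, FALSE, FALSE),
    acceptor = c(FALSE, FALSE, TRUE)
  )
  tibble::tibble(
    compound_id = compound_id, receptor_id = receptor_id,
    pose_index = pose_index, score = score, atoms = list(atoms)
  )
}

#' Generate a docking pose scenario with known outcomes
#'
#' Packaged scenarios over a toy target/antitarget receptor pair with
#' hand-checkable coordinates:
#' \describe{
#'   \item{`asp_only`}{Every pose forms the aspartate contact but none
#'     reaches the secondary pocket: all fail `obp_and_sbp`, all pass
#'     `asp_or_water`.}
#'   \item{`boundary_5A`}{Three poses at secondary-pocket distances 4.9,
#'     5.0 (boundary, inclusive) and 5.1 Angstrom.}
#'   \item{`water_rescue`}{Poses without the aspartate contact; half form
#'     the structural-water hydrogen bond and survive `asp_or_water`.}
#'   \item{`planted_selectives_10`}{30 compounds docked at both receptors,
#'     all poses filter-clean; scores are built so exactly the 10 planted
#'     compounds take the most negative rank difference.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed (used by score jitter where a scenario has any).
#' @return List: `poses` (pose tibble over both receptors), `specs` (named
#'   list of the two `receptor_spec`s), `expected` (scenario-specific truth:
#'   per-pose filter outcomes or the planted selective ids).
#' @export
generate_pose_set <- function(scenario = c(
                                "asp_only", "boundary_5A",
                                "water_rescue", "planted_selectives_10"
                              ),
                              seed = 7L) {
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    stop("unknown scenario; catalogue: asp_only, boundary_5A, water_rescue, ",
      "planted_selectives_10",
      call. = FALSE
    )
  })
  set.seed(seed)
  specs <- list(
    T2B = toy_receptor("T2B", "target"),
    T1B = toy_receptor("T1B", "antitarget")
  )
  if (scenario == "asp_only") {
    poses <- dplyr::bind_rows(lapply(1:4, function(i) {
      probe_pose(sprintf("cmpd%02d", i), "T2B", 1L,
        score = -9 + i * 0.5,
        asp_d = 2.8, sbp_d = 7.5, water_d = 9
      )
    }))
    expected <- tibble::tibble(
      compound_id = sprintf("cmpd%02d", 1:4),
      pass_obp_and_sbp = FALSE, pass_asp_or_water = TRUE
    )
  } else if (scenario == "boundary_5A") {
    d <- c(4.9, 5.0, 5.1)
    poses <- dplyr::bind_rows(lapply(seq_along(d), function(i) {
      probe_pose(sprintf("cmpd%02d", i), "T2B", 1L,
        score = -9 + i * 0.5,
        asp_d = 2.8, sbp_d = d[i], water_d = 9
      )
    }))
    expected <- tibble::tibble(
      compound_id = sprintf("cmpd%02d", 1:3),
      sbp_distance = d,
      pass_obp_and_sbp = c(TRUE, TRUE, FALSE),
      pass_asp_or_water = TRUE
    )
  } else if (scenario == "water_rescue") {
    rescued <- c(TRUE, FALSE, TRUE, FALSE)
    poses <- dplyr::bind_rows(lapply(1:4, function(i) {
      probe_pose(sprintf("cmpd%02d", i), "T2B", 1L,
        score = -9 + i * 0.5,
        asp_d = 6.0, sbp_d = 4.0, water_d = if (rescued[i]) 3.0 else 8.0
      )
    }))
    expected <- tibble::tibble(
      compound_id = sprintf("cmpd%02d", 1:4),
      pass_obp_and_sbp = FALSE, pass_asp_or_water = rescued
    )
  } else {
    n <- 30L
    n_planted <- 10L
    ids <- sprintf("cmpd%02d", seq_len(n))
    planted <- ids[seq_len(n_planted)]
    # planted compounds: best scores at the target, worst at the antitarget;
    # the rest interleave with mild seeded jitter
    s_target <- c(
      -15 + 0.1 * seq_len(n_planted),
      -9 + 0.1 * seq_len(n - n_planted) + stats::runif(n - n_planted, 0, 0.05)
    )
    s_anti <- c(
      -6 + 0.1 * seq_len(n_planted),
      -14 + 0.1 * seq_len(n - n_planted) + stats::runif(n - n_planted, 0, 0.05)
    )
    poses <- dplyr::bind_rows(
      dplyr::bind_rows(purrr::map2(ids, s_target, function(id, s) {
        probe_pose(id, "T2B", 1L, score = s)
      })),
      dplyr::bind_rows(purrr::map2(ids, s_anti, function(id, s) {
        probe_pose(id, "T1B", 1L, score = s)
      }))
    )
    expected <- list(planted_ids = planted, n = n)
  }
  list(poses = poses, specs = specs, expected = expected, scenario = scenario)
}
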