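#' Aggregate contact events into residue-pair occupancy profiles
#'
#' Collapses atomic contact events to the residue-pair level: a frame counts
#' toward a (pair, kind) when at least one event of that kind occurs in it.
#' Within each frame the participating atoms determine each residue's side
#' token: `m` when only main-chain atoms take part, `s` when any polar
#' side-chain atom takes part, `hs` when only the hydrophobic (apolar) atoms
#' of a side chain that also has a polar part take part; fully apolar side
#' chains take part as `s`.
#'
#' @param events Contact events from [detect_all()] (or the per-kind
#'   detectors) produced from `traj`.
#' @param traj The trajectory the events came from (supplies the frame
#'   denominator).
#' @return A `pair_profiles` tibble: one row per (ligand residue, receptor
#'   residue, kind, ligand side, receptor side) with the frame set (`frames`,
#'   list-column), `n_on` and `occupancy` = `n_on / n_frames(traj)`.
#' @export
accumulate <- function(events, traj) {
  nf <- n_frames(traj)
  frames_present <- unique(traj$frame)
  if (nrow(events) > 0 && !all(events$frame %in% frames_present)) {
    abort("events reference frames not present in the trajectory")
  }
  if (nrow(events) == 0) {
    out <- tibble(ligand_chain = character(), ligand_resnum = integer(),
                  ligand_resname = character(), receptor_chain = character(),
                  receptor_resnum = integer(), receptor_resname = character(),
                  kind = character(), lig_side = character(),
                  rec_side = character(), frames = list(), n_on = integer(),
                  occupancy = double())
    return(structure(out, n_frames = nf,
                     class = c("pair_profiles", class(tibble()))))
  }
  lig_roles <- atom_role(events$ligand_resname, events$ligand_atom)
  rec_roles <- atom_role(events$receptor_resname, events$receptor_atom)
  ev <- events %>%
    mutate(lig_sc = !lig_roles$backbone,
           lig_sc_polar = lig_sc & lig_roles$polarity != "apolar",
           rec_sc = !rec_roles$backbone,
           rec_sc_polar = rec_sc & rec_roles$polarity != "apolar")
  sides <- ev %>%
    group_by(.data$ligand_chain, .data$ligand_resnum, .data$ligand_resname,
             .data$receptor_chain, .data$receptor_resnum,
             .data$receptor_resname, .data$kind, .data$frame) %>%
    summarise(lig_any_sc = any(.data$lig_sc),
              lig_any_sc_polar = any(.data$lig_sc_polar),
              rec_any_sc = any(.data$rec_sc),
              rec_any_sc_polar = any(.data$rec_sc_polar),
              .groups = "drop") %>%
    mutate(lig_side = .side_token(.data$lig_any_sc_polar, .data$lig_any_sc,
                                  sidechain_has_polar(.data$ligand_resname)),
           rec_side = .side_token(.data$rec_any_sc_polar, .data$rec_any_sc,
                                  sidechain_has_polar(.data$receptor_resname)))
  out <- sides %>%
    group_by(.data$ligand_chain, .data$ligand_resnum, .data$ligand_resname,
             .data$receptor_chain, .data$receptor_resnum,
             .data$receptor_resname, .data$kind, .data$lig_side,
             .data$rec_side) %>%
    summarise(frames = list(sort(unique(.data$frame))), .groups = "drop") %>%
    mutate(n_on = lengths(.data$frames),
           occupancy = .data$n_on / nf) %>%
    arrange(.data$ligand_resnum, .data$receptor_resnum, .data$kind)
  structure(out, n_frames = nf,
            class = c("pair_profiles", class(tibble())))
}

#' Filter pair profiles to stably occupied interactions
#'
#' Emits one record per residue pair whose best single (kind, sides)
#' combination is present in strictly more than `threshold` of the analysed
#' frames ("stable over more than 30 percent of the simulation time" with
#' the default). When both a polar kind (salt bridge or hydrogen bond) and a
#' hydrophobic contact clear the threshold for the same pair, the polar kind
#' wins; ties beyond that resolve by higher occupancy, then salt bridge
#' before hydrogen bond before hydrophobic. The class label is the winning
#' sides pair, ligand side first (e.g. `"s-m"`), and each record is annotated
#' with the ligand residue's pY offset and interface region.
#'
#' @param profiles A `pair_profiles` tibble from [accumulate()].
#' @param peptide A [make_peptide()] definition covering the ligand chain.
#' @param threshold Occupancy fraction that must be strictly exceeded
#'   (default 0.30).
#' @return An `interaction_table` tibble: one row per stable pair with
#'   `offset`, `region`, `kind`, `class_label`, `n_on` and `occupancy`,
#'   ordered by ligand then receptor residue number. Carries the peptide,
#'   threshold and frame count as attributes.
#' @export
stable_interactions <- function(profiles, peptide, threshold = 0.30) {
  stopifnot(inherits(profiles, "pair_profiles"),
            inherits(peptide, "peptide_def"))
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold >= 0 && threshold < 1)) {
    abort("threshold must be a single fraction in [0, 1)")
  }
  nf <- attr(profiles, "n_frames")
  kind_rank <- c(saltbridge = 1, hbond = 2, hydrophobic = 3)
  cand <- profiles %>%
    filter(.data$occupancy > threshold) %>%
    mutate(polar = .data$kind %in% c("saltbridge", "hbond"))
  if (nrow(cand) > 0) {
    bad_chain <- unique(cand$ligand_chain[cand$ligand_chain != peptide$chain])
    if (length(bad_chain) > 0) {
      abort(paste0("stable ligand residues on chain(s) ",
                   paste(bad_chain, collapse = ", "),
                   " outside the peptide chain ", peptide$chain))
    }
    out_of_window <- unique(cand$ligand_resnum[
      cand$ligand_resnum < peptide$start_number |
        cand$ligand_resnum > peptide$end_number])
    if (length(out_of_window) > 0) {
      abort(paste0("stable ligand residue(s) outside the peptide window ",
                   peptide$start_number, "-", peptide$end_number, ": ",
                   paste(out_of_window, collapse = ", ")))
    }
  }
  records <- cand %>%
    group_by(.data$ligand_chain, .data$ligand_resnum, .data$ligand_resname,
             .data$receptor_chain, .data$receptor_resnum,
             .data$receptor_resname) %>%
    arrange(desc(.data$polar), desc(.data$occupancy),
            kind_rank[.data$kind], .data$lig_side, .data$rec_side,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(offset = .data$ligand_resnum - peptide$py_number,
           region = region_of(.data$offset),
           class_label = paste(.data$lig_side, .data$rec_side, sep = "-")) %>%
    arrange(.data$ligand_resnum, .data$receptor_resnum) %>%
    select("ligand_chain", "ligand_resnum", "ligand_resname", "offset",
           "region", "receptor_chain", "receptor_resnum", "receptor_resname",
           "kind", "class_label", "lig_side", "rec_side", "n_on", "occupancy")
  structure(records, peptide = peptide, threshold = threshold, n_frames = nf,
            class = c("interaction_table", class(tibble())))
}

#' Minimum inter-residue heavy-atom distance per frame
#'
#' Time series of the minimum cross-residue heavy-atom distance between one
#' ligand residue and one receptor residue, optionally over a frame window
#' (e.g. the final stretch of a production run).
#'
#' @param traj A `md_trajectory`.
#' @param ligand_chain,ligand_resnum Ligand residue.
#' @param receptor_chain,receptor_resnum Receptor residue.
#' @param window Integer vector of frame indices to include (default: all
#'   frames). An empty window is an error.
#' @return A `contact_timeseries` tibble with `frame`, `time_ps`
#'   (`frame * dt`), `distance` (Angstrom).
#' @export
distance_timeseries <- function(traj, ligand_chain, ligand_resnum,
                                receptor_chain, receptor_resnum,
                                window = NULL) {
  traj <- as_trajectory(traj, dt = frame_dt(traj), validate = FALSE)
  if (is.null(window)) window <- unique(traj$frame)
  window <- as.integer(window)
  if (length(window) == 0) abort("empty frame window")
  missing_frames <- setdiff(window, unique(traj$frame))
  if (length(missing_frames) > 0) {
    abort(paste0("window frames not in trajectory: ",
                 paste(head(missing_frames, 5), collapse = ", ")))
  }
  pick <- function(ch, rn, label) {
    a <- traj %>%
      filter(.data$chain == ch, .data$resnum == rn, .data$element != "H",
             .data$frame %in% window)
    if (nrow(a) == 0) {
      abort(paste0(label, " residue ", ch, ":", rn, " not found"))
    }
    a
  }
  la <- pick(ligand_chain, ligand_resnum, "ligand")
  ra <- pick(receptor_chain, receptor_resnum, "receptor")
  dt <- frame_dt(traj)
  out <- inner_join(
    la %>% select("frame", lx = "x", ly = "y", lz = "z"),
    ra %>% select("frame", rx = "x", ry = "y", rz = "z"),
    by = "frame", relationship = "many-to-many") %>%
    mutate(d = sqrt((.data$lx - .data$rx)^2 + (.data$ly - .data$ry)^2 +
                      (.data$lz - .data$rz)^2)) %>%
    group_by(.data$frame) %>%
    summarise(distance = min(.data$d), .groups = "drop") %>%
    mutate(time_ps = .data$frame * dt) %>%
    arrange(.data$frame) %>%
    select("frame", "time_ps", "distance")
  structure(out,
            ligand = paste0(ligand_chain, ":", ligand_resnum),
            receptor = paste0(receptor_chain, ":", receptor_resnum),
            class = c("contact_timeseries", class(tibble())))
}
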