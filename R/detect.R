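#' Geometric detection parameters
#'
#' Cutoffs for the three interaction classes, with defaults matching the
#' common VMD-style criteria for analysing solute contacts in MD snapshots:
#' 3.2 Angstrom between the oxygen and nitrogen atoms of salt-bridged
#' residues, 3.0 Angstrom between the heavy atoms of a hydrogen bond together
#' with a donor-hydrogen-acceptor angle of at least 120 degrees, and
#' 5.0 Angstrom between apolar heavy atoms for hydrophobic contacts. All
#' comparisons are inclusive: a distance exactly at the cutoff (and an angle
#' exactly at the minimum) is detected.
#'
#' @param saltbridge_cutoff Max O-N distance (Angstrom) for salt bridges.
#' @param hbond_cutoff Max donor-acceptor heavy-atom distance (Angstrom).
#' @param hbond_angle_min Min D-H-A angle in degrees (180 = linear). Applied
#'   only when the donor carries at least one hydrogen in the structure;
#'   hydrogen-free structures are evaluated on distance alone.
#' @param hydrophobic_cutoff Max apolar heavy-atom distance (Angstrom).
#' @param protonated_his Treat His ND1/NE2 as cationic (default FALSE, so
#'   histidine hydrogen-bonds but does not salt-bridge).
#' @return A `detection_params` list.
#' @export
detection_params <- function(saltbridge_cutoff = 3.2, hbond_cutoff = 3.0,
                             hbond_angle_min = 120, hydrophobic_cutoff = 5.0,
                             protonated_his = FALSE) {
  stopifnot(saltbridge_cutoff > 0, hbond_cutoff > 0, hydrophobic_cutoff > 0,
            hbond_angle_min > 0, hbond_angle_min <= 180,
            is.logical(protonated_his), length(protonated_his) == 1)
  structure(list(saltbridge_cutoff = saltbridge_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 hbond_angle_min = hbond_angle_min,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 protonated_his = protonated_his),
            class = "detection_params")
}

# slack absorbing double rounding so boundary fixtures are exact
.dist_eps <- 1e-9
.angle_eps <- 1e-9

.empty_events <- function() {
  tibble(frame = integer(), kind = character(),
         ligand_chain = character(), ligand_resnum = integer(),
         ligand_resname = character(), ligand_atom = character(),
         ligand_serial = integer(),
         receptor_chain = character(), receptor_resnum = integer(),
         receptor_resname = character(), receptor_atom = character(),
         receptor_serial = integer(),
         distance = double(), angle = double())
}

# Shared worker: per-frame detection of the requested kinds over the whole
# trajectory at once (topology is frame-invariant, so candidate atom pairs
# are computed once and distances vectorised across frames).
.detect_core <- function(traj, ligand_chain, receptor_chain,
                         params = detection_params(),
                         kinds = c("saltbridge", "hbond", "hydrophobic")) {
  stopifnot(inherits(params, "detection_params"))
  traj <- as_trajectory(traj, dt = frame_dt(traj), validate = FALSE)
  f0 <- min(traj$frame)
  top <- traj %>% filter(.data$frame == f0)
  for (ch in c(ligand_chain, receptor_chain)) {
    if (!ch %in% top$chain || sum(top$chain == ch) == 0) {
      warn(paste0("chain ", ch, " has no atoms; returning no events"))
      return(.empty_events())
    }
  }
  side_top <- function(ch) {
    t <- top %>% filter(.data$chain == ch, .data$element != "H")
    roles <- atom_role(t$resname, t$atomname)
    roles <- .role_flags(roles, protonated_his = params$protonated_his)
    t$key <- paste(t$chain, t$resnum, t$atomname, sep = "|")
    dplyr::bind_cols(t, roles[, c("backbone", "polarity", "is_donor",
                                  "is_acceptor", "is_cation_n", "is_anion_o",
                                  "is_apolar")])
  }
  lig <- side_top(ligand_chain)
  rec <- side_top(receptor_chain)
  coords <- traj %>%
    mutate(key = paste(.data$chain, .data$resnum, .data$atomname, sep = "|")) %>%
    select("frame", "key", "x", "y", "z")

  pair_tbl <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) {
      return(tibble(lig_key = character(), rec_key = character()))
    }
    cross_join(tibble(lig_key = a$key), tibble(rec_key = b$key))
  }
  with_dist <- function(pairs, cutoff) {
    if (nrow(pairs) == 0) {
      return(dplyr::mutate(pairs, frame = integer(), distance = double()))
    }
    ev <- pairs %>%
      inner_join(rename(coords, lig_key = "key", lx = "x", ly = "y", lz = "z"),
                 by = "lig_key", relationship = "many-to-many") %>%
      inner_join(rename(coords, rec_key = "key", rx = "x", ry = "y", rz = "z"),
                 by = c("rec_key", "frame")) %>%
      mutate(distance = sqrt((.data$lx - .data$rx)^2 +
                               (.data$ly - .data$ry)^2 +
                               (.data$lz - .data$rz)^2)) %>%
      filter(.data$distance <= cutoff + .dist_eps)
    ev
  }

  out <- list()

  sb <- NULL
  if (any(c("saltbridge", "hbond") %in% kinds)) {
    sb_pairs <- bind_rows(
      pair_tbl(lig[lig$is_anion_o, ], rec[rec$is_cation_n, ]),
      pair_tbl(lig[lig$is_cation_n, ], rec[rec$is_anion_o, ]))
    sb <- with_dist(sb_pairs, params$saltbridge_cutoff) %>%
      mutate(kind = "saltbridge", angle = NA_real_)
  }
  if ("saltbridge" %in% kinds) out$saltbridge <- sb

  if ("hbond" %in% kinds) {
    hb_pairs <- bind_rows(
      pair_tbl(lig[lig$is_donor, ], rec[rec$is_acceptor, ]) %>%
        mutate(donor_side = "lig"),
      pair_tbl(lig[lig$is_acceptor, ], rec[rec$is_donor, ]) %>%
        mutate(donor_side = "rec"))
    hb <- with_dist(hb_pairs, params$hbond_cutoff)
    if (nrow(hb) > 0) {
      hmap <- .donor_hydrogens(top, c(ligand_chain, receptor_chain))
      hb <- hb %>%
        mutate(donor_key = ifelse(.data$donor_side == "lig",
                                  .data$lig_key, .data$rec_key)) %>%
        left_join(hmap, by = "donor_key",
                  relationship = "many-to-many") %>%
        left_join(rename(coords, h_key = "key", hx = "x", hy = "y", hz = "z"),
                  by = c("h_key", "frame")) %>%
        mutate(dx = ifelse(.data$donor_side == "lig", .data$lx, .data$rx),
               dy = ifelse(.data$donor_side == "lig", .data$ly, .data$ry),
               dz = ifelse(.data$donor_side == "lig", .data$lz, .data$rz),
               ax = ifelse(.data$donor_side == "lig", .data$rx, .data$lx),
               ay = ifelse(.data$donor_side == "lig", .data$ry, .data$ly),
               az = ifelse(.data$donor_side == "lig", .data$rz, .data$lz),
               angle = .dha_angle(.data$dx, .data$dy, .data$dz,
                                  .data$hx, .data$hy, .data$hz,
                                  .data$ax, .data$ay, .data$az),
               pass = is.na(.data$h_key) |
                 .data$angle >= params$hbond_angle_min - .angle_eps) %>%
        group_by(.data$lig_key, .data$rec_key, .data$frame,
                 .data$distance) %>%
        summarise(ok = any(.data$pass),
                  angle = ifelse(any(.data$pass & !is.na(.data$angle)),
                                 max(.data$angle[.data$pass], na.rm = TRUE),
                                 NA_real_),
                  .groups = "drop") %>%
        filter(.data$ok) %>%
        select(-"ok") %>%
        mutate(kind = "hbond")
      # a pair already reported as a salt bridge in the same frame is not
      # double-reported as a hydrogen bond
      hb <- anti_join(hb, sb, by = c("lig_key", "rec_key", "frame"))
    } else {
      hb <- hb %>% mutate(kind = character(0), angle = double(0))
    }
    out$hbond <- hb
  }

  if ("hydrophobic" %in% kinds) {
    ph_pairs <- pair_tbl(lig[lig$is_apolar, ], rec[rec$is_apolar, ])
    out$hydrophobic <- with_dist(ph_pairs, params$hydrophobic_cutoff) %>%
      mutate(kind = "hydrophobic", angle = NA_real_)
  }

  ev <- bind_rows(lapply(out, function(d) {
    if (is.null(d) || nrow(d) == 0) NULL else
      d[, c("frame", "kind", "lig_key", "rec_key", "distance", "angle")]
  }))
  if (is.null(ev) || nrow(ev) == 0) return(.empty_events())

  lig_info <- lig %>%
    select(lig_key = "key", ligand_chain = "chain", ligand_resnum = "resnum",
           ligand_resname = "resname", ligand_atom = "atomname",
           ligand_serial = "serial")
  rec_info <- rec %>%
    select(rec_key = "key", receptor_chain = "chain",
           receptor_resnum = "resnum", receptor_resname = "resname",
           receptor_atom = "atomname", receptor_serial = "serial")
  ev %>%
    inner_join(lig_info, by = "lig_key") %>%
    inner_join(rec_info, by = "rec_key") %>%
    select(-"lig_key", -"rec_key") %>%
    arrange(.data$frame, .data$ligand_serial, .data$receptor_serial,
            .data$kind) %>%
    select("frame", "kind", "ligand_chain", "ligand_resnum", "ligand_resname",
           "ligand_atom", "ligand_serial", "receptor_chain",
           "receptor_resnum", "receptor_resname", "receptor_atom",
           "receptor_serial", "distance", "angle")
}

# donor heavy atom -> attached hydrogens, assigned on the first frame:
# hydrogens of the same residue within 1.3 A of the donor.
.donor_hydrogens <- function(top, chains) {
  t <- top %>% filter(.data$chain %in% chains)
  h <- t %>% filter(.data$element == "H")
  heavy <- t %>% filter(.data$element != "H")
  if (nrow(h) == 0 || nrow(heavy) == 0) {
    return(tibble(donor_key = character(), h_key = character()))
  }
  cand <- inner_join(
    heavy %>% select("chain", "resnum", datom = "atomname",
                     dx = "x", dy = "y", dz = "z"),
    h %>% select("chain", "resnum", hatom = "atomname",
                 hx = "x", hy = "y", hz = "z"),
    by = c("chain", "resnum"), relationship = "many-to-many") %>%
    filter((.data$dx - .data$hx)^2 + (.data$dy - .data$hy)^2 +
             (.data$dz - .data$hz)^2 <= 1.3^2)
  tibble(donor_key = paste(cand$chain, cand$resnum, cand$datom, sep = "|"),
         h_key = paste(cand$chain, cand$resnum, cand$hatom, sep = "|"))
}

# D-H-A angle in degrees (angle at the hydrogen; 180 = linear).
.dha_angle <- function(dx, dy, dz, hx, hy, hz, ax, ay, az) {
  v1x <- dx - hx; v1y <- dy - hy; v1z <- dz - hz
  v2x <- ax - hx; v2y <- ay - hy; v2z <- az - hz
  dot <- v1x * v2x + v1y * v2y + v1z * v2z
  nn <- sqrt(v1x^2 + v1y^2 + v1z^2) * sqrt(v2x^2 + v2y^2 + v2z^2)
  acos(pmin(1, pmax(-1, dot / nn))) * 180 / pi
}

#' Detect salt bridges between two chains
#'
#' One event per cross-chain pair of an anionic oxygen and a cationic
#' nitrogen (per the chemistry table) at a distance up to and including the
#' cutoff, evaluated in every frame of the input.
#'
#' @param frame A `md_trajectory` (a single frame or a whole trajectory).
#' @param ligand_chain,receptor_chain Chain identifiers.
#' @param params A [detection_params()] object.
#' @return A tibble of contact events: one row per atom pair per frame with
#'   `frame`, `kind`, ligand/receptor atom identifiers, `distance`, `angle`
#'   (NA except for hydrogen bonds scored through an explicit hydrogen).
#' @export
detect_salt_bridges <- function(frame, ligand_chain, receptor_chain,
                                params = detection_params()) {
  .detect_core(frame, ligand_chain, receptor_chain, params, "saltbridge")
}

#' Detect hydrogen bonds between two chains
#'
#' One event per cross-chain donor/acceptor heavy-atom pair within the
#' distance cutoff. When the donor carries at least one hydrogen in the
#' structure, the best donor-hydrogen-acceptor angle must also reach the
#' angle minimum and is recorded; hydrogen-free donors are admitted on
#' distance alone with an absent angle. A pair already reported as a salt
#' bridge in the same frame is not double-reported here.
#'
#' @inheritParams detect_salt_bridges
#' @return A tibble of contact events; see [detect_salt_bridges()].
#' @export
detect_hydrogen_bonds <- function(frame, ligand_chain, receptor_chain,
                                  params = detection_params()) {
  .detect_core(frame, ligand_chain, receptor_chain, params, "hbond")
}

#' Detect hydrophobic contacts between two chains
#'
#' One event per cross-chain pair of apolar heavy atoms (carbon/sulfur not
#' bonded to N or O, per the chemistry table) within the cutoff.
#'
#' @inheritParams detect_salt_bridges
#' @return A tibble of contact events; see [detect_salt_bridges()].
#' @export
detect_hydrophobic <- function(frame, ligand_chain, receptor_chain,
                               params = detection_params()) {
  .detect_core(frame, ligand_chain, receptor_chain, params, "hydrophobic")
}

#' Detect all contact kinds over a whole trajectory
#'
#' Concatenation of the per-frame salt-bridge, hydrogen-bond and hydrophobic
#' detections with deterministic ordering (frame, ligand atom serial,
#' receptor atom serial).
#'
#' @param traj A `md_trajectory`.
#' @inheritParams detect_salt_bridges
#' @return A tibble of contact events; see [detect_salt_bridges()].
#' @export
detect_all <- function(traj, ligand_chain, receptor_chain,
                       params = detection_params()) {
  .detect_core(traj, ligand_chain, receptor_chain, params,
               c("saltbridge", "hbond", "hydrophobic"))
}
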