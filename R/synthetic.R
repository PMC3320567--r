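#' Describe one planted contact for the synthetic generator
#'
#' A planted contact pins one ligand key atom and one receptor key atom at
#' `on_distance` (inside the detection cutoff for `kind`) in the scheduled
#' "on" frames and at `off_distance` (outside it) otherwise.
#'
#' @param lig_resname,lig_resnum,lig_atom Ligand residue and key atom.
#' @param rec_resname,rec_resnum,rec_atom Receptor residue and key atom.
#' @param kind `"saltbridge"`, `"hbond"` or `"hydrophobic"`.
#' @param occupancy Target fraction of frames in contact.
#' @param schedule `"deterministic"` (evenly spaced on-frames, exact count)
#'   or `"bernoulli"` (i.i.d. per frame).
#' @param on_distance,off_distance Key-atom separations (Angstrom) in on/off
#'   frames; defaults sit comfortably inside/outside the kind's cutoff.
#' @return One-row tibble describing the contact.
#' @export
planted_contact <- function(lig_resname, lig_resnum, lig_atom,
                            rec_resname, rec_resnum, rec_atom,
                            kind = c("saltbridge", "hbond", "hydrophobic"),
                            occupancy = 0.5,
                            schedule = c("deterministic", "bernoulli"),
                            on_distance = NULL, off_distance = NULL) {
  kind <- match.arg(kind)
  schedule <- match.arg(schedule)
  on_def <- c(saltbridge = 2.8, hbond = 2.7, hydrophobic = 4.5)
  off_def <- c(saltbridge = 6.5, hbond = 6.0, hydrophobic = 8.5)
  tibble(lig_resname = lig_resname, lig_resnum = as.integer(lig_resnum),
         lig_atom = lig_atom, rec_resname = rec_resname,
         rec_resnum = as.integer(rec_resnum), rec_atom = rec_atom,
         kind = kind, occupancy = occupancy, schedule = schedule,
         on_distance = if (is.null(on_distance)) unname(on_def[kind]) else on_distance,
         off_distance = if (is.null(off_distance)) unname(off_def[kind]) else off_distance)
}

#' Specify a synthetic multi-frame complex
#'
#' Validates a planted-contact schedule against the detection cutoffs: each
#' `on_distance` must be at most its kind's cutoff and each `off_distance`
#' beyond it, both with a margin of at least four times `jitter_sigma` so the
#' Gaussian positional jitter cannot flip a frame across the cutoff; two
#' contacts must not force incompatible geometry (a receptor residue used
#' twice, one ligand residue with two different key atoms, or a duplicated
#' residue pair).
#'
#' @param planted Tibble of [planted_contact()] rows.
#' @param n_frames Number of frames (default 100).
#' @param dt Frame spacing, ps (default 1).
#' @param jitter_sigma Isotropic Gaussian jitter per atom per frame,
#'   Angstrom (default 0.05).
#' @param seed Single integer driving all randomness (per-contact Bernoulli
#'   streams are derived from it by stable hashing of the contact index).
#' @param ligand Optional tibble (`resnum`, `resname`) giving the full ligand
#'   chain; defaults to the residues named in `planted`.
#' @param ligand_chain,receptor_chain Chain identifiers (defaults B and A).
#' @param hydrogens Place an explicit hydrogen on the donor of each planted
#'   hydrogen bond (default TRUE) so the angle criterion is exercised.
#' @param params [detection_params()] the spec is validated against.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(planted, n_frames = 100, dt = 1,
                           jitter_sigma = 0.05, seed = 1, ligand = NULL,
                           ligand_chain = "B", receptor_chain = "A",
                           hydrogens = TRUE, params = detection_params()) {
  planted <- as_tibble(planted)
  if (nrow(planted) == 0) abort("at least one planted contact is required")
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (jitter_sigma < 0) abort("jitter_sigma must be >= 0")
  if (any(planted$occupancy < 0 | planted$occupancy > 1)) {
    abort("planted occupancy must be within [0, 1]")
  }
  cuts <- c(saltbridge = params$saltbridge_cutoff,
            hbond = params$hbond_cutoff,
            hydrophobic = params$hydrophobic_cutoff)
  cut <- unname(cuts[planted$kind])
  if (any(planted$on_distance > cut)) {
    abort("on_distance exceeds the detection cutoff for its kind")
  }
  if (any(planted$off_distance <= cut)) {
    abort("off_distance must lie beyond the detection cutoff")
  }
  margin <- pmin(cut - planted$on_distance, planted$off_distance - cut)
  if (jitter_sigma > 0 && any(margin < 4 * jitter_sigma)) {
    abort("on/off distances must clear the cutoff by at least 4 * jitter_sigma")
  }
  if (anyDuplicated(planted[, c("lig_resnum", "rec_resnum")]) > 0) {
    abort("conflicting placements: duplicated ligand/receptor residue pair")
  }
  if (anyDuplicated(planted$rec_resnum) > 0) {
    abort("conflicting placements: a receptor residue is used by two planted contacts")
  }
  key_per_lig <- planted %>%
    distinct(.data$lig_resnum, .data$lig_atom, .data$lig_resname)
  if (anyDuplicated(key_per_lig$lig_resnum) > 0) {
    abort("conflicting placements: one ligand residue with two different key atoms")
  }
  if (is.null(ligand)) {
    ligand <- planted %>%
      distinct(resnum = .data$lig_resnum, resname = .data$lig_resname) %>%
      arrange(.data$resnum)
  } else {
    ligand <- as_tibble(ligand) %>% arrange(.data$resnum)
    chk <- planted %>%
      left_join(ligand, by = c(lig_resnum = "resnum"))
    if (any(is.na(chk$resname) | chk$resname != chk$lig_resname)) {
      abort("planted ligand residues must appear in the ligand definition with matching residue names")
    }
  }
  # key atoms must be known to the chemistry table
  atom_role(c(planted$lig_resname, planted$rec_resname),
            c(planted$lig_atom, planted$rec_atom))
  structure(list(planted = planted, n_frames = as.integer(n_frames), dt = dt,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed),
                 ligand = ligand, ligand_chain = ligand_chain,
                 receptor_chain = receptor_chain, hydrogens = hydrogens,
                 params = params),
            class = "synthetic_spec")
}

# evenly spread k on-frames over n (Bresenham spacing); |result| == k
.deterministic_on_frames <- function(n, k) {
  if (k <= 0) return(integer(0))
  as.integer(floor((0:(k - 1)) * n / k))
}

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.hash_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

# schematic residue template: key atom at the stalk tip, remaining heavy
# atoms 1.3 A apart behind it along the approach axis (rotamer-accurate
# geometry is a non-goal; detection only needs names, roles and distances)
.template_atoms <- function(resname, key_atom = NULL,
                            chemistry = chemistry_table()) {
  atoms <- chemistry %>%
    filter(.data$resname == !!resname,
           !.data$atomname %in% c("OXT", "OP1", "OP2", "OP3")) %>%
    pull("atomname")
  if (is.null(key_atom)) key_atom <- atoms[1]
  if (!key_atom %in% atoms) {
    abort(paste0("key atom ", key_atom, " not in template for ", resname))
  }
  c(key_atom, setdiff(atoms, key_atom))
}

# fibonacci directions in a cone of half-angle `cap` degrees around +y
.cone_dirs <- function(m, cap = 40) {
  if (m == 1) return(matrix(c(0, 1, 0), nrow = 1))
  j <- seq_len(m) - 1
  cosc <- cos(cap * pi / 180)
  ct <- 1 - (1 - cosc) * ((j + 0.5) / m)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- j * pi * (3 - sqrt(5))
  cbind(st * cos(phi), ct, st * sin(phi))
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Builds a fixed-topology two-chain complex whose planted key-atom pairs sit
#' exactly at their on/off distances according to each contact's schedule,
#' with Gaussian positional jitter on every atom. Ligand residues are placed
#' 15 Angstrom apart; each receptor residue approaches its ligand partner
#' along its own ray, so non-planted atoms stay at least 8 Angstrom from the
#' opposing chain and no accidental contacts arise. The same seed always
#' yields a bit-identical trajectory.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trajectory` (a `md_trajectory`) and `truth` (tibble:
#'   one row per planted contact with the exact on-frame set, expected
#'   occupancy and expected class label).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pl <- spec$planted
  nf <- spec$n_frames
  frames <- 0:(nf - 1)

  # schedules
  on_frames <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    if (pl$schedule[i] == "deterministic") {
      k <- round(pl$occupancy[i] * nf)
      on_frames[[i]] <- .deterministic_on_frames(nf, k)
    } else {
      on_frames[[i]] <- .with_seed(.hash_seed(spec$seed, i), {
        which(stats::runif(nf) < pl$occupancy[i]) - 1L
      })
    }
  }

  # ligand geometry: residue index i at x = 15*i, stalk along -y
  lig <- spec$ligand %>%
    mutate(tipx = 15 * (row_number() - 1), tipy = 0, tipz = 0)
  key_of <- setNames(as.list(pl$lig_atom), as.character(pl$lig_resnum))
  static <- list()
  for (i in seq_len(nrow(lig))) {
    key <- key_of[[as.character(lig$resnum[i])]]
    atoms <- .template_atoms(lig$resname[i], key)
    static[[length(static) + 1]] <- tibble(
      chain = spec$ligand_chain, resnum = lig$resnum[i],
      resname = lig$resname[i], atomname = atoms,
      x = lig$tipx[i], y = -1.3 * (seq_along(atoms) - 1), z = 0)
  }

  # per-contact ray directions, fanned per ligand residue
  pl <- pl %>%
    group_by(.data$lig_resnum) %>%
    mutate(ray = row_number(), nray = n()) %>%
    ungroup()
  dirs <- matrix(0, nrow(pl), 3)
  for (rn in unique(pl$lig_resnum)) {
    idx <- which(pl$lig_resnum == rn)
    dirs[idx, ] <- .cone_dirs(length(idx))
  }

  dyn <- list()
  dists <- list()
  for (i in seq_len(nrow(pl))) {
    li <- match(pl$lig_resnum[i], lig$resnum)
    tip <- c(lig$tipx[li], 0, 0)
    dir <- dirs[i, ]
    atoms <- .template_atoms(pl$rec_resname[i], pl$rec_atom[i])
    ax <- 1.3 * (seq_along(atoms) - 1)
    unit <- tibble(chain = spec$receptor_chain, resnum = pl$rec_resnum[i],
                   resname = pl$rec_resname[i], atomname = atoms, ax_off = ax)
    if (spec$hydrogens && pl$kind[i] == "hbond") {
      lig_role <- .role_flags(atom_role(pl$lig_resname[i], pl$lig_atom[i]))
      rec_role <- .role_flags(atom_role(pl$rec_resname[i], pl$rec_atom[i]))
      hname <- sprintf("H%02d", i %% 100)
      if (lig_role$is_donor) {
        static[[length(static) + 1]] <- tibble(
          chain = spec$ligand_chain, resnum = pl$lig_resnum[i],
          resname = pl$lig_resname[i], atomname = hname,
          x = tip[1] + dir[1], y = dir[2], z = dir[3])
      } else if (rec_role$is_donor) {
        unit <- bind_rows(unit, tibble(
          chain = spec$receptor_chain, resnum = pl$rec_resnum[i],
          resname = pl$rec_resname[i], atomname = hname, ax_off = -1.0))
      } else {
        abort(paste0("planted hbond ", i,
                     ": neither key atom is a hydrogen-bond donor"))
      }
    }
    d_t <- ifelse(frames %in% on_frames[[i]], pl$on_distance[i],
                  pl$off_distance[i])
    m <- nrow(unit)
    df <- unit[rep(seq_len(m), times = nf), ]
    df$frame <- rep(frames, each = m)
    r <- rep(d_t, each = m) + df$ax_off
    df$x <- tip[1] + r * dir[1]
    df$y <- tip[2] + r * dir[2]
    df$z <- tip[3] + r * dir[3]
    dyn[[i]] <- df %>% select(-"ax_off")
    dists[[i]] <- d_t
  }

  static_tbl <- bind_rows(static)
  static_all <- static_tbl[rep(seq_len(nrow(static_tbl)), times = nf), ]
  static_all$frame <- rep(frames, each = nrow(static_tbl))
  atoms <- bind_rows(static_all, bind_rows(dyn))
  if (spec$jitter_sigma > 0) {
    noise <- .with_seed(.hash_seed(spec$seed, 999983L), {
      matrix(rnorm(3 * nrow(atoms), 0, spec$jitter_sigma), ncol = 3)
    })
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  # stable serials from the frame-0 atom ordering
  ord <- atoms %>%
    filter(.data$frame == 0) %>%
    arrange(.data$chain, .data$resnum, .data$atomname) %>%
    mutate(serial = row_number()) %>%
    select("chain", "resnum", "atomname", "serial")
  atoms <- atoms %>% inner_join(ord, by = c("chain", "resnum", "atomname"))
  traj <- as_trajectory(atoms, dt = spec$dt)

  side_of_key <- function(resname, atomname) {
    role <- atom_role(resname, atomname)
    .side_token(!role$backbone & role$polarity != "apolar", !role$backbone,
                sidechain_has_polar(resname))
  }
  truth <- pl %>%
    select(-"ray", -"nray") %>%
    mutate(contact = row_number(),
           on_frames = on_frames,
           n_on = lengths(on_frames),
           occupancy_observed = .data$n_on / nf,
           class_label = paste(side_of_key(.data$lig_resname, .data$lig_atom),
                               side_of_key(.data$rec_resname, .data$rec_atom),
                               sep = "-"))
  structure(list(trajectory = traj, truth = truth),
            n_frames = nf, seed = spec$seed)
}

#' A shipped fixture echoing a strong three-region binding pattern
#'
#' A 9-residue `GyRPQNVLT` phosphopeptide (residues 113-121, pY at 114) on
#' chain B against a mock receptor on chain A, planting one stable contact in
#' each interface region: a pY phosphate/lysine salt bridge (region I, the
#' classic pY pocket pairing), a Gln/Tyr side-chain hydrogen bond at pY+3
#' (region II), and a Val/Met hydrophobic contact at pY+5 (region III). All
#' three occupancies clear the 30 percent stability filter, so the rendered
#' table shows tight contacts in all three regions.
#'
#' @param n_frames Frames to generate (default 50).
#' @param seed RNG seed (default 42).
#' @return List with `trajectory`, `truth` and the `peptide` definition.
#' @export
three_region_fixture <- function(n_frames = 50, seed = 42) {
  peptide <- make_peptide(114, "GyRPQNVLT", chain = "B")
  planted <- bind_rows(
    planted_contact("PTR", 114, "O1P", "LYS", 591, "NZ",
                    kind = "saltbridge", occupancy = 0.8),
    planted_contact("GLN", 117, "NE2", "TYR", 640, "OH",
                    kind = "hbond", occupancy = 0.6),
    planted_contact("VAL", 119, "CG1", "MET", 648, "SD",
                    kind = "hydrophobic", occupancy = 0.5))
  spec <- synthetic_spec(planted, n_frames = n_frames, seed = seed,
                         ligand = peptide$residues[, c("resnum", "resname")],
                         ligand_chain = peptide$chain)
  out <- generate_trajectory(spec)
  out$peptide <- peptide
  out
}
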