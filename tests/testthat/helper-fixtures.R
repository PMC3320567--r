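# Fixture builders and an independent brute-force contact oracle.
# The oracle deliberately shares no code with the package detectors: plain
# double loops over atom pairs with explicit role tests.

# single-frame trajectory from (chain, resnum, resname, atomname, x, y, z)
frame_fixture <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r[[1]], resnum = as.integer(r[[2]]), resname = r[[3]],
               atomname = r[[4]], x = as.numeric(r[[5]]),
               y = as.numeric(r[[6]]), z = as.numeric(r[[7]]))
  }))
  df$frame <- 0L
  as_trajectory(df)
}

# random but chemically valid frame: n_res residues per chain, sampled from
# the chemistry table, atoms scattered in a box so some pairs land inside
# the cutoffs; optionally hydrogens on a few donors
random_frame <- function(seed, n_res_per_chain = 3, box = 8,
                         with_hydrogens = FALSE) {
  set.seed(seed)
  chem <- chemistry_table()
  resnames <- setdiff(unique(chem$resname), c("ACE", "NME"))
  rows <- list()
  hrows <- list()
  rn <- 0
  for (ch in c("B", "A")) {
    for (i in seq_len(n_res_per_chain)) {
      rn <- rn + 1
      res <- sample(resnames, 1)
      atoms <- chem$atomname[chem$resname == res & chem$atomname != "OXT" &
                               !chem$atomname %in% c("OP1", "OP2", "OP3")]
      n_keep <- sample(seq_len(length(atoms)), 1)
      atoms <- sample(atoms, n_keep)
      for (a in atoms) {
        pos <- runif(3, 0, box)
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, resnum = rn, resname = res, atomname = a,
          x = pos[1], y = pos[2], z = pos[3])
        if (with_hydrogens && runif(1) < 0.4) {
          role <- atom_role(res, a)
          pol <- role$polarity
          elem <- toupper(substr(sub("^[0-9]+", "", a), 1, 1))
          is_don <- pol %in% c("donor", "donor_and_acceptor") |
            (pol == "charged_positive" & elem == "N")
          if (is_don) {
            dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
            hrows[[length(hrows) + 1]] <- data.frame(
              chain = ch, resnum = rn, resname = res,
              atomname = paste0("H", substr(a, 2, 4), "X"),
              x = pos[1] + dirv[1], y = pos[2] + dirv[2],
              z = pos[3] + dirv[3])
          }
        }
      }
    }
  }
  df <- do.call(rbind, c(rows, hrows))
  df$frame <- 0L
  as_trajectory(df)
}

# --- brute-force oracle -----------------------------------------------------

.oracle_polarity <- function(res, atom, protonated_his = FALSE) {
  chem <- chemistry_table()
  pol <- chem$polarity[chem$resname == res & chem$atomname == atom]
  if (length(pol) != 1) stop("oracle: unknown atom ", res, " ", atom)
  if (protonated_his && res == "HIS" && atom %in% c("ND1", "NE2")) {
    pol <- "charged_positive"
  }
  pol
}

.oracle_elem <- function(atom) toupper(substr(sub("^[0-9]+", "", atom), 1, 1))

# all contacts of one kind in one frame, by exhaustive O(n^2) enumeration;
# returns a sorted character vector of "ligres|ligatom|recres|recatom" keys
brute_force_contacts <- function(traj, kind, ligand_chain = "B",
                                 receptor_chain = "A",
                                 params = detection_params()) {
  f0 <- min(traj$frame)
  at <- as.data.frame(traj[traj$frame == f0, ])
  heavy <- at[.oracle_elem(at$atomname) != "H", ]
  lig <- heavy[heavy$chain == ligand_chain, ]
  rec <- heavy[heavy$chain == receptor_chain, ]
  hyd <- at[.oracle_elem(at$atomname) == "H", ]
  out <- character(0)
  sb_keys <- character(0)
  for (i in seq_len(nrow(lig))) {
    pl <- .oracle_polarity(lig$resname[i], lig$atomname[i],
                           params$protonated_his)
    el <- .oracle_elem(lig$atomname[i])
    for (j in seq_len(nrow(rec))) {
      pr <- .oracle_polarity(rec$resname[j], rec$atomname[j],
                             params$protonated_his)
      er <- .oracle_elem(rec$atomname[j])
      d <- sqrt((lig$x[i] - rec$x[j])^2 + (lig$y[i] - rec$y[j])^2 +
                  (lig$z[i] - rec$z[j])^2)
      key <- paste(lig$resnum[i], lig$atomname[i], rec$resnum[j],
                   rec$atomname[j], sep = "|")
      is_sb <- ((pl == "charged_negative" && el == "O" &&
                   pr == "charged_positive" && er == "N") ||
                  (pl == "charged_positive" && el == "N" &&
                     pr == "charged_negative" && er == "O")) &&
        d <= params$saltbridge_cutoff + 1e-9
      if (is_sb) sb_keys <- c(sb_keys, key)
      if (kind == "saltbridge" && is_sb) out <- c(out, key)
      if (kind == "hydrophobic" && pl == "apolar" && pr == "apolar" &&
          d <= params$hydrophobic_cutoff + 1e-9) {
        out <- c(out, key)
      }
      if (kind == "hbond" && d <= params$hbond_cutoff + 1e-9) {
        don_l <- pl %in% c("donor", "donor_and_acceptor") ||
          (pl == "charged_positive" && el == "N")
        acc_l <- pl %in% c("acceptor", "donor_and_acceptor") ||
          (pl == "charged_negative" && el == "O")
        don_r <- pr %in% c("donor", "donor_and_acceptor") ||
          (pr == "charged_positive" && er == "N")
        acc_r <- pr %in% c("acceptor", "donor_and_acceptor") ||
          (pr == "charged_negative" && er == "O")
        angle_ok <- function(drow, arow) {
          hs <- hyd[hyd$chain == drow$chain & hyd$resnum == drow$resnum, ]
          if (nrow(hs) > 0) {
            d2 <- (hs$x - drow$x)^2 + (hs$y - drow$y)^2 + (hs$z - drow$z)^2
            hs <- hs[d2 <= 1.3^2, ]
          }
          if (nrow(hs) == 0) return(TRUE)
          for (k in seq_len(nrow(hs))) {
            v1 <- c(drow$x - hs$x[k], drow$y - hs$y[k], drow$z - hs$z[k])
            v2 <- c(arow$x - hs$x[k], arow$y - hs$y[k], arow$z - hs$z[k])
            ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang >= params$hbond_angle_min - 1e-9) return(TRUE)
          }
          FALSE
        }
        hit <- (don_l && acc_r && angle_ok(lig[i, ], rec[j, ])) ||
          (acc_l && don_r && angle_ok(rec[j, ], lig[i, ]))
        if (hit) out <- c(out, key)
      }
    }
  }
  if (kind == "hbond") out <- setdiff(out, sb_keys)
  sort(unique(out))
}

event_keys <- function(events) {
  sort(unique(paste(events$ligand_resnum, events$ligand_atom,
                    events$receptor_resnum, events$receptor_atom,
                    sep = "|")))
}
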