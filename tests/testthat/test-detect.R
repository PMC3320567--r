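test_that("salt bridges are detected up to and including the 3.2 A cutoff", {
  mk <- function(d) frame_fixture(
    list("B", 1, "LYS", "NZ", 0, 0, 0),
    list("A", 2, "ASP", "OD1", d, 0, 0))
  ev <- detect_salt_bridges(mk(2.8), "B", "A")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "saltbridge")
  expect_equal(ev$distance, 2.8)
  ev <- detect_salt_bridges(mk(3.2), "B", "A")  # boundary inclusive
  expect_equal(nrow(ev), 1)
  ev <- detect_salt_bridges(mk(3.21), "B", "A")
  expect_equal(nrow(ev), 0)
  # uncharged polar oxygen is not a salt-bridge partner
  ser <- frame_fixture(list("B", 1, "LYS", "NZ", 0, 0, 0),
                       list("A", 2, "SER", "OG", 2.8, 0, 0))
  expect_equal(nrow(detect_salt_bridges(ser, "B", "A")), 0)
})

test_that("hydrogen bonds honour the distance cutoff and 120 degree angle
           when a donor hydrogen is present", {
  linear <- frame_fixture(
    list("B", 1, "SER", "OG", 0, 0, 0),
    list("B", 1, "SER", "HG", 1, 0, 0),
    list("A", 2, "GLY", "O", 2.9, 0, 0))
  ev <- detect_hydrogen_bonds(linear, "B", "A")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$angle, 180)
  expect_equal(ev$distance, 2.9)

  # same donor/acceptor separation, hydrogen bent to a 100 degree D-H-A angle
  theta <- 100 * pi / 180
  r <- cos(theta) + sqrt(cos(theta)^2 + (2.9^2 - 1))
  bent <- frame_fixture(
    list("B", 1, "SER", "OG", 1, 0, 0),
    list("B", 1, "SER", "HG", 0, 0, 0),
    list("A", 2, "GLY", "O", r * cos(theta), r * sin(theta), 0))
  expect_equal(nrow(detect_hydrogen_bonds(bent, "B", "A")), 0)

  # hydrogen-free structure falls back to the distance criterion, angle absent
  bare <- frame_fixture(
    list("B", 1, "SER", "OG", 0, 0, 0),
    list("A", 2, "GLY", "O", 2.9, 0, 0))
  ev <- detect_hydrogen_bonds(bare, "B", "A")
  expect_equal(nrow(ev), 1)
  expect_true(is.na(ev$angle))
  far <- frame_fixture(
    list("B", 1, "SER", "OG", 0, 0, 0),
    list("A", 2, "GLY", "O", 3.05, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(far, "B", "A")), 0)
})

test_that("a salt-bridged pair is not double-reported as a hydrogen bond", {
  fr <- frame_fixture(
    list("B", 1, "LYS", "NZ", 0, 0, 0),
    list("A", 2, "ASP", "OD1", 2.8, 0, 0))
  expect_equal(nrow(detect_salt_bridges(fr, "B", "A")), 1)
  expect_equal(nrow(detect_hydrogen_bonds(fr, "B", "A")), 0)
  all_ev <- detect_all(fr, "B", "A")
  expect_equal(all_ev$kind, "saltbridge")
})

test_that("hydrophobic contacts include sulfur and respect the 5.0 A cutoff", {
  vm <- frame_fixture(
    list("B", 1, "VAL", "CG1", 0, 0, 0),
    list("A", 2, "MET", "SD", 4.5, 0, 0))
  ev <- detect_hydrophobic(vm, "B", "A")
  expect_equal(nrow(ev), 1)
  vl <- frame_fixture(
    list("B", 1, "VAL", "CG1", 0, 0, 0),
    list("A", 2, "LEU", "CD1", 5.5, 0, 0))
  expect_equal(nrow(detect_hydrophobic(vl, "B", "A")), 0)
  boundary <- frame_fixture(
    list("B", 1, "VAL", "CG1", 0, 0, 0),
    list("A", 2, "LEU", "CD1", 5.0, 0, 0))
  expect_equal(nrow(detect_hydrophobic(boundary, "B", "A")), 1)
})

test_that("each detector matches the brute-force oracle on random frames", {
  for (seed in 1:30) {
    traj <- random_frame(seed, n_res_per_chain = 3,
                         with_hydrogens = seed %% 2 == 0)
    for (kind in c("saltbridge", "hbond", "hydrophobic")) {
      got <- switch(kind,
                    saltbridge = detect_salt_bridges(traj, "B", "A"),
                    hbond = detect_hydrogen_bonds(traj, "B", "A"),
                    hydrophobic = detect_hydrophobic(traj, "B", "A"))
      expect_equal(event_keys(got), brute_force_contacts(traj, kind),
                   info = paste("seed", seed, kind))
    }
  }
})

test_that("enlarging cutoffs never removes events, shrinking never adds", {
  for (seed in c(3, 14, 27)) {
    traj <- random_frame(seed, n_res_per_chain = 4)
    small <- detection_params(saltbridge_cutoff = 2.8, hbond_cutoff = 2.6,
                              hydrophobic_cutoff = 4.0)
    big <- detection_params(saltbridge_cutoff = 4.0, hbond_cutoff = 3.6,
                            hydrophobic_cutoff = 6.5)
    for (fn in list(detect_salt_bridges, detect_hydrogen_bonds,
                    detect_hydrophobic)) {
      k_small <- event_keys(fn(traj, "B", "A", small))
      k_def <- event_keys(fn(traj, "B", "A", detection_params()))
      k_big <- event_keys(fn(traj, "B", "A", big))
      expect_true(all(k_small %in% k_def))
      expect_true(all(k_def %in% k_big))
    }
  }
})

test_that("swapping ligand and receptor labels preserves unordered pairs", {
  unordered <- function(ev) {
    sort(paste(pmin(ev$ligand_serial, ev$receptor_serial),
               pmax(ev$ligand_serial, ev$receptor_serial), ev$kind))
  }
  for (seed in c(5, 16)) {
    traj <- random_frame(seed, n_res_per_chain = 3, with_hydrogens = TRUE)
    fwd <- detect_all(traj, "B", "A")
    rev <- detect_all(traj, "A", "B")
    expect_equal(unordered(fwd), unordered(rev))
  }
})

test_that("detect_all equals the union of the three detectors with
           deterministic ordering", {
  fx <- three_region_fixture(n_frames = 10, seed = 2)
  traj <- fx$trajectory
  all_ev <- detect_all(traj, "B", "A")
  parts <- dplyr::bind_rows(detect_salt_bridges(traj, "B", "A"),
                            detect_hydrogen_bonds(traj, "B", "A"),
                            detect_hydrophobic(traj, "B", "A"))
  key <- function(e) sort(paste(e$frame, e$ligand_serial, e$receptor_serial,
                                e$kind))
  expect_equal(key(all_ev), key(parts))
  ord <- order(all_ev$frame, all_ev$ligand_serial, all_ev$receptor_serial)
  expect_equal(ord, seq_len(nrow(all_ev)))
})

test_that("a missing chain yields an empty event table with a warning", {
  solo <- frame_fixture(list("A", 1, "GLY", "CA", 0, 0, 0))
  expect_warning(ev <- detect_all(solo, "B", "A"), "no atoms")
  expect_equal(nrow(ev), 0)
})

test_that("protonated_his promotes histidine to a salt-bridge cation", {
  fr <- frame_fixture(
    list("B", 1, "HIS", "NE2", 0, 0, 0),
    list("A", 2, "ASP", "OD1", 3.0, 0, 0))
  expect_equal(nrow(detect_salt_bridges(fr, "B", "A")), 0)
  # neutral His still hydrogen-bonds through the same nitrogen
  expect_equal(nrow(detect_hydrogen_bonds(fr, "B", "A")), 1)
  prot <- detection_params(protonated_his = TRUE)
  expect_equal(nrow(detect_salt_bridges(fr, "B", "A", prot)), 1)
})
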