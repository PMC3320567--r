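# minimal trajectory carrying only the frame structure (accumulate uses the
# trajectory for the frame denominator, events carry the atom identities)
dummy_traj <- function(nf) {
  as_trajectory(data.frame(frame = rep(0:(nf - 1), each = 2),
                           chain = c("B", "A"), resnum = c(1L, 2L),
                           resname = "GLY", atomname = "CA",
                           x = c(0, 50), y = 0, z = 0))
}

mk_events <- function(frames, kind, lig = c("B", 100, "PTR", "O1P"),
                      rec = c("A", 500, "LYS", "NZ")) {
  tibble::tibble(frame = as.integer(frames), kind = kind,
                 ligand_chain = lig[1], ligand_resnum = as.integer(lig[2]),
                 ligand_resname = lig[3], ligand_atom = lig[4],
                 ligand_serial = 1L,
                 receptor_chain = rec[1], receptor_resnum = as.integer(rec[2]),
                 receptor_resname = rec[3], receptor_atom = rec[4],
                 receptor_serial = 2L, distance = 2.8, angle = NA_real_)
}

test_that("occupancy is the fraction of frames with at least one event", {
  traj <- dummy_traj(10)
  pr <- accumulate(mk_events(c(0, 2, 4, 6), "saltbridge"), traj)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$occupancy, 0.4)
  expect_equal(pr$frames[[1]], c(0L, 2L, 4L, 6L))
  # atom-level multiplicity within a frame collapses to one frame count
  ev2 <- dplyr::bind_rows(mk_events(c(0, 0, 1), "saltbridge"),
                          mk_events(c(0, 1), "saltbridge",
                                    lig = c("B", 100, "PTR", "O2P")))
  pr2 <- accumulate(ev2, traj)
  expect_equal(pr2$occupancy, 0.2)
  pr3 <- accumulate(mk_events(0:9, "saltbridge"), traj)
  expect_equal(pr3$occupancy, 1.0)
  expect_error(accumulate(mk_events(12, "saltbridge"), traj),
               "frames not present")
})

test_that("planted occupancies are recovered exactly through the pipeline", {
  fx <- three_region_fixture(n_frames = 50, seed = 9)
  ev <- detect_all(fx$trajectory, "B", "A")
  pr <- accumulate(ev, fx$trajectory)
  for (i in seq_len(nrow(fx$truth))) {
    got <- pr[pr$ligand_resnum == fx$truth$lig_resnum[i] &
                pr$receptor_resnum == fx$truth$rec_resnum[i] &
                pr$kind == fx$truth$kind[i], ]
    expect_equal(got$occupancy, fx$truth$occupancy_observed[i])
    expect_equal(got$frames[[1]], fx$truth$on_frames[[i]])
  }
})

test_that("the stability filter is strictly greater-than the threshold", {
  traj <- dummy_traj(100)
  pep <- make_peptide(100, "GyRPQNVLT", "B")
  mk <- function(n_on, rec_num) {
    mk_events(seq_len(n_on) - 1, "saltbridge",
              rec = c("A", rec_num, "LYS", "NZ"))
  }
  ev <- dplyr::bind_rows(mk(29, 501), mk(30, 502), mk(31, 503))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(tab$receptor_resnum, 503)
  expect_equal(tab$occupancy, 0.31)
  expect_equal(tab$class_label, "s-s")
  expect_equal(tab$region, "I")
})

test_that("side tokens follow the m/s/hs rules", {
  traj <- dummy_traj(10)
  pep <- make_peptide(100, "GyRPQNVLT", "B")
  # ligand polar side chain vs receptor main chain -> s-m
  ev <- mk_events(0:4, "hbond", lig = c("B", 103, "GLN", "NE2"),
                  rec = c("A", 500, "GLY", "O"))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(tab$class_label, "s-m")
  expect_equal(tab$region, "II")
  # only apolar atoms of a polar-bearing side chain -> hs
  ev <- mk_events(0:4, "hydrophobic", lig = c("B", 103, "GLN", "CB"),
                  rec = c("A", 500, "TYR", "CE1"))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(tab$class_label, "hs-hs")
  # fully apolar side chain participates as s, never hs
  ev <- mk_events(0:4, "hydrophobic", lig = c("B", 105, "VAL", "CG1"),
                  rec = c("A", 500, "LEU", "CD1"))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(tab$class_label, "s-s")
  # polar side-chain involvement wins over apolar involvement within a frame
  ev <- dplyr::bind_rows(
    mk_events(0:4, "hbond", lig = c("B", 103, "GLN", "NE2"),
              rec = c("A", 500, "SER", "OG")),
    mk_events(0:4, "hbond", lig = c("B", 103, "GLN", "CB"),
              rec = c("A", 500, "SER", "OG")))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(tab$class_label, "s-s")
})

test_that("polar kinds take precedence over hydrophobic for the same pair", {
  traj <- dummy_traj(10)
  pep <- make_peptide(100, "GyRPQNVLT", "B")
  ev <- dplyr::bind_rows(
    mk_events(0:5, "hydrophobic", lig = c("B", 103, "GLN", "CB"),
              rec = c("A", 500, "TYR", "CE1")),
    mk_events(0:3, "hbond", lig = c("B", 103, "GLN", "NE2"),
              rec = c("A", 500, "TYR", "OH")))
  tab <- stable_interactions(accumulate(ev, traj), pep)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$kind, "hbond")
  expect_equal(tab$occupancy, 0.4)
})

test_that("raising the threshold never adds records; ordering is deterministic", {
  fx <- three_region_fixture(n_frames = 50, seed = 21)
  pr <- accumulate(detect_all(fx$trajectory, "B", "A"), fx$trajectory)
  prev <- NULL
  for (thr in c(0.0, 0.2, 0.45, 0.7, 0.9)) {
    tab <- stable_interactions(pr, fx$peptide, threshold = thr)
    key <- paste(tab$ligand_resnum, tab$receptor_resnum)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
    expect_false(is.unsorted(tab$ligand_resnum))
  }
})

test_that("ligand residues outside the peptide window are an error", {
  traj <- dummy_traj(10)
  pep <- make_peptide(100, "GyRPQNVLT", "B")
  ev <- mk_events(0:8, "saltbridge", lig = c("B", 300, "PTR", "O1P"))
  expect_error(stable_interactions(accumulate(ev, traj), pep),
               "outside the peptide window")
})

test_that("Bernoulli-schedule occupancies recover the rate within binomial
           bounds", {
  ok <- 0
  n <- 200
  p <- 0.5
  for (seed in 1:25) {
    planted <- planted_contact("PTR", 114, "O1P", "LYS", 591, "NZ",
                               kind = "saltbridge", occupancy = p,
                               schedule = "bernoulli")
    spec <- synthetic_spec(planted, n_frames = n, seed = seed,
                           jitter_sigma = 0)
    out <- generate_trajectory(spec)
    pr <- accumulate(detect_all(out$trajectory, "B", "A"), out$trajectory)
    got <- pr$occupancy[pr$kind == "saltbridge"]
    expect_equal(got, out$truth$occupancy_observed)
    if (abs(got - p) <= 3 * sqrt(p * (1 - p) / n)) ok <- ok + 1
  }
  expect_gte(ok, 24)
})

test_that("distance time series tracks rigid and sinusoidal geometries", {
  nf <- 24
  amp <- 1.5
  base <- 6
  d <- base + amp * sin(2 * pi * (0:(nf - 1)) / nf)
  atoms <- dplyr::bind_rows(
    data.frame(frame = 0:(nf - 1), chain = "B", resnum = 1L, resname = "GLY",
               atomname = "CA", x = 0, y = 0, z = 0),
    data.frame(frame = 0:(nf - 1), chain = "A", resnum = 2L, resname = "GLY",
               atomname = "CA", x = d, y = 0, z = 0))
  traj <- as_trajectory(atoms, dt = 1)
  ts <- distance_timeseries(traj, "B", 1, "A", 2)
  expect_equal(nrow(ts), nf)
  expect_equal(ts$distance, d)
  expect_equal(max(ts$distance) - min(ts$distance), 2 * amp, tolerance = 0.05)
  # rigid fixture: constant series
  fx <- three_region_fixture(n_frames = 5, seed = 3)
  spec0 <- synthetic_spec(fx$truth[1, c(1:6, 7)] |>
                            (\(p) planted_contact(p$lig_resname, p$lig_resnum,
                                                  p$lig_atom, p$rec_resname,
                                                  p$rec_resnum, p$rec_atom,
                                                  kind = "saltbridge",
                                                  occupancy = 1))(),
                          n_frames = 5, jitter_sigma = 0, seed = 1)
  rigid <- generate_trajectory(spec0)
  ts0 <- distance_timeseries(rigid$trajectory, "B", 114, "A", 591)
  expect_equal(diff(range(ts0$distance)), 0)
  # a final-15-of-24 window yields 15 values
  ts15 <- distance_timeseries(traj, "B", 1, "A", 2, window = 9:23)
  expect_equal(nrow(ts15), 15)
  expect_equal(ts15$frame, 9:23)
  expect_error(distance_timeseries(traj, "B", 1, "A", 2, window = integer(0)),
               "empty")
})
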