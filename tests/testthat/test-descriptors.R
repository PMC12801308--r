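# minimal frame builder: arbitrary atoms at arbitrary positions
make_frame <- function(residues, names, xyz) {
  atoms <- data.frame(residue_id = residues, atom_name = names,
                      mass = unname(fespath:::.atom_masses[names]),
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = xyz, time = 0), class = "traj_frame")
}

# frame with full backbone for the CV groups plus the two CA anchors
cv_frame <- function(g1_at = c(0, 0, 0), g2_at = c(3, 0, 0),
                     ca218 = c(0, 0, 0), ca250 = c(0, 0, 2)) {
  res <- c(rep(202:204, each = 4), 218, 250, rep(282:284, each = 4))
  nm <- c(rep(c("N", "CA", "C", "O"), 3), "CA", "CA",
          rep(c("N", "CA", "C", "O"), 3))
  xyz <- rbind(matrix(g1_at, 12, 3, byrow = TRUE),
               ca218, ca250,
               matrix(g2_at, 12, 3, byrow = TRUE))
  make_frame(res, nm, xyz)
}

test_that("collective variables match their defining geometry", {
  fr <- cv_frame()
  cv <- compute_cvs(fr)
  expect_equal(unname(cv["d1"]), 3.0, tolerance = 1e-12)
  expect_equal(unname(cv["d2"]), 2.0, tolerance = 1e-12)

  # missing atoms are reported by residue and name
  fr2 <- cv_frame()
  drop <- which(fr2$atoms$residue_id == 218)
  fr2$atoms <- fr2$atoms[-drop, ]
  fr2$xyz <- fr2$xyz[-drop, , drop = FALSE]
  expect_error(compute_cvs(fr2), "CA of residue 218")
})

test_that("CVs agree with an explicit mass-weighted brute-force oracle", {
  traj <- generate_helix_pair_trajectory(seq(150, 30, length.out = 100),
                                         noise_sd = 0.05, seed = 8)
  cv <- compute_cvs(traj)
  for (i in seq(1, 100, by = 7)) {
    expected <- brute_cvs(get_frame(traj, i))
    expect_equal(unname(c(cv$d1[i], cv$d2[i])), expected, tolerance = 1e-12)
  }
})

test_that("interhelical angle matches direct arccos evaluation", {
  angle_frame <- function(v1, v2) {
    make_frame(c(210, 221, 249, 267), rep("CA", 4),
               rbind(c(0, 0, 0), v1, c(5, 5, 5), c(5, 5, 5) + v2))
  }
  expect_equal(interhelical_angle(angle_frame(c(1, 0, 0), c(2, 0, 0))), 0,
               tolerance = 1e-9)
  expect_equal(interhelical_angle(angle_frame(c(1, 0, 0), c(-3, 0, 0))), 180,
               tolerance = 1e-9)
  set.seed(42)
  for (k in 1:1000) {
    v1 <- rnorm(3); v2 <- rnorm(3)
    expected <- acos(pmin(pmax(
      sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
    expect_equal(interhelical_angle(angle_frame(v1, v2)), expected,
                 tolerance = 1e-9)
  }
  expect_error(interhelical_angle(angle_frame(c(0, 0, 0), c(1, 0, 0))),
               "degenerate")
})

test_that("RMSD profile: identity, rigid motion, Procrustes oracle, symmetry", {
  traj <- generate_helix_pair_trajectory(c(90, 90, 70, 50), noise_sd = 0.04,
                                         seed = 12)
  prof <- rmsd_profile(traj, reference = 1L)
  expect_equal(prof$rmsd[1], 0, tolerance = 1e-9)

  # rigidly moved copy of the reference superposes to zero
  rot <- apply_random_rigid(get_frame(traj, 1), seed = 77)
  tr2 <- traj
  tr2$coords[, , 2] <- rot$xyz
  expect_equal(rmsd_profile(tr2, 1L)$rmsd[2], 0, tolerance = 1e-9)

  # single displaced atom: RMSD <= delta/sqrt(N), against the oracle
  delta <- 0.3
  N <- nrow(traj$atoms)
  tr3 <- traj
  tr3$coords[5, 1, 2] <- tr3$coords[5, 1, 1] + delta
  tr3$coords[, , 2] <- tr3$coords[, , 2] * 0 + traj$coords[, , 1]
  tr3$coords[5, 1, 2] <- tr3$coords[5, 1, 2] + delta
  got <- rmsd_profile(tr3, 1L)$rmsd[2]
  expect_lte(got, delta / sqrt(N) + 1e-12)
  expect_equal(got, brute_rmsd(tr3$coords[, , 2], tr3$coords[, , 1]),
               tolerance = 1e-12)

  # symmetry: RMSD(A onto B) == RMSD(B onto A)
  for (i in 2:4) {
    ab <- brute_rmsd(traj$coords[, , i], traj$coords[, , 1])
    ba <- brute_rmsd(traj$coords[, , 1], traj$coords[, , i])
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_equal(prof$rmsd[i], ab, tolerance = 1e-12)
  }

  # roster mismatch is an alignment error
  small <- traj
  small$atoms <- small$atoms[-1, ]
  expect_error(rmsd_profile(traj, structure(
    list(atoms = small$atoms, xyz = traj$coords[-1, , 1], time = 0),
    class = "traj_frame")), "roster")
})

test_that("descriptor matrix: shape, brute force, empty selection", {
  traj <- generate_helix_pair_trajectory(c(100, 40), noise_sd = 0.03,
                                         seed = 3)
  # 3 selected atoms -> 3 pairwise-distance columns
  D3 <- build_descriptors(traj, atom_names = "CA", residues = c(210, 240, 270))
  expect_identical(ncol(D3), 3L)
  expect_identical(nrow(D3), 2L)

  # default CA selection thins to <= 50 atoms; column count = n(n-1)/2
  D <- build_descriptors(traj)
  n_at <- (1 + sqrt(1 + 8 * ncol(D))) / 2
  expect_lte(n_at, 50)
  expect_identical(ncol(D), as.integer(choose(round(n_at), 2)))

  # brute-force nested-loop check on an explicit selection
  sel <- which(traj$atoms$atom_name == "CA" &
               traj$atoms$residue_id %in% seq(202, 284, by = 10))
  Ds <- build_descriptors(traj, residues = seq(202, 284, by = 10))
  expect_equal(unname(Ds[1, ]), brute_pairdists(traj$coords[, , 1], sel),
               tolerance = 1e-12)

  expect_error(build_descriptors(traj, atom_names = "CB"), "empty selection")
})

test_that("geometric observables are invariant under rigid motion", {
  traj <- generate_helix_pair_trajectory(c(120, 80, 40), noise_sd = 0.05,
                                         seed = 19)
  for (i in 1:3) {
    fr <- get_frame(traj, i)
    fr_t <- apply_random_rigid(fr, seed = 100 + i)
    expect_equal(compute_cvs(fr_t), compute_cvs(fr), tolerance = 1e-9)
    expect_equal(interhelical_angle(fr_t), interhelical_angle(fr),
                 tolerance = 1e-9)
  }
  # descriptor rows are invariant too
  tr2 <- traj
  for (i in 1:3)
    tr2$coords[, , i] <- apply_random_rigid(get_frame(traj, i),
                                            seed = 200 + i)$xyz
  expect_equal(build_descriptors(tr2), build_descriptors(traj),
               tolerance = 1e-9)
})
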