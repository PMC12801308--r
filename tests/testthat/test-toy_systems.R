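test_that("double-well construction locates minima and saddles", {
  pot <- make_double_well(rbind(c(-1, 0), c(1, 0)), depths = c(10, 10),
                          widths = 0.5)
  # symmetric wells: equal barriers both ways
  fmin <- potential_energy(pot, pot$known_minima)
  expect_equal(fmin[1], fmin[2], tolerance = 1e-10)
  expect_gte(nrow(pot$known_saddles), 1)
  bar <- pot$saddle_energies[1] - fmin
  expect_equal(bar[1], bar[2], tolerance = 1e-8)
  # minima are stationary points of the composed potential
  for (i in 1:2)
    expect_lt(sqrt(sum(potential_gradient(pot, pot$known_minima[i, ])^2)),
              1e-6)
})

test_that("single well has no saddles; coincident minima are rejected", {
  pot1 <- make_gaussian_wells(c(0.5, 0.5), depths = 10, widths = 0.3)
  expect_identical(nrow(pot1$known_saddles), 0L)
  expect_error(make_double_well(rbind(c(1, 1), c(1, 1)), depths = c(5, 5),
                                widths = 0.2),
               "coincident")
  expect_error(make_gaussian_wells(c(0, 0), depths = -1, widths = 0.2),
               "positive")
})

test_that("well offset equals the free-energy gap between basin minima", {
  # coordinates from a realistic two-basin layout; depths 11.37 kJ/mol apart
  pot <- make_double_well(rbind(c(0.45, 1.61), c(1.09, 1.97)),
                          depths = c(20, 20 - 11.37), widths = 0.15)
  # dense-grid evaluation oracle, no reliance on known_minima refinement
  ax <- seq(0.2, 1.4, length.out = 600)
  ay <- seq(1.3, 2.3, length.out = 600)
  pts <- cbind(rep(ax, times = length(ay)), rep(ay, each = length(ax)))
  G <- matrix(potential_energy(pot, pts), nrow = length(ax))
  n1 <- which.min(G)  # global minimum (deep well)
  # local minimum near the shallow well: restrict to its quadrant
  sub <- which(pts[, 1] > 0.8)
  n2 <- sub[which.min(G[sub])]
  gap <- as.numeric(G)[n2] - as.numeric(G)[n1]
  expect_equal(gap, 11.37, tolerance = 1e-3)
})

test_that("Langevin sampler: determinism, frozen dynamics, equipartition", {
  pot <- make_gaussian_wells(c(0, 0), depths = 1e-12, widths = 1,
                             conf_k = 50, conf_center = c(0, 0),
                             locate_saddles = FALSE)
  # zero potential, zero-ish temperature: position stays put
  still <- langevin_sample(
    make_gaussian_wells(c(0, 0), depths = 1e-300, widths = 1,
                        locate_saddles = FALSE),
    langevin_params(temperature = 1e-12, timestep = 1e-3, n_steps = 100,
                    seed = 3),
    x0 = c(0.2, 0.4))
  expect_equal(max(abs(still$x1 - 0.2)), 0, tolerance = 1e-6)
  expect_equal(max(abs(still$x2 - 0.4)), 0, tolerance = 1e-6)

  # same seed => bitwise-identical series
  p <- langevin_params(temperature = 310.15, timestep = 2e-4, n_steps = 2000,
                       seed = 11)
  s1 <- langevin_sample(pot, p, x0 = c(0, 0))
  s2 <- langevin_sample(pot, p, x0 = c(0, 0))
  expect_identical(s1, s2)

  # equipartition: Var(x) = kB T / kappa within 5% on a long run
  kB <- 0.0083144626
  pe <- langevin_params(temperature = 310.15, timestep = 2e-4,
                        n_steps = 1e6, seed = 5)
  s <- langevin_sample(pot, pe, x0 = c(0, 0), save_stride = 10L)
  v_th <- kB * 310.15 / 50
  expect_equal(var(s$x1), v_th, tolerance = 0.05)
  expect_equal(var(s$x2), v_th, tolerance = 0.05)
})

test_that("unbiased sampling preserves Boltzmann statistics on a harmonic well", {
  kB <- 0.0083144626
  kappa <- 50
  pot <- make_gaussian_wells(0, depths = 1e-300, widths = 1, conf_k = kappa,
                             conf_center = 0, locate_saddles = FALSE)
  p <- langevin_params(temperature = 310.15, timestep = 2e-4, n_steps = 2.5e7,
                       seed = 9)
  # relaxation time friction/kappa = 0.02 ps; sampling every 0.05 ps gives
  # ~1e5 near-decorrelated samples
  s <- langevin_sample(pot, p, x0 = 0, save_stride = 250L)
  sigma <- sqrt(kB * 310.15 / kappa)
  ks <- suppressWarnings(stats::ks.test(s$x1, "pnorm", 0, sigma))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("external bias shifts the sampled stationary distribution", {
  kB <- 0.0083144626
  kappa <- 40
  pot <- make_gaussian_wells(0, depths = 1e-300, widths = 1, conf_k = kappa,
                             conf_center = 0, locate_saddles = FALSE)
  # linear bias V = c*x tilts the harmonic mean to -c/kappa
  cc <- 4
  bias <- function(x) list(energy = cc * x[1], gradient = cc)
  p <- langevin_params(temperature = 310.15, timestep = 2e-4, n_steps = 3e5,
                       seed = 21)
  s <- langevin_sample(pot, p, bias = bias, x0 = 0, save_stride = 20L)
  expect_lt(abs(mean(s$x1) - (-cc / kappa)), 0.025)
})

test_that("helix-pair generator honours the angle schedule and roster", {
  traj <- generate_helix_pair_trajectory(rep(45, 3), noise_sd = 0, seed = 1)
  ang <- interhelical_angle(traj)
  expect_true(all(abs(ang - 45) < 0.5))

  a <- traj$atoms
  for (r in c(202:204, 218, 250, 282:284))
    expect_true(any(a$residue_id == r & a$atom_name == "CA"))
  expect_setequal(unique(a$atom_name), c("N", "CA", "C", "O"))
  expect_identical(sort(unique(a$residue_id)), 202:284)

  t2 <- generate_helix_pair_trajectory(rep(45, 3), noise_sd = 0, seed = 1)
  expect_identical(traj, t2)
  t3 <- generate_helix_pair_trajectory(c(120, 60), noise_sd = 0.02, seed = 2)
  t4 <- generate_helix_pair_trajectory(c(120, 60), noise_sd = 0.02, seed = 2)
  expect_identical(t3, t4)

  expect_error(generate_helix_pair_trajectory(numeric(0)), "empty")
  expect_error(generate_helix_pair_trajectory(c(30, 200)), "0, 180")
  expect_error(generate_helix_pair_trajectory(45, noise_sd = -1), ">= 0")
})

test_that("angle schedule moves the CVs monotonically", {
  traj <- generate_helix_pair_trajectory(c(150, 120, 90, 60, 30),
                                         noise_sd = 0, seed = 1)
  cv <- compute_cvs(traj)
  expect_true(all(diff(cv$d1) < 0) || all(diff(cv$d1) > 0))
})

test_that("trajectory round-trips through PDB within coordinate precision", {
  traj <- generate_helix_pair_trajectory(c(90, 45), noise_sd = 0.02, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, f)
  back <- read_pdb(f)
  expect_identical(back$atoms$residue_id, traj$atoms$residue_id)
  expect_identical(back$atoms$atom_name, traj$atoms$atom_name)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3)  # nm; PDB precision

  fx <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, fx)
  bx <- read_xyz(fx, atoms = traj$atoms)
  expect_lt(max(abs(bx$coords - traj$coords)), 1e-8)
  expect_equal(bx$times, traj$times, tolerance = 1e-6)
})
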