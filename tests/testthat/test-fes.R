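test_that("hills reader enforces the dialect contract", {
  f <- withr::local_tempfile()
  # header-only file: empty series, no error
  writeLines("#! FIELDS time d1 d2 sigma_d1 sigma_d2 height biasf", f)
  h0 <- read_hills(f)
  expect_identical(nrow(h0), 0L)
  expect_identical(attr(h0, "cv_names"), c("d1", "d2"))

  writeLines(c("#! FIELDS time d1 sigma_d1 biasf", "1 0.5 0.2 8"), f)
  expect_error(read_hills(f), "height")

  writeLines(c("#! FIELDS time d1 sigma_d1 height biasf",
               "1 0.5 0.2 1.2 8", "2 oops 0.2 1.2 8"), f)
  expect_error(read_hills(f), "line 3")

  writeLines(c("1 0.5 0.2 1.2 8"), f)
  expect_error(read_hills(f), "FIELDS")
})

test_that("bias-sum surface matches closed forms and the brute-force oracle", {
  # empty hills on an explicit grid: all-zero surface
  empty <- hills_series(numeric(0), matrix(numeric(0), ncol = 2), 0.2,
                        numeric(0), 8)
  grid <- list(d1 = seq(0, 2, length.out = 41), d2 = seq(0, 2, length.out = 41))
  f0 <- bias_sum_fes(empty, grid = grid)
  expect_true(all(f0$values == 0))

  # single hill with WT correction: far plateau sits gamma/(gamma-1)*W0
  # above the minimum at the hill centre
  h1 <- hills_series(1, matrix(c(1, 1), 1), 0.2, 1.2, biasf = 8)
  wide <- list(d1 = seq(-3, 5, length.out = 201),
               d2 = seq(-3, 5, length.out = 201))
  f1 <- bias_sum_fes(h1, grid = wide)
  expect_equal(f1$values[1, 1], (8 / 7) * 1.2, tolerance = 1e-6)
  expect_equal(min(f1$values), 0)
  icent <- c(which.min(abs(wide$d1 - 1)), which.min(abs(wide$d2 - 1)))
  expect_equal(f1$values[icent[1], icent[2]], 0, tolerance = 1e-12)

  # grid summation equals the naive per-node double loop
  set.seed(23)
  hs <- hills_series(1:50, matrix(runif(100, 0.5, 1.5), ncol = 2),
                     c(0.2, 0.3), runif(50, 0.2, 1.2), biasf = 8)
  g <- list(d1 = seq(0, 2, length.out = 21), d2 = seq(0, 2, length.out = 17))
  fes <- bias_sum_fes(hs, grid = g, wt_correction = FALSE)
  pts <- as.matrix(expand.grid(g$d1, g$d2))
  V <- brute_bias(pts, as.data.frame(hs), c("d1", "d2"))
  expected <- matrix(-V, nrow = 21)
  expected <- expected - min(expected)
  expect_equal(fes$values, expected, tolerance = 1e-10)

  # missing bias factor blocks the WT correction
  hna <- hills_series(1, matrix(c(1, 1), 1), 0.2, 1.2, biasf = NA)
  expect_error(bias_sum_fes(hna, grid = grid), "bias factor")
})

test_that("basin detection labels minima by ascending free energy", {
  # single-well surface: one basin at the known node, free energy 0
  pot1 <- make_gaussian_wells(c(1, 1), depths = 10, widths = 0.3,
                              locate_saddles = FALSE)
  f1 <- potential_to_fes(pot1, npoints = 101)
  m1 <- find_minima(f1)
  expect_identical(nrow(m1), 1L)
  expect_identical(m1$label, "A")
  expect_equal(m1$free_energy, 0)
  expect_equal(c(m1$d1, m1$d2), c(1, 1), tolerance = 0.02)

  # two wells at constructed coordinates: exactly two basins, A the deeper
  pot2 <- make_double_well(rbind(c(0.45, 1.61), c(1.09, 1.97)),
                           depths = c(20, 12), widths = 0.15)
  f2 <- potential_to_fes(pot2, npoints = 201)
  m2 <- find_minima(f2)
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$label, c("A", "B"))
  expect_equal(m2$free_energy[1], 0)
  expect_equal(c(m2$d1[1], m2$d2[1]), c(0.45, 1.61), tolerance = 0.02)
  expect_equal(c(m2$d1[2], m2$d2[2]), c(1.09, 1.97), tolerance = 0.02)
  expect_equal(m2$free_energy[2], 8, tolerance = 0.02)

  # shallow minima below the prominence threshold are discarded
  m2b <- find_minima(f2, min_depth = 1e4)
  expect_identical(nrow(m2b), 1L)

  f_bad <- f2
  f_bad$values[1] <- NaN
  expect_error(find_minima(f_bad), "non-finite")
})

test_that("1D thermal marginal follows the Boltzmann-weighted projection", {
  ax <- seq(0, 2, length.out = 81)
  ay <- seq(0, 3, length.out = 61)

  # constant surface: flat (zero) profile
  fc <- new_fes(matrix(5, 81, 61), list(d1 = ax, d2 = ay))
  mc <- marginalize_1d(fc, 1)
  expect_true(all(abs(mc$values) < 1e-12))

  # separable surface: marginal recovers the kept component after min-shift
  fx <- 4 * (ax - 1)^2
  gy <- 10 * sin(ay)^2
  fsep <- new_fes(outer(fx, gy, `+`), list(d1 = ax, d2 = ay),
                  temperature = 310.15)
  ms <- marginalize_1d(fsep, 1)
  expect_lt(max(abs(ms$values - (fx - min(fx)))), 1e-8)
  # keeping the other axis recovers g
  ms2 <- marginalize_1d(fsep, "d2")
  expect_lt(max(abs(ms2$values - (gy - min(gy)))), 1e-8)

  # random surface vs the direct-summation oracle
  set.seed(31)
  vals <- matrix(runif(81 * 61, 0, 40), 81, 61)
  fr <- new_fes(vals, list(d1 = ax, d2 = ay), temperature = 310.15)
  mr <- marginalize_1d(fr, 1)
  expect_equal(mr$values, brute_marginal(vals, ax, ay, 310.15, keep = 1),
               tolerance = 1e-8)

  expect_error(marginalize_1d(mr), "dimensionality")
})

test_that("block convergence splits hills into cumulative prefixes", {
  pot <- two_well_fixture()
  run <- run_wtmetad(pot, wtmetad_params(seed = 13),
                     langevin_params(timestep = 5e-4, n_steps = 1e5, seed = 13))
  h <- run$hills

  b1 <- block_convergence(h, n_blocks = 1)
  expect_identical(length(b1$fes), 1L)
  expect_identical(length(b1$rms_diff), 0L)
  full <- bias_sum_fes(h)
  expect_equal(b1$fes[[1]]$values, full$values)

  b4 <- block_convergence(h, n_blocks = 4)
  expect_identical(b4$n_hills, floor(nrow(h) * (1:4) / 4))
  # prefix property: block b equals the bias-sum of its prefix on that grid
  pref <- bias_sum_fes(h[seq_len(b4$n_hills[2]), ], grid = b4$fes[[4]]$axes)
  expect_equal(b4$fes[[2]]$values, pref$values, tolerance = 1e-12)

  expect_error(block_convergence(h, n_blocks = nrow(h) + 1), "invalid blocks")
  expect_error(block_convergence(h, 0), "invalid blocks")
})

test_that("cumulative bias grows pointwise monotonically in time", {
  pot <- two_well_fixture()
  run <- run_wtmetad(pot, wtmetad_params(seed = 29),
                     langevin_params(timestep = 5e-4, n_steps = 5e4, seed = 29))
  h <- run$hills
  pts <- as.matrix(expand.grid(seq(0.4, 2.2, length.out = 7),
                               seq(0.6, 1.4, length.out = 5)))
  prev <- rep(0, nrow(pts))
  for (b in round(nrow(h) * c(0.25, 0.5, 0.75, 1))) {
    v <- bias_potential(pts, h[seq_len(b), ])
    expect_true(all(v >= prev - 1e-12))
    prev <- v
  }
})

test_that("converged toy run shows decreasing successive block differences", {
  pot <- two_well_fixture()
  run <- run_wtmetad(pot, wtmetad_params(seed = 41),
                     langevin_params(timestep = 5e-4, n_steps = 8e5, seed = 41))
  bc <- block_convergence(run$hills, n_blocks = 4, npoints = 96)
  expect_lt(tail(bc$rms_diff, 1), bc$rms_diff[1])
})

test_that("FES text export round-trips values and metadata", {
  h <- hills_series(1:3, matrix(runif(6, 0.5, 1), ncol = 2), 0.2,
                    c(1.2, 1.1, 1.0), biasf = 8)
  fes <- bias_sum_fes(h, npoints = 11)
  f <- withr::local_tempfile(fileext = ".dat")
  write_fes(fes, f)
  tab <- read.table(f, header = FALSE, skip = 1)
  expect_identical(nrow(tab), 121L)
  expect_equal(sort(tab$V3)[1], 0)
  meta <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_identical(meta$grid$d1$n, 11L)
  expect_true(meta$normalized)
})
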